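#' Read and write the planar contour JSON format
#'
#' A minimal plain-text interchange format for planar contours:
#' `{"organ": str, "slices": [{"z": num, "polygons": [[[x, y], ...], ...]}]}`
#' with coordinates in mm. Floats round-trip exactly (full precision
#' serialization).
#'
#' @param stack A [contour_stack()].
#' @param path File path (`.json`).
#' @return `write_contour_json()` returns `path` invisibly;
#'   `read_contour_json()` returns a [contour_stack()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".json")
#' cyl <- make_phantom("cylinder", radius = 10, n_slices = 2)
#' write_contour_json(cyl, f)
#' identical_z <- all.equal(read_contour_json(f)$slices[[1]]$z, cyl$slices[[1]]$z)
write_contour_json <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  obj <- list(
    organ = stack$organ,
    slices = lapply(stack$slices, function(s) {
      list(z = s$z, polygons = lapply(s$polygons, function(p) {
        lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
      }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$organ) || is.null(obj$slices)) {
    stop_segqa(sprintf("'%s' is not a contour JSON file", path),
               "segqa_io_error")
  }
  slices <- lapply(obj$slices, function(s) {
    list(z = as.numeric(s$z),
         polygons = lapply(s$polygons, function(p) {
           do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
         }))
  })
  contour_stack(as.character(obj$organ), slices)
}
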