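#' Read a DICOM-RT structure set
#'
#' Minimal reader for RT Structure Set files in explicit-VR little-endian
#' transfer syntax (the standard uncompressed encoding): parses the
#' StructureSetROISequence and ROIContourSequence and returns each ROI's
#' CLOSED_PLANAR contours grouped by axial slice. Other transfer syntaxes
#' and non-planar contour types are rejected.
#'
#' @param path Path to a DICOM-RT file.
#' @return A list of class `dicom_rt` with `patient_id`,
#'   `frame_of_reference`, `roi_names`, and `rois` (named list: per ROI a
#'   list of contours, each an n x 3 matrix of (x, y, z) mm).
#' @seealso [dicom_rt_stack()] to extract one ROI as a [contour_stack()],
#'   [write_dicom_rt()] for the counterpart writer.
#' @export
read_dicom_rt <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
  }
  # file meta group (0002,xxxx) is always explicit VR LE; find its end via
  # the group length element, then check the transfer syntax
  elems <- list()
  ts <- NULL
  if (dcm_u16(raw, pos) == 0x0002) {
    meta_end <- length(raw) + 1L
    repeat {
      if (pos >= meta_end || dcm_u16(raw, pos) != 0x0002) break
      e <- dcm_read_element(raw, pos)
      e$value <- raw[seq_len(e$len) + e$next_pos - 1L]
      if (e$elem == 0x0000) meta_end <- e$next_pos + e$len + dcm_value_u32(e)
      if (e$elem == 0x0010) ts <- dcm_value_string(e)
      pos <- e$next_pos + e$len
    }
    if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
      stop_segqa(sprintf("unsupported transfer syntax '%s' (explicit VR little endian required)", ts),
                 "segqa_io_error")
    }
  }
  ds <- dcm_parse(raw, pos, length(raw) + 1L)
  patient_id <- dcm_find_string(ds, 0x0010, 0x0020, default = NA_character_)
  for_uid <- dcm_find_string(ds, 0x0020, 0x0052, default = NA_character_)
  ssr <- dcm_find(ds, 0x3006, 0x0020)
  rcs <- dcm_find(ds, 0x3006, 0x0039)
  if (is.null(ssr) || is.null(rcs)) {
    stop_segqa(sprintf("'%s' is not an RT structure set (ROI sequences missing)", path),
               "segqa_io_error")
  }
  roi_names <- character(); roi_numbers <- integer(); roi_for <- character()
  for (item in ssr$items) {
    roi_numbers <- c(roi_numbers, as.integer(dcm_find_string(item, 0x3006, 0x0022)))
    roi_names <- c(roi_names, dcm_find_string(item, 0x3006, 0x0026))
    roi_for <- c(roi_for, dcm_find_string(item, 0x3006, 0x0024,
                                          default = NA_character_))
  }
  if (is.na(for_uid) && length(roi_for)) for_uid <- roi_for[1]
  rois <- stats::setNames(vector("list", length(roi_names)), roi_names)
  for (item in rcs$items) {
    num <- as.integer(dcm_find_string(item, 0x3006, 0x0084))
    name <- roi_names[match(num, roi_numbers)]
    cs <- dcm_find(item, 0x3006, 0x0040)
    contours <- list()
    if (!is.null(cs)) {
      for (c_item in cs$items) {
        gtype <- dcm_find_string(c_item, 0x3006, 0x0042)
        if (!identical(gtype, "CLOSED_PLANAR")) {
          stop_segqa(sprintf("unsupported contour geometric type '%s'", gtype),
                     "segqa_io_error")
        }
        dat <- as.numeric(strsplit(dcm_find_string(c_item, 0x3006, 0x0050),
                                   "\\", fixed = TRUE)[[1]])
        contours[[length(contours) + 1L]] <- matrix(dat, ncol = 3, byrow = TRUE)
      }
    }
    rois[[name]] <- contours
  }
  structure(list(patient_id = patient_id, frame_of_reference = for_uid,
                 roi_names = roi_names, rois = rois),
            class = "dicom_rt")
}

#' @export
print.dicom_rt <- function(x, ...) {
  cat(sprintf("<dicom_rt> patient '%s', %d ROI(s): %s\n",
              x$patient_id, length(x$roi_names),
              paste(x$roi_names, collapse = ", ")))
  invisible(x)
}

#' Extract one ROI of a structure set as a contour stack
#'
#' @param x A `dicom_rt` object from [read_dicom_rt()].
#' @param roi_name ROI name to extract.
#' @param z_tol Contours whose z differ by at most this (mm) are placed on
#'   the same slice.
#' @return A [contour_stack()].
#' @export
dicom_rt_stack <- function(x, roi_name, z_tol = 1e-6) {
  stopifnot(inherits(x, "dicom_rt"))
  if (!roi_name %in% x$roi_names) {
    stop_segqa(sprintf("ROI '%s' not found (available: %s)", roi_name,
                       paste(x$roi_names, collapse = ", ")),
               "segqa_lookup_error")
  }
  contours <- x$rois[[roi_name]]
  if (!length(contours)) {
    stop_segqa(sprintf("ROI '%s' holds no contours", roi_name), "segqa_io_error")
  }
  zs <- vapply(contours, function(m) m[1, 3], numeric(1))
  uz <- sort(unique(zs))
  grp <- vapply(zs, function(z) which.min(abs(uz - z)), integer(1))
  merged <- uz[vapply(seq_along(uz), function(i) {
    i == 1 || uz[i] - uz[i - 1] > z_tol
  }, logical(1))]
  grp <- vapply(zs, function(z) which.min(abs(merged - z)), integer(1))
  slices <- lapply(seq_along(merged), function(i) {
    list(z = merged[i],
         polygons = lapply(contours[grp == i], function(m) m[, 1:2, drop = FALSE]))
  })
  contour_stack(roi_name, slices)
}

#' Write a DICOM-RT structure set
#'
#' Counterpart of [read_dicom_rt()]: writes one or more contour stacks as
#' CLOSED_PLANAR ROIs into an explicit-VR little-endian RT Structure Set.
#' Used to build interchange files and test fixtures; readable by standard
#' DICOM toolkits.
#'
#' @param stacks A [contour_stack()] or list of them (ROI names are the
#'   organ labels).
#' @param path Output path.
#' @param patient_id PatientID to store.
#' @param frame_of_reference Frame-of-reference UID shared by all ROIs.
#' @return `path`, invisibly.
#' @export
write_dicom_rt <- function(stacks, path, patient_id = "anon",
                           frame_of_reference = "1.2.826.0.1.3680043.9.7434.1.1") {
  if (inherits(stacks, "contour_stack")) stacks <- list(stacks)
  stopifnot(all(vapply(stacks, inherits, logical(1), "contour_stack")))
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.3"
  sop_inst <- paste0("1.2.826.0.1.3680043.9.7434.2.",
                     format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                            trim = TRUE))
  ssr_items <- lapply(seq_along(stacks), function(i) {
    c(dcm_elem_str(0x3006, 0x0022, "IS", as.character(i)),
      dcm_elem_str(0x3006, 0x0024, "UI", frame_of_reference),
      dcm_elem_str(0x3006, 0x0026, "LO", stacks[[i]]$organ),
      dcm_elem_str(0x3006, 0x0036, "CS", "MANUAL"))
  })
  rcs_items <- lapply(seq_along(stacks), function(i) {
    contour_items <- unlist(lapply(stacks[[i]]$slices, function(s) {
      lapply(s$polygons, function(p) {
        xyz <- cbind(p, s$z)
        dat <- paste(sprintf("%.8g", t(xyz)), collapse = "\\")
        c(dcm_elem_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
          dcm_elem_str(0x3006, 0x0046, "IS", as.character(nrow(p))),
          dcm_elem_str(0x3006, 0x0050, "DS", dat))
      })
    }), recursive = FALSE)
    c(dcm_sequence(0x3006, 0x0040, contour_items),
      dcm_elem_str(0x3006, 0x0084, "IS", as.character(i)))
  })
  dataset <- c(
    dcm_elem_str(0x0008, 0x0016, "UI", sop_class),
    dcm_elem_str(0x0008, 0x0018, "UI", sop_inst),
    dcm_elem_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_elem_str(0x0010, 0x0010, "PN", patient_id),
    dcm_elem_str(0x0010, 0x0020, "LO", patient_id),
    dcm_elem_str(0x0020, 0x0052, "UI", frame_of_reference),
    dcm_elem_str(0x3006, 0x0002, "SH", "segqa"),
    dcm_sequence(0x3006, 0x0020, ssr_items),
    dcm_sequence(0x3006, 0x0039, rcs_items))
  meta_body <- c(
    dcm_elem_raw(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_elem_str(0x0002, 0x0002, "UI", sop_class),
    dcm_elem_str(0x0002, 0x0003, "UI", sop_inst),
    dcm_elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_elem_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7434"))
  meta <- c(dcm_elem_raw(0x0002, 0x0000, "UL", dcm_raw_u32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# ---- low-level DICOM encoding helpers (explicit VR little endian) ----

dcm_raw_u16 <- function(x) {
  as.raw(c(bitwAnd(x, 0xFF), bitwAnd(bitwShiftR(x, 8), 0xFF)))
}

dcm_raw_u32 <- function(x) {
  as.raw(c(bitwAnd(x, 0xFF), bitwAnd(bitwShiftR(x, 8), 0xFF),
           bitwAnd(bitwShiftR(x, 16), 0xFF), bitwAnd(bitwShiftR(x, 24), 0xFF)))
}

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_elem_raw <- function(group, elem, vr, value) {
  if (length(value) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value <- c(value, pad)
  }
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% dcm_long_vrs) {
    c(hdr, raw(2), dcm_raw_u32(length(value)), value)
  } else {
    c(hdr, dcm_raw_u16(length(value)), value)
  }
}

dcm_elem_str <- function(group, elem, vr, value) {
  dcm_elem_raw(group, elem, vr, charToRaw(value))
}

# sequence with undefined length; items with undefined length + delimiters
dcm_sequence <- function(group, elem, items) {
  body <- unlist(lapply(items, function(it) {
    c(dcm_raw_u16(0xFFFE), dcm_raw_u16(0xE000), as.raw(rep(0xFF, 4)),
      it,
      dcm_raw_u16(0xFFFE), dcm_raw_u16(0xE00D), raw(4))
  }))
  c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw("SQ"), raw(2),
    as.raw(rep(0xFF, 4)),
    body,
    dcm_raw_u16(0xFFFE), dcm_raw_u16(0xE0DD), raw(4))
}

# ---- low-level DICOM decoding helpers ----

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_u32 <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

# reads one element header; for SQ/undefined lengths 'len' is NA and items
# must be parsed by the caller
dcm_read_element <- function(raw, pos) {
  group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
  if (group == 0xFFFE) {  # item / delimiter tags carry no VR
    len <- dcm_u32(raw, pos + 4L)
    return(list(group = group, elem = elem, vr = NA_character_,
                len = len, next_pos = pos + 8L))
  }
  vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
  if (vr %in% dcm_long_vrs) {
    len <- dcm_u32(raw, pos + 8L)
    list(group = group, elem = elem, vr = vr, len = len, next_pos = pos + 12L)
  } else {
    len <- dcm_u16(raw, pos + 6L)
    list(group = group, elem = elem, vr = vr, len = len, next_pos = pos + 8L)
  }
}

dcm_undef <- 4294967295

# parse a run of data elements in [pos, end); returns list of
# list(group, elem, vr, value raw | items list)
dcm_parse <- function(raw, pos, end) {
  out <- list()
  while (pos < end) {
    e <- dcm_read_element(raw, pos)
    if (e$group == 0xFFFE && e$elem %in% c(0xE00D, 0xE0DD)) break
    if (identical(e$vr, "SQ")) {
      if (e$len == dcm_undef) {
        items <- dcm_parse_items(raw, e$next_pos, end)
      } else {
        items <- dcm_parse_items(raw, e$next_pos, e$next_pos + e$len)
        items$next_pos <- e$next_pos + e$len
      }
      out[[length(out) + 1L]] <- list(group = e$group, elem = e$elem,
                                      vr = "SQ", items = items$items)
      pos <- items$next_pos
    } else {
      out[[length(out) + 1L]] <- list(group = e$group, elem = e$elem, vr = e$vr,
                                      value = raw[seq_len(e$len) + e$next_pos - 1L])
      pos <- e$next_pos + e$len
    }
  }
  out
}

# parse sequence items until the sequence delimiter (or 'end')
dcm_parse_items <- function(raw, pos, end) {
  items <- list()
  while (pos < end) {
    e <- dcm_read_element(raw, pos)
    if (e$group == 0xFFFE && e$elem == 0xE0DD) { pos <- e$next_pos; break }
    if (!(e$group == 0xFFFE && e$elem == 0xE000)) {
      stop_segqa("malformed DICOM sequence (item tag expected)", "segqa_io_error")
    }
    item_end <- if (e$len == dcm_undef) end else e$next_pos + e$len
    item <- dcm_parse_item(raw, e$next_pos, item_end, e$len == dcm_undef)
    items[[length(items) + 1L]] <- item$elems
    pos <- item$next_pos
  }
  list(items = items, next_pos = pos)
}

dcm_parse_item <- function(raw, pos, end, undefined) {
  elems <- list()
  while (pos < end) {
    e <- dcm_read_element(raw, pos)
    if (e$group == 0xFFFE && e$elem == 0xE00D) { pos <- e$next_pos; break }
    if (identical(e$vr, "SQ")) {
      if (e$len == dcm_undef) {
        sq <- dcm_parse_items(raw, e$next_pos, end)
      } else {
        sq <- dcm_parse_items(raw, e$next_pos, e$next_pos + e$len)
        sq$next_pos <- e$next_pos + e$len
      }
      elems[[length(elems) + 1L]] <- list(group = e$group, elem = e$elem,
                                          vr = "SQ", items = sq$items)
      pos <- sq$next_pos
    } else {
      elems[[length(elems) + 1L]] <- list(group = e$group, elem = e$elem,
                                          vr = e$vr,
                                          value = raw[seq_len(e$len) + e$next_pos - 1L])
      pos <- e$next_pos + e$len
    }
  }
  list(elems = elems, next_pos = pos)
}

dcm_find <- function(elems, group, elem) {
  for (e in elems) {
    if (e$group == group && e$elem == elem) return(e)
  }
  NULL
}

dcm_value_string <- function(e) {
  v <- e$value
  while (length(v) && v[length(v)] == as.raw(0)) v <- v[-length(v)]
  sub(" +$", "", rawToChar(v))
}

dcm_value_u32 <- function(e) dcm_u32(e$value, 1L)

dcm_find_string <- function(elems, group, elem, default = NULL) {
  e <- dcm_find(elems, group, elem)
  if (is.null(e)) {
    if (is.null(default)) {
      stop_segqa(sprintf("required DICOM tag (%04X,%04X) missing", group, elem),
                 "segqa_io_error")
    }
    return(default)
  }
  dcm_value_string(e)
}
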