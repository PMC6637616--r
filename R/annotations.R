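#' Annotation records for the semi-automated ground-truth workflow
#'
#' Annotations are plain data frames with one row per image and the fixed
#' schema `image_id, x_min, y_min, x_max, y_max, cx, cy, r, status,
#' confidence, note`.  Boxes are 0-based half-open; the circle columns may
#' be `NA` when only a box is known.  `status` tracks provenance through the
#' machine-proposal / human-correction workflow: `"proposed"` (machine
#' output), `"corrected"` (a human replaced the box), `"verified"` (a human
#' accepted it).  `confidence` is `"normal"` or `"low"` (fallback path of
#' the localizer).
#'
#' @param imageId identifier (must be unique within a store).
#' @param box a [BoundingBox-class].
#' @param circle optional [CircleProposal-class].
#' @param status,confidence,note provenance fields, see above.
#' @return A one-row annotation data frame.
#' @export
annotationRecord <- function(imageId, box, circle = NULL,
                             status = c("proposed", "corrected", "verified"),
                             confidence = c("normal", "low"), note = "") {
  status <- match.arg(status)
  confidence <- match.arg(confidence)
  data.frame(image_id = as.character(imageId),
             x_min = box@xMin, y_min = box@yMin,
             x_max = box@xMax, y_max = box@yMax,
             cx = if (is.null(circle)) NA_real_ else circle@cx,
             cy = if (is.null(circle)) NA_real_ else circle@cy,
             r = if (is.null(circle)) NA_real_ else circle@r,
             status = status, confidence = confidence, note = note,
             stringsAsFactors = FALSE)
}

annotationColumns <- c("image_id", "x_min", "y_min", "x_max", "y_max",
                       "cx", "cy", "r", "status", "confidence", "note")

#' @describeIn annotationRecord Bind localizer results into an annotation
#'   store.
#' @param locs a list of `ODLocalization` results from [localizeDisc()].
#' @export
annotationsFromLocalizations <- function(locs) {
  do.call(rbind, lapply(locs, function(l) {
    annotationRecord(l$imageId, l$box, l$circle, status = l$status,
                     confidence = l$confidence)
  }))
}

validateAnnotations <- function(records, where = "annotations") {
  missing <- setdiff(annotationColumns, names(records))
  if (length(missing)) {
    stop(where, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    line <- sprintf("%s row %d (line %d)", where, i, i + 1L)
    if (is.na(r$image_id) || !nzchar(r$image_id)) {
      stop(line, ": empty image_id")
    }
    if (anyNA(c(r$x_min, r$y_min, r$x_max, r$y_max))) {
      stop(line, ": box coordinates must not be NA")
    }
    if (r$x_min >= r$x_max) stop(line, ": x_min must be < x_max")
    if (r$y_min >= r$y_max) stop(line, ": y_min must be < y_max")
    if (!r$status %in% c("proposed", "corrected", "verified")) {
      stop(line, ": invalid status '", r$status, "'")
    }
    if (!r$confidence %in% c("normal", "low")) {
      stop(line, ": invalid confidence '", r$confidence, "'")
    }
  }
  dup <- records$image_id[duplicated(records$image_id)]
  if (length(dup)) {
    stop(where, ": duplicate image_id ", paste(unique(dup), collapse = ", "))
  }
  invisible(records)
}

#' Save / load annotation stores as CSV
#'
#' UTF-8, comma-separated, header mandatory; the round trip
#' `loadAnnotations(saveAnnotations(x))` is lossless and unknown extra
#' columns are preserved.  Malformed rows fail with the offending line
#' number; duplicate `image_id`s are rejected.
#'
#' @param records annotation data frame (see [annotationRecord()]).
#' @param path CSV file path.
#' @return `loadAnnotations` returns the validated data frame;
#'   `saveAnnotations` the path, invisibly.
#' @export
saveAnnotations <- function(records, path) {
  validateAnnotations(records)
  extra <- setdiff(names(records), annotationColumns)
  utf8 <- records[, c(annotationColumns, extra), drop = FALSE]
  utils::write.csv(utf8, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname saveAnnotations
#' @export
loadAnnotations <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8",
                             colClasses = c(image_id = "character"))
  if (nrow(records)) {
    if (!"note" %in% names(records)) records$note <- ""
    records$note[is.na(records$note)] <- ""
  }
  validateAnnotations(records, where = basename(path))
  records
}

#' Merge human corrections into machine proposals
#'
#' Implements the correction step of the semi-automated workflow.  Every
#' correction row must name an existing proposal.  A correction row with
#' `status = "verified"` accepts the proposal unchanged (provenance only);
#' any other correction row replaces the proposal's box (and circle, if
#' given) and marks it `"corrected"` — even when the corrected box equals
#' the proposed one, since the status records that a human looked at it.
#' All untouched proposals pass through unchanged, so the output has
#' exactly as many rows as `proposals`.  The operation is idempotent.
#'
#' @param proposals,corrections annotation data frames.
#' @return The merged annotation data frame.
#' @export
mergeCorrections <- function(proposals, corrections) {
  validateAnnotations(proposals, "proposals")
  if (is.null(corrections) || nrow(corrections) == 0L) return(proposals)
  validateAnnotations(corrections, "corrections")
  unknown <- setdiff(corrections$image_id, proposals$image_id)
  if (length(unknown)) {
    stop("correction(s) for unknown image_id: ",
         paste(unknown, collapse = ", "))
  }
  out <- proposals
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    j <- match(cr$image_id, out$image_id)
    if (identical(cr$status, "verified")) {
      out$status[j] <- "verified"
    } else {
      out[j, c("x_min", "y_min", "x_max", "y_max")] <-
        cr[, c("x_min", "y_min", "x_max", "y_max")]
      out[j, c("cx", "cy", "r")] <- cr[, c("cx", "cy", "r")]
      out$status[j] <- "corrected"
    }
    if (nzchar(cr$note)) out$note[j] <- cr$note
  }
  out
}

#' Export / import annotations as Pascal-VOC XML
#'
#' One XML file per image with a single `optic_disc` object, in the
#' dialect's 1-based inclusive pixel convention.  Conversion from the
#' internal 0-based half-open boxes is `xmin + 1, ymin + 1` with `xmax`,
#' `ymax` unchanged; `importVocXml` inverts it exactly.
#'
#' @param records annotation data frame; unless `allowProposed`, every
#'   record must be `verified` or `corrected` (detector training wants
#'   human-checked boxes only).
#' @param outDir output directory for the XML files.
#' @param imageDir value written to the `<folder>` element.
#' @param sizes optional data frame `image_id, height, width` written into
#'   `<size>`; unknown sizes are written as 0.
#' @param allowProposed allow exporting unverified (`proposed`) records.
#' @return `exportVocXml`: the paths written, invisibly.
#' @export
exportVocXml <- function(records, outDir, imageDir = "images", sizes = NULL,
                         allowProposed = FALSE) {
  validateAnnotations(records)
  if (!allowProposed && any(records$status == "proposed")) {
    stop("unverified (proposed) records present; ",
         "correct or verify them first, or set allowProposed = TRUE")
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    h <- w <- 0L
    if (!is.null(sizes)) {
      j <- match(r$image_id, sizes$image_id)
      if (!is.na(j)) { h <- sizes$height[j]; w <- sizes$width[j] }
    }
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "folder", imageDir)
    xml2::xml_add_child(doc, "filename", paste0(r$image_id, ".png"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", as.character(w))
    xml2::xml_add_child(size, "height", as.character(h))
    xml2::xml_add_child(size, "depth", "3")
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", "optic_disc")
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(r$x_min + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(r$y_min + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(r$x_max))
    xml2::xml_add_child(bb, "ymax", as.character(r$y_max))
    paths[i] <- file.path(outDir, paste0(r$image_id, ".xml"))
    xml2::write_xml(doc, paths[i])
  }
  invisible(paths)
}

#' @rdname exportVocXml
#' @param paths XML files (or a directory of them) to import.
#' @return `importVocXml`: an annotation data frame with status
#'   `"verified"`.
#' @export
importVocXml <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.xml$", full.names = TRUE)
  }
  rows <- lapply(paths, function(p) {
    doc <- xml2::read_xml(p)
    id <- sub("\\.[^.]+$", "",
              xml2::xml_text(xml2::xml_find_first(doc, "./filename")))
    num <- function(xp) as.integer(
      xml2::xml_text(xml2::xml_find_first(doc, xp)))
    annotationRecord(id,
                     boundingBox(num("./object/bndbox/xmin") - 1L,
                                 num("./object/bndbox/ymin") - 1L,
                                 num("./object/bndbox/xmax"),
                                 num("./object/bndbox/ymax")),
                     status = "verified")
  })
  do.call(rbind, rows)
}
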