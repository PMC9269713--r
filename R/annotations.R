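#' Read lesion annotations
#'
#' Parses lesion annotations in one of two dialects:
#'
#' * `"minimias_info"`: whitespace-delimited lines
#'   `id tissue abnormality severity x y radius`, e.g.
#'   `mdb001 G CIRC B 535 425 197`. Lines without coordinates describe normal
#'   tissue. The coordinate origin is the bottom-left corner of the image (the
#'   digitized-film convention); it is converted to top-left raster coordinates
#'   when ROIs are extracted, once the image height is known.
#' * `"bbox_csv"`: CSV with header `image_id,class,x0,y0,x1,y1`, top-left
#'   origin, one bounding box per line.
#'
#' @param path Annotation file.
#' @param dialect `"minimias_info"` or `"bbox_csv"`.
#' @return A data frame of class `lesion_annotations` with columns `image_id`,
#'   `lesion_class` (factor: normal/benign/malignant), `geometry`
#'   (`"circle"`, `"box"` or `"none"`), circle fields `cx`, `cy`, `radius`,
#'   box fields `x0`, `y0`, `x1`, `y1`, and `origin` (`"top_left"` or
#'   `"bottom_left"`).
#' @export
read_annotations <- function(path, dialect = c("minimias_info", "bbox_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "minimias_info") {
    ann <- parse_minimias(lines)
  } else {
    ann <- parse_bbox_csv(lines)
  }
  class(ann) <- c("lesion_annotations", "data.frame")
  ann
}

empty_annotations <- function(origin) {
  data.frame(image_id = character(0), lesion_class = factor(character(0), levels = lesion_levels()),
             geometry = character(0), cx = numeric(0), cy = numeric(0), radius = numeric(0),
             x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
             origin = character(0), stringsAsFactors = FALSE)
}

lesion_levels <- function() c("normal", "benign", "malignant")

parse_minimias <- function(lines) {
  out <- empty_annotations("bottom_left")
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) == 3L && f[[3]] == "NORM") {
      out[nrow(out) + 1L, c("image_id", "geometry", "origin")] <-
        list(f[[1]], "none", "bottom_left")
      out$lesion_class[nrow(out)] <- "normal"
      next
    }
    if (length(f) != 7L)
      stopf("line %d: expected 7 fields (or 3 for NORM), got %d", i, length(f))
    cls <- switch(f[[4]], B = "benign", M = "malignant",
                  stopf("line %d: unknown severity code '%s'", i, f[[4]]))
    xyr <- suppressWarnings(as.numeric(f[5:7]))
    if (anyNA(xyr)) stopf("line %d: non-numeric circle coordinates", i)
    if (xyr[[3]] <= 0) stopf("line %d: radius must be positive", i)
    out[nrow(out) + 1L, c("image_id", "geometry", "origin")] <-
      list(f[[1]], "circle", "bottom_left")
    out[nrow(out), c("cx", "cy", "radius")] <- as.list(xyr)
    out$lesion_class[nrow(out)] <- cls
  }
  out
}

parse_bbox_csv <- function(lines) {
  header <- tolower(gsub("\\s", "", lines[[1]]))
  if (header != "image_id,class,x0,y0,x1,y1")
    stopf("bbox_csv header must be 'image_id,class,x0,y0,x1,y1'")
  out <- empty_annotations("top_left")
  body <- lines[-1L]
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[[i]]), ",")[[1]]
    if (length(f) != 6L) stopf("line %d: expected 6 comma-separated fields", i + 1L)
    cls <- tolower(trimws(f[[2]]))
    if (!cls %in% lesion_levels()) stopf("line %d: unknown class '%s'", i + 1L, f[[2]])
    box <- suppressWarnings(as.numeric(f[3:6]))
    if (anyNA(box)) stopf("line %d: non-numeric box coordinates", i + 1L)
    if (box[[1]] >= box[[3]] || box[[2]] >= box[[4]])
      stopf("line %d: box requires x0 < x1 and y0 < y1", i + 1L)
    out[nrow(out) + 1L, c("image_id", "geometry", "origin")] <-
      list(trimws(f[[1]]), "box", "top_left")
    out[nrow(out), c("x0", "y0", "x1", "y1")] <- as.list(box)
    out$lesion_class[nrow(out)] <- cls
  }
  out
}
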