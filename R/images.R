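#' Read a grayscale mammogram image
#'
#' Reads an 8-bit grayscale image from PGM (binary `P5` or ASCII `P2`) or PNG.
#' Intensities are returned as a numeric matrix in `[0, 1]`, row 1 being the
#' top raster row.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return Numeric matrix (height x width) with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray stored as RGB(A)
    return(img)
  }
  stopf("unsupported image format '%s' (expected pgm or png)", ext)
}

# PGM parser (P2/P5, maxval <= 255). No installed package reads PNM, so this
# small reader is provided here.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  buf <- character(0)
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stopf("truncated PGM header in %s", path)
      if (grepl("^\\s$", ch)) {
        if (length(buf) > 0L) break
      } else if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else buf <<- c(buf, ch)
    }
    tok <- paste(buf, collapse = "")
    buf <<- character(0)
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file (magic '%s'): %s", magic, path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L) stopf("malformed PGM header in %s", path)
  if (maxval > 255L) stopf("only 8-bit PGM supported (maxval %d): %s", maxval, path)
  n <- w * h
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(raw) < n) stopf("truncated PGM pixel data in %s", path)
  # PGM is row-major from the top-left; R matrices fill column-major
  matrix(raw / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale or pseudo-color image as PNG
#'
#' Intensities in `[0, 1]` are quantized to 8 bits with round-half-up.
#'
#' @param img Matrix (grayscale) or H x W x 3 array (pseudo-color).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_intensity(img)
  q <- floor(clip01(img) * 255 + 0.5) / 255
  png::writePNG(q, target = path)
  invisible(path)
}
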