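# Shared fixtures, all generated in code.

# linear intensity ramp, values spanning [0, 1]
ramp_image <- function(n = 100) matrix(seq(0, 1, length.out = n * n), n, n)

# low-contrast centered blob on a mid-gray background
blob_roi <- function(side = 32, contrast = 0.1) {
  cx <- (side + 1) / 2
  d2 <- outer((seq_len(side) - cx)^2, (seq_len(side) - cx)^2, "+")
  0.45 + contrast * exp(-d2 / (2 * (side / 6)^2))
}

# checkerboard of two mid-gray levels
checker_image <- function(side = 32, lo = 0.45, hi = 0.55) {
  m <- outer(seq_len(side), seq_len(side), function(i, j) (i + j) %% 2)
  lo + (hi - lo) * m
}

# four-point dataset whose sample covariance is exactly diag(v1, v2)
diag_cov_data <- function(v1, v2) {
  a <- sqrt(3 * v1 / 2); b <- sqrt(3 * v2 / 2)
  rbind(c(a, 0), c(-a, 0), c(0, b), c(0, -b))
}

# brute-force overlap oracle for axis-aligned side x side squares
squares_overlap <- function(o1, o2, side) {
  abs(o1[[1]] - o2[[1]]) < side && abs(o1[[2]] - o2[[2]]) < side
}

write_minimias_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# largest principal angle (degrees) between span(Q) and span(dirs)
max_principal_angle <- function(Q, dirs) {
  if (is.null(dim(Q)) || ncol(Q) < ncol(dirs)) return(Inf)
  max(acos(pmin(1, svd(crossprod(Q, qr.Q(qr(dirs))))$d)) * 180 / pi)
}

table1_fixture <- function() {
  read.table(system.file("extdata", "pc_wald_table.tsv", package = "mammocad"),
             header = TRUE, stringsAsFactors = FALSE)
}
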