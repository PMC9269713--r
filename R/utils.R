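# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All user-facing randomness in the package flows through this so that a given
# seed argument fully determines the result without touching global state.
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Intensity grids live in [0,1] internally; clip guards against floating drift
# introduced by filtering/resampling.
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

check_intensity <- function(x, what = "image") {
  if (!is.numeric(x) || anyNA(x)) stopf("%s must be a numeric grid without NA", what)
  invisible(x)
}

# Largest-remainder apportionment of n into parts proportional to w.
apportion <- function(n, w) {
  ideal <- n * w / sum(w)
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}
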