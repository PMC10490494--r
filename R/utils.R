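# Internal helpers shared across modules.

# Run code under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reflect an out-of-range 1-based index into [1, len] without repeating
# the edge sample (period 2*(len - 1)); identity inside the range.
reflectIndex <- function(i, len) {
  if (len == 1L) return(rep(1L, length(i)))
  p <- 2L * (len - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j >= len, p - j, j)
  as.integer(j + 1L)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Rec. 601 luma; used by the dark-cluster = nuclei heuristic.
luminance <- function(rgb) {
  sum(c(0.299, 0.587, 0.114) * rgb)
}

asBinaryMatrix <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1)))
    stop(sprintf("%s must be binary (values 0/1)", what), call. = FALSE)
  matrix(as.integer(m), nrow(m), ncol(m))
}
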