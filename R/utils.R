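# Shared internal helpers: seeded evaluation, padding, small convolutions.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Replicate-pad a matrix by k rows/cols on every side.
pad_replicate <- function(x, k) {
  r <- nrow(x); c <- ncol(x)
  ri <- c(rep(1L, k), seq_len(r), rep(r, k))
  ci <- c(rep(1L, k), seq_len(c), rep(c, k))
  x[ri, ci, drop = FALSE]
}

# Reflect-pad (symmetric, edge pixel not repeated) by k on every side.
# Requires k < dim.
pad_reflect <- function(x, k) {
  r <- nrow(x); c <- ncol(x)
  stopifnot(k < r, k < c)
  ri <- c(seq(k + 1L, 2L), seq_len(r), seq(r - 1L, r - k))
  if (k == 0L) ri <- seq_len(r)
  ci <- c(seq(k + 1L, 2L), seq_len(c), seq(c - 1L, c - k))
  if (k == 0L) ci <- seq_len(c)
  x[ri, ci, drop = FALSE]
}

# 2D cross-correlation of `x` with kernel `k` (odd dims), reflected boundary.
# out[p] = sum_o k[o] * x[p + o], offsets centred on the kernel middle.
xcorr2_reflect <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  h <- max(hr, hc)
  xp <- pad_reflect(x, h)
  r <- nrow(x); c <- ncol(x)
  out <- matrix(0, r, c)
  for (i in seq_len(kr)) {
    di <- i - 1L - hr
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      dj <- j - 1L - hc
      out <- out + k[i, j] *
        xp[(h + 1L + di):(h + r + di), (h + 1L + dj):(h + c + dj)]
    }
  }
  out
}

# 1D Gaussian kernel, sd `sigma`, truncated at 4 sigma, normalised to sum 1.
gaussian_kernel1d <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  u <- (-h):h
  k <- exp(-u^2 / (2 * sigma^2))
  k / sum(k)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric matrix", name), call. = FALSE)
}
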