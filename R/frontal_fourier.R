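# Frontal sagittal arc quantification: degree-6 polynomial fit through the
# ordered landmarks (least squares + Levenberg-Marquardt refinement), XY
# projection, 32-segment sampling, and normalised Fourier amplitudes.

#' Validate an ordered 3D landmark curve
#'
#' @param points numeric matrix `n x 3` (columns x, y, z), `n >= 8`, with
#'   strictly increasing x and finite coordinates.
#' @return The validated matrix, invisibly classed `landmark_curve`.
#' @export
landmark_curve <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("landmarks must have 3 columns", call. = FALSE)
  if (nrow(points) < 8L) stop("need at least 8 landmarks", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (any(diff(points[, 1L]) <= 0))
    stop("landmark x coordinates must be strictly increasing", call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  class(points) <- c("landmark_curve", class(points))
  points
}

#' Project a 3D landmark curve to the XY plane
#'
#' Drops the z coordinate, preserving order.
#'
#' @param curve3d `n x 3` matrix (x, y, z).
#' @return `n x 2` matrix (x, y).
#' @export
project_xy <- function(curve3d) {
  curve3d <- as.matrix(curve3d)
  stopifnot(ncol(curve3d) == 3L)
  out <- curve3d[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Compose polynomial sum(c_j t^j) with t = alpha*x + beta; returns raw-x
# coefficients (degree-ascending) via iterated polynomial multiplication.
.compose_affine <- function(coef_t, alpha, beta) {
  deg <- length(coef_t) - 1L
  out <- numeric(deg + 1L)
  pw <- 1                                  # (alpha*x + beta)^0
  for (j in 0:deg) {
    out[seq_along(pw)] <- out[seq_along(pw)] + coef_t[j + 1L] * pw
    if (j < deg) {
      # multiply pw by (beta + alpha*x)
      pw <- c(pw * beta, 0) + c(0, pw * alpha)
    }
  }
  out
}

.polyval <- function(coef, x) {
  # Horner, coefficients degree-ascending
  y <- numeric(length(x))
  for (j in rev(seq_along(coef))) y <- y * x + coef[j]
  y
}

#' Fit a polynomial through the projected landmark curve
#'
#' Projects the landmarks to XY, maps x to the normalised domain \[-1, 1\]
#' for conditioning, fits y by linear least squares in the monomial basis,
#' then refines the same residual with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]); the refined residual sum of squares never
#' exceeds the plain least-squares one. Coefficients are reported in the raw
#' x basis (`coefficients`) and the normalised basis
#' (`coefficients_normalized`); when the landmark x range is already
#' \[-1, 1\] the two coincide.
#'
#' @param landmarks `n x 3` landmark matrix (see [landmark_curve()]).
#' @param degree polynomial degree; default 6.
#' @return List of class `polynomial_curve` with `coefficients` (length
#'   degree+1, ascending powers of raw x), `coefficients_normalized`,
#'   `domain` (landmark x range) and `rss`.
#' @export
fit_polynomial <- function(landmarks, degree = 6L) {
  landmarks <- landmark_curve(landmarks)
  degree <- as.integer(degree)
  if (nrow(landmarks) < degree + 1L)
    stop(sprintf("need at least %d landmarks for degree %d", degree + 1L,
                 degree), call. = FALSE)
  xy <- project_xy(landmarks)
  x <- xy[, 1L]; y <- xy[, 2L]
  dom <- range(x)
  alpha <- 2 / diff(dom)
  beta <- -(dom[1L] + dom[2L]) / diff(dom)
  t <- alpha * x + beta
  X <- outer(t, 0:degree, `^`)
  fit <- lm.fit(X, y)
  if (fit$rank < degree + 1L)
    stop("rank-deficient design: landmarks do not determine the fit",
         call. = FALSE)
  ls_coef <- fit$coefficients
  rss_ls <- sum(fit$residuals^2)
  lm_fit <- minpack.lm::nls.lm(par = ls_coef,
                               fn = function(cf) y - drop(X %*% cf))
  coef_t <- lm_fit$par
  rss <- sum(lm_fit$fvec^2)
  if (rss > rss_ls) {            # LM may not improve an already-linear fit
    coef_t <- ls_coef
    rss <- rss_ls
  }
  structure(list(coefficients = .compose_affine(coef_t, alpha, beta),
                 coefficients_normalized = unname(coef_t),
                 domain = dom, rss = rss, degree = degree),
            class = "polynomial_curve")
}

#' Sample a fitted curve over equal segments
#'
#' Divides the curve domain \eqn{[x_{min}, x_{max}]} into `n` segments and
#' evaluates the polynomial at the half-open uniform grid
#' \eqn{x_m = x_{min} + m (x_{max} - x_{min})/n}, m = 0, ..., n-1 — the index
#' set of the discrete Fourier sums.
#'
#' @param curve a [fit_polynomial()] result.
#' @param n number of segments; default 32.
#' @return Numeric vector of `n` sampled y values.
#' @export
sample_curve <- function(curve, n = 32L) {
  stopifnot(inherits(curve, "polynomial_curve"))
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  dom <- curve$domain
  if (diff(dom) <= 0) stop("degenerate curve domain", call. = FALSE)
  x <- dom[1L] + (0:(n - 1L)) * diff(dom) / n
  t <- (2 * x - sum(dom)) / diff(dom)
  .polyval(curve$coefficients_normalized, t)
}

#' Fourier descriptors of a 32-sample curve
#'
#' Discrete Fourier decomposition of the sampled arc:
#' \deqn{A_0 = \tfrac{1}{32} \sum_m Y_m,\quad
#'       A_k = \tfrac{1}{16} \sum_m Y_m \cos\tfrac{2\pi k m}{32},\quad
#'       B_k = \tfrac{1}{16} \sum_m Y_m \sin\tfrac{2\pi k m}{32},}
#' for k = 1, ..., 16, with amplitudes \eqn{P_k = \sqrt{A_k^2 + B_k^2}} and
#' size-normalised amplitudes \eqn{P'_k = 100 P_k / A_0}. The normalisation
#' removes overall scale (skull size): multiplying the curve by any positive
#' constant leaves \eqn{P'} unchanged. The Nyquist term k = 16 carries the
#' same 1/16 normalisation as the others (its sine part is identically 0);
#' [inverse_reconstruct()] compensates with a half weight.
#'
#' @param samples numeric vector of 32 finite values.
#' @return List of class `fourier_descriptor` with `A0`, `A`, `B`, `P`
#'   (16 each) and `P_norm`; `P_norm` is `NA` with a warning when `A0 = 0`.
#' @export
fourier_descriptors <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) != 32L || anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be 32 finite values", call. = FALSE)
  m <- 0:31
  A0 <- sum(samples) / 32
  K <- 1:16
  ang <- outer(K, m, function(k, mm) 2 * pi * k * mm / 32)
  A <- drop(cos(ang) %*% samples) / 16
  B <- drop(sin(ang) %*% samples) / 16
  P <- sqrt(A^2 + B^2)
  if (A0 == 0) {
    warning("A0 = 0: normalised amplitudes are undefined")
    P_norm <- rep(NA_real_, 16L)
  } else P_norm <- P * 100 / A0
  structure(list(A0 = A0, A = A, B = B, P = P, P_norm = P_norm),
            class = "fourier_descriptor")
}

#' Reconstruct curve samples from a Fourier descriptor
#'
#' Inverse of [fourier_descriptors()]:
#' \deqn{\hat Y_m = A_0 + \sum_{k=1}^{15} \big[A_k \cos\tfrac{2\pi k m}{32} +
#'       B_k \sin\tfrac{2\pi k m}{32}\big] + \tfrac{A_{16}}{2} \cos(\pi m).}
#' The forward/inverse pair is an exact identity on any 32-sample input
#' (to machine precision).
#'
#' @param desc a [fourier_descriptors()] result.
#' @param n number of samples; default (and the exact-roundtrip case) 32.
#' @return Numeric vector of `n` reconstructed samples.
#' @export
inverse_reconstruct <- function(desc, n = 32L) {
  stopifnot(inherits(desc, "fourier_descriptor"))
  m <- 0:(n - 1L)
  y <- rep(desc$A0, n)
  for (k in 1:15)
    y <- y + desc$A[k] * cos(2 * pi * k * m / 32) +
             desc$B[k] * sin(2 * pi * k * m / 32)
  y + desc$A[16L] / 2 * cos(pi * m)
}

#' Extract the 16 normalised frontal-arc amplitudes
#'
#' Full frontal chain: polynomial fit (degree 6, Levenberg-Marquardt
#' refined), XY projection, 32-segment sampling, Fourier decomposition.
#'
#' @param landmarks `n x 3` landmark matrix.
#' @param degree polynomial degree; default 6.
#' @param n_samples segment count; default 32.
#' @return Named numeric vector `P1 ... P16` of normalised amplitudes.
#' @export
extract_frontal_features <- function(landmarks, degree = 6L, n_samples = 32L) {
  curve <- fit_polynomial(landmarks, degree)
  desc <- fourier_descriptors(sample_curve(curve, n_samples))
  stats::setNames(desc$P_norm, paste0("P", 1:16))
}
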