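# Independent oracles used across the suite. Each recomputes the target
# quantity by a route different from the implementation under test.

# Direct Riemann-sum quadrature of the CWT at one grid point (1-based r, c).
quadrature_cwt <- function(hm, scale, r, c) {
  sp <- hm$spacing
  hw <- max(1L, ceiling(4 * scale / sp))
  wx <- 0; wy <- 0
  for (i in -hw:hw) for (j in -hw:hw) {
    u <- j * sp / scale; v <- i * sp / scale     # x along columns, y along rows
    g <- exp(-(u^2 + v^2) / 2)
    f <- hm$heights[r + i, c + j]
    wx <- wx + (1 / scale) * (-u * g) * f * sp^2
    wy <- wy + (1 / scale) * (-v * g) * f * sp^2
  }
  c(wx = wx, wy = wy)
}

# Brute-force maximiser of the SVM dual on <= 4 points: grid over the free
# multipliers with the equality constraint eliminating the last one, then a
# local refinement pass around the best coarse cell. The coarse resolution
# adapts to the free-dimension count so the grid stays in memory; the
# refinement pass brings the effective resolution well below 1e-3.
brute_force_dual <- function(K, y, C, res = 1e-3) {
  n <- length(y)
  stopifnot(n >= 2, n <= 4)
  if (n == 4L) res <- max(res, 1e-2)
  M <- K * tcrossprod(y)
  eval_W <- function(A) {                        # rows of A are alpha vectors
    rowSums(A) - 0.5 * rowSums((A %*% M) * A)
  }
  search <- function(lo, hi, step) {
    axes <- lapply(seq_len(n - 1L), function(i) seq(lo[i], hi[i], by = step))
    A <- as.matrix(expand.grid(axes))
    last <- -y[n] * as.vector(A %*% y[-n])
    ok <- last >= 0 & last <= C
    A <- cbind(A[ok, , drop = FALSE], last[ok])
    if (nrow(A) == 0L) return(NULL)
    W <- eval_W(A)
    list(alpha = A[which.max(W), ], W = max(W))
  }
  step <- res * max(C, 1)
  coarse <- search(rep(0, n - 1L), rep(C, n - 1L), step)
  a <- coarse$alpha[seq_len(n - 1L)]
  fine <- search(pmax(a - step, 0), pmin(a + step, C), step / 50)
  if (is.null(fine) || fine$W < coarse$W) coarse else fine
}

# Maximum absolute second difference along rows (y axis) of a template.
max_abs_d2y <- function(z) max(abs(diff(z, differences = 2L)))

# Direct 32-term DFT sums (independent of the vectorised implementation).
direct_fourier <- function(Y) {
  stopifnot(length(Y) == 32L)
  A0 <- sum(Y) / 32
  A <- B <- numeric(16L)
  for (k in 1:16) {
    sa <- 0; sb <- 0
    for (m in 0:31) {
      sa <- sa + Y[m + 1L] * cos(2 * pi * k * m / 32)
      sb <- sb + Y[m + 1L] * sin(2 * pi * k * m / 32)
    }
    A[k] <- sa / 16; B[k] <- sb / 16
  }
  list(A0 = A0, A = A, B = B, P = sqrt(A^2 + B^2))
}

# Count of misclassified training points for a trained model.
training_errors <- function(model, X, y) {
  sum(as.numeric(predict(model, X)) != y)
}

# A reproducible overlapping two-class dataset in 2D.
overlapping_classes <- function(n_per_class = 25L, sep = 1.2, seed = 404L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2L * n_per_class, 0), ncol = 2L),
             matrix(rnorm(2L * n_per_class, sep), ncol = 2L))
  list(X = X, y = rep(c(-1, 1), each = n_per_class))
}
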