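# Sex classification: feature fusion, RBF soft-margin SVM trained by an
# SMO-type dual solver, log2 grid search over (C, delta), stratified
# splitting and per-class evaluation. Labels are +1 (male) / -1 (female)
# throughout.

#' Fuse margin and frontal features into one vector
#'
#' The 18-dimensional feature vector per skull: valley area, erosion
#' thickness, and the 16 normalised Fourier amplitudes.
#'
#' @param margin_features list with `area` and `thickness`
#'   (see [extract_margin_features()]).
#' @param frontal_features numeric vector of 16 normalised amplitudes
#'   (see [extract_frontal_features()]).
#' @return Named numeric vector of length 18.
#' @export
fuse_features <- function(margin_features, frontal_features) {
  stopifnot(length(frontal_features) == 16L)
  c(area = as.numeric(margin_features$area),
    thickness = as.numeric(margin_features$thickness),
    stats::setNames(as.numeric(frontal_features), paste0("P", 1:16)))
}

#' Per-feature standardization statistics
#'
#' Training-set means and standard deviations used to z-score features
#' before the RBF kernel (raw areas are orders of magnitude larger than the
#' normalised amplitudes and would otherwise dominate the kernel distance).
#' Constant features (sd = 0) are passed through unscaled with a warning.
#'
#' @param x numeric feature matrix (rows = samples).
#' @return List of class `feature_stats` with `mean`, `sd` and `constant`
#'   (logical flags for sd = 0 features).
#' @export
feature_stats <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  constant <- sdev == 0 | is.na(sdev)
  if (any(constant)) {
    warning(sprintf("%d constant feature(s) left unscaled", sum(constant)))
    sdev[constant] <- 1
  }
  structure(list(mean = mu, sd = sdev, constant = constant),
            class = "feature_stats")
}

#' Standardize features with training-set statistics
#'
#' @param x numeric matrix or vector of features.
#' @param stats a [feature_stats()] object (always computed on the training
#'   set, never on held-out data).
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(x, stats) {
  stopifnot(inherits(stats, "feature_stats"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' RBF kernel
#'
#' \eqn{k(x, x_i) = \exp(-\|x - x_i\|^2 / \delta^2)} with kernel width
#' \eqn{\delta > 0}; equals 1 at x = x_i and decays with squared distance.
#'
#' @param x,xi numeric vectors of equal length.
#' @param delta kernel width, positive.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, xi, delta) {
  if (!is_scalar_num(delta) || delta <= 0)
    stop("`delta` must be positive", call. = FALSE)
  if (length(x) != length(xi)) stop("length mismatch", call. = FALSE)
  exp(-sum((x - xi)^2) / delta^2)
}

# Cross kernel matrix exp(-||x_i - y_j||^2 / delta^2) from squared distances.
rbf_kernel_matrix <- function(X, Y, delta) {
  exp(-.dist2(X, Y) / delta^2)
}

# Squared Euclidean cross-distance matrix (clamped at 0 for roundoff).
.dist2 <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' Dual objective of the soft-margin SVM
#'
#' \eqn{W(\alpha) = \sum_i \alpha_i - \tfrac12 \sum_{ij} y_i y_j \alpha_i
#' \alpha_j K_{ij}}; used to compare the solver against brute-force oracles.
#'
#' @param alpha multiplier vector.
#' @param K kernel matrix.
#' @param y label vector in \{-1, +1\}.
#' @return The scalar objective value.
#' @export
dual_objective <- function(alpha, K, y) {
  sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
}

#' Solve the SVM dual on a precomputed kernel matrix
#'
#' Maximises the dual objective subject to the box constraint
#' \eqn{0 \le \alpha_i \le C} and \eqn{\sum_i \alpha_i y_i = 0} by pairwise
#' (SMO-type) coordinate ascent on the maximal KKT-violating pair. The
#' equality constraint is preserved exactly by construction; convergence is
#' declared when the violation falls below `tol`.
#'
#' @param K symmetric PSD kernel matrix.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param C box penalty, positive.
#' @param tol KKT violation tolerance.
#' @param max_iter pairwise update cap; exceeding it is an error carrying
#'   the residual violation as a diagnostic.
#' @return List with `alpha`, `b`, `objective`, `iterations`,
#'   `kkt_violation`, `converged`.
#' @export
solve_dual <- function(K, y, C, tol = 1e-3, max_iter = 1e6) {
  K <- as.matrix(K)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (!is_scalar_num(C) || C <= 0) stop("`C` must be positive", call. = FALSE)
  res <- .smo_solve(K, y, C, tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf(
      "SMO did not converge in %d iterations (KKT violation %.3e > tol %.3e)",
      res$iterations, res$kkt_violation, tol), call. = FALSE)
  res
}

#' Train an RBF soft-margin SVM
#'
#' Standardizes the features with training-set statistics, builds the RBF
#' kernel and solves the dual with [solve_dual()]. The decision function is
#' \deqn{f(x) = \sum_i y_i \alpha_i k(x, x_i) + b,} and the sign of f
#' assigns the class.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels in \{-1, +1\}.
#' @param C box penalty.
#' @param delta RBF kernel width.
#' @param tol,max_iter passed to [solve_dual()].
#' @param scale standardize features first (default TRUE).
#' @return Object of class `cranio_svm` with support vectors, multipliers,
#'   bias, hyperparameters and the standardization statistics.
#' @export
svm_train <- function(x, y, C = 1, delta = 1, tol = 1e-3, max_iter = 1e6,
                      scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  stats <- if (scale) feature_stats(x) else NULL
  xs <- if (scale) standardize(x, stats) else x
  K <- rbf_kernel_matrix(xs, xs, delta)
  sol <- solve_dual(K, y, C, tol, max_iter)
  sv <- sol$alpha > 1e-9 * max(C, 1)
  structure(list(support_vectors = xs[sv, , drop = FALSE],
                 alphas = sol$alpha[sv], sv_labels = y[sv],
                 b = sol$b, C = C, delta = delta,
                 objective = sol$objective, iterations = sol$iterations,
                 stats = stats, n_features = ncol(x),
                 alphas_full = sol$alpha),
            class = "cranio_svm")
}

#' @export
print.cranio_svm <- function(x, ...) {
  cat(sprintf("<cranio_svm> %d support vectors, C = %g, delta = %g, b = %.4f\n",
              length(x$alphas), x$C, x$delta, x$b))
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' @param model a `cranio_svm` model.
#' @param newdata feature matrix or single feature vector (raw scale; the
#'   model's stored standardization is applied).
#' @return Numeric vector of decision values f(x).
#' @export
decision_values <- function(model, newdata) {
  stopifnot(inherits(model, "cranio_svm"))
  newdata <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(newdata) != model$n_features)
    stop("feature length mismatch", call. = FALSE)
  xs <- if (!is.null(model$stats)) standardize(newdata, model$stats) else newdata
  Kx <- rbf_kernel_matrix(xs, model$support_vectors, model$delta)
  drop(Kx %*% (model$alphas * model$sv_labels)) + model$b
}

#' Predict sex labels from a trained SVM
#'
#' Sign of the decision function; an exact tie f(x) = 0 is reported as +1
#' and flagged in the `tie` attribute.
#'
#' @inheritParams decision_values
#' @param ... unused.
#' @return Vector of labels in \{-1, +1\} with attributes `decision`
#'   (the f values) and `tie` (logical).
#' @export
predict.cranio_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  lab <- ifelse(f >= 0, 1, -1)
  structure(lab, decision = f, tie = f == 0)
}

#' Stratified train/test split
#'
#' Allocates `round(train_frac * n_class)` of each class to the training set
#' (shuffled under `seed`); the split is disjoint and exhaustive. With the
#' study composition of 73 males and 60 females at 70%, this yields 93
#' training (51 male, 42 female) and 40 test samples (22 male, 18 female).
#'
#' @param labels vector of labels in \{-1, +1\}.
#' @param train_frac training fraction in (0, 1); default 0.7.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  if (!is_scalar_num(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  labels <- as.numeric(labels)
  train <- integer(0)
  for (cl in sort(unique(labels), decreasing = TRUE)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop(sprintf("class %+d has fewer than 2 members", cl), call. = FALSE)
    n_tr <- as.integer(round(train_frac * length(idx)))
    perm <- with_seed(seed + as.integer(cl > 0), sample(idx))
    train <- c(train, sort(perm[seq_len(n_tr)]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold assignment: per class, shuffled round-robin.
.stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  for (cl in sort(unique(y), decreasing = TRUE)) {
    idx <- which(y == cl)
    perm <- with_seed(seed + 17L * as.integer(cl > 0), sample(idx))
    fold[perm] <- rep_len(seq_len(folds), length(perm))
  }
  fold
}

#' Log2 grid search for (C, delta)
#'
#' Evaluates stratified `folds`-fold cross-validated accuracy on the
#' training set over the log2 grids \eqn{C = 2^e, e = -5, -4.5, \ldots, 15}
#' and \eqn{\delta = 2^e, e = -15, \ldots, 5} (step 0.5 in the exponent:
#' a 41 x 41 grid). Features are standardized inside each fold with the
#' fold-training statistics. Ties in accuracy are broken towards smaller C,
#' then smaller delta.
#'
#' @param x feature matrix.
#' @param y labels in \{-1, +1\}.
#' @param folds number of CV folds; default 5.
#' @param seed RNG seed driving the fold assignment.
#' @param C_exponents,delta_exponents log2 grids.
#' @param tol SMO tolerance used during the search.
#' @return List of class `grid_search_result` with the `accuracy` matrix
#'   (rows = C, cols = delta, dimnames = exponents), `C_grid`, `delta_grid`,
#'   `best_C`, `best_delta`, `best_accuracy`, `folds`, `seed`.
#' @export
grid_search <- function(x, y, folds = 5L, seed = 1L,
                        C_exponents = seq(-5, 15, by = 0.5),
                        delta_exponents = seq(-15, 5, by = 0.5),
                        tol = 1e-3) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  folds <- as.integer(folds)
  if (length(y) < folds) stop("fewer samples than folds", call. = FALSE)
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("both classes must be present with at least 2 members each",
         call. = FALSE)
  C_grid <- 2^C_exponents
  d_grid <- 2^delta_exponents
  fold <- .stratified_folds(y, folds, seed)
  correct <- matrix(0, length(C_grid), length(d_grid))
  total <- 0L
  for (fd in seq_len(folds)) {
    tr <- fold != fd
    if (length(unique(y[tr])) < 2L || !any(!tr)) next
    stats <- feature_stats(x[tr, , drop = FALSE])
    xtr <- standardize(x[tr, , drop = FALSE], stats)
    xva <- standardize(x[!tr, , drop = FALSE], stats)
    ytr <- y[tr]; yva <- y[!tr]
    D_tr <- .dist2(xtr, xtr)
    D_va <- .dist2(xva, xtr)
    total <- total + length(yva)
    for (di in seq_along(d_grid)) {
      K <- exp(-D_tr / d_grid[di]^2)
      Kva <- exp(-D_va / d_grid[di]^2)
      for (ci in seq_along(C_grid)) {
        sol <- .smo_solve(K, ytr, C_grid[ci], tol, 1000000L)
        f <- drop(Kva %*% (sol$alpha * ytr)) + sol$b
        pred <- ifelse(f >= 0, 1, -1)
        correct[ci, di] <- correct[ci, di] + sum(pred == yva)
      }
    }
  }
  acc <- correct / total
  dimnames(acc) <- list(C = format(C_exponents), delta = format(delta_exponents))
  # argmax with ties to smaller C, then smaller delta (row-major scan)
  best <- c(1L, 1L)
  for (ci in seq_along(C_grid)) for (di in seq_along(d_grid))
    if (acc[ci, di] > acc[best[1L], best[2L]]) best <- c(ci, di)
  structure(list(accuracy = acc, C_grid = C_grid, delta_grid = d_grid,
                 best_C = C_grid[best[1L]], best_delta = d_grid[best[2L]],
                 best_accuracy = acc[best[1L], best[2L]],
                 folds = folds, seed = seed),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %d x %d grid, best C = %g, delta = %g (CV accuracy %.1f%%)\n",
    nrow(x$accuracy), ncol(x$accuracy), x$best_C, x$best_delta,
    100 * x$best_accuracy))
  invisible(x)
}

#' Per-class correct rate
#'
#' `correct / tested * 100`, rounded to one decimal (the convention used in
#' per-class confusion reports: 20 of 22 gives 90.9, 17 of 18 gives 94.4).
#'
#' @param correct,tested counts.
#' @return Percentage with one decimal.
#' @export
class_rate <- function(correct, tested) {
  stopifnot(tested > 0, correct >= 0, correct <= tested)
  round(100 * correct / tested, 1L)
}

#' Evaluate a trained model on a labelled test set
#'
#' Per-class confusion counts and correct rates.
#'
#' @param model a `cranio_svm` model.
#' @param x_test feature matrix.
#' @param y_test labels in \{-1, +1\}.
#' @return Data frame of class `eval_report` with one row per class
#'   (`male` = +1, `female` = -1): `tested`, `correct`, `misjudged`,
#'   `rate` (percent, one decimal).
#' @export
evaluate <- function(model, x_test, y_test) {
  stopifnot(length(y_test) > 0)
  pred <- as.numeric(predict(model, as.matrix(x_test)))
  rows <- lapply(c(male = 1, female = -1), function(cl) {
    idx <- y_test == cl
    tested <- sum(idx)
    correct <- sum(pred[idx] == y_test[idx])
    data.frame(tested = tested, correct = correct,
               misjudged = tested - correct,
               rate = if (tested > 0) class_rate(correct, tested) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- cbind(class = rownames(out), out)
  rownames(out) <- NULL
  class(out) <- c("eval_report", class(out))
  out
}
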