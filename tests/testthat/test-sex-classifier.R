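# SVM training, prediction, model selection and evaluation.

test_that("standardization centres and scales by training statistics only", {
  set.seed(1)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  st <- feature_stats(X)
  Z <- standardize(X, st)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(Z, 2, sd), rep(1, 3), tolerance = 1e-9)
  held <- rnorm(3)
  expect_identical(standardize(held, st), standardize(held, st))
  Xc <- cbind(X, 7)                                  # constant feature
  expect_warning(stc <- feature_stats(Xc), "constant")
  Zc <- standardize(Xc, stc)
  expect_equal(Zc[, 4L], rep(0, 20))                 # centred, unscaled
})

test_that("the RBF kernel honours its definition", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 0.7), 1)
  xi <- x + c(0.7, 0, 0)                             # distance exactly delta
  expect_equal(rbf_kernel(x, xi, 0.7), exp(-1))
  set.seed(6)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(rbf_kernel(a, b, 1.3), rbf_kernel(b, a, 1.3))
    expect_true(rbf_kernel(a, b, 1.3) > 0 && rbf_kernel(a, b, 1.3) <= 1)
  }
  expect_error(rbf_kernel(x, x, 0), "positive")
  expect_error(rbf_kernel(x, c(1, 2), 1), "mismatch")
})

test_that("a separable pair is classified with correct signs", {
  X <- matrix(c(0, 2), 2, 1)
  y <- c(-1, 1)
  m <- svm_train(X, y, C = 10, delta = 1, scale = FALSE, tol = 1e-6)
  expect_identical(as.numeric(predict(m, X)), c(-1, 1))
})

test_that("the dual solution matches a brute-force QP oracle", {
  sets <- list(
    list(X = matrix(c(0, 1, 3), 3, 1), y = c(-1, -1, 1)),
    list(X = matrix(c(0, 0.6, 1.1, 2), 4, 1), y = c(-1, 1, -1, 1)),
    list(X = matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2), y = c(-1, 1, 1, -1)))
  for (s in sets) {
    K <- rbf_kernel_matrix(s$X, s$X, delta = 50)     # near-linear regime
    sol <- solve_dual(K, s$y, C = 1, tol = 1e-6)
    oracle <- brute_force_dual(K, s$y, C = 1, res = 1e-3)
    expect_gte(sol$objective, oracle$W - 1e-9)       # solver at least as good
    expect_lt(abs(sol$objective - oracle$W), 1e-4)
    expect_equal(dual_objective(sol$alpha, K, s$y), sol$objective,
                 tolerance = 1e-10)
  }
})

test_that("every converged model is dual-feasible and satisfies KKT", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 14L
    X <- matrix(rnorm(2L * n, rep(c(0, 1.5), each = n)), ncol = 2L)
    y <- rep(c(-1, 1), each = n / 2L)
    C <- c(0.1, 1, 10, 100, 1000)[rep]
    K <- rbf_kernel_matrix(X, X, 1)
    sol <- solve_dual(K, y, C, tol = 1e-5)
    expect_lt(abs(sum(sol$alpha * y)), 1e-8)
    expect_true(all(sol$alpha >= -1e-9))
    expect_true(all(sol$alpha <= C + 1e-9))
    expect_lte(sol$kkt_violation, 1e-5)
  }
})

test_that("single-class input and invalid penalties are rejected", {
  K <- diag(3)
  expect_error(solve_dual(K, c(1, 1, 1), C = 1), "both classes")
  expect_error(solve_dual(K, c(1, -1, 1), C = -2), "positive")
  expect_error(solve_dual(K, c(1, -1, 0.5), C = 1), "-1/\\+1")
})

test_that("decisions agree with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c(1, -1), each = 20)
  mine <- svm_train(X, y, C = 2, delta = 1.5, tol = 1e-6, scale = FALSE)
  ref <- e1071::svm(X, factor(y), kernel = "radial", gamma = 1 / 1.5^2,
                    cost = 2, scale = FALSE)
  ref_lab <- ifelse(as.integer(as.character(predict(ref, X))) > 0, 1, -1)
  expect_equal(as.numeric(predict(mine, X)), ref_lab)
  dv_mine <- attr(predict(mine, X), "decision")
  dv_ref <- drop(attr(predict(ref, X, decision.values = TRUE),
                      "decision.values"))
  expect_gt(abs(stats::cor(dv_mine, dv_ref)), 0.9999)
})

test_that("prediction reproduces training labels and the kernel-decay limit", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2), matrix(rnorm(20, 3, 0.2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  m <- svm_train(X, y, C = 10, delta = 2, scale = FALSE, tol = 1e-6)
  expect_identical(as.numeric(predict(m, X)), y)
  far <- matrix(c(1e6, 1e6), 1, 2)                  # k(x, sv) ~ 0 -> sign(b)
  expect_identical(as.numeric(predict(m, far)), ifelse(m$b >= 0, 1, -1))
  expect_error(predict(m, c(1, 2, 3)), "mismatch")
})

test_that("splitting a support vector's weight leaves the decision unchanged", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2), matrix(rnorm(20, 2, 0.5), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  m <- svm_train(X, y, C = 5, delta = 1.5, scale = FALSE)
  m2 <- m
  m2$support_vectors <- rbind(m$support_vectors, m$support_vectors[1L, ])
  m2$alphas <- c(m$alphas[1L] / 2, m$alphas[-1L], m$alphas[1L] / 2)
  m2$sv_labels <- c(m$sv_labels, m$sv_labels[1L])
  probe <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_values(m2, probe), decision_values(m, probe),
               tolerance = 1e-12)
})

test_that("training error does not increase with the penalty C", {
  d <- overlapping_classes()
  errs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    m <- svm_train(d$X, d$y, C = C, delta = 2, scale = FALSE, tol = 1e-5)
    training_errors(m, d$X, d$y)
  }, numeric(1L))
  expect_true(all(diff(errs) <= 0))
})

test_that("grid search spans 41 x 41 log2 cells and is deterministic", {
  pop <- generate_population(12, 12, seed = 8)
  X <- t(vapply(pop, function(p)
    individual_features(p$margin, p$frontal_landmarks), numeric(18L)))
  y <- vapply(pop, `[[`, numeric(1L), "sex_label")
  gs <- grid_search(X, y, folds = 3, seed = 2,
                    C_exponents = seq(-5, 15, 1), delta_exponents = seq(-15, 5, 1))
  gs2 <- grid_search(X, y, folds = 3, seed = 2,
                     C_exponents = seq(-5, 15, 1), delta_exponents = seq(-15, 5, 1))
  expect_identical(gs$accuracy, gs2$accuracy)
  sub <- c(which(y == 1)[1:5], which(y == -1)[1:5])
  full <- grid_search(X[sub, ], y[sub], folds = 2, seed = 1)
  expect_identical(dim(full$accuracy), c(41L, 41L))
  expect_equal(full$C_grid[1L], 2^-5)
  expect_equal(full$C_grid[41L], 2^15)
  expect_equal(full$delta_grid[1L], 2^-15)
  expect_equal(full$delta_grid[41L], 2^5)
})

test_that("well-separated classes reach perfect cross-validated accuracy", {
  pop <- generate_population(20, 20,
    male_params = default_dimorphism_params("male", noise_sd = 0.05),
    female_params = default_dimorphism_params("female", noise_sd = 0.05),
    seed = 31)
  X <- t(vapply(pop, function(p)
    individual_features(p$margin, p$frontal_landmarks), numeric(18L)))
  y <- vapply(pop, `[[`, numeric(1L), "sex_label")
  gs <- grid_search(X, y, folds = 5, seed = 3,
                    C_exponents = seq(-5, 15, 1), delta_exponents = seq(-15, 5, 1))
  expect_equal(gs$best_accuracy, 1)
})

test_that("the stratified split reproduces the study allocation", {
  labels <- c(rep(1, 73), rep(-1, 60))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_length(sp$train, 93L)
  expect_length(sp$test, 40L)
  expect_identical(sum(labels[sp$train] == 1), 51L)
  expect_identical(sum(labels[sp$test] == 1), 22L)
  expect_identical(sum(labels[sp$test] == -1), 18L)
  expect_identical(sum(labels[sp$train] == -1), 42L)   # 60 - 18 held out
})

test_that("splits are disjoint, exhaustive and validated", {
  labels <- rep(c(1, -1), each = 10)
  sp <- stratified_split(labels, 0.5, seed = 3)
  expect_identical(sum(labels[sp$train] == 1), 5L)
  expect_identical(sum(labels[sp$train] == -1), 5L)
  set.seed(10)
  for (rep in 1:5) {
    labs <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (min(table(labs)) < 2) next
    sp <- stratified_split(labs, 0.7, seed = rep)
    expect_identical(sort(c(sp$train, sp$test)), seq_along(labs))
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  expect_error(stratified_split(c(1, 1, 1, -1), 0.7, 1), "fewer than 2")
  expect_error(stratified_split(labels, 1.2, 1), "in \\(0, 1\\)")
})

test_that("evaluation reports per-class confusion counts and rates", {
  expect_equal(class_rate(20, 22), 90.9)
  expect_equal(class_rate(17, 18), 94.4)
  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2), matrix(rnorm(20, 3, 0.2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  m <- svm_train(X, y, C = 10, delta = 2, scale = FALSE)
  rep_ <- evaluate(m, X, y)
  expect_identical(rep_$class, c("male", "female"))
  expect_equal(rep_$rate, c(100, 100))
  expect_identical(rep_$tested, rep_$correct + rep_$misjudged)
})
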