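# End-to-end orchestration: synthesise or ingest data, extract margin and
# frontal features, fuse, split, grid-search, train and evaluate, with all
# artifacts (features CSV, model JSON, report JSON) written to disk.

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts (`NULL`: nothing written).
#' @param manifest path to a manifest CSV (columns `id`, `sex`,
#'   `margin_file`, `landmarks_file`) for the real-data path; `NULL` for the
#'   synthetic path.
#' @param n_male,n_female synthetic population composition (used when
#'   `manifest` is `NULL`); defaults follow the study composition 73/60.
#' @param male_params,female_params synthetic [dimorphism_params()].
#' @param margin a [margin_config()].
#' @param degree,n_samples frontal fit degree and segment count.
#' @param train_frac stratified split fraction; default 0.7.
#' @param folds CV folds for the grid search; default 5.
#' @param C_exponents,delta_exponents log2 grids for the search.
#' @param seed master seed (population, split and folds all derive from it).
#' @param verbose print stage progress.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, manifest = NULL,
                            n_male = 73L, n_female = 60L,
                            male_params = default_dimorphism_params("male"),
                            female_params = default_dimorphism_params("female"),
                            margin = margin_config(),
                            degree = 6L, n_samples = 32L,
                            train_frac = 0.7, folds = 5L,
                            C_exponents = seq(-5, 15, by = 0.5),
                            delta_exponents = seq(-15, 5, by = 0.5),
                            seed = 1L, verbose = TRUE) {
  structure(list(out_dir = out_dir, manifest = manifest,
                 n_male = n_male, n_female = n_female,
                 male_params = male_params, female_params = female_params,
                 margin = margin, degree = degree, n_samples = n_samples,
                 train_frac = train_frac, folds = folds,
                 C_exponents = C_exponents, delta_exponents = delta_exponents,
                 seed = seed, verbose = verbose),
            class = "pipeline_config")
}

.stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Extract the fused 18-feature vector of one individual
#'
#' @param margin a [height_map()].
#' @param landmarks `n x 3` landmark matrix.
#' @param config a [pipeline_config()] (margin/frontal settings are taken
#'   from it).
#' @return Named numeric vector of length 18.
#' @export
individual_features <- function(margin, landmarks,
                                config = pipeline_config(verbose = FALSE)) {
  mf <- extract_margin_features(margin, config$margin)
  ff <- extract_frontal_features(landmarks, config$degree, config$n_samples)
  fuse_features(mf, ff)
}

#' Run the full sex-estimation pipeline
#'
#' Stages: data (synthetic generation or manifest ingest), margin features,
#' frontal features, fusion, stratified 70/30 split, log2 grid search with
#' stratified cross-validation, final training at the selected (C, delta),
#' and per-class evaluation on the held-out set. Fully reproducible from
#' `(config, seed)`; any stage failure aborts with the stage named. When
#' `config$out_dir` is set, writes `features.csv`, `model.json`,
#' `report.json` and `config.yaml` (with its MD5 recorded in the report).
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with `features` (data frame),
#'   `split`, `search` ([grid_search_result]), `model` (`cranio_svm`),
#'   `report` ([evaluate()] data frame) and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- isTRUE(config$verbose)

  data <- .stage("data", v, {
    if (is.null(config$manifest)) {
      pop <- generate_population(config$n_male, config$n_female,
                                 config$male_params, config$female_params,
                                 config$seed)
      list(ids = vapply(pop, `[[`, character(1L), "id"),
           sex = vapply(pop, `[[`, numeric(1L), "sex_label"),
           margins = lapply(pop, `[[`, "margin"),
           landmarks = lapply(pop, `[[`, "frontal_landmarks"))
    } else {
      man <- read.csv(config$manifest, stringsAsFactors = FALSE)
      need <- c("id", "sex", "margin_file", "landmarks_file")
      if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
      for (f in c(man$margin_file, man$landmarks_file))
        if (!file.exists(f)) stop(sprintf("missing file '%s'", f))
      list(ids = as.character(man$id), sex = as.numeric(man$sex),
           margins = lapply(man$margin_file, read_height_map_csv),
           landmarks = lapply(man$landmarks_file, read_landmarks_csv))
    }
  })

  feats <- .stage("features", v, {
    m <- t(mapply(function(hm, lm) individual_features(hm, lm, config),
                  data$margins, data$landmarks))
    data.frame(id = data$ids, sex = data$sex, m, stringsAsFactors = FALSE)
  })
  X <- as.matrix(feats[, -(1:2)])
  y <- feats$sex

  split <- .stage("split", v,
                  stratified_split(y, config$train_frac, config$seed))

  search <- .stage("grid_search", v,
                   grid_search(X[split$train, , drop = FALSE], y[split$train],
                               folds = config$folds, seed = config$seed,
                               C_exponents = config$C_exponents,
                               delta_exponents = config$delta_exponents))

  model <- .stage("train", v,
                  svm_train(X[split$train, , drop = FALSE], y[split$train],
                            C = search$best_C, delta = search$best_delta))

  report <- .stage("evaluate", v,
                   evaluate(model, X[split$test, , drop = FALSE],
                            y[split$test]))

  config_hash <- NA_character_
  if (!is.null(config$out_dir)) {
    .stage("write", v, {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(feats, file.path(config$out_dir, "features.csv"),
                row.names = FALSE)
      cfg_path <- file.path(config$out_dir, "config.yaml")
      yaml::write_yaml(.config_as_list(config), cfg_path)
      config_hash <- unname(tools::md5sum(cfg_path))  # promise evaluates here
      write_svm_model(model, file.path(config$out_dir, "model.json"))
      jsonlite::write_json(
        list(config_hash = config_hash, seed = config$seed,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
             n_train = length(split$train), n_test = length(split$test),
             best_C = search$best_C, best_delta = search$best_delta,
             cv_accuracy = search$best_accuracy, report = report),
        file.path(config$out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }

  structure(list(features = feats, split = split, search = search,
                 model = model, report = report, config = config,
                 config_hash = config_hash),
            class = "pipeline_result")
}

.config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$male_params <- unclass(cfg$male_params)
  cfg$female_params <- unclass(cfg$female_params)
  cfg$margin <- unclass(cfg$margin)
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d individuals (%d train / %d test), C = %g, delta = %g\n",
    nrow(x$features), length(x$split$train), length(x$split$test),
    x$search$best_C, x$search$best_delta))
  print(x$report)
  invisible(x)
}

#' Serialize / load a trained SVM model as JSON
#'
#' Stores support vectors, multipliers, bias, hyperparameters and the
#' standardization statistics; the loaded model predicts identically.
#'
#' @param model a `cranio_svm` model.
#' @param path JSON file path.
#' @return `read_svm_model()` returns the restored `cranio_svm`.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "cranio_svm"))
  obj <- list(support_vectors = unname(model$support_vectors),
              alphas = model$alphas, sv_labels = model$sv_labels,
              b = model$b, C = model$C, delta = model$delta,
              n_features = model$n_features,
              stats = if (is.null(model$stats)) NULL else
                list(mean = unname(model$stats$mean),
                     sd = unname(model$stats$sd),
                     constant = unname(model$stats$constant)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- NULL
  if (!is.null(obj$stats))
    stats <- structure(list(mean = obj$stats$mean, sd = obj$stats$sd,
                            constant = obj$stats$constant),
                       class = "feature_stats")
  structure(list(support_vectors = matrix(obj$support_vectors,
                                          ncol = obj$n_features),
                 alphas = obj$alphas, sv_labels = obj$sv_labels,
                 b = obj$b, C = obj$C, delta = obj$delta,
                 objective = NA_real_, iterations = NA_integer_,
                 stats = stats, n_features = obj$n_features,
                 alphas_full = NULL),
            class = "cranio_svm")
}

#' Render an OBJ mesh to an orthographic height map
#'
#' Reads a Wavefront OBJ (vertices and triangular faces; polygonal faces are
#' fanned into triangles), and renders the nearest-surface depth towards the
#' viewer (largest z per cell) on a regular grid over the mesh's XY bounding
#' box — the frontal orthographic view, x right, y up, z toward viewer.
#' Cells not covered by any triangle are inpainted by nearest neighbour.
#'
#' @param mesh_path OBJ file path.
#' @param grid_shape integer `c(rows, cols)` of the output grid.
#' @param spacing physical spacing recorded on the output [height_map()].
#' @return A [height_map()]; row 1 corresponds to the top (largest y).
#' @export
read_obj_heightmap <- function(mesh_path, grid_shape = c(64L, 64L),
                               spacing = 2.5e-5) {
  lines <- readLines(mesh_path, warn = FALSE)
  vt <- strsplit(trimws(lines[startsWith(lines, "v ")]), "\\s+")
  ft <- strsplit(trimws(lines[startsWith(lines, "f ")]), "\\s+")
  if (length(vt) == 0L || length(ft) == 0L)
    stop("degenerate mesh: no vertices or faces", call. = FALSE)
  V <- t(vapply(vt, function(p) as.numeric(p[2:4]), numeric(3L)))
  faces <- lapply(ft, function(p) {
    idx <- as.integer(vapply(strsplit(p[-1L], "/"), `[[`, character(1L), 1L))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(V)))
      stop("invalid face index", call. = FALSE)
    if (length(idx) < 3L) stop("face with fewer than 3 vertices", call. = FALSE)
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])  # fan
  })
  F <- do.call(rbind, faces)
  R <- as.integer(grid_shape[1L]); C <- as.integer(grid_shape[2L])
  xr <- range(V[, 1L]); yr <- range(V[, 2L])
  if (diff(xr) == 0 || diff(yr) == 0)
    stop("degenerate mesh: zero XY extent", call. = FALSE)
  gx <- xr[1L] + (seq_len(C) - 0.5) / C * diff(xr)
  gy <- yr[2L] - (seq_len(R) - 0.5) / R * diff(yr)     # row 1 = top
  Z <- matrix(NA_real_, R, C)
  for (t in seq_len(nrow(F))) {
    p1 <- V[F[t, 1L], ]; p2 <- V[F[t, 2L], ]; p3 <- V[F[t, 3L], ]
    cs <- which(gx >= min(p1[1L], p2[1L], p3[1L]) - 1e-12 &
                gx <= max(p1[1L], p2[1L], p3[1L]) + 1e-12)
    rs <- which(gy >= min(p1[2L], p2[2L], p3[2L]) - 1e-12 &
                gy <= max(p1[2L], p2[2L], p3[2L]) + 1e-12)
    if (length(cs) == 0L || length(rs) == 0L) next
    det <- (p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
           (p3[1L] - p1[1L]) * (p2[2L] - p1[2L])
    if (abs(det) < 1e-300) next
    for (ri in rs) for (ci in cs) {
      dx <- gx[ci] - p1[1L]; dy <- gy[ri] - p1[2L]
      l2 <- ((p3[2L] - p1[2L]) * dx - (p3[1L] - p1[1L]) * dy) / det
      l3 <- (-(p2[2L] - p1[2L]) * dx + (p2[1L] - p1[1L]) * dy) / det
      if (l2 >= -1e-9 && l3 >= -1e-9 && l2 + l3 <= 1 + 1e-9) {
        z <- (1 - l2 - l3) * p1[3L] + l2 * p2[3L] + l3 * p3[3L]
        if (is.na(Z[ri, ci]) || z > Z[ri, ci]) Z[ri, ci] <- z
      }
    }
  }
  if (all(is.na(Z))) stop("mesh does not cover the grid", call. = FALSE)
  if (anyNA(Z)) Z <- .inpaint_nearest(Z)
  height_map(Z, spacing)
}

# Nearest-neighbour inpainting of NA cells by iterative neighbour averaging
# (each pass fills NAs adjacent to known cells with the nearest known value).
.inpaint_nearest <- function(Z) {
  R <- nrow(Z); C <- ncol(Z)
  known <- which(!is.na(Z), arr.ind = TRUE)
  miss <- which(is.na(Z), arr.ind = TRUE)
  for (k in seq_len(nrow(miss))) {
    d2 <- (known[, 1L] - miss[k, 1L])^2 + (known[, 2L] - miss[k, 2L])^2
    Z[miss[k, 1L], miss[k, 2L]] <- Z[known[which.min(d2), , drop = FALSE]]
  }
  Z
}
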