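# Synthetic dimorphic-skull generator.
#
# Real supraorbital height maps and frontal landmark sets come from CT-derived
# skull models held in restricted collections; this module generates labelled
# stand-ins with controllable sexual dimorphism so the whole feature/classifier
# chain is testable. All surfaces are synthetic and labelled as such.

# Fixed geometry of the synthetic templates (grid units = "voxels").
.margin_ridge_height <- 10   # logistic brow-ridge step height
.margin_meander_px   <- 3    # lateral meander amplitude of the margin edge
.frontal_x_extent    <- 40   # landmark x range [0, 40]
.frontal_arc_height  <- 15   # logistic base arc of the forehead profile
.frontal_arc_mid     <- 20   # arc inflection x
.frontal_arc_width   <- 5    # arc steepness scale
.frontal_bump_x      <- 28   # frontal-eminence bump centre
.frontal_bump_sd     <- 4    # frontal-eminence bump sd

# Physical grid spacing declared for synthetic height maps. The analysis
# wavelet scale is expressed in the same units; with this spacing the default
# scale of 5e-5 spans two pixels (a standard derivative-of-Gaussian support).
.synthetic_spacing <- 2.5e-5

#' Dimorphism parameters for the synthetic skull generator
#'
#' Bundles the knobs that control how strongly a generated individual
#' expresses male- or female-typical cranial morphology.
#'
#' @param edge_sharpness positive; curvature scale (1/voxel) of the
#'   supraorbital margin edge. Low values give the broad "blunt thick"
#'   male-typical edge, high values the "sharp" female-typical edge.
#' @param valley_depth depth (voxels) of the trough running along the margin.
#' @param forehead_slope inclination (radians) of the frontal profile; larger
#'   values give the more inclined male-typical forehead.
#' @param eminence_amplitude nonnegative bump height (voxels) of the frontal
#'   eminence; larger values give the prominent female-typical eminence.
#' @param noise_sd standard deviation (voxels) of additive i.i.d. Gaussian
#'   observation noise applied to surfaces and landmark coordinates.
#' @param grid_shape integer vector `c(rows, cols)` of the margin height map;
#'   both at least 16.
#' @param n_landmarks number of frontal landmarks (at least 8; a degree-6
#'   polynomial fit needs 7 or more points). Default 18.
#' @return An object of class `dimorphism_params`.
#' @seealso [default_dimorphism_params()] for the calibrated per-sex defaults.
#' @export
dimorphism_params <- function(edge_sharpness, valley_depth, forehead_slope,
                              eminence_amplitude, noise_sd = 0,
                              grid_shape = c(64L, 64L), n_landmarks = 18L) {
  num <- c(edge_sharpness = edge_sharpness, valley_depth = valley_depth,
           forehead_slope = forehead_slope,
           eminence_amplitude = eminence_amplitude, noise_sd = noise_sd)
  if (!all(vapply(num, is_scalar_num, logical(1L))))
    stop("all dimorphism parameters must be finite scalars", call. = FALSE)
  if (edge_sharpness <= 0) stop("`edge_sharpness` must be positive", call. = FALSE)
  if (eminence_amplitude < 0) stop("`eminence_amplitude` must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 16L))
    stop("`grid_shape` must be two integers, both at least 16", call. = FALSE)
  n_landmarks <- as.integer(n_landmarks)
  if (length(n_landmarks) != 1L || n_landmarks < 8L)
    stop("`n_landmarks` must be a single integer >= 8", call. = FALSE)
  structure(list(edge_sharpness = edge_sharpness, valley_depth = valley_depth,
                 forehead_slope = forehead_slope,
                 eminence_amplitude = eminence_amplitude, noise_sd = noise_sd,
                 grid_shape = grid_shape, n_landmarks = n_landmarks),
            class = "dimorphism_params")
}

#' Calibrated per-sex generator defaults
#'
#' The default study conditions of the synthetic population: males carry a
#' blunt, thick supraorbital edge, a deeper margin trough, a more inclined
#' forehead and a faint frontal eminence; females the sharp edge, shallower
#' trough, steeper forehead and prominent eminence.
#'
#' @param sex `"male"` or `"female"`.
#' @param noise_sd observation noise (voxels); default 0.3.
#' @return A [dimorphism_params()] object.
#' @export
default_dimorphism_params <- function(sex = c("male", "female"), noise_sd = 0.3) {
  sex <- match.arg(sex)
  if (sex == "male")
    dimorphism_params(edge_sharpness = 0.8, valley_depth = 6,
                      forehead_slope = 0.45, eminence_amplitude = 1.5,
                      noise_sd = noise_sd)
  else
    dimorphism_params(edge_sharpness = 2.5, valley_depth = 4,
                      forehead_slope = 0.25, eminence_amplitude = 4,
                      noise_sd = noise_sd)
}

#' Surface height map
#'
#' A regular 2D grid of surface heights over the supraorbital region: the
#' signal f(x, y) analysed by the wavelet gradient. Rows run along the
#' vertical (y) anatomical axis, columns along the lateral (x) axis.
#'
#' @param heights finite numeric matrix, both dimensions at least 16.
#' @param spacing physical grid spacing per pixel (one value, both axes).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, spacing = .synthetic_spacing) {
  stop_if_not_matrix(heights, "heights")
  if (any(dim(heights) < 16L))
    stop("`heights` must be at least 16 x 16", call. = FALSE)
  if (!is_scalar_num(spacing) || spacing <= 0)
    stop("`spacing` must be a positive scalar", call. = FALSE)
  structure(list(heights = heights, spacing = spacing), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, spacing %g, height range [%.3g, %.3g]\n",
              nrow(x$heights), ncol(x$heights), x$spacing,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Closed-form supraorbital margin template
#'
#' The noise-free ridge-and-valley surface underlying
#' [generate_margin_surface()]: a logistic brow-ridge step of height 10
#' voxels whose edge position meanders laterally, minus a Gaussian-profile
#' trough (the margin valley) running parallel to the edge, carrying a
#' fine-scale roughness texture localised in the trough,
#' \deqn{z(i, j) = \frac{10}{1 + e^{-s (i - y_e(j))}} -
#'       d\, e^{-(i - y_v(j))^2 / (2 \sigma_v^2)} +
#'       e^{-(i - y_v(j))^2 / (2 \sigma_v^2)}\, t(i, j),}
#' where the roughness texture is the mean of three oblique plane waves,
#' \deqn{t(i, j) = \tfrac13 \big[\sin\tfrac{2\pi (0.71 i + 0.71 j)}{9} +
#'       \sin\tfrac{2\pi (0.97 i - 0.26 j)}{11} +
#'       \sin\tfrac{2\pi (0.26 i - 0.97 j)}{13}\big],}
#' with edge line \eqn{y_e(j) = R/2 + 3 \sin(2\pi j/(C-1))}, trough line
#' \eqn{y_v(j) = y_e(j) - R/8} and trough width
#' \eqn{\sigma_v = R / (3 (1 + s))} for an \eqn{R \times C} grid (0-based
#' row i, column j). `s` is `edge_sharpness` and `d` is `valley_depth`.
#' The trough width shrinks as the edge sharpens — the blunt thick
#' male-typical margin carries a wide rounded trough, the sharp
#' female-typical margin a narrow crisp one. The roughness term emulates
#' the disordered surface texture of the anatomical valley (the property
#' the orientation-entropy feature detects); its envelope follows the
#' trough, so the high-entropy zone scales with trough width. The maximum
#' of \eqn{|\partial^2 z/\partial y^2|} across the edge grows as
#' \eqn{s^2}, so sharper edges have strictly larger edge curvature.
#'
#' @param params a [dimorphism_params()] object.
#' @return Numeric matrix `grid_shape[1] x grid_shape[2]`.
#' @export
margin_template <- function(params) {
  stopifnot(inherits(params, "dimorphism_params"))
  R <- params$grid_shape[1L]; C <- params$grid_shape[2L]
  i <- matrix(0:(R - 1L), R, C)                    # row index (y)
  j <- matrix(0:(C - 1L), R, C, byrow = TRUE)      # col index (x)
  ye <- R / 2 + .margin_meander_px * sin(2 * pi * j / (C - 1L))
  yv <- ye - R / 8
  sv <- R / (3 * (1 + params$edge_sharpness))
  env <- exp(-(i - yv)^2 / (2 * sv^2))
  tex <- (sin(2 * pi * (0.71 * i + 0.71 * j) / 9) +
          sin(2 * pi * (0.97 * i - 0.26 * j) / 11) +
          sin(2 * pi * (0.26 * i - 0.97 * j) / 13)) / 3
  .margin_ridge_height / (1 + exp(-params$edge_sharpness * (i - ye))) -
    params$valley_depth * env + env * tex
}

#' Generate a synthetic supraorbital margin height map
#'
#' Evaluates the closed-form [margin_template()] on the grid and adds i.i.d.
#' Gaussian observation noise. Deterministic for fixed `(params, seed)`.
#'
#' @param params a [dimorphism_params()] object.
#' @param seed integer RNG seed.
#' @return A [height_map()].
#' @export
generate_margin_surface <- function(params, seed) {
  stopifnot(inherits(params, "dimorphism_params"))
  z <- margin_template(params)
  if (params$noise_sd > 0)
    z <- z + with_seed(seed, matrix(rnorm(length(z), 0, params$noise_sd),
                                    nrow(z), ncol(z)))
  height_map(z, .synthetic_spacing)
}

#' Closed-form frontal profile template
#'
#' The noise-free midsagittal forehead profile underlying
#' [generate_frontal_landmarks()]: a tilted logistic arc plus a Gaussian
#' frontal-eminence bump,
#' \deqn{y(x) = \tan(\phi)\, x + \frac{15}{1 + e^{-(x - 20)/5}} +
#'       A\, e^{-(x - 28)^2 / 32},}
#' where \eqn{\phi} is `forehead_slope` and `A` is `eminence_amplitude`;
#' x runs over \eqn{[0, 40]} voxels. With `eminence_amplitude = 0` this is
#' the slope-only template.
#'
#' @param x numeric vector of x positions (voxels).
#' @param params a [dimorphism_params()] object.
#' @return Numeric vector of template y values.
#' @export
frontal_template <- function(x, params) {
  stopifnot(inherits(params, "dimorphism_params"))
  tan(params$forehead_slope) * x +
    .frontal_arc_height / (1 + exp(-(x - .frontal_arc_mid) / .frontal_arc_width)) +
    params$eminence_amplitude *
      exp(-(x - .frontal_bump_x)^2 / (2 * .frontal_bump_sd^2))
}

#' Generate synthetic frontal-bone landmarks
#'
#' Samples `n_landmarks` ordered points from the [frontal_template()] profile
#' at equally spaced, strictly increasing x positions over \eqn{[0, 40]}
#' voxels, adding Gaussian noise to the measured y and z coordinates (the x
#' positions are the fixed sampling grid, so strict monotonicity is
#' guaranteed). z is zero in the template: the profile lies in the
#' midsagittal plane, and z noise emulates calibration error off-plane.
#'
#' @inheritParams generate_margin_surface
#' @return Numeric matrix `n_landmarks x 3` with columns `x`, `y`, `z`.
#' @export
generate_frontal_landmarks <- function(params, seed) {
  stopifnot(inherits(params, "dimorphism_params"))
  n <- params$n_landmarks
  x <- .frontal_x_extent * (0:(n - 1L)) / (n - 1L)
  y <- frontal_template(x, params)
  z <- numeric(n)
  if (params$noise_sd > 0) {
    eps <- with_seed(seed, matrix(rnorm(2L * n, 0, params$noise_sd), n, 2L))
    y <- y + eps[, 1L]
    z <- z + eps[, 2L]
  }
  cbind(x = x, y = y, z = z)
}

#' Generate a labelled synthetic population
#'
#' Produces `n_male` individuals labelled +1 and `n_female` labelled -1, each
#' with a margin height map and a frontal landmark set drawn under the
#' respective parameter set. Per-individual seeds are derived
#' deterministically from the master seed, so the whole population is
#' reproducible.
#'
#' @param n_male,n_female nonnegative counts.
#' @param male_params,female_params [dimorphism_params()] for each class;
#'   default [default_dimorphism_params()].
#' @param seed master RNG seed.
#' @return A list of `synthetic_individual` objects, each with fields `id`,
#'   `sex_label` (+1 male, -1 female), `margin` ([height_map()]) and
#'   `frontal_landmarks` (n x 3 matrix).
#' @examples
#' pop <- generate_population(3, 2, seed = 1)
#' vapply(pop, `[[`, numeric(1), "sex_label")
#' @export
generate_population <- function(n_male, n_female,
                                male_params = default_dimorphism_params("male"),
                                female_params = default_dimorphism_params("female"),
                                seed = 1L) {
  stopifnot(is_scalar_num(n_male), is_scalar_num(n_female),
            n_male >= 0, n_female >= 0,
            inherits(male_params, "dimorphism_params"),
            inherits(female_params, "dimorphism_params"))
  n_male <- as.integer(n_male); n_female <- as.integer(n_female)
  n <- n_male + n_female
  if (n == 0L) return(list())
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  labels <- c(rep(1L, n_male), rep(-1L, n_female))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    p <- if (labels[k] > 0) male_params else female_params
    out[[k]] <- structure(
      list(id = sprintf("%s%03d", if (labels[k] > 0) "M" else "F",
                        if (labels[k] > 0) k else k - n_male),
           sex_label = labels[k],
           margin = generate_margin_surface(p, sub_seeds[2L * k - 1L]),
           frontal_landmarks = generate_frontal_landmarks(p, sub_seeds[2L * k])),
      class = "synthetic_individual")
  }
  out
}

#' @export
print.synthetic_individual <- function(x, ...) {
  cat(sprintf("<synthetic_individual> id %s, sex %+d, margin %d x %d, %d landmarks\n",
              x$id, x$sex_label, nrow(x$margin$heights), ncol(x$margin$heights),
              nrow(x$frontal_landmarks)))
  invisible(x)
}

#' Write a synthetic population to disk
#'
#' Writes each individual's margin height map (`<id>_margin.csv`, plain CSV
#' matrix) and landmarks (`<id>_landmarks.csv`, columns x,y,z), plus a
#' `manifest.csv` (id, sex, file paths) that [run_pipeline()] can consume.
#'
#' @param population list from [generate_population()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest data frame.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(population, function(ind) {
    mf <- file.path(dir, paste0(ind$id, "_margin.csv"))
    lf <- file.path(dir, paste0(ind$id, "_landmarks.csv"))
    write_height_map_csv(ind$margin, mf)
    write_landmarks_csv(ind$frontal_landmarks, lf)
    data.frame(id = ind$id, sex = ind$sex_label, margin_file = mf,
               landmarks_file = lf, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
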