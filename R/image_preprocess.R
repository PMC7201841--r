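# Image preprocessing chain: grayscale conversion, bicubic upscaling, median
# filtering, fuzzy C-means segmentation, Canny contour extraction.

#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luminance: 0.299 R + 0.587 G + 0.114 B.
#'
#' @param rgb numeric array `rows x cols x 3` with channels in \[0, 1\].
#' @return Numeric matrix of intensities in \[0, 1\].
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("`rgb` must be a rows x cols x 3 array", call. = FALSE)
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 1)
    stop("channel values must lie in [0, 1]", call. = FALSE)
  out <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  if (!is.matrix(out)) out <- matrix(out, dim(rgb)[1L], dim(rgb)[2L])
  out
}

# Catmull-Rom (Keys, a = -0.5) cubic interpolation weight for offset t.
.keys_weight <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# out_len x in_len sparse-ish weight matrix mapping input samples to output
# positions under centre-aligned resampling with edge clamping.
.bicubic_weights <- function(in_len, out_len) {
  pos <- ((seq_len(out_len) - 0.5) * in_len / out_len) - 0.5  # 0-based source
  base <- floor(pos)
  W <- matrix(0, out_len, in_len)
  for (k in -1:2) {
    idx <- base + k                       # 0-based tap index
    w <- .keys_weight(pos - idx)
    idx <- pmin(pmax(idx, 0), in_len - 1L) + 1L   # clamp to image
    W[cbind(seq_len(out_len), idx)] <- W[cbind(seq_len(out_len), idx)] + w
  }
  W
}

#' Upscale a grayscale image by bicubic interpolation
#'
#' Separable Catmull-Rom cubic convolution with centre-aligned sampling and
#' edge clamping. Output dimensions are `round(factor * dim)`. A factor of 1
#' returns the image unchanged; constant images stay constant; linear ramps
#' are reproduced exactly away from borders.
#'
#' @param img numeric matrix of intensities.
#' @param factor scaling factor, at least 1.
#' @return Numeric matrix `round(factor * nrow) x round(factor * ncol)`.
#' @export
upscale <- function(img, factor = 2) {
  stop_if_not_matrix(img, "img")
  if (!is_scalar_num(factor) || factor < 1)
    stop("`factor` must be a scalar >= 1", call. = FALSE)
  out_r <- as.integer(round(factor * nrow(img)))
  out_c <- as.integer(round(factor * ncol(img)))
  if (out_r == nrow(img) && out_c == ncol(img)) return(img)
  Wr <- .bicubic_weights(nrow(img), out_r)
  Wc <- .bicubic_weights(ncol(img), out_c)
  Wr %*% img %*% t(Wc)
}

#' Median filter with edge replication
#'
#' Each output pixel is the median of its `window x window` neighbourhood;
#' borders are handled by replicating edge pixels. Smooths impulse noise
#' while preserving step edges.
#'
#' @param img numeric matrix.
#' @param window odd window side, at least 3.
#' @return Filtered matrix, same dimensions.
#' @export
median_filter <- function(img, window = 3L) {
  stop_if_not_matrix(img, "img")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  k <- (window - 1L) %/% 2L
  r <- nrow(img); c <- ncol(img)
  xp <- pad_replicate(img, k)
  stack <- array(0, c(r, c, window * window))
  s <- 0L
  for (di in 0:(window - 1L)) for (dj in 0:(window - 1L)) {
    s <- s + 1L
    stack[, , s] <- xp[(1L + di):(r + di), (1L + dj):(c + dj)]
  }
  apply(stack, c(1L, 2L), median)
}

#' Fuzzy C-means segmentation of a grayscale image
#'
#' Standard FCM on the pixel intensities: memberships
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{ik})^{2/(m-1)}} and centroids
#' \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m} are iterated until the
#' largest centroid shift falls below `tol`. The fuzzified within-cluster
#' objective \eqn{\sum u^m d^2} is non-increasing across iterations (tracked
#' in `objective`). Centroids are initialised at evenly spaced intensity
#' quantiles, so the result is deterministic; `seed` is accepted for
#' interface stability but the algorithm draws no random numbers.
#'
#' @param img numeric matrix of intensities.
#' @param c number of clusters (>= 2); default 2 (bone vs background).
#' @param fuzzifier fuzziness exponent m > 1; default 2.
#' @param tol centroid-shift convergence tolerance.
#' @param max_iter iteration cap.
#' @param seed unused RNG seed (kept for call-compatibility).
#' @return List with `memberships` (pixels x c, rows sum to 1), `centroids`
#'   (ascending), `labels` (matrix of argmax cluster per pixel), `n_iter`,
#'   `objective` (per-iteration trace) and `degenerate` (TRUE when all
#'   pixels are identical, with a warning).
#' @export
fcm_segment <- function(img, c = 2L, fuzzifier = 2, tol = 1e-5,
                        max_iter = 300L, seed = 1L) {
  stop_if_not_matrix(img, "img")
  c <- as.integer(c)
  if (c < 2L) stop("`c` must be at least 2", call. = FALSE)
  if (fuzzifier <= 1) stop("`fuzzifier` must exceed 1", call. = FALSE)
  x <- as.vector(img)
  if (diff(range(x)) == 0) {
    warning("all pixels identical: degenerate single-cluster segmentation")
    memb <- matrix(1 / c, length(x), c)
    return(list(memberships = memb, centroids = rep(x[1L], c),
                labels = matrix(1L, nrow(img), ncol(img)),
                n_iter = 0L, objective = numeric(0), degenerate = TRUE))
  }
  cent <- as.numeric(quantile(x, probs = (seq_len(c) - 0.5) / c, names = FALSE))
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, cent, function(a, b) (a - b)^2)
    d2 <- pmax(d2, .Machine$double.eps)          # exact hits: huge membership
    inv <- d2^(-1 / (fuzzifier - 1))   # (d_ij/d_ik)^{2/(m-1)} normalisation
    memb <- inv / rowSums(inv)
    um <- memb^fuzzifier
    obj <- c(obj, sum(um * d2))
    new_cent <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_cent - cent))
    cent <- new_cent
    if (shift < tol) break
  }
  ord <- order(cent)
  cent <- cent[ord]
  memb <- memb[, ord, drop = FALSE]
  list(memberships = memb, centroids = cent,
       labels = matrix(max.col(memb, ties.method = "first"),
                       nrow(img), ncol(img)),
       n_iter = it, objective = obj, degenerate = FALSE)
}

# --- Canny -------------------------------------------------------------------

.gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel1d(sigma)
  h <- matrix(k, nrow = 1L)
  xcorr2_reflect(xcorr2_reflect(img, h), t(h))
}

#' Canny contour extraction
#'
#' Gaussian smoothing at `sigma`, Sobel gradients, non-maximum suppression,
#' and hysteresis thresholding with `low`/`high` expressed as fractions of
#' the maximum gradient magnitude. Returns the longest 8-connected edge
#' chain, ordered by traversal from one of its endpoints.
#'
#' @param img numeric matrix of intensities.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 < low < high`.
#' @return Integer matrix `n x 2` of 0-based `(row, col)` contour points;
#'   zero rows (with a warning) when no edge is found.
#' @export
canny_contour <- function(img, sigma = 2, low = 0.1, high = 0.2) {
  stop_if_not_matrix(img, "img")
  if (!(low > 0 && low < high))
    stop("need 0 < low < high", call. = FALSE)
  sm <- .gaussian_blur(img, sigma)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)  # d/dcol
  gx <- xcorr2_reflect(sm, sx)
  gy <- xcorr2_reflect(sm, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) {
    warning("no edges found: gradient is zero everywhere")
    return(matrix(integer(0), 0L, 2L))
  }
  r <- nrow(img); c <- ncol(img)
  # non-maximum suppression along one of 4 quantised gradient directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4L)        # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, r, c)
  ri <- as.vector(matrix(seq_len(r), r, c))
  ci <- as.vector(matrix(seq_len(c), r, c, byrow = TRUE))
  magp <- pad_replicate(mag, 1L)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    n1 <- magp[cbind(ri + 1L + d[1L], ci + 1L + d[2L])]
    n2 <- magp[cbind(ri + 1L - d[1L], ci + 1L - d[2L])]
    keep <- keep | (sector == s & mag >= matrix(n1, r, c) & mag >= matrix(n2, r, c))
  }
  strong <- keep & (mag >= high * mmax)
  weak <- keep & (mag >= low * mmax)
  # hysteresis: grow strong set inside weak set (8-connectivity)
  edge <- strong
  repeat {
    grown <- .dilate8(edge) & weak
    if (identical(grown, edge)) break
    edge <- grown
  }
  if (!any(edge)) {
    warning("no edges found above the high threshold")
    return(matrix(integer(0), 0L, 2L))
  }
  .longest_chain(edge)
}

# 8-connected binary dilation with zero padding.
.dilate8 <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  mp <- matrix(FALSE, r + 2L, c + 2L)
  mp[2:(r + 1L), 2:(c + 1L)] <- mask
  out <- matrix(FALSE, r, c)
  for (di in 0:2) for (dj in 0:2)
    out <- out | mp[(1L + di):(r + di), (1L + dj):(c + dj)]
  out
}

# Largest 8-connected component of `mask`, ordered by depth-first traversal
# from an extreme point; 0-based (row, col) rows.
.longest_chain <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  lab <- matrix(0L, r, c)
  nlab <- 0L
  pts <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) {
    if (lab[pts[k, 1L], pts[k, 2L]] != 0L) next
    nlab <- nlab + 1L
    queue <- matrix(pts[k, ], 1L, 2L)
    lab[pts[k, 1L], pts[k, 2L]] <- nlab
    while (nrow(queue) > 0L) {
      p <- queue[nrow(queue), , drop = FALSE]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1L] + di; jj <- p[2L] + dj
        if (ii >= 1L && ii <= r && jj >= 1L && jj <= c &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nlab
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  best <- which.max(sizes)
  comp <- which(lab == best, arr.ind = TRUE)
  # order by DFS from the point with the fewest in-component neighbours
  inset <- matrix(FALSE, r, c); inset[comp] <- TRUE
  nnb <- function(p) {
    n <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- p[1L] + di; jj <- p[2L] + dj
      if (ii >= 1L && ii <= r && jj >= 1L && jj <= c && inset[ii, jj])
        n <- n + 1L
    }
    n
  }
  deg <- apply(comp, 1L, nnb)
  start <- comp[which.min(deg), ]
  visited <- matrix(FALSE, r, c)
  path <- matrix(0L, nrow(comp), 2L)
  stack <- matrix(start, 1L, 2L)
  np <- 0L
  while (nrow(stack) > 0L) {
    p <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    if (visited[p[1L], p[2L]]) next
    visited[p[1L], p[2L]] <- TRUE
    np <- np + 1L
    path[np, ] <- p
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- p[1L] + di; jj <- p[2L] + dj
      if (ii >= 1L && ii <= r && jj >= 1L && jj <= c &&
          inset[ii, jj] && !visited[ii, jj])
        stack <- rbind(stack, c(ii, jj))
    }
  }
  path[seq_len(np), , drop = FALSE] - 1L
}
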