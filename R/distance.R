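#' Derivative transform of an OD sequence
#'
#' Approximates the first derivative at each interior point as the mean of
#' the backward difference and the central difference:
#' `d_i = ((x_i - x_{i-1}) + (x_{i+1} - x_{i-1})/2) / 2`, in OD units per
#' time step. Endpoints are handled by replication (`d_1 = d_2`,
#' `d_n = d_{n-1}`) or dropped.
#'
#' @param x Numeric vector, length >= 3.
#' @param endpoints `"replicate"` (default, keeps length) or `"drop"`
#'   (returns length - 2).
#' @return Numeric vector of slope estimates.
#' @export
derivative_transform <- function(x, endpoints = c("replicate", "drop")) {
  endpoints <- match.arg(endpoints)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("derivative transform needs at least 3 points")
  i <- 2:(n - 1)
  d <- ((x[i] - x[i - 1]) + (x[i + 1] - x[i - 1]) / 2) / 2
  if (endpoints == "drop") return(d)
  c(d[1], d, d[length(d)])
}

#' Exact dynamic time warping distance
#'
#' Full O(nm) dynamic program with local cost `|a_i - b_j|`, steps
#' \{diagonal, up, right\}, no window, unnormalized path sum. Sequences may
#' differ in length. Not a metric (the triangle inequality can fail), but
#' symmetric, non-negative, and zero iff the sequences are identical.
#'
#' @param a,b Numeric vectors (length >= 1).
#' @return Non-negative scalar.
#' @export
dtw_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("empty sequence")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  .dtw_exact_cpp(a, b)
}

#' Multiresolution approximate DTW (fastdtw)
#'
#' Recursively coarsens both sequences by averaging adjacent pairs, solves
#' the coarse problem, projects the warping path up one resolution, and
#' refines within `radius` cells of it. The result is always an upper
#' bound on [dtw_exact()] and equals it when `radius >= max(length(a),
#' length(b))`. Deterministic. Note the small-radius band makes the
#' distance sensitive to time shifts that unconstrained DTW would warp
#' away — for growth curves this is what lets lag-phase differences
#' register in the DTW term.
#'
#' @inheritParams dtw_exact
#' @param radius Integer >= 0 refinement radius (default 1).
#' @return Non-negative scalar, `>= dtw_exact(a, b)`.
#' @export
dtw_fast <- function(a, b, radius = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0) stop("radius must be a non-negative integer")
  if (length(a) < 1 || length(b) < 1) stop("empty sequence")
  .dtw_fast_cpp(a, b, radius)
}

#' Derivative DTW distance
#'
#' DTW applied to the [derivative_transform()] of each input, so level
#' offsets vanish and only the slope profile matters:
#' `ddtw(x, x + c) == 0`. The default engine is the exact dynamic program.
#'
#' @inheritParams dtw_exact
#' @param mode `"exact"` (default) or `"fast"`.
#' @param radius Radius for `mode = "fast"`.
#' @param endpoints Endpoint convention passed to [derivative_transform()].
#' @return Non-negative scalar.
#' @export
ddtw_distance <- function(a, b, mode = c("exact", "fast"), radius = 1L,
                          endpoints = "replicate") {
  mode <- match.arg(mode)
  da <- derivative_transform(a, endpoints)
  db <- derivative_transform(b, endpoints)
  if (mode == "exact") dtw_exact(da, db) else dtw_fast(da, db, radius)
}

#' Pairwise distance matrix over a set of curves
#'
#' @param curves A `curve_collection` or list of `growth_curve` objects.
#' @param metric `"dtw"` or `"ddtw"`.
#' @param mode Engine: `"fast"` (default for DTW) or `"exact"` (default
#'   for DDTW).
#' @param radius fastdtw radius when `mode = "fast"`.
#' @param endpoints DDTW endpoint convention.
#' @return Symmetric matrix with zero diagonal, dimnames = curve ids.
#' @export
pairwise_matrix <- function(curves, metric = c("dtw", "ddtw"), mode = NULL,
                            radius = 1L, endpoints = "replicate") {
  metric <- match.arg(metric)
  if (inherits(curves, "curve_collection")) curves <- curves$curves
  n <- length(curves)
  if (n < 2) stop("need at least 2 curves")
  if (is.null(mode)) mode <- if (metric == "dtw") "fast" else "exact"
  mode <- match.arg(mode, c("fast", "exact"))
  seqs <- lapply(curves, function(c) if (inherits(c, "growth_curve")) c$od else as.numeric(c))
  if (metric == "ddtw")
    seqs <- lapply(seqs, derivative_transform, endpoints = endpoints)
  fn <- if (mode == "exact") function(x, y) .dtw_exact_cpp(x, y)
        else function(x, y) .dtw_fast_cpp(x, y, as.integer(radius))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      D[i, j] <- D[j, i] <- fn(seqs[[i]], seqs[[j]])
  ids <- if (inherits(curves[[1]], "growth_curve"))
    vapply(curves, curve_id, character(1)) else as.character(seq_len(n))
  dimnames(D) <- list(ids, ids)
  D
}

#' Global DTW/DDTW scaling factor
#'
#' Ratio of the mean off-diagonal DTW distance to the mean off-diagonal
#' DDTW distance. Multiplying the DDTW matrix by this factor aligns the
#' average magnitudes of the two terms, so the mixing weight alpha acts as
#' a true proportion. Dataset-specific — recomputed for every matrix pair.
#'
#' @param dtw_matrix,ddtw_matrix Symmetric matrices of equal shape.
#' @return Positive scalar.
#' @export
scaling_factor <- function(dtw_matrix, ddtw_matrix) {
  if (!all(dim(dtw_matrix) == dim(ddtw_matrix)))
    stop("matrices must have the same shape")
  off <- upper.tri(dtw_matrix) | lower.tri(dtw_matrix)
  if (!any(off)) stop("need at least one off-diagonal entry")
  md <- mean(ddtw_matrix[off])
  if (md <= 0)
    stop("all-zero DDTW matrix: curves are identical up to level offsets; use alpha = 0")
  mean(dtw_matrix[off]) / md
}

#' Bundle DTW and DDTW matrices with their scaling factor
#'
#' Convenience wrapper computing both pairwise matrices and the
#' [scaling_factor()] once, for reuse across the whole (alpha, n) grid.
#'
#' @inheritParams pairwise_matrix
#' @param dtw_mode,ddtw_mode Engines for the two matrices (defaults:
#'   fastdtw radius 1 for DTW, exact DP for DDTW).
#' @return Object of class `distance_bundle`: `labels`, `dtw`, `ddtw`,
#'   `scale`, and the engine settings.
#' @export
distance_bundle <- function(curves, dtw_mode = "fast", ddtw_mode = "exact",
                            radius = 1L, endpoints = "replicate") {
  dtw <- pairwise_matrix(curves, "dtw", dtw_mode, radius, endpoints)
  ddtw <- pairwise_matrix(curves, "ddtw", ddtw_mode, radius, endpoints)
  structure(list(labels = rownames(dtw), dtw = dtw, ddtw = ddtw,
                 scale = scaling_factor(dtw, ddtw),
                 dtw_mode = dtw_mode, ddtw_mode = ddtw_mode,
                 radius = as.integer(radius), endpoints = endpoints),
            class = "distance_bundle")
}

#' @export
print.distance_bundle <- function(x, ...) {
  cat(sprintf("<distance_bundle> %d curves, scale = %.4g (dtw: %s%s, ddtw: %s)\n",
              nrow(x$dtw), x$scale, x$dtw_mode,
              if (x$dtw_mode == "fast") sprintf(" r=%d", x$radius) else "",
              x$ddtw_mode))
  invisible(x)
}

#' Alpha-combined distance matrix
#'
#' `(1 - alpha) * DTW + alpha * scale * DDTW`, entrywise. `alpha = 0`
#' reproduces the DTW matrix, `alpha = 1` the rescaled DDTW matrix; the
#' map is linear in alpha.
#'
#' @param bundle A [distance_bundle()].
#' @param alpha Mixing weight in \[0, 1\].
#' @return Symmetric matrix with zero diagonal.
#' @export
combined_matrix <- function(bundle, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a scalar in [0, 1]")
  (1 - alpha) * bundle$dtw + alpha * bundle$scale * bundle$ddtw
}
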