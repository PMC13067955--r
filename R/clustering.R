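#' UPGMA flat clustering of a distance matrix
#'
#' Builds the average-linkage (UPGMA) dendrogram and cuts it into exactly
#' `n` flat clusters. Cluster ids are 0-based and ordered by decreasing
#' cluster size, so cluster 0 is always the largest (baseline) group;
#' equal-sized clusters keep the order of their original dendrogram ids.
#'
#' @param D Symmetric distance matrix (zero diagonal); dimnames become
#'   curve ids.
#' @param n Number of clusters, `2 <= n <= nrow(D)`.
#' @return Named integer vector of cluster ids (0-based).
#' @export
upgma_labels <- function(D, n) {
  n <- as.integer(n)
  if (n < 2 || n > nrow(D)) stop("n out of range")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  relabel_by_size(stats::cutree(hc, k = n))
}

# map raw cutree labels to 0-based ids ordered by decreasing size,
# ties broken by smallest original id
relabel_by_size <- function(raw) {
  tab <- table(raw)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  remap <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  out <- remap[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Mean silhouette coefficient from a precomputed distance matrix
#'
#' For each point, cohesion `a` is its mean distance to the rest of its
#' own cluster and separation `b` the smallest mean distance to any other
#' cluster; the silhouette is `(b - a) / max(a, b)`. Members of singleton
#' clusters contribute 0. Returns the mean over all points, in \[-1, 1\].
#'
#' @param D Symmetric distance matrix.
#' @param labels Cluster assignment, one id per row of `D` (>= 2 distinct).
#' @return Scalar mean silhouette.
#' @export
silhouette_precomputed <- function(D, labels) {
  labels <- as.vector(labels)
  ks <- unique(labels)
  if (length(ks) < 2) stop("need at least 2 clusters")
  f <- factor(labels, levels = ks)
  cnt <- as.integer(table(f))
  S <- t(rowsum(D, f))            # n x k: summed distance from i to cluster k
  own <- as.integer(f)
  n <- nrow(D)
  idx <- cbind(seq_len(n), own)
  a <- S[idx] / pmax(cnt[own] - 1L, 1L)
  Sb <- sweep(S, 2, cnt, "/")
  Sb[idx] <- Inf
  b <- apply(Sb, 1, min)
  s <- (b - a) / pmax(a, b)
  s[cnt[own] == 1L] <- 0
  s[!is.finite(s)] <- 0           # a = b = 0 (coincident points)
  mean(s)
}

#' Davies-Bouldin index for precomputed distances (medoid variant)
#'
#' The classic index with each cluster centroid replaced by its medoid
#' (the member minimizing summed within-cluster distance) and scatter
#' defined as the mean distance to the medoid. Lower is better. Cluster
#' pairs whose medoids coincide at distance 0 with zero scatter
#' contribute 0.
#'
#' @inheritParams silhouette_precomputed
#' @return Non-negative scalar.
#' @export
davies_bouldin_medoid <- function(D, labels) {
  labels <- as.vector(labels)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2) stop("need at least 2 clusters")
  medoid <- integer(k); scatter <- numeric(k)
  for (ki in seq_len(k)) {
    idx <- which(labels == ks[ki])
    sums <- rowSums(D[idx, idx, drop = FALSE])
    medoid[ki] <- idx[which.min(sums)]
    scatter[ki] <- mean(D[idx, medoid[ki]])
  }
  worst <- numeric(k)
  for (i in seq_len(k)) {
    r <- 0
    for (j in seq_len(k)) {
      if (i == j) next
      sep <- D[medoid[i], medoid[j]]
      num <- scatter[i] + scatter[j]
      r <- max(r, if (sep > 0) num / sep else if (num > 0) Inf else 0)
    }
    worst[i] <- r
  }
  mean(worst)
}

#' Silhouette / split-count grid over (alpha, n)
#'
#' For each mixing weight alpha, clusters the combined distance matrix
#' once and cuts the same dendrogram at every n, recording the mean
#' silhouette, its successive differences, and (when replicate groups are
#' supplied) the number of curves whose replicate group is split across
#' clusters, plus a 3-point moving average of those counts along n.
#'
#' @param bundle A [distance_bundle()].
#' @param alphas Mixing weights (default 0, 0.1, ..., 1).
#' @param ns Cluster numbers (default 2:100, clipped to the curve count).
#' @param groups Optional named list mapping strain to curve ids (or a
#'   `curve_collection`), enabling split counts.
#' @param window Moving-average window for split smoothing (default 3).
#' @return Object of class `cluster_grid`: `alphas`, `ns`, matrices `sc`,
#'   `delta_sc` (alpha x (|ns|-1)), and if groups were given
#'   `split_counts` and `smoothed_splits`.
#' @export
sc_grid <- function(bundle, alphas = seq(0, 1, by = 0.1), ns = 2:100,
                    groups = NULL, window = 3L) {
  ncur <- nrow(bundle$dtw)
  ns <- as.integer(ns[ns >= 2 & ns <= ncur])
  if (length(ns) == 0) stop("no valid cluster numbers")
  if (inherits(groups, "curve_collection")) {
    ids <- curve_ids(groups)
    groups <- lapply(groups$groups, function(ix) ids[ix])
  }
  sc <- matrix(NA_real_, length(alphas), length(ns),
               dimnames = list(sprintf("a%.2f", alphas), sprintf("n%d", ns)))
  splits <- if (!is.null(groups)) sc * NA else NULL
  for (ai in seq_along(alphas)) {
    D <- combined_matrix(bundle, alphas[ai])
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    cuts <- stats::cutree(hc, k = ns)
    for (ni in seq_along(ns)) {
      lab <- cuts[, ni]
      sc[ai, ni] <- silhouette_precomputed(D, lab)
      if (!is.null(groups)) {
        named <- stats::setNames(lab, rownames(bundle$dtw))
        splits[ai, ni] <- replicate_split_counts(named, groups)
      }
    }
  }
  delta <- sc[, -1, drop = FALSE] - sc[, -ncol(sc), drop = FALSE]
  smoothed <- if (!is.null(splits))
    t(apply(splits, 1, smooth_counts, window = window)) else NULL
  structure(list(alphas = alphas, ns = ns, sc = sc, delta_sc = delta,
                 split_counts = splits, smoothed_splits = smoothed),
            class = "cluster_grid")
}

#' @export
print.cluster_grid <- function(x, ...) {
  cat(sprintf("<cluster_grid> %d alphas x %d cluster numbers (sc%s)\n",
              length(x$alphas), length(x$ns),
              if (is.null(x$split_counts)) "" else ", splits"))
  invisible(x)
}

#' Reverse-elbow selection of (alpha, n)
#'
#' As n grows the silhouette first declines slowly and then drops
#' sharply; the cluster number just before the sharpest single-step drop
#' is taken as optimal. The drop is scored per (alpha, n -> n+1) cell;
#' the most negative difference wins, ties going to the smaller n and
#' then the smaller alpha. All per-alpha best drops are returned ranked,
#' so secondary optima stay visible.
#'
#' @param grid A [sc_grid()] result.
#' @return List with `alpha`, `n`, and `ranked` (data frame alpha, n,
#'   delta_sc sorted best first).
#' @export
reverse_elbow_select <- function(grid) {
  d <- grid$delta_sc
  if (is.null(d) || !length(d)) stop("empty grid")
  cand <- expand.grid(ai = seq_along(grid$alphas), ni = seq_len(ncol(d)))
  cand$alpha <- grid$alphas[cand$ai]
  cand$n <- grid$ns[cand$ni]
  cand$delta_sc <- d[cbind(cand$ai, cand$ni)]
  # drops within 1e-12 of each other count as tied, so the n/alpha
  # tie-breaks are not decided by floating-point dust
  tied <- cand$delta_sc <= min(cand$delta_sc) + 1e-12
  cand <- rbind(cand[tied, ][order(cand$n[tied], cand$alpha[tied]), ],
                cand[!tied, ][order(cand$delta_sc[!tied], cand$n[!tied],
                                    cand$alpha[!tied]), ])
  per_alpha <- cand[!duplicated(cand$ai), c("alpha", "n", "delta_sc")]
  per_alpha <- per_alpha[order(per_alpha$delta_sc, per_alpha$n, per_alpha$alpha), ]
  rownames(per_alpha) <- NULL
  list(alpha = cand$alpha[1], n = cand$n[1], ranked = per_alpha)
}

#' Count curves whose replicate group is split across clusters
#'
#' Every member of a split group counts, so one triplicate split 2|1
#' contributes 3.
#'
#' @param labels Named cluster assignment (names = curve ids).
#' @param groups Named list mapping strain to its curve ids, or a
#'   `curve_collection`.
#' @return Integer count.
#' @export
replicate_split_counts <- function(labels, groups) {
  if (inherits(groups, "curve_collection")) {
    ids <- curve_ids(groups)
    groups <- lapply(groups$groups, function(ix) ids[ix])
  }
  total <- 0L
  for (g in groups) {
    if (length(g) < 2) next
    if (length(unique(labels[g])) > 1) total <- total + length(g)
  }
  total
}

#' Centered moving average with shrinking edges
#'
#' @param counts Numeric vector (values along the n axis).
#' @param window Odd window size (default 3); at the edges the window
#'   shrinks to the available neighbors.
#' @return Numeric vector, same length.
#' @export
smooth_counts <- function(counts, window = 3L) {
  n <- length(counts)
  if (n == 0) stop("empty input")
  half <- as.integer(window) %/% 2L
  vapply(seq_len(n), function(i)
    mean(counts[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Replicate-coherence selection of (alpha, n)
#'
#' Among grid cells whose split count is within `tolerance` of the
#' global minimum, picks the largest cluster number — the finest
#' partition with the lowest tendency to separate experimental
#' replicates. Remaining ties prefer the alpha closest to 0.5 (balanced
#' DTW/DDTW weighting), then the smaller alpha. Selection uses the raw
#' per-cell counts; the 3-point moving average (`smoothed_splits`) is
#' the reported mean frequency but would mask the last split-free n at
#' a sharp onset, so it does not drive the choice.
#'
#' @param grid A [sc_grid()] result computed with `groups`.
#' @param tolerance Allowed excess over the minimum split count
#'   (default 0).
#' @return List with `alpha`, `n`, and `frontier` (data frame of all
#'   cells at the tolerated minimum).
#' @export
select_by_replicate_rule <- function(grid, tolerance = 0) {
  sm <- grid$split_counts
  if (is.null(sm)) stop("grid has no split counts; pass groups to sc_grid()")
  gmin <- min(sm)
  ok <- which(sm <= gmin + tolerance, arr.ind = TRUE)
  frontier <- data.frame(alpha = grid$alphas[ok[, 1]], n = grid$ns[ok[, 2]],
                         splits = sm[ok],
                         smoothed = grid$smoothed_splits[ok])
  frontier <- frontier[order(-frontier$n, abs(frontier$alpha - 0.5),
                             frontier$alpha), ]
  rownames(frontier) <- NULL
  list(alpha = frontier$alpha[1], n = frontier$n[1], frontier = frontier)
}

#' Project an external reference curve onto an existing clustering
#'
#' Assigns the curve to the cluster minimizing the mean alpha-combined
#' distance to the cluster's members (the assignment consistent with
#' average linkage). Ties go to the lower cluster id.
#'
#' @param curve A `growth_curve` (e.g. the wild-type reference).
#' @param collection The clustered `curve_collection`.
#' @param labels Named cluster ids for the collection's curves.
#' @param bundle The [distance_bundle()] used for clustering (provides the
#'   DDTW scale and engine settings).
#' @param alpha Mixing weight used for the clustering.
#' @return The assigned cluster id (scalar).
#' @export
project_reference <- function(curve, collection, labels, bundle, alpha) {
  d_dtw <- vapply(collection$curves, function(c)
    if (bundle$dtw_mode == "exact") dtw_exact(curve$od, c$od)
    else dtw_fast(curve$od, c$od, bundle$radius), numeric(1))
  d_ddtw <- vapply(collection$curves, function(c)
    ddtw_distance(curve$od, c$od, mode = bundle$ddtw_mode,
                  radius = bundle$radius, endpoints = bundle$endpoints),
    numeric(1))
  comb <- (1 - alpha) * d_dtw + alpha * bundle$scale * d_ddtw
  labs <- labels[curve_ids(collection)]
  means <- tapply(comb, labs, mean)
  ids <- as.numeric(names(means))
  best <- which(means <= min(means) + 1e-12)
  ids[best[which.min(ids[best])]]
}

#' Parametric growth-model baseline (Gompertz/logistic + K-means)
#'
#' The conventional alternative to shape-based clustering: fit each curve
#' with the reparameterized Gompertz model
#' `K * exp(-exp(mu * e / K * (lambda - t) + 1))` and the logistic model
#' `K / (1 + exp(-mu * (t - t0)))`, keep the better fit by AIC, and
#' K-means-cluster the fitted (growth rate, carrying capacity) pairs.
#' Fits that fail to converge — the expected outcome on flat or aberrant
#' trajectories — are flagged and fall back to their data-derived
#' starting values, mirroring what naive parameter pipelines do.
#'
#' @param curves A `curve_collection` or list of `growth_curve`s.
#' @param k Number of K-means clusters.
#' @param seed RNG seed for K-means (10 restarts).
#' @return List with `params` (data frame: curve, model, rate, capacity,
#'   converged) and `labels` (named K-means cluster ids, 0-based, size
#'   ordered).
#' @export
parametric_baseline <- function(curves, k = 2L, seed = 1L) {
  if (inherits(curves, "curve_collection")) curves <- curves$curves
  fit1 <- function(curve) {
    t <- curve$times; y <- curve$od
    K0 <- max(y)
    sl <- diff(y) / diff(t)
    mu0 <- max(sl)
    tm0 <- t[which.max(sl)]
    gomp <- tryCatch(
      minpack.lm::nlsLM(y ~ K * exp(-exp(mu * exp(1) / K * (lambda - t) + 1)),
                        start = list(K = K0, mu = max(mu0, 1e-3), lambda = tm0),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    logi <- tryCatch(
      minpack.lm::nlsLM(y ~ K / (1 + exp(-mu * (t - t0))),
                        start = list(K = K0, mu = max(mu0, 1e-3), t0 = tm0),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    pick <- NULL; model <- NA_character_
    if (!is.null(gomp) && (is.null(logi) || stats::AIC(gomp) <= stats::AIC(logi))) {
      pick <- gomp; model <- "gompertz"
    } else if (!is.null(logi)) {
      pick <- logi; model <- "logistic"
    }
    if (is.null(pick))
      return(data.frame(curve = curve_id(curve), model = "none",
                        rate = mu0, capacity = K0, converged = FALSE,
                        stringsAsFactors = FALSE))
    cf <- stats::coef(pick)
    conv <- isTRUE(pick$convInfo$isConv)
    data.frame(curve = curve_id(curve), model = model,
               rate = unname(cf["mu"]), capacity = unname(cf["K"]),
               converged = conv, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, lapply(curves, fit1))
  feats <- scale(cbind(params$rate, params$capacity))
  feats[!is.finite(feats)] <- 0
  raw <- if (nrow(feats) <= k) seq_len(nrow(feats))
         else withr_seed(seed, stats::kmeans(feats, centers = k, nstart = 10))$cluster
  labels <- relabel_by_size(raw)
  names(labels) <- params$curve
  list(params = params, labels = labels)
}
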