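dist_1d <- function(x) {
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(as.character(seq_along(x)), as.character(seq_along(x)))
  D
}

test_that("UPGMA cuts recover obvious 1-D structure with size-ordered ids", {
  D <- dist_1d(c(0, 1, 10, 11))
  lab <- upgma_labels(D, 2)
  expect_equal(lab[["1"]], lab[["2"]])
  expect_equal(lab[["3"]], lab[["4"]])
  expect_true(lab[["1"]] != lab[["3"]])
  expect_setequal(unique(lab), c(0L, 1L))
  # n = number of points: all singletons
  expect_equal(sort(unique(upgma_labels(D, 4))), 0:3)
  # duplicates merge first
  D2 <- dist_1d(c(0, 0, 5, 9))
  expect_equal(unname(upgma_labels(D2, 3)[1:2]), c(0L, 0L))
  # cluster 0 is the largest
  D3 <- dist_1d(c(0, 0.5, 1, 20))
  expect_equal(unname(table(upgma_labels(D3, 2))[["0"]]), 3L)
  expect_error(upgma_labels(D, 5), "out of range")
})

test_that("silhouette matches the hand example and a brute-force oracle", {
  D <- dist_1d(c(0, 1, 10))
  s <- silhouette_precomputed(D, c(1, 1, 2))
  expect_equal(s, (0.9 + 8 / 9 + 0) / 3, tolerance = 1e-12)
  # two well-separated identical pairs: a = 0 everywhere
  D2 <- dist_1d(c(0, 0, 8, 8))
  expect_equal(silhouette_precomputed(D2, c(1, 1, 2, 2)), 1.0)
  set.seed(17)
  for (i in 1:15) {
    n <- sample(5:30, 1); k <- sample(2:4, 1)
    x <- runif(n) * 10
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_precomputed(dist_1d(x), lab),
                 silhouette_brute(dist_1d(x), lab), tolerance = 1e-9)
  }
  expect_error(silhouette_precomputed(D, c(1, 1, 1)), "2 clusters")
})

test_that("medoid Davies-Bouldin handles degenerate and symmetric layouts", {
  D <- dist_1d(c(0, 5))
  expect_equal(davies_bouldin_medoid(D, c(1, 2)), 0)
  # collinear triplets: medoid = centroid, scatter 2/3, separation 10
  D2 <- dist_1d(c(0, 1, 2, 10, 11, 12))
  expect_equal(davies_bouldin_medoid(D2, c(1, 1, 1, 2, 2, 2)), (2 / 3 + 2 / 3) / 10)
  expect_error(davies_bouldin_medoid(D, c(1, 1)), "2 clusters")
})

test_that("the silhouette grid is dense and successive cuts nest", {
  set.seed(2)
  cur <- lapply(1:12, function(i)
    make_curve(sigmoid_od(A = c(0.3, 0.8)[1 + i %% 2] + runif(1, 0, 0.05)), "s", i))
  b <- distance_bundle(cur)
  g <- sc_grid(b, alphas = c(0, 0.5, 1), ns = 2:8)
  expect_equal(dim(g$sc), c(3L, 7L))
  expect_equal(dim(g$delta_sc), c(3L, 6L))
  expect_true(all(g$sc >= -1 & g$sc <= 1))
  # hierarchical nesting: cutting at n and n+1 splits exactly one cluster
  D <- combined_matrix(b, 0.5)
  hc <- hclust(as.dist(D), "average")
  for (n in 2:6) {
    a <- cutree(hc, n); bb <- cutree(hc, n + 1)
    split_sizes <- vapply(unique(a), function(k) length(unique(bb[a == k])), 1L)
    expect_equal(sum(split_sizes > 1), 1L)
    expect_equal(max(split_sizes), 2L)
  }
})

test_that("reverse elbow picks the n just before the sharpest SC drop", {
  mk_grid <- function(sc, alphas, ns) structure(
    list(alphas = alphas, ns = ns, sc = sc,
         delta_sc = sc[, -1, drop = FALSE] - sc[, -ncol(sc), drop = FALSE]),
    class = "cluster_grid")
  g <- mk_grid(matrix(c(0.9, 0.88, 0.86, 0.5, 0.48), 1), 0.5, 2:6)
  sel <- reverse_elbow_select(g)
  expect_equal(sel$n, 4L)
  expect_equal(sel$alpha, 0.5)
  # linear decline: every drop ties -> smallest n
  g2 <- mk_grid(matrix(seq(0.9, 0.5, length.out = 5), 1), 0.5, 2:6)
  expect_equal(reverse_elbow_select(g2)$n, 2L)
  # equal drops at two alphas -> smaller alpha
  sc3 <- rbind(c(0.9, 0.4, 0.38), c(0.9, 0.4, 0.38))
  g3 <- mk_grid(sc3, c(0.2, 0.7), 2:4)
  expect_equal(reverse_elbow_select(g3)$alpha, 0.2)
  expect_equal(nrow(reverse_elbow_select(g3)$ranked), 2L)
})

test_that("split counting charges every curve of a split group", {
  labs <- setNames(c(0, 0, 0, 0, 1, 1), paste0(rep(c("a", "b"), each = 3), ":", 1:3))
  groups <- list(a = paste0("a:", 1:3), b = paste0("b:", 1:3))
  expect_equal(replicate_split_counts(labs, groups), 3L)  # b split 1|2
  labs2 <- setNames(rep(0, 6), names(labs))
  expect_equal(replicate_split_counts(labs2, groups), 0L)
  labs3 <- setNames(1:6, names(labs))   # everything apart
  expect_equal(replicate_split_counts(labs3, groups), 6L)
})

test_that("moving average shrinks its window at the edges", {
  expect_equal(smooth_counts(c(0, 0, 3, 6)), c(0, 1, 3, 4.5))
  expect_equal(smooth_counts(rep(2, 5)), rep(2, 5))
  expect_equal(smooth_counts(7), 7)
})

test_that("replicate rule takes the largest split-free n, preferring alpha near 0.5", {
  mk <- function(splits, alphas, ns) structure(
    list(alphas = alphas, ns = ns, split_counts = splits,
         smoothed_splits = t(apply(splits, 1, smooth_counts))),
    class = "cluster_grid")
  g <- mk(matrix(c(0, 0, 5, 9), 1), 0.5, 2:5)   # zero for n <= 3
  expect_equal(select_by_replicate_rule(g)$n, 3L)
  g2 <- mk(matrix(0, 2, 4), c(0.3, 0.6), 2:5)   # degenerate: zero everywhere
  expect_equal(select_by_replicate_rule(g2)$n, 5L)
  # same zero plateau at two alphas -> alpha closest to 0.5
  g3 <- mk(rbind(c(0, 0, 4), c(0, 0, 4)), c(0.1, 0.4), 2:4)
  expect_equal(select_by_replicate_rule(g3)$alpha, 0.4)
  # tolerance can only extend the admissible n upward
  g4 <- mk(matrix(c(0, 0, 2, 9), 1), 0.5, 2:5)
  expect_gte(select_by_replicate_rule(g4, tolerance = 2)$n,
             select_by_replicate_rule(g4, tolerance = 0)$n)
})

test_that("reference curves project into the nearest-mean cluster", {
  set.seed(8)
  cur <- c(lapply(1:4, function(i) make_curve(sigmoid_od() * (1 + 0.01 * i), "n", i)),
           lapply(1:4, function(i) make_curve(rep(0.06, 96) * (1 + 0.01 * i), "f", i)))
  coll <- curve_collection(cur)
  b <- distance_bundle(coll)
  lab <- upgma_labels(combined_matrix(b, 0.5), 2)
  wt <- make_curve(sigmoid_od(A = 0.82), "wt", 1)
  expect_equal(project_reference(wt, coll, lab, b, 0.5), unname(lab[["n:1"]]))
  twin <- make_curve(cur[[5]]$od, "wt", 1)
  expect_equal(project_reference(twin, coll, lab, b, 0.5), unname(lab[["f:1"]]))
})

test_that("parametric fits recover noiseless Gompertz parameters within 1%", {
  t <- seq(0, by = 0.25, length.out = 96)
  od <- gompertz_curve(A = 0.8, mu = 0.6, lambda = 3, baseline = 0, times = t)
  cur <- growth_curve("g", 1, t, od)
  res <- parametric_baseline(list(cur, make_curve(rep(0.05, 96), "f", 1)), k = 2)
  p <- res$params[res$params$curve == "g:1", ]
  expect_equal(p$capacity, 0.8, tolerance = 0.01)
  expect_equal(p$rate, 0.6, tolerance = 0.01)
  expect_true(p$converged)
  # the flat curve is degenerate: tiny fitted capacity or a flagged fit
  f <- res$params[res$params$curve == "f:1", ]
  expect_true(!f$converged || f$capacity < 0.2)
})
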