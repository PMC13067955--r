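test_that("within-replicate pairs enumerate each group's combinations", {
  cur <- c(lapply(1:3, function(i) make_curve(sigmoid_od() * (1 + 0.01 * i), "a", i)),
           lapply(1:2, function(i) make_curve(sigmoid_od(), "b", i)),
           list(make_curve(sigmoid_od(), "c", 1)))
  coll <- curve_collection(cur)
  coll$curves <- lapply(coll$curves, function(c) { c$stage <- "preprocessed"; c })
  p <- within_replicate_pairs(coll)
  expect_equal(table(p$strain)[["a"]], 3L)
  expect_equal(table(p$strain)[["b"]], 1L)
  expect_false("c" %in% p$strain)
  expect_true(all(p$dtw >= 0) && all(p$ddtw >= 0))
})

test_that("quantile thresholds interpolate linearly and are monotone in q", {
  expect_equal(quantile_threshold(c(1, 2, 3, 4), 0.25), 1.75)
  expect_equal(quantile_threshold(rep(7, 5), 0.5), 7)
  v <- runif(50)
  qs <- c(0.05, 0.2, 0.5, 0.9)
  th <- vapply(qs, function(q) quantile_threshold(v, q), numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_equal(quantile_threshold(v, 1e-9), min(v), tolerance = 1e-6)
  expect_error(quantile_threshold(numeric(0), 0.5), "empty")
})

test_that("joint cleaning retains exactly the curves in double-passing pairs", {
  cur <- unlist(lapply(letters[1:4], function(s)
    lapply(1:3, function(i) make_curve(sigmoid_od(), s, i))), recursive = FALSE)
  coll <- curve_collection(cur)
  # hand-built pair table: strain a's (1,2) pair is tight on both metrics,
  # its pairs with replicate 3 are far; other strains are tight throughout
  mk <- function(s, i, j, d1, d2)
    data.frame(strain = s, id_i = paste0(s, ":", i), id_j = paste0(s, ":", j),
               dtw = d1, ddtw = d2)
  pairs <- rbind(
    mk("a", 1, 2, 0.1, 0.001), mk("a", 1, 3, 9, 0.5), mk("a", 2, 3, 9, 0.5),
    mk("b", 1, 2, 0.2, 0.002), mk("b", 1, 3, 0.2, 0.002), mk("b", 2, 3, 0.2, 0.002),
    mk("c", 1, 2, 0.2, 0.002), mk("c", 1, 3, 0.2, 0.002), mk("c", 2, 3, 0.2, 0.002),
    mk("d", 1, 2, 5, 0.0005), mk("d", 1, 3, 0.15, 0.4), mk("d", 2, 3, 5, 0.4))
  res <- clean_collection(coll, pairs, q = 0.7)
  ids <- curve_ids(res$collection)
  expect_true(all(c("a:1", "a:2") %in% ids))
  expect_false("a:3" %in% ids)
  expect_true(all(paste0("b:", 1:3) %in% ids))   # every pair passes
  # strain d: passes dtw via one pair, ddtw via another -> joint excludes,
  # independent includes
  expect_false(any(grepl("^d:", ids)))
  res_ind <- clean_collection(coll, pairs, q = 0.7, pair_mode = "independent")
  expect_true("d:1" %in% curve_ids(res_ind$collection))
  # thresholds are the pooled quantiles of the pre-cleaning pair list
  expect_equal(res$report$dtw_threshold, quantile_threshold(pairs$dtw, 0.7))
  expect_equal(res$report$ddtw_threshold, quantile_threshold(pairs$ddtw, 0.7))
})

test_that("retained sets nest across the sensitivity scan", {
  sim <- simulate_collection(sim_config(n_strains = 25, seed = 5))
  pre <- preprocess_collection(sim$collection)
  pairs <- within_replicate_pairs(pre$collection)
  scan <- sensitivity_scan(pre$collection, pairs)
  sets <- lapply(scan, function(x) curve_ids(x$collection))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  # near-1 quantile retains every curve that appears in some pair
  all_q <- clean_collection(pre$collection, pairs, q = 0.9999)
  in_pairs <- unique(c(pairs$id_i, pairs$id_j))
  expect_setequal(curve_ids(all_q$collection), in_pairs)
})

test_that("a noisy strain drops out at strict but not lenient thresholds", {
  base <- sigmoid_od()
  cur <- unlist(lapply(letters[1:5], function(s)
    lapply(1:3, function(i) make_curve(base * (1 + 0.002 * i), s, i))),
    recursive = FALSE)
  noisy <- lapply(1:3, function(i)
    make_curve(base * (1 + 0.15 * i), "znoisy", i))
  coll <- curve_collection(c(cur, noisy))
  pairs <- within_replicate_pairs(coll)
  strict <- clean_collection(coll, pairs, q = 0.10)
  lenient <- clean_collection(coll, pairs, q = 0.95)
  expect_false("znoisy" %in% names(strict$collection$groups))
  expect_true("znoisy" %in% names(lenient$collection$groups))
})
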