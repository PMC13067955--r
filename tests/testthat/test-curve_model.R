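test_that("growth_curve validates its invariants", {
  t <- seq(0, 1, by = 0.25)
  expect_s3_class(growth_curve("a", 1, t, rep(0.1, 5)), "growth_curve")
  expect_error(growth_curve("a", 1, t, rep(0.1, 4)), "same length")
  expect_error(growth_curve("a", 1, t[1:2], c(0.1, 0.2)), "at least 3")
  expect_error(growth_curve("a", 1, c(0, 0.25, 0.75), rep(0.1, 3)), "non-uniform")
  expect_error(growth_curve("a", 1, rev(t), rep(0.1, 5)), "increasing")
  expect_error(growth_curve("a", 1, t, c(0.1, -0.1, 0.1, 0.1, 0.1)), ">= 0")
  expect_error(growth_curve("a", 0, t, rep(0.1, 5)), "replicate")
})

test_that("collections partition curves into strain groups", {
  cur <- list(make_curve(1:3 / 10, "a", 1), make_curve(1:3 / 10, "a", 2),
              make_curve(1:3 / 10, "b", 1))
  coll <- curve_collection(cur)
  expect_equal(sum(lengths(coll$groups)), length(cur))
  expect_equal(names(coll$groups), c("a", "b"))
  expect_error(curve_collection(c(cur, cur[1])), "duplicate")
})

test_that("wide tables read into one curve per strain:replicate column", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, by = 0.25, length.out = 96)
  df <- data.frame(time = t)
  for (s in c("geneA", "geneB")) for (r in 1:3)
    df[[paste0(s, ":", r)]] <- runif(96)
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  coll <- read_curves(f, "wide")
  expect_equal(length(coll), 6L)
  expect_equal(length(coll$groups), 2L)
  expect_equal(coll$curves[[1]]$times, t)
})

test_that("long tables read, and irregular time steps are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(strain = "g1", replicate = 1,
                   time = seq(0, by = 0.25, length.out = 48), od = runif(48))
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  coll <- read_curves(f, "long")
  expect_equal(length(coll), 1L)
  expect_equal(length(coll$curves[[1]]$od), 48L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,s:1", "0,0.1", "0.25,0.2", "0.5,0.3", "1.0,0.4"), f2)
  expect_error(read_curves(f2, "wide"), "non-uniform time step at row 4")
})

test_that("malformed headers and non-numeric OD give structured errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,badheader", "0,0.1", "0.25,0.2", "0.5,0.3"), f)
  expect_error(read_curves(f, "wide"), "strain:replicate")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,s:1", "0,0.1", "0.25,oops", "0.5,0.3"), f2)
  expect_error(read_curves(f2, "wide"), "non-numeric OD")
})

test_that("both layouts round-trip numeric content to 1e-9", {
  set.seed(4)
  cur <- list(make_curve(runif(96), "a", 1), make_curve(runif(96), "a", 2),
              make_curve(runif(96), "b", 1))
  coll <- curve_collection(cur)
  for (layout in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_curves(coll, f, layout)
    back <- read_curves(f, layout)
    expect_equal(curve_ids(back), curve_ids(coll))
    for (i in seq_along(cur)) {
      expect_equal(back$curves[[i]]$od, coll$curves[[i]]$od, tolerance = 1e-9)
      expect_equal(back$curves[[i]]$times, coll$curves[[i]]$times, tolerance = 1e-9)
    }
  }
})

test_that("mixed-length curves pad with trailing blanks in wide layout", {
  cur <- list(make_curve(runif(48), "a", 1), make_curve(runif(96), "b", 1))
  coll <- curve_collection(cur)
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves(coll, f, "wide")
  back <- read_curves(f, "wide")
  expect_equal(vapply(back$curves, function(c) length(c$od), integer(1)),
               c(48L, 96L))
  expect_equal(back$curves[[1]]$od, cur[[1]]$od, tolerance = 1e-9)
  # interior gaps are not padding
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,s:1", "0,0.1", "0.25,", "0.5,0.3"), f2)
  expect_error(read_curves(f2, "wide"), "interior NA")
})

test_that("empty collections write a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves(curve_collection(list()), f, "wide")
  expect_equal(readLines(f), "time")
})

test_that("annotation maps collapse duplicates and count genes once per category", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tcatA", "g1\tcatB", "g2\tcatA", "g3\tcatB", "g3\tcatB"), f)
  ann <- read_annotations(f)
  expect_equal(sort(unname(ann$category_sizes)), c(2L, 2L))
  expect_equal(sort(ann$gene_to_categories$g1), c("catA", "catB"))
  # idempotence under duplication
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tcatA", "g1\tcatB", "g2\tcatA", "g3\tcatB"), f2)
  expect_equal(read_annotations(f2)$category_sizes, ann$category_sizes)
  # round-trip through the writer
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f3)
  expect_equal(read_annotations(f3)$category_sizes, ann$category_sizes)
})

test_that("annotation edge cases error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_annotations(f))
  writeLines("g1\t", f)
  expect_error(read_annotations(f), "empty category")
})
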