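#' End-to-end shape clustering with statistics-only model selection
#'
#' The statistics-only analysis: preprocess the raw curves, keep one
#' representative curve per strain, compute the DTW/DDTW distance
#' bundle, evaluate the silhouette over the (alpha, n) grid, pick
#' (alpha*, n*) by the reverse-elbow rule, cut the dendrogram, and (when
#' annotations are given) test every cluster for category enrichment
#' against the analyzed strain universe.
#'
#' @param collection A raw [curve_collection()].
#' @param annotations Optional [annotation_map()]; when missing,
#'   enrichment is skipped with a warning.
#' @param alphas,ns Grid ranges (defaults 0-1 by 0.1, and 2:100).
#' @param radius fastdtw radius for the DTW engine.
#' @param representative Rule passed to [select_representative()].
#' @param min_category Enrichment size filter.
#' @param out_dir Optional directory; when given, labels, the grid and
#'   enrichment tables are written as TSV plus a JSON run manifest.
#' @param ... Preprocessing parameters forwarded to
#'   [preprocess_collection()].
#' @return List: `preprocess`, `representatives`, `bundle`, `grid`,
#'   `selection` (alpha, n, ranked), `labels`, `enrichment` (one data
#'   frame per cluster, or NULL), `manifest`.
#' @export
run_statistical_mode <- function(collection, annotations = NULL,
                                 alphas = seq(0, 1, by = 0.1), ns = 2:100,
                                 radius = 1L, representative = "medoid",
                                 min_category = 10L, out_dir = NULL, ...) {
  pre <- preprocess_collection(collection, ...)
  reps <- lapply(pre$collection$groups, function(ix)
    select_representative(pre$collection$curves[ix], rule = representative))
  repcoll <- curve_collection(unname(reps))
  bundle <- distance_bundle(repcoll, radius = radius)
  grid <- sc_grid(bundle, alphas = alphas, ns = ns)
  sel <- reverse_elbow_select(grid)
  D <- combined_matrix(bundle, sel$alpha)
  labels <- upgma_labels(D, sel$n)
  enrichment <- NULL
  strains <- vapply(repcoll$curves, function(c) c$strain_id, character(1))
  if (!is.null(annotations)) {
    enrichment <- cluster_enrichment(labels, stats::setNames(strains, curve_ids(repcoll)),
                                     annotations, min_category)
  } else {
    warning("no annotations supplied; enrichment skipped")
  }
  manifest <- list(
    mode = "statistical",
    n_input = pre$report$n_input,
    n_preprocessed = pre$report$n_retained,
    n_representatives = length(repcoll),
    scale = bundle$scale,
    alpha = sel$alpha, n_clusters = sel$n)
  res <- list(preprocess = pre$report, representatives = repcoll,
              bundle = bundle, grid = grid, selection = sel,
              labels = labels, enrichment = enrichment, manifest = manifest)
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

#' End-to-end shape clustering with replicate-coherence model selection
#'
#' The replicate-aware analysis: preprocess, compute within-replicate
#' pair distances, clean by the pooled top-quantile thresholds, build the
#' distance bundle over the retained curves, fill the (alpha, n) grid
#' with silhouettes and replicate split counts, select (alpha*, n*) by
#' the replicate-coherence rule, label, and run per-cluster enrichment
#' plus the retained-vs-all cleaning enrichment.
#'
#' @inheritParams run_statistical_mode
#' @param q Cleaning quantile (default 0.25).
#' @param pair_mode Cleaning retention rule, see [clean_collection()].
#' @param scan_qs Optional quantiles for a sensitivity scan (NULL skips).
#' @return List: `preprocess`, `pairs`, `cleaning`, `bundle`, `grid`,
#'   `selection`, `labels`, `enrichment`, `cleaning_enrichment`, `scan`,
#'   `manifest`.
#' @export
run_replicate_mode <- function(collection, annotations = NULL, q = 0.25,
                               pair_mode = "joint",
                               alphas = seq(0, 1, by = 0.1), ns = 2:100,
                               radius = 1L, min_category = 10L,
                               scan_qs = NULL, out_dir = NULL, ...) {
  pre <- preprocess_collection(collection, ...)
  pairs <- within_replicate_pairs(pre$collection, radius = radius)
  cleaned <- clean_collection(pre$collection, pairs, q = q, pair_mode = pair_mode)
  coll <- cleaned$collection
  bundle <- distance_bundle(coll, radius = radius)
  grid <- sc_grid(bundle, alphas = alphas, ns = ns, groups = coll)
  sel <- select_by_replicate_rule(grid)
  D <- combined_matrix(bundle, sel$alpha)
  labels <- upgma_labels(D, sel$n)
  strains <- vapply(coll$curves, function(c) c$strain_id, character(1))
  enrichment <- clean_enr <- scan <- NULL
  if (!is.null(annotations)) {
    enrichment <- cluster_enrichment(labels, stats::setNames(strains, curve_ids(coll)),
                                     annotations, min_category)
    before <- unique(vapply(pre$collection$curves, function(c) c$strain_id, character(1)))
    clean_enr <- cleaning_enrichment(before, unique(strains), annotations,
                                     min_category)
  } else {
    warning("no annotations supplied; enrichment skipped")
  }
  if (!is.null(scan_qs))
    scan <- sensitivity_scan(pre$collection, pairs, qs = scan_qs,
                             pair_mode = pair_mode, annotations = annotations)
  manifest <- list(
    mode = "replicate",
    n_input = pre$report$n_input,
    n_preprocessed = pre$report$n_retained,
    n_retained_curves = cleaned$report$n_retained_curves,
    n_retained_strains = cleaned$report$n_retained_strains,
    dtw_threshold = cleaned$report$dtw_threshold,
    ddtw_threshold = cleaned$report$ddtw_threshold,
    scale = bundle$scale,
    alpha = sel$alpha, n_clusters = sel$n)
  res <- list(preprocess = pre$report, pairs = pairs, cleaning = cleaned$report,
              bundle = bundle, grid = grid, selection = sel, labels = labels,
              enrichment = enrichment, cleaning_enrichment = clean_enr,
              scan = scan, manifest = manifest)
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

#' Per-cluster category enrichment
#'
#' Maps curves to strains, assigns each strain the majority cluster of
#' its curves (ties to the smaller cluster id), and tests every cluster's
#' strain set against the full analyzed universe.
#'
#' @param labels Named cluster ids (names = curve ids).
#' @param strain_of Named character vector mapping curve id to strain.
#' @param annotations An [annotation_map()].
#' @param min_category Size filter for [enrich_categories()].
#' @return Named list of enrichment data frames, one per cluster id.
#' @export
cluster_enrichment <- function(labels, strain_of, annotations,
                               min_category = 10L) {
  strains <- strain_of[names(labels)]
  assign1 <- tapply(labels, strains, function(l) {
    tab <- sort(table(l), decreasing = TRUE)
    as.integer(names(tab)[1])
  })
  universe <- names(assign1)
  out <- lapply(sort(unique(as.integer(assign1))), function(cl)
    enrich_categories(universe[assign1 == cl], universe, annotations,
                      min_category))
  names(out) <- paste0("C", sort(unique(as.integer(assign1))))
  out
}

# write labels / grid / enrichment TSVs and a JSON manifest
.write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(curve = names(res$labels), cluster = as.integer(res$labels)),
    file.path(out_dir, "labels.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  g <- res$grid
  rows <- expand.grid(ai = seq_along(g$alphas), ni = seq_along(g$ns))
  gt <- data.frame(alpha = g$alphas[rows$ai], n = g$ns[rows$ni],
                   sc = g$sc[cbind(rows$ai, rows$ni)])
  if (!is.null(g$split_counts)) {
    gt$splits <- g$split_counts[cbind(rows$ai, rows$ni)]
    gt$smoothed <- g$smoothed_splits[cbind(rows$ai, rows$ni)]
  }
  utils::write.table(gt, file.path(out_dir, "grid.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$enrichment))
    for (nm in names(res$enrichment))
      utils::write.table(res$enrichment[[nm]],
                         file.path(out_dir, sprintf("enrichment_%s.tsv", nm)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$cleaning_enrichment))
    utils::write.table(res$cleaning_enrichment,
                       file.path(out_dir, "cleaning_enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
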