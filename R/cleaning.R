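#' Within-replicate pairwise distances
#'
#' For each strain group of size m, emits all choose(m, 2) pairs with
#' their DTW and DDTW distances (so 1 or 3 pairs for duplicate/triplicate
#' groups). Singleton groups emit nothing and can never be retained by
#' the cleaning rule.
#'
#' @param collection A preprocessed [curve_collection()].
#' @param radius fastdtw radius for the DTW term.
#' @param endpoints DDTW endpoint convention.
#' @return Data frame: `strain`, `id_i`, `id_j`, `dtw`, `ddtw`.
#' @export
within_replicate_pairs <- function(collection, radius = 1L,
                                   endpoints = "replicate") {
  rows <- list()
  for (strain in names(collection$groups)) {
    idx <- collection$groups[[strain]]
    m <- length(idx)
    if (m < 2) next
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      ci <- collection$curves[[idx[i]]]
      cj <- collection$curves[[idx[j]]]
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, id_i = curve_id(ci), id_j = curve_id(cj),
        dtw = dtw_fast(ci$od, cj$od, radius),
        ddtw = ddtw_distance(ci$od, cj$od, endpoints = endpoints),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(strain = character(), id_i = character(),
                      id_j = character(), dtw = numeric(), ddtw = numeric()))
  do.call(rbind, rows)
}

#' Pooled quantile threshold
#'
#' The q-quantile of a pooled distance distribution, with linear
#' interpolation between order statistics (type 7). Pairs below the
#' threshold count as "highly similar".
#'
#' @param values Non-empty numeric vector.
#' @param q Quantile in (0, 1).
#' @return Scalar threshold.
#' @export
quantile_threshold <- function(values, q) {
  if (length(values) == 0) stop("empty values")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  unname(stats::quantile(values, q, type = 7))
}

#' Replicate-variance cleaning
#'
#' Thresholds are the q-quantiles of the pooled within-replicate DTW and
#' DDTW distance distributions (the "top q most similar pairs"). Under
#' the default `pair_mode = "joint"`, a curve is retained iff it belongs
#' to at least one pair that is below both thresholds simultaneously;
#' `"independent"` retains a curve if some pair passes the DTW threshold
#' and some (possibly different) pair passes the DDTW threshold.
#' Comparison is strict (`<`). Strains left with fewer than two retained
#' curves are reported but dropped from the retained groups count.
#'
#' @param collection The preprocessed collection the pairs were computed on.
#' @param pairs Output of [within_replicate_pairs()].
#' @param q Similarity quantile (default 0.25, i.e. top 25%).
#' @param pair_mode `"joint"` (default) or `"independent"`.
#' @return List with `collection` (retained curves) and `report`
#'   (thresholds, counts, removed ids, q, pair_mode).
#' @export
clean_collection <- function(collection, pairs, q = 0.25,
                             pair_mode = c("joint", "independent")) {
  pair_mode <- match.arg(pair_mode)
  if (nrow(pairs) == 0) stop("no within-replicate pairs")
  thr_dtw <- quantile_threshold(pairs$dtw, q)
  thr_ddtw <- quantile_threshold(pairs$ddtw, q)
  pass_dtw <- pairs$dtw < thr_dtw
  pass_ddtw <- pairs$ddtw < thr_ddtw
  if (pair_mode == "joint") {
    both <- pass_dtw & pass_ddtw
    keep_ids <- unique(c(pairs$id_i[both], pairs$id_j[both]))
  } else {
    keep_ids <- intersect(unique(c(pairs$id_i[pass_dtw], pairs$id_j[pass_dtw])),
                          unique(c(pairs$id_i[pass_ddtw], pairs$id_j[pass_ddtw])))
  }
  ids <- curve_ids(collection)
  kept <- ids %in% keep_ids
  retained <- curve_collection(collection$curves[kept])
  sizes <- lengths(retained$groups)
  report <- list(q = q, pair_mode = pair_mode,
                 dtw_threshold = thr_dtw, ddtw_threshold = thr_ddtw,
                 n_retained_curves = sum(kept),
                 n_retained_strains = length(retained$groups),
                 n_strains_below_pair = sum(sizes < 2),
                 removed = ids[!kept])
  list(collection = retained, report = report)
}

#' Sensitivity scan over cleaning thresholds
#'
#' Reruns [clean_collection()] at several inclusion quantiles. Because
#' the thresholds come from one pooled pair distribution, retained sets
#' are nested: everything kept at a stricter q is kept at a looser one.
#' Optionally reports, per q, the enrichment of retained vs all genes.
#'
#' @inheritParams clean_collection
#' @param qs Quantiles to scan (default 0.10, 0.20, 0.25, 0.30, 0.50).
#' @param annotations Optional [annotation_map()]; when given, each scan
#'   level also carries a [cleaning_enrichment()] table.
#' @return Named list (one element per q) of [clean_collection()] results,
#'   each possibly with an `enrichment` data frame attached.
#' @export
sensitivity_scan <- function(collection, pairs,
                             qs = c(0.10, 0.20, 0.25, 0.30, 0.50),
                             pair_mode = "joint", annotations = NULL) {
  out <- lapply(qs, function(q) {
    res <- clean_collection(collection, pairs, q, pair_mode)
    if (!is.null(annotations)) {
      before <- unique(vapply(collection$curves, function(c) c$strain_id, character(1)))
      after <- names(res$collection$groups)
      res$enrichment <- cleaning_enrichment(before, after, annotations)
    }
    res
  })
  names(out) <- sprintf("q%.2f", qs)
  out
}
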