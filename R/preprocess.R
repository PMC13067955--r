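#' Locate the maximum-OD window
#'
#' Finds the `w` consecutive OD readings with the highest mean — the
#' operational definition of the stationary-phase plateau. Ties go to the
#' earliest window, so the first plateau of a multiphasic curve wins.
#'
#' @param curve A [growth_curve()] (or bare numeric OD vector).
#' @param w Window length in points (default 5).
#' @return List with `start` (1-based index of the window's first point)
#'   and `mean` (the window mean OD).
#' @export
max_od_window <- function(curve, w = 5L) {
  od <- if (inherits(curve, "growth_curve")) curve$od else as.numeric(curve)
  w <- as.integer(w)
  if (length(od) < w)
    stop(sprintf("curve has %d points, shorter than window w=%d", length(od), w))
  cs <- cumsum(c(0, od))
  means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  start <- which.max(means)  # which.max takes the earliest maximum
  list(start = start, mean = means[start])
}

#' Truncate a curve shortly after stationary phase is reached
#'
#' Retains everything up to `tail` points past the end of the
#' maximum-OD window, so curves end at comparable growth phases while
#' earlier dynamics (diauxic shifts and other multiphasic patterns) are
#' left untouched. Idempotent.
#'
#' @inheritParams max_od_window
#' @param tail Number of points kept after the window (default 5).
#' @return The truncated `growth_curve`.
#' @export
truncate_at_stationary <- function(curve, w = 5L, tail = 5L) {
  win <- max_od_window(curve, w)
  last <- min(length(curve$od), win$start + w - 1L + as.integer(tail))
  if (last == length(curve$od)) return(curve)
  growth_curve(curve$strain_id, curve$replicate,
               curve$times[seq_len(last)], curve$od[seq_len(last)],
               stage = curve$stage)
}

#' Viability filter: did the culture grow and reach stationary phase?
#'
#' A curve is rejected as `no_growth` when the plateau mean exceeds the
#' mean of the first three readings by less than `min_rise`, and as
#' `no_plateau` when it is still rising at the end of the record: the mean
#' slope over the final `tail_points` intervals exceeds `tail_slope_eps`
#' and the maximum-OD window ends within `tail_points` of the last point.
#'
#' @inheritParams max_od_window
#' @param min_rise Minimum OD rise counted as growth (OD units, default 0.1).
#' @param tail_slope_eps Slope above which the tail counts as still rising
#'   (OD per hour, default 0.02).
#' @param tail_points Number of trailing intervals inspected (default 3).
#' @return List with `growing` (logical) and `reason` (`NA`, `"no_growth"`
#'   or `"no_plateau"`).
#' @export
is_growing <- function(curve, min_rise = 0.1, tail_slope_eps = 0.02,
                       tail_points = 3L) {
  od <- curve$od
  win <- max_od_window(curve)
  rise <- win$mean - mean(od[1:3])
  if (rise < min_rise)
    return(list(growing = FALSE, reason = "no_growth"))
  n <- length(od)
  k <- min(as.integer(tail_points), n - 1L)
  dt <- curve$times[2] - curve$times[1]
  tail_slope <- (od[n] - od[n - k]) / (k * dt)
  win_end <- win$start + 5L - 1L
  if (tail_slope > tail_slope_eps && win_end >= n - as.integer(tail_points))
    return(list(growing = FALSE, reason = "no_plateau"))
  list(growing = TRUE, reason = NA_character_)
}

#' Preprocess a raw collection: viability filter then truncation
#'
#' Applies [is_growing()] to every curve, truncates the survivors with
#' [truncate_at_stationary()], marks them `stage = "preprocessed"`, and
#' drops strain groups left empty. Decisions for every input curve are
#' kept in the report; nothing is silently discarded.
#'
#' @param collection A raw [curve_collection()].
#' @param w,tail Truncation parameters, see [truncate_at_stationary()].
#' @param min_rise,tail_slope_eps,tail_points Filter parameters, see
#'   [is_growing()].
#' @return List with `collection` (the preprocessed curves) and `report`,
#'   a list holding `n_input`, `n_retained`, `n_rejected_no_growth`,
#'   `n_rejected_no_plateau` and `decisions` (data frame: curve id, kept,
#'   reason). The counts always partition the input.
#' @export
preprocess_collection <- function(collection, w = 5L, tail = 5L,
                                  min_rise = 0.1, tail_slope_eps = 0.02,
                                  tail_points = 3L) {
  curves <- collection$curves
  verdicts <- lapply(curves, is_growing, min_rise = min_rise,
                     tail_slope_eps = tail_slope_eps, tail_points = tail_points)
  kept <- vapply(verdicts, function(v) v$growing, logical(1))
  reasons <- vapply(verdicts, function(v) v$reason, character(1))
  out <- lapply(curves[kept], function(c) {
    c <- truncate_at_stationary(c, w = w, tail = tail)
    c$stage <- "preprocessed"
    c
  })
  if (length(out) == 0)
    warning("no curves survived preprocessing")
  report <- list(
    n_input = length(curves),
    n_retained = sum(kept),
    n_rejected_no_growth = sum(reasons == "no_growth", na.rm = TRUE),
    n_rejected_no_plateau = sum(reasons == "no_plateau", na.rm = TRUE),
    decisions = data.frame(
      curve = vapply(curves, curve_id, character(1)),
      kept = kept, reason = reasons, stringsAsFactors = FALSE)
  )
  list(collection = curve_collection(out), report = report)
}

#' Pick one representative curve per replicate group
#'
#' For groups of three or more the default is the medoid under the
#' alpha-combined DTW/DDTW distance (alpha = 0.5): the curve whose summed
#' distance to its siblings is smallest. One- and two-member groups, and
#' the `"first"` rule, take the lowest replicate index; `"random"` draws
#' uniformly (seeded). Ties go to the lowest replicate index.
#'
#' @param group List of `growth_curve` objects from one strain.
#' @param rule `"medoid"`, `"first"` or `"random"`.
#' @param alpha Weight of the DDTW term for the medoid rule.
#' @param radius fastdtw radius for the DTW term.
#' @param seed Seed for `"random"`.
#' @return A single `growth_curve`.
#' @export
select_representative <- function(group, rule = c("medoid", "first", "random"),
                                  alpha = 0.5, radius = 1L, seed = 1L) {
  rule <- match.arg(rule)
  if (length(group) == 0) stop("empty replicate group")
  reps <- vapply(group, function(c) c$replicate, integer(1))
  ord <- order(reps)
  if (length(group) <= 2L || rule == "first")
    return(group[[ord[1]]])
  if (rule == "random") {
    return(withr_seed(seed, group[[sample(length(group), 1L)]]))
  }
  m <- length(group)
  dtw <- matrix(0, m, m); ddtw <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    dtw[i, j] <- dtw[j, i] <- dtw_fast(group[[i]]$od, group[[j]]$od, radius)
    ddtw[i, j] <- ddtw[j, i] <- ddtw_distance(group[[i]]$od, group[[j]]$od)
  }
  md <- mean(ddtw[upper.tri(ddtw)])
  sc <- if (md > 0) mean(dtw[upper.tri(dtw)]) / md else 0
  comb <- (1 - alpha) * dtw + alpha * sc * ddtw
  sums <- rowSums(comb)
  # ties -> lowest replicate index
  best <- which(sums <= min(sums) + 1e-12)
  group[[best[which.min(reps[best])]]]
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
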