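#' Simulation configuration for synthetic growth-curve collections
#'
#' Defaults emulate a microplate knockout screen at desk scale: 150
#' strains with 3 replicates each, OD600 sampled every 0.25 h for 24 h
#' (96 points), and four planted shape classes — `normal` sigmoids,
#' `long_lag` sigmoids (lag around 15 h instead of 2 h), `no_growth`
#' (near-flat baseline with a slight instrument drift), and
#' `low_capacity` (plateau around OD 0.3). A `diauxic` class (two
#' stacked sigmoids) exists for exercising truncation but is off by
#' default. Noise is applied to OD only — plate readers sample on a
#' fixed clock — as a multiplicative term, an additive term, and a
#' per-replicate lag jitter. One gene category is planted with
#' over-representation in a target class so that enrichment power can be
#' measured end to end.
#'
#' @param n_strains Number of strains (default 150).
#' @param replicates Replicates per strain (default 3).
#' @param class_probs Named probabilities over
#'   `normal`, `long_lag`, `no_growth`, `low_capacity`, `diauxic`
#'   (must sum to 1).
#' @param noise_mult,noise_add Multiplicative / additive OD noise sd
#'   (defaults 0.02 and 0.005).
#' @param lag_jitter_sd Per-replicate lag jitter sd in hours (default 0.25).
#' @param interval,duration Sampling interval and total duration in hours
#'   (defaults 0.25 and 24; must give 48-96 points).
#' @param categories Category labels for the annotation map (defaults to
#'   eight short labels in the style of gene-category shorthand).
#' @param planted_category,planted_class,planted_factor The planted
#'   enrichment: genes of `planted_class` draw `planted_category` with
#'   `planted_factor` times its baseline weight (defaults "e",
#'   "no_growth", 3).
#' @param seed RNG seed (default 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 150L, replicates = 3L,
                       class_probs = c(normal = 0.70, long_lag = 0.15,
                                       no_growth = 0.10, low_capacity = 0.05,
                                       diauxic = 0),
                       noise_mult = 0.02, noise_add = 0.005,
                       lag_jitter_sd = 0.25,
                       interval = 0.25, duration = 24,
                       categories = c("e", "t", "pe", "pt", "h", "o", "su", "m"),
                       planted_category = "e", planted_class = "no_growth",
                       planted_factor = 3, seed = 1L) {
  classes <- c("normal", "long_lag", "no_growth", "low_capacity", "diauxic")
  if (!setequal(names(class_probs), classes))
    stop("class_probs must be named over the five shape classes")
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (any(c(noise_mult, noise_add, lag_jitter_sd) < 0)) stop("noise sds must be >= 0")
  npts <- floor(duration / interval)
  if (npts < 48 || npts > 96)
    stop(sprintf("duration/interval gives %d points; expected 48-96", npts))
  if (!planted_category %in% categories) stop("planted_category not in categories")
  structure(list(n_strains = as.integer(n_strains),
                 replicates = as.integer(replicates),
                 class_probs = class_probs[classes],
                 noise_mult = noise_mult, noise_add = noise_add,
                 lag_jitter_sd = lag_jitter_sd,
                 interval = interval, duration = duration,
                 categories = categories,
                 planted_category = planted_category,
                 planted_class = planted_class,
                 planted_factor = planted_factor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reparameterized Gompertz growth model
#'
#' `od(t) = baseline + A * exp(-exp(mu * e / A * (lambda - t) + 1))`,
#' where `A` is the amplitude above baseline (carrying capacity), `mu`
#' the maximum slope in OD per hour, and `lambda` the lag time in hours.
#' Monotone non-decreasing; approaches `baseline + A` as t grows.
#'
#' @param A Amplitude above baseline (> 0).
#' @param mu Maximum growth rate, OD/h (> 0).
#' @param lambda Lag time, hours (>= 0).
#' @param baseline Starting OD (>= 0).
#' @param times Numeric vector of times in hours.
#' @return OD values at `times`.
#' @export
gompertz_curve <- function(A, mu, lambda, baseline, times) {
  if (A <= 0 || mu <= 0 || lambda < 0 || baseline < 0)
    stop("require A > 0, mu > 0, lambda >= 0, baseline >= 0")
  baseline + A * exp(-exp(mu * exp(1) / A * (lambda - times) + 1))
}

# strain-level parameter draw for one shape class (uses the current RNG)
.draw_class_params <- function(class) {
  base <- stats::runif(1, 0.05, 0.08)
  switch(class,
    normal = list(baseline = base, A = stats::rnorm(1, 0.85, 0.05),
                  mu = stats::rnorm(1, 0.70, 0.08),
                  lambda = max(0.5, stats::rnorm(1, 2.0, 0.5))),
    long_lag = list(baseline = base, A = stats::rnorm(1, 0.70, 0.05),
                    mu = stats::rnorm(1, 0.70, 0.08),
                    lambda = max(10, stats::rnorm(1, 15, 1.0))),
    low_capacity = list(baseline = base, A = stats::rnorm(1, 0.30, 0.04),
                        mu = stats::rnorm(1, 0.35, 0.05),
                        lambda = max(0.5, stats::rnorm(1, 2.5, 0.5))),
    no_growth = list(baseline = base, drift = stats::runif(1, 0, 0.002)),
    diauxic = list(baseline = base,
                   A1 = stats::rnorm(1, 0.45, 0.04),
                   A2 = stats::rnorm(1, 0.40, 0.04),
                   mu = stats::rnorm(1, 0.60, 0.06),
                   lambda1 = max(0.5, stats::rnorm(1, 2.0, 0.5)),
                   gap = max(4, stats::rnorm(1, 8, 1.0))),
    stop("unknown class"))
}

.noiseless_od <- function(class, p, times) {
  switch(class,
    no_growth = p$baseline + p$drift * times,
    diauxic = p$baseline +
      (gompertz_curve(p$A1, p$mu, p$lambda1, 0, times) +
       gompertz_curve(p$A2, p$mu * 0.7, p$lambda1 + p$gap, 0, times)),
    gompertz_curve(p$A, p$mu, p$lambda, p$baseline, times))
}

#' Simulate one strain's replicate group
#'
#' Class parameters are drawn once per strain; each replicate then gets
#' its own lag jitter and OD noise (`od * (1 + eps_mult) + eps_add`,
#' floored at 0). Uses the calling RNG state — seed upstream for
#' reproducibility.
#'
#' @param strain_id Strain name.
#' @param class Shape class (see [sim_config()]).
#' @param config A `sim_config`.
#' @return List of `growth_curve` objects (the replicates).
#' @export
simulate_strain <- function(strain_id, class, config) {
  times <- seq(0, by = config$interval, length.out = floor(config$duration / config$interval))
  p <- .draw_class_params(class)
  lapply(seq_len(config$replicates), function(r) {
    pr <- p
    if (!is.null(pr$lambda) && config$lag_jitter_sd > 0)
      pr$lambda <- max(0, pr$lambda + stats::rnorm(1, 0, config$lag_jitter_sd))
    if (!is.null(pr$lambda1) && config$lag_jitter_sd > 0)
      pr$lambda1 <- max(0, pr$lambda1 + stats::rnorm(1, 0, config$lag_jitter_sd))
    od <- .noiseless_od(class, pr, times)
    if (config$noise_mult > 0)
      od <- od * (1 + stats::rnorm(length(od), 0, config$noise_mult))
    if (config$noise_add > 0)
      od <- od + stats::rnorm(length(od), 0, config$noise_add)
    growth_curve(strain_id, r, times, pmax(od, 0))
  })
}

#' Simulate a full collection with planted classes and annotations
#'
#' Draws a shape class per strain, simulates all replicate curves, and
#' builds an annotation map in which every gene carries one or two
#' categories; genes of the planted class draw the planted category at
#' `planted_factor` times its baseline weight, giving a known
#' over-representation for power checks. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `collection` (a `curve_collection`), `truth` (data
#'   frame: strain, class) and `annotations` (an [annotation_map()]).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    classes <- names(config$class_probs)
    strain_class <- sample(classes, config$n_strains, replace = TRUE,
                           prob = config$class_probs)
    strains <- sprintf("g%04d", seq_len(config$n_strains))
    curves <- list()
    for (i in seq_len(config$n_strains))
      curves <- c(curves, simulate_strain(strains[i], strain_class[i], config))
    ncat <- length(config$categories)
    g2c <- lapply(seq_len(config$n_strains), function(i) {
      # the planted factor f is the target fold change of the category in
      # the class relative to the whole universe (the FC the enrichment
      # table reports). With background rate r0 = 1/ncat and class
      # fraction pi, the in-class rate solving rate = f * universe_rate
      # (universe inclusive of the planted excess) is
      # f * r0 * (1 - pi) / (1 - pi * f).
      w <- rep(1 / ncat, ncat)
      if (strain_class[i] == config$planted_class) {
        ci <- match(config$planted_category, config$categories)
        pclass <- unname(config$class_probs[config$planted_class])
        f <- config$planted_factor
        rate <- if (pclass * f < 1)
          f * (1 / ncat) * (1 - pclass) / (1 - pclass * f) else 0.9
        w[ci] <- min(0.9, rate)
        w[-ci] <- (1 - w[ci]) / (ncat - 1)
      }
      first <- sample(config$categories, 1, prob = w)
      cats <- first
      if (stats::runif(1) < 0.3)
        cats <- unique(c(cats, sample(config$categories, 1)))
      cats
    })
    names(g2c) <- strains
    list(collection = curve_collection(curves),
         truth = data.frame(strain = strains, class = strain_class,
                            stringsAsFactors = FALSE),
         annotations = annotation_map(g2c))
  })
}
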