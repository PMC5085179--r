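#' Candidate caspase-on-NFkB feedback interaction
#'
#' A positive loop contributes a production term `+k_positive*[caspase]`
#' to the NFkB balance; a negative loop a degradation term
#' `-k_negative*[caspase]*[NFkB]`.
#'
#' @param source_role `"caspase3_active"`, `"caspase6_active"` or
#'   `"caspase8_active"`
#' @param sign `"positive"` or `"negative"`
#' @param strength `k_positive` (1/s) or `k_negative` (1/(amol s)), >= 0
#' @param target_role target species role, normally `"nfkb_active"`
#' @export
feedback_spec <- function(source_role, sign = c("negative", "positive"),
                          strength, target_role = "nfkb_active") {
  source_role <- match.arg(source_role, c("caspase3_active", "caspase6_active",
                                          "caspase8_active"))
  sign <- match.arg(sign)
  stopifnot(strength >= 0)
  structure(list(source_role = source_role, target_role = target_role,
                 sign = sign, strength = strength), class = "feedback_spec")
}

#' Inject a feedback term into a network
#'
#' Adds the spec's rate term to `extra_rate_terms`; the reaction list and
#' stoichiometric matrix are untouched, so [evaluate_rates()] is
#' unchanged while [network_derivative()] picks the term up.  The base
#' network is not modified.
#'
#' @param network a [reaction_network()] with a role map
#' @param spec a [feedback_spec()]
#' @return the modified copy
#' @export
inject_feedback <- function(network, spec) {
  stopifnot(inherits(spec, "feedback_spec"))
  term <- list(source = .role_index(network, spec$source_role),
               target = .role_index(network, spec$target_role),
               sign = spec$sign, strength = spec$strength, spec = spec)
  network$extra_rate_terms <- c(network$extra_rate_terms, list(term))
  network
}

#' Apoptotic phenotype at a supra-critical probe dose
#'
#' Two readouts characterize the response at a dose above the critical
#' dose: the initial time of cell death — the first time the executioner
#' crosses 50% of its own final steady level at that dose — and the
#' executioner steady-state level itself.
#'
#' @param network a [reaction_network()] with a role map
#' @param probe_dose amol; default 1e-2, a supra-critical apoptotic dose
#' @param t_end trajectory horizon (s) for the crossing search
#' @param n_times trajectory resolution
#' @param threshold optional absolute executioner threshold (amol) for
#'   the death-time crossing.  Default: half this network's own final
#'   steady level.  Cross-model strength scans pass the *base* model's
#'   half-level so every scanned model is timed against the same mark —
#'   a model-dependent threshold would confound faster dynamics with a
#'   shifted plateau.
#' @return an `apoptosis_metrics` list: `initial_death_time` (s),
#'   `steady_level` (amol), `probe_dose`, `apoptotic` (flag; the time
#'   and level are NA when apoptosis does not occur at the probe dose).
#' @export
apoptosis_metrics <- function(network, probe_dose = 1e-2,
                              t_end = 48 * 3600, n_times = 2000L,
                              threshold = NULL) {
  exec <- .role_index(network, "caspase3_active")
  ss <- steady_state(network, probe_dose)
  level <- unname(ss$state[exec])
  # supra-critical check: the survival->apoptosis jump must occur at or
  # below the probe dose (a bare ratio against the resting level misfires
  # when the resting executioner sits at zero)
  sub <- vapply(probe_dose * c(0, 1 / 8, 1 / 4, 1 / 2),
                function(d) unname(steady_state(network, d)$state[exec]), 0)
  if (!.detect_switch(c(sub, level))$switch)
    return(structure(list(initial_death_time = NA_real_, steady_level = NA_real_,
                          probe_dose = probe_dose, apoptotic = FALSE),
                     class = "apoptosis_metrics"))
  if (is.null(threshold)) threshold <- 0.5 * level
  traj <- simulate_network(network, probe_dose, t_end,
                           times = seq(0, t_end, length.out = n_times))
  cross <- which(traj$states[, exec] >= threshold)
  if (!length(cross)) # settled between grid points; fall back to horizon end
    cross <- length(traj$times)
  t_lo <- if (cross[1] == 1L) 0 else traj$times[cross[1] - 1L]
  # linear interpolation inside the bracketing reporting step
  y0 <- if (cross[1] == 1L) traj$states[1, exec] else traj$states[cross[1] - 1L, exec]
  y1 <- traj$states[cross[1], exec]
  tdeath <- if (y1 > y0)
    t_lo + (threshold - y0) / (y1 - y0) * (traj$times[cross[1]] - t_lo)
  else traj$times[cross[1]]
  structure(list(initial_death_time = tdeath, steady_level = level,
                 probe_dose = probe_dose, apoptotic = TRUE),
            class = "apoptosis_metrics")
}

#' @export
print.apoptosis_metrics <- function(x, ...) {
  if (x$apoptotic)
    cat("Apoptosis at probe dose ", x$probe_dose, " amol: death time ",
        signif(x$initial_death_time, 5), " s, steady level ",
        signif(x$steady_level, 5), " amol\n", sep = "")
  else cat("No apoptosis at probe dose ", x$probe_dose, " amol\n", sep = "")
  invisible(x)
}

#' Admissible feedback-strength range
#'
#' Scans a log-spaced strength grid and keeps the maximal contiguous
#' prefix over which the bounded phenotype stays within
#' `limit_fraction` (default 20%) of the base model's: the initial death
#' time for negative loops (which shorten it), the executioner steady
#' level for positive loops (which lower it).
#'
#' @param network base [reaction_network()]
#' @param spec_template a [feedback_spec()]; its strength is ignored
#' @param limit_fraction maximal tolerated fractional decrease
#' @param scan_grid increasing strength grid; default 5 points per decade
#'   over `decades`
#' @param decades default grid range, `c(lo, hi)` exponents of 10
#' @param probe_dose passed to [apoptosis_metrics()]
#' @return a `strength_range`: list with `lo`, `hi`, `metric`, `grid`,
#'   `metric_values`, `baseline`, `limit_fraction`.
#' @export
calibrate_range <- function(network, spec_template, limit_fraction = 0.20,
                            scan_grid = NULL, decades = c(-4, 1),
                            probe_dose = 1e-2) {
  stopifnot(inherits(spec_template, "feedback_spec"), limit_fraction >= 0)
  if (is.null(scan_grid))
    scan_grid <- 10^seq(decades[1], decades[2], by = 1 / 5)
  stopifnot(!is.unsorted(scan_grid), all(scan_grid > 0))
  metric_name <- if (spec_template$sign == "negative") "initial_death_time"
                 else "steady_level"
  base <- apoptosis_metrics(network, probe_dose)
  if (!base$apoptotic)
    stop("baseline phenotype undefined: no apoptosis at the probe dose")
  baseline <- base[[metric_name]]
  thr <- 0.5 * base$steady_level # common death-time mark for all strengths
  vals <- rep(NA_real_, length(scan_grid))
  hi_i <- 0L
  for (i in seq_along(scan_grid)) {
    sp <- spec_template; sp$strength <- scan_grid[i]
    m <- apoptosis_metrics(inject_feedback(network, sp), probe_dose,
                           threshold = thr)
    vals[i] <- if (m$apoptotic) m[[metric_name]] else NA_real_
    ok <- is.finite(vals[i]) && vals[i] >= (1 - limit_fraction) * baseline
    if (!ok) break
    hi_i <- i
  }
  structure(list(lo = if (hi_i >= 1L) scan_grid[1] else NA_real_,
                 hi = if (hi_i >= 1L) scan_grid[hi_i] else NA_real_,
                 metric = metric_name, grid = scan_grid,
                 metric_values = vals, baseline = baseline,
                 limit_fraction = limit_fraction),
            class = "strength_range")
}

#' @export
print.strength_range <- function(x, ...) {
  cat("Admissible ", x$metric, " range: [", signif(x$lo, 4), ", ",
      signif(x$hi, 4), "] (baseline ", signif(x$baseline, 5),
      ", limit ", x$limit_fraction * 100, "%)\n", sep = "")
  invisible(x)
}

#' Hamming distance versus feedback strength
#'
#' At every strength the full sensitivity spectrum of the modified model
#' is rebuilt and compared (after dropping excluded parameters) to the
#' projected mutation spectrum; the baseline HD is that of the unmodified
#' model.  Per-strength failures are recorded and the scan continues.
#'
#' @param network base [reaction_network()]
#' @param spec_template a [feedback_spec()]; strength taken from
#'   `strengths`
#' @param strengths strength grid (normally inside the calibrated range)
#' @param mutation_spectrum a [boolean_spectrum()] already projected onto
#'   parameter order (excluded parameters dropped)
#' @param config a [sensitivity_config()]
#' @return an `hd_scan`: data.frame with `strength`, `hd`; attributes
#'   `baseline_hd` and `errors`.
#' @export
hd_strength_scan <- function(network, spec_template, strengths,
                             mutation_spectrum,
                             config = sensitivity_config()) {
  stopifnot(inherits(spec_template, "feedback_spec"),
            inherits(mutation_spectrum, "boolean_spectrum"))
  keep <- mutation_spectrum$ids
  hd_of <- function(net) {
    spec <- build_spectrum(net, parameter_ids = keep, config = config)
    hamming(as_boolean_spectrum(spec), mutation_spectrum)$hd
  }
  baseline_hd <- hd_of(network)
  hd <- rep(NA_integer_, length(strengths))
  errs <- character(length(strengths))
  for (i in seq_along(strengths)) {
    sp <- spec_template; sp$strength <- strengths[i]
    hd[i] <- tryCatch(hd_of(inject_feedback(network, sp)),
                      error = function(e) { errs[i] <<- conditionMessage(e); NA_integer_ })
  }
  structure(data.frame(strength = strengths, hd = hd),
            class = c("hd_scan", "data.frame"),
            baseline_hd = baseline_hd, errors = errs)
}

#' @export
print.hd_scan <- function(x, ...) {
  cat("HD-strength scan (baseline HD = ", attr(x, "baseline_hd"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
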