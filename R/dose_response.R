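#' Steady-state dose-response scan of the executioner caspase
#'
#' Computes the steady state of the executioner (caspase3 role) from the
#' common resting initial condition at every dose in `doses`, and
#' estimates the low/high plateaus as the median of the three
#' lowest-dose points and of the three highest apoptotic-dose points.
#'
#' @param network a [reaction_network()] with a role map
#' @param doses increasing dose grid (amol) within `[0, dose_max]`
#' @param dose_max configured dose cap (amol); default 1e-2, the
#'   in-vitro-equivalent TNF-alpha range
#' @param ... passed to [steady_state()]
#' @return a `dose_response_curve`: data.frame with columns `dose`,
#'   `executioner`, `converged`; attributes `low_plateau`,
#'   `high_plateau` (NA when no switch is found within the grid).
#' @export
scan_doses <- function(network, doses, dose_max = 1e-2, ...) {
  stopifnot(all(doses >= 0), all(doses <= dose_max), !is.unsorted(doses))
  exec <- .role_index(network, "caspase3_active")
  res <- lapply(doses, function(d) steady_state(network, d, ...))
  curve <- data.frame(
    dose = doses,
    executioner = vapply(res, function(r) unname(r$state[exec]), 0),
    converged = vapply(res, `[[`, TRUE, "converged"))
  ok <- curve[curve$converged, , drop = FALSE]
  ok <- ok[order(ok$dose), , drop = FALSE]
  low <- if (nrow(ok) >= 1) median(head(ok$executioner, 3)) else NA_real_
  sw <- .detect_switch(ok$executioner)
  high <- if (sw$switch) median(tail(ok$executioner[seq(sw$first_high, nrow(ok))], 3))
          else NA_real_
  structure(curve, class = c("dose_response_curve", "data.frame"),
            low_plateau = low, high_plateau = high, dose_max = dose_max)
}

# All-or-none switch detection on an ordered steady-state sequence.
# A switch is a consecutive jump that is both large relative to the point
# below it (>= ratio_min) and carries most of the curve's total range
# (>= range_frac): the first condition rejects smooth growth, the second
# rejects relative jumps out of a near-zero resting branch.
.detect_switch <- function(ss, ratio_min = 4, range_frac = 0.25,
                           abs_floor = 1e-9) {
  n <- length(ss)
  if (n < 2 || diff(range(ss)) <= abs_floor)
    return(list(switch = FALSE, first_high = NA_integer_))
  inc <- diff(ss)
  big <- which(ss[-1] >= ratio_min * ss[-n] &
               inc >= range_frac * diff(range(ss)))
  if (!length(big)) return(list(switch = FALSE, first_high = NA_integer_))
  list(switch = TRUE, first_high = big[1] + 1L)
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("Dose-response curve (", nrow(x), " doses)\n", sep = "")
  cat("  low plateau: ", attr(x, "low_plateau"),
      "   high plateau: ", attr(x, "high_plateau"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.dose_response_curve <- function(x, ...) {
  plot(x$dose, x$executioner, type = "b", pch = 16,
       xlab = "TNF-alpha dose (amol)", ylab = "executioner steady state (amol)", ...)
  abline(h = c(attr(x, "low_plateau"), attr(x, "high_plateau")), lty = 3)
  invisible(x)
}

#' Survival/apoptosis fate from an executioner steady state
#'
#' Midpoint rule: apoptosis iff the executioner steady state is at or
#' above the midpoint of the two plateaus (the tie sits on the apoptosis
#' side).  Errors when the plateaus are indistinguishable
#' (`high < 2 * low`).
#'
#' @param executioner_ss steady-state executioner amount(s) (amol)
#' @param low_plateau,high_plateau branch levels (amol)
#' @return character vector, `"survival"` or `"apoptosis"`
#' @export
classify_fate <- function(executioner_ss, low_plateau, high_plateau) {
  if (is.na(low_plateau) || is.na(high_plateau) || high_plateau < 2 * low_plateau)
    stop("plateaus indistinguishable (high < 2*low): no all-or-none switch")
  ifelse(executioner_ss >= (low_plateau + high_plateau) / 2, "apoptosis", "survival")
}

#' Locate the critical TNF-alpha dose by bracketing and bisection
#'
#' Scans a coarse geometric grid up to `dose_max` to bracket the
#' survival-to-apoptosis switch, then bisects [classify_fate()] until the
#' bracket is narrower than `tol`.  When no apoptotic dose exists within
#' `dose_max` the result is flagged `apoptosis_achievable = FALSE` with
#' an undefined critical dose.
#'
#' @inheritParams scan_doses
#' @param tol bisection tolerance (amol), default `dose_max / 2000`
#' @param n_coarse number of nonzero coarse-scan doses (geometric grid)
#' @return a `critical_dose_result`: list with `cd`, `bracket`,
#'   `apoptosis_achievable`, `dose_max`, `low_plateau`, `high_plateau`.
#' @export
find_critical_dose <- function(network, dose_max = 1e-2, tol = dose_max / 2000,
                               n_coarse = 8L, ...) {
  exec <- .role_index(network, "caspase3_active")
  ss_at <- function(d) unname(steady_state(network, d, ...)$state[exec])
  doses <- c(0, dose_max * 2^(-(n_coarse - 1):0))
  ss <- vapply(doses, ss_at, 0)
  sw <- .detect_switch(ss)
  if (!sw$switch) {
    return(structure(list(cd = NA_real_, bracket = c(NA_real_, NA_real_),
                          apoptosis_achievable = FALSE, dose_max = dose_max,
                          low_plateau = ss[1], high_plateau = NA_real_),
                     class = "critical_dose_result"))
  }
  low <- median(head(ss, min(3, sw$first_high - 1L)))
  high <- median(tail(ss, min(3, length(ss) - sw$first_high + 1L)))
  fate <- function(s) classify_fate(s, low, high)
  if (fate(ss[1]) == "apoptosis") stop("degenerate model: apoptosis at dose 0")
  lo_d <- doses[sw$first_high - 1L]; hi_d <- doses[sw$first_high]
  while (hi_d - lo_d > tol) {
    mid <- (lo_d + hi_d) / 2
    if (fate(ss_at(mid)) == "apoptosis") hi_d <- mid else lo_d <- mid
  }
  structure(list(cd = hi_d, bracket = c(lo_d, hi_d),
                 apoptosis_achievable = TRUE, dose_max = dose_max,
                 low_plateau = low, high_plateau = high),
            class = "critical_dose_result")
}

#' @export
print.critical_dose_result <- function(x, ...) {
  if (x$apoptosis_achievable) {
    cat("Critical dose Cd = ", signif(x$cd, 6), " amol (bracket ",
        signif(x$bracket[1], 6), " - ", signif(x$bracket[2], 6), ")\n", sep = "")
  } else {
    cat("No apoptosis achievable within dose_max = ", x$dose_max, " amol\n", sep = "")
  }
  invisible(x)
}

#' Dense-grid critical-dose oracle
#'
#' Brute-force switch location on a uniform dose grid; the independent
#' reference the bisection search is checked against.  The reported value
#' is the first grid dose classified as apoptosis.
#'
#' @inheritParams find_critical_dose
#' @param n_grid number of uniform grid points (default 4000)
#' @return list with `cd` (amol, NA when no switch), `spacing` and
#'   `apoptosis_achievable`
#' @export
critical_dose_grid <- function(network, dose_max = 1e-2, n_grid = 4000L, ...) {
  exec <- .role_index(network, "caspase3_active")
  ss_at <- function(d) unname(steady_state(network, d, ...)$state[exec])
  coarse <- c(0, dose_max * 2^(-7:0))
  ss <- vapply(coarse, ss_at, 0)
  sw <- .detect_switch(ss)
  if (!sw$switch)
    return(list(cd = NA_real_, spacing = dose_max / n_grid,
                apoptosis_achievable = FALSE))
  thr <- (median(head(ss, min(3, sw$first_high - 1L))) +
          median(tail(ss, min(3, length(ss) - sw$first_high + 1L)))) / 2
  doses <- seq(0, dose_max, length.out = n_grid + 1L)[-1]
  # monotone switch: binary search over the uniform grid indices gives the
  # same first-apoptotic index as a full left-to-right scan
  lo_i <- 0L; hi_i <- length(doses)
  while (hi_i - lo_i > 1L) {
    mid <- (lo_i + hi_i) %/% 2L
    if (ss_at(doses[mid]) >= thr) hi_i <- mid else lo_i <- mid
  }
  list(cd = doses[hi_i], spacing = dose_max / n_grid, apoptosis_achievable = TRUE)
}
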