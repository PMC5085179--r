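#' Integrate a network to a trajectory
#'
#' Stiff integration (lsoda) of the mass-action ODEs from the network's
#' initial amounts, with the clamped input species held at `dose` for the
#' whole run (sustained stimulus).
#'
#' @param network a [reaction_network()]
#' @param dose amount (amol, >= 0) at which the input species is clamped;
#'   ignored (with a warning) if the network has no input species
#' @param t_end end time in seconds
#' @param times optional explicit output grid (seconds, strictly
#'   increasing, starting at 0); default 400 equally spaced points —
#'   dense enough to resolve the executioner-caspase switch timing
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-12 amol)
#' @return A `trajectory`: list with `times`, `states` (time x species
#'   matrix, small solver negatives clipped to 0) and `dose`.
#' @export
simulate_network <- function(network, dose, t_end, times = NULL,
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(dose >= 0, t_end > 0)
  y0 <- network$species$initial_amount
  names(y0) <- network$species$id
  if (length(network$.input)) {
    y0[network$.input] <- dose
  } else if (dose != 0) {
    warning("network has no clamped input species; dose ignored")
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 400L)
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must start at 0 and be strictly increasing")
  fn <- .deriv_fn(network)
  out <- deSolve::lsoda(y0, times, fn, parms = NULL, rtol = rtol, atol = atol, maxsteps = 100000L)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integrator failure (istate = ", diagn[1], ") at dose ", dose,
         "; reached t = ", max(out[, 1]))
  if (nrow(out) < length(times))
    stop("integrator stopped early at t = ", max(out[, 1]), " (dose ", dose, ")")
  states <- unname(out[, -1, drop = FALSE])
  low <- states < 0
  if (any(states[low] < -10 * rtol))
    warning("amounts below -10*rtol encountered; clipped")
  states[low] <- 0
  colnames(states) <- network$species$id
  structure(list(times = times, states = states, dose = dose),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " time points over ",
      max(x$times), " s at clamped dose ", x$dose, " amol\n", sep = "")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, species = NULL, log_time = FALSE, ...) {
  sp <- if (is.null(species)) colnames(x$states) else species
  matplot(x$times, x$states[, sp, drop = FALSE], type = "l", lty = 1,
          xlab = "time (s)", ylab = "amount (amol)",
          log = if (log_time) "x" else "", ...)
  legend("topleft", legend = sp, col = seq_along(sp), lty = 1, bty = "n")
  invisible(x)
}

#' Steady state under a sustained stimulus
#'
#' Integrates in doubling time chunks until the relative derivative
#' criterion `max |dC/dt| / (1 + |C|) < ss_tol` holds both at the current
#' time and at a checkpoint 5% of elapsed time earlier, or `t_max` is
#' reached.  Non-convergence is flagged, never thrown.
#'
#' @inheritParams simulate_network
#' @param ss_tol relative-derivative tolerance (1/s), default 1e-9
#' @param t_max horizon in seconds, default 48 simulated hours
#' @param t0 first chunk length (seconds)
#' @return list with `state` (named amounts), `converged` (logical) and
#'   `time` (seconds integrated).
#' @export
steady_state <- function(network, dose, ss_tol = 1e-9, t_max = 48 * 3600,
                         t0 = 1800, rtol = 1e-8, atol = 1e-12) {
  stopifnot(dose >= 0)
  y <- network$species$initial_amount
  names(y) <- network$species$id
  if (length(network$.input)) y[network$.input] <- dose
  fn <- .deriv_fn(network)
  crit <- function(st) max(abs(fn(0, pmax(st, 0), NULL)[[1]]) / (1 + abs(st)))
  elapsed <- 0
  chunk <- t0
  repeat {
    chunk <- min(chunk, t_max - elapsed)
    ts <- c(0, 0.95 * chunk, chunk)
    out <- deSolve::lsoda(y, ts, fn, parms = NULL, rtol = rtol, atol = atol, maxsteps = 100000L)
    if (nrow(out) < 3L)
      stop("integrator failure during steady-state run at dose ", dose,
           " (t = ", elapsed + max(out[, 1]), " s)")
    y_chk <- pmax(out[2, -1], 0)
    y <- pmax(out[3, -1], 0)
    elapsed <- elapsed + chunk
    if (crit(y) < ss_tol && crit(y_chk) < ss_tol)
      return(list(state = y, converged = TRUE, time = elapsed))
    if (elapsed >= t_max)
      return(list(state = y, converged = FALSE, time = elapsed))
    chunk <- chunk * 2
  }
}
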