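#' Sensitivity-analysis configuration
#'
#' The single-parameter protocol: each rate constant is varied by
#' `+/- perturb_fraction` (default 20%) around its default, the critical
#' dose is recomputed for both directions, and the recorded increase
#' `delta_cd` makes the parameter sensitive when
#' `delta_cd >= sensitive_cutoff * cd_base` (default 10%).
#'
#' @param perturb_fraction fractional perturbation, in (0, 1)
#' @param sensitive_cutoff relative-increase cutoff, in (0, 1)
#' @param dose_max,tol passed through to [find_critical_dose()]
#' @param cache logical; reuse cached critical doses keyed by
#'   (network hash, dose_max, tol)
#' @export
sensitivity_config <- function(perturb_fraction = 0.20, sensitive_cutoff = 0.10,
                               dose_max = 1e-2, tol = dose_max / 2000,
                               cache = TRUE) {
  stopifnot(perturb_fraction > 0, perturb_fraction < 1,
            sensitive_cutoff > 0, sensitive_cutoff < 1)
  structure(list(perturb_fraction = perturb_fraction,
                 sensitive_cutoff = sensitive_cutoff,
                 dose_max = dose_max, tol = tol, cache = cache),
            class = "sensitivity_config")
}

.cd_cache <- new.env(parent = emptyenv())

#' Clear the critical-dose cache
#' @export
clear_cd_cache <- function() {
  rm(list = ls(.cd_cache), envir = .cd_cache)
  invisible(NULL)
}

# Cached critical dose as a single number (Inf when apoptosis is lost).
.cd_of <- function(network, config) {
  key <- if (isTRUE(config$cache))
    digest::digest(list(network_hash(network), config$dose_max, config$tol))
  if (!is.null(key) && !is.null(v <- .cd_cache[[key]])) return(v)
  res <- find_critical_dose(network, dose_max = config$dose_max, tol = config$tol)
  v <- if (res$apoptosis_achievable) res$cd else Inf
  if (!is.null(key)) .cd_cache[[key]] <- v
  v
}

#' Scale one rate constant
#'
#' Returns a copy of the network with `k <- factor * k` for the named
#' parameter; the base network is untouched.
#'
#' @param network a [reaction_network()]
#' @param parameter_id parameter to scale
#' @param factor positive multiplier
#' @export
perturb <- function(network, parameter_id, factor) {
  stopifnot(factor > 0)
  i <- match(parameter_id, network$parameters$id)
  if (is.na(i)) stop("unknown parameter id: ", parameter_id)
  network$parameters$value[i] <- factor * network$parameters$value[i]
  .index_network(network)
}

#' Single-parameter sensitivity of the critical dose
#'
#' Perturbs one parameter by `+/- perturb_fraction`, recomputes the
#' critical dose in both directions, and records the increase
#' `delta_cd = max(0, max(cd_up, cd_down) - cd_base)`.  A perturbed model
#' that loses apoptosis within `dose_max` gets an infinite critical dose
#' (and is therefore sensitive).
#'
#' @inheritParams perturb
#' @param config a [sensitivity_config()]
#' @param cd_base optional precomputed base critical dose
#' @return one-row data.frame: `parameter_id`, `cd_base`, `cd_up`,
#'   `cd_down`, `delta_cd`, `relative_delta`, `direction` (the
#'   Cd-increasing factor, NA when neither direction increases Cd) and
#'   `sensitive`.
#' @export
single_parameter_sensitivity <- function(network, parameter_id,
                                         config = sensitivity_config(),
                                         cd_base = NULL) {
  if (is.null(cd_base)) cd_base <- .cd_of(network, config)
  if (!is.finite(cd_base))
    stop("degenerate base model: no finite critical dose within dose_max")
  f <- config$perturb_fraction
  cd_up <- .cd_of(perturb(network, parameter_id, 1 + f), config)
  cd_down <- .cd_of(perturb(network, parameter_id, 1 - f), config)
  delta <- max(0, max(cd_up, cd_down) - cd_base)
  direction <- if (delta == 0) NA_real_ else if (cd_up >= cd_down) 1 + f else 1 - f
  data.frame(parameter_id = parameter_id, cd_base = cd_base,
             cd_up = cd_up, cd_down = cd_down, delta_cd = delta,
             relative_delta = delta / cd_base, direction = direction,
             sensitive = delta >= config$sensitive_cutoff * cd_base)
}

#' Parameter sensitivity spectrum
#'
#' Runs [single_parameter_sensitivity()] over an ordered parameter set
#' and assembles the Boolean spectrum (1 = sensitive).  Per-parameter
#' failures are recorded (`NA` flags) and the run continues.
#'
#' @inheritParams single_parameter_sensitivity
#' @param parameter_ids ordered ids; default all network parameters
#' @return a `sensitivity_spectrum`: list with `parameter_ids`, `flags`
#'   (logical), `records` (row-bound data.frame) and `cd_base`.
#' @export
build_spectrum <- function(network, parameter_ids = NULL,
                           config = sensitivity_config()) {
  if (is.null(parameter_ids)) parameter_ids <- network$parameters$id
  cd_base <- .cd_of(network, config)
  if (!is.finite(cd_base))
    stop("degenerate base model: no finite critical dose within dose_max")
  recs <- lapply(parameter_ids, function(p) {
    tryCatch(single_parameter_sensitivity(network, p, config, cd_base = cd_base),
             error = function(e)
               data.frame(parameter_id = p, cd_base = cd_base, cd_up = NA_real_,
                          cd_down = NA_real_, delta_cd = NA_real_,
                          relative_delta = NA_real_, direction = NA_real_,
                          sensitive = NA, error = conditionMessage(e)))
  })
  recs <- do.call(rbind, lapply(recs, function(r) {
    if (is.null(r$error)) r$error <- NA_character_; r
  }))
  structure(list(parameter_ids = parameter_ids, flags = recs$sensitive,
                 records = recs, cd_base = cd_base),
            class = "sensitivity_spectrum")
}

#' @export
print.sensitivity_spectrum <- function(x, ...) {
  cat("Sensitivity spectrum over ", length(x$parameter_ids), " parameters (Cd_base = ",
      signif(x$cd_base, 5), " amol): ", sum(x$flags, na.rm = TRUE), " sensitive\n", sep = "")
  print(setNames(as.integer(x$flags), x$parameter_ids))
  invisible(x)
}

#' Boolean view of a sensitivity spectrum
#' @param x a `sensitivity_spectrum`
#' @return a [boolean_spectrum()] over parameters
#' @export
as_boolean_spectrum <- function(x) {
  stopifnot(inherits(x, "sensitivity_spectrum"))
  boolean_spectrum(x$parameter_ids, as.logical(x$flags), provenance = "sensitivity")
}

#' Joint perturbation of several parameters
#'
#' Each parameter is moved by `perturb_fraction` in its own
#' single-parameter Cd-increasing direction (parameters whose
#' single-parameter record shows no increasing direction are left at
#' their default), all simultaneously; returns the relative critical-dose
#' change `(Cd_pert - Cd_base) / Cd_base`.
#'
#' @inheritParams single_parameter_sensitivity
#' @param parameter_ids two or more parameter ids (duplicates collapse)
#' @export
multi_parameter_delta <- function(network, parameter_ids,
                                  config = sensitivity_config()) {
  stopifnot(length(parameter_ids) >= 2)
  parameter_ids <- unique(parameter_ids)
  cd_base <- .cd_of(network, config)
  if (!is.finite(cd_base)) stop("degenerate base model: no finite critical dose")
  pert <- network
  for (p in parameter_ids) {
    rec <- single_parameter_sensitivity(network, p, config, cd_base = cd_base)
    if (!is.na(rec$direction)) pert <- perturb(pert, p, rec$direction)
  }
  cd_pert <- .cd_of(pert, config)
  (cd_pert - cd_base) / cd_base
}

#' ROC sweep over the sensitivity cutoff
#'
#' Sweeps the relative-increase cutoff over the observed
#' `relative_delta` values, computing TPR/FPR of the induced sensitive
#' calls against a Boolean truth vector (e.g., a mutation spectrum), plus
#' Youden's J = TPR - FPR.  Ties in J are broken toward the smaller
#' cutoff.
#'
#' @param records data.frame with `relative_delta` (from
#'   [build_spectrum()]`$records`) or a `sensitivity_spectrum`
#' @param truth_labels logical vector over the same parameters
#' @return list with `roc` (data.frame cutoff/tpr/fpr/youden) and
#'   `best_cutoff`
#' @export
cutoff_roc <- function(records, truth_labels) {
  if (inherits(records, "sensitivity_spectrum")) records <- records$records
  scores <- records$relative_delta
  stopifnot(length(scores) == length(truth_labels))
  truth_labels <- as.logical(truth_labels)
  if (all(truth_labels) || !any(truth_labels))
    stop("undefined ROC: truth labels are all equal")
  fin <- scores
  fin[!is.finite(fin)] <- max(fin[is.finite(fin)], 0) + 1 # Inf outranks everything
  cutoffs <- sort(unique(c(0, fin, max(fin) * 1.01)))
  pos <- sum(truth_labels); neg <- sum(!truth_labels)
  roc <- do.call(rbind, lapply(cutoffs, function(cut) {
    call <- fin >= cut
    data.frame(cutoff = cut,
               tpr = sum(call & truth_labels) / pos,
               fpr = sum(call & !truth_labels) / neg)
  }))
  roc$youden <- roc$tpr - roc$fpr
  best <- roc$cutoff[which.max(roc$youden)] # which.max takes the first = smallest
  list(roc = roc, best_cutoff = best)
}
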