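#' Biochemical reaction networks with mass-action kinetics
#'
#' A `reaction_network` bundles an ordered species list, a list of
#' irreversible mass-action reactions, a kinetic-parameter table and the
#' stoichiometric matrix derived from them.  Amounts are in amol, time in
#' seconds.  One species may be flagged as the clamped external input
#' (the TNF-alpha stimulus); its time derivative is forced to zero so a
#' sustained stimulus is modelled as a constant amount.
#'
#' @param species data.frame with columns `id`, `name`, `initial_amount`
#'   (amol, >= 0) and `is_input` (logical; exactly one `TRUE` for a
#'   stimulated network, none for a closed one).
#' @param reactions list of reactions, each a list with elements `id`,
#'   `rate_constant_id` (a row of `parameters`), `reactants` and
#'   `products` (named integer vectors, species id -> stoichiometry;
#'   empty vectors denote pure production/degradation).
#' @param parameters data.frame with columns `id`, `value` (>= 0) and
#'   `category`, one of `"association"`, `"dissociation"`,
#'   `"degradation"`, `"enzymatic"`, `"production"`.  The category drives
#'   the exclusion of production parameters from gene mapping (see
#'   [gene_parameter_map()]).
#' @param roles optional named character vector mapping the standard
#'   roles (`tnf_input`, `complex1`, `complex2`, `nfkb_active`,
#'   `caspase3_active`, `caspase8_active`, `caspase6_active`) to species
#'   ids; required by the dose-response and feedback machinery.
#'
#' @return An object of class `reaction_network`.
#' @seealso [evaluate_rates()], [network_derivative()],
#'   [simulate_network()], [steady_state()]
#' @export
reaction_network <- function(species, reactions, parameters, roles = NULL) {
  stopifnot(is.data.frame(species), is.list(reactions), is.data.frame(parameters))
  species$id <- as.character(species$id)
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$is_input)) species$is_input <- FALSE
  if (anyDuplicated(species$id))
    stop("duplicate species ids: ", paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (any(species$initial_amount < 0))
    stop("negative initial amounts for: ",
         paste(species$id[species$initial_amount < 0], collapse = ", "))
  if (sum(species$is_input) > 1) stop("at most one clamped input species allowed")

  parameters$id <- as.character(parameters$id)
  if (anyDuplicated(parameters$id)) stop("duplicate parameter ids")
  if (any(parameters$value < 0)) stop("negative rate constants")
  ok_cat <- c("association", "dissociation", "degradation", "enzymatic", "production")
  if (is.null(parameters$category) || !all(parameters$category %in% ok_cat))
    stop("every parameter needs a category in: ", paste(ok_cat, collapse = ", "))

  n_sp <- nrow(species)
  n_rx <- length(reactions)
  S <- matrix(0L, n_sp, n_rx,
              dimnames = list(species$id, vapply(reactions, `[[`, "", "id")))
  if (anyDuplicated(colnames(S))) stop("duplicate reaction ids")
  for (b in seq_len(n_rx)) {
    rx <- reactions[[b]]
    for (side in c("reactants", "products")) {
      st <- rx[[side]]
      if (length(st)) {
        if (any(st != as.integer(st)) || any(st <= 0))
          stop("stoichiometries must be positive integers (reaction ", rx$id, ")")
        miss <- setdiff(names(st), species$id)
        if (length(miss)) stop("unknown species in reaction ", rx$id, ": ",
                               paste(miss, collapse = ", "))
      }
    }
    if (!rx$rate_constant_id %in% parameters$id)
      stop("reaction ", rx$id, " references unknown parameter ", rx$rate_constant_id)
    if (length(rx$reactants))
      S[names(rx$reactants), b] <- S[names(rx$reactants), b] - as.integer(rx$reactants)
    if (length(rx$products))
      S[names(rx$products), b] <- S[names(rx$products), b] + as.integer(rx$products)
  }

  net <- structure(list(
    species = species,
    reactions = reactions,
    parameters = parameters,
    stoichiometric_matrix = S,
    extra_rate_terms = list(),
    roles = roles
  ), class = "reaction_network")
  .index_network(net)
}

# Precompute fast-access indices used by the rate/derivative kernels.
.index_network <- function(net) {
  sp_ids <- net$species$id
  pidx <- match(vapply(net$reactions, `[[`, "", "rate_constant_id"), net$parameters$id)
  net$.k <- net$parameters$value[pidx]
  net$.pidx <- pidx
  net$.ridx <- lapply(net$reactions, function(rx) match(names(rx$reactants), sp_ids))
  net$.rst  <- lapply(net$reactions, function(rx) as.numeric(rx$reactants))
  net$.input <- which(net$species$is_input)
  # reactant-stoichiometry matrix (species x reactions) for the vectorized
  # log-space rate kernel: J = k * exp(t(R) %*% log(state))
  R <- matrix(0, nrow(net$species), length(net$reactions))
  for (b in seq_along(net$reactions))
    if (length(net$.ridx[[b]])) R[net$.ridx[[b]], b] <- net$.rst[[b]]
  net$.R <- R
  net$.S <- unname(net$stoichiometric_matrix) * 1.0
  net
}

# Lean derivative closure for the integrator hot path: no validation, no
# names.  pmax(, 0) guards the log against tiny solver negatives.
.deriv_fn <- function(net) {
  k <- net$.k; R <- net$.R; S <- net$.S
  terms <- net$extra_rate_terms
  input <- net$.input
  function(t, y, p) {
    J <- k * exp(crossprod(R, log(pmax(y, 1e-300)))[, 1])
    d <- S %*% J
    for (tm in terms) {
      if (tm$sign == "positive")
        d[tm$target] <- d[tm$target] + tm$strength * max(y[tm$source], 0)
      else
        d[tm$target] <- d[tm$target] - tm$strength * max(y[tm$source], 0) * max(y[tm$target], 0)
    }
    if (length(input)) d[input] <- 0
    list(d[, 1])
  }
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network\n")
  cat("  species:   ", nrow(x$species), "\n")
  cat("  reactions: ", length(x$reactions), "\n")
  cat("  parameters:", nrow(x$parameters), "\n")
  if (length(x$.input)) cat("  clamped input:", x$species$id[x$.input], "\n")
  if (length(x$extra_rate_terms))
    cat("  injected feedback terms:", length(x$extra_rate_terms), "\n")
  invisible(x)
}

.check_state <- function(net, state, neg_tol = 1e-9) {
  if (length(state) != nrow(net$species))
    stop("state length ", length(state), " != species count ", nrow(net$species))
  if (any(state < -neg_tol))
    stop("invalid state: negative amounts beyond tolerance for ",
         paste(net$species$id[state < -neg_tol], collapse = ", "))
  pmax(state, 0)
}

#' Mass-action reaction rates
#'
#' Evaluates every reaction's rate `k * prod(amount[reactant]^stoich)` at
#' the given state.  Injected feedback terms are *not* part of the
#' reaction list; they enter only through [network_derivative()].
#'
#' @param network a [reaction_network()]
#' @param state numeric vector of species amounts (amol), in species order
#' @param neg_tol negative amounts larger than `-neg_tol` are clipped to
#'   zero; anything below errors.
#' @return numeric vector of reaction rates (amol/s), in reaction order.
#' @export
evaluate_rates <- function(network, state, neg_tol = 1e-9) {
  state <- .check_state(network, state, neg_tol)
  n_rx <- length(network$reactions)
  J <- network$.k
  ridx <- network$.ridx
  rst <- network$.rst
  for (b in seq_len(n_rx)) {
    ii <- ridx[[b]]
    if (length(ii)) J[b] <- J[b] * prod(state[ii]^rst[[b]])
  }
  names(J) <- colnames(network$stoichiometric_matrix)
  J
}

#' Time derivative of the species amounts
#'
#' `dC/dt = nu %*% J` plus the contribution of any injected feedback
#' terms (see [inject_feedback()]).  The clamped input species' derivative
#' is forced to zero (sustained stimulus).
#'
#' @inheritParams evaluate_rates
#' @return numeric vector `dC/dt` (amol/s) in species order.
#' @export
network_derivative <- function(network, state, neg_tol = 1e-9) {
  J <- evaluate_rates(network, state, neg_tol)
  d <- drop(network$stoichiometric_matrix %*% J)
  st <- pmax(state, 0)
  for (tm in network$extra_rate_terms) {
    if (tm$sign == "positive") {
      d[tm$target] <- d[tm$target] + tm$strength * st[tm$source]
    } else {
      d[tm$target] <- d[tm$target] - tm$strength * st[tm$source] * st[tm$target]
    }
  }
  if (length(network$.input)) d[network$.input] <- 0
  names(d) <- network$species$id
  d
}

#' Resolve a named role to a species index
#' @keywords internal
.role_index <- function(network, role) {
  if (is.null(network$roles) || is.na(network$roles[role]) || !role %in% names(network$roles))
    stop("network has no species mapped to role '", role, "'")
  i <- match(network$roles[[role]], network$species$id)
  if (is.na(i)) stop("role '", role, "' maps to unknown species '", network$roles[[role]], "'")
  i
}

#' Stable content hash of a network
#'
#' Used as a cache key for critical-dose searches: two networks with the
#' same species, reactions, parameter values, initial amounts and
#' injected terms hash identically.
#' @param network a [reaction_network()]
#' @return character scalar
#' @export
network_hash <- function(network) {
  digest::digest(list(network$species, lapply(network$reactions, function(r)
    r[c("id", "rate_constant_id", "reactants", "products")]),
    network$parameters[c("id", "value")],
    lapply(network$extra_rate_terms, function(t) t[c("source", "target", "sign", "strength")])))
}
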