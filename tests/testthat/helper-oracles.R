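# Shared oracles and miniature fixtures, all built in code.

# Naive per-reaction mass-action rate oracle, independent of the
# package's vectorized kernel.
oracle_rates <- function(net, state) {
  sapply(seq_along(net$reactions), function(b) {
    rx <- net$reactions[[b]]
    k <- net$parameters$value[match(rx$rate_constant_id, net$parameters$id)]
    v <- k
    for (sp in names(rx$reactants))
      v <- v * state[[match(sp, net$species$id)]]^rx$reactants[[sp]]
    v
  })
}

# Element-wise accumulation oracle for nu %*% J.
oracle_deriv <- function(net, state) {
  J <- oracle_rates(net, state)
  d <- numeric(nrow(net$species))
  for (b in seq_along(net$reactions)) {
    rx <- net$reactions[[b]]
    for (sp in names(rx$reactants))
      d[match(sp, net$species$id)] <- d[match(sp, net$species$id)] - rx$reactants[[sp]] * J[b]
    for (sp in names(rx$products))
      d[match(sp, net$species$id)] <- d[match(sp, net$species$id)] + rx$products[[sp]] * J[b]
  }
  if (any(net$species$is_input)) d[net$species$is_input] <- 0
  d
}

# Classic fixed-step RK4 on the package's derivative; the independent
# integration oracle for small horizons.
oracle_rk4 <- function(net, dose, t_end, n_steps) {
  y <- net$species$initial_amount
  if (any(net$species$is_input)) y[net$species$is_input] <- dose
  h <- t_end / n_steps
  f <- function(y) {
    d <- network_derivative(net, pmax(y, 0))
    unname(d)
  }
  for (i in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  setNames(y, net$species$id)
}

# Random small mass-action network (no clamped input, no feedback).
random_network <- function(n_sp = 5, n_rx = 8, seed = 1) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_sp))
  species <- data.frame(id = ids, name = ids,
                        initial_amount = runif(n_sp, 0, 2), is_input = FALSE)
  params <- data.frame(id = paste0("k", seq_len(n_rx)),
                       value = runif(n_rx, 0, 3),
                       category = sample(c("association", "dissociation",
                                           "degradation", "enzymatic"),
                                         n_rx, replace = TRUE))
  reactions <- lapply(seq_len(n_rx), function(b) {
    nr <- sample(0:2, 1); np <- sample(0:2, 1)
    if (nr == 0 && np == 0) np <- 1
    list(id = paste0("r", b), rate_constant_id = paste0("k", b),
         reactants = if (nr) setNames(sample(1:2, nr, TRUE),
                                      sample(ids, nr)) else integer(0),
         products = if (np) setNames(sample(1:2, np, TRUE),
                                     sample(ids, np)) else integer(0))
  })
  reaction_network(species, reactions, params)
}

# One-step conversion A ->(k) B.
ab_network <- function(k = 2, a0 = 3) {
  reaction_network(
    species = data.frame(id = c("A", "B"), name = c("A", "B"),
                         initial_amount = c(a0, 0), is_input = FALSE),
    reactions = list(list(id = "conv", rate_constant_id = "k",
                          reactants = c(A = 1L), products = c(B = 1L))),
    parameters = data.frame(id = "k", value = k, category = "enzymatic"))
}

# Decay A ->(k) 0.
decay_network <- function(k = 1, a0 = 1) {
  reaction_network(
    species = data.frame(id = "A", name = "A", initial_amount = a0,
                         is_input = FALSE),
    reactions = list(list(id = "deg", rate_constant_id = "k",
                          reactants = c(A = 1L), products = integer(0))),
    parameters = data.frame(id = "k", value = k, category = "degradation"))
}

# Reversible isomerization A <-> B (two irreversible reactions).
abba_network <- function(kf = 1, kr = 1, a0 = 1, b0 = 0) {
  reaction_network(
    species = data.frame(id = c("A", "B"), name = c("A", "B"),
                         initial_amount = c(a0, b0), is_input = FALSE),
    reactions = list(
      list(id = "f", rate_constant_id = "kf", reactants = c(A = 1L),
           products = c(B = 1L)),
      list(id = "r", rate_constant_id = "kr", reactants = c(B = 1L),
           products = c(A = 1L))),
    parameters = data.frame(id = c("kf", "kr"), value = c(kf, kr),
                            category = "enzymatic"))
}

# The default toy is expensive to re-derive per file; build it once per
# test session and reuse (validation off: dedicated tests cover it).
toy_cached <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- make_toy_network(toy_config(validate = FALSE))
    net
  }
})

# Small fast-but-valid sensitivity configuration for tests that only
# need label-level agreement.
fast_config <- function() sensitivity_config(tol = 1e-2 / 1000)
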