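#' Configuration for the reduced survival/apoptosis toy network
#'
#' @param rate_overrides named numeric vector of parameter values to
#'   override (ids must exist in the toy parameter table)
#' @param planted_feedback optional [feedback_spec()] injected into the
#'   returned network ("true" biology for recovery experiments)
#' @param seed optional integer; when given, every rate constant is
#'   jittered by an independent log-uniform factor in
#'   `[1 - jitter, 1 + jitter]` — a random re-parameterization inside the
#'   generator's stability envelope
#' @param jitter half-width of the multiplicative jitter (default 0.01;
#'   the all-or-none switch sits in a narrow operating window, and wider
#'   joint jitter of all 30 rate constants walks the critical dose out of
#'   the admissible dose range or off the ground-truth labels)
#' @param validate logical; check the survival/apoptosis switch at build
#'   time (default TRUE)
#' @export
toy_config <- function(rate_overrides = NULL, planted_feedback = NULL,
                       seed = NULL, jitter = 0.01, validate = TRUE) {
  stopifnot(jitter >= 0, jitter < 0.5)
  structure(list(rate_overrides = rate_overrides,
                 planted_feedback = planted_feedback,
                 seed = seed, jitter = jitter, validate = validate),
            class = "toy_config")
}

# Default kinetic constants of the toy network (amol / s units).  The
# *_b parameters are deliberately minor parallel routes (5% of their
# main route): individually weak handles whose joint perturbation still
# accumulates a visible critical-dose shift.  The 5% share keeps their
# relative critical-dose shift well clear of the 10% sensitivity cutoff
# across the generator's whole jitter envelope.
.toy_rates <- function() c(
  kp_rec  = 7e-6,   # receptor production                 [production]
  kd_rec  = 1e-4,   # receptor turnover
  ka_bind = 2.5e-3, # TNF + receptor -> Complex I analog  [association]
  kd_c1   = 2e-4,   # Complex I dissociation back to receptor
  ka_c1c2 = 4.75e-4, # Complex I -> Complex II conversion (main route)
  ka_c1c2b = 2.5e-5, # Complex I -> Complex II, minor parallel route
  kd_c2   = 1e-3,   # Complex II turnover
  kp_nfkb = 1e-5,   # NFkB synthesis (inactive form)      [production]
  kd_nfkbi = 1e-4,  # inactive-NFkB turnover
  ka_nfkb = 1.0,    # Complex-I-catalysed NFkB activation
  ki_nfkb = 5.85e-3, # NFkB inactivation
  kp_iap  = 1e-3,   # NFkB-induced inhibitor production   [production]
  kd_iap  = 1e-3,   # inhibitor turnover
  kp_c8   = 1e-5,   # procaspase8 production (the caspase-production analog) [production]
  kd_c8i  = 1e-4,   # procaspase8 turnover
  ka_c8   = 1.9e-2,  # Complex-II-catalysed caspase8 activation (main route)
  ka_c8b  = 1e-3,   # caspase8 activation, minor parallel route
  kd_c8   = 1e-3,   # caspase8 turnover
  ki_c8   = 6e-2,   # inhibitor-mediated caspase8 removal (FLIP analog)
  kp_pro3 = 1e-4,   # procaspase3 production              [production]
  kd_pro3 = 1e-3,   # procaspase3 turnover
  ka_c3   = 3.8e-2,  # caspase8-catalysed caspase3 activation (main route)
  ka_c3b  = 2e-3,   # caspase3 activation, minor parallel route
  ka_auto = 2.0,    # executioner self-amplification (2 casp3 + pro3 -> 3 casp3)
  kd_c3   = 1e-3,   # caspase3 turnover
  ki_c3   = 1e-2,   # inhibitor-mediated caspase3 removal (XIAP analog)
  ka_c6   = 1e-3,   # caspase3-catalysed caspase6 activation
  kd_c6   = 1e-3,   # caspase6 turnover
  kp_dec  = 5e-5,   # decoy production                     [production]
  kd_dec  = 1e-3    # decoy turnover (the decoy parameter)
)

.toy_categories <- c(
  kp_rec = "production", kd_rec = "degradation", ka_bind = "association",
  kd_c1 = "dissociation", ka_c1c2 = "enzymatic", ka_c1c2b = "enzymatic",
  kd_c2 = "degradation", kp_nfkb = "production", kd_nfkbi = "degradation",
  ka_nfkb = "enzymatic", ki_nfkb = "enzymatic",
  kp_iap = "production", kd_iap = "degradation", kp_c8 = "production",
  kd_c8i = "degradation", ka_c8 = "enzymatic", ka_c8b = "enzymatic",
  kd_c8 = "degradation", ki_c8 = "enzymatic", kp_pro3 = "production",
  kd_pro3 = "degradation", ka_c3 = "enzymatic", ka_c3b = "enzymatic",
  ka_auto = "enzymatic", kd_c3 = "degradation", ki_c3 = "enzymatic",
  ka_c6 = "enzymatic", kd_c6 = "degradation", kp_dec = "production",
  kd_dec = "degradation")

# Ground-truth sensitivity labels of the default toy parameterization
# (sensitive = +/-20% perturbation moves the critical dose by >= 10%).
# Established with the dense-grid critical-dose oracle during generator
# design; the jitter default keeps them stable (the stability envelope).
.toy_truth <- c(
  kp_rec = TRUE,  kd_rec = TRUE,  ka_bind = TRUE,  kd_c1 = FALSE,
  ka_c1c2 = TRUE, ka_c1c2b = FALSE, kd_c2 = TRUE,  kp_nfkb = TRUE,
  kd_nfkbi = TRUE, ka_nfkb = TRUE,
  ki_nfkb = TRUE, kp_iap = TRUE,  kd_iap = TRUE,   kp_c8 = TRUE,
  kd_c8i = TRUE,  ka_c8 = TRUE,   ka_c8b = FALSE,  kd_c8 = TRUE,
  ki_c8 = TRUE,   kp_pro3 = TRUE, kd_pro3 = TRUE,  ka_c3 = TRUE,
  ka_c3b = FALSE, ka_auto = TRUE, kd_c3 = TRUE,    ki_c3 = TRUE,
  ka_c6 = FALSE,  kd_c6 = FALSE,  kp_dec = FALSE,  kd_dec = FALSE)

#' Build the reduced bistable survival/apoptosis network
#'
#' A 13-species, 30-reaction mass-action caricature of the TNF-alpha
#' cell-fate network: clamped TNF input binds a turned-over receptor to
#' form a Complex I analog, which (i) activates NFkB, inducing an
#' anti-apoptotic inhibitor (FLIP/XIAP analog), and (ii) converts to a
#' Complex II analog that activates the initiator caspase; the initiator
#' activates the executioner caspase, whose bimolecular
#' self-amplification produces an all-or-none steady-state switch.  One
#' decoy species is fully decoupled from the fate readout.
#'
#' At the default rates the network survives at dose 0, has a finite
#' critical dose inside (0, 1e-2) amol, loses apoptosis when the
#' caspase-production analog `kp_c8` is scaled by 0.6, and carries the
#' ground-truth sensitive/insensitive labels returned in
#' `attr(net, "truth")`.
#'
#' @param config a [toy_config()]
#' @return a [reaction_network()] with a full role map; attributes
#'   `truth` (named logical ground-truth sensitivity labels) and
#'   `config`.
#' @export
make_toy_network <- function(config = toy_config()) {
  stopifnot(inherits(config, "toy_config"))
  k <- .toy_rates()
  if (!is.null(config$seed)) {
    set.seed(as.integer(config$seed))
    k <- k * exp(runif(length(k), log(1 - config$jitter), log(1 + config$jitter)))
  }
  if (!is.null(config$rate_overrides)) {
    bad <- setdiff(names(config$rate_overrides), names(k))
    if (length(bad)) stop("unknown toy parameters in overrides: ",
                          paste(bad, collapse = ", "))
    k[names(config$rate_overrides)] <- config$rate_overrides
  }

  species <- data.frame(
    id = c("tnf", "rec", "c1", "c2", "nfkb_i", "nfkb", "iap",
           "c8i", "c8", "pro3", "casp3", "casp6", "decoy"),
    name = c("TNF-alpha (clamped)", "receptor", "Complex I analog",
             "Complex II analog", "NFkB (inactive)", "NFkB (active)",
             "anti-apoptotic inhibitor", "procaspase8", "caspase8",
             "procaspase3", "caspase3 (executioner)", "caspase6", "decoy"),
    initial_amount = c(0, k[["kp_rec"]] / k[["kd_rec"]], 0, 0,
                       k[["kp_nfkb"]] / k[["kd_nfkbi"]], 0, 0,
                       k[["kp_c8"]] / k[["kd_c8i"]], 0,
                       k[["kp_pro3"]] / k[["kd_pro3"]], 0, 0, 0.05),
    is_input = c(TRUE, rep(FALSE, 12)))

  rx <- function(id, kid, reac, prod)
    list(id = id, rate_constant_id = kid, reactants = reac, products = prod)
  none <- integer(0)
  reactions <- list(
    rx("prod_rec",  "kp_rec",  none,                    c(rec = 1L)),
    rx("deg_rec",   "kd_rec",  c(rec = 1L),             none),
    rx("bind_tnf",  "ka_bind", c(tnf = 1L, rec = 1L),   c(c1 = 1L)),
    rx("c1_off",    "kd_c1",   c(c1 = 1L),              c(rec = 1L)),
    rx("c1_to_c2",  "ka_c1c2", c(c1 = 1L),              c(c2 = 1L)),
    rx("c1_to_c2b", "ka_c1c2b", c(c1 = 1L),             c(c2 = 1L)),
    rx("deg_c2",    "kd_c2",   c(c2 = 1L),              none),
    rx("prod_nfkb", "kp_nfkb", none,                    c(nfkb_i = 1L)),
    rx("deg_nfkbi", "kd_nfkbi", c(nfkb_i = 1L),         none),
    rx("act_nfkb",  "ka_nfkb", c(c1 = 1L, nfkb_i = 1L), c(c1 = 1L, nfkb = 1L)),
    rx("inact_nfkb","ki_nfkb", c(nfkb = 1L),            c(nfkb_i = 1L)),
    rx("ind_iap",   "kp_iap",  c(nfkb = 1L),            c(nfkb = 1L, iap = 1L)),
    rx("deg_iap",   "kd_iap",  c(iap = 1L),             none),
    rx("prod_c8i",  "kp_c8",   none,                    c(c8i = 1L)),
    rx("deg_c8i",   "kd_c8i",  c(c8i = 1L),             none),
    rx("act_c8",    "ka_c8",   c(c2 = 1L, c8i = 1L),    c(c2 = 1L, c8 = 1L)),
    rx("act_c8b",   "ka_c8b",  c(c2 = 1L, c8i = 1L),    c(c2 = 1L, c8 = 1L)),
    rx("deg_c8",    "kd_c8",   c(c8 = 1L),              none),
    rx("inhib_c8",  "ki_c8",   c(iap = 1L, c8 = 1L),    c(iap = 1L)),
    rx("prod_pro3", "kp_pro3", none,                    c(pro3 = 1L)),
    rx("deg_pro3",  "kd_pro3", c(pro3 = 1L),            none),
    rx("act_c3",    "ka_c3",   c(c8 = 1L, pro3 = 1L),   c(c8 = 1L, casp3 = 1L)),
    rx("act_c3b",   "ka_c3b",  c(c8 = 1L, pro3 = 1L),   c(c8 = 1L, casp3 = 1L)),
    rx("auto_c3",   "ka_auto", c(casp3 = 2L, pro3 = 1L), c(casp3 = 3L)),
    rx("deg_c3",    "kd_c3",   c(casp3 = 1L),           none),
    rx("inhib_c3",  "ki_c3",   c(iap = 1L, casp3 = 1L), c(iap = 1L)),
    rx("act_c6",    "ka_c6",   c(casp3 = 1L),           c(casp3 = 1L, casp6 = 1L)),
    rx("deg_c6",    "kd_c6",   c(casp6 = 1L),           none),
    rx("prod_dec",  "kp_dec",  none,                    c(decoy = 1L)),
    rx("deg_dec",   "kd_dec",  c(decoy = 1L),           none))

  parameters <- data.frame(id = names(k), value = unname(k),
                           category = unname(.toy_categories[names(k)]))
  roles <- c(tnf_input = "tnf", complex1 = "c1", complex2 = "c2",
             nfkb_active = "nfkb", caspase3_active = "casp3",
             caspase8_active = "c8", caspase6_active = "casp6")
  net <- reaction_network(species, reactions, parameters, roles = roles)
  if (!is.null(config$planted_feedback))
    net <- inject_feedback(net, config$planted_feedback)
  if (isTRUE(config$validate))
    .validate_toy(net, check_abolition = is.null(config$seed) &&
                    is.null(config$rate_overrides) &&
                    is.null(config$planted_feedback))
  attr(net, "truth") <- .toy_truth
  attr(net, "config") <- config
  net
}

# Switch check: survival at dose 0 and an all-or-none jump within
# dose_max.  The 0.6x caspase-production abolition is a guarantee of the
# default rates only, so it is asserted just for unjittered,
# non-overridden configurations.
.validate_toy <- function(net, dose_max = 1e-2, check_abolition = FALSE) {
  exec <- .role_index(net, "caspase3_active")
  doses <- c(0, dose_max * 2^(-7:0))
  ss <- vapply(doses, function(d) unname(steady_state(net, d)$state[exec]), 0)
  sw <- .detect_switch(ss)
  if (!sw$switch)
    stop("toy generator validation failed: no survival/apoptosis switch ",
         "within (0, ", dose_max, "] amol for this configuration")
  if (check_abolition) {
    crip <- perturb(net, "kp_c8", 0.6)
    hi2 <- steady_state(crip, dose_max)$state[exec]
    if (hi2 > (min(ss) + max(ss)) / 2)
      stop("toy generator validation failed: apoptosis persists with the ",
           "caspase-production analog scaled by 0.6")
  }
  invisible(TRUE)
}

#' Synthetic mutation tables with controlled concordance
#'
#' Generates one gene per non-excluded (non-production) parameter and,
#' independently for each of the three point-mutation types, lets the
#' gene's mutation bit equal the parameter's sensitivity bit with
#' probability `concordance` (flipped otherwise).  Counts are 0 for bit 0
#' and `1 + Poisson(2)` for bit 1 — magnitudes are cosmetic, since
#' binarization at >= 1 erases them.
#'
#' @param spectrum a [boolean_spectrum()] (typically a sensitivity
#'   spectrum over parameters) supplying the target bits, one per gene
#' @param concordance probability in (0, 1] that a gene bit matches its
#'   parameter's bit
#' @param seed integer; fixed seed gives identical tables
#' @param cancer_type label stored on the table
#' @return list with `table` (a `mutation_table`) and `map` (a
#'   [gene_parameter_map()] with one gene per spectrum id)
#' @export
make_synthetic_mutations <- function(spectrum, concordance, seed,
                                     cancer_type = "synthetic") {
  stopifnot(inherits(spectrum, "boolean_spectrum"),
            concordance > 0, concordance <= 1)
  set.seed(as.integer(seed))
  n <- length(spectrum$ids)
  genes <- paste0("GENE_", toupper(spectrum$ids))
  counts <- sapply(c("missense", "synonymous", "nonsense"), function(type) {
    match_bit <- runif(n) < concordance
    bits <- ifelse(match_bit, spectrum$bits, !spectrum$bits)
    ifelse(bits, 1L + rpois(n, 2), 0L)
  })
  tab <- structure(list(cancer_type = cancer_type,
                        counts = data.frame(gene = genes,
                                            missense = counts[, "missense"],
                                            synonymous = counts[, "synonymous"],
                                            nonsense = counts[, "nonsense"])),
                   class = "mutation_table")
  map <- gene_parameter_map(data.frame(parameter_id = spectrum$ids, gene = genes))
  list(table = tab, map = map)
}
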