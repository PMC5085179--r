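#' Model manifest
#'
#' Dimension counts plus the key-species role map of a loaded model.
#' Every named role must resolve to exactly one species id of the
#' network.
#'
#' @param network a [reaction_network()]
#' @param source `"sbml-file"` or `"builtin-toy"`
#' @param substance_units declared substance units of the source file
#'   (recorded, not interpreted; the toy uses amol)
#' @return a `model_manifest` list.
#' @export
model_manifest <- function(network, source = c("builtin-toy", "sbml-file",
                                               "tsv-file"),
                           substance_units = NA_character_) {
  source <- match.arg(source)
  roles <- network$roles
  if (!is.null(roles)) {
    bad <- roles[!roles %in% network$species$id]
    if (length(bad))
      stop("role map references unknown species: ", paste(bad, collapse = ", "))
  }
  structure(list(source = source,
                 species_count = nrow(network$species),
                 reaction_count = length(network$reactions),
                 parameter_count = nrow(network$parameters),
                 key_species_map = roles,
                 substance_units = substance_units),
            class = "model_manifest")
}

#' @export
print.model_manifest <- function(x, ...) {
  cat("Model manifest (", x$source, "): ", x$species_count, " species, ",
      x$reaction_count, " reactions, ", x$parameter_count, " parameters\n",
      sep = "")
  invisible(x)
}

#' Bundled reduced model
#'
#' Wraps [make_toy_network()] and returns the network together with its
#' manifest; deterministic for a fixed config.
#'
#' @param config a [toy_config()]
#' @return list with `network` and `manifest`
#' @export
load_toy <- function(config = toy_config()) {
  net <- make_toy_network(config)
  list(network = net, manifest = model_manifest(net, "builtin-toy",
                                                substance_units = "amol"))
}

.sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
              m = "http://www.w3.org/1998/Math/MathML")

# Heuristic parameter category from reaction shape, used when the file
# carries no category annotation.
.infer_category <- function(n_reac, n_prod) {
  if (n_reac == 0) "production"
  else if (n_prod == 0 && n_reac == 1) "degradation"
  else if (n_reac >= 2) "association"
  else if (n_prod >= 2) "dissociation"
  else "enzymatic"
}

#' Load an SBML model with mass-action kinetics
#'
#' Minimal SBML Level 3 (and Level-2-compatible) reader restricted to
#' the constructs a mass-action network needs: constant compartments,
#' species with initial amounts, global/local parameters, irreversible
#' reactions whose kinetic law is exactly
#' `k * prod(reactant ^ stoichiometry)`.  Anything else — rules, events,
#' assignments, other rate laws — is rejected with a message naming the
#' offending reaction.  Local parameters are promoted to the global
#' table with a reaction-scoped `<reaction>.` prefix.
#'
#' A species with `boundaryCondition="true"` becomes the clamped input.
#' Parameter categories are taken from a `category` attribute in the
#' package's annotation namespace when present, else inferred from the
#' reaction shape.
#'
#' @param path SBML file
#' @param roles optional named character vector mapping the standard
#'   roles to species ids (species naming in deposited files cannot be
#'   assumed, so the mapping is supplied by the caller)
#' @return list with `network` and `manifest`
#' @export
load_sbml <- function(path, roles = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)
  for (bad in c(".//listOfRules", ".//listOfEvents",
                ".//listOfInitialAssignments", ".//listOfConstraints"))
    if (!inherits(xml2::xml_find_first(model, bad), "xml_missing"))
      stop("unsupported SBML construct: ", sub(".//listOf", "", bad))

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("SBML model declares no species")
  num_or <- function(x, default = NA_real_) {
    v <- suppressWarnings(as.numeric(x)); ifelse(is.na(v), default, v)
  }
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    initial_amount = num_or(xml2::xml_attr(sp_nodes, "initialAmount"), 0),
    is_input = !is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")) &
      xml2::xml_attr(sp_nodes, "boundaryCondition") == "true")

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  params <- data.frame(
    id = xml2::xml_attr(par_nodes, "id"),
    value = num_or(xml2::xml_attr(par_nodes, "value")),
    category = xml2::xml_attr(par_nodes, "category"),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("SBML model declares no reactions")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    rn <- rx_nodes[[i]]
    rid <- xml2::xml_attr(rn, "id")
    side <- function(xp) {
      refs <- xml2::xml_find_all(rn, xp)
      st <- num_or(xml2::xml_attr(refs, "stoichiometry"), 1)
      setNames(as.integer(st), xml2::xml_attr(refs, "species"))
    }
    reac <- side("./listOfReactants/speciesReference")
    prod <- side("./listOfProducts/speciesReference")
    # promote local parameters
    loc <- xml2::xml_find_all(
      rn, "./kineticLaw/listOfLocalParameters/localParameter | ./kineticLaw/listOfParameters/parameter")
    loc_map <- character(0)
    if (length(loc)) {
      lid <- xml2::xml_attr(loc, "id")
      gid <- paste0(rid, ".", lid)
      params <- rbind(params, data.frame(
        id = gid, value = num_or(xml2::xml_attr(loc, "value")),
        category = NA_character_, stringsAsFactors = FALSE))
      loc_map <- setNames(gid, lid)
    }
    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop("reaction ", rid, " has no kinetic law")
    k_id <- .parse_mass_action(math, reac, c(params$id, names(loc_map)), rid)
    if (k_id %in% names(loc_map)) k_id <- loc_map[[k_id]]
    reactions[[i]] <- list(id = rid, rate_constant_id = k_id,
                           reactants = reac, products = prod)
  }
  # fill missing categories by reaction-shape inference
  for (i in seq_along(reactions)) {
    rx <- reactions[[i]]
    j <- match(rx$rate_constant_id, params$id)
    if (is.na(params$category[j]))
      params$category[j] <- .infer_category(length(rx$reactants), length(rx$products))
  }
  params$category[is.na(params$category)] <- "enzymatic"

  net <- reaction_network(species, reactions, params, roles = roles)
  units <- xml2::xml_attr(model, "substanceUnits")
  list(network = net,
       manifest = model_manifest(net, "sbml-file", substance_units = units))
}

# Accept exactly k * prod(reactant^stoich): a lone <ci> (zeroth order
# needs just k), or an <apply><times/> whose factors are one parameter
# ci plus one factor per distinct reactant (plain ci for stoichiometry
# 1, <apply><power/> ci cn for higher).  Returns the rate-constant id.
.parse_mass_action <- function(math, reactants, param_ids, rid) {
  unsupported <- function(why)
    stop("kinetic law of reaction ", rid, " is not mass action (", why, ")")
  kids <- xml2::xml_children(math)
  if (length(kids) != 1) unsupported("expected a single math expression")
  expr <- kids[[1]]
  factors <- list()
  if (xml2::xml_name(expr) == "ci") {
    factors <- list(expr)
  } else if (xml2::xml_name(expr) == "apply") {
    ops <- xml2::xml_children(expr)
    if (xml2::xml_name(ops[[1]]) != "times")
      unsupported(paste0("operator <", xml2::xml_name(ops[[1]]), ">"))
    factors <- as.list(ops[-1])
  } else unsupported(paste0("node <", xml2::xml_name(expr), ">"))

  k_id <- NULL
  pow <- integer(0)
  for (f in factors) {
    nm <- xml2::xml_name(f)
    if (nm == "ci") {
      sym <- trimws(xml2::xml_text(f))
      if (sym %in% names(reactants)) {
        pow[sym] <- (if (sym %in% names(pow)) pow[[sym]] else 0L) + 1L
      } else if (sym %in% param_ids) {
        if (!is.null(k_id)) unsupported("more than one rate constant")
        k_id <- sym
      } else unsupported(paste0("unknown symbol ", sym))
    } else if (nm == "apply") {
      sub <- xml2::xml_children(f)
      if (xml2::xml_name(sub[[1]]) != "power" || length(sub) != 3)
        unsupported("non-power subexpression")
      sym <- trimws(xml2::xml_text(sub[[2]]))
      ex <- suppressWarnings(as.numeric(xml2::xml_text(sub[[3]])))
      if (!sym %in% names(reactants) || is.na(ex) || ex != as.integer(ex))
        unsupported("power of a non-reactant or non-integer exponent")
      pow[sym] <- (if (sym %in% names(pow)) pow[[sym]] else 0L) + as.integer(ex)
    } else unsupported(paste0("factor <", nm, ">"))
  }
  if (is.null(k_id)) unsupported("no rate constant factor")
  if (length(reactants) != length(pow))
    unsupported("factor powers do not match reactant stoichiometries")
  if (length(reactants)) {
    want <- reactants[order(names(reactants))]
    got <- pow[order(names(pow))]
    if (!all(names(want) == names(got)) ||
        !all(as.integer(want) == as.integer(got)))
      unsupported("factor powers do not match reactant stoichiometries")
  }
  k_id
}

# Materialize injected feedback terms as ordinary reactions so exported
# files are self-contained: positive -> catalytic production
# (source -> source + target), negative -> bimolecular degradation
# (source + target -> source).
.materialize_feedback <- function(net) {
  if (!length(net$extra_rate_terms)) return(net)
  species <- net$species
  reactions <- lapply(net$reactions, function(r)
    r[c("id", "rate_constant_id", "reactants", "products")])
  params <- net$parameters
  for (i in seq_along(net$extra_rate_terms)) {
    tm <- net$extra_rate_terms[[i]]
    src <- species$id[tm$source]; tgt <- species$id[tm$target]
    kid <- paste0("k_fb_", i)
    params <- rbind(params, data.frame(id = kid, value = tm$strength,
                                       category = "enzymatic"))
    if (tm$sign == "positive") {
      reactions <- c(reactions, list(list(
        id = paste0("fb_pos_", i), rate_constant_id = kid,
        reactants = setNames(1L, src), products = setNames(c(1L, 1L), c(src, tgt)))))
    } else {
      reactions <- c(reactions, list(list(
        id = paste0("fb_neg_", i), rate_constant_id = kid,
        reactants = setNames(c(1L, 1L), c(src, tgt)), products = setNames(1L, src))))
    }
  }
  reaction_network(species, reactions, params, roles = net$roles)
}

#' Write a network to SBML or tabular TSV
#'
#' Injected feedback terms are first materialized as ordinary reactions
#' (catalytic production / bimolecular degradation), so exported files
#' are self-contained mass-action models.
#'
#' For `format = "tsv"`, `path` is a directory receiving `species.tsv`,
#' `reactions.tsv` (sides encoded `"A:1;B:2"`) and `parameters.tsv`.
#'
#' @param network a [reaction_network()]
#' @param path output file (SBML) or directory (TSV)
#' @param format `"sbml"` or `"tsv"`
#' @return `path`, invisibly
#' @export
write_network <- function(network, path, format = c("sbml", "tsv")) {
  format <- match.arg(format)
  net <- .materialize_feedback(network)
  if (format == "tsv") return(.write_tsv(net, path))
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "network",
                               substanceUnits = "amol")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    xml2::xml_add_child(spl, "species", id = s$id, name = s$name,
      compartment = "cell",
      initialAmount = format(s$initial_amount, digits = 17),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = if (s$is_input) "true" else "false",
      constant = "false")
  }
  pl <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_len(nrow(net$parameters))) {
    p <- net$parameters[i, ]
    xml2::xml_add_child(pl, "parameter", id = p$id,
                        value = format(p$value, digits = 17),
                        constant = "true", category = p$category)
  }
  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in net$reactions) {
    rn <- xml2::xml_add_child(rl, "reaction", id = rx$id, reversible = "false")
    add_side <- function(tag, side) {
      if (!length(side)) return()
      ln <- xml2::xml_add_child(rn, tag)
      for (s in names(side))
        xml2::xml_add_child(ln, "speciesReference", species = s,
                            stoichiometry = as.character(side[[s]]),
                            constant = "true")
    }
    add_side("listOfReactants", rx$reactants)
    add_side("listOfProducts", rx$products)
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    if (!length(rx$reactants)) {
      xml2::xml_add_child(math, "ci", rx$rate_constant_id)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "ci", rx$rate_constant_id)
      for (s in names(rx$reactants)) {
        st <- rx$reactants[[s]]
        if (st == 1L) {
          xml2::xml_add_child(ap, "ci", s)
        } else {
          pw <- xml2::xml_add_child(ap, "apply")
          xml2::xml_add_child(pw, "power")
          xml2::xml_add_child(pw, "ci", s)
          xml2::xml_add_child(pw, "cn", as.character(st), type = "integer")
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.side_to_string <- function(side) {
  if (!length(side)) return("")
  paste(paste0(names(side), ":", as.integer(side)), collapse = ";")
}

.string_to_side <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  setNames(vapply(parts, function(p) as.integer(p[2]), 0L),
           vapply(parts, `[[`, "", 1))
}

.write_tsv <- function(net, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(path, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(net$species, "species.tsv")
  wt(data.frame(
    id = vapply(net$reactions, `[[`, "", "id"),
    rate_constant_id = vapply(net$reactions, `[[`, "", "rate_constant_id"),
    reactants = vapply(net$reactions, function(r) .side_to_string(r$reactants), ""),
    products = vapply(net$reactions, function(r) .side_to_string(r$products), "")),
    "reactions.tsv")
  wt(net$parameters, "parameters.tsv")
  invisible(path)
}

#' Read a network from the tabular TSV layout of [write_network()]
#'
#' @param path directory containing `species.tsv`, `reactions.tsv`,
#'   `parameters.tsv`
#' @param roles optional role map (see [reaction_network()])
#' @return list with `network` and `manifest`
#' @export
read_network_tsv <- function(path, roles = NULL) {
  rd <- function(f) read.delim(file.path(path, f), sep = "\t",
                               stringsAsFactors = FALSE)
  species <- rd("species.tsv")
  species$is_input <- as.logical(species$is_input)
  rx_df <- rd("reactions.tsv")
  reactions <- lapply(seq_len(nrow(rx_df)), function(i) list(
    id = rx_df$id[i], rate_constant_id = rx_df$rate_constant_id[i],
    reactants = .string_to_side(rx_df$reactants[i]),
    products = .string_to_side(rx_df$products[i])))
  net <- reaction_network(species, reactions, rd("parameters.tsv"),
                          roles = roles)
  list(network = net, manifest = model_manifest(net, "tsv-file",
                                                substance_units = "amol"))
}
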