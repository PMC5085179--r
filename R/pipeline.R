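#' End-to-end analysis run
#'
#' Orchestrates the full protocol on one model: dose-response scan and
#' critical dose, parameter sensitivity spectrum, per-rule Hamming
#' distances against a mutation table, and (optionally) feedback-loop
#' calibration plus an HD-strength scan.  All outputs are written under
#' `config$out_dir` as CSV/TSV plus a machine-readable `summary.json`
#' that records the package version, seed, and a hash of the effective
#' configuration.
#'
#' @param config a list (e.g. from [yaml::read_yaml()]) with elements:
#'   \describe{
#'     \item{model}{`"toy"` (default), or a list `list(sbml = path)` /
#'       `list(tsv = path)` with an optional `roles` named vector}
#'     \item{toy}{optional arguments for [toy_config()]}
#'     \item{sensitivity}{optional arguments for [sensitivity_config()]}
#'     \item{mutations}{optional: `list(path =, cancer_type =)` TSV
#'       mutation table; when absent, a synthetic table at
#'       `concordance` (default 0.9) is generated from the model's own
#'       spectrum}
#'     \item{map}{optional path to a gene-parameter map TSV}
#'     \item{rule}{combined binarization rule, default
#'       `"three_at_least_2"`}
#'     \item{feedback}{optional: `list(source_role =, sign =,
#'       strengths =)` for the HD-strength scan}
#'     \item{out_dir}{output directory (required)}
#'     \item{seed}{integer seed for any synthetic generation (default 1)}
#'   }
#' @return the summary list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  rule <- if (is.null(config$rule)) "three_at_least_2" else config$rule
  cfg_hash <- digest::digest(config)
  summary <- list(config_hash = cfg_hash, seed = seed,
                  package_version = as.character(utils::packageVersion("tnfswitch")),
                  stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      summary$stages[[name]] <<- list(status = "error",
                                      message = conditionMessage(res))
      NULL
    } else {
      summary$stages[[name]] <<- list(status = "ok")
      res
    }
  }

  # -- model ---------------------------------------------------------------
  model_cfg <- if (is.null(config$model)) "toy" else config$model
  loaded <- if (identical(model_cfg, "toy")) {
    load_toy(do.call(toy_config, c(list(seed = config$toy$seed),
                                   config$toy[setdiff(names(config$toy), "seed")])))
  } else if (!is.null(model_cfg$sbml)) {
    load_sbml(model_cfg$sbml, roles = unlist(model_cfg$roles))
  } else if (!is.null(model_cfg$tsv)) {
    read_network_tsv(model_cfg$tsv, roles = unlist(model_cfg$roles))
  } else stop("config$model must be 'toy' or list(sbml=)/list(tsv=)")
  net <- loaded$network

  scfg <- do.call(sensitivity_config,
                  config$sensitivity[names(config$sensitivity) %in%
                                       names(formals(sensitivity_config))])

  # -- dose response -------------------------------------------------------
  curve <- stage("dose_response", {
    doses <- c(0, scfg$dose_max * 2^seq(-10, 0, by = 0.5))
    scan_doses(net, doses, dose_max = scfg$dose_max)
  })
  if (!is.null(curve)) {
    utils::write.csv(cbind(as.data.frame(curve),
                           low_plateau = attr(curve, "low_plateau"),
                           high_plateau = attr(curve, "high_plateau")),
                     file.path(out, paste0("dose_response_", cfg_hash, ".csv")),
                     row.names = FALSE)
  }
  cd <- stage("critical_dose",
              find_critical_dose(net, dose_max = scfg$dose_max, tol = scfg$tol))
  if (!is.null(cd)) summary$critical_dose <- cd[c("cd", "apoptosis_achievable")]

  # -- sensitivity spectrum ------------------------------------------------
  spec <- stage("sensitivity", build_spectrum(net, config = scfg))
  if (is.null(spec)) {
    .write_summary(summary, out, cfg_hash)
    return(invisible(summary))
  }
  utils::write.csv(spec$records,
                   file.path(out, paste0("sensitivity_", cfg_hash, ".csv")),
                   row.names = FALSE)
  summary$n_sensitive <- sum(spec$flags, na.rm = TRUE)

  # -- mutation spectra and HD --------------------------------------------
  excl <- production_parameters(net)
  keep <- setdiff(spec$parameter_ids, excl)
  sens_bs <- as_boolean_spectrum(spec)[keep]
  if (!is.null(config$mutations)) {
    tab <- parse_mutation_table(config$mutations$path,
                                cancer_type = config$mutations$cancer_type)
    map <- read_gene_map(config$map)
  } else {
    conc <- if (is.null(config$concordance)) 0.9 else config$concordance
    syn <- make_synthetic_mutations(sens_bs, concordance = conc, seed = seed)
    tab <- syn$table; map <- syn$map
    write.table(tab$counts, file.path(out, paste0("mutations_", cfg_hash, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  hd_tab <- stage("hd", {
    specs <- c(lapply(c("missense", "synonymous", "nonsense"),
                      function(ty) binarize(tab, ty)),
               list(combine_mutations(tab, "two_of", c("missense", "nonsense")),
                    combine_mutations(tab, rule)))
    names(specs) <- c("missense", "synonymous", "nonsense",
                      "missense_nonsense", rule)
    data.frame(spectrum = names(specs),
               hd = vapply(specs, function(bs)
                 hamming(project_to_parameters(bs, map, keep), sens_bs)$hd, 0L),
               n = length(keep), row.names = NULL)
  })
  if (!is.null(hd_tab)) {
    utils::write.csv(hd_tab, file.path(out, paste0("hd_", cfg_hash, ".csv")),
                     row.names = FALSE)
    summary$hd <- setNames(as.list(hd_tab$hd), hd_tab$spectrum)
  }

  # -- feedback ------------------------------------------------------------
  if (!is.null(config$feedback)) {
    fb <- config$feedback
    tpl <- feedback_spec(fb$source_role,
                         if (is.null(fb$sign)) "negative" else fb$sign, 0)
    rng <- stage("feedback_calibration", {
      dec <- if (tpl$sign == "negative") c(-3, 1) else c(-7, -3)
      calibrate_range(net, tpl, decades = if (is.null(fb$decades)) dec
                                          else unlist(fb$decades))
    })
    strengths <- if (!is.null(fb$strengths)) unlist(fb$strengths)
                 else if (!is.null(rng) && is.finite(rng$hi))
                   10^seq(log10(rng$lo), log10(rng$hi), length.out = 5)
    scan <- stage("hd_strength_scan", {
      gene_spec <- combine_mutations(tab, rule)
      proj <- project_to_parameters(gene_spec, map, keep)
      hd_strength_scan(net, tpl, strengths, proj, config = scfg)
    })
    if (!is.null(scan)) {
      utils::write.csv(as.data.frame(scan),
                       file.path(out, paste0("hd_strength_", cfg_hash, ".csv")),
                       row.names = FALSE)
      summary$feedback <- list(
        range = if (!is.null(rng)) rng[c("lo", "hi", "metric")],
        baseline_hd = attr(scan, "baseline_hd"),
        min_hd_strength = scan$strength[which.min(scan$hd)])
    }
  }

  .write_summary(summary, out, cfg_hash)
  invisible(summary)
}

.write_summary <- function(summary, out, cfg_hash) {
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
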