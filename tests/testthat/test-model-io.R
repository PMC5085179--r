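write_sbml_fixture <- function(path, body) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    body,
    '</sbml>'), path)
  path
}

three_species_sbml <- function(path) {
  write_sbml_fixture(path, c(
    '<model id="m" substanceUnits="amol">',
    '<listOfSpecies>',
    '<species id="X" initialAmount="2" boundaryCondition="false"/>',
    '<species id="Y" initialAmount="0"/>',
    '<species id="Z" initialAmount="0.5"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="k1" value="0.3"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="X" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="Y"/></listOfProducts>',
    '<kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k1</ci>',
    '<apply><power/><ci>X</ci><cn type="integer">2</cn></apply></apply></math>',
    '</kineticLaw></reaction>',
    '<reaction id="r2" reversible="false">',
    '<listOfReactants><speciesReference species="Z"/></listOfReactants>',
    '<listOfProducts/>',
    '<kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k2</ci><ci>Z</ci></apply></math>',
    '<listOfLocalParameters><localParameter id="k2" value="0.7"/></listOfLocalParameters>',
    '</kineticLaw></reaction>',
    '</listOfReactions>',
    '</model>'))
}

test_that("a hand-written SBML fixture loads and matches its derivative", {
  f <- withr::local_tempfile(fileext = ".xml")
  three_species_sbml(f)
  res <- load_sbml(f)
  net <- res$network
  expect_equal(res$manifest$species_count, 3)
  expect_equal(res$manifest$reaction_count, 2)
  expect_equal(res$manifest$parameter_count, 2) # k1 + promoted r2.k2
  expect_true("r2.k2" %in% net$parameters$id)
  expect_equal(res$manifest$substance_units, "amol")
  # rate law check: dX/dt = -2*k1*X^2, dY/dt = +k1*X^2, dZ/dt = -0.7*Z
  st <- c(2, 1, 0.5)
  expect_equal(unname(network_derivative(net, st)),
               c(-2 * 0.3 * 4, 0.3 * 4, -0.7 * 0.5), tolerance = 1e-12)
})

test_that("degenerate and non-mass-action SBML inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_fixture(f, c('<model id="empty"><listOfSpecies/></model>'))
  expect_error(load_sbml(f), "no species")

  write_sbml_fixture(f, c(
    '<model id="mm">',
    '<listOfSpecies><species id="X" initialAmount="1"/></listOfSpecies>',
    '<listOfParameters><parameter id="v" value="1"/><parameter id="km" value="1"/></listOfParameters>',
    '<listOfReactions><reaction id="menten">',
    '<listOfReactants><speciesReference species="X"/></listOfReactants>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><divide/><apply><times/><ci>v</ci><ci>X</ci></apply>',
    '<apply><plus/><ci>km</ci><ci>X</ci></apply></apply></math></kineticLaw>',
    '</reaction></listOfReactions></model>'))
  expect_error(load_sbml(f), "menten.*not mass action")

  write_sbml_fixture(f, c(
    '<model id="ev">',
    '<listOfSpecies><species id="X" initialAmount="1"/></listOfSpecies>',
    '<listOfRules/>',
    '</model>'))
  expect_error(load_sbml(f), "unsupported SBML construct")
})

test_that("SBML round trip preserves the derivative to 1e-12", {
  net <- toy_cached()
  f <- withr::local_tempfile(fileext = ".xml")
  write_network(net, f, "sbml")
  back <- load_sbml(f, roles = net$roles)$network
  expect_identical(back$species$id, net$species$id)
  set.seed(11)
  for (i in 1:5) {
    st <- runif(nrow(net$species), 0, 0.2)
    expect_equal(unname(network_derivative(back, st)),
                 unname(network_derivative(net, st)), tolerance = 1e-12)
  }
  # categories survive the round trip through the annotation attribute
  expect_identical(back$parameters$category, net$parameters$category)
})

test_that("TSV round trip reproduces the stoichiometric matrix exactly", {
  net <- toy_cached()
  d <- withr::local_tempdir()
  write_network(net, d, "tsv")
  back <- read_network_tsv(d, roles = net$roles)$network
  expect_identical(back$stoichiometric_matrix, net$stoichiometric_matrix)
  expect_equal(back$parameters$value, net$parameters$value, tolerance = 1e-12)
  expect_equal(back$species$initial_amount, net$species$initial_amount,
               tolerance = 1e-12)
})

test_that("injected feedback terms are materialized as reactions on export", {
  net <- inject_feedback(toy_cached(),
                         feedback_spec("caspase3_active", "negative", 0.25))
  net <- inject_feedback(net, feedback_spec("caspase8_active", "positive", 3e-6))
  f <- withr::local_tempfile(fileext = ".xml")
  write_network(net, f, "sbml")
  back <- load_sbml(f, roles = net$roles)$network
  expect_length(back$extra_rate_terms, 0)
  expect_equal(length(back$reactions), length(net$reactions) + 2)
  set.seed(12)
  for (i in 1:5) {
    st <- runif(nrow(net$species), 0, 0.2)
    expect_equal(unname(network_derivative(back, st)),
                 unname(network_derivative(net, st)), tolerance = 1e-12)
  }
})

test_that("load_toy is deterministic and its manifest counts match", {
  a <- load_toy(toy_config(validate = FALSE))
  b <- load_toy(toy_config(validate = FALSE))
  expect_identical(network_hash(a$network), network_hash(b$network))
  expect_equal(a$manifest$species_count, nrow(a$network$species))
  expect_equal(a$manifest$reaction_count, length(a$network$reactions))
  expect_equal(a$manifest$parameter_count, nrow(a$network$parameters))
  expect_setequal(names(a$manifest$key_species_map),
                  c("tnf_input", "complex1", "complex2", "nfkb_active",
                    "caspase3_active", "caspase8_active", "caspase6_active"))
  # parameter override: identical topology, one changed value
  c <- load_toy(toy_config(rate_overrides = c(ka_c3 = 1e-2), validate = FALSE))
  expect_identical(c$network$stoichiometric_matrix,
                   a$network$stoichiometric_matrix)
  changed <- c$network$parameters$value != a$network$parameters$value
  expect_identical(a$network$parameters$id[changed], "ka_c3")
})

test_that("manifest rejects roles that do not resolve", {
  net <- toy_cached()
  net$roles[["caspase3_active"]] <- "missing_species"
  expect_error(model_manifest(net, "builtin-toy"), "unknown species")
})
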