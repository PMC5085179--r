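write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("both mutation-table dialects parse to identical tables", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  # per-sample rows, one gene repeated
  write_tsv(data.frame(
    gene = c("TP53", "TP53", "CASP8", "TP53"),
    mutation_type = c("missense", "missense", "synonymous", "nonsense")), f1)
  # pre-aggregated dialect of the same data, with a split row to sum
  write_tsv(data.frame(gene = c("TP53", "CASP8", "TP53"),
                       missense = c(1L, 0L, 1L),
                       synonymous = c(0L, 1L, 0L),
                       nonsense = c(1L, 0L, 0L)), f2)
  t1 <- parse_mutation_table(f1, "uat")
  t2 <- parse_mutation_table(f2, "uat")
  expect_equal(t1$counts, t2$counts)
  expect_equal(t1$counts$missense[t1$counts$gene == "TP53"], 2L)
})

test_that("empty and malformed tables are handled per contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene = character(), mutation_type = character()), f)
  expect_equal(nrow(parse_mutation_table(f)$counts), 0)

  write_tsv(data.frame(gene = "TP53", mutation_type = "frameshift"), f)
  expect_error(parse_mutation_table(f), "unknown mutation-type.*line 2")

  write_tsv(data.frame(gene = "TP53", missense = -1, synonymous = 0,
                       nonsense = 0), f)
  expect_error(parse_mutation_table(f), "malformed count.*line 2")
})

make_table <- function(counts) {
  structure(list(cancer_type = "synthetic",
                 counts = cbind(data.frame(gene = paste0("G", seq_len(nrow(counts)))),
                                counts)),
            class = "mutation_table")
}

test_that("binarize thresholds at one mutated sample", {
  tab <- make_table(data.frame(missense = c(0L, 1L, 17L),
                               synonymous = 0L, nonsense = 0L))
  expect_identical(binarize(tab, "missense")$bits, c(FALSE, TRUE, TRUE))
  expect_false(any(binarize(tab, "nonsense")$bits))
  # random tables match a per-gene loop oracle
  set.seed(5)
  for (i in 1:20) {
    cnt <- data.frame(missense = rpois(8, 1), synonymous = rpois(8, 1),
                      nonsense = rpois(8, 1))
    tab <- make_table(cnt)
    for (ty in c("missense", "synonymous", "nonsense")) {
      oracle <- vapply(seq_len(8), function(g) cnt[[ty]][g] >= 1, TRUE)
      expect_identical(binarize(tab, ty)$bits, oracle)
    }
  }
})

test_that("combined-action rules follow the two- and three-type definitions", {
  tab <- make_table(data.frame(missense  = c(1L, 1L, 0L, 0L),
                               synonymous = c(0L, 2L, 0L, 3L),
                               nonsense  = c(0L, 0L, 0L, 2L)))
  # (1,0,0) -> 0 and (1,1,0) -> 1 under the at-least-two rule
  expect_identical(combine_mutations(tab, "three_at_least_2")$bits,
                   c(FALSE, TRUE, FALSE, TRUE))
  # at-least-one equals the OR of the three per-type spectra
  or3 <- binarize(tab, "missense")$bits | binarize(tab, "synonymous")$bits |
    binarize(tab, "nonsense")$bits
  expect_identical(combine_mutations(tab, "three_at_least_1")$bits, or3)
  # two-type rule: at least one of the chosen pair
  expect_identical(combine_mutations(tab, "two_of", c("missense", "nonsense"))$bits,
                   c(TRUE, TRUE, FALSE, TRUE))
  # monotone: at-least-1 dominates at-least-2 bitwise
  set.seed(6)
  for (i in 1:20) {
    tab <- make_table(data.frame(missense = rpois(10, 0.7),
                                 synonymous = rpois(10, 0.7),
                                 nonsense = rpois(10, 0.7)))
    expect_true(all(combine_mutations(tab, "three_at_least_1")$bits >=
                      combine_mutations(tab, "three_at_least_2")$bits))
  }
})

test_that("projection maps gene bits onto parameter order", {
  gs <- boolean_spectrum(c("G1", "G2"), c(TRUE, FALSE))
  map <- gene_parameter_map(data.frame(
    parameter_id = c("p1", "p2", "p3"), gene = c("G1", "G1", "G2")),
    excluded = "p4")
  proj <- project_to_parameters(gs, map, c("p1", "p2", "p3", "p4"))
  expect_identical(proj$ids, c("p1", "p2", "p3")) # excluded dropped
  expect_identical(proj$bits, c(TRUE, TRUE, FALSE)) # many-to-one
  expect_error(project_to_parameters(gs, map, c("p1", "p5")), "unmapped.*p5")

  # all genes unmutated -> all-zero parameter spectrum
  gs0 <- boolean_spectrum(c("G1", "G2"), c(FALSE, FALSE))
  expect_false(any(project_to_parameters(gs0, map, c("p1", "p2", "p3"))$bits))

  # composition oracle on random map/table
  set.seed(7)
  for (i in 1:20) {
    genes <- paste0("G", 1:6)
    bits <- runif(6) < 0.5
    gs <- boolean_spectrum(genes, bits)
    pmap <- gene_parameter_map(data.frame(parameter_id = paste0("p", 1:10),
                                          gene = sample(genes, 10, TRUE)))
    proj <- project_to_parameters(gs, pmap, paste0("p", 1:10))
    oracle <- vapply(1:10, function(j)
      bits[match(pmap$entries$gene[j], genes)], TRUE)
    expect_identical(proj$bits, oracle)
  }
})

test_that("a bijective map preserves zero/one counts", {
  set.seed(8)
  genes <- paste0("G", 1:12)
  bits <- runif(12) < 0.4
  gs <- boolean_spectrum(genes, bits)
  map <- gene_parameter_map(data.frame(parameter_id = paste0("p", 1:12),
                                       gene = sample(genes)))
  proj <- project_to_parameters(gs, map, paste0("p", 1:12))
  expect_equal(sum(proj$bits), sum(bits))
})

test_that("one-to-many maps need the explicit flag and OR the bits", {
  entries <- data.frame(parameter_id = c("p1", "p1"), gene = c("G1", "G2"))
  expect_error(gene_parameter_map(entries), "allow_multi")
  map <- gene_parameter_map(entries, allow_multi = TRUE)
  gs <- boolean_spectrum(c("G1", "G2"), c(FALSE, TRUE))
  expect_true(project_to_parameters(gs, map, "p1")$bits)
})

test_that("hamming distance counts differing positions and refuses misalignment", {
  a <- boolean_spectrum(paste0("p", 1:106), rep(c(TRUE, FALSE), 53))
  expect_equal(hamming(a, a)$hd, 0)
  comp <- boolean_spectrum(a$ids, !a$bits)
  expect_equal(hamming(a, comp)$hd, 106)
  b <- boolean_spectrum(paste0("q", 1:106), a$bits)
  expect_error(hamming(a, b), "alignment")

  set.seed(9)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    ids <- paste0("p", seq_len(n))
    x <- boolean_spectrum(ids, runif(n) < 0.5)
    y <- boolean_spectrum(ids, runif(n) < 0.5)
    z <- boolean_spectrum(ids, runif(n) < 0.5)
    oracle <- sum(vapply(seq_len(n), function(j) x$bits[j] != y$bits[j], TRUE))
    expect_equal(hamming(x, y)$hd, oracle)
    expect_equal(hamming(x, y)$hd, hamming(y, x)$hd) # symmetry
    expect_lte(hamming(x, z)$hd, hamming(x, y)$hd + hamming(y, z)$hd) # triangle
    expect_identical(length(hamming(x, y)$mismatches), as.integer(hamming(x, y)$hd))
  }
})
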