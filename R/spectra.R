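#' Boolean spectra over parameters or genes
#'
#' @param ids ordered identifiers
#' @param bits logical vector, same length
#' @param provenance free-text origin tag (`"mutation-type"`,
#'   `"combined-rule"`, `"sensitivity"`, ...)
#' @export
boolean_spectrum <- function(ids, bits, provenance = "mutation-type") {
  stopifnot(length(ids) == length(bits), !anyDuplicated(ids))
  structure(list(ids = as.character(ids), bits = as.logical(bits),
                 provenance = provenance), class = "boolean_spectrum")
}

#' @export
#' @describeIn boolean_spectrum subset by id (character), position or
#'   logical mask, preserving order of the index.
`[.boolean_spectrum` <- function(x, i, ...) {
  idx <- if (is.character(i)) match(i, x$ids) else seq_along(x$ids)[i]
  if (anyNA(idx)) stop("unknown spectrum ids in subset")
  boolean_spectrum(x$ids[idx], x$bits[idx], x$provenance)
}

#' @export
print.boolean_spectrum <- function(x, ...) {
  cat("Boolean spectrum (", x$provenance, ", n = ", length(x$ids), "): ",
      paste(as.integer(x$bits), collapse = ""), "\n", sep = "")
  invisible(x)
}

.mut_types <- c("missense", "synonymous", "nonsense")

#' Parse a per-gene somatic point-mutation table
#'
#' Accepts two TSV dialects (COSMIC-style extracts):
#' \describe{
#'   \item{per-sample rows}{columns `gene`, `mutation_type`, one row per
#'     mutated sample; counts are aggregated}
#'   \item{pre-aggregated}{columns `gene`, `missense`, `synonymous`,
#'     `nonsense` with integer counts; repeated genes are summed}
#' }
#'
#' @param path TSV file with a header row
#' @param cancer_type label attached to the table
#' @return a `mutation_table`: list with `cancer_type` and `counts`
#'   (data.frame gene/missense/synonymous/nonsense).
#' @export
parse_mutation_table <- function(path, cancer_type = "unspecified") {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    counts <- data.frame(gene = character(), missense = integer(),
                         synonymous = integer(), nonsense = integer())
  } else if ("mutation_type" %in% names(df)) {
    if (!"gene" %in% names(df)) stop("per-sample dialect needs a 'gene' column")
    bad <- which(!df$mutation_type %in% .mut_types)
    if (length(bad))
      stop("unknown mutation-type token '", df$mutation_type[bad[1]],
           "' at line ", bad[1] + 1L)
    counts <- as.data.frame.matrix(table(factor(df$gene),
                                         factor(df$mutation_type, .mut_types)))
    counts <- data.frame(gene = rownames(counts), counts, row.names = NULL)
  } else if (all(c("gene", .mut_types) %in% names(df))) {
    for (ty in .mut_types) {
      v <- df[[ty]]
      bad <- which(is.na(v) | v < 0 | v != as.integer(v))
      if (length(bad))
        stop("malformed count in column '", ty, "' at line ", bad[1] + 1L)
    }
    counts <- aggregate(df[.mut_types], by = list(gene = df$gene), FUN = sum)
  } else {
    stop("unrecognized mutation-table schema: need 'gene' + 'mutation_type' ",
         "or 'gene' + per-type count columns")
  }
  counts <- counts[order(counts$gene), , drop = FALSE]
  row.names(counts) <- NULL
  structure(list(cancer_type = cancer_type, counts = counts),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("Mutation table (", x$cancer_type, "): ", nrow(x$counts), " genes\n", sep = "")
  print(head(x$counts, 10))
  invisible(x)
}

#' Binarize one mutation type
#'
#' Gene bit is 1 iff at least one mutated sample of the given type was
#' recorded.
#'
#' @param table a `mutation_table`
#' @param mutation_type one of `"missense"`, `"synonymous"`, `"nonsense"`
#' @return a [boolean_spectrum()] over genes
#' @export
binarize <- function(table, mutation_type) {
  stopifnot(inherits(table, "mutation_table"))
  mutation_type <- match.arg(mutation_type, .mut_types)
  boolean_spectrum(table$counts$gene, table$counts[[mutation_type]] >= 1,
                   provenance = "mutation-type")
}

#' Combined-action binarization rules
#'
#' Two-type rule: a gene is 1 if at least one of the two types shows a
#' mutation.  Three-type rule (default): 1 if at least two of the three
#' types show mutations; the alternate three-type rule takes at least
#' one.
#'
#' @param table a `mutation_table`
#' @param rule `"three_at_least_2"`, `"three_at_least_1"`, or `"two_of"`
#' @param types for `"two_of"`: the two mutation types combined
#' @return a [boolean_spectrum()] over genes
#' @export
combine_mutations <- function(table, rule = c("three_at_least_2",
                                              "three_at_least_1", "two_of"),
                              types = c("missense", "nonsense")) {
  stopifnot(inherits(table, "mutation_table"))
  rule <- match.arg(rule)
  per_type <- sapply(.mut_types, function(ty) table$counts[[ty]] >= 1)
  if (nrow(table$counts) == 1L) per_type <- matrix(per_type, nrow = 1,
                                                  dimnames = list(NULL, .mut_types))
  bits <- switch(rule,
    three_at_least_2 = rowSums(per_type) >= 2,
    three_at_least_1 = rowSums(per_type) >= 1,
    two_of = {
      types <- match.arg(types, .mut_types, several.ok = TRUE)
      if (length(types) != 2) stop("'two_of' needs exactly two mutation types")
      rowSums(per_type[, types, drop = FALSE]) >= 1
    })
  boolean_spectrum(table$counts$gene, bits, provenance = "combined-rule")
}

#' Gene-to-parameter correspondence
#'
#' Many-to-one (several parameters to one gene) is the normal case;
#' one-to-many (a parameter mapped to several genes, bits OR-ed) is
#' allowed behind `allow_multi`.  Production-process parameters are
#' excluded from the correspondence: they relate to gene
#' amplification/deletion rather than point mutation.
#'
#' @param entries data.frame with columns `parameter_id`, `gene`
#' @param excluded character vector of excluded parameter ids
#' @param allow_multi allow a parameter to map to several genes
#' @export
gene_parameter_map <- function(entries, excluded = character(),
                               allow_multi = FALSE) {
  stopifnot(is.data.frame(entries), all(c("parameter_id", "gene") %in% names(entries)))
  if (any(entries$parameter_id %in% excluded))
    stop("excluded parameters must have no map entry: ",
         paste(intersect(entries$parameter_id, excluded), collapse = ", "))
  if (!allow_multi && anyDuplicated(entries$parameter_id))
    stop("parameter mapped to several genes; set allow_multi = TRUE to OR the bits")
  structure(list(entries = entries, excluded = as.character(excluded)),
            class = "gene_parameter_map")
}

#' Map a network's production parameters to an exclusion set
#'
#' Convenience: builds the excluded-id set for [gene_parameter_map()]
#' from the parameter table's `category` column.
#' @param network a [reaction_network()]
#' @export
production_parameters <- function(network) {
  network$parameters$id[network$parameters$category == "production"]
}

#' Read a gene-parameter map from TSV
#'
#' Columns `parameter_id`, `gene`; an optional logical column `excluded`
#' marks excluded parameters (their `gene` field is ignored).
#' @param path TSV file
#' @param allow_multi see [gene_parameter_map()]
#' @export
read_gene_map <- function(path, allow_multi = FALSE) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  excl <- character()
  if ("excluded" %in% names(df)) {
    excl <- df$parameter_id[as.logical(df$excluded)]
    df <- df[!as.logical(df$excluded), , drop = FALSE]
  }
  gene_parameter_map(df[c("parameter_id", "gene")], excluded = excl,
                     allow_multi = allow_multi)
}

#' Project a gene spectrum onto parameter order
#'
#' The bit of parameter `p` is the bit of its mapped gene (OR over genes
#' under a one-to-many map).  Excluded parameters are dropped from the
#' output, so any spectrum compared against it must drop them too.
#'
#' @param gene_spectrum a [boolean_spectrum()] over genes
#' @param map a [gene_parameter_map()]
#' @param parameter_order character vector of parameter ids defining the
#'   output order (excluded ids are removed from it)
#' @return a [boolean_spectrum()] over the non-excluded parameters
#' @export
project_to_parameters <- function(gene_spectrum, map, parameter_order) {
  stopifnot(inherits(gene_spectrum, "boolean_spectrum"),
            inherits(map, "gene_parameter_map"))
  keep <- setdiff(parameter_order, map$excluded)
  unmapped <- setdiff(keep, map$entries$parameter_id)
  if (length(unmapped))
    stop("unmapped non-excluded parameters: ", paste(unmapped, collapse = ", "))
  bits <- vapply(keep, function(p) {
    genes <- map$entries$gene[map$entries$parameter_id == p]
    gi <- match(genes, gene_spectrum$ids)
    if (anyNA(gi)) stop("map references genes absent from the spectrum: ",
                        paste(genes[is.na(gi)], collapse = ", "))
    any(gene_spectrum$bits[gi])
  }, TRUE)
  boolean_spectrum(keep, bits, provenance = gene_spectrum$provenance)
}

#' Hamming distance between two aligned Boolean spectra
#'
#' Requires identical id sequences — reordering must be explicit, never
#' silent.
#'
#' @param a,b [boolean_spectrum()] objects with identical `ids`
#' @return a `spectrum_comparison`: list with `hd`, `n` and `mismatches`
#'   (ids of differing positions).
#' @export
hamming <- function(a, b) {
  stopifnot(inherits(a, "boolean_spectrum"), inherits(b, "boolean_spectrum"))
  if (length(a$ids) != length(b$ids) || any(a$ids != b$ids))
    stop("spectrum alignment error: id sequences differ")
  diff <- a$bits != b$bits
  structure(list(hd = sum(diff), n = length(diff), mismatches = a$ids[diff]),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("HD = ", x$hd, " / ", x$n, "\n", sep = "")
  invisible(x)
}
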