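#' Degenerate codon library design
#'
#' A library design is an ordered set of randomised sites, each with a 1-based
#' residue position, the wild-type amino acid at that position, and the IUPAC
#' degenerate codon used to randomise it.
#'
#' @param position Integer vector of 1-based residue positions, strictly
#'   increasing.
#' @param wild_type Character vector of wild-type one-letter amino acids.
#' @param codon Character vector of degenerate codons (three IUPAC characters).
#' @param code Genetic code used for all repertoire computations.
#' @return An object of class `library_design`: a data frame with columns
#'   `position`, `wild_type`, `codon` and the genetic code attached as an
#'   attribute.
#' @export
#' @examples
#' des <- library_design(
#'   position  = c(41, 43, 215, 219, 222, 224, 225, 227),
#'   wild_type = c("S", "L", "H", "T", "K", "S", "R", "F"),
#'   codon     = c("NDT", "NDT", "NDT", "NHT", "VNG", "NDT", "NDT", "NDT")
#' )
#' gene_variant_count(des)     # 429981696 = 12^8
#' protein_variant_count(des)  # 394149888 = 12^7 * 11
library_design <- function(position, wild_type, codon,
                           code = standard_genetic_code()) {
  if (length(position) < 1L) stopf("a library design needs at least one site")
  if (length(wild_type) != length(position) || length(codon) != length(position)) {
    stopf("position, wild_type and codon must have equal length")
  }
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) stopf("positions must be positive integers")
  if (is.unsorted(position, strictly = TRUE)) stopf("positions must be strictly increasing")
  wild_type <- toupper(wild_type)
  bad <- setdiff(wild_type, AMINO_ACIDS)
  if (length(bad)) stopf("wild-type residue '%s' is not a standard amino acid", bad[1])
  codon <- toupper(codon)
  for (cd in codon) check_degenerate_codon(cd)
  validate_genetic_code(code)
  out <- data.frame(position = position, wild_type = wild_type, codon = codon,
                    stringsAsFactors = FALSE)
  attr(out, "code") <- code
  class(out) <- c("library_design", "data.frame")
  out
}

design_code <- function(design) {
  code <- attr(design, "code")
  if (is.null(code)) standard_genetic_code() else code
}

#' Read a library design from CSV
#'
#' @param path CSV file with header `position,wild_type,codon` (1-based
#'   residue positions).
#' @param code Genetic code to attach.
#' @return A [library_design()] object.
#' @export
read_design <- function(path, code = standard_genetic_code()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "wild_type", "codon")
  if (!all(need %in% names(df))) {
    stopf("design file must have columns %s", paste(need, collapse = ", "))
  }
  library_design(df$position, df$wild_type, df$codon, code = code)
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("Degenerate codon library design: %d site(s)\n", nrow(x)))
  rep_sizes <- vapply(x$codon, function(cd) {
    r <- amino_acid_repertoire(cd, design_code(x))
    length(setdiff(names(r), "*"))
  }, integer(1))
  df <- data.frame(position = x$position, wild_type = x$wild_type,
                   codon = x$codon,
                   codons = vapply(x$codon, function(cd) length(expand_degenerate_codon(cd)), integer(1)),
                   amino_acids = rep_sizes,
                   wt_included = includes_wild_type(x))
  print(df, row.names = FALSE)
  cat(sprintf("gene variants: %s; protein variants: %s\n",
              format(gene_variant_count(x), big.mark = ","),
              format(protein_variant_count(x), big.mark = ",")))
  invisible(x)
}

#' Total number of gene (DNA) variants in a design
#'
#' The product over sites of the codon-expansion sizes.
#'
#' @param design A [library_design()].
#' @return A numeric count (exact integer value).
#' @export
gene_variant_count <- function(design) {
  stopifnot(inherits(design, "library_design"))
  prod(vapply(design$codon, function(cd) length(expand_degenerate_codon(cd)), integer(1)))
}

#' Total number of protein variants in a design
#'
#' The product over sites of the number of distinct amino acids encoded
#' (stop codons excluded). Always less than or equal to
#' [gene_variant_count()].
#'
#' @inheritParams gene_variant_count
#' @return A numeric count (exact integer value).
#' @export
protein_variant_count <- function(design) {
  stopifnot(inherits(design, "library_design"))
  code <- design_code(design)
  sizes <- vapply(seq_len(nrow(design)), function(i) {
    rep <- amino_acid_repertoire(design$codon[i], code)
    n <- length(setdiff(names(rep), "*"))
    if (n == 0L) stopf("codon '%s' at position %d encodes only stop codons",
                       design$codon[i], design$position[i])
    n
  }, integer(1))
  prod(sizes)
}

#' Does each site's repertoire include the wild-type residue?
#'
#' Degenerate codons do not necessarily encode the native residue; e.g. NDT
#' lacks threonine, so a Thr site randomised with NDT cannot revert.
#'
#' @inheritParams gene_variant_count
#' @return Named logical vector, one entry per site (named `wt+position`).
#' @export
includes_wild_type <- function(design) {
  stopifnot(inherits(design, "library_design"))
  code <- design_code(design)
  out <- vapply(seq_len(nrow(design)), function(i) {
    rep <- amino_acid_repertoire(design$codon[i], code)
    design$wild_type[i] %in% names(rep)
  }, logical(1))
  setNames(out, paste0(design$wild_type, design$position))
}

# Group the library's protein variants into probability classes by codon
# multiplicity. A protein variant choosing amino acid a_i at site i is encoded
# by prod(m_i) DNA sequences out of prod(c_i) total, where m_i is the codon
# multiplicity of a_i and c_i the site's expansion size; its sampling
# probability is prod(m_i)/prod(c_i). Variants sharing the multiplicity
# product form a class, which keeps the coverage sum tractable at 10^8-scale
# diversities without enumerating variants.
variant_probability_classes <- function(design) {
  stopifnot(inherits(design, "library_design"))
  code <- design_code(design)
  classes <- c("1" = 1)  # multiplicity product -> variant count
  total_codons <- 1
  for (i in seq_len(nrow(design))) {
    rep <- amino_acid_repertoire(design$codon[i], code)
    rep <- rep[setdiff(names(rep), "*")]
    total_codons <- total_codons * length(expand_degenerate_codon(design$codon[i]))
    site <- table(rep)  # multiplicity value -> number of amino acids with it
    new <- new.env(parent = emptyenv())
    for (m0 in names(classes)) {
      for (m1 in names(site)) {
        key <- as.character(as.numeric(m0) * as.numeric(m1))
        prev <- if (is.null(new[[key]])) 0 else new[[key]]
        new[[key]] <- prev + classes[[m0]] * as.numeric(site[[m1]])
      }
    }
    classes <- unlist(as.list(new))
  }
  mult <- as.numeric(names(classes))
  ord <- order(mult)
  data.frame(multiplicity = mult[ord],
             count = as.numeric(classes)[ord],
             probability = mult[ord] / total_codons)
}

#' Expected number of distinct protein variants recovered
#'
#' Library completeness: given `num_transformants` independent draws from the
#' library's variant distribution, the expected number of distinct protein
#' variants observed. Variants are grouped into probability classes by codon
#' multiplicity; the exact method evaluates the grouped-binomial sum
#' \eqn{\sum_j k_j (1 - (1 - p_j)^L)} and the Poisson approximation uses
#' \eqn{\sum_j k_j (1 - e^{-L p_j})}.
#'
#' @inheritParams gene_variant_count
#' @param num_transformants Number of transformants sampled (L, >= 0).
#' @param method `"exact"` (default) or `"poisson"`.
#' @return Expected distinct variant count, a real number in
#'   `[0, protein_variant_count(design)]`, nondecreasing in
#'   `num_transformants`.
#' @export
#' @examples
#' des <- library_design(1, "M", "NNN")
#' expected_distinct_variants(des, 10)
expected_distinct_variants <- function(design, num_transformants,
                                       method = c("exact", "poisson")) {
  method <- match.arg(method)
  if (!is_count(num_transformants)) stopf("num_transformants must be a nonnegative integer")
  cl <- variant_probability_classes(design)
  L <- num_transformants
  hit <- switch(method,
    exact   = -expm1(L * log1p(-cl$probability)),
    poisson = -expm1(-L * cl$probability)
  )
  sum(cl$count * hit)
}

#' Per-position side-chain category profile of a variant set
#'
#' For a set of selected variants described by their amino acids at each
#' randomised position, tabulates the percentage of each of the five
#' side-chain categories at every position.
#'
#' @param variants Character matrix (rows = variants, columns = design sites)
#'   of one-letter amino acids, or a character vector of strings whose i-th
#'   character is the residue at the design's i-th site.
#' @param design The [library_design()] the variants come from; supplies
#'   position labels and the expected number of sites.
#' @return Numeric matrix (5 categories x positions) of percentages; each
#'   column sums to 100.
#' @export
category_profile <- function(variants, design) {
  stopifnot(inherits(design, "library_design"))
  if (is.character(variants) && is.null(dim(variants))) {
    if (any(nchar(variants) != nrow(design))) {
      stopf("each variant string must have %d characters (one per design site)", nrow(design))
    }
    variants <- do.call(rbind, strsplit(toupper(variants), ""))
  }
  if (!is.matrix(variants) || ncol(variants) != nrow(design)) {
    stopf("variants must cover all %d design positions", nrow(design))
  }
  cats <- names(SIDE_CHAIN_CATEGORIES)
  out <- sapply(seq_len(ncol(variants)), function(j) {
    cj <- factor(side_chain_category(variants[, j]), levels = cats)
    100 * as.numeric(table(cj)) / nrow(variants)
  })
  rownames(out) <- cats
  colnames(out) <- paste0(design$wild_type, design$position)
  out
}
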