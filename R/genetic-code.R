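#' The standard genetic code
#'
#' Returns the genetic code as a named character vector mapping the 64 DNA
#' triplets to amino-acid one-letter codes, with `"*"` denoting a stop codon.
#' The default is the standard (nuclear) code taken from
#' [Biostrings::GENETIC_CODE]; alternative tables can be loaded from a
#' two-column CSV with [read_genetic_code()].
#'
#' @return Named character vector of length 64 (names are DNA triplets).
#' @export
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]  # "M"
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
}

#' Read a genetic code table from file
#'
#' @param path CSV file with header `codon,aa`; exactly 64 rows, one per DNA
#'   triplet, amino acids as one-letter codes and stop as `*`.
#' @return Named character vector as in [standard_genetic_code()].
#' @export
read_genetic_code <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "aa") %in% names(df))) {
    stopf("genetic code file must have columns 'codon' and 'aa'")
  }
  code <- setNames(toupper(df$aa), toupper(df$codon))
  validate_genetic_code(code)
  code
}

validate_genetic_code <- function(code) {
  if (length(code) != 64L || anyDuplicated(names(code))) {
    stopf("a genetic code must map exactly the 64 distinct triplets")
  }
  bad <- setdiff(names(code), names(Biostrings::GENETIC_CODE))
  if (length(bad)) stopf("invalid codon(s) in code table: %s", paste(bad, collapse = ", "))
  if (!all(unique(code) %in% c(AMINO_ACIDS, "*"))) {
    stopf("code values must be one-letter amino acids or '*'")
  }
  invisible(code)
}

# The 20 standard amino acids, one-letter codes.
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# IUPAC nucleotide ambiguity alphabet, e.g. N = ACGT, D = AGT (no C),
# H = ACT (no G), V = ACG (no T).
iupac_sets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(setNames(as.character(m), names(m)), function(s) strsplit(s, "")[[1]])
}

#' Expand a degenerate codon into its concrete triplets
#'
#' A degenerate codon is written with IUPAC ambiguity characters
#' (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N). Expansion is the Cartesian product of the
#' three per-character base sets, so e.g. `NDT` (N = 4 bases, D = 3, T = 1)
#' expands to 12 triplets.
#'
#' @param codon A string of exactly three IUPAC characters.
#' @return Character vector of concrete DNA triplets, in a deterministic
#'   (alphabetical within position) order.
#' @export
#' @examples
#' length(expand_degenerate_codon("NDT"))  # 12
#' expand_degenerate_codon("ATG")          # "ATG"
expand_degenerate_codon <- function(codon) {
  chars <- check_degenerate_codon(codon)
  sets <- iupac_sets()
  parts <- lapply(chars, function(ch) sets[[ch]])
  grid <- expand.grid(parts[[3]], parts[[2]], parts[[1]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
}

check_degenerate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    stopf("a degenerate codon must be a single string")
  }
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stopf("a degenerate codon must have exactly 3 characters, got '%s'", codon)
  chars <- strsplit(codon, "")[[1]]
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) {
    stopf("invalid IUPAC nucleotide character '%s' in codon '%s'", bad[1], codon)
  }
  chars
}

#' Amino-acid repertoire of a degenerate codon
#'
#' Translates every concrete triplet of a degenerate codon and tabulates the
#' codon multiplicity of each encoded amino acid. Stop codons, if encoded, are
#' reported separately under the key `"*"`.
#'
#' @param codon Degenerate codon string (see [expand_degenerate_codon()]).
#' @param code Genetic code table; defaults to the standard code.
#' @return Named integer vector of codon multiplicities; amino acids sorted
#'   alphabetically, with `"*"` (if present) last. Multiplicities sum to the
#'   expansion size of the codon.
#' @export
#' @examples
#' amino_acid_repertoire("NDT")  # 12 amino acids, each encoded once
#' amino_acid_repertoire("VNG")  # 11 amino acids, Arg twice
amino_acid_repertoire <- function(codon, code = standard_genetic_code()) {
  validate_genetic_code(code)
  triplets <- expand_degenerate_codon(codon)
  aas <- code[triplets]
  tab <- table(aas)
  out <- setNames(as.integer(tab), names(tab))
  aa <- sort(setdiff(names(out), "*"))
  if ("*" %in% names(out)) aa <- c(aa, "*")
  out[aa]
}

# Side-chain categories: the usual textbook five-way partition of the 20
# standard amino acids.
SIDE_CHAIN_CATEGORIES <- list(
  "nonpolar aliphatic"  = c("G", "A", "V", "L", "I", "M", "P"),
  "aromatic"            = c("F", "Y", "W"),
  "polar uncharged"     = c("S", "T", "C", "N", "Q"),
  "positively charged"  = c("K", "R", "H"),
  "negatively charged"  = c("D", "E")
)

#' Side-chain category of an amino acid
#'
#' Classifies each of the 20 standard amino acids into one of five disjoint
#' side-chain categories: nonpolar aliphatic (G,A,V,L,I,M,P), aromatic
#' (F,Y,W), polar uncharged (S,T,C,N,Q), positively charged (K,R,H) and
#' negatively charged (D,E).
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Character vector of category names (a factor-free character).
#' @export
#' @examples
#' side_chain_category(c("Y", "D", "R"))
side_chain_category <- function(aa) {
  aa <- toupper(aa)
  lut <- unlist(lapply(names(SIDE_CHAIN_CATEGORIES), function(cat) {
    setNames(rep(cat, length(SIDE_CHAIN_CATEGORIES[[cat]])), SIDE_CHAIN_CATEGORIES[[cat]])
  }))
  bad <- setdiff(aa, names(lut))
  if (length(bad)) stopf("unknown amino acid code '%s'", bad[1])
  unname(lut[aa])
}
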