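# Standard genetic code and single-nucleotide reachability between amino acids.

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. This is the canonical column/row
#' ordering used throughout the package unless a display ordering is requested.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino acids ordered by physicochemical property
#'
#' A fixed display ordering for heat-map emission: aliphatic/hydrophobic,
#' aromatic, small/polar, amide, acidic, basic, then the conformationally
#' special residues. Editable via the `order` argument of
#' [order_weight_table()].
#'
#' @export
AA_PROPERTY_ORDER <- c("I", "V", "L", "M", "C", "A", "F", "W", "Y",
                       "T", "S", "N", "Q", "D", "E", "H", "K", "R", "G", "P")

# Standard genetic code, DNA alphabet. Verified against an installed
# reference translation table in the test suite.
.CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Codon table
#'
#' Returns the codon-to-amino-acid mapping as a tibble. By default the
#' standard genetic code is used; a tab-separated override file with columns
#' `codon` and `aa` may be supplied (intended for testing). RNA-alphabet
#' codons (U) are accepted and converted to the DNA alphabet.
#'
#' @param path Optional path to a two-column tab-separated file
#'   (codon, amino acid or `*` for stop).
#' @return A tibble with columns `codon` (64 DNA triplets) and `aa`
#'   (one-letter amino acid or `"*"`).
#' @export
codon_table <- function(path = NULL) {
  if (is.null(path)) {
    return(tibble::tibble(codon = names(.CODON_TABLE), aa = unname(.CODON_TABLE)))
  }
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  names(tbl) <- tolower(names(tbl))
  tbl$codon <- toupper(gsub("U", "T", toupper(tbl$codon)))
  validate_codon_table(tibble::as_tibble(tbl[c("codon", "aa")]))
}

validate_codon_table <- function(tbl) {
  if (anyDuplicated(tbl$codon) > 0) {
    stop("codon table contains duplicate codons", call. = FALSE)
  }
  all_codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G")), 1, paste0, collapse = "")
  if (!setequal(tbl$codon, all_codons)) {
    stop("codon table is incomplete: expected all 64 triplets", call. = FALSE)
  }
  missing_aa <- setdiff(AA_ALPHABET, tbl$aa)
  if (length(missing_aa) > 0) {
    stop("codon table lacks codons for: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Single-mutation reachability between amino acids
#'
#' Builds the 20 x 20 logical matrix whose `(ref, mut)` entry is `TRUE` when
#' some sense codon of the reference amino acid can be turned into a sense
#' codon of the mutant amino acid by changing exactly one nucleotide. Stop
#' codons are excluded on both sides, and the diagonal is stored as `FALSE`
#' (a self-substitution is not a variant). Under the standard code 150 of
#' the 380 ordered amino-acid pairs are reachable.
#'
#' @param table A codon table as returned by [codon_table()].
#' @return A named 20 x 20 logical matrix (rows = reference, cols = mutant),
#'   rows and columns in [AA_ALPHABET] order.
#' @export
reachability_matrix <- function(table = codon_table()) {
  table <- validate_codon_table(table)
  sense <- table[table$aa != "*", ]
  codons <- strsplit(sense$codon, "")
  aa <- sense$aa
  reach <- matrix(FALSE, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  n <- length(codons)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (aa[i] != aa[j] && sum(codons[[i]] != codons[[j]]) == 1L) {
        reach[aa[i], aa[j]] <- TRUE
      }
    }
  }
  reach
}

#' Mutant amino acids unreachable by a single codon mutation
#'
#' For a reference amino acid, the set of amino acids that cannot result
#' from a single nucleotide change in any of its codons. Variants with such
#' substitutions are multi-nucleotide events and are excluded from the
#' analysis set.
#'
#' @param ref_aa A single one-letter amino-acid code.
#' @param reach A reachability matrix from [reachability_matrix()].
#' @return Character vector of unreachable mutant amino acids (sorted,
#'   excluding `ref_aa` itself).
#' @export
unreachable_mutants <- function(ref_aa, reach = reachability_matrix()) {
  if (length(ref_aa) != 1L || !ref_aa %in% AA_ALPHABET) {
    stop("`ref_aa` must be one of the 20 standard amino acids", call. = FALSE)
  }
  setdiff(AA_ALPHABET[!reach[ref_aa, ]], ref_aa)
}
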