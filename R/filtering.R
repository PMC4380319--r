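# Dataset-construction filters: class-overlap resolution, basic sanity
# filters, single-mutation (codon) reachability, sequence fit, and
# duplicate-window de-duplication.

#' Resolve variants present in both classes
#'
#' A variant reported both as disease-associated and as neutral is assumed
#' to be disease-associated: the neutral copy is removed.
#'
#' @param variants A labeled variant tibble.
#' @return The tibble with overlapping neutral records dropped; the number
#'   removed is in attribute `"n_removed"`.
#' @export
resolve_class_overlap <- function(variants) {
  key <- variant_id(variants)
  disease_keys <- key[variants$label == 1L]
  drop <- variants$label == 0L & key %in% disease_keys
  out <- variants[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Basic variant sanity filters
#'
#' Removes synonymous records (`ref == mut`), exact duplicates, variants in
#' the start codon (position 1), and records with letters outside the
#' twenty unambiguous amino acids.
#'
#' @param variants A variant tibble.
#' @return Filtered tibble; counts of removals per rule in attribute
#'   `"removed"` (named integer vector).
#' @export
basic_filters <- function(variants) {
  syn <- variants$ref_aa == variants$mut_aa
  start_codon <- variants$position == 1L
  ambiguous <- !(variants$ref_aa %in% AA_ALPHABET) |
    !(variants$mut_aa %in% AA_ALPHABET)
  dup <- duplicated(paste(variant_id(variants), variants$label))
  drop <- syn | start_codon | ambiguous | dup
  out <- variants[!drop, ]
  attr(out, "removed") <- c(synonymous = sum(syn), start_codon = sum(start_codon),
                            ambiguous = sum(ambiguous), duplicate = sum(dup),
                            total = sum(drop))
  out
}

#' Remove substitutions requiring more than one codon mutation
#'
#' Keeps only variants whose reference-to-mutant substitution is achievable
#' by a single nucleotide change in some codon of the reference amino acid.
#'
#' @param variants A variant tibble (standard amino acids only).
#' @param reach Reachability matrix from [reachability_matrix()].
#' @return Filtered tibble with attribute `"n_removed"`.
#' @export
filter_multinucleotide <- function(variants, reach = reachability_matrix()) {
  if (nrow(variants) == 0) {
    attr(variants, "n_removed") <- 0L
    return(variants)
  }
  keep <- reach[cbind(variants$ref_aa, variants$mut_aa)]
  out <- variants[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove variants that do not fit the protein sequence
#'
#' Drops records whose protein is absent from `proteins` or whose sequence
#' does not carry the reference amino acid at the stated position.
#'
#' @param variants A variant tibble.
#' @param proteins Named character vector of protein sequences.
#' @return Filtered tibble; attribute `"removed"` holds counts for
#'   `no_sequence` and `mismatch`.
#' @export
filter_sequence_fit <- function(variants, proteins) {
  known <- variants$protein_id %in% names(proteins)
  at <- rep(NA_character_, nrow(variants))
  if (any(known)) {
    at[known] <- substr_at(proteins[variants$protein_id[known]],
                           variants$position[known])
  }
  fits <- known & !is.na(at) & at == variants$ref_aa
  out <- variants[fits, ]
  attr(out, "removed") <- c(no_sequence = sum(!known),
                            mismatch = sum(known & !fits))
  out
}

substr_at <- function(seqs, pos) {
  out <- substr(seqs, pos, pos)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Sequence window around a variant position
#'
#' The window of `length` residues centred on the position, truncated at
#' sequence ends.
#'
#' @param seqs Character vector of sequences (recycled against `pos`).
#' @param pos Integer positions.
#' @param length Odd window length (default 19).
#' @return Character vector of window strings.
#' @export
sequence_window <- function(seqs, pos, length = 19L) {
  half <- (length - 1L) %/% 2L
  lo <- pmax(1L, pos - half)
  hi <- pmin(nchar(seqs), pos + half)
  substr(seqs, lo, hi)
}

#' De-duplicate variants with identical surrounding windows
#'
#' Variants at different locations sharing the same substitution and the
#' same surrounding sequence in a window of `window` residues are assumed
#' to be the same underlying DNA mutation mapped to multiple proteins. One
#' canonical record per group is kept (smallest protein id, then smallest
#' position) unless `drop_all = TRUE`, in which case every member of a
#' duplicated group is removed.
#'
#' @param variants A variant tibble that already passed [filter_sequence_fit()].
#' @param proteins Named character vector of sequences.
#' @param window Window length in residues.
#' @param drop_all Drop whole duplicated groups instead of keeping one.
#' @param within_label Compare windows only among variants with the same
#'   label, instead of across the whole set.
#' @return Filtered tibble with attribute `"n_removed"`.
#' @export
filter_duplicate_windows <- function(variants, proteins, window = 19L,
                                     drop_all = FALSE, within_label = FALSE) {
  if (nrow(variants) == 0) {
    attr(variants, "n_removed") <- 0L
    return(variants)
  }
  win <- sequence_window(proteins[variants$protein_id], variants$position, window)
  key <- paste(win, variants$ref_aa, variants$mut_aa, sep = "|")
  if (within_label) key <- paste(key, variants$label, sep = "|")
  ord <- order(key, variants$protein_id, variants$position)
  first_of_group <- !duplicated(key[ord])
  keep_ord <- if (drop_all) {
    grp_sizes <- table(key)
    first_of_group & grp_sizes[key[ord]] == 1L
  } else {
    first_of_group
  }
  keep <- logical(nrow(variants))
  keep[ord] <- keep_ord
  out <- variants[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full dataset-construction pipeline
#'
#' Applies, in order: class-overlap resolution, basic filters, the
#' single-codon-mutation filter, the sequence-fit filter, and
#' duplicate-window de-duplication.
#'
#' @param variants A labeled variant tibble.
#' @param proteins Named character vector of protein sequences.
#' @param reach Reachability matrix.
#' @param window Duplicate-window length.
#' @param drop_all_window_dups,within_label Passed to
#'   [filter_duplicate_windows()].
#' @return A list of class `variant_filter` with elements `variants` (the
#'   analysis set) and `report` (a one-row tibble of per-rule counts; input
#'   always equals output plus the removals).
#' @export
filter_variants <- function(variants, proteins, reach = reachability_matrix(),
                            window = 19L, drop_all_window_dups = FALSE,
                            within_label = FALSE) {
  n_in <- nrow(variants)
  v <- resolve_class_overlap(variants)
  n_overlap <- attr(v, "n_removed")
  v <- basic_filters(v)
  n_basic <- attr(v, "removed")[["total"]]
  v <- filter_multinucleotide(v, reach)
  n_multi <- attr(v, "n_removed")
  v <- filter_sequence_fit(v, proteins)
  n_fit <- sum(attr(v, "removed"))
  v <- filter_duplicate_windows(v, proteins, window,
                                drop_all = drop_all_window_dups,
                                within_label = within_label)
  n_dupwin <- attr(v, "n_removed")
  report <- tibble::tibble(
    input = n_in,
    removed_overlap = n_overlap,
    removed_synonymous_or_duplicate = n_basic,
    removed_multinucleotide = n_multi,
    removed_nonfitting = n_fit,
    removed_duplicate_window = n_dupwin,
    output = nrow(v),
    output_neutral = sum(v$label == 0L),
    output_disease = sum(v$label == 1L)
  )
  stopifnot(report$input == report$output + n_overlap + n_basic + n_multi +
              n_fit + n_dupwin)
  attr(v, "removed") <- NULL
  attr(v, "n_removed") <- NULL
  structure(list(variants = tibble::as_tibble(v), report = report),
            class = "variant_filter")
}

#' @export
print.variant_filter <- function(x, ...) {
  cat("Variant filtering:", x$report$input, "in ->", x$report$output, "out (",
      x$report$output_neutral, "neutral,", x$report$output_disease, "disease )\n")
  print(tidyr::pivot_longer(x$report, dplyr::everything(),
                            names_to = "rule", values_to = "n"))
  invisible(x)
}
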