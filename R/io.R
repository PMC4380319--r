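# Readers and writers for the on-disk formats the tool consumes and emits:
# protein FASTA, aligned FASTA (MSA), two labeled-variant dialects, Pfam
# annotation tables, and amino-acid scale tables.

#' Read protein sequences from a FASTA file
#'
#' Sequence identifiers are the first whitespace-delimited token of the
#' header; `db|ACC|name` headers are reduced to the accession. Sequences are
#' upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, names = protein ids.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- fasta_id(names(seqs))
  if (anyDuplicated(ids) > 0) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(toupper(as.character(seqs)), ids)
}

fasta_id <- function(headers) {
  tok <- stringr::str_split_i(headers, "\\s+", 1)
  # sp|Q9XYZ1|NAME -> Q9XYZ1
  ifelse(stringr::str_detect(tok, "^[A-Za-z]+\\|[^|]+\\|"),
         stringr::str_split_i(tok, "\\|", 2), tok)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read labeled variants
#'
#' Two dialects are supported. `"id_label"` files have two tab-separated
#' columns: a variant id `protein_pos_ref_mut` (underscores; parsed from the
#' right so protein ids containing underscores survive) and a label, 0 for
#' neutral and 1 for disease-associated. A header line naming the labels is
#' tolerated. `"twelve_col"` files carry twelve tab-separated columns per
#' row (id, position, reference, mutant, label, window sequence, window
#' size, nucleotide window, reference codon, mutant codon, then two
#' structure-mapping columns which are ignored).
#'
#' @param path Path to the variant file.
#' @param dialect `"id_label"` or `"twelve_col"`.
#' @param fail_fast If `TRUE`, stop at the first malformed record; otherwise
#'   malformed records are dropped with a single summarising warning.
#' @return A variant tibble with columns `protein_id`, `position`, `ref_aa`,
#'   `mut_aa`, `label` (integer 0/1 or `NA`), and for the twelve-column
#'   dialect also `window_seq`, `ref_codon`, `mut_codon`.
#' @export
read_variants <- function(path, dialect = c("id_label", "twelve_col"),
                          fail_fast = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (dialect == "id_label") {
    # tolerate a header such as "neutral (0)\tdisease (1)"
    if (length(lines) > 0 && !grepl("^\\S+_\\d+_[A-Za-z]_[A-Za-z]\\t", lines[1])) {
      lines <- lines[-1]
    }
    parts <- stringr::str_split_fixed(lines, "\t", 2)
    m <- stringr::str_match(parts[, 1], "^(.*)_(\\d+)_([A-Za-z])_([A-Za-z])$")
    out <- tibble::tibble(
      protein_id = m[, 2],
      position = suppressWarnings(as.integer(m[, 3])),
      ref_aa = toupper(m[, 4]),
      mut_aa = toupper(m[, 5]),
      label = suppressWarnings(as.integer(parts[, 2]))
    )
  } else {
    f <- stringr::str_split_fixed(lines, "\t", 12)
    out <- tibble::tibble(
      protein_id = f[, 1],
      position = suppressWarnings(as.integer(f[, 2])),
      ref_aa = toupper(f[, 3]),
      mut_aa = toupper(f[, 4]),
      label = suppressWarnings(as.integer(f[, 5])),
      window_seq = f[, 6],
      ref_codon = toupper(f[, 9]),
      mut_codon = toupper(f[, 10])
    )
  }
  bad <- is.na(out$protein_id) | is.na(out$position) | out$position < 1 |
    is.na(out$label) | !out$label %in% c(0L, 1L) |
    out$ref_aa == out$mut_aa |
    !nzchar(out$protein_id)
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed variant record(s) in ", path,
                  " (first: line ", which(bad)[1], ")")
    if (fail_fast) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    out <- out[!bad, ]
  }
  out
}

#' Write variants
#'
#' The `"id_label"` dialect writes the two-column id/label form; the
#' `"twelve_col"` dialect writes all twelve columns, filling the
#' structure-mapping columns with their no-mapping sentinels (`None`, -1)
#' and any absent optional field with an empty string.
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @param dialect `"id_label"` or `"twelve_col"`.
#' @param header Write the label-description header line (id_label only).
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, dialect = c("id_label", "twelve_col"),
                           header = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "id_label") {
    lines <- paste(variant_id(variants), variants$label, sep = "\t")
    if (header) lines <- c("neutral (0)\tdisease (1)", lines)
    writeLines(lines, path)
    return(invisible(path))
  }
  opt <- function(col) {
    if (col %in% names(variants)) dplyr::coalesce(variants[[col]], "") else
      rep("", nrow(variants))
  }
  win <- opt("window_seq")
  lines <- paste(variants$protein_id, variants$position, variants$ref_aa,
                 variants$mut_aa, variants$label, win, nchar(win),
                 "", opt("ref_codon"), opt("mut_codon"), "None", "-1",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Variant id string
#'
#' `protein_pos_ref_mut`, the id form of the two-column dialect.
#'
#' @param variants A variant tibble.
#' @return Character vector of ids.
#' @export
variant_id <- function(variants) {
  paste(variants$protein_id, variants$position, variants$ref_aa,
        variants$mut_aa, sep = "_")
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA whose first sequence is the query protein.
#' Columns where the query has a gap are dropped, so column `j` of the
#' result corresponds to residue `j` of the (ungapped) query. Lower-case
#' letters, `-` and `.` in homolog rows are treated as gaps.
#'
#' @param path Path to an aligned FASTA.
#' @return A tibble of class `msa_columns` with one row per query position:
#'   `position`, `residues` (list of upper-case non-gap letters observed,
#'   query included), `n_proteins` (alignment depth, constant), and
#'   `n_residues` (non-gap count in the column).
#' @export
read_msa <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty alignment: ", path, call. = FALSE)
  chars <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment in ", path, ": row lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, chars)
  master <- mat[1, ]
  keep <- !(master %in% c("-", ".")) & master == toupper(master)
  mat <- mat[, keep, drop = FALSE]
  is_gap <- mat %in% c("-", ".") | mat != toupper(mat)
  dim(is_gap) <- dim(mat)
  mat <- toupper(mat)
  cols <- purrr::map(seq_len(ncol(mat)), function(j) {
    unname(mat[!is_gap[, j], j])
  })
  out <- tibble::tibble(
    position = seq_len(ncol(mat)),
    residues = cols,
    n_proteins = nrow(mat),
    n_residues = lengths(cols)
  )
  class(out) <- c("msa_columns", class(out))
  out
}

#' Extract one alignment column
#'
#' @param msa An `msa_columns` tibble from [read_msa()].
#' @param position 1-based query position.
#' @return A list with `residues`, `n_proteins`, `n_residues`; `NULL` if the
#'   position is outside the alignment.
#' @export
msa_column <- function(msa, position) {
  i <- match(position, msa$position)
  if (is.na(i)) return(NULL)
  list(residues = msa$residues[[i]],
       n_proteins = msa$n_proteins[[i]],
       n_residues = msa$n_residues[[i]])
}

#' Read a Pfam annotation table
#'
#' Tab-separated columns: protein id, start, end (1-based inclusive), match
#' type (`family`, `domain`, or `clan-member`), and an optional clan id.
#'
#' @param path Path to the table.
#' @return Tibble with columns `protein_id`, `start`, `end`, `match_type`,
#'   `clan_id`.
#' @export
read_pfam_table <- function(path) {
  tbl <- utils::read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                           colClasses = "character",
                           col.names = c("protein_id", "start", "end",
                                         "match_type", "clan_id"))
  out <- tibble::tibble(
    protein_id = tbl$protein_id,
    start = as.integer(tbl$start),
    end = as.integer(tbl$end),
    match_type = tolower(tbl$match_type),
    clan_id = dplyr::na_if(tbl$clan_id, "")
  )
  bad_type <- !out$match_type %in% c("family", "domain", "clan-member")
  if (any(bad_type)) {
    stop("unknown Pfam match type(s): ",
         paste(unique(out$match_type[bad_type]), collapse = ", "),
         call. = FALSE)
  }
  if (any(out$start > out$end)) stop("Pfam span with start > end", call. = FALSE)
  out
}

#' Write a Pfam annotation table
#'
#' @param pfam Tibble as returned by [read_pfam_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfam_table <- function(pfam, path) {
  utils::write.table(
    data.frame(pfam$protein_id, pfam$start, pfam$end, pfam$match_type,
               ifelse(is.na(pfam$clan_id), "", pfam$clan_id)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an amino-acid scale table
#'
#' A tab-separated table with a header line and twenty rows: first column
#' the one-letter amino acid, remaining columns one numeric scale each.
#'
#' @param path Path to the table; defaults to the packaged set of 19
#'   mutually uncorrelated scales derived from the AAIndex collection.
#' @return A tibble of class `scale_set`: column `aa` plus one numeric
#'   column per scale.
#' @export
read_scales <- function(path = default_scales_path()) {
  tbl <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             check.names = FALSE))
  names(tbl)[1] <- "aa"
  tbl$aa <- toupper(tbl$aa)
  missing <- setdiff(AA_ALPHABET, tbl$aa)
  if (length(missing) > 0 || nrow(tbl) != 20) {
    stop("scale table must have exactly the 20 standard amino acids; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (ncol(tbl) < 2) stop("scale table has no scale columns", call. = FALSE)
  if (anyNA(tbl[-1])) stop("scale table contains missing values", call. = FALSE)
  class(tbl) <- c("scale_set", class(tbl))
  tbl
}

#' @rdname read_scales
#' @export
default_scales_path <- function() {
  system.file("extdata", "aa_scales_varimax19.tsv", package = "misvep",
              mustWork = TRUE)
}

#' Write an amino-acid scale table
#'
#' @param scales A `scale_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scales <- function(scales, path) {
  utils::write.table(scales, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
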