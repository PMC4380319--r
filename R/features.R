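# The five feature categories: amino-acid substitution identity,
# surrounding-sequence composition, alignment-column conservation,
# physicochemical conservation, and Pfam domain membership; plus
# feature-matrix assembly, constant-column removal and standardization.

FEATURE_CATEGORIES <- c("substitution", "surrounding", "conservation",
                        "physchem", "domain")

#' Window specification for surrounding-sequence features
#'
#' @param length Odd window length in residues (default 19, i.e. nine
#'   residues either side of the variant).
#' @param include_center Whether the substituted residue itself is counted.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(length = 19L, include_center = TRUE) {
  length <- as.integer(length)
  if (length < 3L || length %% 2L == 0L) {
    stop("window length must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(length = length, include_center = isTRUE(include_center)),
            class = "window_spec")
}

#' Amino-acid substitution features
#'
#' Twenty features, one per amino acid: the reference amino acid is set to
#' -1, the mutant to +1, all others to 0. Each row therefore sums to zero.
#'
#' @param variants A variant tibble (or vectors `ref_aa`, `mut_aa`).
#' @return Numeric matrix, one row per variant, columns `sub_A` ... `sub_Y`.
#' @export
substitution_features <- function(variants) {
  ref <- variants$ref_aa
  mut <- variants$mut_aa
  if (any(!ref %in% AA_ALPHABET) || any(!mut %in% AA_ALPHABET)) {
    stop("non-standard amino-acid letter in substitution", call. = FALSE)
  }
  if (any(ref == mut)) stop("synonymous record: ref == mut", call. = FALSE)
  m <- matrix(0, nrow = length(ref), ncol = 20,
              dimnames = list(NULL, paste0("sub_", AA_ALPHABET)))
  m[cbind(seq_along(ref), match(ref, AA_ALPHABET))] <- -1
  m[cbind(seq_along(mut), match(mut, AA_ALPHABET))] <- 1
  m
}

#' Surrounding-sequence features
#'
#' Counts of each amino acid in a window of `spec$length` residues centred
#' on the variant position, truncated at sequence ends.
#'
#' @param variants A variant tibble.
#' @param proteins Named character vector of sequences.
#' @param spec A [window_spec()].
#' @return Numeric matrix, columns `count_A` ... `count_Y`.
#' @export
surrounding_features <- function(variants, proteins, spec = window_spec()) {
  win <- sequence_window(proteins[variants$protein_id], variants$position,
                         spec$length)
  m <- matrix(0, nrow = nrow(variants), ncol = 20,
              dimnames = list(NULL, paste0("count_", AA_ALPHABET)))
  for (i in seq_len(nrow(variants))) {
    letters_i <- strsplit(win[i], "")[[1]]
    if (!spec$include_center) {
      center <- variants$position[i] - max(1L, variants$position[i] -
                                             (spec$length - 1L) %/% 2L) + 1L
      letters_i <- letters_i[-center]
    }
    tab <- table(factor(letters_i, levels = AA_ALPHABET))
    m[i, ] <- as.integer(tab)
  }
  m
}

#' Conservation features
#'
#' Four features from the alignment column at the variant position: the
#' frequency of the reference amino acid, the frequency of the mutant amino
#' acid (both over the non-gap residues in the column; 0 when the column is
#' empty), the number of aligned proteins, and the number of aligned
#' (non-gap) residues in the column.
#'
#' @param variants A variant tibble.
#' @param msas Named list of `msa_columns` objects, keyed by protein id.
#' @return Numeric matrix with columns `f_mut`, `f_ref`, `n_proteins`,
#'   `n_residues`.
#' @export
conservation_features <- function(variants, msas) {
  m <- matrix(0, nrow = nrow(variants), ncol = 4,
              dimnames = list(NULL, c("f_mut", "f_ref", "n_proteins",
                                      "n_residues")))
  for (i in seq_len(nrow(variants))) {
    col <- msa_column(msas[[variants$protein_id[i]]], variants$position[i])
    if (is.null(col)) next
    nr <- col$n_residues
    m[i, "f_ref"] <- if (nr > 0) sum(col$residues == variants$ref_aa[i]) / nr else 0
    m[i, "f_mut"] <- if (nr > 0) sum(col$residues == variants$mut_aa[i]) / nr else 0
    m[i, "n_proteins"] <- col$n_proteins
    m[i, "n_residues"] <- nr
  }
  m
}

#' Physicochemical conservation features
#'
#' For each amino-acid scale, the minimal absolute difference between the
#' mutant amino acid's scale value and the scale values of the residues
#' observed in the alignment column at the variant position. Zero when the
#' mutant itself occurs in the column, and zero (no information) when the
#' column is empty.
#'
#' @param variants A variant tibble.
#' @param msas Named list of `msa_columns` objects.
#' @param scales A `scale_set` from [read_scales()].
#' @return Numeric matrix with one column per scale, named `pc_<scale>`.
#' @export
physchem_features <- function(variants, msas, scales = read_scales()) {
  smat <- as.matrix(scales[-1])
  rownames(smat) <- scales$aa
  if (anyNA(smat[AA_ALPHABET, ])) {
    stop("scale set lacks values for some amino acids", call. = FALSE)
  }
  m <- matrix(0, nrow = nrow(variants), ncol = ncol(smat),
              dimnames = list(NULL, paste0("pc_", colnames(smat))))
  for (i in seq_len(nrow(variants))) {
    col <- msa_column(msas[[variants$protein_id[i]]], variants$position[i])
    if (is.null(col) || col$n_residues == 0) next
    res <- unique(col$residues)
    res <- res[res %in% AA_ALPHABET]
    if (length(res) == 0) next
    diffs <- abs(smat[res, , drop = FALSE] -
                   rep(smat[variants$mut_aa[i], ], each = length(res)))
    m[i, ] <- apply(diffs, 2, min)
  }
  m
}

#' Pfam domain features
#'
#' Three binary features: 1 when the variant position lies inside an
#' annotated Pfam family, domain, or clan span of its protein.
#'
#' @param variants A variant tibble.
#' @param pfam Annotation tibble from [read_pfam_table()]. A span counts as
#'   clan membership when its `match_type` is `"clan-member"` or it carries
#'   a `clan_id`.
#' @return Numeric 0/1 matrix with columns `in_clan`, `in_domain`,
#'   `in_family`.
#' @export
domain_features <- function(variants, pfam) {
  m <- matrix(0, nrow = nrow(variants), ncol = 3,
              dimnames = list(NULL, c("in_clan", "in_domain", "in_family")))
  if (nrow(pfam) == 0) return(m)
  by_protein <- split(pfam, pfam$protein_id)
  for (i in seq_len(nrow(variants))) {
    ann <- by_protein[[variants$protein_id[i]]]
    if (is.null(ann)) next
    hit <- ann$start <= variants$position[i] & variants$position[i] <= ann$end
    if (!any(hit)) next
    types <- ann$match_type[hit]
    m[i, "in_family"] <- as.numeric("family" %in% types)
    m[i, "in_domain"] <- as.numeric("domain" %in% types)
    m[i, "in_clan"] <- as.numeric("clan-member" %in% types ||
                                    any(!is.na(ann$clan_id[hit])))
  }
  m
}

#' Assemble the feature matrix
#'
#' Builds the requested feature categories for every variant and binds them
#' into a single tibble, one row per variant in input order. Column order is
#' deterministic: categories in their canonical order (substitution,
#' surrounding, conservation, physchem, domain), features alphabetical
#' within a category. Variants whose protein sequence or alignment is
#' missing are excluded and listed in attribute `"excluded"`.
#'
#' @param variants A variant tibble.
#' @param proteins Named character vector of sequences.
#' @param msas Named list of `msa_columns`, keyed by protein id.
#' @param pfam Pfam annotation tibble.
#' @param scales A `scale_set`.
#' @param categories Subset of the five category names.
#' @param spec A [window_spec()].
#' @return A tibble of class `feature_matrix`: column `variant_id` followed
#'   by the feature columns. Attribute `"categories"` maps feature name to
#'   category; `"excluded"` lists dropped variants and the reason.
#' @export
assemble_features <- function(variants, proteins = NULL, msas = NULL,
                              pfam = NULL, scales = read_scales(),
                              categories = FEATURE_CATEGORIES,
                              spec = window_spec()) {
  categories <- match.arg(categories, FEATURE_CATEGORIES, several.ok = TRUE)
  need_seq <- any(c("surrounding") %in% categories)
  need_msa <- any(c("conservation", "physchem") %in% categories)
  excl_reason <- rep(NA_character_, nrow(variants))
  if (need_seq || need_msa) {
    no_seq <- need_seq & !variants$protein_id %in% names(proteins)
    no_msa <- need_msa & !variants$protein_id %in% names(msas)
    excl_reason[no_msa] <- "missing MSA"
    excl_reason[no_seq] <- "missing protein sequence"
  }
  keep <- is.na(excl_reason)
  excluded <- tibble::tibble(variant_id = variant_id(variants[!keep, ]),
                             reason = excl_reason[!keep])
  v <- variants[keep, ]
  blocks <- list()
  if ("substitution" %in% categories) {
    blocks$substitution <- substitution_features(v)
  }
  if ("surrounding" %in% categories) {
    blocks$surrounding <- surrounding_features(v, proteins, spec)
  }
  if ("conservation" %in% categories) {
    blocks$conservation <- conservation_features(v, msas)
  }
  if ("physchem" %in% categories) {
    blocks$physchem <- physchem_features(v, msas, scales)
  }
  if ("domain" %in% categories) {
    blocks$domain <- domain_features(v, if (is.null(pfam))
      tibble::tibble(protein_id = character(), start = integer(),
                     end = integer(), match_type = character(),
                     clan_id = character()) else pfam)
  }
  blocks <- blocks[intersect(FEATURE_CATEGORIES, names(blocks))]
  blocks <- lapply(blocks, function(b) b[, sort(colnames(b)), drop = FALSE])
  cat_map <- unlist(lapply(names(blocks), function(nm)
    stats::setNames(rep(nm, ncol(blocks[[nm]])), colnames(blocks[[nm]]))))
  mat <- do.call(cbind, unname(blocks))
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(variant_id = variant_id(v)), out)
  new_feature_matrix(out, categories = cat_map, excluded = excluded)
}

new_feature_matrix <- function(tbl, categories, excluded = NULL,
                               scaler = NULL, dropped = NULL) {
  structure(tbl, categories = categories, excluded = excluded,
            scaler = scaler, dropped = dropped,
            class = unique(c("feature_matrix", class(tbl))))
}

#' Feature columns of a feature matrix
#'
#' @param M A `feature_matrix`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(M) setdiff(names(M), "variant_id")

#' Feature-to-category map
#'
#' @param M A `feature_matrix`.
#' @return Named character vector mapping feature name to category.
#' @export
feature_categories <- function(M) attr(M, "categories")[feature_names(M)]

as_matrix <- function(M) {
  m <- as.matrix(as.data.frame(M)[feature_names(M)])
  rownames(m) <- M$variant_id
  m
}

#' Remove constant feature columns
#'
#' Features with zero variance on the given (sub)set carry no information
#' for classification and are removed; the removal list is retained so the
#' same columns can be dropped from prediction-time inputs.
#'
#' @param M A `feature_matrix` built for one training subset.
#' @return The matrix without constant columns; dropped names in attribute
#'   `"dropped"`.
#' @export
drop_constant_columns <- function(M) {
  feats <- feature_names(M)
  constant <- vapply(feats, function(f) {
    x <- M[[f]]
    all(x == x[1])
  }, logical(1))
  if (all(constant)) stop("all feature columns are constant", call. = FALSE)
  out <- M[c("variant_id", feats[!constant])]
  new_feature_matrix(out, categories = attr(M, "categories"),
                     excluded = attr(M, "excluded"),
                     scaler = attr(M, "scaler"),
                     dropped = feats[constant])
}

#' Standardize features to zero mean and unit variance
#'
#' Fits per-column mean and (population) standard deviation on the given
#' rows and rescales. The fitted scaler is stored in attribute `"scaler"`
#' and can be re-applied verbatim to new rows with [apply_scaler()].
#'
#' @param M A `feature_matrix` without constant columns.
#' @return The standardized matrix with attribute `"scaler"` (tibble of
#'   `feature`, `mean`, `sd`).
#' @export
standardize_features <- function(M) {
  feats <- feature_names(M)
  mu <- vapply(feats, function(f) mean(M[[f]]), numeric(1))
  sd_pop <- vapply(feats, function(f) {
    x <- M[[f]]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  if (any(sd_pop == 0)) {
    stop("constant column(s) present; call drop_constant_columns() first: ",
         paste(feats[sd_pop == 0], collapse = ", "), call. = FALSE)
  }
  scaler <- tibble::tibble(feature = feats, mean = unname(mu),
                           sd = unname(sd_pop))
  apply_scaler(M, scaler)
}

#' Apply a fitted scaler
#'
#' @param M A `feature_matrix` whose feature columns match the scaler.
#' @param scaler Tibble of `feature`, `mean`, `sd` from
#'   [standardize_features()].
#' @return The rescaled matrix, scaler attached as attribute `"scaler"`.
#' @export
apply_scaler <- function(M, scaler) {
  feats <- feature_names(M)
  if (!identical(sort(feats), sort(scaler$feature))) {
    stop("scaler columns do not match feature matrix columns", call. = FALSE)
  }
  out <- M
  for (k in seq_len(nrow(scaler))) {
    f <- scaler$feature[k]
    out[[f]] <- (out[[f]] - scaler$mean[k]) / scaler$sd[k]
  }
  new_feature_matrix(out, categories = attr(M, "categories"),
                     excluded = attr(M, "excluded"), scaler = scaler,
                     dropped = attr(M, "dropped"))
}

#' Write a feature matrix with a two-row header
#'
#' Emits a tab-separated file whose first header row gives the feature
#' category and second row the feature name; the first column is the
#' variant id.
#'
#' @param M A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(M, path) {
  feats <- feature_names(M)
  cats <- feature_categories(M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("category", unname(cats)), collapse = "\t"), con)
  writeLines(paste(c("variant_id", feats), collapse = "\t"), con)
  utils::write.table(as.data.frame(M), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
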