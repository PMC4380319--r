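# Synthetic fixture generator: random proteins, alignments with
# controllable per-column conservation, Pfam-like interval annotations, and
# labeled variants whose disease labels follow a logistic model over
# planted feature effects. Everything downstream of real data acquisition
# can be exercised and parameter recovery measured without downloads.

#' Synthetic-data generator configuration
#'
#' The label of each generated variant is drawn from a logistic model over
#' the z-scored true feature values:
#' `P(disease) = plogis(b0 + sum_f beta_f z_f)`, with the intercept `b0`
#' solved so the expected class balance matches `class_balance`. Effect
#' sizes are therefore on the log-odds scale per standard deviation of the
#' feature.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Length range (uniform).
#' @param n_variants Number of distinct variants.
#' @param class_balance Expected disease fraction.
#' @param planted_effects Named vector of log-odds effect sizes, names are
#'   feature names of [assemble_features()] (one per category by default).
#' @param msa_depth Alignment depth range (uniform, query included).
#' @param conservation Range of the per-column probability that a homolog
#'   residue copies the query; drawn per column.
#' @param gap_prob Probability of a gap at a homolog position.
#' @param pfam_coverage Fraction of proteins given a Pfam-like annotation.
#' @param subset_heterogeneity If `TRUE`, every planted effect's sign is
#'   flipped for variants whose reference amino acid falls in the first
#'   half of the alphabet, planting subset-specific rules that a single
#'   entire-set linear classifier cannot represent.
#' @param composition Optional named amino-acid sampling weights
#'   (default uniform).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 60L,
                             protein_length = c(120L, 400L),
                             n_variants = 20000L,
                             class_balance = 0.125,
                             planted_effects = c(sub_G = 1.5,
                                                 count_S = -1.5,
                                                 f_ref = 2.0,
                                                 pc_V1 = 1.5,
                                                 in_domain = 1.5),
                             msa_depth = c(20L, 80L),
                             conservation = c(0.2, 0.95),
                             gap_prob = 0.1,
                             pfam_coverage = 0.5,
                             subset_heterogeneity = FALSE,
                             composition = NULL,
                             seed = 1L) {
  stopifnot(all(is.finite(planted_effects)),
            class_balance > 0, class_balance < 1,
            all(conservation >= 0), all(conservation <= 1),
            gap_prob >= 0, gap_prob < 1,
            pfam_coverage >= 0, pfam_coverage <= 1)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 n_variants = as.integer(n_variants),
                 class_balance = class_balance,
                 planted_effects = planted_effects,
                 msa_depth = as.integer(msa_depth),
                 conservation = conservation,
                 gap_prob = gap_prob,
                 pfam_coverage = pfam_coverage,
                 subset_heterogeneity = isTRUE(subset_heterogeneity),
                 composition = composition,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic variant dataset
#'
#' @param cfg A [generator_config()].
#' @param scales Scale set used for the true physicochemical features.
#' @return A list of class `simulated_data`: `proteins` (named sequences),
#'   `msas` (named list of `msa_columns`), `alignments` (named list of
#'   aligned character matrices, for file emission), `pfam`, `variants`
#'   (labeled tibble), and `truth` (features used by the label model, the
#'   linear predictor `eta`, effect sizes and intercept).
#' @export
simulate_variant_data <- function(cfg = generator_config(),
                                  scales = read_scales()) {
  set.seed(cfg$seed)
  aas <- names(cfg$composition)
  probs <- cfg$composition / sum(cfg$composition)
  ids <- sprintf("SYN%04d", seq_len(cfg$n_proteins))
  lens <- sample(cfg$protein_length[1]:cfg$protein_length[2],
                 cfg$n_proteins, replace = TRUE)
  proteins <- stats::setNames(vapply(lens, function(L) {
    paste(sample(aas, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1)), ids)

  alignments <- purrr::map(proteins, function(seq) {
    q <- strsplit(seq, "")[[1]]
    L <- length(q)
    depth <- sample(cfg$msa_depth[1]:cfg$msa_depth[2], 1)
    alpha <- stats::runif(L, cfg$conservation[1], cfg$conservation[2])
    mat <- matrix("", nrow = depth, ncol = L)
    mat[1, ] <- q
    for (r in seq_len(depth - 1L) + 1L) {
      u <- stats::runif(L)
      row <- ifelse(u < alpha, q, sample(aas, L, replace = TRUE, prob = probs))
      row[stats::runif(L) < cfg$gap_prob] <- "-"
      mat[r, ] <- row
    }
    mat
  })
  msas <- purrr::map(alignments, msa_from_matrix)

  pfam <- purrr::map_dfr(ids, function(id) {
    if (stats::runif(1) >= cfg$pfam_coverage) return(NULL)
    L <- nchar(proteins[[id]])
    span <- sort(sample(seq_len(L), 2))
    out <- tibble::tibble(protein_id = id, start = span[1], end = span[2],
                          match_type = "domain",
                          clan_id = if (stats::runif(1) < 0.5)
                            "CL0001" else NA_character_)
    if (stats::runif(1) < 0.5) {
      span2 <- sort(sample(seq_len(L), 2))
      out <- dplyr::bind_rows(out, tibble::tibble(
        protein_id = id, start = span2[1], end = span2[2],
        match_type = "family", clan_id = NA_character_))
    }
    out
  })
  if (nrow(pfam) == 0) {
    pfam <- tibble::tibble(protein_id = character(), start = integer(),
                           end = integer(), match_type = character(),
                           clan_id = character())
  }

  reach <- reachability_matrix()
  n_target <- cfg$n_variants
  seen <- character(0)
  parts <- list()
  while (length(seen) < n_target) {
    n_draw <- ceiling((n_target - length(seen)) * 1.3)
    pid <- sample(ids, n_draw, replace = TRUE)
    pos <- 2L + floor(stats::runif(n_draw) * (nchar(proteins[pid]) - 1L))
    ref <- substr_at(proteins[pid], pos)
    mut <- vapply(ref, function(r) {
      sample(AA_ALPHABET[reach[r, ]], 1)
    }, character(1), USE.NAMES = FALSE)
    cand <- tibble::tibble(protein_id = pid, position = as.integer(pos),
                           ref_aa = ref, mut_aa = mut)
    key <- variant_id(cand)
    new <- !duplicated(key) & !key %in% seen
    parts[[length(parts) + 1L]] <- cand[new, ]
    seen <- c(seen, key[new])
  }
  variants <- dplyr::slice_head(dplyr::bind_rows(parts), n = n_target)

  M <- assemble_features(variants, proteins, msas, pfam, scales)
  beta <- cfg$planted_effects
  missing_f <- setdiff(names(beta), feature_names(M))
  if (length(missing_f) > 0) {
    stop("planted effect on unknown feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  Z <- vapply(names(beta), function(f) {
    x <- M[[f]]
    s <- stats::sd(x)
    if (s == 0) stop("planted feature '", f, "' is constant in the ",
                     "generated data; infeasible config", call. = FALSE)
    (x - mean(x)) / s
  }, numeric(nrow(M)))
  sign_mod <- if (cfg$subset_heterogeneity) {
    ifelse(variants$ref_aa %in% AA_ALPHABET[1:10], -1, 1)
  } else {
    rep(1, nrow(variants))
  }
  eta0 <- drop(Z %*% beta) * sign_mod
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) -
                         cfg$class_balance,
                       interval = c(-30, 30))$root
  eta <- b0 + eta0
  variants$label <- stats::rbinom(nrow(variants), 1L, stats::plogis(eta))

  structure(list(proteins = proteins, msas = msas, alignments = alignments,
                 pfam = pfam, variants = variants,
                 truth = list(features = M, eta = eta, beta = beta, b0 = b0,
                              sign_mod = sign_mod),
                 config = cfg),
            class = "simulated_data")
}

msa_from_matrix <- function(mat) {
  is_gap <- mat %in% c("-", ".") | mat != toupper(mat)
  dim(is_gap) <- dim(mat)
  cols <- purrr::map(seq_len(ncol(mat)), function(j) {
    toupper(mat[!is_gap[, j], j])
  })
  out <- tibble::tibble(position = seq_len(ncol(mat)), residues = cols,
                        n_proteins = nrow(mat), n_residues = lengths(cols))
  class(out) <- c("msa_columns", class(out))
  out
}

#' Monte-Carlo estimate of the Bayes-optimal AUC of a generator config
#'
#' Generates a dataset under `cfg` (with `n_mc` variants and a shifted
#' seed) and computes the AUC of the true linear predictor against the
#' sampled labels — the performance ceiling any classifier can reach on
#' data from this config. Used to calibrate recovery thresholds.
#'
#' @param cfg A [generator_config()].
#' @param n_mc Monte-Carlo sample size.
#' @return AUC in `[0, 1]`.
#' @export
oracle_auc <- function(cfg = generator_config(), n_mc = 20000L) {
  cfg$n_variants <- as.integer(n_mc)
  cfg$seed <- seed_for(cfg$seed, "oracle")
  sim <- simulate_variant_data(cfg)
  safe_auc(sim$variants$label, sim$truth$eta)
}

#' Write a simulated dataset to a directory
#'
#' Emits `proteins.fasta`, one aligned FASTA per protein under `msa/`,
#' `pfam.tsv`, and `variants.tsv` (two-column id/label dialect) — all valid
#' inputs for the package's readers.
#'
#' @param sim A `simulated_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(file.path(dir, "msa"), recursive = TRUE, showWarnings = FALSE)
  write_protein_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  for (id in names(sim$alignments)) {
    mat <- sim$alignments[[id]]
    rows <- apply(mat, 1, paste0, collapse = "")
    hdr <- c(id, sprintf("%s_hom%03d", id, seq_len(nrow(mat) - 1L)))
    writeLines(paste0(">", hdr, "\n", rows),
               file.path(dir, "msa", paste0(id, ".afa")))
  }
  write_pfam_table(sim$pfam, file.path(dir, "pfam.tsv"))
  write_variants(sim$variants, file.path(dir, "variants.tsv"))
  invisible(dir)
}
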