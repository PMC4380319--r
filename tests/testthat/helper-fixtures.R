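# Small in-code fixtures shared across test files.

# a tiny protein set with known content
tiny_proteins <- function() {
  c(P1 = "MKVLASTGRW", P2 = "MAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
}

# an msa_columns object built from explicit alignment rows (first = query)
msa_fixture <- function(rows) {
  tf <- withr::local_tempfile(fileext = ".afa",
                              .local_envir = parent.frame())
  writeLines(paste0(">s", seq_along(rows), "\n", rows), tf)
  read_msa(tf)
}

# variants tibble shorthand
vt <- function(protein_id, position, ref_aa, mut_aa, label = NA_integer_) {
  tibble::tibble(protein_id = protein_id, position = as.integer(position),
                 ref_aa = ref_aa, mut_aa = mut_aa, label = as.integer(label))
}

# a linearly separable 2-feature toy set, as a feature_matrix + labels
toy_separable <- function(n = 20, gap = 2, seed = 42) {
  set.seed(seed)
  x1 <- c(stats::rnorm(n, -gap, 0.3), stats::rnorm(n, gap, 0.3))
  x2 <- stats::rnorm(2 * n, 0, 0.3)
  tbl <- tibble::tibble(variant_id = paste0("v", seq_len(2 * n)),
                        fA = x1, fB = x2)
  M <- misvep:::new_feature_matrix(tbl, categories = c(fA = "conservation",
                                                       fB = "conservation"))
  list(M = M, labels = rep(c(0L, 1L), each = n))
}

# brute-force amino-acid reachability from enumerating all sense codon pairs
brute_force_reachability <- function() {
  tbl <- codon_table()
  sense <- tbl[tbl$aa != "*", ]
  reach <- matrix(FALSE, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_len(nrow(sense))) {
    ci <- strsplit(sense$codon[i], "")[[1]]
    for (j in seq_len(nrow(sense))) {
      cj <- strsplit(sense$codon[j], "")[[1]]
      if (sum(ci != cj) == 1 && sense$aa[i] != sense$aa[j]) {
        reach[sense$aa[i], sense$aa[j]] <- TRUE
      }
    }
  }
  reach
}

# Mann-Whitney AUC by brute-force pair counting
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# small simulated dataset reused by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_variant_data(
        generator_config(n_proteins = 20L, n_variants = 2000L, seed = 7L))
    }
    cache
  }
})
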