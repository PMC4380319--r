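test_that("substitution encoding sets -1/+1 and sums to zero", {
  m <- substitution_features(vt("P", 5, "D", "G"))
  expect_equal(unname(m[1, "sub_D"]), -1)
  expect_equal(unname(m[1, "sub_G"]), 1)
  expect_equal(sum(m[1, ] == 0), 18)
  expect_equal(sum(m), 0)

  # property: any reachable substitution sums to zero
  reach <- reachability_matrix()
  pairs <- which(reach, arr.ind = TRUE)
  v <- vt("P", 1, AA_ALPHABET[pairs[, 1]], AA_ALPHABET[pairs[, 2]])
  expect_true(all(rowSums(substitution_features(v)) == 0))

  expect_error(substitution_features(vt("P", 5, "A", "A")), "synonymous")
  expect_error(substitution_features(vt("P", 5, "A", "X")), "non-standard")
})

test_that("surrounding counts match a direct window count", {
  polyA <- c(P = strrep("A", 30))
  v <- vt("P", 10, "A", "V")
  m <- surrounding_features(v, polyA, window_spec(19, include_center = FALSE))
  expect_equal(unname(m[1, "count_A"]), 18)
  expect_equal(sum(m), 18)
  m_c <- surrounding_features(v, polyA, window_spec(19, include_center = TRUE))
  expect_equal(sum(m_c), 19)

  # boundary truncation at position 1
  v1 <- vt("P", 1, "A", "V")
  m1 <- surrounding_features(v1, polyA, window_spec(19, include_center = TRUE))
  expect_equal(sum(m1), 10)
  m1x <- surrounding_features(v1, polyA, window_spec(19, include_center = FALSE))
  expect_equal(sum(m1x), 9)

  # mixed-content oracle: counts equal table() of the window letters
  proteins <- c(Q = "ACDEFGHIKLMNPQRSTVWY")
  vq <- vt("Q", 10, "L", "V")
  mq <- surrounding_features(vq, proteins, window_spec(19, TRUE))
  win <- substr(proteins[["Q"]], 1, 19)
  for (aa in AA_ALPHABET) {
    expect_equal(unname(mq[1, paste0("count_", aa)]),
                 lengths(regmatches(win, gregexpr(aa, win, fixed = TRUE))))
  }
})

test_that("conservation features are column frequencies plus counts", {
  msa <- msa_fixture(c("A", "A", "A", "V"))
  v <- vt("q", 1, "A", "V")
  m <- conservation_features(v, list(q = msa))
  expect_equal(unname(m[1, c("f_ref", "f_mut", "n_proteins", "n_residues")]),
               c(0.75, 0.25, 4, 4))

  # query-only column
  m1 <- conservation_features(v, list(q = msa_fixture("A")))
  expect_equal(unname(m1[1, "f_ref"]), 1)
  expect_equal(unname(m1[1, "f_mut"]), 0)

  # frequencies in [0,1] and f_ref + f_mut <= 1 on simulated data
  sim <- small_sim()
  mm <- conservation_features(sim$variants[1:200, ], sim$msas)
  expect_true(all(mm[, "f_ref"] >= 0 & mm[, "f_ref"] <= 1))
  expect_true(all(mm[, "f_mut"] >= 0 & mm[, "f_mut"] <= 1))
  expect_true(all(mm[, "f_ref"] + mm[, "f_mut"] <= 1 + 1e-12))
})

test_that("physicochemical distances are minimal scale differences", {
  scales <- structure(
    tibble::tibble(aa = AA_ALPHABET,
                   s1 = seq(0, 1.9, by = 0.1),
                   s2 = rep(c(0, 2), 10)),
    class = c("scale_set", "tbl_df", "tbl", "data.frame"))
  # column {G}, mutant W: distance = |s(W) - s(G)| on each scale
  msa <- msa_fixture("G")
  v <- vt("q", 1, "G", "W")
  m <- physchem_features(v, list(q = msa), scales)
  sG <- as.numeric(scales[scales$aa == "G", -1])
  sW <- as.numeric(scales[scales$aa == "W", -1])
  expect_equal(unname(m[1, ]), abs(sW - sG))

  # min over several residues
  msa2 <- msa_fixture(c("A", "V"))
  vL <- vt("q", 1, "A", "L")
  m2 <- physchem_features(vL, list(q = msa2), scales)
  sA <- as.numeric(scales[scales$aa == "A", -1])
  sV <- as.numeric(scales[scales$aa == "V", -1])
  sL <- as.numeric(scales[scales$aa == "L", -1])
  expect_equal(unname(m2[1, ]), pmin(abs(sL - sA), abs(sL - sV)))

  # mutant observed in column -> all distances zero
  msa3 <- msa_fixture(c("A", "L"))
  m3 <- physchem_features(vL, list(q = msa3), scales)
  expect_true(all(m3 == 0))
})

test_that("physchem distance is zero whenever the mutant frequency is positive", {
  sim <- small_sim()
  v <- sim$variants[1:300, ]
  cons <- conservation_features(v, sim$msas)
  phys <- physchem_features(v, sim$msas, read_scales())
  seen <- cons[, "f_mut"] > 0
  expect_true(all(phys[seen, ] == 0))
})

test_that("domain features encode family/domain/clan membership bits", {
  pfam <- tibble::tibble(protein_id = "P", start = 10L, end = 80L,
                         match_type = "domain", clan_id = NA_character_)
  m <- domain_features(vt("P", 50, "A", "T"), pfam)
  expect_equal(unname(m[1, c("in_family", "in_domain", "in_clan")]), c(0, 1, 0))

  m0 <- domain_features(vt("Q", 50, "A", "T"), pfam)
  expect_true(all(m0 == 0))

  pfam2 <- tibble::tibble(protein_id = "P", start = c(10L, 40L), end = c(80L, 60L),
                          match_type = c("family", "clan-member"),
                          clan_id = c(NA, "CL1"))
  m2 <- domain_features(vt("P", 50, "A", "T"), pfam2)
  expect_equal(unname(m2[1, c("in_family", "in_domain", "in_clan")]), c(1, 0, 1))
})

test_that("assembled matrices have deterministic order and row equivariance", {
  sim <- small_sim()
  v <- sim$variants[1:50, ]
  M <- assemble_features(v, sim$proteins, sim$msas, sim$pfam)
  cats <- feature_categories(M)
  expect_equal(unique(unname(cats)),
               c("substitution", "surrounding", "conservation", "physchem",
                 "domain"))
  # alphabetical within category
  for (cat in unique(cats)) {
    f <- names(cats)[cats == cat]
    expect_equal(f, sort(f))
  }
  expect_equal(length(feature_names(M)), 20 + 20 + 4 + 19 + 3)

  # permutation equivariance
  perm <- sample(nrow(v))
  Mp <- assemble_features(v[perm, ], sim$proteins, sim$msas, sim$pfam)
  expect_equal(as.data.frame(Mp), as.data.frame(M[perm, ]),
               ignore_attr = TRUE)

  # missing resources are reported, not silently dropped
  v_bad <- dplyr::bind_rows(v, vt("UNKNOWN", 5, "A", "T", 0))
  Mx <- assemble_features(v_bad, sim$proteins, sim$msas, sim$pfam)
  excl <- attr(Mx, "excluded")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "missing")
})

test_that("constant columns are removed; the serine subset loses its exact list", {
  # serine-reference variants over every reachable mutant
  muts <- setdiff(AA_ALPHABET, c("S", unreachable_mutants("S")))
  v <- vt("P", 1, "S", muts)
  M <- misvep:::new_feature_matrix(
    dplyr::bind_cols(tibble::tibble(variant_id = variant_id(v)),
                     tibble::as_tibble(as.data.frame(substitution_features(v)))),
    categories = stats::setNames(rep("substitution", 20),
                                 paste0("sub_", AA_ALPHABET)))
  out <- drop_constant_columns(M)
  dropped <- attr(out, "dropped")
  expect_setequal(dropped, paste0("sub_", c("S", "D", "E", "H", "K", "M", "Q", "V")))
  expect_equal(length(feature_names(out)), 12)

  expect_equal(feature_names(drop_constant_columns(out)), feature_names(out))
  Mconst <- misvep:::new_feature_matrix(
    tibble::tibble(variant_id = c("a", "b"), f = c(1, 1)),
    categories = c(f = "domain"))
  expect_error(drop_constant_columns(Mconst), "all feature columns")
})

test_that("standardization uses population sd and re-applies verbatim", {
  M <- misvep:::new_feature_matrix(
    tibble::tibble(variant_id = c("a", "b"), f = c(0, 2)),
    categories = c(f = "conservation"))
  S <- standardize_features(M)
  expect_equal(S$f, c(-1, 1))    # population sd of (0,2) is 1
  sc <- attr(S, "scaler")
  expect_equal(sc$mean, 1)
  expect_equal(sc$sd, 1)

  S2 <- standardize_features(S)
  expect_equal(S2$f, S$f, tolerance = 1e-12)

  # verbatim reapplication to new rows
  Mnew <- misvep:::new_feature_matrix(
    tibble::tibble(variant_id = "c", f = 5),
    categories = c(f = "conservation"))
  expect_equal(apply_scaler(Mnew, sc)$f, 4)

  sc_bad <- dplyr::mutate(sc, feature = "g")
  expect_error(apply_scaler(Mnew, sc_bad), "do not match")

  # standardized columns have mean 0 and sd 1 on the fitted set
  sim <- small_sim()
  Mbig <- assemble_features(sim$variants[1:200, ], sim$proteins, sim$msas,
                            sim$pfam)
  Sb <- standardize_features(drop_constant_columns(Mbig))
  for (f in feature_names(Sb)[1:10]) {
    expect_lt(abs(mean(Sb[[f]])), 1e-9)
    expect_lt(abs(sqrt(mean((Sb[[f]] - mean(Sb[[f]]))^2)) - 1), 1e-9)
  }
})

test_that("feature matrices write with a two-row category header", {
  sim <- small_sim()
  M <- assemble_features(sim$variants[1:5, ], sim$proteins, sim$msas, sim$pfam)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(M, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "^category\tsubstitution")
  expect_match(lines[2], "^variant_id\tsub_A")
  expect_equal(length(lines), 2 + 5)
})
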