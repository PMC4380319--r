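trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      v <- suppressWarnings(split_subsets(sim$variants, min_size = 10))
      M <- assemble_features(v, sim$proteins, sim$msas, sim$pfam)
      ens <- suppressWarnings(train_ensemble(v, M, svm_config(seed = 5)))
      cache <<- list(sim = sim, v = v, M = M, ens = ens)
    }
    cache
  }
})

test_that("dual-sum weights reproduce the decision function on every model", {
  fx <- trained_fixture()
  for (m in fx$ens) {
    w <- extract_weights(m)
    rows <- fx$v$subset == m$key
    Msub <- misvep:::new_feature_matrix(fx$M[rows, ][1:5, ],
                                        categories = attr(fx$M, "categories"))
    p <- predict(m, Msub)
    Ms <- apply_scaler(misvep:::new_feature_matrix(
      Msub[c("variant_id", m$retained_features)],
      categories = attr(fx$M, "categories")), m$scaler)
    x <- as.matrix(as.data.frame(Ms)[m$retained_features])
    rebuilt <- drop(x %*% w) + m$b
    expect_equal(max(abs(rebuilt - p$decision)) / max(abs(p$decision), 1e-9),
                 0, tolerance = 1e-6)
    expect_equal(w, m$w, tolerance = 1e-12)
  }
})

test_that("a two-point symmetric toy problem gives the expected direction", {
  M <- misvep:::new_feature_matrix(
    tibble::tibble(variant_id = c(paste0("a", 1:2), paste0("b", 1:2)),
                   f1 = c(0.01, -0.01, 0.01, -0.01),
                   f2 = c(1, 1, -1, -1)),
    categories = c(f1 = "domain", f2 = "domain"))
  m <- train_subset(M, c(1L, 1L, 0L, 0L), svm_config(probability = FALSE),
                    key = "T")
  w <- extract_weights(m)
  expect_gt(w[["f2"]], 0)
  expect_gt(abs(w[["f2"]]), 10 * abs(w[["f1"]]))
})

test_that("weight extraction refuses RBF models", {
  toy <- toy_separable()
  m <- train_subset(toy$M, toy$labels,
                    svm_config(kernel = "rbf", probability = FALSE), key = "T")
  expect_error(extract_weights(m), "does not allow for interpretation")
})

test_that("weight standardization matches hand computation", {
  expect_equal(standardize_weights(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- standardize_weights(c(0.3, -2, 5, 1))
  expect_equal(standardize_weights(z), z, tolerance = 1e-12)
  expect_error(standardize_weights(c(2, 2, 2)), "constant")
  expect_error(standardize_weights(2), "at least two")
})

test_that("weight tables align subsets, mask removed features, standardize rows", {
  fx <- trained_fixture()
  whole <- train_subset(fx$M, fx$v$label, svm_config(seed = 5), key = "ALL")
  wt <- weight_table(fx$ens, whole_model = whole)
  expect_s3_class(wt, "weight_table")
  expect_equal(wt$subset[nrow(wt)], "ALL")
  expect_equal(nrow(wt), length(fx$ens) + 1)

  # masked cells are exactly the features dropped as constant per subset
  for (m in fx$ens) {
    row <- wt[wt$subset == m$key, ]
    masked <- names(row)[-1][is.na(as.numeric(row[-1]))]
    expect_setequal(masked, m$dropped_features)
    vals <- as.numeric(row[-1])
    vals <- vals[!is.na(vals)]
    expect_lt(abs(mean(vals)), 1e-9)
    expect_lt(abs(sqrt(mean((vals - mean(vals))^2)) - 1), 1e-9)
  }

  # serine row: the unreachable substitution features are masked
  srow <- wt[wt$subset == "S", ]
  expect_true(all(is.na(srow[paste0("sub_", c("D", "E", "H", "K", "M", "Q", "V"))])))

  t1 <- tidy(fx$ens[[1]])
  expect_named(t1, c("subset", "feature", "category", "weight"))
  expect_equal(nrow(glance(fx$ens[[1]])), 1)
})

test_that("row/column ordering modes permute without changing values", {
  fx <- trained_fixture()
  wt <- weight_table(fx$ens)
  byprop <- order_weight_table(wt, "aa_property")
  expect_setequal(byprop$subset, wt$subset)
  expect_setequal(names(byprop), names(wt))
  for (s in wt$subset) {
    expect_equal(sort(as.numeric(byprop[byprop$subset == s, -1])),
                 sort(as.numeric(wt[wt$subset == s, -1])))
  }

  clustered <- order_weight_table(wt, "cluster")
  expect_setequal(clustered$subset, wt$subset)

  # identical columns end up adjacent under complete linkage
  dup <- wt
  dup$dupcol <- dup[[2]]
  attr(dup, "categories") <- c(attr(wt, "categories"),
                               stats::setNames(attr(wt, "categories")[[names(wt)[2]]],
                                               "dupcol"))
  cl <- order_weight_table(dup, "cluster")
  i <- match(names(wt)[2], names(cl))
  j <- match("dupcol", names(cl))
  expect_equal(abs(i - j), 1)

  one_row <- weight_table(fx$ens[1])
  expect_equal(order_weight_table(one_row, "cluster")$subset, one_row$subset)
})

test_that("log-odds matrix matches hand counts and is label-antisymmetric", {
  # counts d=2, n=1 for A->V with totals D=4, N=4 and c=0 -> log 2
  v <- dplyr::bind_rows(
    vt("P", 2, "A", "V", 1), vt("P", 3, "A", "V", 1),
    vt("P", 4, "A", "T", 1), vt("P", 5, "A", "S", 1),
    vt("P", 6, "A", "V", 0), vt("P", 7, "A", "T", 0),
    vt("P", 8, "A", "S", 0), vt("P", 9, "A", "P", 0))
  lo <- log_odds_matrix(v, pseudocount = 0)
  expect_equal(lo["A", "V"], log(2), tolerance = 1e-12)
  expect_equal(lo["A", "T"], 0, tolerance = 1e-12)   # equal relative frequency

  flipped <- dplyr::mutate(v, label = 1L - label)
  lo_f <- log_odds_matrix(flipped, pseudocount = 0)
  expect_equal(lo_f["A", "V"], -lo["A", "V"], tolerance = 1e-12)

  sim <- small_sim()
  lo1 <- log_odds_matrix(sim$variants)
  lo2 <- log_odds_matrix(dplyr::mutate(sim$variants, label = 1L - label))
  reach <- reachability_matrix()
  expect_equal(lo1[reach], -lo2[reach], tolerance = 1e-12)

  # mask: exactly the 230 unreachable off-diagonal cells (plus the diagonal)
  off_diag_na <- is.na(lo1) & !diag(20)
  expect_equal(sum(off_diag_na), 230)
  expect_true(all(is.na(diag(lo1))))

  expect_error(log_odds_matrix(dplyr::mutate(v, label = 1L), pseudocount = 0),
               "both classes")
})

test_that("heat maps and TSVs are emitted and plots build", {
  fx <- trained_fixture()
  wt <- order_weight_table(weight_table(fx$ens), "aa_property")
  td <- withr::local_tempdir()
  paths <- heatmap_emit(wt, file.path(td, "weights.tsv"))
  expect_true(all(file.exists(paths)))
  back <- read.delim(file.path(td, "weights.tsv"), check.names = FALSE)
  expect_equal(back$subset, wt$subset)

  p1 <- ggplot2::autoplot(wt)
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(log_odds_matrix(fx$sim$variants))
  expect_s3_class(p2, "ggplot")
})
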