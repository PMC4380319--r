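# Per-reference-amino-acid subset classifiers: maximum-margin training with
# probability (Platt) outputs, stratified cross-validation, and pooled ROC
# evaluation.

#' Training configuration
#'
#' @param kernel `"linear"` (default) or `"rbf"`. The radial-basis kernel
#'   gives a non-linear classifier whose weights cannot be interpreted.
#' @param C Soft-margin cost; defaults to 0.1 for the linear kernel and 1.0
#'   for the RBF kernel.
#' @param gamma RBF kernel width (ignored for the linear kernel).
#' @param n_folds Number of stratified cross-validation folds.
#' @param seed Integer seed controlling fold assignment and probability
#'   calibration.
#' @param probability Fit Platt-style sigmoid calibration so that subset
#'   outputs are comparable probabilities.
#' @param class_weights Use inverse-class-frequency weights (off by
#'   default; the class imbalance of the data is represented faithfully).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), C = NULL, gamma = 0.01,
                       n_folds = 10L, seed = 1L, probability = TRUE,
                       class_weights = FALSE) {
  kernel <- match.arg(kernel)
  if (is.null(C)) C <- if (kernel == "linear") 0.1 else 1.0
  stopifnot(C > 0, gamma > 0, n_folds >= 2)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 probability = isTRUE(probability),
                 class_weights = isTRUE(class_weights)),
            class = "svm_config")
}

#' Assign variants to reference-amino-acid subsets
#'
#' Groups variants by their reference amino acid. Tryptophan, tyrosine and
#' phenylalanine yield too few substitutions for separate classifiers and
#' are always merged into one `"WYF"` subset, giving 18 subsets for 20
#' reference amino acids. Any other subset smaller than `min_size` triggers
#' a warning (it is kept, not merged).
#'
#' @param variants A labeled variant tibble.
#' @param min_size Warning threshold for small subsets.
#' @param merge_all Put every variant into a single `"ALL"` subset (the
#'   entire-set protocol).
#' @return The tibble with a `subset` column added.
#' @export
split_subsets <- function(variants, min_size = 500L, merge_all = FALSE) {
  subset <- if (merge_all) {
    rep("ALL", nrow(variants))
  } else {
    ifelse(variants$ref_aa %in% c("W", "Y", "F"), "WYF", variants$ref_aa)
  }
  out <- dplyr::mutate(variants, subset = subset)
  sizes <- table(out$subset)
  small <- names(sizes)[sizes < min_size]
  if (length(small) > 0) {
    warning("subset(s) below min_size (", min_size, "): ",
            paste0(small, " (n=", sizes[small], ")", collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Train one subset classifier
#'
#' Removes constant columns, standardizes the remaining features (zero
#' mean, unit population variance), and fits a support vector machine on
#' them (libsvm via e1071; linear kernel with C = 0.1 by default). The
#' model is oriented so that a positive decision value / weight means
#' disease-predictive.
#'
#' @param M A `feature_matrix` for the subset (raw, unstandardized).
#' @param labels Integer 0/1 labels, 1 = disease.
#' @param cfg An [svm_config()].
#' @param key Subset identifier stored with the model.
#' @return An object of class `subset_model`.
#' @export
train_subset <- function(M, labels, cfg = svm_config(), key = "ALL") {
  if (length(labels) != nrow(M)) stop("labels do not match rows", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("subset '", key, "' has a single class; untrainable", call. = FALSE)
  }
  if (min(table(labels)) < 2) {
    stop("subset '", key, "' needs at least 2 variants per class", call. = FALSE)
  }
  M <- drop_constant_columns(M)
  M <- standardize_features(M)
  x <- as_matrix(M)
  y <- factor(ifelse(labels == 1L, "disease", "neutral"),
              levels = c("neutral", "disease"))
  cw <- if (cfg$class_weights) {
    n <- table(y)
    stats::setNames(as.numeric(sum(n) / (2 * n)), names(n))
  } else NULL
  seed_i <- seed_for(cfg$seed, key)
  set.seed(seed_i)
  fit <- e1071::svm(x, y, scale = FALSE,
                    kernel = if (cfg$kernel == "linear") "linear" else "radial",
                    cost = cfg$C, gamma = cfg$gamma,
                    probability = cfg$probability, class.weights = cw)
  # libsvm's decision value is positive for the class listed first in the
  # decision-value column name; orient so positive = disease.
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sign_flip <- if (startsWith(colnames(dv), "disease")) 1 else -1
  w <- b <- NULL
  if (cfg$kernel == "linear") {
    w <- drop(t(fit$coefs) %*% fit$SV) * sign_flip
    names(w) <- colnames(x)
    b <- -fit$rho * sign_flip
  }
  structure(list(
    key = key, fit = fit, sign = sign_flip, w = w, b = b,
    scaler = attr(M, "scaler"), retained_features = feature_names(M),
    dropped_features = attr(M, "dropped"),
    categories = attr(M, "categories"), config = cfg,
    n = nrow(M), class_counts = table(labels)
  ), class = "subset_model")
}

seed_for <- function(seed, key, fold = 0L) {
  as.integer((abs(seed) * 10007 + sum(utf8ToInt(key)) * 131 + fold * 17) %%
               2147483647)
}

#' @export
print.subset_model <- function(x, ...) {
  cat("Subset classifier '", x$key, "': ", x$config$kernel, " kernel, n = ",
      x$n, ", ", length(x$retained_features), " features\n", sep = "")
  invisible(x)
}

#' Predict disease probability from a trained subset model
#'
#' @param object A `subset_model`.
#' @param M A `feature_matrix` of new variants (raw); constant columns
#'   dropped at training time are removed and the training scaler is
#'   re-applied verbatim.
#' @param ... Unused.
#' @return A tibble with `variant_id`, `p_disease` and the decision value.
#' @export
predict.subset_model <- function(object, M, ...) {
  feats <- intersect(feature_names(M), object$retained_features)
  if (!setequal(feats, object$retained_features)) {
    stop("feature matrix lacks columns required by the model", call. = FALSE)
  }
  Msub <- M[c("variant_id", object$retained_features)]
  Msub <- new_feature_matrix(Msub, categories = attr(M, "categories"))
  Msub <- apply_scaler(Msub, object$scaler)
  x <- as_matrix(Msub)
  pr <- stats::predict(object$fit, x, probability = object$config$probability,
                       decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values")) * object$sign
  p <- if (object$config$probability) {
    attr(pr, "probabilities")[, "disease"]
  } else {
    stats::plogis(dv)
  }
  tibble::tibble(variant_id = M$variant_id, p_disease = unname(p),
                 decision = unname(dv))
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified cross-validation over subset classifiers
#'
#' Runs seeded stratified k-fold cross-validation independently within each
#' subset, collecting out-of-fold probability predictions. The combined
#' subset-classifier performance (the C_S protocol) is the AUC of the ROC
#' built from the union of all subset test predictions; with
#' `merge_all = TRUE` in [split_subsets()] the same machinery yields the
#' entire-set protocol (C_E), conventionally summarised by the mean of the
#' ten per-fold AUCs.
#'
#' @param variants A labeled variant tibble with a `subset` column (see
#'   [split_subsets()]).
#' @param M The assembled `feature_matrix` for these variants (raw).
#' @param cfg An [svm_config()].
#' @return An object of class `vep_evaluation`: list with `predictions`
#'   (variant_id, subset, fold, label, p_disease), `subset_auc`,
#'   `fold_auc`, `pooled_auc`, `mean_fold_auc`, `untrainable`, `config`.
#' @export
cross_validate <- function(variants, M, cfg = svm_config()) {
  stopifnot("subset" %in% names(variants))
  if (!identical(variant_id(variants), M$variant_id)) {
    stop("feature matrix rows do not match variants", call. = FALSE)
  }
  cats <- attr(M, "categories")
  preds <- list()
  untrainable <- character(0)
  for (key in sort(unique(variants$subset))) {
    rows <- which(variants$subset == key)
    labs <- variants$label[rows]
    # a subset needs both classes, and enough minority examples that every
    # stratified training fold keeps both classes
    if (length(unique(labs)) < 2 || min(table(labs)) < cfg$n_folds) {
      warning("subset '", key, "' lacks enough variants in both classes; ",
              "flagged untrainable", call. = FALSE)
      untrainable <- c(untrainable, key)
      next
    }
    fold <- stratified_folds(labs, cfg$n_folds, seed_for(cfg$seed, key))
    for (f in sort(unique(fold))) {
      tr <- rows[fold != f]
      te <- rows[fold == f]
      if (length(unique(variants$label[tr])) < 2) {
        fold <- stratified_folds(labs, cfg$n_folds,
                                 seed_for(cfg$seed + 1L, key))
        tr <- rows[fold[match(tr, rows)] != f]
        if (length(unique(variants$label[tr])) < 2) {
          stop("subset '", key, "', fold ", f,
               ": training fold has a single class", call. = FALSE)
        }
      }
      Mtr <- new_feature_matrix(M[tr, ], categories = cats)
      Mte <- new_feature_matrix(M[te, ], categories = cats)
      cfg_f <- cfg
      cfg_f$seed <- seed_for(cfg$seed, key, f)
      model <- train_subset(Mtr, variants$label[tr], cfg_f, key = key)
      p <- stats::predict(model, Mte)
      preds[[paste(key, f)]] <- tibble::tibble(
        variant_id = p$variant_id, subset = key, fold = f,
        label = variants$label[te], p_disease = p$p_disease)
    }
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0) stop("no trainable subsets", call. = FALSE)
  subset_auc <- predictions |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(n = dplyr::n(), auc = safe_auc(.data$label, .data$p_disease),
                     .groups = "drop")
  fold_auc <- predictions |>
    dplyr::group_by(.data$subset, .data$fold) |>
    dplyr::summarise(n = dplyr::n(), auc = safe_auc(.data$label, .data$p_disease),
                     .groups = "drop")
  structure(list(
    predictions = predictions,
    subset_auc = subset_auc,
    fold_auc = fold_auc,
    pooled_auc = safe_auc(predictions$label, predictions$p_disease),
    mean_fold_auc = mean(fold_auc$auc, na.rm = TRUE),
    untrainable = untrainable,
    config = cfg
  ), class = "vep_evaluation")
}

safe_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(response = labels, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Pooled ROC curve of an evaluation
#'
#' @param eval A `vep_evaluation`.
#' @return Tibble with `threshold`, `fpr`, `tpr` (decreasing thresholds).
#' @export
roc_points <- function(eval) {
  r <- pROC::roc(response = eval$predictions$label,
                 predictor = eval$predictions$p_disease,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  tibble::tibble(threshold = r$thresholds, fpr = 1 - r$specificities,
                 tpr = r$sensitivities) |>
    dplyr::arrange(dplyr::desc(.data$threshold))
}

#' @export
print.vep_evaluation <- function(x, ...) {
  cat("Cross-validation over", length(unique(x$predictions$subset)),
      "subset(s),", nrow(x$predictions), "predictions\n")
  cat("  pooled AUC:", round(x$pooled_auc, 4),
      " mean per-fold AUC:", round(x$mean_fold_auc, 4), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.vep_evaluation <- function(x, ...) {
  tibble::tibble(n = nrow(x$predictions),
                 n_subsets = length(unique(x$predictions$subset)),
                 pooled_auc = x$pooled_auc,
                 mean_fold_auc = x$mean_fold_auc)
}

#' @export
tidy.vep_evaluation <- function(x, ...) x$subset_auc

#' Train the full subset ensemble
#'
#' Trains one classifier per subset on all of its variants (the models used
#' for weight interpretation, after cross-validation has established that
#' performance is adequate).
#'
#' @param variants A labeled variant tibble with a `subset` column.
#' @param M The assembled `feature_matrix`.
#' @param cfg An [svm_config()].
#' @return A named list of `subset_model`s, class `subset_ensemble`.
#' @export
train_ensemble <- function(variants, M, cfg = svm_config()) {
  stopifnot("subset" %in% names(variants))
  cats <- attr(M, "categories")
  keys <- sort(unique(variants$subset))
  models <- list()
  for (key in keys) {
    rows <- which(variants$subset == key)
    if (length(unique(variants$label[rows])) < 2 ||
        min(table(variants$label[rows])) < 2) {
      warning("subset '", key, "' lacks enough variants in both classes; ",
              "skipped", call. = FALSE)
      next
    }
    Msub <- new_feature_matrix(M[rows, ], categories = cats)
    models[[key]] <- train_subset(Msub, variants$label[rows], cfg, key = key)
  }
  structure(models, class = "subset_ensemble")
}

#' Predict disease probabilities for variants
#'
#' Routes each variant to the classifier of its reference amino acid
#' (W/Y/F to the merged model), builds the model's retained features, and
#' returns calibrated probabilities. Substitutions that cannot arise from a
#' single codon mutation draw a warning but are still scored.
#'
#' @param object A `subset_ensemble` from [train_ensemble()].
#' @param variants A variant tibble (labels not required).
#' @param proteins,msas,pfam,scales Feature resources as in
#'   [assemble_features()].
#' @param spec A [window_spec()].
#' @param reach Reachability matrix used for the warning.
#' @param ... Unused.
#' @return Tibble with `variant_id`, `subset`, `p_disease`, `decision`.
#' @export
predict.subset_ensemble <- function(object, variants, proteins = NULL,
                                    msas = NULL, pfam = NULL,
                                    scales = read_scales(),
                                    spec = window_spec(),
                                    reach = reachability_matrix(), ...) {
  merged <- "ALL" %in% names(object)
  v <- split_subsets(variants, min_size = 0L, merge_all = merged)
  unreachable <- !reach[cbind(v$ref_aa, v$mut_aa)]
  if (any(unreachable)) {
    warning(sum(unreachable), " variant(s) are not single-codon-mutation ",
            "substitutions; predictions may extrapolate", call. = FALSE)
  }
  missing_models <- setdiff(unique(v$subset), names(object))
  if (length(missing_models) > 0) {
    stop("no trained model for subset(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  M <- assemble_features(v, proteins, msas, pfam, scales, spec = spec)
  out <- purrr::map_dfr(unique(v$subset), function(key) {
    rows <- which(v$subset == key & variant_id(v) %in% M$variant_id)
    Msub <- new_feature_matrix(M[match(variant_id(v)[rows], M$variant_id), ],
                               categories = attr(M, "categories"))
    p <- stats::predict(object[[key]], Msub)
    dplyr::mutate(p, subset = key, .after = "variant_id")
  })
  out[match(intersect(variant_id(v), out$variant_id), out$variant_id), ]
}
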