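# Feature-weight extraction from the trained subset classifiers, weight
# standardization and heat-map arrangement, and the validating log-odds
# substitution matrix.

#' Extract the weight vector of a linear subset classifier
#'
#' Reconstructs the weight vector from the support coefficients,
#' `w = sum_i alpha_i y_i Phi(v_i)`, where the sum runs over the support
#' vectors in standardized feature space and y is +1 for disease, -1 for
#' neutral. Positive weights are disease-predictive. For an RBF model the
#' weight vector lives in an implicit feature space and cannot be
#' extracted.
#'
#' @param model A `subset_model` with a linear kernel.
#' @return Named numeric weight vector over the model's retained features.
#' @export
extract_weights <- function(model) {
  if (model$config$kernel != "linear") {
    stop("weights are undefined for a non-linear (RBF) kernel; ",
         "that classifier does not allow for interpretation", call. = FALSE)
  }
  w <- drop(t(model$fit$coefs) %*% model$fit$SV) * model$sign
  stats::setNames(w, model$retained_features)
}

#' Standardize a weight vector
#'
#' Shifts and scales to zero mean and unit (population) standard deviation
#' so that weight patterns are comparable across subset classifiers.
#'
#' @param w Numeric vector with at least two entries and non-zero spread.
#' @return The standardized vector.
#' @export
standardize_weights <- function(w) {
  if (sum(is.finite(w)) < 2) stop("need at least two finite weights", call. = FALSE)
  s <- sqrt(mean((w - mean(w))^2))
  if (s == 0) stop("constant weight vector cannot be standardized", call. = FALSE)
  (w - mean(w)) / s
}

#' @export
tidy.subset_model <- function(x, standardize = FALSE, ...) {
  w <- extract_weights(x)
  if (standardize) w <- standardize_weights(w)
  tibble::tibble(subset = x$key, feature = names(w),
                 category = unname(x$categories[names(w)]),
                 weight = unname(w))
}

#' @export
glance.subset_model <- function(x, ...) {
  tibble::tibble(subset = x$key, kernel = x$config$kernel, C = x$config$C,
                 n = x$n, n_support = nrow(x$fit$SV),
                 n_features = length(x$retained_features))
}

#' Subset-by-feature table of standardized weights
#'
#' Collects the standardized weight vector of every linear subset
#' classifier into one table, rows = subsets, columns = the union of
#' feature names. Features that were removed for a subset (constant on that
#' subset) are masked (`NA`); each row's standardization statistics use its
#' retained features only. A classifier trained on the entire set may be
#' appended as an `"ALL"` row.
#'
#' @param ensemble A `subset_ensemble` (or list of `subset_model`s).
#' @param whole_model Optional `subset_model` trained on all variants.
#' @param standardize Standardize each row (default) or keep raw weights.
#' @return A tibble of class `weight_table`: column `subset` then one
#'   column per feature; attribute `"categories"` maps features to
#'   categories.
#' @export
weight_table <- function(ensemble, whole_model = NULL, standardize = TRUE) {
  models <- unclass(ensemble)
  if (!is.null(whole_model)) models <- c(models, list(ALL = whole_model))
  cats <- purrr::reduce(purrr::map(models, "categories"), function(a, b) {
    shared <- intersect(names(a), names(b))
    if (!identical(a[shared], b[shared])) {
      stop("models disagree on feature categories", call. = FALSE)
    }
    c(a, b[setdiff(names(b), names(a))])
  })
  rows <- purrr::imap(models, function(m, key) {
    w <- extract_weights(m)
    if (standardize) w <- standardize_weights(w)
    tibble::tibble(subset = if (is.null(m$key)) key else m$key,
                   feature = names(w), weight = unname(w))
  })
  long <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(long, names_from = "feature",
                             values_from = "weight")
  feat_order <- feature_order(setdiff(names(wide), "subset"), cats)
  wide <- wide[c("subset", feat_order)]
  structure(wide, categories = cats,
            class = unique(c("weight_table", class(wide))))
}

feature_order <- function(features, cats) {
  cat_rank <- match(cats[features], FEATURE_CATEGORIES)
  features[order(cat_rank, features)]
}

#' Order the rows and columns of a weight table
#'
#' `"aa_property"` applies the fixed physicochemical amino-acid ordering
#' ([AA_PROPERTY_ORDER]) to subset rows and, for substitution or
#' surrounding features, to the amino-acid-indexed columns; other columns
#' keep their category order. `"cluster"` orders rows and columns by
#' complete-linkage hierarchical clustering of the Euclidean distances,
#' with masked cells treated as 0 for the distance computation only.
#'
#' @param table A `weight_table`.
#' @param mode `"aa_property"` or `"cluster"`.
#' @param aa_order Replacement amino-acid ordering for `"aa_property"`.
#' @return The reordered `weight_table`.
#' @export
order_weight_table <- function(table, mode = c("aa_property", "cluster"),
                               aa_order = AA_PROPERTY_ORDER) {
  mode <- match.arg(mode)
  feats <- setdiff(names(table), "subset")
  if (mode == "aa_property") {
    row_rank <- aa_subset_rank(table$subset, aa_order)
    col_aa <- stringr::str_match(feats, "^(?:sub|count)_([A-Z])$")[, 2]
    col_rank <- ifelse(is.na(col_aa), NA, match(col_aa, aa_order))
    cat_rank <- match(attr(table, "categories")[feats], FEATURE_CATEGORIES)
    new_feats <- feats[order(cat_rank, col_rank, feats)]
    out <- table[order(row_rank), c("subset", new_feats)]
  } else {
    m <- as.matrix(as.data.frame(table)[feats])
    m[is.na(m)] <- 0
    row_ord <- if (nrow(m) > 2) {
      stats::hclust(stats::dist(m), method = "complete")$order
    } else seq_len(nrow(m))
    col_ord <- if (ncol(m) > 2) {
      stats::hclust(stats::dist(t(m)), method = "complete")$order
    } else seq_len(ncol(m))
    out <- table[row_ord, c("subset", feats[col_ord])]
  }
  structure(out, categories = attr(table, "categories"),
            class = unique(c("weight_table", class(out))))
}

aa_subset_rank <- function(keys, aa_order) {
  first <- substr(keys, 1, 1)
  rank <- match(first, aa_order)
  rank[keys == "WYF"] <- match("W", aa_order)
  rank[keys == "ALL"] <- length(aa_order) + 1L  # whole-set row at the bottom
  rank
}

#' Log-odds substitution matrix
#'
#' For every ordered substitution `(ref, mut)` reachable by a single codon
#' mutation, the log odds of observing it among disease-associated versus
#' neutral variants:
#' `log[(d + c) / (D + 380 c)] - log[(n + c) / (N + 380 c)]`,
#' with `d`, `n` the counts of the substitution in the disease/neutral
#' sets, `D`, `N` the class totals, and `c` a pseudocount. Positive values
#' mark substitutions relatively often disease-associated. Unreachable
#' cells and the diagonal are `NA`.
#'
#' @param variants A labeled variant tibble.
#' @param pseudocount Haldane–Anscombe style pseudocount `c` (default 0.5;
#'   0 reproduces raw log odds where counts permit).
#' @param reach Reachability matrix defining the mask.
#' @return A 20 x 20 numeric matrix (rows = reference, cols = mutant) of
#'   class `log_odds_matrix`, reachability mask in attribute `"mask"`.
#' @export
log_odds_matrix <- function(variants, pseudocount = 0.5,
                            reach = reachability_matrix()) {
  d_tot <- sum(variants$label == 1L)
  n_tot <- sum(variants$label == 0L)
  if (d_tot == 0 || n_tot == 0) {
    stop("both classes must be present to form log odds", call. = FALSE)
  }
  cnt <- function(lab) {
    tab <- table(factor(variants$ref_aa[variants$label == lab],
                        levels = AA_ALPHABET),
                 factor(variants$mut_aa[variants$label == lab],
                        levels = AA_ALPHABET))
    matrix(as.numeric(tab), 20, 20, dimnames = dimnames(reach))
  }
  d <- cnt(1L)
  n <- cnt(0L)
  c0 <- pseudocount
  denom <- 20 * 19 * c0
  lo <- log((d + c0) / (d_tot + denom)) - log((n + c0) / (n_tot + denom))
  lo[!reach] <- NA_real_
  structure(lo, mask = !reach,
            class = c("log_odds_matrix", class(lo)))
}

#' Heat-map plot of a weight table
#'
#' Diverging palette: blue = negative = neutral-predictive, red = positive
#' = disease-predictive; masked (removed) features in grey.
#'
#' @param object A `weight_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_table <- function(object, ...) {
  feats <- setdiff(names(object), "subset")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"subset",
                              names_to = "feature", values_to = "weight")
  long$feature <- factor(long$feature, levels = feats)
  long$subset <- factor(long$subset, levels = rev(object$subset))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$subset,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey80") +
    ggplot2::labs(x = NULL, y = "subset", fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Heat-map plot of a log-odds substitution matrix
#'
#' @param object A `log_odds_matrix`.
#' @param aa_order Row/column display ordering.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.log_odds_matrix <- function(object, aa_order = AA_PROPERTY_ORDER,
                                     ...) {
  long <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                                stringsAsFactors = FALSE))
  names(long) <- c("ref", "mut", "log_odds")
  long$ref <- factor(long$ref, levels = rev(aa_order))
  long$mut <- factor(long$mut, levels = aa_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mut, y = .data$ref,
                                     fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey80") +
    ggplot2::labs(x = "mutant", y = "reference", fill = "log odds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a weight table as TSV and rendered heat map
#'
#' Writes the numeric matrix (tab-separated, masked cells as `NA`) next to
#' a PNG heat map with the diverging blue/white/red palette.
#'
#' @param table A `weight_table` (ordered as desired).
#' @param path Output path for the TSV; the image takes the same path with
#'   a `.png` extension.
#' @param width,height Image size in inches.
#' @return Invisible character vector of the two paths written.
#' @export
heatmap_emit <- function(table, path, width = 10, height = 6) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  img <- paste0(sub("\\.[^.]*$", "", path), ".png")
  ggplot2::ggsave(img, autoplot.weight_table(table), width = width,
                  height = height, dpi = 150)
  invisible(c(path, img))
}
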