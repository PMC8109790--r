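#' Label a yield about the high/low cutoff
#'
#' A specimen is "high" iff its berry yield strictly exceeds the cutoff
#' (default 40 ton/ha, above the regional average of about 30 ton/ha);
#' exactly at the cutoff is "low".
#'
#' @param yield Berry yield(s), ton/ha.
#' @param cutoff Yield cutoff, ton/ha.
#' @return Factor with levels `low`, `high`.
#' @export
label_yield_class <- function(yield, cutoff = 40) {
  if (any(!is.finite(yield)) || any(yield < 0)) {
    stop("yield must be non-negative", call. = FALSE)
  }
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  factor(ifelse(yield > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Named feature groups of the observation schema
#'
#' Groups of feature columns used to assemble classifier feature sets and
#' the ablation ladder. `tissue_test` stands for the 10 isometric log-ratio
#' coordinates of the closed tissue composition under the default sequential
#' binary partition (computed by the model functions from the raw nutrient
#' columns), so the classifier sees the composition in its native simplex
#' geometry.
#'
#' @return Named list of column-name vectors.
#' @export
feature_groups <- function() {
  list(
    region_cultivar = c("region", "cultivar"),
    farming = "farming_system",
    fertilization = paste0("dose_", c("N", "P", "K", "Mg", "S", "Cu", "B")),
    tissue_test = paste0("ilr", 1:10),
    soil_test = c("soil_pH", "soil_C", "soil_N",
                  paste0("mehlich_", c("P", "K", "Ca", "Mg", "Cu", "Zn",
                                       "Mn", "Fe", "Al"))),
    texture = c("clay", "silt", "sand_vc", "sand_co", "sand_me",
                "sand_fi", "sand_vf"),
    density = c("bd_0_10", "bd_10_20", "bd_20_30"),
    soil_series = "soil_series",
    climate = c(paste0("temp_", month_labels), paste0("prec_", month_labels))
  )
}

#' Default feature-set ladder for the ablation study
#'
#' Ordered list of named feature subsets of increasing richness, from region
#' and cultivar alone up to the full feature set, used to measure how much
#' each factor family contributes to classification accuracy.
#'
#' @return Named list; each element a vector of feature-group names.
#' @export
default_feature_ladder <- function() {
  list(
    "region+cultivar" = c("region_cultivar"),
    "region+cultivar+climate" = c("region_cultivar", "climate"),
    "region+cultivar+soil test" = c("region_cultivar", "soil_test"),
    "region+cultivar+tissue test" = c("region_cultivar", "tissue_test"),
    "region+cultivar+tissue test+climate" =
      c("region_cultivar", "tissue_test", "climate"),
    "region+cultivar+tissue test+soil test" =
      c("region_cultivar", "tissue_test", "soil_test"),
    "region+cultivar+tissue test+soil test+texture+density" =
      c("region_cultivar", "tissue_test", "soil_test", "texture", "density"),
    "full" = c("region_cultivar", "farming", "fertilization", "tissue_test",
               "soil_test", "texture", "density", "soil_series", "climate")
  )
}

resolve_features <- function(features) {
  grp <- feature_groups()
  if (is.character(features) && all(features %in% names(grp))) {
    return(unique(unlist(grp[features], use.names = FALSE)))
  }
  unique(features)
}

# numeric model frame: ilr coordinates added, categoricals one-hot encoded
encode_features <- function(data, feature_cols, sbp = default_sbp()) {
  if (any(grepl("^ilr", feature_cols)) && !"ilr1" %in% names(data)) {
    ilr <- t(apply(as.matrix(data[, nutrient_parts]), 1, function(x) {
      ilr_transform(close_composition(structure(x, names = nutrient_parts)), sbp)
    }))
    colnames(ilr) <- paste0("ilr", 1:10)
    data <- dplyr::bind_cols(data, tibble::as_tibble(ilr))
  }
  missing <- setdiff(feature_cols, names(data))
  if (length(missing)) {
    stop("feature column(s) absent from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- data[, feature_cols, drop = FALSE]
  is_cat <- vapply(X, function(col) is.character(col) || is.factor(col),
                   logical(1))
  num <- X[, !is_cat, drop = FALSE]
  if (any(is_cat)) {
    dummies <- lapply(names(X)[is_cat], function(nm) {
      f <- as.character(X[[nm]])
      lev <- sort(unique(f))
      m <- outer(f, lev, `==`) * 1
      colnames(m) <- paste(nm, lev, sep = ".")
      tibble::as_tibble(m)
    })
    num <- dplyr::bind_cols(num, dummies)
  }
  as.data.frame(num, check.names = TRUE)
}

make_stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

make_grouped_folds <- function(groups, k, seed) {
  withr::with_seed(seed, {
    u <- unique(groups)
    gf <- stats::setNames(sample(rep_len(seq_len(k), length(u))), u)
    unname(gf[as.character(groups)])
  })
}

#' Train the yield classifier with stratified cross-validation
#'
#' Fits a random-forest classifier of the high/low yield class (about
#' `cutoff`) on the requested feature set and evaluates it by stratified
#' k-fold cross-validation with out-of-fold predictions. Classification
#' accuracy (CA) is the proportion of correctly classified specimens; AUC is
#' the area under the ROC curve of the out-of-fold probability of exceeding
#' the cutoff. The model is flagged informative when AUC > 0.7. A specimen
#' whose predicted probability ties at exactly 0.5 is classed "low"
#' (imbalanced).
#'
#' @param data Observation tibble (see [generate_dataset()] /
#'   [read_observations()]).
#' @param features Feature-group names (see [feature_groups()]) or explicit
#'   column names. Default: the full ladder set.
#' @param cutoff Yield cutoff, ton/ha.
#' @param folds Number of CV folds; 5, 10 or 20.
#' @param seed Integer seed controlling fold assignment and the forests.
#' @param num_trees Trees per forest.
#' @param fold_id Optional pre-computed fold assignment (used by
#'   [ablation_study()] to share folds across feature sets).
#' @return A `yield_classifier` object: out-of-fold probabilities and
#'   classes, pooled `auc` and `ca`, per-fold metrics, the final forest
#'   refit on all rows (used to score new specimens), and the data.
#' @export
train_classifier <- function(data,
                             features = default_feature_ladder()$full,
                             cutoff = 40, folds = 10, seed = 1,
                             num_trees = 500, fold_id = NULL) {
  if (!folds %in% c(5, 10, 20)) {
    stop("folds must be 5, 10, or 20", call. = FALSE)
  }
  obs <- label_yield_class(data$yield, cutoff)
  if (nlevels(droplevels(obs)) < 2) {
    stop("degenerate labels: all specimens fall on one side of the cutoff",
         call. = FALSE)
  }
  if (min(table(obs)) < folds) {
    stop("folds (", folds, ") exceeds the size of the smallest class (",
         min(table(obs)), ")", call. = FALSE)
  }
  feature_cols <- resolve_features(features)
  X <- encode_features(data, feature_cols)
  if (is.null(fold_id)) fold_id <- make_stratified_folds(obs, folds, seed)
  prob_high <- rep(NA_real_, nrow(X))
  df <- cbind(X, .label = obs)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = df[tr, , drop = FALSE],
      probability = TRUE, num.trees = num_trees, seed = seed + f,
      num.threads = 1
    )
    prob_high[!tr] <- stats::predict(fit, df[!tr, , drop = FALSE],
                                     num.threads = 1)$predictions[, "high"]
  }
  pred <- factor(ifelse(prob_high > 0.5, "high", "low"),
                 levels = c("low", "high"))
  ca <- mean(pred == obs)
  auc <- as.numeric(pROC::auc(pROC::roc(obs, prob_high,
                                        levels = c("low", "high"),
                                        direction = "<", quiet = TRUE)))
  per_fold <- vapply(sort(unique(fold_id)), function(f) {
    mean(pred[fold_id == f] == obs[fold_id == f])
  }, numeric(1))
  final <- ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(list(
    data = data, obs = obs, prob_high = prob_high, pred = pred,
    fold_id = fold_id, auc = auc, ca = ca, per_fold_ca = per_fold,
    informative = auc > 0.7, cutoff = cutoff, folds = folds, seed = seed,
    feature_cols = feature_cols, model = final
  ), class = "yield_classifier")
}

#' @export
print.yield_classifier <- function(x, ...) {
  cat("Random-forest yield classifier (cutoff ", x$cutoff, " ton/ha, ",
      x$folds, "-fold stratified CV)\n", sep = "")
  cat(sprintf("  AUC = %.3f  CA = %.3f  (%sinformative: AUC %s 0.7)\n",
              x$auc, x$ca, if (x$informative) "" else "not ",
              if (x$informative) ">" else "<="))
  invisible(x)
}

#' Probability that a specimen exceeds the yield cutoff
#'
#' Scores one or more observation rows with the classifier's final forest.
#'
#' @param fit A `yield_classifier`.
#' @param records Observation rows with the classifier's feature columns.
#' @return Numeric vector of probabilities of the "high" class.
#' @export
predict_high_probability <- function(fit, records) {
  X <- encode_features(records, intersect(fit$feature_cols,
                                          c(names(records), paste0("ilr", 1:10))))
  # align one-hot columns with the training frame
  train_cols <- fit$model$forest$independent.variable.names
  for (nm in setdiff(train_cols, names(X))) X[[nm]] <- 0
  X <- X[, train_cols, drop = FALSE]
  stats::predict(fit$model, X, num.threads = 1)$predictions[, "high"]
}

#' Partition specimens into confusion-matrix quadrants
#'
#' Crosses the observed yield class (high = negative condition, i.e.
#' nutritionally balanced outcome; low = positive) with the out-of-fold
#' predicted class: true negatives are high-yielding specimens predicted
#' balanced, false negatives low-yielding but predicted balanced, false
#' positives high-yielding but predicted imbalanced, true positives
#' low-yielding and predicted imbalanced. `CA = (TN + TP) / n`.
#'
#' @param fit A `yield_classifier` (its out-of-fold predictions are used;
#'   training predictions never are).
#' @return A `confusion_quadrants` object: row indices and key tibbles per
#'   quadrant, counts, and `ca`.
#' @export
confusion_partition <- function(fit) {
  stopifnot(inherits(fit, "yield_classifier"))
  if (anyNA(fit$prob_high)) {
    stop("out-of-fold predictions are incomplete", call. = FALSE)
  }
  obs_high <- fit$obs == "high"
  pred_high <- fit$pred == "high"
  idx <- list(
    tn = which(obs_high & pred_high),
    fn = which(!obs_high & pred_high),
    fp = which(obs_high & !pred_high),
    tp = which(!obs_high & !pred_high)
  )
  counts <- vapply(idx, length, integer(1))
  key_cols <- intersect(c("region", "site", "bed", "year"), names(fit$data))
  keys <- lapply(idx, function(i) fit$data[i, key_cols, drop = FALSE])
  structure(list(index = idx, keys = keys, counts = counts,
                 ca = (counts[["tn"]] + counts[["tp"]]) / sum(counts),
                 cutoff = fit$cutoff, data = fit$data),
            class = "confusion_quadrants")
}

#' @export
print.confusion_quadrants <- function(x, ...) {
  cat("Confusion quadrants (cutoff ", x$cutoff, " ton/ha): ",
      paste(toupper(names(x$counts)), x$counts, collapse = ", "),
      sprintf("; CA = %.3f\n", x$ca), sep = "")
  invisible(x)
}

#' Feature-set ablation study
#'
#' Trains the classifier once per feature subset of the ladder, sharing the
#' same stratified folds and seed across subsets so rows are paired, and
#' reports AUC and CA per subset.
#'
#' @param data Observation tibble.
#' @param ladder Named list of feature subsets (vectors of feature-group
#'   names); default [default_feature_ladder()].
#' @inheritParams train_classifier
#' @return Tibble with columns `feature_set`, `auc`, `ca`.
#' @export
ablation_study <- function(data, ladder = default_feature_ladder(),
                           cutoff = 40, folds = 10, seed = 1,
                           num_trees = 500) {
  if (!length(ladder) || any(!lengths(ladder))) {
    stop("the ladder must be a non-empty list of non-empty feature subsets",
         call. = FALSE)
  }
  obs <- label_yield_class(data$yield, cutoff)
  fold_id <- make_stratified_folds(obs, folds, seed)
  rows <- purrr::imap(ladder, function(fs, nm) {
    fit <- train_classifier(data, features = fs, cutoff = cutoff,
                            folds = folds, seed = seed,
                            num_trees = num_trees, fold_id = fold_id)
    tibble::tibble(feature_set = nm, auc = fit$auc, ca = fit$ca)
  })
  dplyr::bind_rows(rows)
}
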