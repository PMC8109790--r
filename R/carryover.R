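#' Assemble the lagged bed-year panel
#'
#' Pairs each bed-year with the same bed's following year, producing one
#' panel row per consecutive (t, t+1) pair: the full year-t record plus
#' `year_next` and `yield_next`. Non-consecutive years never pair. Site-year
#' combinations can be excluded (e.g. beds damaged by early frost) before
#' pairing, so an excluded year contributes neither as t nor as t+1.
#'
#' @param records Observation tibble with `region`, `site`, `bed`, `year`
#'   keys and `yield`.
#' @param exclude Optional data frame with columns `site` and `year` listing
#'   site-years to drop.
#' @return Tibble of panel rows.
#' @export
assemble_panel <- function(records, exclude = NULL) {
  key_cols <- c("region", "site", "bed", "year")
  missing <- setdiff(c(key_cols, "yield"), names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(records$site, records$year) %in%
      paste(exclude$site, exclude$year)
    records <- records[!drop, , drop = FALSE]
  }
  keys <- do.call(paste, c(records[key_cols], sep = "/"))
  if (anyDuplicated(keys)) {
    stop("duplicate (bed, year) record(s): ",
         paste(utils::head(keys[duplicated(keys)], 3), collapse = "; "),
         call. = FALSE)
  }
  nxt <- records[, c(key_cols, "yield")]
  nxt$year <- nxt$year - 1L  # align next year onto current rows
  names(nxt)[names(nxt) == "yield"] <- "yield_next"
  panel <- dplyr::inner_join(records, nxt,
                             by = c("region", "site", "bed", "year"))
  panel$year_next <- panel$year + 1L
  panel
}

variant_labels <- c(
  "1" = "Y_t+1 = f(C_t)",
  "2" = "Y_t+1 = f(C_t, F_t)",
  "3" = "Y_t+1 = f(C_t, F_t, Y_t)",
  "4" = "Y_t+1 = f(F_t, Y_t) + soil test",
  "5" = "Y_t+1 = f(C_t, Y_t) + soil test",
  "6" = "Y_t+1 = f(C_t, F_t, Y_t) + soil test"
)

#' Feature blocks of the six next-year yield functions
#'
#' Variant 1 uses current-year tissue composition alone; 2 adds the
#' fertilization regime; 3 adds current-year yield; 4 drops composition but
#' adds the soil test; 5 composition + yield + soil test; 6 all four blocks.
#' Composition enters as ilr coordinates under the default sequential
#' binary partition unless `use_ilr = FALSE`, in which case the raw
#' concentrations are used.
#'
#' @param variant Integer 1..6.
#' @param use_ilr Represent the composition as ilr balances (default).
#' @return Character vector of feature column names.
#' @export
variant_features <- function(variant, use_ilr = TRUE) {
  stopifnot(variant %in% 1:6)
  grp <- feature_groups()
  comp <- if (use_ilr) grp$tissue_test else nutrient_parts
  blocks <- list(
    `1` = comp,
    `2` = c(comp, grp$fertilization),
    `3` = c(comp, grp$fertilization, "yield"),
    `4` = c(grp$fertilization, "yield", grp$soil_test),
    `5` = c(comp, "yield", grp$soil_test),
    `6` = c(comp, grp$fertilization, "yield", grp$soil_test)
  )
  blocks[[as.character(variant)]]
}

#' Fit the next-year yield functions by random-forest regression
#'
#' Fits one random-forest regression of `yield_next` per requested variant,
#' under cross-validation with folds grouped by bed (all years of a bed
#' stay in one fold, so no bed leaks across the train/test split) and
#' shared across variants for paired comparison. R-squared is the squared
#' correlation between out-of-fold predictions and observed next-year
#' yields.
#'
#' @param panel Panel tibble from [assemble_panel()].
#' @param variants Integer subset of 1..6.
#' @param folds,seed,num_trees Cross-validation and forest controls.
#' @param use_ilr Passed to [variant_features()].
#' @param ... Further arguments for [ranger::ranger()] (e.g. `mtry`,
#'   `min.node.size`).
#' @return Tibble with columns `variant`, `label`, `r2`; out-of-fold
#'   predictions in attribute `oof`.
#' @export
fit_yield_functions <- function(panel, variants = 1:6, folds = 10, seed = 1,
                                num_trees = 500, use_ilr = TRUE, ...) {
  if (nrow(panel) < 50) {
    stop("panel too small to cross-validate (", nrow(panel), " rows)",
         call. = FALSE)
  }
  if (stats::var(panel$yield_next) == 0) {
    stop("constant next-year yield: R-squared undefined", call. = FALSE)
  }
  bed_key <- paste(panel$region, panel$site, panel$bed, sep = "/")
  fold_id <- make_grouped_folds(bed_key, folds, seed)
  oof <- list()
  rows <- lapply(variants, function(v) {
    cols <- variant_features(v, use_ilr)
    X <- encode_features(panel, cols)
    df <- cbind(X, .target = panel$yield_next)
    pred <- rep(NA_real_, nrow(df))
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      fit <- ranger::ranger(dependent.variable.name = ".target",
                            data = df[tr, , drop = FALSE],
                            num.trees = num_trees, seed = seed + f,
                            num.threads = 1, ...)
      pred[!tr] <- stats::predict(fit, df[!tr, , drop = FALSE],
                                  num.threads = 1)$predictions
    }
    oof[[as.character(v)]] <<- pred
    tibble::tibble(variant = v, label = variant_labels[as.character(v)],
                   r2 = stats::cor(pred, panel$yield_next)^2)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "oof") <- oof
  attr(out, "fold_id") <- fold_id
  out
}

#' Next-year yield classification and the next-year reference bank
#'
#' Classifies panel rows about the cutoff on the *next-year* yield using the
#' full variant-6 feature blocks, with bed-grouped cross-validation, and
#' partitions rows into confusion quadrants. The true negatives — beds whose
#' observed next-year yield exceeds the cutoff and whose out-of-fold
#' prediction is balanced — form the predictive reference bank.
#'
#' @inheritParams fit_yield_functions
#' @param cutoff Yield cutoff, ton/ha, applied to `yield_next`.
#' @return List with the `yield_classifier`-like fit, `quadrants`, `ca`,
#'   and `bank` (a `reference_bank` of next-year true negatives).
#' @export
predict_next_year_class <- function(panel, cutoff = 40, folds = 10, seed = 1,
                                    num_trees = 500, use_ilr = TRUE) {
  obs <- label_yield_class(panel$yield_next, cutoff)
  if (nlevels(droplevels(obs)) < 2) {
    stop("degenerate labels: all next-year yields on one side of the cutoff",
         call. = FALSE)
  }
  cols <- variant_features(6, use_ilr)
  X <- encode_features(panel, cols)
  bed_key <- paste(panel$region, panel$site, panel$bed, sep = "/")
  fold_id <- make_grouped_folds(bed_key, folds, seed)
  df <- cbind(X, .label = obs)
  prob_high <- rep(NA_real_, nrow(df))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- ranger::ranger(dependent.variable.name = ".label",
                          data = df[tr, , drop = FALSE], probability = TRUE,
                          num.trees = num_trees, seed = seed + f,
                          num.threads = 1)
    prob_high[!tr] <- stats::predict(fit, df[!tr, , drop = FALSE],
                                     num.threads = 1)$predictions[, "high"]
  }
  pred <- factor(ifelse(prob_high > 0.5, "high", "low"),
                 levels = c("low", "high"))
  fitobj <- structure(list(
    data = panel, obs = obs, prob_high = prob_high, pred = pred,
    fold_id = fold_id, ca = mean(pred == obs),
    auc = as.numeric(pROC::auc(pROC::roc(obs, prob_high,
                                         levels = c("low", "high"),
                                         direction = "<", quiet = TRUE))),
    cutoff = cutoff, folds = folds, seed = seed, feature_cols = cols,
    model = NULL
  ), class = "yield_classifier")
  quad <- confusion_partition(fitobj)
  bank <- build_reference_bank(quad)
  list(fit = fitobj, quadrants = quad, ca = fitobj$ca, bank = bank)
}

#' Predictive diagnosis against the next-year reference bank
#'
#' Same mechanics as [diagnose_local()], but the references are next-year
#' true negatives: the attainable yield is the reference bed's *next-year*
#' yield, so the report reads as the yield the diagnosed bed could reach
#' next season by rebalancing its current tissue composition.
#'
#' @param record One-row observation record or bare composition.
#' @param bank Next-year `reference_bank` from [predict_next_year_class()].
#' @param filter As in [diagnose_local()].
#' @return A `diagnosis_report` with scope `"predictive"`.
#' @export
predictive_diagnosis <- function(record, bank,
                                 filter = c("cultivar", "cultivar+region",
                                            "none")) {
  if (!nrow(bank)) stop("next-year reference bank is empty", call. = FALSE)
  rep_local <- diagnose_local(record, bank, filter = filter)
  rep_local$scope <- "predictive"
  ref_key <- rep_local$reference
  if ("yield_next" %in% names(bank)) {
    # attainable yield is the next-year yield of the matched reference
    i <- which(vapply(seq_len(nrow(bank)), function(i) {
      record_key(bank[i, ]) == ref_key
    }, logical(1)))[1]
    rep_local$attainable_yield <- bank$yield_next[i]
  }
  rep_local
}
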