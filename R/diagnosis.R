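#' Build the reference bank of nutritionally balanced, high-yielding specimens
#'
#' The diagnostic standards are the true-negative specimens: observed above
#' the yield cutoff and predicted nutritionally balanced out-of-fold. When
#' true negatives are scarce, false negatives (nutritionally balanced but
#' low-yielding) can be appended as additional benchmarks and are flagged.
#' False positives and true positives are never admitted: they would bias
#' the nutrient standards exactly the way luxury consumption and
#' contamination bias range-based norms.
#'
#' @param quadrants A `confusion_quadrants` from [confusion_partition()] (or
#'   [predict_next_year_class()]).
#' @param include_fn Append flagged false-negative specimens.
#' @return A `reference_bank`: the specimen rows with a `flag` column
#'   (`"TN"`/`"FN"`) and the producing cutoff in attribute `cutoff`.
#' @export
build_reference_bank <- function(quadrants, include_fn = FALSE) {
  stopifnot(inherits(quadrants, "confusion_quadrants"))
  tn <- quadrants$data[quadrants$index$tn, , drop = FALSE]
  if (nrow(tn) == 0 && !include_fn) {
    stop("no true-negative specimens; consider include_fn = TRUE to admit ",
         "balanced low-yielding specimens as additional benchmarks",
         call. = FALSE)
  }
  bank <- dplyr::mutate(tn, flag = "TN")
  if (include_fn) {
    fn <- quadrants$data[quadrants$index$fn, , drop = FALSE]
    if (nrow(fn)) bank <- dplyr::bind_rows(bank, dplyr::mutate(fn, flag = "FN"))
  }
  structure(bank, cutoff = quadrants$cutoff,
            class = c("reference_bank", class(bank)))
}

record_key <- function(record) {
  cols <- intersect(c("region", "site", "bed", "year"), names(record))
  if (!length(cols)) return(NA_character_)
  paste(unlist(record[1, cols]), collapse = "/")
}

#' Nearest successful neighbour of a diagnosed composition
#'
#' Finds the reference-bank specimen minimizing the Aitchison distance to
#' the diagnosed composition. Distance ties are broken by higher yield, then
#' by bank row order. Optional filters restrict candidates to the same
#' cultivar and/or region, making the diagnosis factor-specific.
#'
#' @param specimen A `tissue_composition`, a 10-vector of nutrient
#'   concentrations, or a one-row observation record.
#' @param bank A `reference_bank`.
#' @param cultivar,region Optional filter values.
#' @return List with `reference` (the bank row), `distance`, and
#'   `filters_used`.
#' @export
nearest_successful <- function(specimen, bank, cultivar = NULL, region = NULL) {
  comp <- if (is.data.frame(specimen)) record_composition(specimen)
          else as_composition(specimen)
  cand <- bank
  filters <- character(0)
  if (!is.null(cultivar)) {
    cand <- cand[cand$cultivar == cultivar, , drop = FALSE]
    filters <- c(filters, paste0("cultivar=", cultivar))
  }
  if (!is.null(region)) {
    cand <- cand[cand$region == region, , drop = FALSE]
    filters <- c(filters, paste0("region=", region))
  }
  if (!nrow(cand)) {
    stop("no reference specimens left after filtering (",
         paste(filters, collapse = ", "), ")", call. = FALSE)
  }
  d <- vapply(seq_len(nrow(cand)), function(i) {
    aitchison_distance(comp, record_composition(cand[i, ]))
  }, numeric(1))
  ties <- which(d <= min(d) + 1e-12)
  best <- ties[order(-cand$yield[ties], ties)][1]
  list(reference = cand[best, , drop = FALSE], distance = d[best],
       filters_used = filters)
}

new_diagnosis_report <- function(specimen_key, scope, reference_key, distance,
                                 attainable_yield, probability, ratios,
                                 filters_used) {
  ranking <- rank_nutrients(ratios)
  structure(list(
    specimen = specimen_key, scope = scope, reference = reference_key,
    filters_used = filters_used, distance = distance,
    attainable_yield = attainable_yield, probability = probability,
    ratios = ratios, ranking = ranking,
    excess = ranking$nutrient[ranking$status == "excess"],
    shortage = ranking$nutrient[ranking$status == "shortage"]
  ), class = "diagnosis_report")
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat("Nutrient diagnosis (", x$scope, " scale)\n", sep = "")
  cat("  specimen:  ", x$specimen, "\n  reference: ", x$reference, "\n", sep = "")
  cat(sprintf("  Aitchison distance: %.2f\n", x$distance))
  if (!is.null(x$attainable_yield)) {
    cat(sprintf("  attainable yield:   %.1f ton/ha\n", x$attainable_yield))
  }
  if (!is.null(x$probability)) {
    cat(sprintf("  P(yield > cutoff):  %.2f\n", x$probability))
  }
  cat("  excess:   ", paste(x$excess, collapse = ", "), "\n", sep = "")
  cat("  shortage: ", paste(x$shortage, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Local factor-specific diagnosis against the nearest successful neighbour
#'
#' Compares the diagnosed specimen to its nearest successful neighbour in
#' the reference bank. The neighbour's yield is the attainable yield the
#' diagnosed bed could reach by rebalancing its tissue nutrients; the
#' perturbation vector (diagnosed / reference) ranks nutrients as relative
#' excess or shortage. By default candidates are restricted to the
#' specimen's cultivar when that cultivar is present in the bank.
#'
#' @param record One-row observation record (or bare composition).
#' @param bank A `reference_bank`.
#' @param fit Optional `yield_classifier`; if supplied the report carries
#'   the modelled probability that the specimen exceeds the cutoff.
#' @param filter `"cultivar"` (default; applied when the cultivar is
#'   represented in the bank), `"cultivar+region"`, or `"none"`.
#' @return A `diagnosis_report`.
#' @export
diagnose_local <- function(record, bank, fit = NULL,
                           filter = c("cultivar", "cultivar+region", "none")) {
  filter <- match.arg(filter)
  cultivar <- region <- NULL
  if (is.data.frame(record) && filter != "none") {
    if ("cultivar" %in% names(record) &&
        record$cultivar[1] %in% bank$cultivar) {
      cultivar <- record$cultivar[1]
    }
    if (filter == "cultivar+region" && "region" %in% names(record) &&
        record$region[1] %in% bank$region) {
      region <- record$region[1]
    }
  }
  nn <- nearest_successful(record, bank, cultivar = cultivar, region = region)
  comp <- if (is.data.frame(record)) record_composition(record)
          else as_composition(record)
  prob <- if (!is.null(fit) && is.data.frame(record)) {
    predict_high_probability(fit, record)
  }
  new_diagnosis_report(
    specimen_key = if (is.data.frame(record)) record_key(record) else "specimen",
    scope = "local",
    reference_key = record_key(nn$reference),
    distance = nn$distance,
    attainable_yield = nn$reference$yield[1],
    probability = prob,
    ratios = perturbation(comp, record_composition(nn$reference)),
    filters_used = nn$filters_used
  )
}

#' Regional diagnosis against the average true-negative composition
#'
#' The reference is the component-wise mean of the bank compositions,
#' re-closed to 1000 g/kg — a statistical construct averaged across
#' factors, as opposed to the factor-specific local neighbour. No attainable
#' yield is reported: the average is not an observed specimen.
#'
#' @param record One-row observation record or bare composition.
#' @param bank A `reference_bank`.
#' @param mean_type Arithmetic (default) or geometric mean of the raw
#'   concentrations before re-closure.
#' @param fit Optional `yield_classifier` for the exceedance probability.
#' @return A `diagnosis_report` (scope `"regional"`, no attainable yield).
#' @export
diagnose_regional <- function(record, bank,
                              mean_type = c("arithmetic", "geometric"),
                              fit = NULL) {
  mean_type <- match.arg(mean_type)
  if (!nrow(bank)) stop("reference bank is empty", call. = FALSE)
  M <- as.matrix(bank[, nutrient_parts])
  avg <- if (mean_type == "arithmetic") colMeans(M) else exp(colMeans(log(M)))
  ref <- close_composition(structure(as.numeric(avg), names = nutrient_parts))
  comp <- if (is.data.frame(record)) record_composition(record)
          else as_composition(record)
  prob <- if (!is.null(fit) && is.data.frame(record)) {
    predict_high_probability(fit, record)
  }
  new_diagnosis_report(
    specimen_key = if (is.data.frame(record)) record_key(record) else "specimen",
    scope = "regional",
    reference_key = "TN-average",
    distance = aitchison_distance(comp, ref),
    attainable_yield = NULL,
    probability = prob,
    ratios = perturbation(comp, ref),
    filters_used = character(0)
  )
}

#' Quartile concentration ranges of the reference bank
#'
#' First and third quartiles of each raw nutrient concentration over the
#' bank specimens (linear-interpolation quantile definition, R type 7) —
#' the compatibility intervals of balanced, high-yielding tissue.
#'
#' @param bank A `reference_bank` with at least 4 specimens.
#' @return Tibble with columns `nutrient`, `q1`, `q3` (g/kg).
#' @export
quartile_ranges <- function(bank) {
  if (nrow(bank) < 4) {
    stop("at least 4 reference specimens are needed for quartile ranges (got ",
         nrow(bank), ")", call. = FALSE)
  }
  M <- as.matrix(bank[, nutrient_parts])
  tibble::tibble(
    nutrient = nutrient_parts,
    q1 = unname(apply(M, 2, stats::quantile, probs = 0.25, type = 7,
                      names = FALSE)),
    q3 = unname(apply(M, 2, stats::quantile, probs = 0.75, type = 7,
                      names = FALSE))
  )
}
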