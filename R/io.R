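#' Column schema of the observation table
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`/`"integer"`/`"double"`).
#' @export
observation_schema <- function() {
  c(region = "character", site = "character", bed = "character",
    year = "integer", cultivar = "character", farming_system = "character",
    stats::setNames(rep("double", 7),
                    paste0("dose_", c("N", "P", "K", "Mg", "S", "Cu", "B"))),
    stats::setNames(rep("double", 10), nutrient_parts),
    soil_pH = "double", soil_C = "double", soil_N = "double",
    stats::setNames(rep("double", 9),
                    paste0("mehlich_", c("P", "K", "Ca", "Mg", "Cu", "Zn",
                                         "Mn", "Fe", "Al"))),
    stats::setNames(rep("double", 7),
                    c("clay", "silt", "sand_vc", "sand_co", "sand_me",
                      "sand_fi", "sand_vf")),
    bd_0_10 = "double", bd_10_20 = "double", bd_20_30 = "double",
    soil_series = "character",
    stats::setNames(rep("double", 6), paste0("temp_", month_labels)),
    stats::setNames(rep("double", 6), paste0("prec_", month_labels)),
    yield = "double")
}

#' Read an observation table from CSV
#'
#' Validates the schema (every required column present), the tissue test of
#' every row (strictly positive nutrient concentrations whose sum stays
#' below the 1000 g/kg measurement unit) and, when an `Fv` column is
#' present, its consistency with closure by difference. Error messages name
#' the offending column and row.
#'
#' @param path CSV file path (comma-delimited, UTF-8, header required).
#' @return Tibble of typed observation records.
#' @export
read_observations <- function(path) {
  schema <- observation_schema()
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(names(schema), names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(schema)) {
    data[[nm]] <- switch(schema[[nm]],
                         character = as.character(data[[nm]]),
                         integer = as.integer(data[[nm]]),
                         double = as.numeric(data[[nm]]))
  }
  nut <- as.matrix(data[, nutrient_parts])
  bad_pos <- which(!is.finite(nut) | nut <= 0, arr.ind = TRUE)
  if (nrow(bad_pos)) {
    stop("non-positive nutrient concentration: part ",
         nutrient_parts[bad_pos[1, 2]], ", row ", bad_pos[1, 1], call. = FALSE)
  }
  sums <- rowSums(nut)
  if (any(sums >= 1000)) {
    stop("infeasible composition (nutrient sum >= 1000 g/kg) at row ",
         which(sums >= 1000)[1], call. = FALSE)
  }
  if ("Fv" %in% names(data)) {
    off <- which(abs(data$Fv - (1000 - sums)) > 0.05 + 1e-9)
    if (length(off)) {
      stop("Fv column inconsistent with closure by difference at row ",
           off[1], call. = FALSE)
    }
  }
  if (any(data$yield < 0, na.rm = TRUE)) {
    stop("negative yield at row ", which(data$yield < 0)[1], call. = FALSE)
  }
  tex <- rowSums(as.matrix(data[, c("clay", "silt", "sand_vc", "sand_co",
                                    "sand_me", "sand_fi", "sand_vf")]))
  if (any(abs(tex - 100) > 0.01)) {
    stop("grain-size fractions do not sum to 100% at row ",
         which(abs(tex - 100) > 0.01)[1], call. = FALSE)
  }
  data
}

#' Write an observation table to CSV
#'
#' @param data Observation tibble.
#' @param path Output CSV path.
#' @export
write_observations <- function(data, path) {
  readr::write_csv(data[, intersect(names(observation_schema()), names(data)),
                        drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Read / write a sequential binary partition sign matrix
#'
#' Plain-text format: a header row of the 11 part labels, then one contrast
#' per row with whitespace-separated entries in {-1, 0, +1}.
#'
#' @param path File path.
#' @return `read_sbp()`: an `sbp` object.
#' @export
read_sbp <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  as_sbp(as.matrix(tab))
}

#' @rdname read_sbp
#' @param sbp An `sbp` object.
#' @export
write_sbp <- function(sbp, path) {
  if (!inherits(sbp, "sbp")) sbp <- as_sbp(sbp)
  utils::write.table(unclass(sbp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diagnosis report to JSON
#'
#' Deterministic key order; distances and ratios are displayed at 2 decimal
#' places with the full-precision values preserved in a `raw` block, so two
#' writes of the same report are byte-identical and a read round-trips.
#'
#' @param report A `diagnosis_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "diagnosis_report"))
  ratios <- unclass(report$ratios)
  closed <- attr(report$ratios, "closed")
  attributes(ratios) <- list(names = tissue_parts)
  doc <- list(
    specimen = report$specimen,
    scope = report$scope,
    reference = report$reference,
    filters_used = as.list(report$filters_used),
    distance = round(report$distance, 2),
    attainable_yield = if (!is.null(report$attainable_yield))
      round(report$attainable_yield, 1),
    probability = if (!is.null(report$probability))
      round(as.numeric(report$probability), 3),
    perturbation = as.list(round(ratios, 2)),
    excess = as.list(report$excess),
    shortage = as.list(report$shortage),
    ranking = report$ranking,
    raw = list(distance = report$distance,
               attainable_yield = report$attainable_yield,
               probability = if (!is.null(report$probability))
                 as.numeric(report$probability),
               perturbation = as.list(ratios),
               perturbation_closed = as.list(closed))
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: the reconstructed `diagnosis_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ratios <- structure(unlist(doc$raw$perturbation),
                      closed = unlist(doc$raw$perturbation_closed),
                      class = "perturbation_vector")
  new_diagnosis_report(
    specimen_key = doc$specimen, scope = doc$scope,
    reference_key = doc$reference, distance = doc$raw$distance,
    attainable_yield = doc$raw$attainable_yield,
    probability = doc$raw$probability, ratios = ratios,
    filters_used = unlist(doc$filters_used) %||% character(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline run configuration
#'
#' Validated bundle of the knobs shared by the end-to-end workflow
#' (simulate, train, diagnose, carryover).
#'
#' @param cutoff Yield cutoff, ton/ha.
#' @param folds CV folds; 5, 10, or 20.
#' @param seed Integer seed for every stochastic stage.
#' @param ladder Feature-set ladder for the ablation stage.
#' @param sbp An `sbp` or `"default"`.
#' @param filter Neighbour filter policy for diagnosis.
#' @param generator A [generator_config()] for the simulation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(cutoff = 40, folds = 10, seed = 1,
                       ladder = default_feature_ladder(), sbp = "default",
                       filter = "cultivar",
                       generator = generator_config(seed = seed)) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (!folds %in% c(5, 10, 20)) stop("folds must be 5, 10, or 20", call. = FALSE)
  if (is.na(as.integer(seed))) stop("seed must be an integer", call. = FALSE)
  if (identical(sbp, "default")) sbp <- default_sbp() else sbp <- as_sbp(sbp)
  structure(list(cutoff = cutoff, folds = folds, seed = as.integer(seed),
                 ladder = ladder, sbp = sbp, filter = filter,
                 generator = generator),
            class = "run_config")
}

#' Run the end-to-end diagnostic workflow
#'
#' Simulate (or accept) an observation table, train the current-year
#' classifier, build the true-negative reference bank, assemble the lagged
#' panel, fit the next-year yield functions, build the next-year bank, and
#' return every intermediate product. Fully reproducible from the config
#' seed.
#'
#' @param config A [run_config()].
#' @param data Optional observation tibble; simulated from
#'   `config$generator` when omitted.
#' @param num_trees Trees per forest.
#' @return List: `data`, `fit`, `quadrants`, `bank`, `panel`,
#'   `yield_functions`, `next_year`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL, num_trees = 500) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) data <- generate_dataset(config$generator)
  fit <- train_classifier(data, cutoff = config$cutoff, folds = config$folds,
                          seed = config$seed, num_trees = num_trees)
  quad <- confusion_partition(fit)
  bank <- build_reference_bank(quad)
  panel <- assemble_panel(data)
  yf <- fit_yield_functions(panel, folds = config$folds, seed = config$seed,
                            num_trees = num_trees)
  ny <- predict_next_year_class(panel, cutoff = config$cutoff,
                                folds = config$folds, seed = config$seed,
                                num_trees = num_trees)
  list(data = data, fit = fit, quadrants = quad, bank = bank, panel = panel,
       yield_functions = yf, next_year = ny)
}
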