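#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every knob of the synthetic multi-site, multi-year
#' cranberry survey. The defaults emulate the structure the diagnostic
#' pipeline assumes: log-normal tissue variation around a region-by-cultivar
#' optimum with micronutrients much more variable than macronutrients, berry
#' yield decaying with the Aitchison distance of the tissue composition from
#' the local optimum, a bounded site-level climate/soil modifier, and a
#' linear carryover of prior fertilization (storage) and prior yield
#' (depletion) into next-year yield.
#'
#' @param n_sites Number of sites (farms).
#' @param n_beds_per_site Beds per site.
#' @param years Consecutive calendar years simulated.
#' @param regions Named numeric vector of region sampling weights (sites are
#'   assigned to regions by these weights).
#' @param cultivars Named numeric vector of cultivar sampling weights (beds
#'   are assigned cultivars by these weights).
#' @param optimum Nutrient concentrations (10-vector, g/kg) at the centre of
#'   the balanced population; default is the across-region true-negative
#'   average tissue composition. Each region-by-cultivar combination gets
#'   its own optimum by log-normal jitter of this anchor.
#' @param optimum_jitter_sd Log-scale SD of the region-by-cultivar jitter.
#' @param sd_log_macro,sd_log_micro Log-scale SDs of within-bed tissue
#'   variation for the 5 macronutrients and 5 micronutrients.
#' @param yield_max_range Range (ton/ha) of the site maximum attainable
#'   yield, drawn uniformly per site.
#' @param modifier_range Range of the bounded multiplicative site
#'   climate/soil yield modifier.
#' @param tau Decay scale (Aitchison distance units) of the Gaussian yield
#'   response to compositional imbalance.
#' @param beta_dep Depletion weight: ton/ha of next-year yield lost per
#'   standard deviation of prior-year yield (carbohydrate depletion).
#' @param beta_store Storage weight: ton/ha gained per standard deviation of
#'   prior-year N+K fertilization (nutrient storage).
#' @param noise_sd SD (ton/ha) of the Gaussian yield noise.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sites = 10,
                             n_beds_per_site = 20,
                             years = 2014:2018,
                             regions = c(Quebec = 0.7, Wisconsin = 0.3),
                             cultivars = c(Stevens = 0.55, `Crimson Queen` = 0.1,
                                           `Ben Lear` = 0.1, HyRed = 0.1,
                                           GH1 = 0.1, Pilgrim = 0.05),
                             optimum = c(N = 10.6, P = 1.1, K = 5.4, Mg = 2.0,
                                         Ca = 8.9, B = 0.052, Cu = 0.004,
                                         Zn = 0.021, Mn = 0.355, Fe = 0.117),
                             optimum_jitter_sd = 0.05,
                             sd_log_macro = 0.08,
                             sd_log_micro = 0.35,
                             yield_max_range = c(45, 65),
                             modifier_range = c(0.8, 1.2),
                             tau = 1.0,
                             beta_dep = 3,
                             beta_store = 2,
                             noise_sd = 3,
                             seed = 42) {
  cfg <- list(n_sites = n_sites, n_beds_per_site = n_beds_per_site,
              years = sort(as.integer(years)), regions = regions,
              cultivars = cultivars, optimum = optimum,
              optimum_jitter_sd = optimum_jitter_sd,
              sd_log_macro = sd_log_macro, sd_log_micro = sd_log_micro,
              yield_max_range = yield_max_range,
              modifier_range = modifier_range, tau = tau,
              beta_dep = beta_dep, beta_store = beta_store,
              noise_sd = noise_sd, seed = as.integer(seed),
              # fixed standardization constants of the carryover terms,
              # so the planted model is closed-form checkable
              yield_ref = c(mean = 40, sd = 10),
              dose_nk_ref = c(mean = 100, sd = 40))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1, cfg$n_beds_per_site >= 1)
  if (any(diff(cfg$years) != 1)) {
    stop("years must be consecutive", call. = FALSE)
  }
  if (cfg$tau <= 0) stop("tau must be strictly positive", call. = FALSE)
  for (nm in c("optimum_jitter_sd", "sd_log_macro", "sd_log_micro", "noise_sd")) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (is.null(names(cfg$regions)) || is.null(names(cfg$cultivars))) {
    stop("regions and cultivars must be named weight vectors", call. = FALSE)
  }
  if (!identical(names(cfg$optimum), nutrient_parts)) {
    stop("optimum must name the 10 nutrients in the fixed order", call. = FALSE)
  }
  close_composition(cfg$optimum) # errors if infeasible
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# fertilizer dose levels mirroring a multi-nutrient on-farm trial design
dose_levels <- list(
  N = c(0, 15, 30, 45, 60), P = c(0, 15, 30), K = c(0, 40, 80, 120),
  Mg = c(0, 12), S = c(0, 250, 500, 1000), Cu = c(0, 2), B = c(0, 1)
)

month_labels <- c("may", "jun", "jul", "aug", "sep", "oct")

#' Generate a synthetic multi-site, multi-year cranberry survey
#'
#' Draws a complete observation table (one row per bed-year) under the
#' planted data-generating model described in [generator_config()]:
#'
#' * tissue composition: log-normal around the region-by-cultivar optimum;
#' * yield: `yield_max * modifier * exp(-(eps/tau)^2) + carryover + noise`,
#'   truncated at zero, where `eps` is the Aitchison distance of the bed's
#'   composition from its optimum;
#' * carryover (years after the first):
#'   `beta_store * z(prior N+K dose) - beta_dep * z(prior yield)` with the
#'   fixed standardization constants recorded in the config.
#'
#' The returned tibble carries a `truth` attribute (per-row optimum, site
#' `yield_max` and `modifier`, imbalance distance `eps`, carryover term and
#' noise draw) and the generating `config`, so planted values can be
#' recovered exactly in tests and by [plant_defect()].
#'
#' @param config A [generator_config()].
#' @return Tibble of observation records, schema-complete for
#'   [read_observations()] / [write_observations()].
#' @export
generate_dataset <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  sites <- sprintf("S%02d", seq_len(cfg$n_sites))
  site_region <- sample(names(cfg$regions), cfg$n_sites, replace = TRUE,
                        prob = cfg$regions)
  site_yield_max <- stats::runif(cfg$n_sites, cfg$yield_max_range[1],
                                 cfg$yield_max_range[2])
  site_modifier <- stats::runif(cfg$n_sites, cfg$modifier_range[1],
                                cfg$modifier_range[2])
  site_series <- sample(c("St-Judes", "St-Samuel", "Ste-Sophie"),
                        cfg$n_sites, replace = TRUE)

  # region-by-cultivar optima: log-normal jitter of the anchor
  combos <- expand.grid(region = names(cfg$regions),
                        cultivar = names(cfg$cultivars),
                        stringsAsFactors = FALSE)
  optima <- lapply(seq_len(nrow(combos)), function(i) {
    close_composition(cfg$optimum *
                        exp(stats::rnorm(10, 0, cfg$optimum_jitter_sd)))
  })
  names(optima) <- paste(combos$region, combos$cultivar, sep = "|")

  # site-level soil properties, mildly tied to the yield modifier
  soil_site <- lapply(seq_len(cfg$n_sites), function(s) {
    tex_raw <- stats::rgamma(7, shape = c(2, 3, 1, 4, 8, 10, 5))
    tex <- tex_raw / sum(tex_raw) * 100
    list(
      soil_pH = stats::runif(1, 4.0, 5.5),
      soil_C = stats::rlnorm(1, log(30), 0.4) * site_modifier[s]^0.5,
      soil_N = NA, # filled below from C
      mehlich = stats::rlnorm(9, log(c(P = 55, K = 45, Ca = 350, Mg = 60,
                                       Cu = 1.2, Zn = 2.5, Mn = 8, Fe = 180,
                                       Al = 900)), 0.3) * site_modifier[s]^0.3,
      texture = tex,
      bd = sort(stats::runif(3, 1.15, 1.65)),
      farming = sample(c("conventional", "organic"), 1, prob = c(0.8, 0.2))
    )
  })
  for (s in seq_len(cfg$n_sites)) {
    soil_site[[s]]$soil_N <- soil_site[[s]]$soil_C / stats::runif(1, 18, 25)
  }

  # region-by-year climate
  temp_base <- c(12, 17, 20, 19, 14, 8)
  clim <- list()
  for (rg in names(cfg$regions)) {
    for (yr in cfg$years) {
      clim[[paste(rg, yr)]] <- list(
        temp = temp_base + stats::rnorm(6, ifelse(rg == "Wisconsin", 1, 0), 1.2),
        prec = stats::rgamma(6, shape = 6, rate = 6 / 100)
      )
    }
  }

  macro_idx <- match(macro_parts, nutrient_parts)
  sd_log <- ifelse(seq_len(10) %in% macro_idx, cfg$sd_log_macro, cfg$sd_log_micro)

  n_beds <- cfg$n_sites * cfg$n_beds_per_site
  bed_site <- rep(seq_len(cfg$n_sites), each = cfg$n_beds_per_site)
  bed_id <- sprintf("B%02d", rep(seq_len(cfg$n_beds_per_site), cfg$n_sites))
  bed_cultivar <- sample(names(cfg$cultivars), n_beds, replace = TRUE,
                         prob = cfg$cultivars)

  rows <- vector("list", n_beds * length(cfg$years))
  truth <- vector("list", n_beds * length(cfg$years))
  k <- 0
  for (b in seq_len(n_beds)) {
    s <- bed_site[b]
    rg <- site_region[s]
    opt <- optima[[paste(rg, bed_cultivar[b], sep = "|")]]
    prev_yield <- NA_real_
    prev_dose_nk <- NA_real_
    for (yr in cfg$years) {
      k <- k + 1
      nutrients <- cfg$optimum * NA
      nutrients[] <- as.numeric(opt[1:10]) * exp(stats::rnorm(10, 0, sd_log))
      comp <- close_composition(nutrients)
      eps <- aitchison_distance(comp, opt)
      doses <- vapply(dose_levels, function(lv) sample(lv, 1), numeric(1))
      carry <- 0
      if (!is.na(prev_yield)) {
        z_dose <- (prev_dose_nk - cfg$dose_nk_ref[["mean"]]) / cfg$dose_nk_ref[["sd"]]
        z_yield <- (prev_yield - cfg$yield_ref[["mean"]]) / cfg$yield_ref[["sd"]]
        carry <- unname(cfg$beta_store * z_dose - cfg$beta_dep * z_yield)
      }
      noise <- stats::rnorm(1, 0, cfg$noise_sd)
      base <- site_yield_max[s] * site_modifier[s] * exp(-(eps / cfg$tau)^2)
      yield <- max(base + carry + noise, 0)
      cl <- clim[[paste(rg, yr)]]
      ss <- soil_site[[s]]
      row <- c(
        list(region = rg, site = sites[s], bed = bed_id[b], year = yr,
             cultivar = bed_cultivar[b], farming_system = ss$farming),
        stats::setNames(as.list(doses), paste0("dose_", names(dose_levels))),
        stats::setNames(as.list(as.numeric(comp[1:10])), nutrient_parts),
        list(soil_pH = ss$soil_pH, soil_C = ss$soil_C, soil_N = ss$soil_N),
        stats::setNames(as.list(ss$mehlich),
                        paste0("mehlich_", c("P", "K", "Ca", "Mg", "Cu", "Zn",
                                             "Mn", "Fe", "Al"))),
        stats::setNames(as.list(ss$texture),
                        c("clay", "silt", "sand_vc", "sand_co", "sand_me",
                          "sand_fi", "sand_vf")),
        stats::setNames(as.list(ss$bd), c("bd_0_10", "bd_10_20", "bd_20_30")),
        list(soil_series = site_series[s]),
        stats::setNames(as.list(cl$temp), paste0("temp_", month_labels)),
        stats::setNames(as.list(cl$prec), paste0("prec_", month_labels)),
        list(yield = yield)
      )
      rows[[k]] <- tibble::as_tibble(row)
      truth[[k]] <- tibble::tibble(
        eps = eps, yield_max = site_yield_max[s], modifier = site_modifier[s],
        carry = carry, noise = noise, base = base,
        !!!stats::setNames(as.list(as.numeric(opt)), paste0("opt_", tissue_parts))
      )
      prev_yield <- yield
      prev_dose_nk <- doses["N"] + doses["K"]
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "config") <- cfg
  out
}

#' Plant a single-nutrient defect into a generated record
#'
#' Multiplies one nutrient of the record's tissue composition by
#' `exp(log_magnitude)`, re-closes the composition, and re-evaluates the
#' yield under the planted model of the generating configuration (keeping
#' the record's original carryover term and noise draw). Used to test that
#' the diagnosis chain recovers a known nutrient imbalance.
#'
#' @param data A tibble from [generate_dataset()] (must still carry its
#'   `truth` and `config` attributes).
#' @param row Row index of the record to perturb.
#' @param nutrient One of the 10 nutrient labels (not `Fv`).
#' @param log_magnitude Log-scale size of the defect; positive plants an
#'   excess, negative a shortage; 0 leaves the record unchanged.
#' @return The modified one-row tibble, with attribute `planted` recording
#'   the nutrient and magnitude.
#' @export
plant_defect <- function(data, row, nutrient, log_magnitude) {
  truth <- attr(data, "truth"); cfg <- attr(data, "config")
  if (is.null(truth) || is.null(cfg)) {
    stop("data must be a freshly generated dataset carrying its truth ",
         "and config attributes", call. = FALSE)
  }
  if (!nutrient %in% nutrient_parts) {
    stop("nutrient must be one of the 10 measured nutrients, not ",
         nutrient, call. = FALSE)
  }
  rec <- data[row, ]
  tr <- truth[row, ]
  nut <- as.numeric(rec[1, nutrient_parts])
  names(nut) <- nutrient_parts
  nut[nutrient] <- nut[nutrient] * exp(log_magnitude)
  comp <- close_composition(nut)
  opt <- structure(as.numeric(tr[paste0("opt_", tissue_parts)]),
                   names = tissue_parts, class = "tissue_composition")
  eps <- aitchison_distance(comp, opt)
  base <- tr$yield_max * tr$modifier * exp(-(eps / cfg$tau)^2)
  rec[1, nutrient_parts] <- as.list(as.numeric(comp[1:10]))
  rec$yield <- max(base + tr$carry + tr$noise, 0)
  attr(rec, "planted") <- list(nutrient = nutrient,
                               log_magnitude = log_magnitude, eps = eps)
  rec
}

#' Extract the closed tissue composition of one observation row
#'
#' @param record A one-row data frame with the 10 nutrient columns.
#' @return A `tissue_composition`.
#' @export
record_composition <- function(record) {
  stopifnot(nrow(record) == 1)
  close_composition(structure(as.numeric(record[1, nutrient_parts]),
                              names = nutrient_parts))
}
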