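# shared fixture: a small Table-like bank of two successful specimens
two_specimen_bank <- function() {
  bank <- tibble::tibble(
    region = c("Quebec", "Wisconsin"),
    site = c("S01", "S02"), bed = c("B01", "B01"),
    year = c(2017L, 2017L),
    cultivar = c("Stevens", "Crimson Queen"),
    yield = c(stevens_yield_successful, crimson_yield_successful),
    flag = "TN"
  )
  comps <- rbind(stevens_successful, crimson_successful)
  for (nm in nutrient_parts) bank[[nm]] <- comps[, nm]
  structure(bank, cutoff = 40, class = c("reference_bank", class(bank)))
}

test_that("reference bank keeps TN specimens and optionally flags FN", {
  dat <- small_dataset(seed = 60)
  fit <- train_classifier(dat, folds = 5, seed = 5, num_trees = 200)
  quad <- confusion_partition(fit)
  bank <- build_reference_bank(quad)
  expect_equal(nrow(bank), quad$counts[["tn"]])
  expect_true(all(bank$yield > 40))
  expect_true(all(bank$flag == "TN"))

  bank_fn <- build_reference_bank(quad, include_fn = TRUE)
  expect_equal(nrow(bank_fn), quad$counts[["tn"]] + quad$counts[["fn"]])
  expect_setequal(unique(bank_fn$flag), c("TN", "FN"))
  expect_true(all(bank_fn$yield[bank_fn$flag == "FN"] <= 40))

  # an empty TN set asks for the FN fallback
  empty <- quad
  empty$index$tn <- integer(0)
  expect_error(build_reference_bank(empty), "include_fn")
})

test_that("nearest successful neighbour honours distance, ties, and filters", {
  bank <- two_specimen_bank()
  q <- close_composition(stevens_defective)
  nn <- nearest_successful(q, bank)
  expect_equal(nn$reference$cultivar, "Stevens")
  expect_equal(round(nn$distance, 2), 0.66)

  # a bank member queried against the bank returns itself at distance 0
  self <- nearest_successful(close_composition(stevens_successful), bank)
  expect_equal(self$distance, 0)
  expect_equal(self$reference$cultivar, "Stevens")

  # exact distance tie resolves to the higher yield
  twin <- bank[c(1, 1), ]
  twin$yield <- c(50, 60)
  twin$bed <- c("B01", "B02")
  class(twin) <- class(bank)
  tied <- nearest_successful(q, twin)
  expect_equal(tied$reference$yield, 60)

  expect_error(nearest_successful(q, bank, cultivar = "HyRed"),
               "cultivar=HyRed")
})

test_that("neighbour choice is invariant to bank row order", {
  dat <- small_dataset(seed = 61)
  fit <- train_classifier(dat, folds = 5, seed = 6, num_trees = 200)
  bank <- build_reference_bank(confusion_partition(fit))
  q <- close_composition(stevens_defective)
  a <- nearest_successful(q, bank)
  withr::with_seed(4, perm <- sample(nrow(bank)))
  shuffled <- bank[perm, ]
  class(shuffled) <- class(bank)
  b <- nearest_successful(q, shuffled)
  expect_equal(a$distance, b$distance)
  expect_equal(cranberrydx:::record_key(a$reference),
               cranberrydx:::record_key(b$reference))
})

test_that("local diagnosis reproduces the worked Quebec and Wisconsin cases", {
  bank <- two_specimen_bank()
  q_rec <- tibble::tibble(region = "Quebec", site = "S09", bed = "B09",
                          year = 2017L, cultivar = "Stevens",
                          yield = stevens_yield_defective)
  for (nm in nutrient_parts) q_rec[[nm]] <- stevens_defective[[nm]]
  rep_q <- diagnose_local(q_rec, bank)
  expect_equal(round(rep_q$distance, 2), 0.66)
  expect_equal(rep_q$attainable_yield, 57.6)
  expect_equal(rep_q$filters_used, "cultivar=Stevens")

  w_rec <- q_rec
  w_rec$region <- "Wisconsin"; w_rec$cultivar <- "Crimson Queen"
  for (nm in nutrient_parts) w_rec[[nm]] <- crimson_defective[[nm]]
  rep_w <- diagnose_local(w_rec, bank)
  expect_lt(abs(rep_w$distance - 1.64), 0.01)
  expect_equal(rep_w$attainable_yield, 62.8)

  # a specimen identical to a bank member diagnoses as balanced
  s_rec <- q_rec
  for (nm in nutrient_parts) s_rec[[nm]] <- stevens_successful[[nm]]
  rep_s <- diagnose_local(s_rec, bank)
  expect_equal(rep_s$distance, 0)
  expect_length(rep_s$excess, 0)
  expect_length(rep_s$shortage, 0)
})

test_that("regional diagnosis uses the re-closed mean of the bank", {
  bank <- two_specimen_bank()
  one <- bank[1, ]; class(one) <- class(bank)
  q <- close_composition(stevens_defective)
  reg1 <- diagnose_regional(q, one)
  loc1 <- diagnose_local(q, one, filter = "none")
  expect_equal(reg1$distance, loc1$distance)
  expect_null(reg1$attainable_yield)
  expect_equal(reg1$reference, "TN-average")

  dup <- bank[c(1, 1), ]; class(dup) <- class(bank)
  reg2 <- diagnose_regional(q, dup)
  expect_equal(reg2$distance, reg1$distance, tolerance = 1e-12)

  # the printed all-regions TN average row, by the distance oracle
  avg_bank <- one
  for (nm in nutrient_parts) avg_bank[[nm]] <- tn_average[[nm]]
  class(avg_bank) <- class(bank)
  reg3 <- diagnose_regional(q, avg_bank)
  expect_equal(reg3$distance,
               aitchison_distance(q, close_composition(tn_average)),
               tolerance = 1e-12)
  # geometric-mean variant coincides for a single-specimen bank
  reg4 <- diagnose_regional(q, avg_bank, mean_type = "geometric")
  expect_equal(reg4$distance, reg3$distance, tolerance = 1e-12)
})

test_that("quartile ranges follow the linear-interpolation definition", {
  bank <- two_specimen_bank()
  big <- bank[rep(1, 4), ]
  big$N <- c(1, 2, 3, 4)
  class(big) <- class(bank)
  qr <- quartile_ranges(big)
  expect_equal(qr$q1[qr$nutrient == "N"], 1.75)
  expect_equal(qr$q3[qr$nutrient == "N"], 3.25)
  # identical specimens collapse the interval
  same <- bank[rep(2, 5), ]; class(same) <- class(bank)
  qr2 <- quartile_ranges(same)
  expect_equal(qr2$q1, qr2$q3)
  expect_error(quartile_ranges(bank), "at least 4")

  dat <- small_dataset(seed = 62)
  fit <- train_classifier(dat, folds = 5, seed = 7, num_trees = 200)
  bank_s <- build_reference_bank(confusion_partition(fit))
  qr3 <- quartile_ranges(bank_s)
  expect_true(all(qr3$q1 > 0))
  expect_true(all(qr3$q1 < qr3$q3))
})
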