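test_that("closure computes the filling value by difference and validates input", {
  comp <- close_composition(stevens_defective)
  expect_s3_class(comp, "tissue_composition")
  expect_named(comp, tissue_parts)
  expect_equal(sum(comp), 1000, tolerance = 1e-9)
  # printed filling values of the worked specimens, 1 d.p.
  expect_equal(round(unname(comp["Fv"]), 1), 972.7)
  expect_equal(round(unname(close_composition(crimson_defective)["Fv"]), 1),
               968.9)
  expect_equal(round(unname(close_composition(crimson_successful)["Fv"]), 1),
               962.0)

  bad <- stevens_defective
  bad["Cu"] <- 0
  expect_error(close_composition(bad), "Cu")
  expect_error(close_composition(stevens_defective * 100), "infeasible")
  expect_error(close_composition(stevens_defective[1:9]), "10 nutrient")
})

test_that("clr is centred, scale-invariant, and matches the frozen oracle", {
  v <- clr_transform(close_composition(stevens_defective))
  expect_equal(sum(v), 0, tolerance = 1e-9)
  # arbitrary-precision oracle value for ln(N / geometric mean), frozen
  expect_equal(unname(v["N"]), 2.7540232558176104, tolerance = 1e-12)

  equal_comp <- structure(rep(1000 / 11, 11), names = tissue_parts,
                          class = "tissue_composition")
  expect_equal(unname(clr_transform(equal_comp)), rep(0, 11),
               tolerance = 1e-12)

  # multiplying the parts by a constant and re-closing changes nothing
  comp <- close_composition(stevens_defective)
  rescaled <- unclass(comp) * 3.7
  reclosed <- structure(rescaled / sum(rescaled) * 1000,
                        names = tissue_parts, class = "tissue_composition")
  expect_equal(clr_transform(reclosed), clr_transform(comp), tolerance = 1e-9)

  withr::with_seed(7, {
    sums <- replicate(1000, sum(clr_transform(random_composition())))
  })
  expect_true(all(abs(sums) < 1e-9))
})

test_that("ilr follows the balance formula and is isometric with clr", {
  # 3-part hand oracle embedded in the 11-part space is impractical; check
  # the printed formula directly on the default SBP's macro/micro contrast
  sbp <- default_sbp()
  expect_equal(nrow(sbp), 10)
  expect_equal(sum(sbp[1, nutrient_parts] == 1), 10)
  expect_equal(unname(sbp[1, "Fv"]), -1)
  expect_equal(sum(sbp[2, ] == 1), 5)
  expect_equal(sum(sbp[2, ] == -1), 5)

  comp <- close_composition(stevens_defective)
  b <- ilr_transform(comp, sbp)
  lg <- log(unclass(comp))
  gr <- exp(mean(lg[c("N", "P", "K", "Mg", "Ca")]))
  gs <- exp(mean(lg[c("B", "Cu", "Zn", "Mn", "Fe")]))
  expect_equal(unname(b["ilr2"]), sqrt(25 / 10) * log(gr / gs),
               tolerance = 1e-12)

  # norm equals the clr norm (orthonormality) for the worked composition
  expect_equal(sqrt(sum(b^2)), sqrt(sum(clr_transform(comp)^2)),
               tolerance = 1e-9)

  # toy symmetric balance: equal geometric means give a zero coordinate
  equal_comp <- structure(rep(1000 / 11, 11), names = tissue_parts,
                          class = "tissue_composition")
  expect_equal(unname(ilr_transform(equal_comp, sbp)), rep(0, 10),
               tolerance = 1e-12)
})

test_that("hand-evaluated balance on a grouped contrast matches sqrt(rs/(r+s))ln(Gr/Gs)", {
  # contrast isolating {N, P} against {K}: r = 2, s = 1 inside an SBP
  micro <- c("B", "Cu", "Zn", "Mn", "Fe")
  m <- matrix(0, 10, 11, dimnames = list(NULL, tissue_parts))
  m[1, nutrient_parts] <- 1; m[1, "Fv"] <- -1
  m[2, c("N", "P", "K")] <- 1; m[2, c("Mg", "Ca", micro)] <- -1
  m[3, c("N", "P")] <- 1; m[3, "K"] <- -1
  m[4, "N"] <- 1; m[4, "P"] <- -1
  m[5, "Mg"] <- 1; m[5, c("Ca", micro)] <- -1
  m[6, "Ca"] <- 1; m[6, micro] <- -1
  m[7, "B"] <- 1; m[7, micro[-1]] <- -1
  m[8, "Cu"] <- 1; m[8, micro[-(1:2)]] <- -1
  m[9, "Zn"] <- 1; m[9, micro[-(1:3)]] <- -1
  m[10, "Mn"] <- 1; m[10, "Fe"] <- -1
  sbp <- as_sbp(m)
  comp <- close_composition(stevens_defective)
  b <- ilr_transform(comp, sbp)
  gr <- exp(mean(log(comp[c("N", "P")])))
  expect_equal(unname(b["ilr3"]),
               sqrt(2 * 1 / 3) * log(gr / unname(comp["K"])),
               tolerance = 1e-12)
})

test_that("sbp validation rejects malformed partitions", {
  m <- unclass(default_sbp())
  expect_error(as_sbp(m[1:9, ]), "10 contrasts")
  m2 <- m; m2[3, ] <- m[3, ] * 0; m2[3, "N"] <- 1 # no -1 side
  expect_error(as_sbp(m2), "at least one")
  m3 <- m; m3[2, "Fv"] <- 1 # contrast 2 re-involves the already-split Fv
  expect_error(as_sbp(m3), "sequential binary partition")
  m4 <- m; m4[5, 5] <- 2
  expect_error(as_sbp(m4), "-1, 0, or \\+1")
})

test_that("Aitchison distance reproduces the worked diagnoses", {
  d_qs <- aitchison_distance(close_composition(stevens_defective),
                             close_composition(stevens_successful))
  d_wc <- aitchison_distance(close_composition(crimson_defective),
                             close_composition(crimson_successful))
  d_ny <- aitchison_distance(close_composition(stevens_defective),
                             close_composition(next_year_reference))
  expect_equal(round(d_qs, 2), 0.66)
  expect_equal(round(d_ny, 2), 0.99)
  # the printed 1.64 does not recompute exactly from the printed (rounded)
  # concentrations; agreement is to within one unit of the printed precision
  expect_lt(abs(d_wc - 1.64), 0.01)
  expect_equal(aitchison_distance(close_composition(stevens_defective),
                                  close_composition(stevens_defective)), 0)
})

test_that("ilr-space distance is SBP-invariant and satisfies metric axioms", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      a <- random_composition(); b <- random_composition()
      d_clr <- aitchison_distance(a, b)
      for (k in 1:5) {
        sbp <- random_sbp()
        d_ilr <- sqrt(sum((ilr_transform(a, sbp) - ilr_transform(b, sbp))^2))
        expect_equal(d_ilr, d_clr, tolerance = 1e-9)
      }
    }
    for (rep in 1:50) {
      a <- random_composition(); b <- random_composition()
      c_ <- random_composition()
      expect_equal(aitchison_distance(a, b), aitchison_distance(b, a),
                   tolerance = 1e-12)
      expect_lte(aitchison_distance(a, c_),
                 aitchison_distance(a, b) + aitchison_distance(b, c_) + 1e-12)
    }
  })
})

test_that("scale invariance holds for clr, ilr, and distances", {
  withr::with_seed(13, {
    a <- random_composition(); b <- random_composition()
  })
  resc <- function(comp, k) {
    v <- unclass(comp) * k
    structure(v / sum(v) * 1000, names = tissue_parts,
              class = "tissue_composition")
  }
  expect_equal(clr_transform(resc(a, 17)), clr_transform(a), tolerance = 1e-9)
  expect_equal(ilr_transform(resc(a, 17)), ilr_transform(a), tolerance = 1e-9)
  expect_equal(aitchison_distance(resc(a, 0.3), resc(b, 5)),
               aitchison_distance(a, b), tolerance = 1e-9)
})

test_that("perturbation ratios read as excess/shortage and invert exactly", {
  d <- close_composition(stevens_defective)
  ref <- close_composition(next_year_reference)
  p <- perturbation(d, ref)
  expect_equal(unname(p["P"]), 1.1 / 0.7, tolerance = 1e-12)
  expect_equal(unname(p["K"]), 4.0 / 4.8, tolerance = 1e-12)
  expect_true(all(p[c("P", "Ca", "Cu")] > 1))
  expect_true(all(p[c("K", "B", "Zn")] < 1))

  expect_equal(as.numeric(perturbation(d, d)), rep(1, 11))

  # perturbation(reference (*) p, reference) recovers p up to closure
  withr::with_seed(5, {
    ref2 <- random_composition()
    ratios <- exp(stats::rnorm(11, 0, 0.2))
  })
  shifted <- unclass(ref2) * ratios
  shifted <- structure(shifted / sum(shifted) * 1000, names = tissue_parts,
                       class = "tissue_composition")
  rec <- attr(perturbation(shifted, ref2), "closed")
  expect_equal(unname(rec), unname(ratios / sum(ratios) * 11),
               tolerance = 1e-9)
})

test_that("nutrient ranking orders by |log ratio| with direction tags", {
  d <- close_composition(stevens_defective)
  ref <- close_composition(next_year_reference)
  rk <- rank_nutrients(perturbation(d, ref))
  expect_equal(nrow(rk), 10)            # Fv excluded
  expect_false("Fv" %in% rk$nutrient)
  expect_true(all(diff(abs(rk$log_ratio)) <= 1e-12))
  # six largest departures, with the stated directions
  expect_setequal(rk$nutrient[1:6], c("Cu", "P", "Zn", "B", "Ca", "K"))
  dir <- setNames(rk$status, rk$nutrient)
  expect_true(all(dir[c("P", "Ca", "Cu")] == "excess"))
  expect_true(all(dir[c("K", "B", "Zn")] == "shortage"))

  all_ones <- perturbation(d, d)
  rk1 <- rank_nutrients(all_ones)
  expect_true(all(rk1$status == "balanced"))

  single <- unclass(all_ones)
  single["N"] <- 2
  rk2 <- rank_nutrients(structure(single, class = "perturbation_vector"))
  expect_equal(rk2$nutrient[1], "N")
  expect_equal(rk2$status[1], "excess")
  expect_true(all(rk2$status[-1] == "balanced"))
})
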