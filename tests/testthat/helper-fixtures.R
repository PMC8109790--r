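# Worked tissue-test fixtures: two defective specimens, their closest
# successful cultivar-specific neighbours, the all-regions true-negative
# average, and the next-year reference specimen. Concentrations in g/kg.
stevens_defective <- c(N = 12.1, P = 1.1, K = 4.0, Mg = 1.5, Ca = 8.2,
                       B = 0.030, Cu = 0.005, Zn = 0.030, Mn = 0.220,
                       Fe = 0.090)
stevens_successful <- c(N = 10.1, P = 1.0, K = 4.7, Mg = 1.9, Ca = 9.0,
                        B = 0.029, Cu = 0.006, Zn = 0.018, Mn = 0.222,
                        Fe = 0.097)
crimson_defective <- c(N = 10.2, P = 1.4, K = 6.9, Mg = 2.0, Ca = 9.3,
                       B = 0.024, Cu = 0.004, Zn = 0.017, Mn = 1.198,
                       Fe = 0.060)
crimson_successful <- c(N = 12.3, P = 1.5, K = 6.2, Mg = 2.8, Ca = 14.7,
                        B = 0.053, Cu = 0.003, Zn = 0.020, Mn = 0.339,
                        Fe = 0.074)
tn_average <- c(N = 10.6, P = 1.1, K = 5.4, Mg = 2.0, Ca = 8.9,
                B = 0.052, Cu = 0.004, Zn = 0.021, Mn = 0.355, Fe = 0.117)
next_year_reference <- c(N = 11.4, P = 0.7, K = 4.8, Mg = 1.5, Ca = 5.7,
                         B = 0.043, Cu = 0.003, Zn = 0.048, Mn = 0.197,
                         Fe = 0.077)

stevens_yield_defective <- 26.7
stevens_yield_successful <- 57.6
crimson_yield_defective <- 11.7
crimson_yield_successful <- 62.8

# random valid composition: log-normal spread around the TN average
random_composition <- function() {
  close_composition(tn_average * exp(stats::rnorm(10, 0, 0.3)))
}

# random valid SBP over the 11 parts by recursive random splitting
random_sbp <- function() {
  D <- length(tissue_parts)
  m <- matrix(0, nrow = D - 1, ncol = D, dimnames = list(NULL, tissue_parts))
  row <- 0
  split_group <- function(g) {
    if (length(g) < 2) return(invisible(NULL))
    k <- sample(seq_len(length(g) - 1), 1)
    plus <- sample(g, k)
    minus <- setdiff(g, plus)
    row <<- row + 1
    m[row, plus] <<- 1
    m[row, minus] <<- -1
    split_group(plus)
    split_group(minus)
  }
  split_group(seq_len(D))
  as_sbp(m)
}

# small generated dataset shared by model-level tests
small_dataset <- function(seed = 101, ...) {
  generate_dataset(generator_config(n_sites = 6, n_beds_per_site = 10,
                                    years = 2014:2018, seed = seed, ...))
}
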