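#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Part labels of the cranberry tissue composition
#'
#' The fixed order of the eleven parts of a closed tissue composition: the
#' five macronutrients, the five micronutrients (all in g/kg dry weight),
#' and the filling value `Fv` that completes the vector to the
#' 1000 g/kg measurement unit.
#'
#' @format Character vector of length 11.
#' @export
tissue_parts <- c("N", "P", "K", "Mg", "Ca", "B", "Cu", "Zn", "Mn", "Fe", "Fv")

#' The ten measured nutrients (tissue composition without the filling value)
#' @rdname tissue_parts
#' @export
nutrient_parts <- tissue_parts[1:10]

macro_parts <- c("N", "P", "K", "Mg", "Ca")
micro_parts <- c("B", "Cu", "Zn", "Mn", "Fe")

TOTAL_GKG <- 1000 # measurement unit, g/kg dry weight

#' Close a tissue test to the 1000 g/kg simplex
#'
#' Completes the ten measured nutrient concentrations with a filling value
#' `Fv = 1000 - sum(nutrients)` so the eleven parts sum to the dry-weight
#' measurement unit. All log-ratio operations in the package act on closed
#' compositions.
#'
#' @param x Numeric vector of the 10 nutrient concentrations in g/kg dry
#'   weight, ordered as `nutrient_parts` (names, if present, are checked).
#' @return A `tissue_composition`: a named numeric vector of length 11
#'   (parts in `tissue_parts` order) summing to 1000.
#' @examples
#' close_composition(c(12.1, 1.1, 4.0, 1.5, 8.2,
#'                     0.030, 0.005, 0.030, 0.220, 0.090))
#' @export
close_composition <- function(x) {
  x <- unlist(x, use.names = TRUE)
  if (length(x) == 11 && !is.null(names(x)) && identical(names(x), tissue_parts)) {
    # already closed: validate and pass through
    return(validate_composition(structure(as.numeric(x), names = tissue_parts,
                                          class = "tissue_composition")))
  }
  if (length(x) != 10) {
    stop("expected 10 nutrient concentrations, got ", length(x), call. = FALSE)
  }
  if (!is.null(names(x)) && !all(names(x) == nutrient_parts)) {
    stop("nutrient names must be in the fixed order: ",
         paste(nutrient_parts, collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(x)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop("non-positive or missing concentration for part(s): ",
         paste(nutrient_parts[bad], collapse = ", "), call. = FALSE)
  }
  if (sum(x) >= TOTAL_GKG) {
    stop("infeasible composition: nutrient sum ", format(sum(x)),
         " g/kg is not below the 1000 g/kg measurement unit", call. = FALSE)
  }
  comp <- c(x, TOTAL_GKG - sum(x))
  names(comp) <- tissue_parts
  class(comp) <- "tissue_composition"
  comp
}

validate_composition <- function(comp) {
  v <- as.numeric(comp)
  if (length(v) != 11) stop("a tissue composition has 11 parts", call. = FALSE)
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad)) {
    stop("non-positive concentration for part(s): ",
         paste(tissue_parts[bad], collapse = ", "), call. = FALSE)
  }
  if (abs(sum(v) - TOTAL_GKG) > 1e-6) {
    stop("parts must sum to 1000 g/kg (got ", format(sum(v)), ")", call. = FALSE)
  }
  comp
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat("Tissue composition (g/kg dry weight):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "tissue_composition")) return(x)
  close_composition(x)
}

#' Centred log-ratio transform
#'
#' `clr_i = ln(x_i / g(x))` with `g(x)` the geometric mean of all eleven
#' parts. clr vectors sum to zero; Euclidean distance between clr vectors is
#' the Aitchison distance between the compositions.
#'
#' @param comp A `tissue_composition` (or a 10-vector of nutrients, which is
#'   closed first).
#' @return Named numeric vector of length 11 summing to 0.
#' @export
clr_transform <- function(comp) {
  comp <- as_composition(comp)
  lg <- log(as.numeric(comp))
  out <- lg - mean(lg)
  names(out) <- tissue_parts
  out
}

#' Sequential binary partitions
#'
#' An SBP is a hierarchy of binary splits of the parts: an ordered set of
#' D-1 sign vectors (+1 numerator group, -1 denominator group, 0 not
#' involved) in which the first contrast involves all parts and every later
#' contrast splits one of the groups created before it. It defines an
#' orthonormal isometric log-ratio basis.
#'
#' `as_sbp()` validates a sign matrix (rows = contrasts, columns = the 11
#' parts); `default_sbp()` builds the package default: contrast 1 opposes
#' the ten nutrients to the filling value, contrast 2 opposes macronutrients
#' (N, P, K, Mg, Ca) to micronutrients (B, Cu, Zn, Mn, Fe), and the
#' remaining contrasts peel parts off left to right within each group.
#'
#' @param m Numeric matrix with entries in {-1, 0, +1}, one contrast per
#'   row, columns named (or ordered) as `tissue_parts`.
#' @return An object of class `sbp`: the validated sign matrix.
#' @export
as_sbp <- function(m) {
  m <- as.matrix(m)
  D <- length(tissue_parts)
  if (ncol(m) != D) {
    stop("an SBP over the tissue composition needs ", D, " columns", call. = FALSE)
  }
  if (is.null(colnames(m))) {
    colnames(m) <- tissue_parts
  } else if (!identical(colnames(m), tissue_parts)) {
    if (!setequal(colnames(m), tissue_parts)) {
      stop("SBP columns must be the 11 tissue parts", call. = FALSE)
    }
    m <- m[, tissue_parts, drop = FALSE]
  }
  if (nrow(m) != D - 1) {
    stop("an SBP has exactly D-1 = ", D - 1, " contrasts, got ", nrow(m),
         call. = FALSE)
  }
  if (!all(m %in% c(-1, 0, 1))) {
    stop("SBP entries must be -1, 0, or +1", call. = FALSE)
  }
  if (any(rowSums(m == 1) < 1) || any(rowSums(m == -1) < 1)) {
    stop("every contrast needs at least one +1 and one -1 part", call. = FALSE)
  }
  # hierarchy check: each contrast must split exactly one currently
  # unsplit group, starting from the full part set
  groups <- list(seq_len(D))
  for (i in seq_len(nrow(m))) {
    involved <- which(m[i, ] != 0)
    hit <- Find(function(g) setequal(g, involved), groups)
    if (is.null(hit)) {
      stop("contrast ", i, " does not split a previously unsplit group; ",
           "not a valid sequential binary partition", call. = FALSE)
    }
    groups <- Filter(function(g) !setequal(g, involved), groups)
    plus <- which(m[i, ] == 1); minus <- which(m[i, ] == -1)
    if (length(plus) > 1) groups <- c(groups, list(plus))
    if (length(minus) > 1) groups <- c(groups, list(minus))
  }
  structure(m, class = c("sbp", "matrix"))
}

#' @rdname as_sbp
#' @export
default_sbp <- function() {
  D <- length(tissue_parts)
  m <- matrix(0, nrow = D - 1, ncol = D, dimnames = list(NULL, tissue_parts))
  m[1, nutrient_parts] <- 1; m[1, "Fv"] <- -1
  m[2, macro_parts] <- 1; m[2, micro_parts] <- -1
  row <- 3
  for (grp in list(macro_parts, micro_parts)) {
    for (i in seq_len(length(grp) - 1)) {
      m[row, grp[i]] <- 1
      m[row, grp[(i + 1):length(grp)]] <- -1
      row <- row + 1
    }
  }
  as_sbp(m)
}

#' Isometric log-ratio coordinates under a sequential binary partition
#'
#' For contrast i with r parts in the numerator group and s in the
#' denominator group, `ilr_i = sqrt(r*s/(r+s)) * ln(G_r / G_s)` with G the
#' geometric means of the two groups. The coordinates are orthonormal, so
#' their Euclidean norm (and distances between compositions) equal the clr
#' norm whatever valid SBP is used.
#'
#' @param comp A `tissue_composition`.
#' @param sbp An `sbp` object; defaults to `default_sbp()`.
#' @return Numeric vector of length 10, one balance per contrast, named
#'   `ilr1..ilr10`.
#' @export
ilr_transform <- function(comp, sbp = default_sbp()) {
  comp <- as_composition(comp)
  if (!inherits(sbp, "sbp")) sbp <- as_sbp(sbp)
  lg <- log(as.numeric(comp))
  names(lg) <- tissue_parts
  out <- apply(sbp, 1, function(s) {
    r <- sum(s == 1); sneg <- sum(s == -1)
    gr <- mean(lg[s == 1]); gs <- mean(lg[s == -1])
    sqrt(r * sneg / (r + sneg)) * (gr - gs)
  })
  names(out) <- paste0("ilr", seq_along(out))
  out
}

#' Aitchison distance between two tissue compositions
#'
#' Euclidean distance in clr space over all eleven parts (equivalently, in
#' ilr coordinates under any valid SBP). This is the metric used to find the
#' nearest successful neighbour of a diagnosed specimen.
#'
#' @param a,b `tissue_composition`s (10-vectors are closed first).
#' @return Non-negative scalar, dimensionless.
#' @examples
#' d <- close_composition(c(12.1, 1.1, 4.0, 1.5, 8.2,
#'                          0.030, 0.005, 0.030, 0.220, 0.090))
#' s <- close_composition(c(10.1, 1.0, 4.7, 1.9, 9.0,
#'                          0.029, 0.006, 0.018, 0.222, 0.097))
#' round(aitchison_distance(d, s), 2)  # 0.66
#' @export
aitchison_distance <- function(a, b) {
  ca <- clr_transform(a); cb <- clr_transform(b)
  sqrt(sum((ca - cb)^2))
}

#' Perturbation vector between diagnosed and reference compositions
#'
#' The component-wise ratio `X_i / x*_i` of the diagnosed composition X to
#' the reference composition x*. Ratios above 1 read as relative excess of
#' that part in the diagnosed tissue, below 1 as relative shortage. The raw
#' ratios are the default interpretation surface; the re-closed variant
#' (ratios rescaled to sum to the number of parts, the formal simplex
#' perturbation-difference) is carried alongside as attribute `"closed"`.
#'
#' @param diagnosed,reference `tissue_composition`s sharing the fixed part
#'   order.
#' @return A `perturbation_vector`: named ratios of length 11 with attribute
#'   `closed` (the re-closed ratios).
#' @export
perturbation <- function(diagnosed, reference) {
  X <- as_composition(diagnosed); x <- as_composition(reference)
  p <- as.numeric(X) / as.numeric(x)
  names(p) <- tissue_parts
  closed <- p / sum(p) * length(p)
  structure(p, closed = closed, class = "perturbation_vector")
}

#' @export
print.perturbation_vector <- function(x, ...) {
  cat("Perturbation vector (diagnosed / reference):\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Rank nutrients by departure from balance
#'
#' Orders the parts of a perturbation vector by `|ln(ratio)|`, the magnitude
#' of the log departure from the balanced ratio of 1, and tags each part as
#' excess (ratio > 1), shortage (ratio < 1) or balanced
#' (`|ln ratio| <= tol`). The filling value is excluded by default: it is an
#' accounting part, not a nutrient.
#'
#' @param p A `perturbation_vector`.
#' @param exclude_filling Drop `Fv` from the ranking (default `TRUE`).
#' @param tol Balance tolerance on `|ln(ratio)|` (default 0.01, i.e. about a
#'   1 percent departure).
#' @return A tibble with columns `nutrient`, `ratio`, `log_ratio`, `status`,
#'   sorted by `abs(log_ratio)` descending.
#' @export
rank_nutrients <- function(p, exclude_filling = TRUE, tol = 0.01) {
  stopifnot(inherits(p, "perturbation_vector") || is.numeric(p))
  r <- unclass(p)
  if (exclude_filling) r <- r[setdiff(names(r), "Fv")]
  lr <- log(r)
  status <- ifelse(abs(lr) <= tol, "balanced",
                   ifelse(lr > 0, "excess", "shortage"))
  out <- tibble::tibble(nutrient = names(r), ratio = unname(r),
                        log_ratio = unname(lr), status = unname(status))
  dplyr::arrange(out, dplyr::desc(abs(.data$log_ratio)))
}
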