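#' Ratio-of-averages descent estimate
#'
#' The basic estimation step: for per-variant target sharing `a_y` and
#' reference sharing `a_r`, the estimate of the descent measure of the target
#' pair(s) relative to the reference set is
#' `sum(a_y - a_r) / sum(1 - a_r)`, with the sums taken over the variants
#' where both statistics are defined. Summing numerator and denominator over
#' variants before dividing (rather than averaging per-variant ratios) is
#' what makes the multi-locus estimator converge to the compound parameter
#' `(theta_Y - theta_R) / (1 - theta_R)`.
#'
#' @param a_y,a_r Equal-length numeric vectors of per-variant sharing
#'   statistics for the target and the reference set (`NA`s dropped pairwise).
#' @param target,reference Optional tags recorded in the output.
#' @return A one-row tibble with `target`, `value`, `num`, `den`,
#'   `n_variants`; `value = num / den`.
#' @examples
#' ratio_estimate(c(1, 0.5), c(0.5, 0.5))  # 0.5
#' @export
ratio_estimate <- function(a_y, a_r, target = "target", reference = "reference") {
  if (length(a_y) != length(a_r)) {
    abort("`a_y` and `a_r` must have the same length (one value per variant).")
  }
  ok <- !is.na(a_y) & !is.na(a_r)
  num <- sum(a_y[ok] - a_r[ok])
  den <- sum(1 - a_r[ok])
  if (!sum(ok) || den <= 0) {
    abort("monomorphic reference: sum(1 - a_r) is zero, the reference pairs share alleles at every variant.")
  }
  out <- tibble(target = target, value = num / den, num = num, den = den,
                n_variants = sum(ok))
  attr(out, "reference") <- reference
  out
}

resolve_reference <- function(comp, reference, panel) {
  switch(reference,
    whole_study = comp$A_S_star,
    between_populations = {
      if (length(comp$pops) < 2) {
        abort("between-population reference requires >=2 populations.")
      }
      comp$A_B
    },
    within_population = abort("within_population reference is resolved per population."),
    abort(sprintf("unknown reference set '%s'.", reference))
  )
}

ratio_rows <- function(Y, V, a_r) {
  # per-row ratio estimates: Y numerator statistics (rows x variants, masked
  # to 0 off V), V validity mask, a_r per-variant reference (NA -> excluded)
  keep <- !is.na(a_r)
  Vk <- V & rep(keep, each = nrow(V))
  Ar <- ifelse(keep, a_r, 0)
  num <- rowSums(Vk * (Y - rep(Ar, each = nrow(Y))), na.rm = TRUE)
  den <- rowSums(Vk * rep(1 - Ar, each = nrow(V)))
  list(num = num, den = den, n = rowSums(Vk))
}

#' Allele-sharing inbreeding estimates
#'
#' Estimates the inbreeding coefficient of every individual as the sharing of
#' its own two (or more) alleles relative to a reference set of allele pairs:
#' `f_j = sum(A_j - A_R) / sum(1 - A_R)` over typed variants. The reference
#' can be the pairs of distinct individuals of the individual's own
#' population (`"within_population"`), all pairs of distinct individuals in
#' the study (`"whole_study"`), or pairs of alleles in distinct populations
#' (`"between_populations"`). Estimates can be negative: the individual is
#' then less homozygous than the reference pairs share.
#'
#' @param panel A diploid-or-higher [build_panel()] object.
#' @param reference Reference set of allele pairs.
#' @return An `as_inbreeding` tibble with columns `id`, `pop`, `value`,
#'   `num`, `den`, `n_variants`; use [glance.as_inbreeding()] for the
#'   population and study averages (the population averages are pooled
#'   ratios, equivalent to weighting per-population averages by
#'   `1 - A_S^i`).
#' @export
as_inbreeding <- function(panel,
                          reference = c("within_population", "whole_study",
                                        "between_populations")) {
  stopifnot_panel(panel)
  reference <- match.arg(reference)
  if (panel$ploidy < 2L) abort("inbreeding is undefined for haploid panels.")
  comp <- allele_sharing(panel)
  n <- nrow(panel$dosages)
  W <- ifelse(is.na(comp$within), 0, comp$within)
  V0 <- comp$typed & !is.na(comp$within)

  if (reference == "within_population") {
    num <- den <- nv <- numeric(n)
    for (i in seq_along(comp$pops)) {
      rows <- which(panel$pops == comp$pops[i])
      if (length(rows) < 2) {
        abort(sprintf(
          "within_population reference needs >=2 individuals; population '%s' has %d.",
          comp$pops[i], length(rows)))
      }
      rr <- ratio_rows(W[rows, , drop = FALSE], V0[rows, , drop = FALSE],
                       comp$A_S_pop[i, ])
      num[rows] <- rr$num; den[rows] <- rr$den; nv[rows] <- rr$n
    }
  } else {
    a_r <- resolve_reference(comp, reference, panel)
    rr <- ratio_rows(W, V0, a_r)
    num <- rr$num; den <- rr$den; nv <- rr$n
  }
  if (any(den <= 0)) {
    abort("monomorphic reference: reference allele pairs share at every usable variant.")
  }
  out <- tibble(id = panel$individual_ids, pop = as.character(panel$pops),
                value = num / den, num = num, den = den, n_variants = nv)
  class(out) <- c("as_inbreeding", class(out))
  attr(out, "reference") <- reference
  attr(out, "components") <- comp
  out
}

#' Population and study average inbreeding
#'
#' @param x An [as_inbreeding()] result.
#' @param ... Unused.
#' @return A tibble with one row per population plus a study row: pooled
#'   ratio-of-sums averages of the individual estimates.
#' @exportS3Method generics::glance
glance.as_inbreeding <- function(x, ...) {
  comp <- attr(x, "components")
  reference <- attr(x, "reference")
  a_r_study <- switch(reference,
    within_population = comp$A_S,
    whole_study = comp$A_S_star,
    between_populations = comp$A_B)
  a_i_study <- switch(reference,
    whole_study = comp$A_I_star,
    comp$A_I)
  rows <- purrr::map_dfr(seq_along(comp$pops), function(i) {
    a_r <- if (reference == "within_population") comp$A_S_pop[i, ]
           else switch(reference, whole_study = comp$A_S_star,
                       between_populations = comp$A_B)
    ratio_estimate(comp$A_I_pop[i, ], a_r,
                   target = comp$pops[i], reference = reference)
  })
  study <- ratio_estimate(a_i_study, a_r_study, target = ".study",
                          reference = reference)
  out <- dplyr::bind_rows(rows, study)
  names(out)[1] <- "pop"
  attr(out, "reference") <- reference
  out
}

#' Allele-sharing kinship matrix
#'
#' Estimates pairwise kinship (coancestry relative to a reference set) for
#' every pair of individuals, `k_jj' = sum(A_jj' - A_R) / sum(1 - A_R)`, and
#' assembles the kinship matrix with diagonal `(1 + f_j) / 2`. With the
#' within-population reference the matrix is block-diagonal by population
#' (cross-population entries are `NA`) and the average off-diagonal entry of
#' each block is exactly zero; with the whole-study reference the average
#' over all pairs of individuals is exactly zero (complete data).
#'
#' @inheritParams as_inbreeding
#' @return An `as_kinship` object: list with `entries` (symmetric matrix),
#'   `estimates` (long tibble of distinct pairs with `num`, `den`),
#'   `inbreeding` (the [as_inbreeding()] tibble used for the diagonal),
#'   `reference`, `family = "AS"`.
#' @export
as_kinship <- function(panel,
                       reference = c("within_population", "whole_study",
                                     "between_populations")) {
  stopifnot_panel(panel)
  reference <- match.arg(reference)
  comp <- allele_sharing(panel)
  n <- nrow(panel$dosages)
  P <- panel$dosages / panel$ploidy
  typed <- comp$typed

  pair_sums <- function(rows, a_r) {
    keep <- !is.na(a_r)
    V <- typed[rows, , drop = FALSE] & rep(keep, each = length(rows))
    Pm <- ifelse(V, P[rows, , drop = FALSE], 0)
    Qm <- ifelse(V, 1 - P[rows, , drop = FALSE], 0)
    N <- Pm %*% t(Pm) + Qm %*% t(Qm)
    Ar <- ifelse(keep, a_r, 0)
    SR <- (V * rep(Ar, each = length(rows))) %*% t(V)
    C <- V %*% t(V)
    list(num = N - SR, den = C - SR, n = C)
  }

  K <- matrix(NA_real_, n, n,
              dimnames = list(panel$individual_ids, panel$individual_ids))
  numM <- denM <- nM <- matrix(NA_real_, n, n)

  if (reference == "within_population") {
    for (i in seq_along(comp$pops)) {
      rows <- which(panel$pops == comp$pops[i])
      if (length(rows) < 2) {
        abort(sprintf(
          "within_population reference needs >=2 individuals; population '%s' has %d.",
          comp$pops[i], length(rows)))
      }
      ps <- pair_sums(rows, comp$A_S_pop[i, ])
      K[rows, rows] <- ps$num / ps$den
      numM[rows, rows] <- ps$num; denM[rows, rows] <- ps$den
      nM[rows, rows] <- ps$n
    }
  } else {
    a_r <- resolve_reference(comp, reference, panel)
    ps <- pair_sums(seq_len(n), a_r)
    K <- ps$num / ps$den
    dimnames(K) <- list(panel$individual_ids, panel$individual_ids)
    numM <- ps$num; denM <- ps$den; nM <- ps$n
  }

  inb <- if (panel$ploidy >= 2L) as_inbreeding(panel, reference) else NULL
  if (!is.null(inb)) diag(K) <- (1 + inb$value) / 2

  ut <- which(upper.tri(K), arr.ind = TRUE)
  est <- tibble(
    id1 = panel$individual_ids[ut[, 1]], id2 = panel$individual_ids[ut[, 2]],
    pop1 = as.character(panel$pops)[ut[, 1]],
    pop2 = as.character(panel$pops)[ut[, 2]],
    value = numM[ut] / denM[ut], num = numM[ut], den = denM[ut],
    n_variants = nM[ut])

  structure(list(entries = K, estimates = est, inbreeding = inb,
                 reference = reference, family = "AS"),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d x %d, family %s, reference %s\n",
              nrow(x$entries), ncol(x$entries), x$family, x$reference))
  off <- x$estimates$value
  cat(sprintf("  off-diagonal kinship: mean %.4g, range [%.4g, %.4g]\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kinship_matrix <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.kinship_matrix <- function(x, ...) {
  tibble(family = x$family, reference = x$reference,
         n_individuals = nrow(x$entries),
         mean_kinship = mean(x$estimates$value, na.rm = TRUE),
         mean_inbreeding = if (!is.null(x$inbreeding))
           mean(x$inbreeding$value) else NA_real_)
}

#' Population-level F-statistics from allele sharing
#'
#' Estimates the population-structure descent measures with alleles in
#' distinct populations as the reference set: overall `F_IB` (inbreeding
#' relative to between-population pairs) and `F_SB` (the allele-sharing
#' analogue of Wright's FST), their population-specific versions, the
#' pairwise between-population kinships `k_SB^{ii'}` (whose average over
#' population pairs is exactly zero), and the two-population `F_SBp^{ii'}`
#' computed using only the pair of populations.
#'
#' @param panel A [build_panel()] object with at least two populations.
#' @return An `as_fst` object: list of tibbles `overall`, `by_pop`,
#'   `by_pair`, plus `n_variants`.
#' @export
as_fst <- function(panel) {
  stopifnot_panel(panel)
  comp <- allele_sharing(panel)
  if (length(comp$pops) < 2) {
    abort("between-population reference requires >=2 populations.")
  }
  genotypic <- panel$ploidy >= 2L

  overall <- dplyr::bind_rows(
    if (genotypic) ratio_estimate(comp$A_I, comp$A_B, "F_IB", "between_populations"),
    ratio_estimate(comp$A_S, comp$A_B, "F_SB", "between_populations"))
  names(overall)[1] <- "statistic"

  by_pop <- purrr::map_dfr(seq_along(comp$pops), function(i) {
    res <- dplyr::bind_rows(
      if (genotypic) ratio_estimate(comp$A_I_pop[i, ], comp$A_B, "F_IB_i"),
      ratio_estimate(comp$A_S_pop[i, ], comp$A_B, "F_SB_i"))
    res$pop <- comp$pops[i]
    res
  })
  names(by_pop)[1] <- "statistic"
  by_pop <- dplyr::relocate(by_pop, "pop")

  keys <- rownames(comp$A_B_pair)
  by_pair <- purrr::map_dfr(seq_along(keys), function(ii) {
    ps <- strsplit(keys[ii], "|", fixed = TRUE)[[1]]
    i1 <- match(ps[1], comp$pops); i2 <- match(ps[2], comp$pops)
    between <- ratio_estimate(comp$A_B_pair[ii, ], comp$A_B, "k_SB_iip")
    pairwise <- ratio_estimate(
      (comp$A_S_pop[i1, ] + comp$A_S_pop[i2, ]) / 2,
      comp$A_B_pair[ii, ], "F_SBp_iip")
    res <- dplyr::bind_rows(between, pairwise)
    res$pop1 <- ps[1]; res$pop2 <- ps[2]
    res
  })
  names(by_pair)[1] <- "statistic"
  by_pair <- dplyr::relocate(by_pair, "pop1", "pop2")

  structure(list(overall = overall, by_pop = by_pop, by_pair = by_pair,
                 n_variants = max(overall$n_variants)),
            class = "as_fst")
}

#' @export
print.as_fst <- function(x, ...) {
  cat(sprintf("<as_fst> %d variants\n", x$n_variants))
  for (i in seq_len(nrow(x$overall))) {
    cat(sprintf("  %s = %.6f\n", x$overall$statistic[i], x$overall$value[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.as_fst <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$overall, level = "overall"),
    dplyr::mutate(x$by_pop, level = "population"),
    dplyr::mutate(x$by_pair, level = "population_pair"))
}

#' @exportS3Method generics::glance
glance.as_fst <- function(x, ...) {
  tidyr::pivot_wider(x$overall[c("statistic", "value")],
                     names_from = "statistic", values_from = "value") |>
    dplyr::mutate(n_variants = x$n_variants)
}

#' Re-express estimates relative to a different reference set
#'
#' Changing the reference set applies a positive-slope affine map to
#' allele-sharing estimates, so their ranking never changes:
#' `k' = [(1 - A_R) k + (A_R - A_R')] / (1 - A_R')`. With
#' `new_reference = "minimum"` the new reference average is set to the
#' smallest target sharing, so the smallest estimate becomes exactly zero and
#' all others positive (the convention of minimum-referenced estimators).
#'
#' @param estimates A tibble of descent estimates carrying `value`, `num`,
#'   `den`, `n_variants` columns (as produced by the estimator functions).
#' @param new_reference Either `"minimum"` or a numeric scalar: the average
#'   per-variant sharing of the new reference set (must be < 1).
#' @return The same tibble with `value`, `num`, `den` transformed.
#' @export
rescale_reference <- function(estimates, new_reference = "minimum") {
  need <- c("value", "num", "den", "n_variants")
  if (!all(need %in% names(estimates))) {
    abort("`estimates` must carry value/num/den/n_variants columns.")
  }
  L <- estimates$n_variants
  a_y <- 1 - (estimates$den - estimates$num) / L   # average target sharing
  if (identical(new_reference, "minimum")) {
    a_rp <- min(a_y)
  } else {
    a_rp <- as.numeric(new_reference)
    if (length(a_rp) != 1 || is.na(a_rp)) {
      abort("`new_reference` must be \"minimum\" or a single number.")
    }
  }
  if (a_rp >= 1) abort("new reference sharing must be < 1.")
  out <- estimates
  out$num <- L * (a_y - a_rp)
  out$den <- L * (1 - a_rp)
  out$value <- out$num / out$den
  attr(out, "reference") <- if (identical(new_reference, "minimum"))
    "minimum" else sprintf("custom(A_R'=%g)", a_rp)
  out
}

#' F-statistics from descent-measure parameters
#'
#' Parameter-level algebra: given per-population inbreeding `F_I^i`,
#' within-population coancestries `theta_S^i`, the between-population average
#' `theta_B`, and sample sizes, returns both the classical Wright-form
#' F-statistics (which involve random-pair measures `theta_W`, `theta_T` and
#' therefore depend on the numbers of individuals and populations) and the
#' allele-sharing-form statistics (which contrast distinct-individual and
#' distinct-population pairs and are free of study dimensions). Both forms
#' satisfy the product identity `(1 - F_IT) = (1 - F_ST)(1 - F_IS)`.
#'
#' @param F_I Numeric vector of per-population average inbreeding.
#' @param theta_S Numeric vector of per-population average coancestries.
#' @param theta_B Average between-population descent measure (scalar).
#' @param n Per-population sample sizes (recycled to `length(F_I)`).
#' @return A tibble with columns `statistic` (`F_IT`/`F_IS`/`F_ST` and
#'   `F_IB`/`F_IS`/`F_SB`), `form` (`"wright"` / `"allele_sharing"`) and
#'   `value`; the intermediate `theta_W`, `theta_T` averages are attached as
#'   attributes.
#' @examples
#' fstats_from_theta(F_I = 0.1, theta_S = 0.1, theta_B = 0.05, n = 20)
#' @export
fstats_from_theta <- function(F_I, theta_S, theta_B, n) {
  r <- length(F_I)
  if (length(theta_S) != r) abort("`F_I` and `theta_S` must have equal length.")
  n <- rep_len(n, r)
  if (any(c(F_I, theta_S, theta_B) < -1) || any(c(F_I, theta_S, theta_B) > 1)) {
    abort("descent measures must lie in [-1, 1].")
  }
  theta_I <- (1 + F_I) / 2
  theta_W_i <- theta_S + (theta_I - theta_S) / n
  theta_W <- mean(theta_W_i)
  theta_T <- theta_B + (theta_W - theta_B) / r
  FI <- mean(F_I); thS <- mean(theta_S)
  if (theta_T >= 1 || theta_B >= 1) {
    abort("theta_T and theta_B must be < 1 for the ratios to exist.")
  }
  out <- tibble(
    statistic = c("F_IT", "F_IS", "F_ST", "F_IB", "F_IS", "F_SB"),
    form = rep(c("wright", "allele_sharing"), each = 3),
    value = c((FI - theta_T) / (1 - theta_T),
              (FI - theta_W) / (1 - theta_W),
              (theta_W - theta_T) / (1 - theta_T),
              (FI - theta_B) / (1 - theta_B),
              (FI - thS) / (1 - thS),
              (thS - theta_B) / (1 - theta_B)))
  attr(out, "theta_W") <- theta_W
  attr(out, "theta_T") <- theta_T
  out
}

#' Self-coancestry of an individual
#'
#' Descent measure for two alleles drawn with replacement from one
#' individual: `[1 + (k - 1) F] / k` at ploidy `k`. For diploids this is the
#' familiar `(1 + F) / 2`; for haploids (`k = 1`) inbreeding is undefined and
#' the self-coancestry is identically 1, whatever `f` is supplied.
#'
#' @param f Inbreeding coefficient(s).
#' @param ploidy Ploidy (>= 1).
#' @return Numeric self-coancestry values.
#' @examples
#' self_coancestry(0.25)              # 0.625
#' self_coancestry(0.9, ploidy = 1)   # 1
#' @export
self_coancestry <- function(f, ploidy = 2) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 1L) abort("`ploidy` must be a positive integer.")
  (1 + (ploidy - 1) * f) / ploidy
}
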