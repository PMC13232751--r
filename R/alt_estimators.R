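#' Standard (dosage-centered) kinship matrix
#'
#' The widely used quantitative-genetics kinship estimator built from
#' centered allele dosages and sample allele frequencies: per variant,
#' `(X_j - 2p)(X_j' - 2p) / (4 p (1 - p))` with `p` the sample frequency
#' computed from the panel itself. `mode = "average_of_ratios"` averages the
#' per-variant ratios (skipping fixed variants, where the ratio is
#' undefined); `mode = "ratio_of_averages"` sums numerators and denominators
#' over variants before dividing, which is the stable form. The diagonal is
#' the `j = j'` case of the same formula, with no ad-hoc adjustment.
#'
#' Unlike allele-sharing kinship, this estimator's large-sample expectation
#' is `k_jj' - kbar_j - kbar_j'` (the pair's kinship minus each member's
#' average kinship with the sample), so its rankings change with the
#' reference sample; it equals a double-centered allele-sharing matrix in
#' large samples.
#'
#' @param panel A diploid [build_panel()] object.
#' @param mode Multi-variant combination rule.
#' @return A `kinship_matrix` object with `family = "standard"`.
#' @export
standard_kinship <- function(panel,
                             mode = c("ratio_of_averages", "average_of_ratios")) {
  stopifnot_panel(panel)
  stopifnot_diploid(panel, "standard kinship")
  mode <- match.arg(mode)
  D <- panel$dosages
  typed <- !is.na(D)
  m <- colSums(typed)
  p <- colSums(D, na.rm = TRUE) / (2 * m)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("all variants are monomorphic in this panel.")

  if (mode == "ratio_of_averages") {
    Y <- ifelse(typed, sweep(D, 2, 2 * p), 0)
    num <- Y %*% t(Y)
    wden <- 4 * p * (1 - p)
    den <- (typed * rep(wden, each = nrow(D))) %*% t(typed)
    K <- num / den
  } else {
    wden <- 4 * p * (1 - p)
    Ys <- ifelse(typed, sweep(D, 2, 2 * p), 0)
    Ys <- sweep(Ys[, poly, drop = FALSE], 2, sqrt(wden[poly]), "/")
    num <- Ys %*% t(Ys)
    cnt <- typed[, poly, drop = FALSE] %*% t(typed[, poly, drop = FALSE])
    K <- num / cnt
  }
  dimnames(K) <- list(panel$individual_ids, panel$individual_ids)

  ut <- which(upper.tri(K), arr.ind = TRUE)
  est <- tibble(
    id1 = panel$individual_ids[ut[, 1]], id2 = panel$individual_ids[ut[, 2]],
    pop1 = as.character(panel$pops)[ut[, 1]],
    pop2 = as.character(panel$pops)[ut[, 2]],
    value = K[ut])
  structure(list(entries = K, estimates = est, inbreeding = NULL,
                 reference = "sample_frequencies", family = "standard",
                 mode = mode),
            class = "kinship_matrix")
}

#' KING-robust pairwise kinship
#'
#' The heterozygosity-referenced pairwise estimator: for each pair of
#' individuals, sharing between them relative to the average of their own
#' within-individual sharings,
#' `[A_jj' - (A_j + A_j')/2] / [1 - (A_j + A_j')/2]`, combined over variants
#' by summing numerator and denominator separately over the variants where
#' both are typed. Its expectation is
#' `(theta_jj' - Fbar) / (1 - Fbar)` with `Fbar` the mean of the two
#' inbreeding coefficients: kinship relative to the pair's own inbreeding,
#' which is why inbred pairs get strongly negative values and rankings are
#' not preserved across pairs with different inbreeding.
#'
#' @param panel A diploid [build_panel()] object.
#' @return A `kinship_matrix` object with `family = "KING"`; the diagonal is
#'   `NA` (the estimator is defined for pairs only).
#' @export
king_robust <- function(panel) {
  stopifnot_panel(panel)
  stopifnot_diploid(panel, "KING-robust kinship")
  D <- panel$dosages
  typed <- !is.na(D)
  n <- nrow(D)
  P <- D / 2
  Pm <- ifelse(typed, P, 0)
  Qm <- ifelse(typed, 1 - P, 0)
  A_pair <- Pm %*% t(Pm) + Qm %*% t(Qm)          # sum A_jj' over co-typed
  a <- ifelse(typed, (D - 1)^2, 0)
  half <- (a %*% t(typed) + typed %*% t(a)) / 2  # sum (A_j + A_j')/2
  C <- typed %*% t(typed)
  num <- A_pair - half
  den <- C - half
  off <- upper.tri(den)
  if (any(den[off] <= 0)) {
    bad <- which(den <= 0 & off, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "no heterozygosity: individuals '%s' and '%s' are homozygous at every shared variant.",
      panel$individual_ids[bad[1]], panel$individual_ids[bad[2]]))
  }
  K <- num / den
  diag(K) <- NA_real_
  dimnames(K) <- list(panel$individual_ids, panel$individual_ids)
  ut <- which(upper.tri(K), arr.ind = TRUE)
  est <- tibble(
    id1 = panel$individual_ids[ut[, 1]], id2 = panel$individual_ids[ut[, 2]],
    pop1 = as.character(panel$pops)[ut[, 1]],
    pop2 = as.character(panel$pops)[ut[, 2]],
    value = K[ut], num = num[ut], den = den[ut], n_variants = C[ut])
  structure(list(entries = K, estimates = est, inbreeding = NULL,
                 reference = "pair_heterozygosity", family = "KING"),
            class = "kinship_matrix")
}

#' Li-Horvitz heterozygosity-based inbreeding estimate
#'
#' The classical estimate `1 - H_obs / (2 p (1 - p))` per population, with
#' the observed heterozygote proportion in the numerator and the sample
#' allele frequencies in the denominator, combined over variants by summing
#' `H_obs` and `2 p (1 - p)` separately. Despite its usual reading as an
#' estimator of the population inbreeding coefficient `F_I`, its large-sample
#' expectation is the within-population relative inbreeding
#' `f_IS = (F_I - theta_S) / (1 - theta_S)`: inbreeding relative to the
#' population's own distinct-individual allele pairs.
#'
#' @param panel A diploid [build_panel()] object.
#' @param pop Optional population label(s) to restrict to.
#' @return A tibble with one row per population: `pop`, `value`,
#'   `h_obs_sum`, `h_exp_sum`, `n_variants`.
#' @export
li_horvitz <- function(panel, pop = NULL) {
  stopifnot_panel(panel)
  stopifnot_diploid(panel, "the Li-Horvitz estimator")
  comp <- allele_sharing(panel)
  pops <- if (is.null(pop)) comp$pops else intersect(comp$pops, pop)
  if (!length(pops)) abort("no matching population.")
  purrr::map_dfr(pops, function(pp) {
    i <- match(pp, comp$pops)
    h_obs <- 1 - comp$A_I_pop[i, ]
    p <- comp$p_pop[i, ]
    h_exp <- 2 * p * (1 - p)
    ok <- !is.na(h_obs) & !is.na(h_exp)
    if (!any(ok) || sum(h_exp[ok]) <= 0) {
      abort(sprintf("all variants are monomorphic in population '%s'.", pp))
    }
    tibble(pop = pp, value = 1 - sum(h_obs[ok]) / sum(h_exp[ok]),
           h_obs_sum = sum(h_obs[ok]), h_exp_sum = sum(h_exp[ok]),
           n_variants = sum(ok))
  })
}

#' Nei's FST estimators
#'
#' `version = "1973"` is the original sample-heterozygosity contrast
#' `(H_T - H_S) / H_T` with `H_S` the average within-population
#' `2 p_i (1 - p_i)` and `H_T = 2 pbar (1 - pbar)` from the frequency
#' averaged over populations; its expectation depends on the number of
#' populations sampled (it targets the Wright-form `F_ST`, not the
#' allele-sharing `F_SB`). `version = "1986"` is the later revision that
#' replaces random-pair heterozygosities by distinct-individual and
#' distinct-population ones, `H_S = 1 - A_S`, `H_T = 1 - A_B`: it is
#' algebraically identical to the allele-sharing `F_SB` of [as_fst()].
#' Both versions sum numerators and denominators over variants before
#' dividing.
#'
#' @param panel A [build_panel()] object with >= 2 populations.
#' @param version Which definition to evaluate.
#' @return A one-row tibble with `statistic`, `version`, `value`,
#'   `n_variants`.
#' @export
nei_fst <- function(panel, version = c("1986", "1973")) {
  stopifnot_panel(panel)
  version <- match.arg(version)
  comp <- allele_sharing(panel)
  r <- length(comp$pops)
  if (r < 2) abort("Nei's FST requires >=2 populations.")
  if (version == "1986") {
    est <- ratio_estimate(comp$A_S, comp$A_B, "F_ST_nei1986")
    out <- tibble(statistic = "F_ST", version = "1986", value = est$value,
                  n_variants = est$n_variants)
  } else {
    hs <- 2 * comp$p_pop * (1 - comp$p_pop)
    H_S <- colMeans(hs, na.rm = TRUE)
    H_S[colSums(!is.na(hs)) == 0] <- NA_real_
    pbar <- colMeans(comp$p_pop, na.rm = TRUE)
    H_T <- 2 * pbar * (1 - pbar)
    ok <- !is.na(H_S) & !is.na(H_T)
    if (!any(ok) || sum(H_T[ok]) <= 0) {
      abort("total heterozygosity is zero: all variants fixed for one allele.")
    }
    out <- tibble(statistic = "F_ST", version = "1973",
                  value = (sum(H_T[ok]) - sum(H_S[ok])) / sum(H_T[ok]),
                  n_variants = sum(ok))
  }
  out
}

#' Weir-Cockerham (1984) ANOVA F-statistics
#'
#' The genotypic analysis-of-variance estimators: per variant, the total
#' indicator variance is decomposed into between-population (`a`),
#' between-individual-within-population (`b`) and within-individual (`c`)
#' components using the sample-size-weighted mean squares of the original
#' layout; components are summed over variants before the ratios
#' `F_ST = a / (a + b + c)`, `F_IS = b / (b + c)`,
#' `F_IT = (a + b) / (a + b + c)` are formed. With equal sample sizes in all
#' populations `F_ST` is algebraically identical to the allele-sharing
#' `F_SB`; with unequal sizes the sample-size weighting makes it differ.
#'
#' @param panel A diploid [build_panel()] object with >= 2 populations.
#' @return A tibble with rows `F_ST`, `F_IS`, `F_IT` and a `components`
#'   attribute holding the per-variant `a`, `b`, `c` sums.
#' @export
wc84_fst <- function(panel) {
  stopifnot_panel(panel)
  stopifnot_diploid(panel, "the WC84 ANOVA estimator")
  D <- panel$dosages
  pops <- levels(panel$pops)
  r_all <- length(pops)
  if (r_all < 2) abort("the WC84 estimator requires >=2 populations.")
  typed <- !is.na(D)
  L <- ncol(D)

  m <- matrix(0, r_all, L)     # typed sample sizes
  p <- matrix(NA_real_, r_all, L)
  h <- matrix(NA_real_, r_all, L)  # observed heterozygote proportions
  for (i in seq_len(r_all)) {
    rows <- panel$pops == pops[i]
    Ti <- typed[rows, , drop = FALSE]
    m[i, ] <- colSums(Ti)
    p[i, ] <- ifelse(m[i, ] > 0, colSums(D[rows, , drop = FALSE], na.rm = TRUE) /
                       (2 * m[i, ]), NA_real_)
    h[i, ] <- ifelse(m[i, ] > 0,
                     colSums(D[rows, , drop = FALSE] == 1, na.rm = TRUE) / m[i, ],
                     NA_real_)
  }

  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- which(m[, l] >= 1)
    r <- length(use)
    if (r < 2) next
    ni <- m[use, l]; pi <- p[use, l]; hi <- h[use, l]
    N <- sum(ni)
    nbar <- N / r
    if (nbar <= 1) next
    nc <- (N - sum(ni^2) / N) / (r - 1)
    pbar <- sum(ni * pi) / N
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / N
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc[l] <- hbar / 2
  }
  ok <- !is.na(a)
  if (!any(ok)) abort("no variant is usable for the WC84 estimator.")
  A <- sum(a[ok]); B <- sum(b[ok]); C <- sum(cc[ok])
  if (A + B + C <= 0) abort("all usable variants are monomorphic.")
  out <- tibble(
    statistic = c("F_ST", "F_IS", "F_IT"),
    value = c(A / (A + B + C), B / (B + C), (A + B) / (A + B + C)),
    n_variants = sum(ok))
  attr(out, "components") <- c(a = A, b = B, c = C)
  out
}

#' Hudson's FST from allelic data
#'
#' The allelic estimator `1 - Hw / Hb` with `Hw = 1 - A_D` (random distinct
#' alleles within populations) and `Hb = 1 - A_B` (alleles from distinct
#' populations), i.e. `F_DB = (A_D - A_B) / (1 - A_B)` with numerator and
#' denominator summed over variants. Because it is computed from allele
#' counts only, it targets the distinct-allele measure `F_DB`; it equals the
#' genotypic `F_SB` only when inbreeding equals coancestry in every
#' population (no departure from Hardy-Weinberg proportions).
#'
#' @param x Either a [build_panel()] object (reduced internally with
#'   [reduce_to_allelic()]) or an allele-count tibble with columns `pop`,
#'   `variant`, `designated`, `total`.
#' @return A one-row tibble with `statistic = "F_DB"`, `value`,
#'   `n_variants`.
#' @export
hudson_fst <- function(x) {
  counts <- if (inherits(x, "dosage_panel")) reduce_to_allelic(x) else as_tibble(x)
  need <- c("pop", "variant", "designated", "total")
  if (!all(need %in% names(counts))) {
    abort("allele counts need columns pop/variant/designated/total.")
  }
  if (length(unique(counts$pop)) < 2) abort("Hudson's FST requires >=2 populations.")
  wide_p <- tidyr::pivot_wider(
    dplyr::mutate(counts,
                  p = ifelse(.data$total > 0, .data$designated / .data$total, NA_real_)),
    id_cols = "variant", names_from = "pop", values_from = "p")
  wide_t <- tidyr::pivot_wider(counts, id_cols = "variant",
                               names_from = "pop", values_from = "total")
  P <- as.matrix(wide_p[-1]); M <- as.matrix(wide_t[-1])
  P[!is.na(M) & M < 2] <- NA_real_           # need >=2 alleles for A_D
  AD <- 1 - (M / (M - 1)) * 2 * P * (1 - P)
  A_D <- rowMeans(AD, na.rm = TRUE)
  A_D[rowSums(!is.na(AD)) == 0] <- NA_real_
  r <- ncol(P)
  prs <- utils::combn(r, 2)
  AB <- sapply(seq_len(ncol(prs)), function(ii) {
    pa <- P[, prs[1, ii]]; pb <- P[, prs[2, ii]]
    pa * pb + (1 - pa) * (1 - pb)
  })
  AB <- matrix(AB, nrow = nrow(P))
  A_B <- rowMeans(AB, na.rm = TRUE)
  A_B[rowSums(!is.na(AB)) == 0] <- NA_real_
  ok <- !is.na(A_D) & !is.na(A_B)
  if (!any(ok) || sum(1 - A_B[ok]) <= 0) {
    abort("between-population sharing is complete: denominator is zero.")
  }
  tibble(statistic = "F_DB",
         value = sum(A_D[ok] - A_B[ok]) / sum(1 - A_B[ok]),
         n_variants = sum(ok))
}

ab_pair_lookup <- function(comp, p1, p2) {
  key1 <- pair_key(p1, p2); key2 <- pair_key(p2, p1)
  ii <- match(key1, rownames(comp$A_B_pair))
  if (is.na(ii)) ii <- match(key2, rownames(comp$A_B_pair))
  if (is.na(ii)) abort(sprintf("no population pair (%s, %s) in the panel.", p1, p2))
  comp$A_B_pair[ii, ]
}

check_pops_distinct <- function(comp, pops) {
  if (anyDuplicated(pops)) abort("populations must be distinct.")
  miss <- setdiff(pops, comp$pops)
  if (length(miss)) abort(sprintf("unknown population(s): %s.",
                                  paste(miss, collapse = ", ")))
}

f_den <- function(comp) {
  if (length(comp$pops) < 2) abort("f-statistics require >=2 populations.")
  comp$A_B
}

#' Admixture f-statistics from allele sharing
#'
#' The f2/f3/f4 drift statistics expressed through allele-sharing
#' statistics, with the study-wide `1 - A_B` as a common denominator so
#' values are comparable across population subsets. Using the genotypic
#' within-population sharing `A_S^i` (distinct individuals) rather than
#' squared sample frequencies means no Hardy-Weinberg assumption is needed.
#' Expectations in terms of between-population kinships `k_SB`:
#' `E(f2(i,i')) = (k_SB^i + k_SB^{i'})/2 - k_SB^{ii'}`;
#' `E(f3(i;i',i'')) = (k_SB^i - k_SB^{ii'} - k_SB^{ii''} + k_SB^{i'i''})/2`;
#' `E(f4(i,i';i'',i''')) = (k_SB^{ii''} + k_SB^{i'i'''} - k_SB^{ii'''} -
#' k_SB^{i'i''})/2`. f2 is symmetric in its arguments and f4 changes sign
#' when its two pairs are swapped; note f2 is not itself a ratio-of-averages
#' descent estimator and is biased for the pair coancestry.
#'
#' @param panel A [build_panel()] object.
#' @param p1,p2,p3,p4 Population labels (distinct where required).
#' @return A one-row tibble with `statistic`, `value`, `n_variants`.
#' @name f_statistics
NULL

#' @rdname f_statistics
#' @export
f2_stat <- function(panel, p1, p2) {
  comp <- allele_sharing(panel)
  check_pops_distinct(comp, c(p1, p2))
  i1 <- match(p1, comp$pops); i2 <- match(p2, comp$pops)
  numv <- (comp$A_S_pop[i1, ] + comp$A_S_pop[i2, ]) / 2 -
    ab_pair_lookup(comp, p1, p2)
  f_ratio(numv, f_den(comp), sprintf("f2(%s,%s)", p1, p2))
}

#' @rdname f_statistics
#' @export
f3_stat <- function(panel, p1, p2, p3) {
  comp <- allele_sharing(panel)
  check_pops_distinct(comp, c(p1, p2, p3))
  i1 <- match(p1, comp$pops)
  numv <- (comp$A_S_pop[i1, ] - ab_pair_lookup(comp, p1, p2) -
             ab_pair_lookup(comp, p1, p3) + ab_pair_lookup(comp, p2, p3)) / 2
  f_ratio(numv, f_den(comp), sprintf("f3(%s;%s,%s)", p1, p2, p3))
}

#' @rdname f_statistics
#' @export
f4_stat <- function(panel, p1, p2, p3, p4) {
  comp <- allele_sharing(panel)
  check_pops_distinct(comp, c(p1, p2, p3, p4))
  numv <- (ab_pair_lookup(comp, p1, p3) + ab_pair_lookup(comp, p2, p4) -
             ab_pair_lookup(comp, p1, p4) - ab_pair_lookup(comp, p2, p3)) / 2
  f_ratio(numv, f_den(comp), sprintf("f4(%s,%s;%s,%s)", p1, p2, p3, p4))
}

f_ratio <- function(numv, denv, tag) {
  ok <- !is.na(numv) & !is.na(denv)
  den <- sum(1 - denv[ok])
  if (!any(ok) || den <= 0) abort("denominator 1 - A_B is zero.")
  tibble(statistic = tag, value = sum(numv[ok]) / den, n_variants = sum(ok))
}

#' Forensic average match probability
#'
#' Corrects a database-derived average profile match proportion for the
#' population structure of the database: if the sample match proportion `M`
#' was computed from frequencies pooled over subpopulations, an unbiased
#' estimate of the within-subpopulation average match probability is
#' `M + (1 - M) * (theta_W - theta_B) / (1 - theta_B)`.
#'
#' @param m_sample Observed average match proportion in `[0, 1]`.
#' @param theta_w Average within-subpopulation random-pair descent measure.
#' @param theta_b Between-subpopulation descent measure (< 1).
#' @return The corrected match probability.
#' @examples
#' match_probability(0.1, 0.03, 0.01)
#' @export
match_probability <- function(m_sample, theta_w, theta_b) {
  if (any(m_sample < 0 | m_sample > 1)) abort("`m_sample` must lie in [0, 1].")
  if (any(theta_b >= 1)) abort("`theta_b` must be < 1.")
  m_sample + (1 - m_sample) * (theta_w - theta_b) / (1 - theta_b)
}
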