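#' Within-individual allele sharing
#'
#' Proportion of the `ploidy * (ploidy - 1)` ordered pairs of distinct alleles
#' carried by one individual that are identical in state. For diploids this is
#' `(X - 1)^2`: 1 for homozygotes, 0 for heterozygotes. For higher ploidy it
#' is the pair-enumeration value
#' `[X(X-1) + (k-X)(k-X-1)] / [k(k-1)]` with `k` the ploidy.
#'
#' @param x Allele dosage(s), integers in `0..ploidy` (`NA` allowed).
#' @param ploidy Ploidy, at least 2 (a haploid carries no within-individual
#'   allele pair).
#' @return Numeric vector of sharing proportions in `[0, 1]`.
#' @examples
#' sharing_within(c(0, 1, 2))      # 1, 0, 1
#' sharing_within(2, ploidy = 4)   # 1/3
#' @export
sharing_within <- function(x, ploidy = 2) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L) {
    abort("within-individual sharing is undefined for haploids (ploidy 1).")
  }
  if (any(!is.na(x) & (x < 0 | x > ploidy))) {
    abort(sprintf("dosages must lie in 0..%d.", ploidy))
  }
  (x * (x - 1) + (ploidy - x) * (ploidy - x - 1)) / (ploidy * (ploidy - 1))
}

#' Between-individual allele sharing
#'
#' Proportion of the `ploidy^2` allele pairs, one allele from each of two
#' individuals, that are identical in state:
#' `[X X' + (k-X)(k-X')] / k^2`. For diploids this is 1 when both are
#' homozygous for the same allele, 0 when homozygous for different alleles,
#' and 0.5 whenever either is heterozygous.
#'
#' @param x,xp Allele dosages of the two individuals (vectorized).
#' @param ploidy Ploidy (>= 1).
#' @return Numeric sharing proportions in `[0, 1]`; symmetric in `x`, `xp`.
#' @examples
#' sharing_pair(2, 2)  # 1
#' sharing_pair(1, 0)  # 0.5
#' sharing_pair(2, 0)  # 0
#' @export
sharing_pair <- function(x, xp, ploidy = 2) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 1L) abort("`ploidy` must be a positive integer.")
  if (any(!is.na(x) & (x < 0 | x > ploidy)) ||
      any(!is.na(xp) & (xp < 0 | xp > ploidy))) {
    abort(sprintf("dosages must lie in 0..%d.", ploidy))
  }
  (x * xp + (ploidy - x) * (ploidy - xp)) / ploidy^2
}

pair_key <- function(a, b) paste(a, b, sep = "|")

new_sharing_components <- function(fields) {
  structure(fields, class = "sharing_components")
}

#' Per-variant allele-sharing statistics for a panel
#'
#' Computes, for every variant, the full set of allele-sharing statistics:
#' within-individual values, per-population averages over distinct-individual
#' pairs (`A_S^i`), within-individual averages (`A_I^i`), random-pair and
#' distinct-allele averages (`A_W^i`, `A_D^i`), between-population sharing
#' (`A_B^{ii'}` and its average `A_B`), study-wide pair and individual
#' averages (`A_S*`, `A_I*`) and the total `A_T`. Statistics are kept
#' per-variant (unaggregated) so that downstream ratio estimators can sum
#' numerators and denominators over variants before dividing.
#'
#' Missing dosages are handled by averaging each statistic over the typed
#' individuals or pairs at each variant; a statistic with no typed
#' contributors (or a single individual where a pair is needed) is `NA`, never
#' zero. Averages over populations are unweighted and skip populations where
#' the statistic is undefined.
#'
#' @param panel A [build_panel()] object.
#' @return A `sharing_components` object (see [tidy.sharing_components()] for
#'   a tabular view): per-variant matrices `within` (individuals x variants),
#'   `A_S_pop`, `A_I_pop`, `A_W_pop`, `A_D_pop`, `p_pop`, `typed_pop`
#'   (populations x variants), `A_B_pair` (population pairs x variants), and
#'   per-variant vectors `A_S`, `A_I`, `A_W`, `A_D`, `A_B`, `A_T`, `A_S_star`,
#'   `A_I_star`.
#' @examples
#' p <- build_panel(matrix(c(2L, 0L, 1L, 1L), 2, 2), pops = c("A", "B"))
#' allele_sharing(p)$A_B
#' @export
allele_sharing <- function(panel) {
  stopifnot_panel(panel)
  D <- panel$dosages
  k <- panel$ploidy
  n <- nrow(D)
  L <- ncol(D)
  pops <- levels(panel$pops)
  r <- length(pops)
  typed <- !is.na(D)
  P <- D / k
  Pm <- ifelse(typed, P, 0)

  # within-individual sharing (NA for haploids / missing)
  if (k >= 2L) {
    within <- (D * (D - 1) + (k - D) * (k - D - 1)) / (k * (k - 1))
  } else {
    within <- matrix(NA_real_, n, L, dimnames = dimnames(D))
  }
  within_m <- ifelse(typed & !is.na(within), within, 0)

  mk <- function(nr) matrix(NA_real_, nr, L)
  m_pop <- mk(r); p_pop <- mk(r)
  A_S_pop <- mk(r); A_I_pop <- mk(r); A_W_pop <- mk(r); A_D_pop <- mk(r)
  rownames(m_pop) <- rownames(p_pop) <- rownames(A_S_pop) <-
    rownames(A_I_pop) <- rownames(A_W_pop) <- rownames(A_D_pop) <- pops

  for (i in seq_len(r)) {
    rows <- which(panel$pops == pops[i])
    Ti <- typed[rows, , drop = FALSE]
    m <- colSums(Ti)
    s <- colSums(Pm[rows, , drop = FALSE])       # sum of p_j over typed
    q <- colSums(Pm[rows, , drop = FALSE]^2)     # sum of p_j^2 over typed
    m_pop[i, ] <- m
    p_pop[i, ] <- ifelse(m > 0, s / m, NA_real_)

    # average pairwise sharing over ordered distinct typed pairs:
    # A_jj' = p_j p_j' + (1-p_j)(1-p_j')
    sum_pp <- s^2 - q
    sum_qq <- (m - s)^2 - (m - 2 * s + q)
    A_S_pop[i, ] <- ifelse(m >= 2, (sum_pp + sum_qq) / (m * (m - 1)), NA_real_)

    if (k >= 2L) {
      A_I_pop[i, ] <- ifelse(
        m > 0, colSums(within_m[rows, , drop = FALSE]) / m, NA_real_)
    }
    # self-pair sharing with replacement: (1 + (k-1) A_j) / k
    a_self <- if (k >= 2L) (1 + (k - 1) * within_m[rows, , drop = FALSE]) / k
              else Ti * 1
    selfbar <- ifelse(m > 0, colSums(ifelse(Ti, a_self, 0)) / m, NA_real_)
    A_W_pop[i, ] <- ifelse(m >= 2,
                           A_S_pop[i, ] + (selfbar - A_S_pop[i, ]) / m,
                           ifelse(m == 1, selfbar, NA_real_))
    AI_term <- if (k >= 2L) (k - 1) * A_I_pop[i, ] else 0
    A_D_pop[i, ] <- ifelse(m >= 2,
                           (k * (m - 1) * A_S_pop[i, ] + AI_term) / (k * m - 1),
                           ifelse(m == 1 & k >= 2, A_I_pop[i, ], NA_real_))
  }

  # between-population sharing from per-population typed-sample frequencies
  if (r >= 2) {
    prs <- utils::combn(r, 2)
    A_B_pair <- matrix(NA_real_, ncol(prs), L)
    rownames(A_B_pair) <- pair_key(pops[prs[1, ]], pops[prs[2, ]])
    for (ii in seq_len(ncol(prs))) {
      pa <- p_pop[prs[1, ii], ]
      pb <- p_pop[prs[2, ii], ]
      A_B_pair[ii, ] <- pa * pb + (1 - pa) * (1 - pb)
    }
    A_B <- colMeans(A_B_pair, na.rm = TRUE)
    A_B[colSums(!is.na(A_B_pair)) == 0] <- NA_real_
  } else {
    A_B_pair <- matrix(NA_real_, 0, L)
    A_B <- rep(NA_real_, L)
  }

  avg_pop <- function(M) {
    out <- colMeans(M, na.rm = TRUE)
    out[colSums(!is.na(M)) == 0] <- NA_real_
    out
  }
  A_S <- avg_pop(A_S_pop); A_I <- avg_pop(A_I_pop)
  A_W <- avg_pop(A_W_pop); A_D <- avg_pop(A_D_pop)
  A_T <- if (r >= 2) ((r - 1) / r) * A_B + A_W / r else A_W

  # study-wide pair average over all distinct typed pairs (any population)
  mT <- colSums(typed)
  sT <- colSums(Pm)
  qT <- colSums(Pm^2)
  A_S_star <- ifelse(mT >= 2,
                     ((sT^2 - qT) + ((mT - sT)^2 - (mT - 2 * sT + qT))) /
                       (mT * (mT - 1)),
                     NA_real_)
  A_I_star <- if (k >= 2L) ifelse(mT > 0, colSums(within_m) / mT, NA_real_)
              else rep(NA_real_, L)

  new_sharing_components(list(
    ploidy = k, pops = pops, n_pop = pop_sizes(panel),
    variant_ids = panel$variant_ids,
    within = ifelse(typed, within, NA_real_),
    typed = typed,
    typed_pop = m_pop, p_pop = p_pop,
    A_S_pop = A_S_pop, A_I_pop = A_I_pop, A_W_pop = A_W_pop, A_D_pop = A_D_pop,
    A_B_pair = A_B_pair,
    A_S = A_S, A_I = A_I, A_W = A_W, A_D = A_D,
    A_B = A_B, A_T = A_T, A_S_star = A_S_star, A_I_star = A_I_star
  ))
}

#' @export
print.sharing_components <- function(x, ...) {
  cat(sprintf(
    "<sharing_components> %d variants, %d population%s, ploidy %d\n",
    length(x$A_S), length(x$pops), if (length(x$pops) == 1) "" else "s",
    x$ploidy))
  invisible(x)
}

#' Tidy per-variant sharing statistics
#'
#' @param x A [allele_sharing()] object.
#' @param ... Unused.
#' @return A long tibble with columns `variant`, `statistic`, `pop` (or
#'   population pair, `NA` for study-level statistics) and `value`.
#' @exportS3Method generics::tidy
tidy.sharing_components <- function(x, ...) {
  L <- length(x$A_S)
  lvl <- function(M, stat) {
    if (!nrow(M)) return(NULL)
    tibble(variant = rep(x$variant_ids, each = nrow(M)),
           statistic = stat,
           pop = rep(rownames(M), L),
           value = as.vector(M))
  }
  study <- function(v, stat) {
    tibble(variant = x$variant_ids, statistic = stat,
           pop = NA_character_, value = v)
  }
  dplyr::bind_rows(
    lvl(x$A_S_pop, "A_S"), lvl(x$A_I_pop, "A_I"),
    lvl(x$A_W_pop, "A_W"), lvl(x$A_D_pop, "A_D"),
    lvl(x$A_B_pair, "A_B_pair"),
    study(x$A_S, "A_S_avg"), study(x$A_I, "A_I_avg"),
    study(x$A_W, "A_W_avg"), study(x$A_D, "A_D_avg"),
    study(x$A_B, "A_B"), study(x$A_T, "A_T"),
    study(x$A_S_star, "A_S_star"), study(x$A_I_star, "A_I_star")
  )
}

#' Brute-force allele-sharing statistics by explicit pair enumeration
#'
#' Same contract as [allele_sharing()], computed by expanding every typed
#' individual into its allele copies and enumerating allele pairs directly.
#' Intended as a test oracle on small panels; the fast implementation must
#' agree with it exactly.
#'
#' @param panel A [build_panel()] object (keep it small; cost is quadratic in
#'   allele count per population).
#' @return A `sharing_components` object.
#' @export
brute_force_sharing <- function(panel) {
  stopifnot_panel(panel)
  D <- panel$dosages
  k <- panel$ploidy
  n <- nrow(D)
  L <- ncol(D)
  pops <- levels(panel$pops)
  r <- length(pops)
  typed <- !is.na(D)

  alleles_of <- function(x) c(rep(1, x), rep(0, k - x))
  share_sets <- function(a, b) {           # mean identity over cross pairs
    mean(outer(a, b, "=="))
  }

  within <- matrix(NA_real_, n, L, dimnames = dimnames(D))
  mk <- function(nr) {
    m <- matrix(NA_real_, nr, L)
    rownames(m) <- pops
    m
  }
  m_pop <- mk(r); p_pop <- mk(r)
  A_S_pop <- mk(r); A_I_pop <- mk(r); A_W_pop <- mk(r); A_D_pop <- mk(r)
  if (r >= 2) {
    prs <- utils::combn(r, 2)
    A_B_pair <- matrix(NA_real_, ncol(prs), L)
    rownames(A_B_pair) <- pair_key(pops[prs[1, ]], pops[prs[2, ]])
  } else {
    prs <- NULL
    A_B_pair <- matrix(NA_real_, 0, L)
  }
  A_S_star <- rep(NA_real_, L); A_I_star <- rep(NA_real_, L)

  for (l in seq_len(L)) {
    al <- vector("list", n)               # allele copies per typed individual
    for (j in seq_len(n)) {
      if (typed[j, l]) {
        al[[j]] <- alleles_of(D[j, l])
        if (k >= 2L) {
          prs_w <- outer(al[[j]], al[[j]], "==")
          within[j, l] <- (sum(prs_w) - k) / (k * (k - 1))
        }
      }
    }
    for (i in seq_len(r)) {
      rows <- which(panel$pops == pops[i] & typed[, l])
      m <- length(rows)
      m_pop[i, l] <- m
      if (m == 0) next
      pool <- unlist(al[rows])
      p_pop[i, l] <- mean(pool)
      if (k >= 2L) A_I_pop[i, l] <- mean(within[rows, l])
      if (m >= 2) {
        vals <- utils::combn(rows, 2, function(jj)
          share_sets(al[[jj[1]]], al[[jj[2]]]))
        A_S_pop[i, l] <- mean(vals)
      }
      nall <- length(pool)
      eqm <- outer(pool, pool, "==")
      if (nall >= 1 && m >= 1) A_W_pop[i, l] <- mean(eqm)          # with replacement
      if (nall >= 2) A_D_pop[i, l] <- (sum(eqm) - nall) / (nall * (nall - 1))
      if (m == 1 && k < 2) A_W_pop[i, l] <- 1
    }
    if (!is.null(prs)) {
      for (ii in seq_len(ncol(prs))) {
        ra <- which(panel$pops == pops[prs[1, ii]] & typed[, l])
        rb <- which(panel$pops == pops[prs[2, ii]] & typed[, l])
        if (length(ra) && length(rb)) {
          A_B_pair[ii, l] <- share_sets(unlist(al[ra]), unlist(al[rb]))
        }
      }
    }
    rows_all <- which(typed[, l])
    if (length(rows_all) >= 2) {
      vals <- utils::combn(rows_all, 2, function(jj)
        share_sets(al[[jj[1]]], al[[jj[2]]]))
      A_S_star[l] <- mean(vals)
    }
    if (length(rows_all) >= 1 && k >= 2L) A_I_star[l] <- mean(within[rows_all, l])
  }

  avg_pop <- function(M) {
    out <- colMeans(M, na.rm = TRUE)
    out[colSums(!is.na(M)) == 0] <- NA_real_
    out
  }
  A_S <- avg_pop(A_S_pop); A_I <- avg_pop(A_I_pop)
  A_W <- avg_pop(A_W_pop); A_D <- avg_pop(A_D_pop)
  if (r >= 2) {
    A_B <- colMeans(A_B_pair, na.rm = TRUE)
    A_B[colSums(!is.na(A_B_pair)) == 0] <- NA_real_
    A_T <- ((r - 1) / r) * A_B + A_W / r
  } else {
    A_B <- rep(NA_real_, L)
    A_T <- A_W
  }

  new_sharing_components(list(
    ploidy = k, pops = pops, n_pop = pop_sizes(panel),
    variant_ids = panel$variant_ids,
    within = within, typed = typed,
    typed_pop = m_pop, p_pop = p_pop,
    A_S_pop = A_S_pop, A_I_pop = A_I_pop, A_W_pop = A_W_pop, A_D_pop = A_D_pop,
    A_B_pair = A_B_pair,
    A_S = A_S, A_I = A_I, A_W = A_W, A_D = A_D,
    A_B = A_B, A_T = A_T, A_S_star = A_S_star, A_I_star = A_I_star
  ))
}
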