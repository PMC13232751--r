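#' Simulate a structured-population dosage panel
#'
#' Balding-Nichols-style generator used for parameter-recovery testing.
#' Per locus, an ancestral designated-allele probability `pi` is fixed (or
#' drawn uniformly from a range); each population draws its own frequency
#' from a Beta distribution with mean `pi` and variance
#' `pi (1 - pi) theta_i`, so `theta_i` is the population's drift from the
#' common ancestor and populations are independent given the ancestor
#' (`theta_B = 0` between populations). Within a population, an individual's
#' genotype is drawn with inbreeding `f`: with probability `f` a single
#' allele draw is copied to all `ploidy` positions (all within-individual
#' pairs ibd), otherwise all copies are drawn independently from the
#' population frequency. Unconditionally the within-individual descent
#' measure is therefore `F_I^i = f + (1 - f) theta_i` and the
#' distinct-individual measure is `theta_S^i = theta_i`, both relative to
#' the ancestral reference.
#'
#' @param n_pops Number of populations `r`.
#' @param n_ind Individuals per population (scalar or length `n_pops`).
#' @param n_loci Number of independent variants.
#' @param theta Per-population drift `theta_i` in `[0, 1)` (scalar or
#'   length `n_pops`).
#' @param f Within-individual inbreeding in `[0, 1]` (scalar, length
#'   `n_pops`, or one value per individual).
#' @param pi Ancestral allele probability: a single value in (0, 1) or a
#'   range `c(lo, hi)` to draw per-locus values uniformly.
#' @param ploidy Ploidy of the simulated individuals.
#' @param seed Integer seed (required).
#' @return A list with `panel` (a [build_panel()] object), `truth` (tibble
#'   of per-population `theta_S`, `F_I`, `f`, `n`; `theta_B = 0`), `pi`
#'   (per-locus ancestral probabilities) and `pop_freq` (populations x loci
#'   realized frequencies).
#' @examples
#' sim <- sim_panel(n_pops = 2, n_ind = 5, n_loci = 50, theta = 0.05, seed = 1)
#' sim$truth
#' @export
sim_panel <- function(n_pops, n_ind, n_loci, theta = 0, f = 0, pi = 0.5,
                      ploidy = 2, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  n_pops <- as.integer(n_pops)
  n_ind <- rep_len(as.integer(n_ind), n_pops)
  theta <- rep_len(theta, n_pops)
  if (any(theta < 0 | theta >= 1)) abort("`theta` must lie in [0, 1).")
  n_T <- sum(n_ind)
  f_ind <- if (length(f) == n_T) f else rep(rep_len(f, n_pops), n_ind)
  if (any(f_ind < 0 | f_ind > 1)) abort("`f` must lie in [0, 1].")
  if (any(pi <= 0 | pi >= 1)) abort("`pi` must lie in (0, 1).")
  ploidy <- as.integer(ploidy)
  set.seed(seed)

  pi_l <- if (length(pi) == 2L) runif(n_loci, pi[1], pi[2])
          else rep_len(pi, n_loci)
  pop_freq <- matrix(NA_real_, n_pops, n_loci)
  for (i in seq_len(n_pops)) {
    if (theta[i] == 0) {
      pop_freq[i, ] <- pi_l
    } else {
      shape <- (1 - theta[i]) / theta[i]
      pop_freq[i, ] <- rbeta(n_loci, pi_l * shape, (1 - pi_l) * shape)
    }
  }

  D <- matrix(NA_real_, n_T, n_loci)
  pops <- rep(paste0("pop", seq_len(n_pops)), n_ind)
  row <- 0L
  for (i in seq_len(n_pops)) {
    for (j in seq_len(n_ind[i])) {
      row <- row + 1L
      ibd <- runif(n_loci) < f_ind[row]
      dose <- rbinom(n_loci, ploidy, pop_freq[i, ])
      dose[ibd] <- ploidy * rbinom(sum(ibd), 1, pop_freq[i, ibd])
      D[row, ] <- dose
    }
  }
  panel <- build_panel(D, pops = pops, ploidy = ploidy)
  f_pop <- vapply(split(f_ind, factor(pops, levels = unique(pops))), mean,
                  numeric(1))
  truth <- tibble(pop = paste0("pop", seq_len(n_pops)), n = n_ind,
                  theta_S = theta, f = unname(f_pop),
                  F_I = unname(f_pop + (1 - f_pop) * theta))
  list(panel = panel, truth = truth, theta_B = 0, pi = pi_l,
       pop_freq = pop_freq, f_ind = f_ind)
}

#' Simulate two source populations and an admixed population
#'
#' Fixture for reference-set rank-concordance experiments: two well
#' differentiated source populations (independent per-locus frequencies
#' drawn uniformly) and an admixed population in which each individual has
#' its own admixture proportion `alpha` drawn uniformly, each allele copied
#' from source A with probability `alpha` and from source B otherwise.
#' Individual-specific ancestry makes pairs of admixed individuals differ
#' strongly in their average relatedness to the rest of the study, the
#' situation in which dosage-centered kinship rankings depend on the
#' reference sample while allele-sharing rankings do not.
#'
#' @param n_src Individuals in the two source populations, `c(nA, nB)`. The
#'   default is deliberately unbalanced: the study is dominated by one
#'   ancestry, the situation (an admixed minority population inside a large
#'   panel) in which reference-dependent rank changes of dosage-centered
#'   kinship are most visible.
#' @param n_adm Admixed individuals.
#' @param n_loci Number of independent variants.
#' @param freq_range Range from which per-locus source frequencies are drawn.
#' @param seed Integer seed (required).
#' @return A list with `panel` (populations `A`, `B`, `ADM`) and `alpha`
#'   (admixture proportions of the admixed individuals).
#' @export
sim_admixed_panel <- function(n_src = c(45, 5), n_adm = 30, n_loci = 2000,
                              freq_range = c(0.05, 0.95), seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  n_src <- rep_len(n_src, 2)
  pA <- runif(n_loci, freq_range[1], freq_range[2])
  pB <- runif(n_loci, freq_range[1], freq_range[2])
  alpha <- runif(n_adm)
  draw_pop <- function(n, p) {
    t(vapply(seq_len(n), function(j) rbinom(n_loci, 2, p), numeric(n_loci)))
  }
  DA <- draw_pop(n_src[1], pA)
  DB <- draw_pop(n_src[2], pB)
  DM <- t(vapply(seq_len(n_adm), function(j) {
    pj <- alpha[j] * pA + (1 - alpha[j]) * pB
    rbinom(n_loci, 2, pj)
  }, numeric(n_loci)))
  D <- rbind(DA, DB, DM)
  pops <- rep(c("A", "B", "ADM"), c(n_src, n_adm))
  list(panel = build_panel(D, pops = pops, ploidy = 2), alpha = alpha)
}
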