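#' Block bootstrap for ratio-of-averages estimators
#'
#' Variants are partitioned, in their given (genomic) order, into contiguous
#' non-overlapping blocks (the last block may be shorter); blocks are
#' resampled with replacement and the estimator is recomputed per replicate
#' by summing the sampled per-variant numerator and denominator
#' contributions before dividing. Resampling blocks of neighbouring variants
#' preserves within-block dependencies (linkage disequilibrium), which
#' per-variant resampling would destroy. Percentile confidence intervals are
#' returned; the point estimate itself does not depend on the block
#' partition.
#'
#' @param num,den Per-variant numerator (`A_Y - A_R`) and denominator
#'   (`1 - A_R`) contributions; variants where either is `NA` are dropped
#'   (pairwise) before blocking.
#' @param block_size Variants per block (default 100).
#' @param B Number of bootstrap replicates.
#' @param level Confidence level for the percentile interval.
#' @param seed Integer seed (required).
#' @return A `block_bootstrap` object: `estimate`, `replicates`, `ci`
#'   (length 2), `level`, `block_size`, `n_blocks`, `B`, `seed`,
#'   `n_excluded` (replicates dropped for a non-positive denominator, with a
#'   warning when any).
#' @export
block_bootstrap <- function(num, den, block_size = 100, B = 1000,
                            level = 0.95, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  if (length(num) != length(den)) abort("`num` and `den` must have equal length.")
  ok <- !is.na(num) & !is.na(den)
  num <- num[ok]; den <- den[ok]
  L <- length(num)
  if (L < 1) abort("no usable variants.")
  block_size <- as.integer(block_size)
  if (block_size < 1 || block_size > L) {
    abort(sprintf("`block_size` must lie in 1..%d.", L))
  }
  if (B < 1) abort("`B` must be >= 1.")
  if (sum(den) <= 0) abort("denominator sum is not positive.")

  blk <- ceiling(seq_len(L) / block_size)
  bnum <- tapply(num, blk, sum)
  bden <- tapply(den, blk, sum)
  nb <- length(bnum)
  estimate <- sum(num) / sum(den)

  set.seed(seed)
  idx <- matrix(sample.int(nb, nb * B, replace = TRUE), nrow = nb)
  rep_num <- colSums(matrix(bnum[idx], nrow = nb))
  rep_den <- colSums(matrix(bden[idx], nrow = nb))
  bad <- rep_den <= 0
  if (any(bad)) {
    warn(sprintf("%d bootstrap replicate(s) had a non-positive denominator and were excluded.",
                 sum(bad)))
  }
  reps <- rep_num[!bad] / rep_den[!bad]
  alpha <- (1 - level) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  structure(list(estimate = estimate, replicates = reps, ci = ci,
                 level = level, block_size = block_size, n_blocks = nb,
                 B = B, seed = seed, n_excluded = sum(bad)),
            class = "block_bootstrap")
}

#' @export
print.block_bootstrap <- function(x, ...) {
  cat(sprintf("<block_bootstrap> estimate %.6f, %g%% CI [%.6f, %.6f]\n",
              x$estimate, 100 * x$level, x$ci[1], x$ci[2]))
  cat(sprintf("  %d replicates over %d blocks of %d variants (seed %d)\n",
              length(x$replicates), x$n_blocks, x$block_size, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.block_bootstrap <- function(x, ...) {
  tibble(estimate = x$estimate, conf.low = x$ci[1], conf.high = x$ci[2],
         level = x$level, B = x$B, block_size = x$block_size,
         n_excluded = x$n_excluded)
}

#' Block-bootstrap confidence interval for population-structure estimates
#'
#' Convenience wrapper around [block_bootstrap()] that extracts the
#' per-variant numerator and denominator contributions of the overall
#' `F_SB` (kinship within populations relative to between-population allele
#' pairs) or `F_IB` (inbreeding relative to the same reference) from a
#' panel and bootstraps them.
#'
#' @param panel A [build_panel()] object with >= 2 populations.
#' @param statistic Which overall statistic to bootstrap.
#' @inheritParams block_bootstrap
#' @return A [block_bootstrap()] object.
#' @export
bootstrap_fst <- function(panel, statistic = c("F_SB", "F_IB"),
                          block_size = 100, B = 1000, level = 0.95, seed) {
  stopifnot_panel(panel)
  statistic <- match.arg(statistic)
  comp <- allele_sharing(panel)
  if (length(comp$pops) < 2) {
    abort("between-population reference requires >=2 populations.")
  }
  a_y <- switch(statistic, F_SB = comp$A_S, F_IB = comp$A_I)
  block_bootstrap(a_y - comp$A_B, 1 - comp$A_B, block_size = block_size,
                  B = B, level = level, seed = seed)
}
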