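test_that("ratio estimates sum numerator and denominator before dividing", {
  expect_equal(ratio_estimate(0.5, 0.5)$value, 0)
  expect_equal(ratio_estimate(c(1, 0.5), c(0.5, 0.5))$value, 0.5)
  expect_equal(ratio_estimate(rep(1, 5), runif(5, 0, 0.9))$value, 1)
  expect_error(ratio_estimate(c(0.2, 0.3), c(1, 1)), "monomorphic reference")
  # ratio of sums, not mean of ratios
  a_y <- c(0.9, 0.1); a_r <- c(0.8, 0.6)
  expect_equal(ratio_estimate(a_y, a_r)$value,
               sum(a_y - a_r) / sum(1 - a_r))
})

test_that("inbreeding hits the boundary values for extreme homozygosity", {
  # fully homozygous individual against a polymorphic reference
  D <- matrix(c(2L, 2L, 0L,
                2L, 0L, 1L,
                2L, 1L, 0L), 3, 3, byrow = FALSE)
  p <- build_panel(D, pops = rep("A", 3))
  f <- as_inbreeding(p)
  expect_equal(f$value[1], 1)

  # everyone heterozygous: A_S = 0.5 so every f = (0 - .5)/(1 - .5) = -1
  ph <- build_panel(matrix(1L, 4, 5), pops = rep("A", 4))
  expect_equal(as_inbreeding(ph)$value, rep(-1, 4))
})

test_that("null simulation gives mean inbreeding near zero", {
  sim <- sim_panel(n_pops = 1, n_ind = 60, n_loci = 3000, theta = 0, f = 0,
                   pi = c(0.1, 0.9), seed = 11)
  f <- as_inbreeding(sim$panel)
  mc_se <- stats::sd(f$value) / sqrt(length(f$value))
  expect_lt(abs(mean(f$value)), 3 * mc_se + 1e-3)
})

test_that("population-average inbreeding equals the sharing-weighted combination", {
  p <- random_panel(c(6, 8), n_loci = 20, seed = 21)
  f <- as_inbreeding(p, "within_population")
  g <- glance(f)
  comp <- allele_sharing(p)
  # study row reproduces the pooled ratio over population averages
  expect_equal(g$value[g$pop == ".study"],
               sum(comp$A_I - comp$A_S) / sum(1 - comp$A_S))
  # and equals the (1 - A_S^i)-weighted mean of population-specific values
  w <- rowSums(1 - comp$A_S_pop)
  fis <- g$value[g$pop != ".study"]
  expect_equal(g$value[g$pop == ".study"], sum(w * fis) / sum(w))
})

test_that("kinship honours its structural zero-mean constraints exactly", {
  for (s in 1:3) {
    p <- random_panel(c(5, 7, 4), n_loci = 25, seed = 30 + s)
    kw <- as_kinship(p, "within_population")
    td <- tidy(kw)
    within <- td[td$pop1 == td$pop2, ]
    for (pp in unique(within$pop1)) {
      expect_lt(abs(mean(within$value[within$pop1 == pp])), 1e-12)
    }
    ks <- as_kinship(p, "whole_study")
    expect_lt(abs(mean(tidy(ks)$value)), 1e-12)
  }
})

test_that("kinship of identical homozygous individuals is one", {
  D <- rbind(c(2L, 2L, 0L),   # ind1 and ind2 identical, ind3 breaks
             c(2L, 2L, 0L),   # the monomorphy of the reference
             c(0L, 1L, 2L))
  p <- build_panel(D, pops = rep("A", 3))
  k <- as_kinship(p, "within_population")
  expect_equal(k$entries[1, 2], 1)
})

test_that("kinship diagonal carries (1 + f)/2", {
  p <- random_panel(c(5, 5), n_loci = 15, seed = 41)
  k <- as_kinship(p, "whole_study")
  f <- as_inbreeding(p, "whole_study")
  expect_equal(diag(k$entries), setNames((1 + f$value) / 2, f$id))
})

test_that("population F-statistics use the between-population reference", {
  p <- random_panel(c(5, 5, 5), n_loci = 30, seed = 51)
  fst <- as_fst(p)
  comp <- allele_sharing(p)
  expect_equal(fst$overall$value[fst$overall$statistic == "F_SB"],
               sum(comp$A_S - comp$A_B) / sum(1 - comp$A_B))
  # average between-population kinship is exactly zero
  ksb <- fst$by_pair$value[fst$by_pair$statistic == "k_SB_iip"]
  expect_lt(abs(mean(ksb)), 1e-12)
  # independent samples from one pool show no differentiation
  sim0 <- sim_panel(2, 25, 2000, theta = 0, f = 0, pi = c(0.2, 0.8),
                    seed = 52)
  f0 <- as_fst(sim0$panel)$overall
  expect_lt(abs(f0$value[f0$statistic == "F_SB"]), 0.01)
  # single population is refused
  expect_error(as_fst(build_panel(matrix(c(1L, 2L), 2), pops = c("A", "A"))),
               ">=2 populations")
})

test_that("changing the reference set is a positive-slope affine map", {
  p <- random_panel(c(6, 6), n_loci = 40, seed = 61)
  k <- tidy(as_kinship(p, "whole_study"))

  same <- rescale_reference(k, new_reference = 1 - k$den[1] / k$n_variants[1])
  expect_equal(same$value, k$value, tolerance = 1e-12)

  mn <- rescale_reference(k, "minimum")
  expect_equal(min(mn$value), 0)
  expect_true(all(mn$value >= 0))
  expect_equal(cor(mn$value, k$value, method = "spearman"), 1)
  expect_equal(order(mn$value), order(k$value))

  shifted <- rescale_reference(k, 0.3)
  expect_equal(cor(shifted$value, k$value, method = "spearman"), 1)
  expect_error(rescale_reference(k, 1), "< 1")
})

test_that("hand-computed values follow from the parameter algebra", {
  ft <- fstats_from_theta(F_I = 0.1, theta_S = 0.1, theta_B = 0.05, n = 1000)
  expect_equal(ft$value[ft$statistic == "F_SB"], 0.05 / 0.95)

  # theta_W = theta_T makes Wright's F_ST zero: one population limit
  ft1 <- fstats_from_theta(F_I = 0.2, theta_S = 0.1, theta_B = 0.1, n = 1e9)
  w <- ft1[ft1$form == "wright", ]
  expect_equal(w$value[w$statistic == "F_ST"], 0, tolerance = 1e-8)
})

test_that("the product identity (1-F_IT) = (1-F_ST)(1-F_IS) holds in both forms", {
  set.seed(71)
  for (rep in 1:10) {
    r <- sample(2:6, 1)
    ft <- fstats_from_theta(F_I = runif(r, -0.2, 0.5),
                            theta_S = runif(r, 0, 0.4),
                            theta_B = runif(1, 0, 0.2),
                            n = sample(2:50, r, replace = TRUE))
    for (fm in c("wright", "allele_sharing")) {
      v <- ft$value[ft$form == fm]
      expect_equal((1 - v[1]), (1 - v[3]) * (1 - v[2]), tolerance = 1e-12)
    }
  }
})

test_that("Wright and allele-sharing F_ST converge for many populations", {
  r <- 1e6
  ft <- fstats_from_theta(F_I = rep(0.12, r), theta_S = rep(0.1, r),
                          theta_B = 0.05, n = 1e9)
  fw <- ft$value[ft$form == "wright"]
  fa <- ft$value[ft$form == "allele_sharing"]
  expect_lt(abs(fw[3] - fa[3]), 1e-6)
  expect_lt(abs(fw[1] - fa[1]), 1e-6)
  # while at small r they differ appreciably
  ft2 <- fstats_from_theta(F_I = rep(0.12, 2), theta_S = rep(0.1, 2),
                           theta_B = 0.05, n = 1e9)
  fw2 <- ft2$value[ft2$form == "wright"]
  expect_gt(abs(fw2[3] - fa[3]), 0.01)
})

test_that("self-coancestry interpolates between haploid 1 and (1+F)/2", {
  expect_equal(self_coancestry(0.4), 0.7)
  expect_equal(self_coancestry(c(0, 0.3, 0.9), ploidy = 1), c(1, 1, 1))
  expect_equal(self_coancestry(0.3, ploidy = 4), (1 + 3 * 0.3) / 4)
})
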