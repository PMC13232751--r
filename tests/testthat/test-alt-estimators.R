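test_that("standard kinship reproduces the hand-computable two-individual case", {
  # opposite homozygotes at every variant: p = 0.5, (2-1)(0-1)/(4*0.25) = -1
  p <- build_panel(matrix(c(2L, 0L, 2L, 0L), 2, 2), pops = c("A", "A"))
  for (mode in c("ratio_of_averages", "average_of_ratios")) {
    K <- standard_kinship(p, mode = mode)
    expect_equal(K$entries[1, 2], -1)
    expect_equal(K$entries[1, 1], 1)   # (2-1)^2 / (4*0.25)
  }
  mono <- build_panel(matrix(2L, 3, 2), pops = rep("A", 3))
  expect_error(standard_kinship(mono), "monomorphic")
})

test_that("standard kinship approaches the double-centered allele-sharing matrix", {
  dc <- function(K) {
    n <- nrow(K)
    H <- diag(n) - matrix(1 / n, n, n)
    H %*% K %*% H
  }
  dev <- sapply(c(20, 200), function(n) {
    sim <- sim_panel(1, n, 2000, theta = 0, f = 0.05, pi = c(0.2, 0.8),
                     seed = 500 + n)
    kstd <- standard_kinship(sim$panel)$entries
    kas <- as_kinship(sim$panel, "within_population")$entries
    comp <- allele_sharing(sim$panel)
    C <- sum(1 - comp$A_W) / sum(1 - comp$A_S)
    delta <- kstd - C * dc(kas)
    max(abs(delta[upper.tri(delta)]))
  })
  expect_lt(dev[2], dev[1])     # large-sample relation tightens with n
  expect_lt(dev[2], 0.02)
})

test_that("per-variant ratio averaging does not converge to the target with rare variants", {
  # a parent-offspring pair in a pool of unrelated individuals: the
  # ratio-of-averages estimate tends to k - kbar_j - kbar_j' (about 0.24
  # here), while averaging per-variant ratios is pulled away by the noisy
  # low-frequency denominators
  res <- sapply(1:10, function(s) {
    set.seed(6000 + s)
    L <- 2000
    pf <- runif(L, 0.01, 0.05)
    pool <- t(vapply(1:50, function(j) rbinom(L, 2, pf), numeric(L)))
    par1 <- rbinom(L, 1, pf); par2 <- rbinom(L, 1, pf)
    child <- ifelse(runif(L) < 0.5, par1, par2) + rbinom(L, 1, pf)
    p <- build_panel(rbind(pool, par1 + par2, child), pops = rep("A", 52))
    c(aor = standard_kinship(p, "average_of_ratios")$entries[51, 52],
      roa = standard_kinship(p, "ratio_of_averages")$entries[51, 52])
  })
  target <- 0.25 - 2 * 0.25 / 51     # pair kinship minus its row averages
  expect_lt(abs(mean(res["roa", ]) - target), 0.025)
  expect_gt(abs(mean(res["aor", ]) - target), 0.04)
})

test_that("KING-robust zeroes when pair sharing equals mean self-sharing", {
  # ind1 het everywhere, ind2 homozygous: A_jj' = 0.5 = (0 + 1)/2 per variant
  p <- build_panel(rbind(c(1L, 1L), c(2L, 0L)), pops = c("A", "A"))
  kr <- king_robust(p)
  expect_equal(kr$entries[1, 2], 0)

  both_hom <- build_panel(rbind(c(2L, 0L), c(0L, 2L)), pops = c("A", "A"))
  expect_error(king_robust(both_hom), "no heterozygosity")
})

test_that("KING-robust is near zero for unrelated non-inbred pairs", {
  sim <- sim_panel(1, 40, 4000, theta = 0, f = 0, pi = c(0.2, 0.8), seed = 81)
  kr <- tidy(king_robust(sim$panel))
  expect_lt(abs(mean(kr$value)), 0.01)
})

test_that("Li-Horvitz recovers its closed-form extremes and targets f_IS", {
  # all heterozygous, p = 0.5: 1 - 1/0.5 = -1
  p1 <- build_panel(matrix(1L, 4, 6), pops = rep("A", 4))
  expect_equal(li_horvitz(p1)$value, -1)
  # all homozygous at p = 0.5: H_obs = 0
  p2 <- build_panel(matrix(c(2L, 0L), 4, 6), pops = rep("A", 4))
  expect_equal(li_horvitz(p2)$value, 1)
  expect_error(li_horvitz(build_panel(matrix(2L, 3, 2), pops = rep("A", 3))),
               "monomorphic")
  # HWE population: estimate near zero
  sim <- sim_panel(1, 100, 3000, theta = 0, f = 0, pi = c(0.2, 0.8), seed = 91)
  expect_lt(abs(li_horvitz(sim$panel)$value), 0.01)
})

test_that("Nei 1986 is the allele-sharing F_SB, Nei 1973 is not", {
  for (s in 1:3) {
    p <- random_panel(c(4, 6, 5), n_loci = 20, seed = 110 + s)
    fsb <- as_fst(p)$overall
    expect_equal(nei_fst(p, "1986")$value,
                 fsb$value[fsb$statistic == "F_SB"], tolerance = 1e-12)
  }
  # fixed different alleles: within-sample heterozygosity zero, 1973 value 1
  p <- build_panel(rbind(c(2L, 2L), c(2L, 2L), c(0L, 0L), c(0L, 0L)),
                   pops = c("A", "A", "B", "B"))
  expect_equal(nei_fst(p, "1973")$value, 1)
})

test_that("Nei 1973 tracks the Wright-form F_ST at its study dimensions", {
  # two large populations, theta = 0.1: Eq-4-style value theta/(1 + (1-theta))
  sim <- sim_panel(2, 100, 8000, theta = 0.1, f = 0, pi = c(0.2, 0.8),
                   seed = 121)
  expected_w <- 0.1 / ((1 - 0) + (1 / (2 - 1)) * (1 - 0.1))
  got <- nei_fst(sim$panel, "1973")$value
  expect_lt(abs(got - expected_w), 0.01)
  # and is far from the allele-sharing F_SB = 0.1 target
  expect_gt(abs(got - 0.1), 0.03)
})

test_that("WC84 ANOVA F_ST is identical to allele-sharing F_SB at equal sample sizes", {
  for (s in 1:5) {
    p <- random_panel(c(6, 6, 6), n_loci = 25, seed = 130 + s)
    wc <- wc84_fst(p)
    fsb <- as_fst(p)$overall
    expect_equal(wc$value[wc$statistic == "F_ST"],
                 fsb$value[fsb$statistic == "F_SB"], tolerance = 1e-12)
  }
})

test_that("WC84 and allele-sharing estimates part ways for unequal sample sizes", {
  p <- random_panel(c(4, 14), n_loci = 40, seed = 140)
  wc <- wc84_fst(p)
  fsb <- as_fst(p)$overall
  expect_gt(abs(wc$value[wc$statistic == "F_ST"] -
                  fsb$value[fsb$statistic == "F_SB"]), 1e-6)
  # undifferentiated populations: independent samples from one pool
  sim0 <- sim_panel(3, 20, 2000, theta = 0, f = 0, pi = c(0.2, 0.8),
                    seed = 142)
  wc0 <- wc84_fst(sim0$panel)
  expect_lt(abs(wc0$value[wc0$statistic == "F_ST"]), 0.01)
})

test_that("Hudson's allelic estimator matches hand counts and the sharing module", {
  # identical counts in both populations: no differentiation signal (the
  # finite-sample A_D correction vanishes as allele totals grow)
  counts <- tibble::tibble(pop = c("A", "B"), variant = "v1",
                           designated = c(500L, 500L), total = c(1000L, 1000L))
  expect_lt(abs(hudson_fst(counts)$value), 2e-3)
  # at tiny totals the distinct-allele correction is visible and exact:
  # A_D = 1 - (4/3) * 0.5 = 1/3 against A_B = 1/2
  tiny <- tibble::tibble(pop = c("A", "B"), variant = "v1",
                         designated = c(2L, 2L), total = c(4L, 4L))
  expect_equal(hudson_fst(tiny)$value, (1 / 3 - 1 / 2) / (1 - 1 / 2))
  # fixed for different alleles: H_w = 0
  fixed <- tibble::tibble(pop = c("A", "B"), variant = "v1",
                          designated = c(4L, 0L), total = c(4L, 4L))
  expect_equal(hudson_fst(fixed)$value, 1)
  # genotypic panel reduced to alleles equals (A_D - A_B)/(1 - A_B) exactly
  for (s in 1:3) {
    p <- random_panel(c(5, 4, 6), n_loci = 15, seed = 150 + s)
    comp <- allele_sharing(p)
    expect_equal(hudson_fst(p)$value,
                 sum(comp$A_D - comp$A_B) / sum(1 - comp$A_B),
                 tolerance = 1e-12)
  }
})

test_that("f-statistics have the symmetries their definitions demand", {
  p <- random_panel(c(4, 4, 4, 4), n_loci = 30, seed = 161)
  expect_equal(f2_stat(p, "p1", "p2")$value, f2_stat(p, "p2", "p1")$value)
  # exchanging the two pairs leaves f4 unchanged ...
  expect_equal(f4_stat(p, "p1", "p2", "p3", "p4")$value,
               f4_stat(p, "p3", "p4", "p1", "p2")$value)
  # ... while swapping the members of one pair flips its sign
  expect_equal(f4_stat(p, "p2", "p1", "p3", "p4")$value,
               -f4_stat(p, "p1", "p2", "p3", "p4")$value)
  expect_error(f3_stat(p, "p1", "p1", "p2"), "distinct")
})

test_that("f3 of independently drifted populations recovers half the focal drift", {
  # with the common 1 - A_B denominator, E(f3) = theta_S(focal)/2 when all
  # between-population coancestries vanish
  sims <- sapply(1:6, function(s) {
    sim <- sim_panel(3, 50, 4000, theta = c(0.1, 0.02, 0.02), f = 0,
                     pi = c(0.2, 0.8), seed = 170 + s)
    f3_stat(sim$panel, "pop1", "pop2", "pop3")$value
  })
  mc_se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - 0.1 / 2), 3 * mc_se + 0.005)
})

test_that("match probability correction behaves at its anchors", {
  expect_equal(match_probability(0.1, 0.02, 0.02), 0.1)
  expect_equal(match_probability(1, 0.05, 0.01), 1)
  expect_equal(match_probability(0.1, 0.03, 0.01),
               0.1 + 0.9 * 0.02 / 0.99)
  expect_error(match_probability(0.1, 0.02, 1), "< 1")
})
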