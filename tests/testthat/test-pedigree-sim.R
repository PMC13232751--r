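test_that("pedigree construction rejects malformed structures", {
  expect_error(pedigree(tibble::tibble(id = "a", parent1 = "b", parent2 = NA)),
               "one known parent")
  expect_error(pedigree(tibble::tibble(id = c("a", "b"),
                                       parent1 = c("b", "a"),
                                       parent2 = c("b", "a"))),
               "cycle")
  expect_error(pedigree(tibble::tibble(id = "a", parent1 = "x", parent2 = "y")),
               "not present")
  ped <- family_pedigree()
  expect_true(all(ped$founder[1:4]))
})

test_that("tabular coancestry reproduces the classical relationship values", {
  pc <- pedigree_coancestry(family_pedigree())
  th <- pc$coancestry
  expect_equal(th["m1", "s1"], 0.25)       # parent-offspring
  expect_equal(th["s1", "s2"], 0.25)       # full sibs
  expect_equal(th["s1", "h"], 0.125)       # half sibs
  expect_equal(pc$inbreeding[["o"]], 0.25) # offspring of full sibs
  expect_equal(th["o", "o"], (1 + 0.25) / 2)
  expect_equal(pc$inbreeding[["m1"]], 0)
  expect_equal(th["m1", "m2"], 0)          # unrelated founders
})

test_that("tabular method equals explicit path enumeration on small pedigrees", {
  pc <- pedigree_coancestry(family_pedigree())
  bp <- coancestry_paths(family_pedigree())
  expect_equal(pc$coancestry, bp$coancestry, tolerance = 1e-15)
  expect_equal(pc$inbreeding, bp$inbreeding, tolerance = 1e-15)

  # deeper 12-member pedigree with repeated inbreeding
  ped12 <- pedigree(tibble::tibble(
    id      = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l"),
    parent1 = c(NA, NA, NA, NA, "a", "a", "c", "e", "e", "h", "h", "j"),
    parent2 = c(NA, NA, NA, NA, "b", "b", "d", "f", "g", "i", "i", "k")))
  pc12 <- pedigree_coancestry(ped12)
  bp12 <- coancestry_paths(ped12)
  expect_equal(pc12$coancestry, bp12$coancestry, tolerance = 1e-12)
})

test_that("gene dropping is reproducible and matches pedigree ibd in expectation", {
  ped <- family_pedigree()
  d1 <- gene_drop(ped, 200, p = 0.4, seed = 5, track_origin = TRUE)
  d2 <- gene_drop(ped, 200, p = 0.4, seed = 5, track_origin = TRUE)
  expect_identical(d1$dosages, d2$dosages)
  expect_identical(d1$origin, d2$origin)

  big <- gene_drop(ped, 8000, p = 0.5, seed = 6, track_origin = TRUE)
  ibd <- realized_ibd(big)
  th <- pedigree_coancestry(ped)$coancestry
  # realized proportions are binomial-ish around the pedigree values
  for (pr in list(c("m1", "s1"), c("s1", "s2"), c("s1", "h"), c("m1", "m2"))) {
    theta <- th[pr[1], pr[2]]
    se <- sqrt(max(theta * (1 - theta), 0.25 / 4) / 8000) * 2  # conservative
    expect_lt(abs(ibd[pr[1], pr[2]] - theta), 3 * se + 0.01)
  }
})

test_that("pedigree-simulated genotypes rank kinship classes correctly", {
  ped <- family_pedigree()
  drop <- gene_drop(ped, 6000, p = runif(6000, 0.2, 0.8), seed = 7)
  # add a pool of unrelated individuals as the reference backdrop
  extra <- sim_panel(1, 12, 6000, theta = 0, f = 0, pi = c(0.2, 0.8),
                     seed = 8)$panel$dosages
  D <- rbind(drop$dosages, extra)
  panel <- build_panel(D, pops = rep("A", nrow(D)))
  K <- as_kinship(panel, "within_population")$entries
  k_po <- K["m1", "s1"]; k_fs <- K["s1", "s2"]; k_hs <- K["s1", "h"]
  k_un <- K["m1", "m2"]
  expect_gt(min(k_po, k_fs), k_hs)
  expect_gt(k_hs, k_un)
})

test_that("population simulation is seeded, validated, and honest about its truth", {
  s1 <- sim_panel(2, 5, 50, theta = 0.1, f = 0.2, seed = 3)
  s2 <- sim_panel(2, 5, 50, theta = 0.1, f = 0.2, seed = 3)
  expect_identical(s1$panel$dosages, s2$panel$dosages)
  expect_error(sim_panel(2, 5, 50, theta = 1, seed = 1), "theta")
  expect_error(sim_panel(2, 5, 50, f = 2, seed = 1), "f")
  expect_error(sim_panel(2, 5, 50, pi = 0, seed = 1), "pi")
  expect_equal(s1$truth$F_I, rep(0.2 + 0.8 * 0.1, 2))
  expect_equal(s1$truth$theta_S, c(0.1, 0.1))
})

test_that("null simulation hits its expected sharing level", {
  sim <- sim_panel(1, 50, 4000, theta = 0, f = 0, pi = 0.5, seed = 13)
  comp <- allele_sharing(sim$panel)
  # E(A_W) = 1 - 2 pi (1 - pi)(1 - theta_W), theta_W = 1/(2n) at theta = F = 0
  expect_lt(abs(mean(comp$A_W) - (1 - 0.5 * (1 - 1 / 100))), 0.01)
})

test_that("drift identity decays geometrically from the ancestral value", {
  expect_equal(drift_theta(0.2, N = 50, t = 0), 0.2)
  expect_equal(drift_theta(0.2, N = 1e12, t = 500), 0.2, tolerance = 1e-8)
  expect_equal(drift_theta(0, N = 100, t = 100), 1 - 0.995^100)
  # log-identity is linear in t
  th <- drift_theta(0.1, N = 30, t = c(10, 20, 40))
  li <- log((1 - th) / 0.9)
  expect_equal(li[2] / li[1], 2, tolerance = 1e-12)
  expect_equal(li[3] / li[1], 4, tolerance = 1e-12)
  expect_error(drift_theta(1, 10, 1), "theta12")
})
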