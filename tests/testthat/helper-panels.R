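# Random panel generators used across tests. All seeded by the caller.

random_panel <- function(n_per_pop = c(4, 5), n_loci = 12, ploidy = 2,
                         miss_prob = 0, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_pop)
  repeat {
    D <- matrix(sample(0:ploidy, n * n_loci, replace = TRUE), n, n_loci)
    if (miss_prob > 0) {
      D[matrix(runif(n * n_loci) < miss_prob, n, n_loci)] <- NA
    }
    # keep panels where every population is typed at >= 2 individuals per
    # variant, so all per-population statistics are defined
    pops <- rep(paste0("p", seq_along(n_per_pop)), n_per_pop)
    ok <- TRUE
    for (pp in unique(pops)) {
      if (any(colSums(!is.na(D[pops == pp, , drop = FALSE])) < 2)) ok <- FALSE
    }
    if (ok) break
  }
  build_panel(D, pops = pops, ploidy = ploidy)
}

expect_components_equal <- function(a, b, tol = 1e-12) {
  fields <- c("A_S_pop", "A_I_pop", "A_W_pop", "A_D_pop", "A_B_pair",
              "A_S", "A_I", "A_W", "A_D", "A_B", "A_T",
              "A_S_star", "A_I_star", "within", "p_pop")
  strip <- function(x) {
    attributes(x) <- attributes(x)["dim"]
    x
  }
  for (f in fields) {
    expect_equal(strip(is.na(a[[f]])), strip(is.na(b[[f]])),
                 info = paste("NA pattern of", f))
    d <- abs(a[[f]] - b[[f]])
    if (any(!is.na(d))) {
      expect_lt(max(d, na.rm = TRUE), tol, label = paste("max deviation of", f))
    }
  }
}

# two-generation pedigree: founders m1,f1,m2,f2; sibs s1,s2 (of m1,f1);
# half-sib h (m1 with f2); o = offspring of full sibs s1,s2
family_pedigree <- function() {
  pedigree(tibble::tibble(
    id      = c("m1", "f1", "m2", "f2", "s1", "s2", "h", "o"),
    parent1 = c(NA, NA, NA, NA, "m1", "m1", "m1", "s1"),
    parent2 = c(NA, NA, NA, NA, "f1", "f1", "f2", "s2")))
}
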