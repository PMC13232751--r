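#' Build a pedigree
#'
#' @param data Data frame with columns `id`, `parent1`, `parent2`. Founders
#'   have both parents `NA`, `""` or `"0"`. An individual has either two
#'   known parents or none (single known parents are rejected).
#' @return A `pedigree` tibble in topological order (parents before
#'   offspring), with a `founder` logical column.
#' @examples
#' pedigree(tibble::tibble(id = c("m", "f", "o"),
#'                         parent1 = c(NA, NA, "m"), parent2 = c(NA, NA, "f")))
#' @export
pedigree <- function(data) {
  data <- as_tibble(data)
  need <- c("id", "parent1", "parent2")
  if (!all(need %in% names(data))) {
    abort("a pedigree needs columns id, parent1, parent2.")
  }
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0")] <- NA_character_
    x
  }
  data$id <- as.character(data$id)
  data$parent1 <- norm(data$parent1)
  data$parent2 <- norm(data$parent2)
  if (anyDuplicated(data$id)) abort("duplicated individual ids in pedigree.")
  half <- xor(is.na(data$parent1), is.na(data$parent2))
  if (any(half)) {
    abort(sprintf("individual '%s' has exactly one known parent; supply both or none.",
                  data$id[which(half)[1]]))
  }
  known <- c(data$parent1, data$parent2)
  miss <- setdiff(known[!is.na(known)], data$id)
  if (length(miss)) {
    abort(sprintf("parent(s) not present as individuals: %s.",
                  paste(miss, collapse = ", ")))
  }
  data$founder <- is.na(data$parent1)

  # Kahn topological sort; failure means a cycle (an ancestor of itself)
  placed <- character(0)
  remaining <- data
  out <- data[0, ]
  while (nrow(remaining)) {
    ready <- remaining$founder |
      (remaining$parent1 %in% placed & remaining$parent2 %in% placed)
    if (!any(ready)) {
      abort(sprintf("pedigree contains a cycle involving: %s.",
                    paste(remaining$id, collapse = ", ")))
    }
    out <- dplyr::bind_rows(out, remaining[ready, ])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  class(out) <- c("pedigree", class(out))
  out
}

#' Pedigree coancestry and inbreeding by the recursive tabular method
#'
#' Computes the coancestry coefficient for every pair of pedigree members
#' (the probability an allele drawn from each is identical by descent,
#' relative to the founders, who are taken as unrelated and non-inbred) and
#' the inbreeding coefficient of each individual (the coancestry of its
#' parents). Processing individuals parents-first,
#' `theta(j, m) = [theta(p1, m) + theta(p2, m)] / 2` and the self-coancestry
#' is `theta(j, j) = [1 + theta(p1, p2)] / 2`. This is equivalent to summing
#' `(1/2)^n (1 + F_J)` over all paths of `n` individuals joining the pair
#' through each common ancestor `J` (see [coancestry_paths()] for the
#' enumeration oracle).
#'
#' @param ped A [pedigree()].
#' @return A list with `coancestry` (symmetric matrix, self-coancestries
#'   `(1 + F)/2` on the diagonal) and `inbreeding` (named vector).
#' @examples
#' ped <- pedigree(tibble::tibble(id = c("m", "f", "o"),
#'                                parent1 = c(NA, NA, "m"),
#'                                parent2 = c(NA, NA, "f")))
#' pedigree_coancestry(ped)$coancestry["m", "o"]  # 0.25
#' @export
pedigree_coancestry <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  ids <- ped$id
  n <- length(ids)
  th <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    if (ped$founder[j]) {
      th[j, j] <- 0.5
    } else {
      p1 <- match(ped$parent1[j], ids)
      p2 <- match(ped$parent2[j], ids)
      if (j > 1) {
        prev <- seq_len(j - 1)
        th[j, prev] <- (th[p1, prev] + th[p2, prev]) / 2
        th[prev, j] <- th[j, prev]
      }
      th[j, j] <- (1 + th[p1, p2]) / 2
    }
  }
  list(coancestry = th, inbreeding = setNames(2 * diag(th) - 1, ids))
}

#' Pedigree coancestry by explicit path enumeration
#'
#' Brute-force oracle for [pedigree_coancestry()]: enumerates every ascending
#' path from each member of a pair to each common ancestor `J` and sums
#' `(1/2)^n (1 + F_J)` over path pairs that share only `J`, where `n` is the
#' number of individuals in the joining chain. Exponential in pedigree depth;
#' intended for small pedigrees in tests.
#'
#' @inheritParams pedigree_coancestry
#' @return Same structure as [pedigree_coancestry()].
#' @export
coancestry_paths <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  ids <- ped$id
  n <- length(ids)
  parent_idx <- cbind(match(ped$parent1, ids), match(ped$parent2, ids))

  up_paths <- vector("list", n)   # ascending paths (vectors of indices)
  paths_of <- function(j) {
    if (!is.null(up_paths[[j]])) return(up_paths[[j]])
    res <- list(j)
    if (!ped$founder[j]) {
      for (p in parent_idx[j, ]) {
        res <- c(res, lapply(paths_of(p), function(pp) c(j, pp)))
      }
    }
    up_paths[[j]] <<- res
    res
  }
  for (j in seq_len(n)) paths_of(j)

  f_of <- rep(NA_real_, n)
  theta_pair <- function(j, m) {
    tot <- 0
    for (pj in up_paths[[j]]) {
      for (pm in up_paths[[m]]) {
        J <- pj[length(pj)]
        if (J != pm[length(pm)]) next
        if (length(intersect(pj, pm)) != 1L) next   # paths may share only J
        nn <- length(pj) + length(pm) - 1L
        tot <- tot + 0.5^nn * (1 + inbreeding_of(J))
      }
    }
    tot
  }
  inbreeding_of <- function(j) {
    if (!is.na(f_of[j])) return(f_of[j])
    val <- if (ped$founder[j]) 0 else
      theta_pair(parent_idx[j, 1], parent_idx[j, 2])
    f_of[j] <<- val
    val
  }

  th <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    for (m in seq_len(n)) {
      if (m < j) next
      if (m == j) th[j, j] <- (1 + inbreeding_of(j)) / 2
      else th[j, m] <- th[m, j] <- theta_pair(j, m)
    }
  }
  list(coancestry = th, inbreeding = setNames(vapply(seq_len(n), inbreeding_of,
                                                     numeric(1)), ids))
}

#' Gene-dropping simulation through a pedigree
#'
#' Assigns each founder two alleles (designated-allele indicators drawn
#' independently with probability `p` per locus) and transmits one randomly
#' chosen allele from each parent to each offspring, independently per
#' locus. With `track_origin = TRUE` every founder allele gets a unique
#' label that is carried through transmission, so realized identity by
#' descent can be read off the labels (see [realized_ibd()]).
#'
#' @param ped A [pedigree()].
#' @param n_loci Number of independent loci to drop.
#' @param p Designated-allele probability (scalar or length `n_loci`).
#' @param seed Integer seed (required; all randomness is seeded).
#' @param track_origin Keep founder-allele labels?
#' @return A list with `dosages` (individuals x loci), `ped`, and when
#'   tracked, `origin` (individuals x loci x 2 array of founder-allele
#'   labels).
#' @export
gene_drop <- function(ped, n_loci, p = 0.5, seed, track_origin = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  ids <- ped$id
  n <- length(ids)
  p <- rep_len(p, n_loci)
  state <- array(NA_integer_, c(n, n_loci, 2))
  origin <- if (track_origin) array(NA_integer_, c(n, n_loci, 2)) else NULL
  next_label <- 1L
  for (j in seq_len(n)) {
    if (ped$founder[j]) {
      state[j, , 1] <- rbinom(n_loci, 1, p)
      state[j, , 2] <- rbinom(n_loci, 1, p)
      if (track_origin) {
        origin[j, , 1] <- next_label
        origin[j, , 2] <- next_label + 1L
        next_label <- next_label + 2L
      }
    } else {
      p1 <- match(ped$parent1[j], ids)
      p2 <- match(ped$parent2[j], ids)
      pick1 <- sample.int(2, n_loci, replace = TRUE)
      pick2 <- sample.int(2, n_loci, replace = TRUE)
      idx <- cbind(seq_len(n_loci), pick1)
      state[j, , 1] <- state[p1, , ][idx]
      idx2 <- cbind(seq_len(n_loci), pick2)
      state[j, , 2] <- state[p2, , ][idx2]
      if (track_origin) {
        origin[j, , 1] <- origin[p1, , ][idx]
        origin[j, , 2] <- origin[p2, , ][idx2]
      }
    }
  }
  dos <- state[, , 1] + state[, , 2]
  dimnames(dos) <- list(ids, paste0("v", seq_len(n_loci)))
  list(dosages = dos, ped = ped, origin = origin)
}

#' Realized identity-by-descent proportions from a gene drop
#'
#' For every pair of pedigree members, the proportion over loci and allele
#' pairs (one allele from each individual) whose founder-origin labels
#' match: the realized coancestry, which averages to the pedigree coancestry
#' over many independent loci.
#'
#' @param drop A [gene_drop()] result with `track_origin = TRUE`.
#' @return A symmetric matrix of realized ibd proportions (diagonal: within
#'   individual, distinct-allele pairs).
#' @export
realized_ibd <- function(drop) {
  if (is.null(drop$origin)) abort("gene_drop() must be run with track_origin = TRUE.")
  o <- drop$origin
  n <- dim(o)[1]; L <- dim(o)[2]
  out <- matrix(0, n, n, dimnames = list(rownames(drop$dosages),
                                         rownames(drop$dosages)))
  for (j in seq_len(n)) {
    for (m in j:n) {
      if (m == j) {
        out[j, j] <- mean(o[j, , 1] == o[j, , 2])
      } else {
        eq <- (o[j, , 1] == o[m, , 1]) + (o[j, , 1] == o[m, , 2]) +
          (o[j, , 2] == o[m, , 1]) + (o[j, , 2] == o[m, , 2])
        out[j, m] <- out[m, j] <- mean(eq / 4)
      }
    }
  }
  out
}

#' Expected descent measure under pure drift
#'
#' Identity accumulates in a closed population of size `N` as
#' `1 - theta_t = (1 - theta_12) (1 - 1/(2N))^t`, starting from the
#' between-population (ancestral) value `theta_12`; `theta_t` rises to 1 as
#' generations pass. The log-identity `log[(1 - theta_t)/(1 - theta_12)] =
#' t log(1 - 1/(2N))` is linear in time, which is what makes the
#' corresponding F-statistic usable as a drift distance.
#'
#' @param theta12 Descent measure in the ancestral (reference) population,
#'   in `[0, 1)`.
#' @param N Population size (>= 1).
#' @param t Generations since divergence (vectorized, >= 0).
#' @return `theta_t`, same length as `t`.
#' @examples
#' drift_theta(0, N = 100, t = 100)  # ~0.394
#' @export
drift_theta <- function(theta12, N, t) {
  if (theta12 < 0 || theta12 >= 1) abort("`theta12` must lie in [0, 1).")
  if (N < 1) abort("`N` must be >= 1.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  1 - (1 - theta12) * (1 - 1 / (2 * N))^t
}
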