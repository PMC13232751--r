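#' Build a dosage panel from a matrix
#'
#' A dosage panel is the core container: an individuals-by-variants matrix of
#' integer allele dosages (counts of the designated allele, `0..ploidy`, `NA`
#' for missing), together with a population label for every individual and a
#' constant ploidy. All estimators in the package consume panels.
#'
#' @param dosages Integer matrix, individuals in rows, variants in columns.
#'   Entries must lie in `0..ploidy` or be `NA`.
#' @param pops Character (or factor) vector of population labels, one per row.
#' @param ploidy Number of allele copies per individual per locus (default 2).
#' @param individual_ids,variant_ids Optional identifier vectors; taken from
#'   dimnames when present, otherwise generated.
#' @return An object of class `dosage_panel`: a list with elements `dosages`,
#'   `pops` (factor), `ploidy`, `individual_ids`, `variant_ids`, and
#'   `missing_mask` (`TRUE` where the dosage is missing).
#' @examples
#' build_panel(matrix(c(2L, 0L), 2, 1), pops = c("A", "A"))
#' @export
build_panel <- function(dosages, pops, ploidy = 2,
                        individual_ids = NULL, variant_ids = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) < 1L || ncol(dosages) < 1L) {
    abort("`dosages` must have at least one individual and one variant.")
  }
  if (length(pops) != nrow(dosages)) {
    abort(sprintf("length(pops) is %d but the panel has %d individuals.",
                  length(pops), nrow(dosages)))
  }
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) abort("`ploidy` must be a positive integer.")
  if (anyNA(pops)) abort("population labels may not be missing.")

  individual_ids <- as.character(
    individual_ids %||% rownames(dosages) %||% paste0("ind", seq_len(nrow(dosages)))
  )
  variant_ids <- as.character(
    variant_ids %||% colnames(dosages) %||% paste0("v", seq_len(ncol(dosages)))
  )
  bad <- which(!is.na(dosages) &
                 (dosages < 0 | dosages > ploidy | dosages != round(dosages)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(dosages)) + 1L
    l <- ((bad[1] - 1L) %/% nrow(dosages)) + 1L
    abort(sprintf(
      "dosage %s for individual '%s' at variant '%s' is outside 0..%d.",
      format(dosages[bad[1]]), individual_ids[i], variant_ids[l], ploidy))
  }
  dimnames(dosages) <- list(individual_ids, variant_ids)
  structure(
    list(
      dosages = dosages,
      pops = factor(as.character(pops)),
      ploidy = ploidy,
      individual_ids = individual_ids,
      variant_ids = variant_ids,
      missing_mask = is.na(dosages)
    ),
    class = "dosage_panel"
  )
}

#' Build a dosage panel from a tidy data frame
#'
#' Convenience constructor for the data-frame-first workflow: a tibble with an
#' individual-id column, a population column, and one column per variant.
#'
#' @param data Data frame with columns `id`, `pop` (names configurable) and
#'   one integer dosage column per variant.
#' @param ploidy Ploidy, constant for the panel.
#' @param id,pop Names of the identifier and population columns.
#' @return A [build_panel()] object.
#' @examples
#' df <- tibble::tibble(id = c("a", "b"), pop = "P1", v1 = c(2L, 1L))
#' dosage_panel(df)
#' @export
dosage_panel <- function(data, ploidy = 2, id = "id", pop = "pop") {
  data <- as.data.frame(data)
  if (!all(c(id, pop) %in% names(data))) {
    abort(sprintf("`data` must contain columns '%s' and '%s'.", id, pop))
  }
  vcols <- setdiff(names(data), c(id, pop))
  if (!length(vcols)) abort("`data` has no variant columns.")
  m <- as.matrix(data[vcols])
  rownames(m) <- as.character(data[[id]])
  build_panel(m, pops = data[[pop]], ploidy = ploidy,
              individual_ids = data[[id]], variant_ids = vcols)
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf(
    "<dosage_panel> %d individuals x %d variants, ploidy %d, %d population%s (%s)\n",
    nrow(x$dosages), ncol(x$dosages), x$ploidy, nlevels(x$pops),
    if (nlevels(x$pops) == 1) "" else "s",
    paste(levels(x$pops), collapse = ", ")))
  miss <- mean(x$missing_mask)
  if (miss > 0) cat(sprintf("  %.2f%% missing dosages\n", 100 * miss))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.dosage_panel <- function(x, ...) {
  out <- as_tibble(x$dosages, .name_repair = "minimal")
  dplyr::bind_cols(tibble(id = x$individual_ids, pop = as.character(x$pops)), out)
}

n_pops <- function(panel) nlevels(panel$pops)

pop_sizes <- function(panel) as.integer(table(panel$pops))

stopifnot_panel <- function(panel) {
  if (!inherits(panel, "dosage_panel")) {
    abort("expected a `dosage_panel`; build one with build_panel() or dosage_panel().")
  }
  invisible(panel)
}

stopifnot_diploid <- function(panel, what) {
  if (panel$ploidy != 2L) {
    abort(sprintf("%s is defined for diploid data only (panel ploidy is %d).",
                  what, panel$ploidy))
  }
  invisible(panel)
}

#' Reduce a genotypic panel to per-population allele counts
#'
#' Collapses genotypes to allelic data: for every population and variant, the
#' number of designated-allele copies among typed individuals and the total
#' number of typed allele copies. Allelic estimators (Hudson's FST) consume
#' this table; reduction discards within-individual information, so the
#' resulting estimators target random distinct alleles rather than alleles in
#' distinct individuals.
#'
#' @param panel A [build_panel()] object.
#' @return A tibble with columns `pop`, `variant`, `designated`, `total`.
#' @examples
#' p <- build_panel(matrix(c(2L, 1L), 2, 1), pops = c("A", "A"))
#' reduce_to_allelic(p)
#' @export
reduce_to_allelic <- function(panel) {
  stopifnot_panel(panel)
  D <- panel$dosages
  pops <- levels(panel$pops)
  res <- purrr::map_dfr(pops, function(pp) {
    rows <- panel$pops == pp
    sub <- D[rows, , drop = FALSE]
    typed <- colSums(!is.na(sub))
    des <- colSums(sub, na.rm = TRUE)
    tibble(pop = pp, variant = panel$variant_ids,
           designated = as.integer(des),
           total = as.integer(panel$ploidy * typed))
  })
  res
}
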