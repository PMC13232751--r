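#' Read and write dosage panels as TSV
#'
#' The plain-text interchange format for panels: one metadata comment line
#' `#ploidy=<k>`, a header of `id`, `pop` and variant identifiers, then one
#' row per individual with integer dosages (`NA` for missing). Writing then
#' reading reproduces the panel exactly, including the missing mask.
#'
#' @param panel A [build_panel()] object.
#' @param path File path.
#' @return `write_dosage_tsv()` returns `path` invisibly;
#'   `read_dosage_tsv()` returns a `dosage_panel`.
#' @export
write_dosage_tsv <- function(panel, path) {
  stopifnot_panel(panel)
  df <- as_tibble(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ploidy=%d", panel$ploidy), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  header <- readLines(path, n = 5)
  meta <- grep("^#ploidy=", header, value = TRUE)
  ploidy <- if (length(meta)) as.integer(sub("^#ploidy=", "", meta[1])) else 2L
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "pop") %in% names(df))) {
    abort(sprintf("'%s' is not a dosage TSV: columns id and pop are required.",
                  path))
  }
  vcols <- setdiff(names(df), c("id", "pop"))
  bad <- which(!vapply(df[vcols], is.numeric, logical(1)))
  if (length(bad)) {
    abort(sprintf("non-numeric dosage column '%s' in '%s'.", vcols[bad[1]], path))
  }
  dosage_panel(df, ploidy = ploidy)
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file (sample identifier, population label), no
#' header, `#` comments allowed; one VCF can then be analysed under several
#' groupings.
#'
#' @param path File path.
#' @return A tibble with columns `id`, `pop`.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort(sprintf("'%s' must have two columns: sample, population.", path))
  tibble(id = as.character(df[[1]]), pop = as.character(df[[2]]))
}

#' Read a VCF into a dosage panel
#'
#' Parses GT fields into designated-allele dosages. Genotypes must have a
#' constant ploidy across samples and records; half-called genotypes (any
#' missing allele) are treated as fully missing. Biallelic records give one
#' variant with the dosage of the designated (`REF` or `ALT`) allele.
#' Multiallelic records are split into one biallelic layer per alternate
#' allele (dosage of that allele vs all others); the layers then enter
#' multi-locus sums like additional variants, which is the genotypic
#' summation convention for multiple alleles.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param pop_map Optional population assignment: a path to a
#'   [read_pop_map()] file or a data frame with columns `id`, `pop`. With
#'   `NULL`, all samples form one population `"all"`.
#' @param designated Which allele to count in biallelic records.
#' @return A [build_panel()] object; variant ids are `CHROM:POS` (with an
#'   `_<allele>` suffix for multiallelic layers).
#' @export
read_vcf_panel <- function(path, pop_map = NULL, designated = c("ALT", "REF")) {
  designated <- match.arg(designated)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || !nrow(gt)) abort("no GT genotypes found in the VCF.")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {           # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  samples <- colnames(gt)

  split_gt <- function(g) strsplit(g, "[/|]")
  ploidies <- unique(unlist(lapply(split_gt(gt[!is.na(gt)]), length)))
  ploidies <- setdiff(ploidies, 0L)
  if (length(ploidies) > 1) {
    abort(sprintf("mixed ploidy in GT fields (%s); a panel needs constant ploidy.",
                  paste(sort(ploidies), collapse = ", ")))
  }
  ploidy <- if (length(ploidies)) ploidies else 2L

  cols <- list()
  ids <- character(0)
  for (v in seq_len(nrow(gt))) {
    alts <- strsplit(fix[v, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- split_gt(gt[v, ])
    counts <- function(target) {
      vapply(alleles, function(al) {
        if (length(al) != ploidy || anyNA(al) || any(al == ".")) return(NA_real_)
        sum(al == as.character(target))
      }, numeric(1))
    }
    base_id <- paste0(fix[v, "CHROM"], ":", fix[v, "POS"])
    if (length(alts) <= 1) {
      cols[[length(cols) + 1L]] <- counts(if (designated == "ALT") 1 else 0)
      ids <- c(ids, base_id)
    } else {
      for (u in seq_along(alts)) {
        cols[[length(cols) + 1L]] <- counts(u)
        ids <- c(ids, paste0(base_id, "_", alts[u]))
      }
    }
  }
  D <- do.call(cbind, cols)
  rownames(D) <- samples
  colnames(D) <- ids

  if (is.null(pop_map)) {
    pops <- rep("all", length(samples))
  } else {
    pm <- if (is.character(pop_map)) read_pop_map(pop_map) else as_tibble(pop_map)
    idx <- match(samples, pm$id)
    if (anyNA(idx)) {
      abort(sprintf("samples without a population assignment: %s.",
                    paste(samples[is.na(idx)], collapse = ", ")))
    }
    pops <- pm$pop[idx]
  }
  build_panel(D, pops = pops, ploidy = ploidy)
}

#' Read and write pedigrees as TSV
#'
#' Three columns (`id`, `parent1`, `parent2`), tab separated, with header;
#' `0` or empty marks a founder.
#'
#' @param ped A [pedigree()].
#' @param path File path.
#' @return `write_pedigree_tsv()` returns `path` invisibly;
#'   `read_pedigree_tsv()` returns a `pedigree`.
#' @export
write_pedigree_tsv <- function(ped, path) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  df <- as.data.frame(ped[c("id", "parent1", "parent2")])
  df$parent1[is.na(df$parent1)] <- "0"
  df$parent2[is.na(df$parent2)] <- "0"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  pedigree(df)
}

#' Write a kinship matrix as annotated TSV
#'
#' Square matrix with individual identifiers as header row and first
#' column, preceded by `#`-prefixed metadata lines recording the estimator
#' family and reference set.
#'
#' @param x A `kinship_matrix` (from [as_kinship()], [standard_kinship()],
#'   [king_robust()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(x, path) {
  if (!inherits(x, "kinship_matrix")) abort("`x` must be a kinship_matrix.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#family=%s", x$family),
               sprintf("#reference=%s", x$reference)), con)
  df <- data.frame(id = rownames(x$entries), x$entries, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
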