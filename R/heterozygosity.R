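#' Observed heterozygosity
#'
#' Per-locus observed heterozygosity is the fraction of non-missing
#' genotypes that are heterozygous; the multi-locus value is the unweighted
#' mean over loci with at least one non-missing genotype. Loci with no data
#' are dropped from the mean (locus-wise deletion, the standard treatment
#' for microsatellite panels with scattered missingness).
#'
#' @param table a [genotype_table()].
#' @return A list with `per_locus` (named numeric vector, `NA` for loci with
#'   no data) and `mean`.
#' @export
observed_heterozygosity <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  per <- vapply(loci(table), function(loc) {
    al <- locus_alleles(table, loc)
    ok <- !is.na(al[, 1])
    if (!any(ok)) return(NA_real_)
    mean(al[ok, 1] != al[ok, 2])
  }, numeric(1))
  if (all(is.na(per)))
    stop("genotype table contains no non-missing genotypes")
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Nei's unbiased expected heterozygosity
#'
#' Per locus, with `n` non-missing genotypes and allele frequencies `p_i`,
#' the unbiased estimator is `(2n / (2n - 1)) * (1 - sum(p_i^2))`. The
#' multi-locus value is the unweighted mean over estimable loci. A locus
#' with fewer than two non-missing genotypes cannot be estimated; it is
#' skipped with a warning, or rejected when `strict = TRUE`.
#'
#' @param table a [genotype_table()].
#' @param strict error (rather than warn and skip) on loci with fewer than
#'   two non-missing genotypes.
#' @return A list with `per_locus`, `mean`, and `n` (non-missing genotype
#'   count per locus).
#' @export
expected_heterozygosity <- function(table, strict = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  locs <- loci(table)
  n <- numeric(length(locs)); names(n) <- locs
  per <- rep(NA_real_, length(locs)); names(per) <- locs
  for (loc in locs) {
    al <- locus_alleles(table, loc)
    obs <- al[!is.na(al[, 1]), , drop = FALSE]
    n[loc] <- nrow(obs)
    if (nrow(obs) < 2) {
      if (strict)
        stop("locus ", loc, ": fewer than 2 non-missing genotypes")
      warning("locus ", loc,
              " skipped: fewer than 2 non-missing genotypes")
      next
    }
    p <- tabulate(factor(c(obs[, 1], obs[, 2])))
    p <- p / sum(p)
    nn <- nrow(obs)
    per[loc] <- (2 * nn / (2 * nn - 1)) * (1 - sum(p^2))
  }
  if (all(is.na(per))) stop("no locus with >= 2 non-missing genotypes")
  list(per_locus = per, mean = mean(per, na.rm = TRUE), n = n)
}
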