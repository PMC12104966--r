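#' Private alleles and immigrant-offspring flagging
#'
#' An allele is private to the candidate set if it is carried by at least
#' one candidate and never occurs in the reference table (e.g., the
#' population as genotyped before any translocation). Individuals carrying
#' at least one private allele are flagged as putative first-generation
#' offspring of immigrants: a single private allele suffices because a
#' parent outside the reference gene pool must transmit alleles absent from
#' it, while reference-bred animals cannot carry them (barring mutation or
#' genotyping error, which this screen does not model).
#'
#' @param reference a [genotype_table()] defining the baseline allele pool;
#'   must be non-empty.
#' @param candidates a [genotype_table()] of individuals to screen. Loci
#'   are matched by name; loci absent from the reference are ignored.
#' @return A list with components:
#'   \item{per_locus}{named list of integer vectors of private alleles;}
#'   \item{n_private}{total count of private alleles across loci;}
#'   \item{n_loci}{number of loci carrying at least one private allele;}
#'   \item{flagged}{data frame `individual_id`, `n_private_alleles`,
#'     `f1_candidate`.}
#' @export
private_alleles <- function(reference, candidates) {
  stopifnot(inherits(reference, "genotype_table"),
            inherits(candidates, "genotype_table"))
  if (nrow(reference) == 0) stop("reference table is empty")
  locs <- intersect(loci(candidates), loci(reference))
  per <- lapply(locs, function(loc) {
    ref_alleles <- unique(as.vector(locus_alleles(reference, loc)))
    cand_alleles <- unique(as.vector(locus_alleles(candidates, loc)))
    sort(setdiff(cand_alleles[!is.na(cand_alleles)],
                 ref_alleles[!is.na(ref_alleles)]))
  })
  names(per) <- locs
  carries <- rep(0L, nrow(candidates))
  for (loc in locs) {
    priv <- per[[loc]]
    if (!length(priv)) next
    al <- locus_alleles(candidates, loc)
    carries <- carries + (al[, 1] %in% priv) + (al[, 2] %in% priv)
  }
  list(per_locus = per,
       n_private = sum(lengths(per)),
       n_loci = sum(lengths(per) > 0),
       flagged = data.frame(individual_id = candidates$individual_id,
                            n_private_alleles = carries,
                            f1_candidate = carries > 0L))
}

#' @rdname private_alleles
#' @param individual_id id to look up in the screening result.
#' @param screen result of `private_alleles()`.
#' @return `flag_f1` returns a single logical.
#' @export
flag_f1 <- function(screen, individual_id) {
  i <- match(individual_id, screen$flagged$individual_id)
  if (is.na(i)) stop("individual not in screened candidates: ", individual_id)
  screen$flagged$f1_candidate[i]
}
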