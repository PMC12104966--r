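#' Genotype tables
#'
#' A genotype table holds one row per individual: an identifier, the sample
#' date, a group label describing the individual's origin (remnant
#' population, translocated, first-generation offspring of a translocated
#' animal, later-generation offspring, or unknown), the translocation
#' destination (the reinforced core population, the stepping-stone release
#' area, or none), and two integer allele columns per microsatellite locus
#' (`<locus>_a1`, `<locus>_a2`). Missing genotypes are encoded as `NA` on
#' both allele columns; a half-missing genotype is rejected.
#'
#' @param df data frame with columns `individual_id`, `sample_date`,
#'   `group`, `destination`, followed by paired allele columns.
#' @param loci character vector of locus names; defaults to every name
#'   inferred from `<locus>_a1`/`<locus>_a2` column pairs.
#' @return An object of class `genotype_table` (a data frame with a `loci`
#'   attribute).
#' @examples
#' df <- data.frame(individual_id = c("a", "b"),
#'                  sample_date = as.Date(c("2020-01-01", "2020-06-01")),
#'                  group = "remnant", destination = "none",
#'                  L1_a1 = c(1L, 1L), L1_a2 = c(2L, 1L))
#' gt <- genotype_table(df)
#' observed_heterozygosity(gt)
#' @export
genotype_table <- function(df, loci = NULL) {
  stopifnot(is.data.frame(df))
  req <- c("individual_id", "sample_date", "group", "destination")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("genotype table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id))
    stop("individual_id must be unique within a genotype table")
  df$individual_id <- as.character(df$individual_id)
  df$sample_date <- as.Date(df$sample_date)
  if (anyNA(df$sample_date)) stop("sample_date must parse to a finite date")
  df$group <- match_enum(df$group, GROUP_LEVELS, "group")
  df$destination <- match_enum(df$destination, DEST_LEVELS, "destination")
  if (is.null(loci)) {
    a1 <- grep("_a1$", names(df), value = TRUE)
    loci <- sub("_a1$", "", a1)
  }
  for (loc in loci) {
    c1 <- paste0(loc, "_a1"); c2 <- paste0(loc, "_a2")
    if (!c1 %in% names(df) || !c2 %in% names(df))
      stop("missing allele columns for locus ", loc)
    df[[c1]] <- as.integer(df[[c1]]); df[[c2]] <- as.integer(df[[c2]])
    half <- xor(is.na(df[[c1]]), is.na(df[[c2]]))
    if (any(half))
      stop("locus ", loc, ": allele pair must be both present or both missing")
  }
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

GROUP_LEVELS <- c("remnant", "translocated", "offspring_f1",
                  "offspring_later", "unknown")
DEST_LEVELS <- c("dinaric", "alpine_stepping_stone", "none")

match_enum <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !x %in% levels
  if (any(bad))
    stop("invalid ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x), "individuals,",
      length(attr(x, "loci")), "loci\n")
  cat("Groups:", paste(names(table(x$group)), table(x$group),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_table
#' @export
loci <- function(table) attr(table, "loci")

# Extract the n x 2 allele matrix for one locus (NA rows = missing).
locus_alleles <- function(table, locus) {
  cbind(table[[paste0(locus, "_a1")]], table[[paste0(locus, "_a2")]])
}

#' Read and write genotype CSV files
#'
#' The on-disk format has header
#' `individual_id,sample_date,group,destination,<locus>_a1,<locus>_a2,...`
#' with ISO-8601 dates; a missing allele is an empty field or `0`. The
#' reader/writer pair round-trips losslessly.
#'
#' @param path file path.
#' @param table a `genotype_table`.
#' @return `read_genotypes` returns a `genotype_table`; `write_genotypes`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  allele_cols <- grep("_a[12]$", names(df), value = TRUE)
  for (cc in allele_cols) {
    v <- df[[cc]]
    v[!is.na(v) & v == 0] <- NA
    df[[cc]] <- as.integer(v)
  }
  genotype_table(df)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  df <- as.data.frame(table)
  df$sample_date <- format(df$sample_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
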