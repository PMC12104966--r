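# Compact constructors for small genotype tables used across tests.

# make_gt(list(L1 = rbind(c(1,2), c(1,1))), groups = ...)
# Each list element is an n x 2 allele matrix for one locus (NA = missing).
make_gt <- function(allele_list, groups = NULL, destinations = NULL,
                    dates = NULL, ids = NULL) {
  n <- nrow(allele_list[[1]])
  df <- data.frame(
    individual_id = ids %||% sprintf("i%03d", seq_len(n)),
    sample_date = dates %||% (as.Date("2020-01-01") + seq_len(n) - 1),
    group = groups %||% rep("remnant", n),
    destination = destinations %||% rep("none", n))
  for (loc in names(allele_list)) {
    df[[paste0(loc, "_a1")]] <- as.integer(allele_list[[loc]][, 1])
    df[[paste0(loc, "_a2")]] <- as.integer(allele_list[[loc]][, 2])
  }
  genotype_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 50 tracking periods, 5 ending in disappearance; one animal monitored
# twice (two independent periods).
fifty_periods <- function() {
  set.seed(61)
  status <- c(rep("alive", 33), rep("disappeared", 5),
              rep(c("suspected_illegal_killing",
                    "confirmed_illegal_killing", "roadkill",
                    "natural_mortality"), 3))
  ids <- c(sprintf("lx%02d", 1:49), "lx01")  # lx01 recaptured
  data.frame(animal_id = ids,
             group = rep(c("translocated", "f1", "remnant"),
                         length.out = 50),
             start = as.Date("2019-05-01"),
             end = as.Date("2019-05-01") + sample(30:1400, 50,
                                                  replace = TRUE),
             end_status = sample(status))
}

# Random genotype table: n individuals, L loci, k alleles, missingness rate.
random_gt <- function(n, L = 3, k = 4, miss = 0.1) {
  al <- lapply(seq_len(L), function(l) {
    m <- matrix(sample.int(k, 2 * n, replace = TRUE), n, 2)
    gone <- runif(n) < miss
    m[gone, ] <- NA
    m
  })
  names(al) <- sprintf("L%d", seq_len(L))
  make_gt(al)
}
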