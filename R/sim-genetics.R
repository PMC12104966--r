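#' Simulate a founder-bottleneck microsatellite population with optional
#' immigrant reinforcement
#'
#' Emulates the genetic history of a population founded by a handful of
#' individuals drawn from a diverse source: per-locus source allele
#' frequencies are calibrated so the source-sample expected heterozygosity
#' matches a target (default 0.592); a small founder group then drifts
#' through discrete Wright-Fisher-style generations at low effective size,
#' eroding heterozygosity; optionally, outbred immigrants carrying a
#' disjoint allele-identifier range are injected at a stated generation.
#' Immigrants released into the core area join the core breeding pool,
#' while stepping-stone immigrants found a separate subpopulation that
#' breeds on its own — mirroring a reinforcement plus stepping-stone
#' design, where the counterfactual ("remnant only"), the core
#' reinforcement, and the fully connected system form nested sample sets
#' with decreasing inbreeding.
#'
#' Every simulated individual is emitted as one genotype record with a
#' sample date (one nominal year per generation), a group label
#' (`remnant`, `translocated`, `offspring_f1`, `offspring_later`), a
#' destination label for immigrants and their descendants, and true
#' parents in the truth sidecar.
#'
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @param n_founders founder count (default 6).
#' @param n_loci number of microsatellite loci (default 19).
#' @param n_alleles alleles per locus in the source pool (default 6).
#' @param source_he target source expected heterozygosity (default 0.592);
#'   per-locus frequencies are Dirichlet-drawn and resampled until the
#'   locus' expected heterozygosity is within `he_tol` of the target.
#' @param he_tol calibration tolerance (default 0.01).
#' @param n_generations generations of drift (default 40).
#' @param ne per-generation size of the core population after the founder
#'   generation (default 20).
#' @param immigrants `NULL`, or a list with elements `generation`
#'   (injection time), `n_dinaric` (immigrants joining the core pool),
#'   `n_alpine` (immigrants founding the stepping-stone pool),
#'   `ne_alpine` (per-generation stepping-stone size, default 10), and
#'   `n_excluded` (dinaric immigrants that never reproduce, emitted and
#'   flagged `excluded` in the truth table, default 0). Immigrant alleles
#'   are drawn uniformly from a disjoint identifier range (source allele
#'   ids + 100).
#' @param start_date date of generation-0 samples (default
#'   `"1980-01-01"`); each generation advances one nominal year.
#' @return A list: `table` (a [genotype_table()] of all individuals),
#'   `truth` (data frame with `individual_id`, `generation`, `group`,
#'   `destination`, `mother_id`, `father_id`, `excluded`), and
#'   `source_frequencies` (per-locus allele frequency vectors).
#' @export
simulate_drift_population <- function(seed = 1L, n_founders = 6L,
                                      n_loci = 19L, n_alleles = 6L,
                                      source_he = 0.592, he_tol = 0.01,
                                      n_generations = 40L, ne = 20L,
                                      immigrants = NULL,
                                      start_date = as.Date("1980-01-01")) {
  stopifnot(n_founders >= 2, ne >= 2, n_loci >= 1, n_alleles >= 2)
  max_he <- 1 - 1 / n_alleles
  if (source_he > max_he - he_tol)
    stop("target He ", source_he, " unattainable with ", n_alleles,
         " alleles (max attainable ", round(max_he, 3), ")")
  with_seed(derive_seed(seed, "drift"), {
    locs <- sprintf("L%02d", seq_len(n_loci))
    freqs <- lapply(locs, function(l)
      calibrate_locus_freqs(n_alleles, source_he, he_tol))
    names(freqs) <- locs

    counter <- 0L
    new_id <- function(prefix) {
      counter <<- counter + 1L
      sprintf("%s%04d", prefix, counter)
    }
    draw_source_genotype <- function(shift = 0L) {
      g <- vapply(freqs, function(p)
        sample.int(length(p), 2, replace = TRUE, prob = p), integer(2))
      g + shift
    }

    all_records <- list(); truth_rows <- list()
    emit <- function(ind, gen, excluded = FALSE) {
      rec <- c(list(individual_id = ind$id,
                    sample_date = start_date + round(gen * 365.25),
                    group = ind$group, destination = ind$destination),
               as.list(stats::setNames(as.vector(ind$geno),
                                       paste0(rep(locs, each = 2),
                                              c("_a1", "_a2")))))
      all_records[[length(all_records) + 1L]] <<- as.data.frame(rec)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        individual_id = ind$id, generation = gen, group = ind$group,
        destination = ind$destination, mother_id = ind$mother,
        father_id = ind$father, excluded = excluded)
    }
    make_offspring <- function(pool, n_off, prefix_pool) {
      lapply(seq_len(n_off), function(i) {
        pa <- sample.int(length(pool), 2, replace = FALSE)
        m <- pool[[pa[1]]]; f <- pool[[pa[2]]]
        geno <- vapply(seq_len(length(locs)), function(l)
          c(m$geno[sample.int(2, 1), l], f$geno[sample.int(2, 1), l]),
          integer(2))
        par_groups <- c(m$group, f$group)
        grp <- if (any(par_groups == "translocated")) "offspring_f1"
          else if (any(par_groups %in% c("offspring_f1",
                                         "offspring_later")))
            "offspring_later" else "remnant"
        dst <- if (grp == "remnant") "none" else {
          dsts <- c(m$destination, f$destination)
          if ("dinaric" %in% dsts) "dinaric"
          else if ("alpine_stepping_stone" %in% dsts)
            "alpine_stepping_stone" else "none"
        }
        list(id = new_id(if (grp == "remnant") "RM" else
                         paste0("OF", prefix_pool)),
             geno = geno, group = grp, destination = dst,
             mother = m$id, father = f$id)
      })
    }

    core <- lapply(seq_len(n_founders), function(i)
      list(id = new_id("RM"), geno = draw_source_genotype(),
           group = "remnant", destination = "none",
           mother = NA_character_, father = NA_character_))
    for (ind in core) emit(ind, 0L)
    alpine <- list()

    imm_gen <- if (is.null(immigrants)) NA_integer_ else
      as.integer(immigrants$generation)
    for (gen in seq_len(n_generations)) {
      if (!is.na(imm_gen) && gen == imm_gen) {
        n_din <- immigrants$n_dinaric %||% 0L
        n_alp <- immigrants$n_alpine %||% 0L
        n_exc <- immigrants$n_excluded %||% 0L
        for (i in seq_len(n_din + n_exc)) {
          ind <- list(id = new_id("TR"),
                      geno = draw_source_genotype(shift = 100L),
                      group = "translocated", destination = "dinaric",
                      mother = NA_character_, father = NA_character_)
          excluded <- i > n_din
          emit(ind, gen, excluded = excluded)
          if (!excluded) core[[length(core) + 1L]] <- ind
        }
        for (i in seq_len(n_alp)) {
          ind <- list(id = new_id("TR"),
                      geno = draw_source_genotype(shift = 100L),
                      group = "translocated",
                      destination = "alpine_stepping_stone",
                      mother = NA_character_, father = NA_character_)
          emit(ind, gen)
          alpine[[length(alpine) + 1L]] <- ind
        }
      }
      core <- make_offspring(core, ne, "C")
      for (ind in core) emit(ind, gen)
      if (length(alpine) >= 2) {
        alpine <- make_offspring(alpine,
                                 immigrants$ne_alpine %||% 10L, "A")
        for (ind in alpine) emit(ind, gen)
      }
    }
    records <- do.call(rbind, all_records)
    list(table = genotype_table(records, loci = locs),
         truth = do.call(rbind, truth_rows),
         source_frequencies = freqs)
  })
}

# Dirichlet(1, ..., 1) frequency draws, resampled until the locus'
# expected heterozygosity (1 - sum p^2) is within tolerance of the target.
calibrate_locus_freqs <- function(n_alleles, target_he, tol,
                                  max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    g <- stats::rgamma(n_alleles, 1)
    p <- g / sum(g)
    if (abs(1 - sum(p^2) - target_he) <= tol) return(p)
  }
  stop("could not calibrate allele frequencies to He = ", target_he)
}
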