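#' Simulate censored tracking periods in groups
#'
#' Per group, event (death) times are exponential with the group's hazard
#' and censoring is uniform on `(0, max_follow_days)`: the recorded time
#' is the smaller of the two, `alive` when censoring wins, otherwise an
#' end status drawn from a configured mortality-cause mix. A configurable
#' fraction of animals is relabelled `disappeared` (fate unknown) at
#' their recorded end time, mimicking lost collars.
#'
#' @param seed integer seed.
#' @param groups named numeric vector of per-day hazards, e.g.
#'   `c(translocated = 1/1500, f1 = 1/2000, remnant = 1/900)`.
#' @param n_per_group animals per group (recycled; default 20).
#' @param max_follow_days maximum follow-up (default 1440).
#' @param cause_mix named probabilities over mortality causes (defaults
#'   to an even split of suspected/confirmed illegal killing, roadkill,
#'   natural mortality).
#' @param p_disappeared probability a period is relabelled disappeared
#'   (default 0).
#' @param start_date nominal tracking start (default `"2019-05-01"`).
#' @return A list: `periods` (data frame `animal_id`, `group`, `start`,
#'   `end`, `end_status`) and `truth` (hazards and the true event
#'   indicator before the disappeared relabelling).
#' @export
simulate_survival <- function(seed = 1L,
                              groups = c(translocated = 1 / 1500,
                                         f1 = 1 / 2000,
                                         remnant = 1 / 900),
                              n_per_group = 20L, max_follow_days = 1440,
                              cause_mix = c(suspected_illegal_killing = 0.3,
                                            confirmed_illegal_killing = 0.3,
                                            roadkill = 0.2,
                                            natural_mortality = 0.2),
                              p_disappeared = 0,
                              start_date = as.Date("2019-05-01")) {
  stopifnot(all(groups >= 0), length(groups) >= 1,
            abs(sum(cause_mix) - 1) < 1e-8)
  n_per_group <- rep(n_per_group, length.out = length(groups))
  with_seed(derive_seed(seed, "survival"), {
    rows <- list(); truth <- list()
    for (g in seq_along(groups)) {
      gname <- names(groups)[g]
      for (i in seq_len(n_per_group[g])) {
        t_event <- if (groups[g] > 0)
          stats::rexp(1, rate = groups[g]) else Inf
        t_cens <- stats::runif(1, 0, max_follow_days)
        t_obs <- min(t_event, t_cens)
        died <- t_event <= t_cens
        status <- if (!died) "alive" else
          sample(names(cause_mix), 1, prob = cause_mix)
        if (stats::runif(1) < p_disappeared) status <- "disappeared"
        id <- sprintf("%s_%03d", gname, i)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = gname, start = start_date,
          end = start_date + round(t_obs), end_status = status)
        truth[[length(truth) + 1L]] <- data.frame(
          animal_id = id, group = gname, true_event = died,
          true_time = t_obs)
      }
    }
    list(periods = do.call(rbind, rows),
         truth = list(hazards = groups,
                      records = do.call(rbind, truth)))
  })
}
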