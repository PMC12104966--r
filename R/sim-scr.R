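#' Simulate a multi-session SCR dataset
#'
#' Generates capture histories from the same half-normal encounter model
#' the SCR likelihood assumes: per session, `N ~ Poisson(D * A)` activity
#' centers are placed uniformly on the state-space cells, each individual
#' is assigned a sex, and Bernoulli detections are drawn per trap and
#' occasion with `p = p0 * exp(-d^2 / (2 sigma^2))`, optionally with a
#' male effect on `p0` (logit scale) and/or `sigma` (log scale) and a
#' trap-specific behavioral response switching after first capture.
#'
#' @param seed integer seed.
#' @param traps data frame `trap_id`, `x`, `y`, `location_type` (reused in
#'   every session); see [make_trap_grid()] for a quick lattice.
#' @param grid a [build_state_space()] grid defining the simulation arena
#'   (activity centers uniform over its cells).
#' @param density true density per 100 km^2 (default 1.0).
#' @param p0 baseline female detection probability per occasion
#'   (default 0.1).
#' @param sigma spatial scale in meters (default 2500).
#' @param n_sessions number of survey years (default 3).
#' @param n_occasions occasions per session (default 10).
#' @param beta_sex_p0 male effect on logit(p0) (default 0).
#' @param beta_sex_sigma male effect on log(sigma) (default 0).
#' @param beta_b behavioral-response effect on logit(p0) (default 0).
#' @param sex_ratio probability an individual is male (default 0.5).
#' @return A list: `data` (a [capture_data()] object; sessions with no
#'   detections are dropped from the detection table but keep their
#'   traps), and `truth` (true parameter list plus per-session realized
#'   `N` and activity centers).
#' @export
simulate_scr_dataset <- function(seed = 1L, traps, grid, density = 1.0,
                                 p0 = 0.1, sigma = 2500,
                                 n_sessions = 3L, n_occasions = 10L,
                                 beta_sex_p0 = 0, beta_sex_sigma = 0,
                                 beta_b = 0, sex_ratio = 0.5) {
  stopifnot(is.data.frame(traps), inherits(grid, "state_space"))
  with_seed(derive_seed(seed, "scr"), {
    A <- state_space_area(grid)
    sessions <- sprintf("Y%d", seq_len(n_sessions))
    trap_rows <- list(); det_rows <- list(); truth_N <- integer(n_sessions)
    centers <- list()
    eta0 <- stats::qlogis(p0)
    for (s in seq_len(n_sessions)) {
      trap_rows[[s]] <- data.frame(session = sessions[s],
                                   trap_id = traps$trap_id,
                                   x = traps$x, y = traps$y,
                                   location_type = traps$location_type,
                                   n_occasions_active = n_occasions)
      N <- stats::rpois(1, density * A / 100)
      truth_N[s] <- N
      if (N == 0) next
      cells <- sample.int(nrow(grid), N, replace = TRUE)
      # jitter uniformly within the cell so centers are continuous
      half <- attr(grid, "cell") / 2
      cx <- grid$x[cells] + stats::runif(N, -half, half)
      cy <- grid$y[cells] + stats::runif(N, -half, half)
      sex <- ifelse(stats::runif(N) < sex_ratio, "male", "female")
      centers[[sessions[s]]] <- data.frame(x = cx, y = cy, sex = sex)
      for (i in seq_len(N)) {
        eta_i <- eta0 + if (sex[i] == "male") beta_sex_p0 else 0
        sig_i <- sigma * exp(if (sex[i] == "male") beta_sex_sigma else 0)
        d2 <- (traps$x - cx[i])^2 + (traps$y - cy[i])^2
        kern <- exp(-d2 / (2 * sig_i^2))
        caught_at <- rep(FALSE, nrow(traps))
        for (k in seq_len(n_occasions)) {
          p <- stats::plogis(eta_i + beta_b * caught_at) * kern
          y <- stats::runif(nrow(traps)) < p
          if (any(y)) {
            det_rows[[length(det_rows) + 1L]] <- data.frame(
              session = sessions[s],
              individual_id = sprintf("%s_i%03d", sessions[s], i),
              sex = sex[i], trap_id = traps$trap_id[y], occasion = k)
            caught_at <- caught_at | y
          }
        }
      }
    }
    dets <- if (length(det_rows)) do.call(rbind, det_rows) else
      data.frame(session = character(), individual_id = character(),
                 sex = character(), trap_id = character(),
                 occasion = integer())
    list(data = capture_data(dets, do.call(rbind, trap_rows)),
         truth = list(density = density, p0 = p0, sigma = sigma,
                      beta_sex_p0 = beta_sex_p0,
                      beta_sex_sigma = beta_sex_sigma, beta_b = beta_b,
                      N = stats::setNames(truth_N, sessions),
                      area_km2 = A, centers = centers))
  })
}

#' @rdname simulate_scr_dataset
#' @param nx,ny trap lattice dimensions.
#' @param spacing trap spacing in meters.
#' @param origin lattice origin (x = y) in meters.
#' @param location_type recycled over traps.
#' @export
make_trap_grid <- function(nx = 7L, ny = 7L, spacing = 2500,
                           origin = 0, location_type = "marking_site") {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(trap_id = sprintf("T%03d", seq_len(nrow(g))),
             x = origin + (g$ix - 1) * spacing,
             y = origin + (g$iy - 1) * spacing,
             location_type = rep(location_type, length.out = nrow(g)))
}
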