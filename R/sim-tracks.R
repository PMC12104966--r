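#' Simulate a GPS track with embedded kill clusters
#'
#' Generates the two-phase movement pattern kill-site screening relies
#' on: the animal alternates between handling phases (fixes jittered
#' tightly around a kill location for a gamma-distributed handling time)
#' and travel phases (a correlated random walk with step lengths much
#' larger than the cluster radius, so travel fixes do not aggregate).
#' Inter-kill intervals are gamma distributed; a kill's handling time is
#' truncated when the next kill arrives first. Defaults reflect reported
#' lynx predation tempo on large prey: mean inter-kill interval about
#' 4.37 days and mean feeding time about 2.41 days.
#'
#' @param seed integer seed.
#' @param n_kills number of kills (0 gives a pure travel track).
#' @param fix_rate GPS fixes per day (default 8).
#' @param duration_days track length in days; defaults to enough to cover
#'   all kills plus a day.
#' @param ik_shape,ik_mean gamma shape and mean (days) of inter-kill
#'   intervals (defaults 2 and 4.37).
#' @param handling_shape,handling_mean gamma shape and mean (days) of
#'   handling time (defaults 3 and 2.41).
#' @param jitter_sd isotropic fix jitter around the kill point in meters
#'   (default 40, well inside a 200-m cluster radius).
#' @param travel_step travel-phase step length per fix in meters
#'   (default 1000).
#' @param travel_heading_sd standard deviation (radians) of the per-fix
#'   turning angle of the travel walk (default 0.2; straighter walks
#'   revisit their own path less, keeping travel fixes from aggregating
#'   into spurious clusters).
#' @param start_time first fix time (default `"2021-01-01 00:00:00"` UTC).
#' @param animal_id id stamped on the track.
#' @return A list: `track` (data frame `animal_id`, `timestamp`, `x`,
#'   `y`) and `truth` (data frame of true kill `time`, `end_time`
#'   (handling end), `x`, `y`).
#' @export
simulate_track <- function(seed = 1L, n_kills = 20L, fix_rate = 8,
                           duration_days = NULL, ik_shape = 2,
                           ik_mean = 4.37, handling_shape = 3,
                           handling_mean = 2.41, jitter_sd = 40,
                           travel_step = 1000,
                           travel_heading_sd = 0.2,
                           start_time = as.POSIXct("2021-01-01 00:00:00",
                                                   tz = "UTC"),
                           animal_id = "A1") {
  stopifnot(fix_rate > 0, n_kills >= 0)
  with_seed(derive_seed(seed, "tracks"), {
    kill_times <- if (n_kills > 0)
      cumsum(stats::rgamma(n_kills, shape = ik_shape,
                           scale = ik_mean / ik_shape)) else numeric(0)
    handling <- if (n_kills > 0)
      stats::rgamma(n_kills, shape = handling_shape,
                    scale = handling_mean / handling_shape) else numeric(0)
    # truncate handling at the next kill
    if (n_kills > 1)
      handling[-n_kills] <- pmin(handling[-n_kills], diff(kill_times))
    if (is.null(duration_days))
      duration_days <- if (n_kills > 0)
        kill_times[n_kills] + handling[n_kills] + 1 else 30
    # kill locations: successive displacements well above cluster scale
    kx <- ky <- numeric(n_kills)
    px <- py <- 0
    heading <- stats::runif(1, 0, 2 * pi)
    for (k in seq_len(n_kills)) {
      step <- stats::runif(1, 2000, 5000)
      heading <- heading + stats::rnorm(1, 0, 0.8)
      px <- px + step * cos(heading); py <- py + step * sin(heading)
      kx[k] <- px; ky[k] <- py
    }
    t_fix <- seq(0, duration_days, by = 1 / fix_rate)
    n <- length(t_fix)
    x <- y <- numeric(n)
    cur_x <- 0; cur_y <- 0
    for (i in seq_len(n)) {
      k <- if (n_kills > 0)
        which(t_fix[i] >= kill_times & t_fix[i] <= kill_times + handling)
      else integer(0)
      if (length(k)) {
        k <- k[length(k)]
        x[i] <- kx[k] + stats::rnorm(1, 0, jitter_sd)
        y[i] <- ky[k] + stats::rnorm(1, 0, jitter_sd)
        cur_x <- x[i]; cur_y <- y[i]
      } else {
        heading <- heading + stats::rnorm(1, 0, travel_heading_sd)
        cur_x <- cur_x + travel_step * cos(heading)
        cur_y <- cur_y + travel_step * sin(heading)
        x[i] <- cur_x; y[i] <- cur_y
      }
    }
    list(track = data.frame(animal_id = animal_id,
                            timestamp = start_time + t_fix * 86400,
                            x = x, y = y),
         truth = if (n_kills > 0)
           data.frame(time = start_time + kill_times * 86400,
                      end_time = start_time +
                        (kill_times + handling) * 86400,
                      x = kx, y = ky)
         else data.frame(time = as.POSIXct(character(), tz = "UTC"),
                         end_time = as.POSIXct(character(), tz = "UTC"),
                         x = numeric(), y = numeric()))
  })
}
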