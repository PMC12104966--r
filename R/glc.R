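#' GPS location-cluster (GLC) detection of kill sites
#'
#' Predation sites of a GPS-collared predator are predicted from clusters
#' of temporally and spatially aggregated fixes. The sweep is sequential
#' and deterministic: the earliest unassigned fix seeds a candidate
#' cluster; each later fix joins if it lies within `radius` of the current
#' cluster centroid AND within `window_days` of the cluster's latest
#' member; the centroid is recomputed after every join. A candidate is
#' emitted as a cluster when it holds at least `min_fixes` fixes; its
#' members are removed and the sweep restarts from the earliest remaining
#' fix. Each fix belongs to at most one cluster. The defaults (200 m, 2
#' days, 2 fixes) are the criteria used for lynx kill-site screening.
#' Because the centroid drifts as members join, a member can end up
#' slightly farther than `radius` from the final centroid; members are not
#' evicted retroactively (single-pass rule).
#'
#' @param track data frame with columns `animal_id`, `timestamp`
#'   (`POSIXct` or parseable), `x`, `y` (projected meters), time-ordered
#'   (it is re-sorted defensively; exact duplicate timestamps keep input
#'   order).
#' @param radius spatial criterion in meters (default 200).
#' @param window_days temporal criterion in days: maximum gap between a
#'   joining fix and the cluster's latest member (default 2).
#' @param min_fixes minimum cluster size (default 2).
#' @return Data frame of clusters: `animal_id`, `cluster_id`, `t_start`,
#'   `t_end`, `n_fixes`, `centroid_x`, `centroid_y`, `feeding_days`
#'   (= span from first to last member fix), with a `members` attribute
#'   (list of row indices into the sorted track).
#' @export
find_clusters <- function(track, radius = 200, window_days = 2,
                          min_fixes = 2L) {
  stopifnot(is.data.frame(track))
  if (nrow(track) == 0)
    return(empty_clusters())
  req <- c("animal_id", "timestamp", "x", "y")
  if (length(setdiff(req, names(track))))
    stop("track lacks columns: ",
         paste(setdiff(req, names(track)), collapse = ", "))
  tt <- as.POSIXct(track$timestamp, tz = "UTC")
  ord <- order(tt)
  track <- track[ord, , drop = FALSE]; tt <- tt[ord]
  if (!all(is.finite(track$x)) || !all(is.finite(track$y)))
    stop("coordinates must be finite")
  n <- nrow(track)
  unassigned <- rep(TRUE, n)
  win_s <- window_days * 86400
  xs <- track$x; ys <- track$y; ts <- as.numeric(tt)
  out <- list(); members <- list()
  repeat {
    seed <- which(unassigned)[1]
    if (is.na(seed)) break
    mem <- seed
    cx <- xs[seed]; cy <- ys[seed]; t_last <- ts[seed]
    cand <- which(unassigned); cand <- cand[cand > seed]
    for (i in cand) {
      # candidates are in time order and t_last only advances on joins,
      # so the first window violation ends the scan
      if (ts[i] - t_last > win_s) break
      if ((xs[i] - cx)^2 + (ys[i] - cy)^2 > radius^2) next
      mem <- c(mem, i)
      cx <- mean(xs[mem]); cy <- mean(ys[mem])
      t_last <- ts[i]
    }
    unassigned[mem] <- FALSE
    if (length(mem) >= min_fixes) {
      members[[length(members) + 1L]] <- mem
      out[[length(out) + 1L]] <- data.frame(
        animal_id = track$animal_id[seed],
        t_start = tt[mem[1]], t_end = tt[mem[length(mem)]],
        n_fixes = length(mem), centroid_x = cx, centroid_y = cy,
        feeding_days = as.numeric(difftime(tt[mem[length(mem)]],
                                           tt[mem[1]], units = "days")))
    }
  }
  if (!length(out)) return(empty_clusters())
  res <- do.call(rbind, out)
  res <- cbind(animal_id = res$animal_id,
               cluster_id = seq_len(nrow(res)), res[-1])
  attr(res, "members") <- members
  res
}

empty_clusters <- function() {
  data.frame(animal_id = character(), cluster_id = integer(),
             t_start = as.POSIXct(character(), tz = "UTC"),
             t_end = as.POSIXct(character(), tz = "UTC"),
             n_fixes = integer(), centroid_x = numeric(),
             centroid_y = numeric(), feeding_days = numeric())
}

#' Inter-kill intervals
#'
#' Differences in days between consecutive predicted kill times (the first
#' fix time of each kill cluster) of one animal.
#'
#' @param kill_times vector of predicted kill times (`POSIXct` or numeric
#'   days), time-ordered (re-sorted defensively).
#' @return Numeric vector of intervals in days (empty for < 2 kills).
#' @export
inter_kill_intervals <- function(kill_times) {
  if (length(kill_times) < 2) return(numeric(0))
  if (inherits(kill_times, "POSIXct")) {
    kill_times <- sort(kill_times)
    as.numeric(diff(kill_times), units = "days")
  } else diff(sort(as.numeric(kill_times)))
}

#' Days from release to the first kill
#'
#' @param release_time release time (`POSIXct`).
#' @param clusters a cluster table from [find_clusters()]. Clusters
#'   starting before the release are ignored.
#' @return Days from release to the first predicted kill, or `NA` if no
#'   post-release cluster exists.
#' @export
time_to_first_kill <- function(release_time, clusters) {
  if (nrow(clusters) == 0) return(NA_real_)
  post <- clusters$t_start >= release_time
  if (!any(post)) return(NA_real_)
  as.numeric(difftime(min(clusters$t_start[post]), release_time,
                      units = "days"))
}

#' Kleptoparasitism rate with exact binomial confidence interval
#'
#' Proportion of monitored kills visited by the kleptoparasite (here,
#' brown bears usurping lynx kills), with a Clopper-Pearson 95% interval.
#'
#' @param n_visited number of kills with a kleptoparasite visit.
#' @param n_monitored number of monitored kills (`>= 1`).
#' @param conf_level confidence level (default 0.95).
#' @return List with `rate`, `lcl`, `ucl`, `n_visited`, `n_monitored`.
#' @export
kleptoparasitism_rate <- function(n_visited, n_monitored,
                                  conf_level = 0.95) {
  stopifnot(n_monitored >= 1, n_visited >= 0, n_visited <= n_monitored)
  bt <- stats::binom.test(n_visited, n_monitored, conf.level = conf_level)
  list(rate = n_visited / n_monitored,
       lcl = bt$conf.int[1], ucl = bt$conf.int[2],
       n_visited = n_visited, n_monitored = n_monitored)
}

#' Read GPS tracks from a Movebank-style CSV
#'
#' Expects columns `animal_id,timestamp,x,y` with ISO-8601 UTC timestamps
#' and projected coordinates in meters. Exact-duplicate timestamps within
#' an animal are dropped (first record kept).
#'
#' @param path CSV path.
#' @return Data frame ordered by animal and time.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df <- df[order(df$animal_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[, c("animal_id", "timestamp")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_tracks
#' @param clusters cluster table from [find_clusters()].
#' @export
write_clusters <- function(clusters, path) {
  df <- as.data.frame(clusters)
  df$t_start <- format(df$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$t_end <- format(df$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
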