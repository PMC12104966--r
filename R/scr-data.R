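#' Multi-session capture data for spatial capture-recapture
#'
#' Bundles a long-format detection table with the trap register.
#' Detections are binary at the individual x trap x occasion level (at
#' most one record per combination; duplicates are collapsed). Sessions
#' are the survey years of a multi-session design; occasions are ordered
#' time bins within the closure window.
#'
#' @param detections data frame with columns `session`, `individual_id`,
#'   `sex` (`"female"`, `"male"`, or `"unknown"`), `trap_id`, `occasion`
#'   (integer >= 1).
#' @param traps data frame with columns `session`, `trap_id`, `x`, `y`,
#'   `location_type` (`"marking_site"`, `"forest_road"`, `"other"`), and
#'   optionally `n_occasions_active` (defaults to the session maximum
#'   occasion).
#' @return An object of class `capture_data`.
#' @export
capture_data <- function(detections, traps) {
  stopifnot(is.data.frame(detections), is.data.frame(traps))
  req_d <- c("session", "individual_id", "sex", "trap_id", "occasion")
  req_t <- c("session", "trap_id", "x", "y", "location_type")
  if (length(setdiff(req_d, names(detections))))
    stop("detections lack columns: ",
         paste(setdiff(req_d, names(detections)), collapse = ", "))
  if (length(setdiff(req_t, names(traps))))
    stop("traps lack columns: ",
         paste(setdiff(req_t, names(traps)), collapse = ", "))
  traps$location_type <- match_enum(traps$location_type, TYPE_LEVELS,
                                    "location_type")
  detections$sex <- match_enum(detections$sex,
                               c("female", "male", "unknown"), "sex")
  sessions <- sort(unique(as.character(traps$session)))
  detections$session <- as.character(detections$session)
  traps$session <- as.character(traps$session)
  if (!all(detections$session %in% sessions))
    stop("detections reference sessions absent from the trap register")
  detections$occasion <- as.integer(detections$occasion)
  if (any(detections$occasion < 1L)) stop("occasions must be >= 1")
  key <- with(detections, paste(session, individual_id, trap_id, occasion))
  detections <- detections[!duplicated(key), , drop = FALSE]
  if (is.null(traps$n_occasions_active)) {
    kmax <- tapply(detections$occasion, detections$session, max)
    nact <- as.integer(kmax[traps$session])
    nact[is.na(nact)] <- 1L
    traps$n_occasions_active <- nact
  }
  for (s in sessions) {
    ds <- detections[detections$session == s, ]
    ts <- traps[traps$session == s, ]
    bad <- !ds$trap_id %in% ts$trap_id
    if (any(bad)) stop("session ", s, ": detections at unregistered traps")
    kj <- ts$n_occasions_active[match(ds$trap_id, ts$trap_id)]
    if (any(ds$occasion > kj))
      stop("session ", s, ": detection beyond a trap's active occasions")
  }
  structure(list(detections = detections, traps = traps,
                 sessions = sessions),
            class = "capture_data")
}

TYPE_LEVELS <- c("marking_site", "forest_road", "other")

#' @export
print.capture_data <- function(x, ...) {
  cat("Capture data:", length(x$sessions), "session(s),",
      length(unique(x$detections$individual_id)), "individuals,",
      nrow(x$detections), "detections,", nrow(x$traps), "trap-sessions\n")
  invisible(x)
}

#' Read capture data from CSV files
#'
#' @param detections_path long-format detections CSV
#'   (`session,individual_id,sex,trap_id,occasion`).
#' @param traps_path trap register CSV
#'   (`session,trap_id,x,y,location_type,n_occasions_active`).
#' @return A [capture_data()] object.
#' @export
read_capture_data <- function(detections_path, traps_path) {
  capture_data(utils::read.csv(detections_path, stringsAsFactors = FALSE),
               utils::read.csv(traps_path, stringsAsFactors = FALSE))
}

#' Restrict detection records to the seasonal closure window
#'
#' Camera-trap records are limited to the cross-year window from August 15
#' to February 15 (inclusive on both ends) to meet the demographic closure
#' assumption, and assigned to the session (survey year) of the window's
#' August boundary: records from August 15 to December 31 of year `Y` and
#' from January 1 to February 15 of year `Y + 1` both belong to session
#' `Y`. The operation is idempotent.
#'
#' @param records data frame with a `date` column (coercible to `Date`).
#' @param start_month,start_day,end_month,end_day window boundaries
#'   (defaults August 15 and February 15).
#' @return The in-window subset of `records` with a `session` column
#'   (integer year) added or overwritten.
#' @export
seasonal_filter <- function(records, start_month = 8L, start_day = 15L,
                            end_month = 2L, end_day = 15L) {
  stopifnot(is.data.frame(records), "date" %in% names(records))
  d <- as.Date(records$date)
  mo <- as.integer(format(d, "%m")); day <- as.integer(format(d, "%d"))
  yr <- as.integer(format(d, "%Y"))
  after_start <- mo > start_month | (mo == start_month & day >= start_day)
  before_end <- mo < end_month | (mo == end_month & day <= end_day)
  keep <- after_start | before_end
  out <- records[keep, , drop = FALSE]
  out$session <- ifelse(after_start[keep], yr[keep], yr[keep] - 1L)
  out
}

#' Annual turnover of identified individuals
#'
#' For each year `t` with a following year in the data, the proportion of
#' individuals identified in year `t` that were detected again in year
#' `t + 1`.
#'
#' @param year_sets named list of character vectors: individuals identified
#'   per year, names coercible to integers and ordered by year.
#' @return Data frame `year`, `n`, `n_redetected`, `proportion`.
#' @export
turnover <- function(year_sets) {
  stopifnot(is.list(year_sets), length(year_sets) >= 2)
  yrs <- as.integer(names(year_sets))
  if (anyNA(yrs)) stop("year_sets names must be years")
  ord <- order(yrs); yrs <- yrs[ord]; year_sets <- year_sets[ord]
  rows <- lapply(seq_len(length(yrs) - 1L), function(i) {
    if (yrs[i + 1L] != yrs[i] + 1L) return(NULL)
    s1 <- unique(year_sets[[i]]); s2 <- unique(year_sets[[i + 1L]])
    data.frame(year = yrs[i], n = length(s1),
               n_redetected = length(intersect(s1, s2)),
               proportion = length(intersect(s1, s2)) / length(s1))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no consecutive year pairs in year_sets")
  do.call(rbind, rows)
}
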