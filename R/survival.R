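#' Convert tracking periods to survival records
#'
#' Each monitored interval (one tracking period) ends in one of six status
#' categories: `alive`, `disappeared`, `suspected_illegal_killing`,
#' `confirmed_illegal_killing`, `roadkill`, `natural_mortality`. The
#' default policy excludes periods ending in `disappeared` (unknown fate),
#' censors `alive` at the period end, and counts every mortality category
#' as an event. An animal with two independent tracking periods
#' contributes two records. Alternative policies:
#' \describe{
#'   \item{`disappeared_censored`}{keeps disappeared animals, censored at
#'     last contact;}
#'   \item{`human_caused_only`}{only suspected/confirmed illegal killing
#'     and roadkill are events; natural mortality is censored at the death
#'     date (disappeared still excluded).}
#' }
#'
#' @param periods data frame with columns `animal_id`, `group`, `start`,
#'   `end` (dates), `end_status`.
#' @param policy one of `"default"`, `"disappeared_censored"`,
#'   `"human_caused_only"`.
#' @return Data frame `animal_id`, `group`, `time` (days), `event`
#'   (1 = death, 0 = censored).
#' @export
to_survival_records <- function(periods,
                                policy = c("default",
                                           "disappeared_censored",
                                           "human_caused_only")) {
  policy <- match.arg(policy)
  req <- c("animal_id", "group", "start", "end", "end_status")
  if (length(setdiff(req, names(periods))))
    stop("periods lack columns: ",
         paste(setdiff(req, names(periods)), collapse = ", "))
  status_levels <- c("alive", "disappeared", "suspected_illegal_killing",
                     "confirmed_illegal_killing", "roadkill",
                     "natural_mortality")
  st <- match_enum(periods$end_status, status_levels, "end_status")
  start <- as.Date(periods$start); end <- as.Date(periods$end)
  if (any(end < start)) stop("tracking period ends before it starts")
  keep <- if (policy == "disappeared_censored") rep(TRUE, nrow(periods))
          else st != "disappeared"
  mortality <- c("suspected_illegal_killing", "confirmed_illegal_killing",
                 "roadkill", "natural_mortality")
  event_set <- if (policy == "human_caused_only")
    setdiff(mortality, "natural_mortality") else mortality
  data.frame(animal_id = as.character(periods$animal_id)[keep],
             group = as.character(periods$group)[keep],
             time = as.numeric(end - start)[keep],
             event = as.integer(st[keep] %in% event_set))
}

#' Kaplan-Meier (product-limit) survival curve
#'
#' Nonparametric estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' distinct event times, with Greenwood standard errors. At tied times,
#' events are resolved before censorings (the standard convention: a
#' censored animal at time `t` is still at risk for deaths at `t`).
#'
#' @param time non-negative times in days.
#' @param event 1 = event (death), 0 = right-censored.
#' @return An object of class `km_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `se` (Greenwood), rows at distinct
#'   observed times.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1,
            all(time >= 0), all(event %in% c(0, 1)))
  tu <- sort(unique(time))
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(tu))
  surv <- se <- numeric(length(tu))
  s <- 1; gw <- 0
  for (k in seq_along(tu)) {
    t0 <- tu[k]
    n_risk[k] <- sum(time >= t0)
    n_event[k] <- sum(time == t0 & event == 1)
    n_censor[k] <- sum(time == t0 & event == 0)
    if (n_event[k] > 0) {
      s <- s * (1 - n_event[k] / n_risk[k])
      if (n_risk[k] > n_event[k])
        gw <- gw + n_event[k] / (n_risk[k] * (n_risk[k] - n_event[k]))
      else gw <- Inf
    }
    surv[k] <- s
    se[k] <- if (is.finite(gw)) s * sqrt(gw) else 0
  }
  structure(data.frame(time = tu, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv, se = se),
            class = c("km_curve", "data.frame"))
}

#' @rdname kaplan_meier
#' @param curve a `km_curve`.
#' @param t time at which to evaluate the step function (e.g., 183 days
#'   for six-month survivorship).
#' @return `km_survival_at` returns `S(t)` (1 before the first observed
#'   time).
#' @export
km_survival_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  if (i == 0) 1 else curve$survival[i]
}

#' K-sample log-rank test
#'
#' Standard log-rank comparison of survival across `k` groups: observed
#' minus expected event counts accumulated over distinct event times, with
#' the hypergeometric covariance; the statistic is asymptotically
#' chi-square with `k - 1` degrees of freedom.
#'
#' @param time,event as in [kaplan_meier()].
#' @param group group labels (>= 2 groups, >= 1 event overall).
#' @return List with `statistic`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  gl <- sort(unique(group))
  k <- length(gl)
  if (k < 2) stop("need >= 2 groups")
  if (sum(event) < 1) stop("need >= 1 event")
  gi <- match(group, gl)
  tev <- sort(unique(time[event == 1]))
  O <- tapply(event, gi, sum)
  O[is.na(O)] <- 0
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t0 in tev) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t0)
    ni <- tabulate(gi[at_risk], nbins = k)
    E <- E + d * ni / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        V[a, b] <- V[a, b] +
          f * (ni[a] / n) * ((a == b) - ni[b] / n)
      }
    }
  }
  z <- (as.numeric(O) - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vk, z)), error = function(e) NA_real_)
  if (is.na(stat)) {  # singular covariance (e.g., a group with no risk time)
    stat <- drop(t(z) %*% pseudo_inverse(Vk) %*% z)
  }
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = stats::setNames(as.numeric(O), gl),
       expected = stats::setNames(E, gl))
}

# Moore-Penrose pseudoinverse via SVD (fallback for singular covariance).
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Export survival curves to CSV
#'
#' Columns `group,time_days,n_risk,n_event,survival,se`.
#'
#' @param curves named list of `km_curve` objects (names = group labels).
#' @param path output file.
#' @export
write_survival_curves <- function(curves, path) {
  rows <- lapply(names(curves), function(g) {
    cv <- curves[[g]]
    data.frame(group = g, time_days = cv$time, n_risk = cv$n_risk,
               n_event = cv$n_event, survival = cv$survival, se = cv$se)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
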