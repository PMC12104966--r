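#' Half-normal detection probability
#'
#' The encounter model is half-normal in the distance between a trap and
#' the latent activity center: `p(d) = p0 * exp(-d^2 / (2 * sigma^2))`,
#' where `p0` is the baseline per-occasion detection probability at
#' distance zero and `sigma` the spatial scale of the home-range-driven
#' decline.
#'
#' @param distance distance(s) in meters, `>= 0`.
#' @param p0 baseline detection probability in `(0, 1]`.
#' @param sigma spatial scale in meters, `> 0`.
#' @return Detection probability, same length as `distance`.
#' @export
detection_prob <- function(distance, p0, sigma) {
  stopifnot(all(distance >= 0), all(p0 >= 0 & p0 <= 1), all(sigma > 0))
  p0 * exp(-distance^2 / (2 * sigma^2))
}

#' Specify an SCR detection model
#'
#' Detection submodel: the baseline detection probability `p0` uses a
#' logit link with optional additive effects of session (survey year),
#' sex, camera-site location type, and a local (trap-specific) behavioral
#' response `b` that switches permanently after an individual's first
#' capture at a given trap. The spatial scale `sigma` uses a log link with
#' an optional sex effect. Reference categories: female, marking site,
#' first session, pre-response state.
#'
#' @param p0 character subset of `c("session", "sex", "type", "b")`.
#' @param sigma character subset of `c("sex")`.
#' @return An object of class `scr_model_spec`.
#' @export
scr_model_spec <- function(p0 = character(), sigma = character()) {
  bad <- setdiff(p0, c("session", "sex", "type", "b"))
  if (length(bad)) stop("unknown p0 covariates: ", paste(bad, collapse = ", "))
  bad <- setdiff(sigma, "sex")
  if (length(bad)) stop("unknown sigma covariates: ", paste(bad, collapse = ", "))
  structure(list(p0 = p0, sigma = sigma), class = "scr_model_spec")
}

# Parameter layout for a spec over the given sessions. Returns a character
# vector of parameter names, in optimization order.
scr_par_names <- function(spec, sessions) {
  nm <- "p0_logit"
  if ("session" %in% spec$p0 && length(sessions) > 1)
    nm <- c(nm, paste0("p0_session_", sessions[-1]))
  if ("sex" %in% spec$p0) nm <- c(nm, "p0_male")
  if ("type" %in% spec$p0) nm <- c(nm, "p0_forest_road", "p0_other")
  if ("b" %in% spec$p0) nm <- c(nm, "p0_b")
  nm <- c(nm, "log_sigma")
  if ("sex" %in% spec$sigma) nm <- c(nm, "log_sigma_male")
  nm
}

# Linear predictors for one session/sex stratum: logit-scale p0 per trap
# (naive state) and sigma. `type` is an integer vector (1 = marking_site,
# 2 = forest_road, 3 = other) over traps.
scr_linpred <- function(par, spec, sessions, session, sex, type) {
  eta <- par[["p0_logit"]]
  if ("session" %in% spec$p0 && session != sessions[1])
    eta <- eta + par[[paste0("p0_session_", session)]]
  if ("sex" %in% spec$p0 && sex == "male") eta <- eta + par[["p0_male"]]
  eta <- rep(eta, length(type))
  if ("type" %in% spec$p0) {
    eta[type == 2L] <- eta[type == 2L] + par[["p0_forest_road"]]
    eta[type == 3L] <- eta[type == 3L] + par[["p0_other"]]
  }
  ls <- par[["log_sigma"]]
  if ("sex" %in% spec$sigma && sex == "male")
    ls <- ls + par[["log_sigma_male"]]
  list(eta = eta, sigma = exp(ls),
       b = if ("b" %in% spec$p0) par[["p0_b"]] else 0)
}

# Precompute per-session structures used by the likelihood: distance^2
# matrices, per-individual detection-count matrices split by behavioral
# state, and session/sex strata.
scr_prep <- function(data, grid, spec) {
  stopifnot(inherits(data, "capture_data"), inherits(grid, "state_space"))
  M <- nrow(grid)
  preps <- lapply(data$sessions, function(s) {
    ts <- data$traps[data$traps$session == s, , drop = FALSE]
    ds <- data$detections[data$detections$session == s, , drop = FALSE]
    J <- nrow(ts)
    D2 <- outer(grid$x, ts$x, "-")^2 + outer(grid$y, ts$y, "-")^2
    type <- match(ts$location_type, TYPE_LEVELS)
    Kj <- ts$n_occasions_active
    ids <- unique(ds$individual_id)
    I <- length(ids)
    sex <- ds$sex[match(ids, ds$individual_id)]
    y1n <- matrix(0, I, J); y1r <- matrix(0, I, J)
    n0n <- matrix(rep(Kj, each = I), I, J); n0r <- matrix(0, I, J)
    if (I > 0) {
      ti <- match(ds$trap_id, ts$trap_id)
      ii <- match(ds$individual_id, ids)
      for (r in seq_len(nrow(ds))) {
        i <- ii[r]; j <- ti[r]
        y1r[i, j] <- y1r[i, j] + 1   # provisionally all responded
      }
      # first capture per (i, j) is in the naive state; occasions before
      # it are naive zeros, occasions after are responded zeros
      first <- tapply(ds$occasion, list(ii, ti), min)
      for (i in seq_len(I)) for (j in seq_len(J)) {
        y <- y1r[i, j]
        if (y > 0) {
          o1 <- first[as.character(i), as.character(j)]
          y1n[i, j] <- 1; y1r[i, j] <- y - 1
          n0n[i, j] <- o1 - 1
          n0r[i, j] <- (Kj[j] - o1) - (y - 1)
        }
      }
    }
    list(session = s, D2 = D2, type = type, Kj = Kj, ids = ids,
         sex = sex, y1n = y1n, y1r = y1r, n0n = n0n, n0r = n0r)
  })
  names(preps) <- data$sessions
  list(sessions = data$sessions, M = M, preps = preps)
}

# Negative log of the conditional-on-detection SCR likelihood.
# For each detected individual, P(history | detected) integrates the
# half-normal encounter model over a uniform prior on state-space cells
# and divides by the overall detection probability computed with
# pre-response (naive) parameters.
scr_nll_prepped <- function(par, prep, spec) {
  names(par) <- attr(prep, "par_names")
  nll <- 0
  for (ps in prep$preps) {
    if (!length(ps$ids)) next
    for (sx in unique(ps$sex)) {
      lp <- scr_linpred(par, spec, prep$sessions, ps$session, sx, ps$type)
      p0n <- stats::plogis(lp$eta)
      p0r <- stats::plogis(lp$eta + lp$b)
      Kmat <- exp(-ps$D2 / (2 * lp$sigma^2))        # M x J kernel
      Pn <- sweep(Kmat, 2, p0n, "*")
      l1mPn <- log1p(-Pn)
      tot <- drop(l1mPn %*% ps$Kj)                  # all-zero history, naive
      pbar <- mean(1 - exp(tot))
      if (!is.finite(pbar) || pbar <= 0) return(1e10)
      sel <- which(ps$sex == sx)
      A <- l1mPn %*% t(ps$n0n[sel, , drop = FALSE]) +
        log(Pn) %*% t(ps$y1n[sel, , drop = FALSE])
      if (lp$b != 0 || any(ps$y1r[sel, ] > 0) || any(ps$n0r[sel, ] > 0)) {
        Pr <- sweep(Kmat, 2, p0r, "*")
        A <- A + log1p(-Pr) %*% t(ps$n0r[sel, , drop = FALSE]) +
          log(Pr) %*% t(ps$y1r[sel, , drop = FALSE])
      }
      amax <- apply(A, 2, max)
      lse <- log(colMeans(exp(sweep(A, 2, amax, "-")))) + amax
      ll <- sum(lse - log(pbar))
      if (!is.finite(ll)) return(1e10)
      nll <- nll - ll
    }
  }
  nll
}

#' Negative log-likelihood of an SCR model
#'
#' Conditional-on-detection likelihood for a multi-session spatial
#' capture-recapture model with half-normal detection (see
#' [scr_model_spec()]). Mostly useful for diagnostics and testing;
#' [fit_scr()] wraps it in an optimizer.
#'
#' @param par named numeric parameter vector as in `scr_par_names`.
#' @param data a [capture_data()] object.
#' @param grid a [build_state_space()] grid.
#' @param spec an [scr_model_spec()].
#' @return Scalar negative log-likelihood (a large finite penalty value if
#'   the likelihood is numerically invalid at `par`).
#' @export
scr_nll <- function(par, data, grid, spec = scr_model_spec()) {
  prep <- scr_prep(data, grid, spec)
  attr(prep, "par_names") <- scr_par_names(spec, prep$sessions)
  scr_nll_prepped(par, prep, spec)
}

# Overall detection probability for a session/sex stratum under naive
# parameters (used for conditioning and Horvitz-Thompson abundance).
scr_pbar <- function(par, prep, spec, session, sex) {
  ps <- prep$preps[[session]]
  lp <- scr_linpred(par, spec, prep$sessions, session, sex, ps$type)
  Pn <- sweep(exp(-ps$D2 / (2 * lp$sigma^2)), 2, stats::plogis(lp$eta), "*")
  tot <- drop(log1p(-Pn) %*% ps$Kj)
  mean(1 - exp(tot))
}
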