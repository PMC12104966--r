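#' Fit a maximum-likelihood SCR model
#'
#' Minimizes the conditional-on-detection negative log-likelihood by
#' quasi-Newton (BFGS) search with numeric gradients from documented,
#' deterministic start values: baseline detection `p0` at logit scale -2,
#' `log(sigma)` at the log of half the median inter-trap distance, and all
#' covariate effects at 0. Abundance is estimated per session and sex by
#' the Horvitz-Thompson estimator `N = sum_i 1 / pbar_i` over detected
#' individuals, with variance combining a first-stage sampling term (see
#' `distribution`) and a delta-method term propagating parameter
#' uncertainty; confidence intervals are lognormal on `N`.
#' Density is reported per 100 km^2 of the state space.
#'
#' @param data a [capture_data()] object with >= 2 detected individuals.
#' @param grid a [build_state_space()] grid.
#' @param spec an [scr_model_spec()].
#' @param start optional named start vector overriding the defaults.
#' @param control passed to [stats::optim()] (`maxit` defaults to 500).
#' @param hessian compute standard errors from the numeric Hessian
#'   (default `TRUE`).
#' @param distribution distribution of the number of activity centers on
#'   the state space: `"poisson"` (default; the estimand is the density
#'   parameter of a Poisson superpopulation, first-stage variance
#'   `sum 1 / pbar_i^2`) or `"binomial"` (fixed realized N, variance
#'   `sum (1 - pbar_i) / pbar_i^2`).
#' @return An object of class `scr_fit`: parameter estimates and standard
#'   errors, `logLik`, `AIC`, convergence status with final gradient norm,
#'   and an `abundance` data frame (`session`, `sex`, `n_obs`, `pbar`,
#'   `N`, `se_N`, `lcl_N`, `ucl_N`, `D`, `lcl_D`, `ucl_D`).
#' @export
fit_scr <- function(data, grid, spec = scr_model_spec(), start = NULL,
                    control = list(), hessian = TRUE,
                    distribution = c("poisson", "binomial")) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(data, "capture_data"))
  n_det <- length(unique(data$detections$individual_id))
  if (n_det < 2) stop("need >= 2 detected individuals")
  if (nrow(data$traps) < 2) stop("need >= 2 traps")
  prep <- scr_prep(data, grid, spec)
  pn <- scr_par_names(spec, prep$sessions)
  attr(prep, "par_names") <- pn

  # default start: half the median inter-trap distance as sigma
  t1 <- data$traps
  dmat <- sqrt(outer(t1$x, t1$x, "-")^2 + outer(t1$y, t1$y, "-")^2)
  med <- stats::median(dmat[upper.tri(dmat)])
  p0 <- stats::setNames(rep(0, length(pn)), pn)
  p0["p0_logit"] <- -2
  p0["log_sigma"] <- log(pmax(med / 2, attr(grid, "cell") / 2))
  if (!is.null(start)) p0[names(start)] <- start

  control$maxit <- control$maxit %||% 500L
  fn <- function(p) scr_nll_prepped(p, prep, spec)
  opt <- stats::optim(p0, fn, method = "BFGS", control = control,
                      hessian = hessian)
  grad <- num_grad(fn, opt$par)
  converged <- opt$convergence == 0
  vcov <- NULL; se <- rep(NA_real_, length(pn))
  if (hessian) {
    vcov <- try(solve(opt$hessian), silent = TRUE)
    if (inherits(vcov, "try-error") ||
        any(!is.finite(diag(vcov))) || any(diag(vcov) < 0)) {
      vcov <- NULL
      warning("singular Hessian: standard errors reported missing")
    } else se <- sqrt(diag(vcov))
  }
  names(se) <- pn

  area <- state_space_area(grid)
  ab <- scr_abundance(opt$par, prep, spec, vcov, area, distribution)
  k <- length(pn)
  structure(list(par = opt$par, se = se, vcov = vcov,
                 logLik = -opt$value, AIC = 2 * k + 2 * opt$value,
                 n_par = k, converged = converged,
                 gradient_norm = sqrt(sum(grad^2)),
                 abundance = ab, area_km2 = area,
                 spec = spec, sessions = prep$sessions),
            class = "scr_fit")
}

num_grad <- function(fn, par, eps = 1e-5) {
  vapply(seq_along(par), function(i) {
    h <- eps * max(1, abs(par[i]))
    pp <- par; pp[i] <- par[i] + h
    pm <- par; pm[i] <- par[i] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, numeric(1))
}

# Horvitz-Thompson abundance per session x sex stratum with lognormal CIs.
# pbar is shared by all individuals of a stratum, so N = sum_sex n_sex/pbar.
scr_abundance <- function(par, prep, spec, vcov, area,
                          distribution = "poisson") {
  v1_term <- function(cnt, pb)
    if (distribution == "poisson") cnt / pb^2 else cnt * (1 - pb) / pb^2
  rows <- list()
  ht_fun <- function(p, session, counts) {
    names(p) <- attr(prep, "par_names")
    sum(vapply(names(counts), function(sx)
      counts[[sx]] / scr_pbar(p, prep, spec, session, sx), numeric(1)))
  }
  for (s in prep$sessions) {
    ps <- prep$preps[[s]]
    if (!length(ps$ids)) next
    strata <- c(as.list(table(ps$sex)),
                list(total = as.list(table(ps$sex))))
    names(par) <- attr(prep, "par_names")
    pbar_sex <- vapply(unique(ps$sex), function(z)
      scr_pbar(par, prep, spec, s, z), numeric(1))
    for (sx in names(strata)) {
      counts <- if (sx == "total") unlist(strata$total) else
        stats::setNames(strata[[sx]], sx)
      counts <- counts[counts > 0]
      pb <- pbar_sex[names(counts)]
      N <- sum(counts / pb)
      v1 <- sum(v1_term(counts, pb))
      v2 <- 0
      if (!is.null(vcov)) {
        g <- num_grad(function(p) ht_fun(p, s, as.list(counts)), par)
        v2 <- drop(t(g) %*% vcov %*% g)
      }
      v <- v1 + v2
      n_obs <- sum(counts)
      cv2 <- v / N^2
      C <- exp(stats::qnorm(0.975) * sqrt(log(1 + cv2)))
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, sex = sx, n_obs = n_obs,
        pbar = n_obs / N, N = N, se_N = sqrt(v),
        lcl_N = N / C, ucl_N = N * C,
        D = N / area * 100, lcl_D = N / C / area * 100,
        ucl_D = N * C / area * 100)
    }
  }
  out <- do.call(rbind, rows)
  # overall row: abundance summed over sessions, density per session
  # (sessions share parameters, so the delta-method term is computed on
  # the joint Horvitz-Thompson sum, not added per session)
  tot <- out[out$sex == "total", , drop = FALSE]
  if (nrow(tot) >= 1) {
    S <- nrow(tot)
    ht_all <- function(p) {
      names(p) <- attr(prep, "par_names")
      total <- 0
      for (s in prep$sessions) {
        ps <- prep$preps[[s]]
        if (!length(ps$ids)) next
        cnt <- table(ps$sex)
        total <- total + sum(vapply(names(cnt), function(sx)
          cnt[[sx]] / scr_pbar(p, prep, spec, s, sx), numeric(1)))
      }
      total
    }
    N <- sum(tot$N)
    v1_all <- sum(vapply(prep$sessions, function(s) {
      ps <- prep$preps[[s]]
      if (!length(ps$ids)) return(0)
      cnt <- table(ps$sex)
      sum(vapply(names(cnt), function(sx) {
        pb <- scr_pbar(par, prep, spec, s, sx)
        v1_term(cnt[[sx]], pb)
      }, numeric(1)))
    }, numeric(1)))
    v2_all <- 0
    if (!is.null(vcov)) {
      g <- num_grad(ht_all, par)
      v2_all <- drop(t(g) %*% vcov %*% g)
    }
    v <- v1_all + v2_all
    C <- exp(stats::qnorm(0.975) * sqrt(log(1 + v / N^2)))
    out <- rbind(out, data.frame(
      session = "overall", sex = "total", n_obs = sum(tot$n_obs),
      pbar = sum(tot$n_obs) / N, N = N, se_N = sqrt(v),
      lcl_N = N / C, ucl_N = N * C,
      D = N / (S * area) * 100, lcl_D = N / C / (S * area) * 100,
      ucl_D = N * C / (S * area) * 100))
  }
  out
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("Maximum-likelihood SCR fit\n")
  cat("  logLik:", round(x$logLik, 3), " AIC:", round(x$AIC, 3),
      " converged:", x$converged,
      " |grad|:", signif(x$gradient_norm, 3), "\n")
  est <- data.frame(estimate = round(x$par, 4), se = round(x$se, 4))
  print(est)
  cat("Abundance / density (per 100 km^2, state-space area",
      round(x$area_km2, 1), "km^2):\n")
  ab <- x$abundance
  ab[, c("pbar", "N", "se_N", "lcl_N", "ucl_N", "D", "lcl_D", "ucl_D")] <-
    round(ab[, c("pbar", "N", "se_N", "lcl_N", "ucl_N", "D", "lcl_D",
                 "ucl_D")], 3)
  print(ab, row.names = FALSE)
  invisible(x)
}

#' Rank SCR models by AIC
#'
#' @param fits named list of [fit_scr()] results on the same data.
#' @return Data frame sorted by AIC with `model`, `k`, `logLik`, `AIC`,
#'   `dAIC`, and Akaike weights `w = exp(-dAIC / 2) / sum(...)`.
#' @export
aic_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("m", seq_along(fits))
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$n_par, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  w <- exp(-tab$dAIC / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  tab
}
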