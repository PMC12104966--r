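# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Nei's unbiased expected heterozygosity by explicit allele counting.
he_oracle <- function(gt) {
  locs <- loci(gt)
  vals <- c()
  for (loc in locs) {
    a1 <- gt[[paste0(loc, "_a1")]]; a2 <- gt[[paste0(loc, "_a2")]]
    keep <- !is.na(a1)
    if (sum(keep) < 2) next
    alleles <- c(a1[keep], a2[keep])
    counts <- table(alleles)
    p <- as.numeric(counts) / length(alleles)
    nn <- sum(keep)
    vals <- c(vals, (2 * nn / (2 * nn - 1)) * (1 - sum(p * p)))
  }
  mean(vals)
}

# Sequential-sweep GPS clustering, naive implementation: no early scan
# termination, centroid tracked via explicit sums, times via difftime.
glc_oracle <- function(track, radius = 200, window_days = 2,
                       min_fixes = 2) {
  tt <- as.POSIXct(track$timestamp, tz = "UTC")
  ord <- order(tt)
  track <- track[ord, , drop = FALSE]; tt <- tt[ord]
  left <- seq_len(nrow(track))
  clusters <- list()
  while (length(left) > 0) {
    mem <- left[1]
    sx <- track$x[mem]; sy <- track$y[mem]
    t_last <- tt[mem]
    for (i in left[-1]) {
      dt <- as.numeric(difftime(tt[i], t_last, units = "days"))
      if (dt > window_days) next
      cx <- sx / length(mem); cy <- sy / length(mem)
      dd <- sqrt((track$x[i] - cx)^2 + (track$y[i] - cy)^2)
      if (dd > radius) next
      mem <- c(mem, i)
      sx <- sx + track$x[i]; sy <- sy + track$y[i]
      t_last <- tt[i]
    }
    left <- setdiff(left, mem)
    if (length(mem) >= min_fixes)
      clusters[[length(clusters) + 1L]] <-
        list(members = mem, n = length(mem),
             cx = sx / length(mem), cy = sy / length(mem),
             t_start = tt[mem[1]], t_end = tt[mem[length(mem)]])
  }
  clusters
}

# Random toy track for oracle-equivalence sweeps.
random_track <- function(n = 10, span_days = 6, scale = 400) {
  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  data.frame(animal_id = "T",
             timestamp = t0 + sort(runif(n, 0, span_days * 86400)),
             x = runif(n, 0, scale), y = runif(n, 0, scale))
}

# Conditional SCR likelihood by direct enumeration over cells for tiny
# instances, working straight off the long detection table. Behavioral
# state at (individual, trap, occasion): detected at that trap at an
# earlier occasion.
scr_nll_oracle <- function(par_list, dets, traps, grid, n_occasions) {
  # par_list: p0 (prob scale, per location_type naive), b_odds multiplier
  # applied on the logit scale, sigma, optionally p0_male etc. Keep the
  # minimal general form: eta0, beta_male, beta_type (len 3, first 0),
  # beta_b, log_sigma, beta_sigma_male.
  M <- nrow(grid)
  ids <- unique(dets$individual_id)
  nll <- 0
  for (id in ids) {
    di <- dets[dets$individual_id == id, , drop = FALSE]
    sex <- di$sex[1]
    eta0 <- par_list$eta0 +
      if (sex == "male") par_list$beta_male else 0
    sig <- exp(par_list$log_sigma +
                 if (sex == "male") par_list$beta_sigma_male else 0)
    lik_cells <- numeric(M)
    pbar_cells <- numeric(M)
    for (m in seq_len(M)) {
      ll <- 0
      p_no <- 1
      for (j in seq_len(nrow(traps))) {
        d2 <- (grid$x[m] - traps$x[j])^2 + (grid$y[m] - traps$y[j])^2
        kern <- exp(-d2 / (2 * sig^2))
        ty <- match(traps$location_type[j],
                    c("marking_site", "forest_road", "other"))
        eta_j <- eta0 + par_list$beta_type[ty]
        dj <- di[di$trap_id == traps$trap_id[j], , drop = FALSE]
        first <- if (nrow(dj)) min(dj$occasion) else Inf
        for (k in seq_len(n_occasions)) {
          responded <- k > first
          p <- plogis(eta_j + if (responded) par_list$beta_b else 0) * kern
          y <- k %in% dj$occasion
          ll <- ll + if (y) log(p) else log(1 - p)
          p_no <- p_no * (1 - plogis(eta_j) * kern)  # naive parameters
        }
      }
      lik_cells[m] <- exp(ll)
      pbar_cells[m] <- 1 - p_no
    }
    nll <- nll - log(mean(lik_cells) / mean(pbar_cells))
  }
  nll
}

# All ways to assign offspring alleles (o1, o2) one-from-mother,
# one-from-father; a locus is compatible if any assignment works.
pair_compat_oracle <- function(off, mom, dad, tol = 0) {
  bad <- 0
  for (l in seq_along(off)) {
    o <- off[[l]]; m <- mom[[l]]; d <- dad[[l]]
    if (anyNA(o)) next
    if (anyNA(m) || anyNA(d)) next
    ok <- FALSE
    for (perm in list(c(1, 2), c(2, 1)))
      if (o[perm[1]] %in% m && o[perm[2]] %in% d) ok <- TRUE
    if (!ok) bad <- bad + 1
  }
  bad <= tol
}

# Kaplan-Meier via the survival package (cross-implementation oracle).
km_oracle <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  summary(sf, times = sort(unique(time)), extend = TRUE)
}
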