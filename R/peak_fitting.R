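# Ks-density smoothing and Gaussian multi-peak decomposition.
#
# Following the source procedure for WGD dating, the density curve (Gaussian
# KDE, bandwidth 0.05 by default) is fitted by a sum of Gaussians using the
# smallest number of components reaching the goodness-of-fit threshold; the
# principal (heaviest) component represents the event.
#
# Numerical convention: the fit minimizes density-weighted least squares and
# R-squared is density-weighted (weights proportional to squared density). An
# unweighted R-squared over the full
# evaluation window is dominated by its long near-zero tail and saturates
# near 1 for any fit, which would defeat the minimal-component rule.

#' Kernel density estimate of a Ks sample
#'
#' Gaussian-kernel density on a uniform grid. Values outside the window are
#' ignored; the returned curve is scaled by the in-window mass fraction, so
#' its integral over the window approximates the fraction of the sample
#' inside it.
#'
#' @param sample numeric vector of Ks values (or a data.frame with a `Ks`
#'   column).
#' @param bandwidth kernel standard deviation (default 0.05).
#' @param window fit window, default `c(0, 3)`.
#' @param grid_points number of grid points (601).
#' @param min_n minimal in-window sample size (50).
#' @return a `density_curve`: list(grid, density, bandwidth, n, mass_fraction).
#' @export
kde_density <- function(sample, bandwidth = 0.05, window = c(0, 3),
                        grid_points = 601L, min_n = 50L) {
  if (is.data.frame(sample)) sample <- sample$Ks
  sample <- sample[is.finite(sample)]
  x <- sample[sample >= window[1] & sample <= window[2]]
  if (length(x) < min_n) {
    insufficient_data_error("kde_density: %d in-window Ks values (need >= %d)",
                            length(x), min_n)
  }
  grid <- seq(window[1], window[2], length.out = grid_points)
  ## chunked outer to bound memory
  dens <- numeric(grid_points)
  step <- 200000L %/% grid_points + 1L
  for (i in seq(1, length(x), by = step)) {
    xx <- x[i:min(i + step - 1L, length(x))]
    dens <- dens + colSums(dnorm(outer(xx, grid, "-"), sd = bandwidth))
  }
  dens <- dens / length(x) * (length(x) / length(sample))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 n = length(x), mass_fraction = length(x) / length(sample)),
            class = "density_curve")
}

mixture_predict <- function(par, grid) {
  m <- matrix(par, 3)
  rowSums(vapply(seq_len(ncol(m)),
                 function(i) m[1, i] * dnorm(grid, m[2, i], m[3, i]),
                 numeric(length(grid))))
}

weighted_r2 <- function(obs, pred, w) {
  mw <- sum(w * obs) / sum(w)
  1 - sum(w * (obs - pred)^2) / sum(w * (obs - mw)^2)
}

fit_k_gaussians <- function(curve, k, mu_bounds = NULL) {
  grid <- curve$grid; dens <- curve$density; bw <- curve$bandwidth
  dx <- diff(grid[1:2])
  wts <- (dens / max(dens))^2
  fn <- function(p) sqrt(wts) * (mixture_predict(p, grid) - dens)
  if (is.null(mu_bounds)) {
    mu_lo <- rep(min(grid), k); mu_hi <- rep(max(grid), k)
  } else {
    mu_lo <- vapply(mu_bounds, `[`, 0, 1L); mu_hi <- vapply(mu_bounds, `[`, 0, 2L)
  }

  ## deterministic initializations: (a) k highest local maxima, (b) mass
  ## quantiles of the curve, (c) equal spacing over the support
  d2 <- diff(sign(diff(dens)))
  locmax <- which(d2 < 0) + 1L
  locmax <- locmax[order(dens[locmax], decreasing = TRUE)]
  supp <- grid[dens > max(dens) / 20]
  qs <- seq(0.5 / k, 1 - 0.5 / k, length.out = k)
  cmass <- cumsum(dens) / sum(dens)
  inits <- list()
  mu_a <- grid[locmax]
  if (length(mu_a) >= k) inits$maxima <- sort(mu_a[seq_len(k)])
  inits$quantiles <- vapply(qs, function(q) grid[which.min(abs(cmass - q))], 0)
  inits$spread <- seq(min(supp), max(supp), length.out = k + 2)[2:(k + 1)]
  if (length(mu_a) >= 1 && length(mu_a) < k) {
    inits$mixed <- sort(c(mu_a, inits$quantiles)[seq_len(k)])
  }

  best <- NULL
  for (mu0 in inits) {
    for (s0v in c(bw * 3, bw * 6)) {
      mu0c <- pmin(pmax(sort(mu0), mu_lo + 1e-9), mu_hi - 1e-9)
      par0 <- as.vector(rbind(rep(sum(dens) * dx / k, k), mu0c, rep(s0v, k)))
      fit <- minpack.lm::nls.lm(par0, fn = fn,
                                lower = as.vector(rbind(rep(1e-8, k), mu_lo, rep(bw / 2, k))),
                                upper = as.vector(rbind(rep(100, k), mu_hi,
                                                        rep(diff(range(grid)), k))),
                                control = minpack.lm::nls.lm.control(maxiter = 400))
      pred <- mixture_predict(fit$par, grid)
      r2 <- weighted_r2(dens, pred, wts)
      if (is.null(best) || (is.finite(r2) && r2 > best$r2)) {
        best <- list(par = fit$par, r2 = r2)
      }
    }
  }
  comp <- as.data.frame(t(matrix(best$par, 3)))
  names(comp) <- c("weight", "mean", "sd")
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, n_components = k, r2 = best$r2,
                 principal = which.max(comp$weight),
                 bandwidth = bw, window = range(grid)),
            class = "mixture_fit")
}

#' Decompose a Ks density curve into Gaussian components
#'
#' Fits sums of k = 1, 2, ... Gaussians to the curve by (density-weighted)
#' nonlinear least squares, with means initialized at the k highest local
#' maxima, and returns the first k whose weighted R-squared reaches
#' `r2_threshold` — the minimal number of normal components representing the
#' distribution. Deterministic given the curve. When the number of
#' underlying events is known a priori, `n_components` forces that k.
#'
#' @param curve a `density_curve` from [kde_density()].
#' @param r2_threshold goodness-of-fit threshold (0.95).
#' @param max_components largest k tried (6).
#' @param n_components optional: fit exactly this many components.
#' @param mu_bounds optional list of `c(lo, hi)` bounds for each component
#'   mean (ascending), e.g. to pin the oldest shared event's peak near its
#'   position in a reference genome given bounded rate variation.
#' @return a `mixture_fit`: list(components (weight/mean/sd, ascending mean),
#'   n_components, r2, principal, bandwidth, window).
#' @export
fit_mixture <- function(curve, r2_threshold = 0.95, max_components = 6L,
                        n_components = NULL, mu_bounds = NULL) {
  if (!is.null(n_components)) return(fit_k_gaussians(curve, n_components, mu_bounds))
  best <- NULL
  for (k in seq_len(max_components)) {
    fit <- fit_k_gaussians(curve, k)
    if (is.null(best) || fit$r2 > best$r2) best <- fit
    if (!is.na(fit$r2) && fit$r2 >= r2_threshold) return(fit)
  }
  cond <- structure(class = c("wgdscan_fit_failure", "wgdscan_error", "error", "condition"),
                    list(message = sprintf(
                      "no fit with <= %d components reached R2 >= %.3f (best: %.4f with %d)",
                      max_components, r2_threshold, best$r2, best$n_components),
                      call = sys.call(-1), best = best))
  stop(cond)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d component(s), weighted R2 = %.4f\n",
              x$n_components, x$r2))
  print(transform(x$components, weight = round(weight, 4),
                  mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}

#' Fit per-event Ks peaks for one genome using block structure
#'
#' Implements the block-classification route to event peaks: the oldest
#' (shared) event's peak region is separated from the younger duplications
#' at the deepest density valley below the reference old-event peak; blocks
#' in the young region are classified into the remaining events by 1-D
#' k-means on their Ks medians (block medians are far less dispersed than
#' per-pair Ks, so close peaks that blend in the pooled curve separate
#' cleanly at block level); each event's pooled anchor Ks is then fitted by
#' a single Gaussian component.
#'
#' @param blocks a `colinear_set` with Ks attached ([block_ks_median()]).
#' @param n_events number of polyploidy events in this genome's history.
#' @param oldest_ref reference position of the oldest shared event's peak
#'   (e.g. from the reference genome's own single-component fit); required
#'   when `n_events > 1`.
#' @param bandwidth,window KDE parameters (see [kde_density()]).
#' @return a `mixture_fit` with `n_events` components (ascending mean).
#' @export
fit_event_peaks <- function(blocks, n_events, oldest_ref = NULL,
                            bandwidth = 0.05, window = c(0, 3)) {
  ks <- blocks$anchors$ks
  ks <- ks[!is.na(ks)]
  fit1 <- function(v) fit_k_gaussians(kde_density(v, bandwidth, window, min_n = 30L), 1L)
  if (n_events == 1) {
    f <- fit1(ks)
    return(f)
  }
  if (is.null(oldest_ref)) {
    config_error("fit_event_peaks needs oldest_ref when n_events > 1")
  }
  curve <- kde_density(ks, bandwidth, window)
  sel <- which(curve$grid > 0.5 * oldest_ref & curve$grid < 1.1 * oldest_ref)
  d2 <- diff(sign(diff(curve$density)))
  mins <- intersect(which(d2 > 0) + 1L, sel)
  valley <- if (length(mins)) {
    curve$grid[mins[which.min(curve$density[mins])]]
  } else 0.72 * oldest_ref
  old <- fit1(ks[ks >= valley])
  med <- blocks$blocks$ks_median
  young <- which(!is.na(med) & med < valley)
  if (length(young) < n_events - 1) {
    insufficient_data_error("only %d young blocks for %d young events",
                            length(young), n_events - 1)
  }
  k <- n_events - 1L
  comps <- old$components
  if (k == 1) {
    bids <- blocks$blocks$block_id[young]
    kk <- blocks$anchors$ks[blocks$anchors$block_id %in% bids]
    f <- fit1(kk[!is.na(kk) & kk < valley])
    comps <- rbind(f$components, comps)
  } else {
    centers <- quantile(med[young], seq(0.5 / k, 1 - 0.5 / k, length.out = k))
    km <- kmeans(med[young], centers = matrix(sort(centers)), iter.max = 50L)
    grp <- match(km$cluster, order(km$centers))
    for (j in rev(seq_len(k))) {
      bids <- blocks$blocks$block_id[young[grp == j]]
      kk <- blocks$anchors$ks[blocks$anchors$block_id %in% bids]
      f <- fit1(kk[!is.na(kk) & kk < valley])
      comps <- rbind(f$components, comps)
    }
  }
  comps <- comps[order(comps$mean), , drop = FALSE]
  rownames(comps) <- NULL
  structure(list(components = comps, n_components = n_events,
                 r2 = NA_real_, principal = which.max(comps$weight),
                 bandwidth = bandwidth, window = window, valley = valley),
            class = "mixture_fit")
}

#' Assign fitted components to named polyploidy events
#'
#' Components are matched to events by ascending mean against the supplied
#' event ordering (youngest/lowest-Ks event first). A mismatch between the
#' number of components and the number of expected events is reported as an
#' ambiguity error, not guessed.
#'
#' @param fit a `mixture_fit`.
#' @param events character vector of event names ordered by expected
#'   ascending Ks.
#' @return data.frame `event`, `weight`, `mean`, `sd`.
#' @export
assign_events <- function(fit, events) {
  if (fit$n_components != length(events)) {
    stop_wgd("ambiguity", "fit has %d component(s) but %d event(s) expected (%s)",
             fit$n_components, length(events), paste(events, collapse = ", "))
  }
  comp <- fit$components[order(fit$components$mean), , drop = FALSE]
  data.frame(event = events, weight = comp$weight, mean = comp$mean, sd = comp$sd,
             stringsAsFactors = FALSE)
}
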