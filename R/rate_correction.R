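# Evolutionary-rate alignment across lineages through a shared polyploidy
# event, Ks correction, second-stage re-correction between lineages sharing
# a later event, and conversion of corrected peaks to absolute dates.

#' Estimate a lineage rate-correction factor from a shared event
#'
#' A shared event (e.g. the ancient hexaploidy retained by the reference)
#' produced duplicates in every descendant lineage at the same time, so
#' differences in their Ks peak positions measure relative evolutionary
#' rates. The correction aligns lineage `i`'s peak to the reference:
#' `lambda_i = mu_ref / mu_i` (and `lambda_ref = 1` exactly).
#'
#' @param assigned_i event table for lineage i (from [assign_events()]).
#' @param assigned_ref event table for the reference lineage.
#' @param shared_event name of the shared event used for alignment.
#' @param lineage,reference lineage labels.
#' @return a one-row `rate_factor` data.frame: `lineage`, `lambda`,
#'   `shared_event`, `reference`, `mu_i`, `mu_ref`, `sigma_i_corrected`.
#' @export
estimate_rate_factor <- function(assigned_i, assigned_ref, shared_event,
                                 lineage, reference) {
  pick <- function(tab, who) {
    row <- tab[tab$event == shared_event, , drop = FALSE]
    if (!nrow(row)) stop_wgd("assignment", "no component assigned to event '%s' for %s",
                             shared_event, who)
    row
  }
  ri <- pick(assigned_i, lineage); rr <- pick(assigned_ref, reference)
  if (ri$mean <= 0) integrity_error("nonpositive peak mean for lineage '%s'", lineage)
  lambda <- rr$mean / ri$mean
  data.frame(lineage = lineage, lambda = lambda, shared_event = shared_event,
             reference = reference, mu_i = ri$mean, mu_ref = rr$mean,
             sigma_i_corrected = ri$sd * lambda, stringsAsFactors = FALSE)
}

#' Apply rate correction to Ks values or assigned peaks
#'
#' Within-lineage duplicate Ks are scaled by that lineage's lambda;
#' cross-lineage ortholog Ks by the mean of the two lambdas (both branches
#' assumed to carry half of the divergence). Reference values (lambda = 1)
#' are unchanged.
#'
#' @param x numeric Ks vector, or an [assign_events()] table (its `mean` and
#'   `sd` are scaled).
#' @param lambda named vector of correction factors by lineage.
#' @param lineage_a lineage of the (first) gene copies.
#' @param lineage_b second lineage for ortholog samples (omit for paralogs).
#' @return corrected object of the same shape.
#' @export
correct_ks <- function(x, lambda, lineage_a, lineage_b = NULL) {
  get_l <- function(l) {
    if (!l %in% names(lambda)) stop_wgd("assignment", "no rate factor for lineage '%s'", l)
    unname(lambda[[l]])
  }
  f <- if (is.null(lineage_b)) get_l(lineage_a) else
    (get_l(lineage_a) + get_l(lineage_b)) / 2
  if (is.data.frame(x)) {
    x$mean <- x$mean * f
    if ("sd" %in% names(x)) x$sd <- x$sd * f
    x
  } else {
    x * f
  }
}

#' Re-correct the faster of two lineages sharing a later event
#'
#' After first-stage alignment through an old shared event, lineages that
#' experienced additional shared events with rate change between them still
#' disagree on the later event's corrected peak. Taking the slower lineage
#' as reference, the faster lineage's factor receives the multiplicative
#' update `mu'_slow / mu'_fast` computed on first-stage-corrected peaks.
#'
#' @param assigned_slow_corr,assigned_fast_corr first-stage-corrected event
#'   tables ([correct_ks()] on [assign_events()] output).
#' @param shared_later_event name of the later shared event.
#' @param lambda_fast the faster lineage's current lambda.
#' @return list `lambda` (updated), `update` (the factor applied).
#' @export
recorrect_pair <- function(assigned_slow_corr, assigned_fast_corr,
                           shared_later_event, lambda_fast) {
  pick <- function(tab) {
    row <- tab[tab$event == shared_later_event, , drop = FALSE]
    if (!nrow(row)) stop_wgd("assignment", "no component assigned to event '%s'",
                             shared_later_event)
    row$mean
  }
  update <- pick(assigned_slow_corr) / pick(assigned_fast_corr)
  list(lambda = lambda_fast * update, update = update)
}

#' Date events from corrected Ks peaks
#'
#' With a reference clock rate `r_ref` (Ks per Mya per branch), an event
#' whose corrected peak is at `mu'` dates to `T = mu' / (2 r_ref)`. The
#' calibration is either `r_ref` directly or an anchored event age
#' (`r_ref = mu'_anchor / (2 T_anchor)`); dating the anchor event then
#' returns its anchor age exactly. The interval reported is
#' `(mu' +/- sigma') / (2 r_ref)`.
#'
#' @param assigned_corr corrected event table (`event`, `mean`, `sd`).
#' @param calibration list with either `r_ref`, or `anchor_event` +
#'   `anchor_age` (Mya).
#' @return a `calibrated_dates` data.frame: `event`, `mu`, `sigma`, `T`,
#'   `T_lo`, `T_hi`, `r_ref`.
#' @export
date_events <- function(assigned_corr, calibration) {
  if (!is.null(calibration$r_ref)) {
    r_ref <- calibration$r_ref
  } else {
    if (is.null(calibration$anchor_event) || is.null(calibration$anchor_age)) {
      config_error("calibration needs r_ref or anchor_event + anchor_age")
    }
    if (calibration$anchor_age <= 0) config_error("anchor age must be positive")
    row <- assigned_corr[assigned_corr$event == calibration$anchor_event, , drop = FALSE]
    if (!nrow(row)) stop_wgd("assignment", "anchor event '%s' not in fitted events",
                             calibration$anchor_event)
    r_ref <- row$mean / (2 * calibration$anchor_age)
  }
  if (is.na(r_ref) || r_ref <= 0) config_error("nonpositive calibration rate")
  out <- data.frame(event = assigned_corr$event,
                    mu = assigned_corr$mean, sigma = assigned_corr$sd,
                    T = assigned_corr$mean / (2 * r_ref),
                    T_lo = (assigned_corr$mean - assigned_corr$sd) / (2 * r_ref),
                    T_hi = (assigned_corr$mean + assigned_corr$sd) / (2 * r_ref),
                    r_ref = r_ref, stringsAsFactors = FALSE)
  class(out) <- c("calibrated_dates", "data.frame")
  out
}
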