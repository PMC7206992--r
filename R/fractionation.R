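# Fractionation statistics: deletion-run extraction, geometric run-length
# modelling, and retention divergence between duplicated regions.

#' Extract deletion runs from an event-table column
#'
#' Maximal runs of consecutive missing reference positions per target
#' column, counted only inside block-covered reference intervals (a run
#' cannot span a region never covered by any block of that column). Runs
#' truncated by a coverage boundary are flagged and excluded from fitting by
#' default.
#'
#' @param et an `event_table`.
#' @param genome target genome id (default: all).
#' @return data.frame `genome`, `column`, `chr`, `start_order`, `length`,
#'   `truncated`.
#' @export
extract_runs <- function(et, genome = NULL) {
  gs <- if (is.null(genome)) names(et$cells) else genome
  chr <- et$ref_genes$chr
  out <- list()
  for (tg in gs) {
    m <- et$cells[[tg]]; cov <- et$coverage[[tg]]
    for (col in seq_len(ncol(m))) {
      for (ch in unique(chr)) {
        rows <- which(chr == ch)
        cv <- cov[rows, col]
        if (!any(cv)) next
        ## maximal covered intervals
        r <- rle(cv)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (iv in which(r$values)) {
          seg <- rows[starts[iv]:ends[iv]]
          miss <- is.na(m[seg, col])
          rr <- rle(miss)
          re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
          for (k in which(rr$values)) {
            out[[length(out) + 1L]] <- data.frame(
              genome = tg, column = col, chr = ch,
              start_order = et$ref_genes$order_index[seg[rs[k]]],
              length = rr$lengths[k],
              truncated = (rs[k] == 1L) || (re[k] == length(seg)),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(genome = character(), column = integer(), chr = character(),
                      start_order = integer(), length = integer(),
                      truncated = logical()))
  }
  do.call(rbind, out)
}

#' Fit a geometric model to deletion-run lengths
#'
#' Run lengths are modelled as Geometric(p) on support 1, 2, ... (a deleted
#' segment contains at least one gene), with MLE `p = 1 / mean(length)`.
#' Reports the observed and model-implied fraction of runs shorter than 10
#' genes (`1 - (1-p)^9`) — and the corresponding fractions of *genes*
#' removed in such runs — plus a chi-square goodness of fit over binned
#' lengths. Truncated runs are excluded.
#'
#' @param runs data.frame from [extract_runs()], or a numeric vector of run
#'   lengths.
#' @param min_runs minimal number of runs (30).
#' @param relax_min unit-test escape hatch to fit tiny samples.
#' @return a `geometric_fit` list: `p_hat`, `se`, `n_runs`,
#'   `frac_lt10_obs`, `frac_lt10_model`, `gene_frac_lt10_obs`,
#'   `gene_frac_lt10_model`, `chisq`, `chisq_df`, `chisq_p`.
#' @export
fit_geometric <- function(runs, min_runs = 30L, relax_min = FALSE) {
  len <- if (is.data.frame(runs)) runs$length[!runs$truncated] else runs
  len <- len[is.finite(len) & len >= 1]
  if (length(len) < min_runs && !relax_min) {
    insufficient_data_error("fit_geometric: %d usable runs (need >= %d)",
                            length(len), min_runs)
  }
  n <- length(len)
  p <- 1 / mean(len)
  se <- sqrt(p^2 * (1 - p) / n)
  frac_obs <- mean(len < 10)
  frac_model <- 1 - (1 - p)^9
  gene_obs <- sum(len[len < 10]) / sum(len)
  ## model-implied fraction of deleted genes lying in runs < 10:
  ## E[L 1(L<10)] / E[L] for Geometric(p) on 1,2,...
  k <- 1:9
  gene_model <- sum(k * p * (1 - p)^(k - 1)) * p  # = sum(k pmf) / (1/p)
  ## chi-square GOF over bins 1..9, 10+
  obs <- c(tabulate(pmin(len, 10), nbins = 10))
  probs <- c(p * (1 - p)^(0:8), (1 - p)^9)
  keep <- probs * n >= 1e-9
  chisq <- sum((obs[keep] - n * probs[keep])^2 / (n * probs[keep]))
  df <- max(sum(keep) - 2L, 1L)
  structure(list(p_hat = p, se = se, n_runs = n,
                 frac_lt10_obs = frac_obs, frac_lt10_model = frac_model,
                 gene_frac_lt10_obs = gene_obs, gene_frac_lt10_model = gene_model,
                 chisq = chisq, chisq_df = df,
                 chisq_p = pchisq(chisq, df, lower.tail = FALSE)),
            class = "geometric_fit")
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf("geometric_fit: p = %.4f (se %.4f, n = %d); runs < 10 genes: %.1f%% observed, %.1f%% model\n",
              x$p_hat, x$se, x$n_runs, 100 * x$frac_lt10_obs, 100 * x$frac_lt10_model))
  invisible(x)
}

#' Windowed retention profile and sibling-column divergence test
#'
#' Sliding-window retention fraction per column along the reference order,
#' and for each sibling column pair (adjacent columns duplicated by the
#' youngest event) a paired sign test over windows for divergent retention.
#'
#' @param et an `event_table`.
#' @param genome target genome id.
#' @param window window size in reference genes (30).
#' @param step step between windows (5).
#' @return list `profile` (data.frame column, chr, window_start, retention),
#'   `tests` (data.frame per sibling pair: n_windows, n_first_higher,
#'   n_second_higher, p_value).
#' @export
retention_profile <- function(et, genome, window = 30L, step = 5L) {
  m <- et$cells[[genome]]; cov <- et$coverage[[genome]]
  chr <- et$ref_genes$chr
  max_chr <- max(table(chr))
  if (window > max_chr) {
    config_error("window (%d) larger than the longest chromosome (%d genes)",
                 window, max_chr)
  }
  prof <- list()
  for (col in seq_len(ncol(m))) {
    for (ch in unique(chr)) {
      rows <- which(chr == ch)
      n <- length(rows)
      if (n < window) next
      for (ws in seq(1L, n - window + 1L, by = step)) {
        idx <- rows[ws:(ws + window - 1L)]
        cvd <- cov[idx, col]
        if (!any(cvd)) next
        prof[[length(prof) + 1L]] <- data.frame(
          column = col, chr = ch, window_start = ws,
          retention = mean(!is.na(m[idx, col][cvd])),
          stringsAsFactors = FALSE)
      }
    }
  }
  prof <- if (length(prof)) do.call(rbind, prof) else
    data.frame(column = integer(), chr = character(), window_start = integer(),
               retention = numeric())
  ## sibling pairs: youngest event duplicates adjacent column pairs
  events <- et$schema$targets[[genome]]
  tests <- list()
  if (length(events) && ncol(m) %% 2 == 0 && events[length(events)] == 2) {
    for (pair in seq_len(ncol(m) / 2)) {
      c1 <- 2L * pair - 1L; c2 <- 2L * pair
      p1 <- prof[prof$column == c1, ]
      p2 <- prof[prof$column == c2, ]
      mm <- merge(p1, p2, by = c("chr", "window_start"))
      gt <- sum(mm$retention.x > mm$retention.y)
      lt <- sum(mm$retention.x < mm$retention.y)
      pv <- if (gt + lt > 0) binom.test(gt, gt + lt)$p.value else NA_real_
      tests[[pair]] <- data.frame(column_1 = c1, column_2 = c2,
                                  n_windows = nrow(mm), n_first_higher = gt,
                                  n_second_higher = lt, p_value = pv)
    }
  }
  list(profile = prof,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(column_1 = integer(), column_2 = integer(),
                    n_windows = integer(), n_first_higher = integer(),
                    n_second_higher = integer(), p_value = numeric()))
}
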