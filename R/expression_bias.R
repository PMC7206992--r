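# Expression divergence between duplicated copies and between retention
# classes: per-pair fold-change divergence, subgenome dominance tests, and
# the one-copy vs two-copy comparison.

#' Expression divergence between duplicated gene copies
#'
#' Duplicate pairs are read off the event table: sibling columns duplicated
#' by the youngest event form the within-group ("alpha") pairs, and
#' cross-group combinations the older-event ("beta") pairs. A pair is
#' diverged in a condition when `|log2((a+1)/(b+1))| >= log2(fold_threshold)`
#' on replicate-mean FPKM, and diverged overall when diverged in at least
#' one condition. Fractions are also reported at 1.5x and 3x for
#' sensitivity.
#'
#' @param et an `event_table`.
#' @param expr an `expression_matrix` for the target genome.
#' @param genome target genome id.
#' @param fold_threshold fold-change divergence threshold (2).
#' @return list `pairs` (data.frame event, region_pair, gene_a, gene_b,
#'   max_abs_lr, diverged, higher), `fractions` (per event), `sensitivity`
#'   (fractions at 1.5x/2x/3x).
#' @export
pair_divergence <- function(et, expr, genome, fold_threshold = 2) {
  cm <- condition_means(expr)
  if (!ncol(cm)) config_error("expression matrix has no conditions")
  m <- et$cells[[genome]]
  events <- et$schema$targets[[genome]]
  chr <- et$ref_genes$chr
  pairs <- list()
  add_pairs <- function(c1, c2, event) {
    both <- which(!is.na(m[, c1]) & !is.na(m[, c2]))
    if (!length(both)) return()
    pairs[[length(pairs) + 1L]] <<- data.frame(
      event = event, region_pair = paste0(chr[both], ":", c1, "-", c2),
      gene_a = m[both, c1], gene_b = m[both, c2], stringsAsFactors = FALSE)
  }
  nc <- ncol(m)
  if (length(events) && events[length(events)] == 2 && nc %% 2 == 0) {
    young <- names(events)[length(events)]
    for (p in seq_len(nc / 2)) add_pairs(2L * p - 1L, 2L * p, young)
    if (length(events) > 1) {
      older <- names(events)[length(events) - 1]
      for (c1 in seq_len(nc / 2)) {
        for (c2 in (nc / 2 + 1):nc) {
          if (nc == 4) add_pairs(c1, c2, older)
        }
      }
    }
  } else if (nc >= 2) {
    ev <- if (length(events)) names(events)[1] else "duplication"
    for (c1 in seq_len(nc - 1)) for (c2 in (c1 + 1):nc) add_pairs(c1, c2, ev)
  }
  if (!length(pairs)) {
    empty <- data.frame(event = character(), region_pair = character(),
                        gene_a = character(), gene_b = character(),
                        max_abs_lr = numeric(), diverged = logical(),
                        higher = character())
    return(list(pairs = empty, fractions = data.frame(), sensitivity = data.frame()))
  }
  pr <- do.call(rbind, pairs)
  known <- pr$gene_a %in% rownames(cm) & pr$gene_b %in% rownames(cm)
  pr <- pr[known, , drop = FALSE]
  lr <- log2((cm[pr$gene_a, , drop = FALSE] + 1) / (cm[pr$gene_b, , drop = FALSE] + 1))
  pr$max_abs_lr <- apply(abs(lr), 1, max)
  pr$mean_lr <- rowMeans(lr)
  thr <- log2(fold_threshold)
  pr$diverged <- pr$max_abs_lr >= thr
  pr$higher <- ifelse(pr$mean_lr >= 0, "a", "b")
  rownames(pr) <- NULL
  fractions <- aggregate(diverged ~ event, pr, mean)
  names(fractions)[2] <- "fraction_diverged"
  fractions$n_pairs <- aggregate(diverged ~ event, pr, length)$diverged
  sens <- do.call(rbind, lapply(c(1.5, 2, 3), function(f)
    data.frame(fold_threshold = f,
               fraction_diverged = mean(pr$max_abs_lr >= log2(f)))))
  list(pairs = pr, fractions = fractions, sensitivity = sens)
}

#' Subgenome dominance test per duplicated region pair
#'
#' Among significantly diverged pairs of each region pair, tests whether the
#' higher-expressed copy concentrates on one side (exact two-sided binomial
#' test against 0.5). Region pairs with fewer than `min_pairs` diverged
#' pairs are skipped with a note.
#'
#' @param pairs the `pairs` data.frame from [pair_divergence()].
#' @param min_pairs minimal diverged pairs per region pair (10).
#' @param event restrict to one event's pairs (default: all).
#' @return data.frame `region_pair`, `n_diverged`, `n_first_higher`,
#'   `fraction_first_higher`, `p_value`, `dominant_side`, `skipped`.
#' @export
dominance_test <- function(pairs, min_pairs = 10L, event = NULL) {
  if (!is.null(event)) pairs <- pairs[pairs$event %in% event, , drop = FALSE]
  div <- pairs[pairs$diverged, , drop = FALSE]
  out <- lapply(split(div, div$region_pair), function(d) {
    n <- nrow(d); na <- sum(d$higher == "a")
    skipped <- n < min_pairs
    data.frame(region_pair = d$region_pair[1], n_diverged = n,
               n_first_higher = na, fraction_first_higher = na / n,
               p_value = if (skipped) NA_real_ else binom.test(na, n)$p.value,
               dominant_side = if (na >= n - na) "a" else "b",
               skipped = skipped, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) res <- data.frame(region_pair = character(), n_diverged = integer(),
                                      n_first_higher = integer(),
                                      fraction_first_higher = numeric(),
                                      p_value = numeric(), dominant_side = character(),
                                      skipped = logical())
  res
}

#' One-copy vs two-copy expression comparison
#'
#' For the youngest duplication's sibling pairs: genes whose partner column
#' is missing form the one-copy group; rows retaining both copies contribute
#' the per-pair mean of the two copies. Welch's two-sample t-test on
#' log2(FPKM + 1), per condition.
#'
#' @param et an `event_table`.
#' @param expr an `expression_matrix`.
#' @param genome target genome id.
#' @param min_genes minimal group size (3).
#' @return data.frame per condition: `condition`, `n_one`, `n_two`,
#'   `mean_one`, `mean_two`, `p_value`.
#' @export
one_vs_two_copy_test <- function(et, expr, genome, min_genes = 3L) {
  cm <- condition_means(expr)
  m <- et$cells[[genome]]
  nc <- ncol(m)
  if (nc %% 2 != 0) config_error("genome '%s' has no sibling column pairs", genome)
  ones <- character(0); twos_a <- character(0); twos_b <- character(0)
  for (p in seq_len(nc / 2)) {
    c1 <- 2L * p - 1L; c2 <- 2L * p
    a <- m[, c1]; b <- m[, c2]
    ones <- c(ones, a[!is.na(a) & is.na(b)], b[is.na(a) & !is.na(b)])
    both <- !is.na(a) & !is.na(b)
    twos_a <- c(twos_a, a[both]); twos_b <- c(twos_b, b[both])
  }
  ones <- ones[ones %in% rownames(cm)]
  keep2 <- twos_a %in% rownames(cm) & twos_b %in% rownames(cm)
  twos_a <- twos_a[keep2]; twos_b <- twos_b[keep2]
  if (length(ones) < min_genes || length(twos_a) < min_genes) {
    insufficient_data_error("one-copy group has %d genes, two-copy %d (need >= %d)",
                            length(ones), length(twos_a), min_genes)
  }
  out <- lapply(colnames(cm), function(cond) {
    x1 <- log2(cm[ones, cond] + 1)
    x2 <- (log2(cm[twos_a, cond] + 1) + log2(cm[twos_b, cond] + 1)) / 2
    tt <- t.test(x1, x2)
    data.frame(condition = cond, n_one = length(x1), n_two = length(x2),
               mean_one = mean(x1), mean_two = mean(x2),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
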