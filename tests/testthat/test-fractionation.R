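# Deletion runs, geometric run-length modelling, retention divergence.

make_column_table <- function(present, covered = rep(TRUE, length(present))) {
  ## single-column event table over one reference chromosome
  n <- length(present)
  ann <- toy_annotation("R", n = n, chrs = "c1")
  schema <- table_schema("R", integer(0), list(X = c(W = 2)))
  cells <- cbind(ifelse(present, "g", NA), rep("x", n))
  structure(list(schema = schema, ref_genes = ann$genes, ref_paralogs = NULL,
                 cells = list(X = cells),
                 coverage = list(X = cbind(covered, rep(TRUE, n))),
                 columns = data.frame(genome = "X", column = 1:2,
                                      path = c("a", "b"))),
            class = "event_table")
}

test_that("runs are maximal missing stretches inside covered intervals", {
  et <- make_column_table(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  runs <- extract_runs(et, "X")
  r1 <- runs[runs$column == 1, ]
  expect_equal(r1$length, 3)
  expect_false(r1$truncated)
  ## all present -> no runs
  expect_equal(nrow(extract_runs(make_column_table(rep(TRUE, 6)), "X")[
    extract_runs(make_column_table(rep(TRUE, 6)), "X")$column == 1, , drop = FALSE]), 0)
  ## two runs of 2 and 5, the trailing one truncated at the coverage edge
  pat <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  runs2 <- extract_runs(make_column_table(pat), "X")
  r2 <- runs2[runs2$column == 1, ]
  expect_equal(sort(r2$length), c(2, 5))
  expect_equal(r2$truncated[r2$length == 5], TRUE)
  ## a run cannot span an uncovered region
  pat3 <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  cov3 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  r3 <- extract_runs(make_column_table(pat3, cov3), "X")
  r3 <- r3[r3$column == 1, ]
  expect_equal(nrow(r3), 2)   # split by the uncovered gap, both truncated
  expect_true(all(r3$truncated))
})

test_that("geometric MLE is 1/mean with the stated closed forms", {
  f <- fit_geometric(c(2, 2, 2), relax_min = TRUE)
  expect_equal(f$p_hat, 0.5)
  expect_equal(f$frac_lt10_model, 1 - 0.5^9)
  f3 <- fit_geometric(rep(c(1, 2, 7), 20), relax_min = TRUE)
  expect_equal(f3$p_hat, 1 / mean(c(1, 2, 7)))
  expect_equal(f3$frac_lt10_model, 1 - (1 - f3$p_hat)^9)
  expect_error(fit_geometric(1:5), class = "wgdscan_insufficient_data")
})

test_that("simulated geometric runs recover p", {
  set.seed(8)
  runs <- rgeom(2000, 0.3) + 1
  f <- fit_geometric(runs)
  expect_gt(f$p_hat, 0.27); expect_lt(f$p_hat, 0.33)
  expect_equal(f$frac_lt10_obs, f$frac_lt10_model, tolerance = 0.05)
  expect_gt(f$chisq_p, 1e-4)
})

test_that("runs + retained genes account for every covered position", {
  ds <- simulate_gene_orders(double_wgd_config(400, 1, retain_alpha = 0.6, seed = 18))
  et <- build_truth_table(ds)
  runs <- extract_runs(et, "X")
  for (col in 1:4) {
    covered <- sum(et$coverage$X[, col])
    present <- sum(!is.na(et$cells$X[et$coverage$X[, col], col]))
    expect_equal(present + sum(runs$length[runs$column == col]), covered)
  }
})

test_that("windowed retention matches manual computation on a toy pattern", {
  pat <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  et <- make_column_table(pat)
  rp <- retention_profile(et, "X", window = 5, step = 5)
  p1 <- rp$profile[rp$profile$column == 1, ]
  expect_equal(p1$retention, c(mean(pat[1:5]), mean(pat[6:10])))
  expect_error(retention_profile(et, "X", window = 50),
               class = "wgdscan_config_error")
})

test_that("divergent sibling retention is detected by the sign test", {
  ## plant asymmetric loss between the two youngest-event columns by
  ## simulating, then knocking out extra genes from column 1
  ds <- simulate_gene_orders(single_wgd_config(2000, 1, retain = 0.85,
                                               seed = 19))
  evs <- ds$truth$tip_events$X
  schema <- table_schema("V", integer(0), list(X = setNames(2L, evs)))
  hom <- filter_families(ds$homology)
  cs <- chain_blocks(hom, ds$annotations$V, ds$annotations$X, strict = FALSE)
  groups <- list(X = truth_block_groups(ds, cs, "X", schema))
  et <- build_event_table(schema, ds$annotations$V, list(X = cs), groups)
  set.seed(1)
  filled <- which(!is.na(et$cells$X[, 1]))
  et$cells$X[sample(filled, length(filled) * 0.3), 1] <- NA
  rp <- retention_profile(et, "X")
  expect_lt(rp$tests$p_value[1], 0.01)
  expect_gt(rp$tests$n_second_higher[1], rp$tests$n_first_higher[1])
  ## balanced retention is not significant
  et2 <- build_event_table(schema, ds$annotations$V, list(X = cs), groups)
  rp2 <- retention_profile(et2, "X")
  expect_gt(rp2$tests$p_value[1], 0.001)
})
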