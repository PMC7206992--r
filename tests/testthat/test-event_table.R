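# Reference-anchored colinear gene tables, retention statistics and
# Dollo-parsimony loss-epoch classification.

test_that("schema column counts follow m_ref * (1 + sum m_g)", {
  paper_like <- table_schema("V", c(ECH = 3),
                             list(C = integer(0), L = c(ACH = 3),
                                  D = c(`A-beta` = 2, `A-alpha` = 2),
                                  X = c(`A-beta` = 2, `A-alpha` = 2)))
  expect_equal(paper_like$n_columns, 39)
  expect_equal(table_schema("V", integer(0), list(X = c(W = 2)))$n_columns, 3)
  expect_equal(unname(paper_like$m_g), c(1L, 3L, 4L, 4L))
})

test_that("a hand-built table fills covered cells and dots the rest", {
  ann_ref <- toy_annotation("R", n = 5, chrs = "c1")
  ann_t <- toy_annotation("T", n = 10, chrs = "c1")
  rid <- ann_ref$genes$gene_id; tid <- ann_t$genes$gene_id
  h <- toy_homology(rid[1:3], tid[1:3])
  cs <- chain_blocks(h, ann_ref, ann_t, min_anchors = 3)
  schema <- table_schema("R", integer(0), list(T = c(W = 2)))
  et <- build_event_table(schema, ann_ref, list(T = cs))
  expect_equal(unname(et$cells$T[1:3, 1]), tid[1:3])
  expect_true(all(is.na(et$cells$T[4:5, ])))
  expect_true(all(is.na(et$cells$T[, 2])))
  full <- compose_full_table(et)
  expect_equal(ncol(full), 3)
  expect_equal(nrow(full), 5)
})

test_that("zero-loss simulation leaves no missing cells in covered columns", {
  ds <- simulate_gene_orders(double_wgd_config(100, 1, seed = 13))
  et <- build_truth_table(ds)
  expect_equal(ncol(et$cells$X), 4)
  expect_true(all(!is.na(et$cells$X)))
  rs <- retention_stats(et, "X")
  expect_equal(rs$pct[rs$depth == 4], 100)
  expect_equal(rs$deleted_cell_fraction[1], 0)
})

test_that("retention percentages sum to 100 and match planted loss", {
  ds <- simulate_gene_orders(double_wgd_config(400, 1, retain_alpha = 0.6,
                                               seed = 14))
  et <- build_truth_table(ds)
  rs <- retention_stats(et, "X")
  expect_equal(sum(rs$pct), 100, tolerance = 1e-9)
  ## per-row depth equals the true copy number
  tg <- ds$truth$genes[ds$truth$genes$genome == "X", ]
  truth_depth <- table(factor(tg$anc, levels = sort(unique(ds$truth$genes$anc))))
  ref_anc <- ds$truth$genes$anc[match(et$ref_genes$gene_id, ds$truth$genes$gene_id)]
  expect_equal(unname(retained_depth(et, "X")),
               unname(as.integer(truth_depth[as.character(ref_anc)])))
})

test_that("loss epochs classify by Dollo parsimony on the column hierarchy", {
  schema <- table_schema("R", integer(0),
                         list(X = c(`A-beta` = 2, `A-alpha` = 2)))
  ann_ref <- toy_annotation("R", n = 4, chrs = "c1")
  ## hand-built event table: 4 rows with chosen presence patterns
  cells <- rbind(c("a", "b", "c", "d"),     # all present: no loss
                 c("a", NA, "c", "d"),      # single missing sibling: after A-alpha
                 c(NA, NA, "c", "d"),       # one A-beta side gone: between events
                 c(NA, NA, NA, NA))         # all gone: before A-beta
  et <- structure(list(schema = schema,
                       ref_genes = ann_ref$genes,
                       ref_paralogs = NULL,
                       cells = list(X = cells),
                       coverage = list(X = matrix(TRUE, 4, 4)),
                       columns = data.frame(genome = "X", column = 1:4,
                                            path = wgdscan:::column_paths(schema$targets$X))),
                  class = "event_table")
  cl <- classify_loss_epochs(et, "X")
  s <- setNames(cl$summary$n_events, cl$summary$epoch)
  expect_equal(unname(s["before_A-beta"]), 1)
  expect_equal(unname(s["between_A-beta_A-alpha"]), 1)
  expect_equal(unname(s["after_A-alpha"]), 1)
  cellcount <- setNames(cl$summary$n_cells, cl$summary$epoch)
  expect_equal(unname(cellcount["before_A-beta"]), 4)
  expect_equal(unname(cellcount["between_A-beta_A-alpha"]), 2)
  ## pattern (missing, missing | present, missing): between + after
  et$cells$X <- rbind(c(NA, NA, "c", NA))
  et$coverage$X <- matrix(TRUE, 1, 4)
  et$ref_genes <- ann_ref$genes[1, ]
  cl2 <- classify_loss_epochs(et, "X")
  s2 <- setNames(cl2$summary$n_events, cl2$summary$epoch)
  expect_equal(unname(s2["between_A-beta_A-alpha"]), 1)
  expect_equal(unname(s2["after_A-alpha"]), 1)
  expect_equal(unname(s2["before_A-beta"]), 0)
})

test_that("zero-loss simulations classify zero loss events everywhere", {
  ds <- simulate_gene_orders(double_wgd_config(100, 1, seed = 15))
  et <- build_truth_table(ds)
  cl <- classify_loss_epochs(et, "X")
  expect_equal(sum(cl$summary$n_events), 0)
})

test_that("losses planted in one epoch are assigned to that epoch", {
  ds <- simulate_gene_orders(double_wgd_config(800, 2, retain_beta = 0.75,
                                               retain_alpha = 1, seed = 16))
  et <- build_truth_table(ds)
  cl <- classify_loss_epochs(et, "X")
  s <- setNames(cl$summary$n_events, cl$summary$epoch)
  expect_gt(sum(s), 100)
  expect_gte(s[["between_A-beta_A-alpha"]] / sum(s), 0.95)
})

test_that("the five-genome paper-like configuration composes to 39 columns", {
  hc <- history_config_clade5(80, 1, seed = 17)
  ds <- simulate_gene_orders(hc)
  schema <- table_schema("V", c(ECH = 3),
                         list(C = integer(0), L = c(ACH = 3),
                              D = c(`A-beta` = 2, `A-alpha` = 2),
                              X = c(`A-beta` = 2, `A-alpha` = 2)))
  hom <- filter_families(ds$homology)
  bl <- list(self = chain_blocks(hom, ds$annotations$V, ds$annotations$V,
                                 min_anchors = 4, strict = FALSE))
  groups <- list()
  for (g in c("C", "L", "D", "X")) {
    cs <- chain_blocks(hom, ds$annotations$V, ds$annotations[[g]],
                       min_anchors = 4, strict = FALSE)
    lab <- block_event_labels(cs, ds$homology)
    keep <- which(lab == "speciation")
    cs$blocks <- cs$blocks[cs$blocks$block_id %in% keep, , drop = FALSE]
    cs$anchors <- cs$anchors[cs$anchors$block_id %in% keep, , drop = FALSE]
    bl[[g]] <- cs
    groups[[g]] <- truth_block_groups(ds, cs, g, schema)
  }
  et <- build_event_table(schema, ds$annotations$V, bl, groups)
  expect_equal(n_table_columns(et), 39)
  full <- compose_full_table(et)
  expect_equal(ncol(full), 39)
  expect_equal(nrow(full), nrow(ds$annotations$V$genes))
  ## circles figure renders one circle per column, deterministically
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  render_homology_circles(et, ds$annotations, p1)
  render_homology_circles(et, ds$annotations, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(sum(grepl('<circle cx', readLines(p1), fixed = TRUE)), 39)
})
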