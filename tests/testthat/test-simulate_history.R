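# Genome-history simulator: multiplicity arithmetic, loss accounting,
# determinism, sequence divergence calibration, expression planting.

test_that("no events and no loss reproduce the ancestor in every genome", {
  tree <- list(age = 50, rate = 1, children = list(
    list(tip = "A", rate = 1), list(tip = "B", rate = 1)))
  cfg <- history_config(ancestor = list(n_chromosomes = 2, genes_per_chromosome = 40),
                        root_age = 60, tree = tree, events = list(), seed = 1)
  ds <- simulate_gene_orders(cfg)
  expect_equal(nrow(ds$annotations$A$genes), 80)
  expect_equal(nrow(ds$annotations$B$genes), 80)
  ## homology is a perfect 1:1 matching between genomes
  hom <- ds$homology
  expect_equal(nrow(hom), 80)
  expect_equal(sort(unique(hom$event)), "speciation")
  expect_equal(anyDuplicated(hom$query), 0)
})

test_that("two nested tetraploidizations without loss give 4 copies everywhere", {
  ds <- simulate_gene_orders(double_wgd_config(50, 1, seed = 2))
  tg <- ds$truth$genes
  copies <- table(tg$anc[tg$genome == "X"])
  expect_true(all(copies == 4))
  expect_equal(nrow(ds$annotations$X$genes), 200)
  ## subgenome labels partition the copies
  expect_equal(sort(unique(tg$subgenome[tg$genome == "X"])),
               c("b1.a1", "b1.a2", "b2.a1", "b2.a2"))
})

test_that("a fixed seed reproduces the dataset exactly", {
  d1 <- simulate_gene_orders(single_wgd_config(60, 1, retain = 0.7, seed = 9))
  d2 <- simulate_gene_orders(single_wgd_config(60, 1, retain = 0.7, seed = 9))
  expect_identical(d1$annotations$X$genes, d2$annotations$X$genes)
  expect_identical(d1$homology, d2$homology)
  s1 <- realize_sequences(d1); s2 <- realize_sequences(d2)
  expect_identical(as.character(s1$cds$X), as.character(s2$cds$X))
})

test_that("retained plus lost genes balance the pre-loss copy count", {
  ds <- simulate_gene_orders(single_wgd_config(200, 1, retain = 0.75, seed = 3))
  n_pre <- 200 * 2           # after one tetraploidy of a 200-gene chromosome
  n_post <- nrow(ds$annotations$X$genes)
  n_lost <- sum(ds$truth$deletion_runs$deleted)
  expect_equal(n_post + n_lost, n_pre)
})

test_that("deletion run lengths follow the configured geometric distribution", {
  ds <- simulate_gene_orders(single_wgd_config(4000, 1, retain = 0.5,
                                               p_loss = 0.3, seed = 5,
                                               keep_one_copy = FALSE))
  runs <- ds$truth$deletion_runs
  expect_gt(nrow(runs), 500)
  expect_equal(mean(runs$drawn), 1 / 0.3, tolerance = 0.1)
})

test_that("infeasible retention under last-copy protection is a config error", {
  ## retain 0.1 would need deleting protected last copies
  cfg <- single_wgd_config(50, 1, retain = 0.1, seed = 1)
  expect_error(simulate_gene_orders(cfg), class = "wgdscan_config_error")
})

test_that("true Ks equals twice the rate-weighted path length", {
  cfg <- double_wgd_config(40, 1, seed = 1)
  ds <- simulate_gene_orders(cfg)
  tk <- ds$truth$true_ks
  get <- function(g, ev) tk$ks[tk$genome_a == g & tk$event == ev]
  ## X branch rate 1, r_ref 0.005: Ks = 2 * 0.005 * age
  expect_equal(get("X", "A-alpha"), 2 * 0.005 * 48)
  expect_equal(get("X", "A-beta"), 2 * 0.005 * 58)
  cross <- tk[tk$type == "cross", ]
  expect_equal(cross$ks, 2 * 0.005 * 85)
})

test_that("a zero-length branch leaves sequences identical and Ks estimates at 0", {
  prs <- simulate_cds_pairs(5, 0, n_codons = 100, seed = 2)
  expect_identical(prs$cds_a, prs$cds_b)
  est <- mapply(function(a, b) nei_gojobori(align_codons(a, b))$Ks,
                prs$cds_a, prs$cds_b)
  expect_true(all(est == 0))
})

test_that("within-lineage duplicate Ks concentrates at 2 r_ref age without dispersion", {
  cfg <- single_wgd_config(80, 1, retain = 1, seed = 7, sigma_event = 0)
  ds <- simulate_gene_orders(cfg)
  ds <- realize_sequences(ds)
  hom <- ds$homology[ds$homology$event == "A-alpha", ]
  est <- ks_for_pairs(hom[1:60, c("query", "subject")] |>
                        setNames(c("gene_a", "gene_b")), ds$cds$X)
  expect_equal(mean(est$Ks), 2 * 0.005 * 48, tolerance = 0.04)
})

test_that("expression planting controls dominance, deficit and zero rows", {
  ds <- simulate_gene_orders(double_wgd_config(80, 1, retain_alpha = 0.7, seed = 6))
  zg <- ds$truth$genes$gene_id[ds$truth$genes$genome == "X"][1:3]
  ds <- simulate_expression(ds, target = "X", delta = 2,
                            noise_sd_log = 1e-3, cond_sd_log = 0,
                            zero_genes = zg)
  em <- ds$expression
  expect_true(all(em$fpkm[zg, ] == 0))
  tr <- ds$truth$expression$genes
  dom <- tr$gene_id[tr$dominant]
  oth <- tr$gene_id[!tr$dominant & !tr$one_copy]
  expect_gt(length(dom), 10)
  ## delta = 2 with negligible noise: dominant copies ~2x their baseline
  sub <- ds$truth$genes[ds$truth$genes$genome == "X", ]
  anc_of <- setNames(sub$anc, sub$gene_id)
  m <- condition_means(em)
  pick_a <- intersect(dom, rownames(m)); pick_a <- setdiff(pick_a, zg)
  sib <- vapply(pick_a, function(g) {
    cand <- sub$gene_id[sub$anc == anc_of[[g]] & !(sub$gene_id %in% dom)]
    if (length(cand)) cand[1] else NA_character_
  }, "")
  keep <- !is.na(sib) & !(sib %in% zg)
  ratio <- m[pick_a[keep], 1] / m[sib[keep], 1]
  expect_equal(unname(median(ratio)), 2, tolerance = 0.01)
  ## delta = 1 gives expected zero log-ratio
  ds1 <- simulate_expression(ds, target = "X", delta = 1, noise_sd_log = 1e-3,
                             cond_sd_log = 0)
  m1 <- condition_means(ds1$expression)
  r1 <- log2(m1[pick_a[keep], 1] / m1[sib[keep], 1])
  expect_equal(unname(median(r1)), 0, tolerance = 0.01)
  expect_error(simulate_expression(ds, target = "X", delta = 0),
               class = "wgdscan_config_error")
})
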