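# Family filtering, anchor chaining (with brute-force oracle), duplicate
# classification, depth profiles and dot-plot rendering.

test_that("family filtering removes single-linkage families above the threshold", {
  ## a chain a1-a2-...-a31 is one single-linkage family of 31 genes
  big_q <- paste0("a", 1:30); big_s <- paste0("a", 2:31)
  small_q <- paste0("b", 1:29); small_s <- paste0("b", 2:30)   # 30 members
  h <- toy_homology(c(big_q, small_q, "x1"), c(big_s, small_s, "x2"))
  f <- filter_families(h, 30)
  genes_left <- unique(c(f$query, f$subject))
  expect_false(any(grepl("^a", genes_left)))   # 31-member family removed
  expect_true(all(paste0("b", 1:30) %in% genes_left))  # 30 kept (strict >)
  expect_true("x1" %in% genes_left)
  expect_equal(nrow(filter_families(toy_homology(character(0), character(0)))), 0)
})

test_that("a perfect diagonal chains into one same-orientation block", {
  ann_a <- toy_annotation("A", n = 10, chrs = "c1")
  ann_b <- toy_annotation("B", n = 10, chrs = "c1")
  h <- toy_homology(ann_a$genes$gene_id[1:6], ann_b$genes$gene_id[1:6])
  cs <- chain_blocks(h, ann_a, ann_b, min_anchors = 5)
  expect_equal(nrow(cs$blocks), 1)
  expect_equal(cs$blocks$orientation, "same")
  expect_equal(cs$blocks$n_anchors, 6)
})

test_that("an inverted diagonal is chained with descending order_b", {
  ann_a <- toy_annotation("A", n = 10, chrs = "c1")
  ann_b <- toy_annotation("B", n = 10, chrs = "c1")
  h <- toy_homology(ann_a$genes$gene_id[1:6], ann_b$genes$gene_id[6:1])
  cs <- chain_blocks(h, ann_a, ann_b, min_anchors = 5)
  expect_equal(nrow(cs$blocks), 1)
  expect_equal(cs$blocks$orientation, "inverted")
  anc <- cs$anchors
  expect_true(all(diff(anc$order_a) > 0))
  expect_true(all(diff(anc$order_b) < 0))
})

test_that("a gap beyond the limit splits a diagonal into two blocks", {
  ann_a <- toy_annotation("A", n = 120, chrs = "c1")
  ann_b <- toy_annotation("B", n = 120, chrs = "c1")
  idx <- c(1:10, 62:71)   # 51-gene gap on both axes between anchors 10 and 62
  h <- toy_homology(ann_a$genes$gene_id[idx], ann_b$genes$gene_id[idx])
  cs <- chain_blocks(h, ann_a, ann_b, gap_limit = 50, min_anchors = 5)
  expect_equal(nrow(cs$blocks), 2)
  ## the same instance with the gap exactly at the limit stays one block
  idx2 <- c(1:10, 61:70)  # 50-gene gap
  h2 <- toy_homology(ann_a$genes$gene_id[idx2], ann_b$genes$gene_id[idx2])
  cs2 <- chain_blocks(h2, ann_a, ann_b, gap_limit = 50, min_anchors = 5)
  expect_equal(nrow(cs2$blocks), 1)
})

test_that("chain score equals exhaustive enumeration on random small instances", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    a <- sample.int(10, n, replace = TRUE)
    b <- sample.int(10, n, replace = TRUE)
    s <- round(runif(n, 1, 100), 1)
    gap <- sample(c(2, 4, 50), 1)
    ord <- order(a, b)
    a <- a[ord]; b <- b[ord]; s <- s[ord]
    idx <- wgdscan:::chain_best_cpp(as.integer(a), as.integer(b), s,
                                    as.integer(gap) + 1L)
    expect_equal(sum(s[idx]), oracle_chain_score(a, b, s, gap),
                 tolerance = 1e-9)
  }
})

test_that("emitted blocks satisfy monotonicity and gap invariants", {
  ds <- simulate_gene_orders(double_wgd_config(150, 1, retain_beta = 0.8,
                                               retain_alpha = 0.7, seed = 2))
  cs <- chain_blocks(filter_families(ds$homology), ds$annotations$V,
                     ds$annotations$X, strict = FALSE)
  expect_gt(nrow(cs$blocks), 0)
  for (bid in cs$blocks$block_id) {
    anc <- cs$anchors[cs$anchors$block_id == bid, ]
    orient <- cs$blocks$orientation[cs$blocks$block_id == bid]
    da <- diff(anc$order_a)
    db <- diff(anc$order_b) * (if (orient == "same") 1 else -1)
    expect_true(all(da > 0))
    expect_true(all(db > 0))
    if (nrow(anc) > 1) expect_true(all(pmax(da, abs(diff(anc$order_b))) - 1 <= 50))
  }
})

test_that("unknown gene ids in strict mode raise an integrity error", {
  ann <- toy_annotation("A", n = 5, chrs = "c1")
  h <- toy_homology("nosuch", ann$genes$gene_id[1])
  expect_error(chain_blocks(h, ann, toy_annotation("B", 5, "c1")),
               class = "wgdscan_integrity_error")
})

test_that("duplicate classes follow the WGD > tandem > proximal > dispersed precedence", {
  ann <- toy_annotation("G", n = 30, chrs = c("c1", "c2"))
  ids <- function(ch, i) sprintf("G_%s_g%02d", ch, i)
  h <- toy_homology(
    q = c(ids("c2", 7), ids("c1", 1), ids("c1", 20),
          ids("c1", 2:7), ids("c2", 20)),
    s = c(ids("c2", 8), ids("c1", 6), ids("c2", 5),
          ids("c2", 10:15), ids("c2", 21)))
  blocks <- chain_blocks(h, ann, ann, min_anchors = 5)
  cls <- classify_duplicates(ann, h, blocks, proximal_window = 10)
  cl <- setNames(cls$class, cls$gene_id)
  expect_equal(unname(cl[ids("c1", 6)]), "WGD")      # block anchor beats proximal
  expect_equal(unname(cl[ids("c2", 7)]), "tandem")   # adjacent pair, not in a block
  expect_equal(unname(cl[ids("c1", 1)]), "proximal") # 5 apart, not in block
  expect_equal(unname(cl[ids("c1", 20)]), "dispersed")
  expect_equal(unname(cl[ids("c2", 20)]), "tandem")
  expect_equal(unname(cl[ids("c1", 9)]), "singleton")
})

test_that("depth profile counts covering block regions, not anchors", {
  ann_ref <- toy_annotation("R", n = 12, chrs = "c1")
  ann_t <- toy_annotation("T", n = 30, chrs = "c1")
  rid <- ann_ref$genes$gene_id; tid <- ann_t$genes$gene_id
  ## two target regions cover reference genes 1..6 (second with a deletion at
  ## reference gene 3: still covered by the block span)
  h <- toy_homology(c(rid[1:6], rid[c(1, 2, 4, 5, 6)]),
                    c(tid[1:6], tid[c(11, 12, 14, 15, 16)]))
  cs <- chain_blocks(h, ann_ref, ann_t, min_anchors = 5)
  dp <- depth_profile(ann_ref, cs)
  expect_equal(dp$depths$depth[1:6], rep(2, 6))
  expect_equal(dp$depths$depth[7:12], rep(0, 6))
  expect_equal(dp$modal_depth, 2)
  expect_equal(dp$ratio, "1:2")
  expect_equal(dp$deleted_fraction, 0.5)
  ## no blocks at all
  dp0 <- depth_profile(ann_ref, chain_blocks(toy_homology(character(0), character(0)),
                                             ann_ref, ann_t))
  expect_true(all(dp0$depths$depth == 0))
  expect_equal(dp0$deleted_fraction, 1)
})

test_that("zero-loss double tetraploidy gives modal depth 4 against the outgroup", {
  ds <- simulate_gene_orders(double_wgd_config(120, 1, seed = 4))
  cs <- chain_blocks(filter_families(ds$homology), ds$annotations$V,
                     ds$annotations$X, strict = FALSE)
  dp <- depth_profile(ds$annotations$V, cs)
  expect_equal(dp$modal_depth, 4)
  expect_equal(dp$ratio, "1:4")
})

test_that("dot plots colour best/secondary/other hits and are byte-deterministic", {
  ann_a <- toy_annotation("A", n = 10, chrs = "c1")
  ann_b <- toy_annotation("B", n = 10, chrs = "c1")
  h <- homology_table(data.frame(
    query = rep(ann_a$genes$gene_id[1], 3),
    subject = ann_b$genes$gene_id[1:3],
    pident = 90, evalue = 1e-30, score = c(300, 250, 200)))
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  render_dotplot(h, ann_a, ann_b, p1)
  render_dotplot(h, ann_a, ann_b, p2)
  svg <- readLines(p1)
  expect_identical(readLines(p2), svg)
  expect_equal(sum(grepl('fill="red"', svg)), 1)
  expect_equal(sum(grepl('fill="blue"', svg)), 1)
  expect_equal(sum(grepl('fill="grey"', svg)), 1)
  ## empty input still renders a valid plot
  p0 <- tempfile(fileext = ".svg")
  render_dotplot(toy_homology(character(0), character(0)), ann_a, ann_b, p0)
  expect_true(file.exists(p0))
  expect_false(any(grepl("circle", readLines(p0))))
})
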