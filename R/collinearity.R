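# Colinear (synteny) block inference: gene-family filtering, score-maximal
# anchor chaining with a gap constraint in gene units, duplicate-origin
# classification, orthology depth profiles and dot plots.

#' Remove pairs belonging to oversized gene families
#'
#' Genes are clustered into families by single linkage over homology pairs;
#' all pairs touching a family with more than `max_family_size` members are
#' removed (large families blur colinearity signals).
#'
#' @param homology a `homology_table`.
#' @param max_family_size strictly-greater-than threshold (default 30).
#' @return the filtered `homology_table`.
#' @export
filter_families <- function(homology, max_family_size = 30L) {
  if (!nrow(homology)) return(homology)
  g <- igraph::graph_from_data_frame(homology[, c("query", "subject")], directed = FALSE)
  comp <- igraph::components(g)
  fam_size <- comp$csize[comp$membership]
  big <- names(comp$membership)[fam_size > max_family_size]
  keep <- !(homology$query %in% big | homology$subject %in% big)
  out <- homology[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage family membership from a homology table
#' @param homology a `homology_table`.
#' @return named integer vector: gene id -> family id.
#' @export
homology_families <- function(homology) {
  if (!nrow(homology)) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(homology[, c("query", "subject")], directed = FALSE)
  comp <- igraph::components(g)
  setNames(as.integer(comp$membership), names(comp$membership))
}

#' Restrict a homology table to one genome pair
#' @param homology a `homology_table`.
#' @param ann_a,ann_b the two annotations.
#' @return the subset whose pairs have both genes in the union of the two
#'   annotations.
#' @export
homology_for_pair <- function(homology, ann_a, ann_b) {
  ids <- c(ann_a$genes$gene_id, ann_b$genes$gene_id)
  out <- homology[homology$query %in% ids & homology$subject %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

anchor_table <- function(homology, ann_a, ann_b, strict = TRUE) {
  if (!strict) homology <- homology_for_pair(homology, ann_a, ann_b)
  ga <- ann_a$genes; gb <- ann_b$genes
  intra <- identical(ann_a$genome_id, ann_b$genome_id)
  q_in_a <- homology$query %in% ga$gene_id
  s_in_b <- homology$subject %in% gb$gene_id
  if (intra) {
    pairs <- homology
    unknown <- !(q_in_a & s_in_b)
  } else {
    ## orient every pair as (gene in A, gene in B); drop within-genome pairs
    q_in_b <- homology$query %in% gb$gene_id
    s_in_a <- homology$subject %in% ga$gene_id
    unknown <- !((q_in_a | q_in_b) & (s_in_a | s_in_b))
    fwd <- q_in_a & s_in_b
    rev <- q_in_b & s_in_a & !fwd
    pairs <- rbind(
      data.frame(query = homology$query[fwd], subject = homology$subject[fwd],
                 score = homology$score[fwd], stringsAsFactors = FALSE),
      data.frame(query = homology$subject[rev], subject = homology$query[rev],
                 score = homology$score[rev], stringsAsFactors = FALSE))
  }
  if (any(unknown)) {
    bad <- homology[which(unknown)[1], ]
    integrity_error("gene pair (%s, %s) references gene(s) absent from annotations",
                    bad$query, bad$subject)
  }
  ia <- match(pairs$query, ga$gene_id)
  ib <- match(pairs$subject, gb$gene_id)
  anc <- data.frame(gene_a = pairs$query, gene_b = pairs$subject,
                    chr_a = ga$chr[ia], chr_b = gb$chr[ib],
                    order_a = ga$order_index[ia], order_b = gb$order_index[ib],
                    score = pairs$score, stringsAsFactors = FALSE)
  if (intra) {
    ## keep upper triangle so each duplicated segment pair yields one block;
    ## self-diagonal anchors excluded
    keyA <- paste(anc$chr_a, formatC(anc$order_a, width = 9, flag = "0"))
    keyB <- paste(anc$chr_b, formatC(anc$order_b, width = 9, flag = "0"))
    flip <- keyA > keyB
    anc[flip, c("gene_a", "gene_b", "chr_a", "chr_b", "order_a", "order_b")] <-
      anc[flip, c("gene_b", "gene_a", "chr_b", "chr_a", "order_b", "order_a")]
    anc <- anc[!(anc$chr_a == anc$chr_b & anc$order_a == anc$order_b), , drop = FALSE]
    anc <- anc[!duplicated(paste(anc$gene_a, anc$gene_b)), , drop = FALSE]
  }
  anc
}

#' Chain homologous gene pairs into colinear blocks
#'
#' Per chromosome pair, blocks are score-maximal chains of anchors under
#' strict monotonicity (found separately for `same` and `inverted`
#' orientation) and the gap constraint `max(|d order_a|, |d order_b|) - 1 <=
#' gap_limit` (measured in genes). Chains are extracted best-first; an anchor
#' consumed by a chain is unavailable to later chains of the same orientation
#' on that chromosome pair. Chains with fewer than `min_anchors` anchors are
#' discarded. A gene may still appear in several blocks overall (recursive
#' duplications place it in distinct chromosome pairs or orientations).
#'
#' @param homology a (family-filtered) `homology_table`.
#' @param ann_a,ann_b annotations of the two genomes (identical object for an
#'   intra-genome run, in which case self-diagonal anchors are excluded).
#' @param gap_limit maximal gap between consecutive colinear genes (50).
#' @param min_anchors minimal anchors per reported block (5).
#' @param strict error on gene ids absent from the annotations; with
#'   `strict = FALSE` a combined multi-genome homology table may be passed
#'   and non-matching pairs are dropped.
#' @return a `colinear_set`: list with `blocks` and `anchors` data.frames.
#' @export
chain_blocks <- function(homology, ann_a, ann_b, gap_limit = 50L, min_anchors = 5L,
                         strict = TRUE) {
  anc <- anchor_table(homology, ann_a, ann_b, strict = strict)
  blocks <- list(); anchors <- list(); bid <- 0L
  if (nrow(anc)) {
    anc_split <- split(anc, list(anc$chr_a, anc$chr_b), drop = TRUE)
    ## deterministic chromosome-pair order
    anc_split <- anc_split[order(names(anc_split))]
    for (grp in anc_split) {
      for (orient in c("same", "inverted")) {
        g <- grp
        g$bb <- if (orient == "same") g$order_b else -g$order_b
        g <- g[order(g$order_a, g$bb), , drop = FALSE]
        while (nrow(g)) {
          idx <- chain_best_cpp(as.integer(g$order_a), as.integer(g$bb),
                                g$score, as.integer(gap_limit) + 1L)
          chain <- g[idx, , drop = FALSE]
          g <- g[-idx, , drop = FALSE]
          if (nrow(chain) >= min_anchors) {
            bid <- bid + 1L
            blocks[[bid]] <- data.frame(
              block_id = bid, genome_a = ann_a$genome_id, genome_b = ann_b$genome_id,
              chr_a = chain$chr_a[1], chr_b = chain$chr_b[1], orientation = orient,
              n_anchors = nrow(chain), score = sum(chain$score),
              start_a = min(chain$order_a), end_a = max(chain$order_a),
              start_b = min(chain$order_b), end_b = max(chain$order_b),
              ks_median = NA_real_, stringsAsFactors = FALSE)
            anchors[[bid]] <- data.frame(
              block_id = bid, gene_a = chain$gene_a, gene_b = chain$gene_b,
              order_a = chain$order_a, order_b = chain$order_b,
              score = chain$score, stringsAsFactors = FALSE)
          }
          if (nrow(g) < 1) break
        }
      }
    }
  }
  empty_blocks <- data.frame(block_id = integer(), genome_a = character(),
                             genome_b = character(), chr_a = character(),
                             chr_b = character(), orientation = character(),
                             n_anchors = integer(), score = numeric(),
                             start_a = integer(), end_a = integer(),
                             start_b = integer(), end_b = integer(),
                             ks_median = numeric(), stringsAsFactors = FALSE)
  empty_anchors <- data.frame(block_id = integer(), gene_a = character(),
                              gene_b = character(), order_a = integer(),
                              order_b = integer(), score = numeric(),
                              stringsAsFactors = FALSE)
  bl <- if (length(blocks)) do.call(rbind, blocks) else empty_blocks
  an <- if (length(anchors)) do.call(rbind, anchors) else empty_anchors
  ## renumber blocks deterministically
  if (nrow(bl)) {
    ord <- order(bl$chr_a, bl$chr_b, bl$orientation, bl$start_a, bl$start_b)
    remap <- setNames(seq_along(ord), bl$block_id[ord])
    bl <- bl[ord, , drop = FALSE]
    bl$block_id <- seq_len(nrow(bl))
    an$block_id <- unname(remap[as.character(an$block_id)])
    an <- an[order(an$block_id, an$order_a), , drop = FALSE]
    rownames(bl) <- rownames(an) <- NULL
  }
  structure(list(blocks = bl, anchors = an,
                 genome_a = ann_a$genome_id, genome_b = ann_b$genome_id),
            class = "colinear_set")
}

#' @export
print.colinear_set <- function(x, ...) {
  cat(sprintf("colinear_set %s vs %s: %d blocks, %d anchor pairs\n",
              x$genome_a, x$genome_b, nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

#' Classify gene duplicate origins
#'
#' Precedence WGD > tandem > proximal > dispersed: an anchor gene of any
#' intra-genome colinear block is `WGD`; else a gene homologous to an
#' adjacent gene (distance 1 on the same chromosome) is `tandem`; else
#' homologous within `proximal_window` genes on the same chromosome is
#' `proximal`; else any homolog makes it `dispersed`; genes without homologs
#' are `singleton`.
#'
#' @param annotation the genome's [genome_annotation()].
#' @param homology intra-genome `homology_table`.
#' @param blocks intra-genome `colinear_set` from [chain_blocks()].
#' @param proximal_window window (genes) for the proximal class (10).
#' @return data.frame `gene_id`, `class`.
#' @export
classify_duplicates <- function(annotation, homology, blocks, proximal_window = 10L) {
  g <- annotation$genes
  cls <- rep("singleton", nrow(g))
  names(cls) <- g$gene_id
  has_hom <- g$gene_id %in% c(homology$query, homology$subject)
  cls[has_hom] <- "dispersed"
  if (nrow(homology)) {
    io <- match(homology$query, g$gene_id)
    is <- match(homology$subject, g$gene_id)
    same_chr <- !is.na(io) & !is.na(is) & g$chr[io] == g$chr[is]
    d <- abs(g$order_index[io] - g$order_index[is])
    prox <- same_chr & d <= proximal_window & d >= 1
    cls[unique(c(homology$query[prox], homology$subject[prox]))] <- "proximal"
    tand <- same_chr & d == 1
    cls[unique(c(homology$query[tand], homology$subject[tand]))] <- "tandem"
  }
  wgd_genes <- unique(c(blocks$anchors$gene_a, blocks$anchors$gene_b))
  cls[names(cls) %in% wgd_genes] <- "WGD"
  data.frame(gene_id = g$gene_id, class = unname(cls[g$gene_id]),
             stringsAsFactors = FALSE)
}

#' Orthology depth profile of a reference genome
#'
#' For each reference gene, depth is the number of distinct target block
#' regions whose anchor span covers the gene's `order_index` (so a reference
#' gene locally deleted in the target still counts as covered). Reports the
#' per-gene depths, a histogram, the modal correspondence ratio `1:mode`
#' (over genes with depth >= 1) and the fraction with depth 0.
#'
#' @param ref_annotation reference [genome_annotation()].
#' @param blocks `colinear_set` with the reference as genome `a`.
#' @return list `depths` (data.frame), `histogram`, `modal_depth`, `ratio`,
#'   `deleted_fraction`.
#' @export
depth_profile <- function(ref_annotation, blocks) {
  g <- ref_annotation$genes
  depth <- integer(nrow(g))
  bl <- blocks$blocks
  for (chr in unique(g$chr)) {
    sel <- which(g$chr == chr)
    bsel <- bl[bl$chr_a == chr, , drop = FALSE]
    if (!nrow(bsel)) next
    ord <- g$order_index[sel]
    for (k in seq_len(nrow(bsel))) {
      depth[sel] <- depth[sel] + (ord >= bsel$start_a[k] & ord <= bsel$end_a[k])
    }
  }
  hist <- table(factor(depth, levels = 0:max(c(depth, 0))))
  covered <- depth[depth >= 1]
  modal <- if (length(covered)) as.integer(names(which.max(table(covered)))) else NA_integer_
  list(depths = data.frame(gene_id = g$gene_id, chr = g$chr,
                           order_index = g$order_index, depth = depth,
                           stringsAsFactors = FALSE),
       histogram = hist,
       modal_depth = modal,
       ratio = if (is.na(modal)) NA_character_ else paste0("1:", modal),
       deleted_fraction = mean(depth == 0))
}

#' Render a homologous-gene dot plot as SVG
#'
#' Chromosomes are laid out in annotation order with axes in Mb. Per query
#' gene, the best-scoring hit is drawn red, the second best blue and the
#' rest grey. Optional block outlines are drawn as rectangles coloured by Ks
#' median. Output is deterministic: identical inputs give byte-identical SVG.
#'
#' @param homology `homology_table` (scores rank best/secondary hits).
#' @param ann_a,ann_b annotations for x (query) and y (subject) axes.
#' @param blocks optional `colinear_set` to outline.
#' @param out_path output `.svg` path.
#' @param size plot edge in pixels.
#' @return `out_path`, invisibly.
#' @export
render_dotplot <- function(homology, ann_a, ann_b, out_path, blocks = NULL,
                           size = 800) {
  margin <- 60
  lay <- function(ann) {
    len <- tapply(ann$genes$end, ann$genes$chr, max)
    len <- len[unique(ann$genes$chr)]   # annotation order
    off <- cumsum(c(0, as.numeric(len)))
    list(chr = names(len), len = as.numeric(len), off = off[-length(off)],
         total = sum(as.numeric(len)))
  }
  la <- lay(ann_a); lb <- lay(ann_b)
  sc_a <- (size - 2 * margin) / la$total
  sc_b <- (size - 2 * margin) / lb$total
  doc <- svg_new(size, size)
  doc <- svg_add(doc, svg_rect(margin, margin, size - 2 * margin, size - 2 * margin,
                               fill = "white", stroke = "black"))
  for (i in seq_along(la$chr)) {
    x <- margin + la$off[i] * sc_a
    doc <- svg_add(doc, svg_line(x, margin, x, size - margin, stroke = "#cccccc", sw = 0.5),
                   svg_text(x + la$len[i] * sc_a / 2, margin - 8, la$chr[i], size = 9))
  }
  for (i in seq_along(lb$chr)) {
    y <- margin + lb$off[i] * sc_b
    doc <- svg_add(doc, svg_line(margin, y, size - margin, y, stroke = "#cccccc", sw = 0.5),
                   svg_text(margin - 8, y + lb$len[i] * sc_b / 2, lb$chr[i],
                            size = 9, anchor = "end"))
  }
  doc <- svg_add(doc,
                 svg_text(size / 2, size - 15,
                          sprintf("%s (Mb)", ann_a$genome_id), size = 11),
                 svg_text(15, size / 2, sprintf("%s (Mb)", ann_b$genome_id), size = 11))
  if (nrow(homology)) {
    anc <- anchor_table(homology, ann_a, ann_b, strict = FALSE)
    ga <- ann_a$genes; gb <- ann_b$genes
    pa <- (ga$start + ga$end) / 2; names(pa) <- ga$gene_id
    pb <- (gb$start + gb$end) / 2; names(pb) <- gb$gene_id
    offa <- setNames(la$off, la$chr); offb <- setNames(lb$off, lb$chr)
    ## hit rank per query gene: best red, second blue, rest grey
    anc <- anc[order(anc$gene_a, -anc$score, anc$gene_b), , drop = FALSE]
    rank <- stats::ave(seq_len(nrow(anc)), anc$gene_a, FUN = seq_along)
    col <- ifelse(rank == 1, "red", ifelse(rank == 2, "blue", "grey"))
    x <- margin + (offa[anc$chr_a] + pa[anc$gene_a]) * sc_a
    y <- margin + (offb[anc$chr_b] + pb[anc$gene_b]) * sc_b
    for (i in order(anc$chr_a, anc$order_a, anc$chr_b, anc$order_b)) {
      doc <- svg_add(doc, svg_circle(x[i], y[i], 1.2, fill = col[i]))
    }
  }
  if (!is.null(blocks) && nrow(blocks$blocks)) {
    ks <- blocks$blocks$ks_median
    kcol <- ifelse(is.na(ks), "#888888",
                   ifelse(ks < 0.5, "#e6a700", ifelse(ks < 1, "#d55e00", "#0072b2")))
    ga <- ann_a$genes; gb <- ann_b$genes
    offa <- setNames(la$off, la$chr); offb <- setNames(lb$off, lb$chr)
    pos_a <- function(chr, ord) {
      gsel <- ga[ga$chr == chr, ]
      (gsel$start[match(ord, gsel$order_index)] + gsel$end[match(ord, gsel$order_index)]) / 2
    }
    pos_b <- function(chr, ord) {
      gsel <- gb[gb$chr == chr, ]
      (gsel$start[match(ord, gsel$order_index)] + gsel$end[match(ord, gsel$order_index)]) / 2
    }
    for (i in seq_len(nrow(blocks$blocks))) {
      b <- blocks$blocks[i, ]
      x1 <- margin + (offa[b$chr_a] + pos_a(b$chr_a, b$start_a)) * sc_a
      x2 <- margin + (offa[b$chr_a] + pos_a(b$chr_a, b$end_a)) * sc_a
      y1 <- margin + (offb[b$chr_b] + pos_b(b$chr_b, b$start_b)) * sc_b
      y2 <- margin + (offb[b$chr_b] + pos_b(b$chr_b, b$end_b)) * sc_b
      doc <- svg_add(doc, svg_rect(min(x1, x2), min(y1, y2),
                                   abs(x2 - x1), abs(y2 - y1),
                                   fill = "none", stroke = kcol[i], sw = 0.8))
    }
  }
  svg_write(doc, out_path)
  invisible(out_path)
}
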