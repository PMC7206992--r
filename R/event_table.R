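# Reference-anchored, event-structured colinear gene tables across genomes,
# and the retention / loss-epoch statistics derived from them.

#' Define an event-table schema
#'
#' The reference genome contributes `m_ref` paralogous column sets (3 for a
#' hexaploid reference); every other genome g contributes `m_g` orthologous
#' columns per reference column set, where `m_g` is the product of the
#' multiplicities of the polyploidy events g experienced since its split
#' from the reference. Total column count is `m_ref * (1 + sum(m_g))`.
#'
#' @param reference reference genome id.
#' @param ref_events named integer vector: reference-lineage events (name ->
#'   multiplicity), oldest first; empty for an unduplicated reference.
#' @param targets named list; per target genome a named integer vector of
#'   its post-split events (name -> multiplicity), oldest first; an empty
#'   vector for a single-copy outgroup.
#' @return a `table_schema`.
#' @export
table_schema <- function(reference, ref_events = integer(0), targets = list()) {
  m_ref <- as.integer(prod(ref_events))
  m_g <- vapply(targets, function(v) as.integer(prod(v)), 1L)
  structure(list(reference = reference, ref_events = ref_events, targets = targets,
                 m_ref = max(m_ref, 1L), m_g = m_g,
                 n_columns = max(m_ref, 1L) * (1L + sum(m_g))),
            class = "table_schema")
}

# leaf column paths for an event vector, e.g. c(`A-beta` = 2, `A-alpha` = 2)
# -> "A-beta:1/A-alpha:1", ... ; order groups siblings of the youngest event
# adjacently, matching the loss-epoch hierarchy.
column_paths <- function(events) {
  if (!length(events)) return("ortholog")
  grids <- lapply(events, seq_len)
  g <- do.call(expand.grid, rev(grids))[, rev(seq_along(events)), drop = FALSE]
  names(g) <- names(events)
  apply(g, 1, function(r) paste(sprintf("%s:%s", names(events), r), collapse = "/"))
}

## greedy interval scheduling of blocks into columns.
## spans: data.frame(block_id, chr, start, end, size); allowed: optional list
## of permitted columns per block. Returns block -> column or raises overflow.
schedule_blocks <- function(spans, n_cols, allowed = NULL, strict = TRUE) {
  assignment <- rep(NA_integer_, nrow(spans))
  ord <- order(-spans$size, spans$chr, spans$start)
  occupied <- vector("list", n_cols)  # per column: list of (chr,start,end)
  for (i in ord) {
    cand <- if (is.null(allowed)) seq_len(n_cols) else allowed[[i]]
    placed <- FALSE
    for (col in cand) {
      occ <- occupied[[col]]
      clash <- FALSE
      if (!is.null(occ)) {
        same <- occ[occ$chr == spans$chr[i], , drop = FALSE]
        clash <- any(same$start <= spans$end[i] & same$end >= spans$start[i])
      }
      if (!clash) {
        occupied[[col]] <- rbind(occ, data.frame(chr = spans$chr[i],
                                                 start = spans$start[i],
                                                 end = spans$end[i]))
        assignment[i] <- col
        placed <- TRUE
        break
      }
    }
    if (!placed && strict && is.null(allowed)) {
      stop_wgd("overflow",
               "more than %d overlapping block layers at %s:%d-%d (mis-grouped events?)",
               n_cols, spans$chr[i], spans$start[i], spans$end[i])
    }
  }
  assignment
}

#' Build the reference-anchored colinear gene table
#'
#' Rows are reference genes in genome order. The reference's own paralogous
#' columns are filled from reference-self blocks; for each other genome the
#' (orthologous) blocks are partitioned into `m_g` mutually non-overlapping
#' column layers — via supplied subgenome `groups` where available,
#' otherwise greedy interval scheduling by descending block size. Covered
#' reference genes take their colinear partner's id; uncovered cells stay
#' missing (serialized as '.').
#'
#' @param schema a [table_schema()].
#' @param ref_annotation the reference [genome_annotation()] (row backbone).
#' @param blocks named list of `colinear_set`s: `self` (reference self
#'   comparison, needed when `m_ref > 1`) plus one entry per target genome
#'   (reference as genome a). Supply orthologous blocks only (see
#'   [block_event_labels()] for routing).
#' @param groups optional named list: per genome an integer vector (one per
#'   block, `NA` = unconstrained) giving its column index, e.g. from
#'   [truth_block_groups()].
#' @return an `event_table`: list(schema, ref_genes, ref_paralogs, cells,
#'   coverage, columns).
#' @export
build_event_table <- function(schema, ref_annotation, blocks, groups = NULL) {
  g <- ref_annotation$genes
  g <- g[order(g$chr, g$order_index), , drop = FALSE]
  rownames(g) <- NULL
  nrows <- nrow(g)
  row_of <- setNames(seq_len(nrows), g$gene_id)
  key_of <- setNames(seq_len(nrows), paste(g$chr, g$order_index))

  fill_panel <- function(proj, n_cols, grp = NULL) {
    ## proj: data.frame(block_id, chr, start, end, size) + anchors list
    cells <- matrix(NA_character_, nrows, n_cols)
    cover <- matrix(FALSE, nrows, n_cols)
    if (!nrow(proj$spans)) return(list(cells = cells, cover = cover))
    allowed <- NULL
    if (!is.null(grp)) {
      allowed <- lapply(seq_len(nrow(proj$spans)), function(i) {
        ci <- grp[[as.character(proj$spans$block_id[i])]]
        if (is.na(ci)) seq_len(n_cols) else ci
      })
    }
    assignment <- schedule_blocks(proj$spans, n_cols, allowed,
                                  strict = is.null(grp))
    for (i in order(-proj$spans$size)) {
      col <- assignment[i]
      if (is.na(col)) next
      sp <- proj$spans[i, ]
      rows_cov <- key_of[paste(sp$chr, sp$start:sp$end)]
      rows_cov <- rows_cov[!is.na(rows_cov)]
      cover[rows_cov, col] <- TRUE
      anc <- proj$anchors[[as.character(sp$block_id)]]
      ri <- row_of[anc$ref_gene]
      ok <- !is.na(ri) & is.na(cells[cbind(ri, col)])
      cells[cbind(ri[ok], col)] <- anc$partner[ok]
    }
    list(cells = cells, cover = cover)
  }

  proj_target <- function(cs) {
    bl <- cs$blocks
    spans <- data.frame(block_id = bl$block_id, chr = bl$chr_a,
                        start = bl$start_a, end = bl$end_a, size = bl$n_anchors,
                        stringsAsFactors = FALSE)
    anchors <- lapply(split(cs$anchors, cs$anchors$block_id), function(a)
      data.frame(ref_gene = a$gene_a, partner = a$gene_b, stringsAsFactors = FALSE))
    list(spans = spans, anchors = anchors)
  }

  cells <- list(); coverage <- list(); columns <- list()

  ## reference self-paralog columns
  ref_paralogs <- NULL; ref_par_cover <- NULL
  if (schema$m_ref > 1) {
    if (is.null(blocks$self)) config_error("schema needs reference-self blocks ('self')")
    cs <- blocks$self
    bl <- cs$blocks
    ## both projections of every self block (a-side rows get b partners and
    ## vice versa)
    spans <- rbind(
      data.frame(block_id = paste0(bl$block_id, "F"), chr = bl$chr_a,
                 start = bl$start_a, end = bl$end_a, size = bl$n_anchors),
      data.frame(block_id = paste0(bl$block_id, "R"), chr = bl$chr_b,
                 start = bl$start_b, end = bl$end_b, size = bl$n_anchors))
    anchors <- list()
    for (b in split(cs$anchors, cs$anchors$block_id)) {
      id <- as.character(b$block_id[1])
      anchors[[paste0(id, "F")]] <- data.frame(ref_gene = b$gene_a, partner = b$gene_b)
      anchors[[paste0(id, "R")]] <- data.frame(ref_gene = b$gene_b, partner = b$gene_a)
    }
    pan <- fill_panel(list(spans = spans, anchors = anchors), schema$m_ref - 1L,
                      grp = NULL)
    ref_paralogs <- pan$cells; ref_par_cover <- pan$cover
  }

  for (tg in names(schema$targets)) {
    if (is.null(blocks[[tg]])) config_error("no blocks supplied for genome '%s'", tg)
    grp <- if (!is.null(groups)) groups[[tg]] else NULL
    if (!is.null(grp)) grp <- setNames(grp, blocks[[tg]]$blocks$block_id)
    pan <- fill_panel(proj_target(blocks[[tg]]), schema$m_g[[tg]], grp = grp)
    cells[[tg]] <- pan$cells
    coverage[[tg]] <- pan$cover
    columns[[tg]] <- data.frame(genome = tg, column = seq_len(schema$m_g[[tg]]),
                                path = column_paths(schema$targets[[tg]]),
                                stringsAsFactors = FALSE)
  }

  structure(list(schema = schema, ref_genes = g,
                 ref_paralogs = ref_paralogs, ref_par_cover = ref_par_cover,
                 cells = cells, coverage = coverage,
                 columns = do.call(rbind, c(columns, list(make.row.names = FALSE)))),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d reference genes (%s), %d columns total\n",
              nrow(x$ref_genes), x$schema$reference, x$schema$n_columns))
  invisible(x)
}

#' Number of columns of the full composed table
#' @param et an `event_table`.
#' @return integer column count (`m_ref * (1 + sum(m_g))`).
#' @export
n_table_columns <- function(et) et$schema$n_columns

#' Compose the full multi-panel table
#'
#' One panel per reference paralogous column set: the first is anchored on
#' the reference gene itself, further panels on its paralogs (rows looked up
#' through the paralog's own row). Missing cells are `NA` (written as '.').
#'
#' @param et an `event_table`.
#' @return data.frame with `m_ref * (1 + sum(m_g))` columns.
#' @export
compose_full_table <- function(et) {
  g <- et$ref_genes
  row_of <- setNames(seq_len(nrow(g)), g$gene_id)
  base_target <- function(rows) {
    out <- lapply(names(et$cells), function(tg) {
      m <- et$cells[[tg]][rows, , drop = FALSE]
      colnames(m) <- paste0(tg, ".", et$columns$path[et$columns$genome == tg])
      m
    })
    do.call(cbind, out)
  }
  n <- nrow(g)
  panels <- list(data.frame(ref = g$gene_id, stringsAsFactors = FALSE))
  m_ref <- et$schema$m_ref
  if (m_ref > 1) {
    for (p in seq_len(m_ref - 1)) {
      panels[[1]][[paste0("ref_p", p + 1)]] <- et$ref_paralogs[, p]
    }
  }
  panels[[2]] <- as.data.frame(base_target(seq_len(n)), stringsAsFactors = FALSE)
  out <- cbind(panels[[1]], panels[[2]])
  if (m_ref > 1) {
    for (p in seq_len(m_ref - 1)) {
      prow <- row_of[et$ref_paralogs[, p]]
      pm <- base_target(ifelse(is.na(prow), 1L, prow))
      pm[is.na(prow), ] <- NA_character_
      colnames(pm) <- paste0("p", p + 1, ".", colnames(pm))
      out <- cbind(out, as.data.frame(pm, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Retention statistics per target genome
#'
#' For each reference gene, the retained copy count is the number of filled
#' cells among that genome's columns. Reports the depth histogram (counts
#' and percentages over all reference genes, summing to 100) and the
#' fraction of cells missing ("deleted from the orthologous regions").
#'
#' @param et an `event_table`.
#' @param genome target genome (default: all).
#' @return data.frame with one row per genome x depth, plus attribute-free
#'   summary columns `deleted_cell_fraction`.
#' @export
retention_stats <- function(et, genome = NULL) {
  gs <- if (is.null(genome)) names(et$cells) else genome
  out <- list()
  for (tg in gs) {
    m <- et$cells[[tg]]
    depth <- rowSums(!is.na(m))
    tab <- table(factor(depth, levels = 0:ncol(m)))
    out[[tg]] <- data.frame(genome = tg, depth = as.integer(names(tab)),
                            n = as.integer(tab),
                            pct = 100 * as.integer(tab) / length(depth),
                            deleted_cell_fraction = mean(is.na(m)),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-row retained depth for a genome
#' @param et an `event_table`.
#' @param genome target genome id.
#' @return integer vector (one per reference gene).
#' @export
retained_depth <- function(et, genome) as.integer(rowSums(!is.na(et$cells[[genome]])))

#' Classify gene-loss events into epochs by Dollo parsimony
#'
#' The genome's columns form a balanced hierarchy following its event list
#' (oldest event at the top). Each maximal all-missing subtree counts as one
#' loss event, assigned to the epoch of its root edge: the whole tree
#' missing means a loss after the reference split / oldest shared context
#' and before the first event; a missing subtree created by event `e_j`
#' (with some sibling present) means a loss between `e_j` and `e_{j+1}`, or
#' after the last event for single columns. Rows with no block coverage in
#' any column carry no evidence and are skipped. Both per-event and
#' per-missing-cell counts are reported.
#'
#' @param et an `event_table`.
#' @param genome target genome id.
#' @return list `per_row` (data.frame gene_id, epoch), `summary`
#'   (data.frame epoch, n_events, n_cells), `n_rows_used`.
#' @export
classify_loss_epochs <- function(et, genome) {
  events <- et$schema$targets[[genome]]
  if (is.null(events) || !length(events)) {
    config_error("genome '%s' has no event hierarchy in the schema", genome)
  }
  evn <- names(events)
  K <- length(events)
  epoch_names <- c(paste0("before_", evn[1]),
                   if (K > 1) paste0("between_", evn[-K], "_", evn[-1]),
                   paste0("after_", evn[K]))
  m <- et$cells[[genome]]
  cov <- et$coverage[[genome]]
  use <- rowSums(cov) > 0
  per_row <- list()
  counts <- setNames(numeric(K + 1), epoch_names)
  cellcounts <- setNames(numeric(K + 1), epoch_names)
  subtree_sizes <- rev(cumprod(rev(c(events, 1))))  # size at each level
  classify <- function(pres, level, cols) {
    ## returns list of epochs for maximal missing subtrees under this node
    if (!any(pres[cols])) return(list(level))
    if (level > K) return(list())
    mlt <- events[level]
    size <- length(cols) / mlt
    res <- list()
    for (k in seq_len(mlt)) {
      sub <- cols[((k - 1) * size + 1):(k * size)]
      res <- c(res, classify(pres, level + 1, sub))
    }
    res
  }
  for (r in which(use)) {
    pres <- !is.na(m[r, ])
    hits <- classify(pres, 1L, seq_len(ncol(m)))
    for (lv in hits) {
      ## a maximal missing subtree entered at `lv` was lost in epoch lv
      ## (epoch 1 = before first event, ..., K+1 = after last event)
      ep <- epoch_names[lv]
      counts[ep] <- counts[ep] + 1
      cellcounts[ep] <- cellcounts[ep] + subtree_sizes[lv]
      per_row[[length(per_row) + 1L]] <-
        data.frame(gene_id = et$ref_genes$gene_id[r], epoch = ep,
                   stringsAsFactors = FALSE)
    }
  }
  list(per_row = if (length(per_row)) do.call(rbind, per_row) else
         data.frame(gene_id = character(), epoch = character()),
       summary = data.frame(epoch = epoch_names, n_events = as.numeric(counts),
                            n_cells = as.numeric(cellcounts),
                            stringsAsFactors = FALSE),
       n_rows_used = sum(use))
}

#' Majority divergence-event label per block
#'
#' Routes blocks to events using per-pair labels (e.g. the simulator's true
#' divergence events, or labels derived from Ks grouping).
#'
#' @param blocks a `colinear_set`.
#' @param homology data.frame with `query`, `subject`, `event`.
#' @return character vector, one label per block.
#' @export
block_event_labels <- function(blocks, homology) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  evmap <- setNames(homology$event, key(homology$query, homology$subject))
  anc <- blocks$anchors
  ev <- evmap[key(anc$gene_a, anc$gene_b)]
  vapply(split(ev, anc$block_id), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_character_ else names(which.max(table(v)))
  }, "")[as.character(blocks$blocks$block_id)]
}

#' Column assignment of blocks from simulator ground truth
#'
#' Maps each block's majority target-gene subgenome path to the schema's
#' column index for that genome.
#'
#' @param dataset a `simulated_dataset`.
#' @param blocks `colinear_set` (reference vs target).
#' @param target target genome id.
#' @param schema a [table_schema()].
#' @return integer vector of column indices (NA where undetermined).
#' @export
truth_block_groups <- function(dataset, blocks, target, schema) {
  events <- schema$targets[[target]]
  if (!length(events)) return(rep(1L, nrow(blocks$blocks)))
  tagof <- setNames(dataset$truth$events$tag, dataset$truth$events$name)
  tags <- unname(tagof[names(events)])
  sub_of <- setNames(dataset$truth$genes$subgenome, dataset$truth$genes$gene_id)
  paths <- column_paths(events)
  ## expected tag-label per column path
  grids <- lapply(events, seq_len)
  gidx <- do.call(expand.grid, rev(grids))[, rev(seq_along(events)), drop = FALSE]
  labels <- apply(gidx, 1, function(r) paste0(tags, r, collapse = "."))
  anc <- blocks$anchors
  gene_label <- vapply(strsplit(sub_of[anc$gene_b], ".", fixed = TRUE), function(e) {
    parts <- vapply(tags, function(tg) {
      hit <- grep(paste0("^", tg, "[0-9]+$"), e, value = TRUE)
      if (length(hit)) hit[1] else NA_character_
    }, "")
    if (anyNA(parts)) NA_character_ else paste(parts, collapse = ".")
  }, "")
  maj <- vapply(split(gene_label, anc$block_id), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_character_ else names(which.max(table(v)))
  }, "")[as.character(blocks$blocks$block_id)]
  unname(match(maj, labels))
}

#' Render the multi-genome homology circle figure
#'
#' One concentric circle per composed-table column; filled cells are drawn
#' as radial ticks colour-coded by the source chromosome of the cell's gene.
#' Deterministic layout (byte-identical SVG for identical inputs).
#'
#' @param et an `event_table`.
#' @param annotations named list of [genome_annotation()] covering every
#'   genome appearing in the table.
#' @param out_path output `.svg` path.
#' @param size figure edge in pixels.
#' @return `out_path`, invisibly.
#' @export
render_homology_circles <- function(et, annotations, out_path, size = 900) {
  full <- compose_full_table(et)
  ncol_full <- ncol(full)
  nrows <- nrow(full)
  chr_of <- list()
  for (g in names(annotations)) {
    chr_of[[g]] <- setNames(annotations[[g]]$genes$chr, annotations[[g]]$genes$gene_id)
  }
  lookup_chr <- function(ids) {
    out <- rep(NA_character_, length(ids))
    for (g in names(chr_of)) {
      hit <- !is.na(ids) & ids %in% names(chr_of[[g]])
      out[hit] <- chr_of[[g]][ids[hit]]
    }
    out
  }
  palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00", "#a65628",
               "#f781bf", "#999999", "#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3")
  all_chr <- sort(unique(unlist(lapply(annotations, function(a) unique(a$genes$chr)))))
  chr_col <- setNames(rep(palette, length.out = length(all_chr)), all_chr)
  cx <- size / 2; cy <- size / 2
  r0 <- 60; r1 <- size / 2 - 20
  doc <- svg_new(size, size)
  theta <- 2 * pi * (seq_len(nrows) - 0.5) / max(nrows, 1)
  for (ci in seq_len(ncol_full)) {
    r <- r0 + (ci - 1) * (r1 - r0) / max(ncol_full - 1, 1)
    doc <- svg_add(doc, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#dddddd" stroke-width="0.5"/>',
      fmt_num(cx), fmt_num(cy), fmt_num(r)))
    vals <- as.character(full[[ci]])
    chrs <- lookup_chr(vals)
    hit <- which(!is.na(vals))
    tick <- (r1 - r0) / max(ncol_full - 1, 1) * 0.35
    for (i in hit) {
      col <- chr_col[chrs[i]]
      if (is.na(col)) col <- "#000000"
      doc <- svg_add(doc, svg_line(cx + (r - tick) * cos(theta[i]),
                                   cy + (r - tick) * sin(theta[i]),
                                   cx + (r + tick) * cos(theta[i]),
                                   cy + (r + tick) * sin(theta[i]),
                                   stroke = col, sw = 0.6))
    }
  }
  svg_write(doc, out_path)
  invisible(out_path)
}
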