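# Genome-history simulator: polyploidy events on a species tree, geometric
# segmental gene loss, lineage-specific rate variation, codon-level
# synonymous divergence and subgenome-biased expression. Emits the same
# objects the pipeline consumes plus a TruthRecord for parameter recovery.

#' Build a genome-history configuration
#'
#' The species tree is a nested list: a tip is `list(tip = "X", rate = r)`,
#' an internal node `list(age = a, rate = r, children = list(...))`; `rate`
#' is the substitution-rate multiplier of the edge above the node (relative
#' to the reference lineage). Events are placed on the edge above the node
#' whose extant descendant set equals `lineages`, carry a multiplicity (2 =
#' tetraploidy, 3 = hexaploidy), and open a loss epoch: `retain` is the
#' fraction of genes surviving to the end of the epoch (the next event on
#' the path, or the present), with deletion-run lengths drawn from
#' Geometric(`p_loss`) on support 1, 2, ...
#'
#' @param ancestor list(n_chromosomes, genes_per_chromosome).
#' @param root_age age (Mya) at which the simulation starts (stem above root).
#' @param tree nested species-tree list (see Details).
#' @param events list of event specs: `name`, `age`, `multiplicity`, `tag`
#'   (short label used in subgenome paths), `lineages`, `retain`, `p_loss`.
#' @param r_ref clock rate: synonymous substitutions per synonymous site per
#'   Mya along one branch of the reference-rate lineage (a pair diverged t
#'   Mya ago at rate 1 has expected Ks = 2 * r_ref * t).
#' @param sigma_event per-gene lognormal rate dispersion (sdlog); widens Ks
#'   peaks beyond estimator noise.
#' @param cds_length_range CDS length range in nt (multiples of 3).
#' @param ka_ks nonsynonymous/synonymous rate ratio for sequence evolution.
#' @param keep_one_copy never delete the last surviving copy of an ancestral
#'   gene in a genome.
#' @param homology_noise fraction of spurious homology pairs added.
#' @param expression expression-simulation parameters (see
#'   [simulate_expression()]).
#' @param seed master integer seed.
#' @return a validated `history_config`.
#' @export
history_config <- function(ancestor = list(n_chromosomes = 2, genes_per_chromosome = 300),
                           root_age, tree, events = list(),
                           r_ref = 0.005, sigma_event = 0.05,
                           cds_length_range = c(300, 900), ka_ks = 0.2,
                           keep_one_copy = TRUE, homology_noise = 0,
                           expression = NULL, seed = 1L) {
  cfg <- structure(list(ancestor = ancestor, root_age = root_age, tree = tree,
                        events = events, r_ref = r_ref, sigma_event = sigma_event,
                        cds_length_range = cds_length_range, ka_ks = ka_ks,
                        keep_one_copy = keep_one_copy, homology_noise = homology_noise,
                        expression = expression, seed = as.integer(seed)),
                   class = "history_config")
  validate_history_config(cfg)
}

node_tips <- function(node) {
  if (!is.null(node$tip)) return(node$tip)
  sort(unlist(lapply(node$children, node_tips)))
}

validate_history_config <- function(cfg) {
  if (cfg$root_age <= 0) config_error("root_age must be positive")
  check_node <- function(node, t_top) {
    if (is.null(node$rate)) node$rate <- 1
    if (node$rate <= 0) config_error("branch rate must be > 0")
    if (!is.null(node$tip)) return(invisible())
    if (node$age >= t_top) config_error("node ages must strictly decrease from root to tips")
    for (ch in node$children) check_node(ch, node$age)
  }
  check_node(cfg$tree, cfg$root_age)
  tags <- character(0)
  for (ev in cfg$events) {
    if (!ev$multiplicity %in% c(2, 3)) config_error("event '%s': multiplicity must be 2 or 3", ev$name)
    if (is.null(ev$retain)) ev$retain <- 1
    if (ev$retain <= 0 || ev$retain > 1) config_error("event '%s': retain must be in (0, 1]", ev$name)
    if (!is.null(ev$p_loss) && (ev$p_loss <= 0 || ev$p_loss > 1)) {
      config_error("event '%s': p_loss must be in (0, 1]", ev$name)
    }
    tags <- c(tags, ev$tag)
  }
  if (anyDuplicated(tags)) config_error("event tags must be unique")
  if (cfg$r_ref <= 0) config_error("r_ref must be positive")
  if (any(cfg$cds_length_range %% 3 != 0)) config_error("cds_length_range must be multiples of 3")
  cfg
}

#' Five-genome demonstration history
#'
#' An outgroup clade emulating a core-eudicot configuration: reference
#' outgroup `V` retaining only the ancient hexaploidy `ECH`; single-copy
#' outgroup `C`; lineage `L` with its own later triplication `ACH`; and two
#' lineages `D` and `X` sharing two nested tetraploidizations (`A-beta` then
#' `A-alpha`) before splitting from each other.
#'
#' @param genes_per_chromosome,n_chromosomes ancestral genome size.
#' @param seed master seed.
#' @param ... overrides passed to [history_config()].
#' @return a `history_config`.
#' @export
history_config_clade5 <- function(genes_per_chromosome = 300, n_chromosomes = 2,
                                  seed = 1L, ...) {
  tree <- list(age = 118, rate = 1, children = list(
    list(tip = "V", rate = 1),
    list(age = 110, rate = 1, children = list(
      list(tip = "C", rate = 0.95),
      list(age = 85, rate = 1, children = list(
        list(tip = "L", rate = 1.05),
        list(age = 26, rate = 1, children = list(
          list(tip = "D", rate = 1.15),
          list(tip = "X", rate = 0.9)))))))))
  events <- list(
    list(name = "ECH", age = 125, multiplicity = 3, tag = "E",
         lineages = c("C", "D", "L", "V", "X"), retain = 0.55, p_loss = 0.35),
    list(name = "ACH", age = 60, multiplicity = 3, tag = "h",
         lineages = "L", retain = 0.5, p_loss = 0.35),
    list(name = "A-beta", age = 58, multiplicity = 2, tag = "b",
         lineages = c("D", "X"), retain = 0.7, p_loss = 0.3),
    list(name = "A-alpha", age = 48, multiplicity = 2, tag = "a",
         lineages = c("D", "X"), retain = 0.65, p_loss = 0.3))
  history_config(ancestor = list(n_chromosomes = n_chromosomes,
                                 genes_per_chromosome = genes_per_chromosome),
                 root_age = 130, tree = tree, events = events, seed = seed, ...)
}

## ---- gene-order simulation -------------------------------------------------

new_genome <- function(cfg) {
  lapply(seq_len(cfg$ancestor$n_chromosomes), function(i) {
    n <- cfg$ancestor$genes_per_chromosome
    list(name = sprintf("c%d", i), subpath = character(0),
         anc = (i - 1L) * n + seq_len(n))
  })
}

genome_anc_counts <- function(genome) {
  tabulate(unlist(lapply(genome, `[[`, "anc")))
}

apply_event_dup <- function(genome, ev) {
  out <- list()
  for (chr in genome) {
    for (k in seq_len(ev$multiplicity)) {
      nc <- chr
      nc$name <- paste0(chr$name, ".", ev$tag, k)
      nc$subpath <- c(chr$subpath, paste0(ev$tag, k))
      out[[length(out) + 1L]] <- nc
    }
  }
  out
}

apply_loss <- function(genome, ev, keep_one_copy, run_log, epoch) {
  n_now <- sum(lengths(lapply(genome, `[[`, "anc")))
  target <- round(ev$retain * n_now)
  counts <- genome_anc_counts(genome)
  n_anc_present <- sum(counts > 0)
  if (keep_one_copy && target < n_anc_present) {
    config_error("epoch '%s': retain=%.2f needs %d genes but %d protected last copies remain",
                 epoch, ev$retain, target, n_anc_present)
  }
  p <- if (is.null(ev$p_loss)) 0.3 else ev$p_loss
  lens <- vapply(genome, function(ch) length(ch$anc), 1L)
  remaining <- n_now
  guard <- 0L
  while (remaining > target && guard < 50L * n_now) {
    guard <- guard + 1L
    ci <- sample.int(length(genome), 1L, prob = pmax(lens, 1e-9))
    len <- lens[ci]
    if (len == 0L) next
    start <- sample.int(len, 1L)
    drawn <- rgeom(1L, p) + 1L
    run <- min(drawn, len - start + 1L, remaining - target)
    idx <- start:(start + run - 1L)
    anc_idx <- genome[[ci]]$anc[idx]
    if (keep_one_copy) {
      deletable <- counts[anc_idx] > 1L
      idx <- idx[deletable]; anc_idx <- anc_idx[deletable]
    }
    if (!length(idx)) next
    counts[anc_idx] <- counts[anc_idx] - 1L
    genome[[ci]]$anc <- genome[[ci]]$anc[-idx]
    lens[ci] <- lens[ci] - length(idx)
    remaining <- remaining - length(idx)
    run_log$runs[[length(run_log$runs) + 1L]] <-
      data.frame(epoch = epoch, drawn = drawn, deleted = length(idx))
  }
  if (remaining > target) {
    config_error("epoch '%s': could not reach retained fraction %.2f (protected copies)",
                 epoch, ev$retain)
  }
  genome
}

edge_events <- function(cfg, tips, t_top, t_bot) {
  evs <- Filter(function(ev) identical(sort(ev$lineages), tips) &&
                  ev$age <= t_top && ev$age > t_bot, cfg$events)
  evs[order(-vapply(evs, `[[`, 1, "age"))]
}

#' Simulate gene orders, homology and ground truth for a genome history
#'
#' Walks the species tree from the root: each event copies every chromosome
#' multiplicity-fold (copies tagged into subgenome paths); the loss epoch a
#' duplication opens is realized at the epoch end (the next event on the
#' path, or the tip) by drawing deletion start positions uniformly and run
#' lengths from Geometric(p_loss) until the epoch's retained fraction is
#' reached. Deleted segments collapse (neighbours become adjacent). Homology
#' pairs connect all extant gene pairs sharing an ancestral gene, labelled
#' with the true divergence event.
#'
#' @param cfg a `history_config`.
#' @return a `simulated_dataset`: list with `annotations` (named list of
#'   [genome_annotation()]), `homology` (a `homology_table` with an extra
#'   `event` column), `truth` (TruthRecord), `config`.
#' @export
simulate_gene_orders <- function(cfg) {
  cfg <- validate_history_config(cfg)
  set.seed(derive_seed(cfg$seed, "gene_orders"))
  run_log <- new.env(parent = emptyenv()); run_log$runs <- list()
  tip_genomes <- list()
  tip_paths <- list()    # per tip: data.frame(t_top, t_bot, rate) root->tip
  tip_events <- list()   # per tip: events experienced (ordered old -> young)

  walk <- function(node, genome, pending, t_top, path, evs) {
    tips <- node_tips(node)
    t_bot <- if (!is.null(node$tip)) 0 else node$age
    rate <- if (is.null(node$rate)) 1 else node$rate
    for (ev in edge_events(cfg, tips, t_top, t_bot)) {
      if (!is.null(pending)) {
        genome <- apply_loss(genome, pending, cfg$keep_one_copy, run_log,
                             paste0("after_", pending$name))
        pending <- NULL
      }
      genome <- apply_event_dup(genome, ev)
      evs <- c(evs, list(ev))
      if (ev$retain < 1) pending <- ev
    }
    path <- rbind(path, data.frame(branch = paste(tips, collapse = ","),
                                   t_top = t_top, t_bot = t_bot, rate = rate))
    if (!is.null(node$tip)) {
      if (!is.null(pending)) {
        genome <- apply_loss(genome, pending, cfg$keep_one_copy, run_log,
                             paste0("after_", pending$name))
      }
      tip_genomes[[node$tip]] <<- genome
      tip_paths[[node$tip]] <<- path
      tip_events[[node$tip]] <<- evs
    } else {
      for (ch in node$children) walk(ch, genome, pending, t_bot, path, evs)
    }
  }
  walk(cfg$tree, new_genome(cfg), NULL, cfg$root_age,
       data.frame(branch = character(), t_top = numeric(), t_bot = numeric(),
                  rate = numeric()), list())

  ## finalize annotations + truth gene table
  annotations <- list(); truth_genes <- list()
  for (g in names(tip_genomes)) {
    rows <- list()
    for (chr in tip_genomes[[g]]) {
      n <- length(chr$anc)
      if (!n) next
      sub <- if (length(chr$subpath)) paste(chr$subpath, collapse = ".") else "-"
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s:a%05d:%s", g, chr$anc, sub),
        chr = chr$name, anc = chr$anc, subgenome = sub,
        pos = seq_len(n), stringsAsFactors = FALSE)
    }
    tg <- do.call(rbind, rows)
    ann <- genome_annotation(g, data.frame(
      gene_id = tg$gene_id, chr = tg$chr,
      start = as.integer((tg$pos - 1) * 1500 + 1),
      end = as.integer((tg$pos - 1) * 1500 + 1000),
      strand = rep_len(c("+", "-"), nrow(tg)), stringsAsFactors = FALSE))
    annotations[[g]] <- ann
    tg$genome <- g
    truth_genes[[g]] <- tg[, c("genome", "gene_id", "chr", "anc", "subgenome")]
  }
  truth_genes <- do.call(rbind, truth_genes)
  rownames(truth_genes) <- NULL

  ## homology from common descent, labelled with the divergence event
  tag2event <- setNames(vapply(cfg$events, `[[`, "", "name"),
                        vapply(cfg$events, `[[`, "", "tag"))
  split_sub <- strsplit(ifelse(truth_genes$subgenome == "-", "", truth_genes$subgenome),
                        ".", fixed = TRUE)
  hom <- divergence_pairs(truth_genes, split_sub, tag2event)
  if (cfg$homology_noise > 0 && nrow(hom)) {
    set.seed(derive_seed(cfg$seed, "homology_noise"))
    n_noise <- round(cfg$homology_noise * nrow(hom))
    ids <- truth_genes$gene_id
    noise <- data.frame(query = sample(ids, n_noise, replace = TRUE),
                        subject = sample(ids, n_noise, replace = TRUE),
                        pident = 40, evalue = 1e-5, score = 60,
                        event = "noise", stringsAsFactors = FALSE)
    noise <- noise[noise$query != noise$subject, , drop = FALSE]
    hom <- rbind(hom, noise)
  }
  hom_tbl <- homology_table(hom)

  runs <- if (length(run_log$runs)) do.call(rbind, run_log$runs) else
    data.frame(epoch = character(), drawn = integer(), deleted = integer())

  truth <- structure(list(
    genes = truth_genes,
    events = do.call(rbind, lapply(cfg$events, function(e)
      data.frame(name = e$name, age = e$age, multiplicity = e$multiplicity,
                 tag = e$tag, lineages = paste(sort(e$lineages), collapse = ","),
                 retain = if (is.null(e$retain)) 1 else e$retain,
                 p_loss = if (is.null(e$p_loss)) NA_real_ else e$p_loss,
                 stringsAsFactors = FALSE))),
    deletion_runs = runs,
    tip_paths = tip_paths,
    tip_events = lapply(tip_events, function(evs) vapply(evs, `[[`, "", "name")),
    true_ks = true_ks_table(cfg, tip_paths, tip_events),
    expression = NULL), class = "truth_record")

  structure(list(config = cfg, annotations = annotations, homology = hom_tbl,
                 truth = truth, cds = NULL, expression = NULL),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d genomes (%s), %d homology pairs\n",
              length(x$annotations), paste(names(x$annotations), collapse = ", "),
              nrow(x$homology)))
  invisible(x)
}

# all extant pairs sharing an ancestral gene + divergence-event label
divergence_pairs <- function(genes, split_sub, tag2event) {
  ord <- order(genes$anc)
  genes <- genes[ord, ]; split_sub <- split_sub[ord]
  grp <- split(seq_len(nrow(genes)), genes$anc)
  out <- vector("list", length(grp))
  for (k in seq_along(grp)) {
    idx <- grp[[k]]
    n <- length(idx)
    if (n < 2) next
    cmb <- utils::combn(n, 2)
    q <- idx[cmb[1, ]]; s <- idx[cmb[2, ]]
    ev <- mapply(function(i, j) {
      pa <- split_sub[[i]]; pb <- split_sub[[j]]
      m <- min(length(pa), length(pb))
      if (m > 0) {
        for (t in seq_len(m)) {
          ta <- sub("[0-9]+$", "", pa[t]); tb <- sub("[0-9]+$", "", pb[t])
          if (ta != tb) break
          if (pa[t] != pb[t]) return(unname(tag2event[ta]))
        }
      }
      "speciation"
    }, q, s)
    out[[k]] <- data.frame(query = genes$gene_id[q], subject = genes$gene_id[s],
                           pident = 90, evalue = 1e-80, score = 200, event = ev,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(data.frame(query = character(), subject = character(),
                                      pident = numeric(), evalue = numeric(),
                                      score = numeric(), event = character()))
  do.call(rbind, out)
}

# expected Ks peaks implied by the configuration (TruthRecord)
true_ks_table <- function(cfg, tip_paths, tip_events) {
  seg_dist <- function(path, from_age) {
    # branch synonymous distance from `from_age` down to the tip
    sum(pmax(pmin(path$t_top, from_age) - path$t_bot, 0) * path$rate) * cfg$r_ref
  }
  rows <- list()
  for (g in names(tip_paths)) {
    for (ev in cfg$events) {
      if (!ev$name %in% vapply(tip_events[[g]], `[[`, "", "name")) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = "within", genome_a = g, genome_b = g, event = ev$name,
        ks = 2 * seg_dist(tip_paths[[g]], ev$age), stringsAsFactors = FALSE)
    }
  }
  tips <- names(tip_paths)
  if (length(tips) > 1) {
    for (i in seq_along(tips)) for (j in seq_along(tips)) {
      if (i >= j) next
      pa <- tip_paths[[tips[i]]]; pb <- tip_paths[[tips[j]]]
      ## split age = bottom of the deepest branch shared by both paths
      shared <- intersect(pa$branch, pb$branch)
      split_age <- if (length(shared)) min(pa$t_bot[pa$branch %in% shared]) else
        max(pa$t_top)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "cross", genome_a = tips[i], genome_b = tips[j], event = "speciation",
        ks = seg_dist(pa, split_age) + seg_dist(pb, split_age),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
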