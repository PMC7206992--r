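# Codon-level sequence realization for simulated histories.
#
# Root CDS are drawn from codon families whose third position is fourfold
# degenerate and whose first/second positions admit no synonymous change
# (Val GTN, Ser TCN, Pro CCN, Thr ACN, Ala GCN, Gly GGN). Third positions
# then evolve as an exact Jukes-Cantor chain, so branch synonymous distance
# is additive along the tree and the Nei-Gojobori estimator is consistent:
# a pair diverged by total distance d has E[ps] = 3/4 (1 - exp(-4d/3)) and
# the Jukes-Cantor inversion recovers d. Nonsynonymous changes move between
# the six families (single-nucleotide steps that stay inside the set) at a
# configured Ka/Ks ratio; stop codons are unreachable.

FAM_PREFIX <- c("GT", "TC", "CC", "AC", "GC", "GG")
FAM_MOVES <- list(5L, c(3L, 4L, 5L), c(2L, 4L, 5L), c(2L, 3L, 5L),
                  c(2L, 3L, 4L, 1L, 6L), 5L)

random_root_seq <- function(n_codons) {
  list(fam = sample.int(6L, n_codons, replace = TRUE),
       third = sample.int(4L, n_codons, replace = TRUE))
}

evolve_seq <- function(seq, d, ka_ks) {
  if (d <= 0) return(seq)
  L <- length(seq$fam)
  ## synonymous: exact JC transition at the third position
  p_diff <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- runif(L) < p_diff
  nhit <- sum(hit)
  if (nhit) {
    seq$third[hit] <- ((seq$third[hit] - 1L + sample.int(3L, nhit, replace = TRUE)) %% 4L) + 1L
  }
  ## nonsynonymous: Poisson family moves (2 nonsynonymous sites per codon)
  nev <- rpois(L, 2 * ka_ks * d)
  for (i in which(nev > 0L)) {
    f <- seq$fam[i]
    for (k in seq_len(nev[i])) {
      opts <- FAM_MOVES[[f]]
      f <- opts[sample.int(length(opts), 1L)]
    }
    seq$fam[i] <- f
  }
  seq
}

seq_to_cds <- function(seq) {
  paste0(paste0(FAM_PREFIX[seq$fam], c("A", "C", "G", "T")[seq$third]), collapse = "")
}

#' Realize coding sequences for a simulated dataset
#'
#' Replays the gene-order history at the sequence level: every ancestral gene
#' receives a random in-frame CDS; along each branch, synonymous divergence
#' accrues at `r_ref * rate` per Mya (so two copies diverged t Mya apart have
#' expected pairwise Ks equal to the rate-weighted path length), and
#' nonsynonymous changes at `ka_ks` times that rate. Per-gene lognormal rate
#' factors (sdlog `sigma_event`) widen event peaks.
#'
#' @param dataset a `simulated_dataset` from [simulate_gene_orders()].
#' @return the dataset with `cds` filled in (named list, one `DNAStringSet`
#'   per genome).
#' @export
realize_sequences <- function(dataset) {
  cfg <- dataset$config
  genes <- dataset$truth$genes
  set.seed(derive_seed(cfg$seed, "root_seqs"))
  anc_ids <- sort(unique(genes$anc))
  lens <- sample(seq(cfg$cds_length_range[1] / 3, cfg$cds_length_range[2] / 3),
                 length(anc_ids), replace = TRUE)
  roots <- lapply(lens, random_root_seq)
  names(roots) <- as.character(anc_ids)
  set.seed(derive_seed(cfg$seed, "gene_rates"))
  gf <- rlnorm(length(anc_ids), meanlog = -cfg$sigma_event^2 / 2, sdlog = cfg$sigma_event)
  names(gf) <- as.character(anc_ids)

  ## per tip: needed (anc|subpath-prefix) classes
  subsplit <- strsplit(ifelse(genes$subgenome == "-", "", genes$subgenome), ".", fixed = TRUE)
  tip_prefix <- list()
  for (g in unique(genes$genome)) {
    sel <- which(genes$genome == g)
    pref <- unlist(lapply(sel, function(i) {
      sp <- subsplit[[i]]
      ps <- vapply(0:length(sp), function(k) paste(sp[seq_len(k)], collapse = "."), "")
      paste0(genes$anc[i], "|", ps)
    }))
    tip_prefix[[g]] <- unique(pref)
  }

  set.seed(derive_seed(cfg$seed, "sequences"))
  out_cds <- list()

  walk <- function(node, seqs, t_top) {
    tips <- node_tips(node)
    needed <- unique(unlist(tip_prefix[tips]))
    t_bot <- if (!is.null(node$tip)) 0 else node$age
    rate <- if (is.null(node$rate)) 1 else node$rate
    t_cur <- t_top
    for (ev in edge_events(cfg, tips, t_top, t_bot)) {
      dt <- t_cur - ev$age
      if (dt > 0) seqs <- evolve_all(seqs, cfg$r_ref * rate * dt, cfg$ka_ks, gf)
      t_cur <- ev$age
      new_seqs <- list()
      for (key in names(seqs)) {
        for (k in seq_len(ev$multiplicity)) {
          nk <- if (endsWith(key, "|")) paste0(key, ev$tag, k)
                else paste0(key, ".", ev$tag, k)
          if (nk %in% needed) new_seqs[[nk]] <- seqs[[key]]
        }
      }
      seqs <- new_seqs
    }
    if (t_cur - t_bot > 0) seqs <- evolve_all(seqs, cfg$r_ref * rate * (t_cur - t_bot),
                                              cfg$ka_ks, gf)
    if (!is.null(node$tip)) {
      g <- node$tip
      sel <- which(genes$genome == g)
      keys <- paste0(genes$anc[sel], "|", ifelse(genes$subgenome[sel] == "-", "",
                                                 genes$subgenome[sel]))
      cds <- vapply(seqs[keys], seq_to_cds, "")
      names(cds) <- genes$gene_id[sel]
      out_cds[[g]] <<- Biostrings::DNAStringSet(cds)
    } else {
      for (ch in node$children) {
        child_needed <- unique(unlist(tip_prefix[node_tips(ch)]))
        walk(ch, seqs[names(seqs) %in% child_needed], t_bot)
      }
    }
  }

  root_seqs <- list()
  for (a in anc_ids) root_seqs[[paste0(a, "|")]] <- roots[[as.character(a)]]
  walk(cfg$tree, root_seqs, cfg$root_age)
  dataset$cds <- out_cds
  dataset
}

evolve_all <- function(seqs, d, ka_ks, gene_factors) {
  for (key in names(seqs)) {
    anc <- sub("\\|.*$", "", key)
    seqs[[key]] <- evolve_seq(seqs[[key]], d * gene_factors[[anc]], ka_ks)
  }
  seqs
}

#' Simulate coding-sequence pairs at a target Ks
#'
#' Stand-alone helper (no genome history): generates `n` independent pairs
#' whose expected pairwise synonymous divergence is `ks`.
#'
#' @param n number of pairs.
#' @param ks target pairwise Ks.
#' @param n_codons codons per sequence.
#' @param ka_ks nonsynonymous/synonymous ratio.
#' @param seed integer seed.
#' @return data.frame with columns `cds_a`, `cds_b`.
#' @export
simulate_cds_pairs <- function(n, ks, n_codons = 500L, ka_ks = 0.2, seed = 1L) {
  set.seed(derive_seed(seed, paste0("cds_pairs_", ks)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    root <- random_root_seq(n_codons)
    a <- evolve_seq(root, ks / 2, ka_ks)
    b <- evolve_seq(root, ks / 2, ka_ks)
    out[[i]] <- data.frame(cds_a = seq_to_cds(a), cds_b = seq_to_cds(b),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate replicate expression with planted subgenome dominance
#'
#' Base expression per ancestral gene is lognormal; copies on the designated
#' dominant subgenome are multiplied by `delta`; genes whose duplicate
#' partner (for `pair_event`) was lost are multiplied by `one_copy_factor`;
#' per-condition effects are shared between copies and replicate noise is
#' multiplicative lognormal.
#'
#' @param dataset a `simulated_dataset`.
#' @param target genome to simulate expression for.
#' @param conditions condition (replicate-group) labels.
#' @param replicates replicates per condition.
#' @param mu_log,sd_log lognormal parameters of base FPKM.
#' @param delta dominance factor (> 0) applied to the dominant subgenome.
#' @param dominant list(event, copy): copies whose subgenome path carries
#'   copy index `copy` for `event` are dominant. Default: copy 1 of the
#'   youngest event on the target's path.
#' @param pair_event event defining duplicate sibling pairs (default:
#'   youngest event on the target's path).
#' @param one_copy_factor factor applied to genes whose sibling was lost.
#' @param cond_sd_log per-condition lognormal effect (shared by copies).
#' @param noise_sd_log replicate lognormal noise.
#' @param zero_genes gene ids forced to zero in all samples.
#' @return the dataset with `expression` (an `expression_matrix`) filled in
#'   and dominance truth recorded in `truth$expression`.
#' @export
simulate_expression <- function(dataset, target = NULL,
                                conditions = c("leaf", "root"), replicates = 3L,
                                mu_log = 2, sd_log = 1, delta = 1,
                                dominant = NULL, pair_event = NULL,
                                one_copy_factor = 1, cond_sd_log = 0.3,
                                noise_sd_log = 0.2, zero_genes = NULL) {
  cfg <- dataset$config
  ex <- cfg$expression
  passed <- names(as.list(match.call())[-1])
  if (!is.null(ex)) {
    for (nm in setdiff(names(ex), passed)) assign(nm, ex[[nm]])
  }
  if (is.null(target)) config_error("expression target genome not specified")
  if (delta <= 0) config_error("dominance factor delta must be > 0")
  genes <- dataset$truth$genes
  genes <- genes[genes$genome == target, , drop = FALSE]
  if (!nrow(genes)) config_error("no genes for target genome '%s'", target)
  evnames <- dataset$truth$tip_events[[target]]
  if (is.null(pair_event)) pair_event <- if (length(evnames)) evnames[length(evnames)] else NA
  if (is.null(dominant)) dominant <- list(event = pair_event, copy = 1L)
  tagof <- setNames(dataset$truth$events$tag, dataset$truth$events$name)

  set.seed(derive_seed(cfg$seed, "expression"))
  anc_ids <- sort(unique(genes$anc))
  base <- rlnorm(length(anc_ids), mu_log, sd_log)
  names(base) <- as.character(anc_ids)
  cond_eff <- matrix(rlnorm(length(anc_ids) * length(conditions), 0, cond_sd_log),
                     nrow = length(anc_ids),
                     dimnames = list(as.character(anc_ids), conditions))

  sub_elems <- strsplit(ifelse(genes$subgenome == "-", "", genes$subgenome),
                        ".", fixed = TRUE)
  elem_for <- function(tag) vapply(sub_elems, function(e) {
    hit <- grep(paste0("^", tag, "[0-9]+$"), e, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }, "")
  is_dom <- if (!is.na(dominant$event) && dominant$event %in% names(tagof)) {
    elem_for(tagof[[dominant$event]]) == paste0(tagof[[dominant$event]], dominant$copy)
  } else rep(FALSE, nrow(genes))
  is_dom[is.na(is_dom)] <- FALSE

  ## duplicate sibling groups for pair_event: subgenome path minus that element
  one_copy <- rep(FALSE, nrow(genes))
  if (!is.na(pair_event) && pair_event %in% names(tagof)) {
    tg <- tagof[[pair_event]]
    sib_key <- vapply(seq_len(nrow(genes)), function(i) {
      e <- sub_elems[[i]]
      paste(genes$anc[i], paste(e[!grepl(paste0("^", tg, "[0-9]+$"), e)], collapse = "."),
            sep = "|")
    }, "")
    sizes <- table(sib_key)
    one_copy <- sizes[sib_key] == 1
  }

  samples <- as.vector(outer(conditions, seq_len(replicates),
                             function(c, r) paste0(c, "_r", r)))
  groups <- setNames(rep(conditions, replicates), samples)
  fpkm <- matrix(0, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (ci in seq_along(conditions)) {
    mu <- base[as.character(genes$anc)] * cond_eff[as.character(genes$anc), ci] *
      ifelse(is_dom, delta, 1) * ifelse(one_copy, one_copy_factor, 1)
    for (r in seq_len(replicates)) {
      col <- paste0(conditions[ci], "_r", r)
      fpkm[, col] <- mu * rlnorm(nrow(genes), 0, noise_sd_log)
    }
  }
  if (!is.null(zero_genes)) fpkm[rownames(fpkm) %in% zero_genes, ] <- 0
  dataset$expression <- expression_matrix(fpkm, groups)
  dataset$truth$expression <- list(
    delta = delta, dominant = dominant, pair_event = pair_event,
    one_copy_factor = one_copy_factor, target = target,
    genes = data.frame(gene_id = genes$gene_id, dominant = unname(is_dom),
                       one_copy = unname(as.logical(one_copy)),
                       stringsAsFactors = FALSE))
  dataset
}
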