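# Independent oracles used by the tests. These deliberately re-derive the
# quantities with different algorithms/data structures than the package.

## Exhaustive best-chain score: depth-first search over all strictly
## monotone anchor chains under the gap constraint. Anchors must be sorted
## by (a, b).
oracle_chain_score <- function(a, b, s, gap_limit) {
  n <- length(a)
  best <- 0
  rec <- function(last, score, from) {
    best <<- max(best, score)
    if (from > n) return()
    for (j in from:n) {
      ok <- if (last == 0) TRUE else {
        da <- a[j] - a[last]; db <- b[j] - b[last]
        da >= 1 && db >= 1 && max(da, db) - 1 <= gap_limit
      }
      if (ok) rec(j, score + s[j], j + 1)
    }
  }
  rec(0, 0, 1)
  best
}

## Independent Nei-Gojobori: per-codon site fractions and recursive pathway
## enumeration (stop-crossing paths dropped; codon pairs with no valid path
## or containing stops excluded entirely).
oracle_ng_counts <- function(codons_a, codons_b) {
  GC <- Biostrings::GENETIC_CODE
  NTS <- c("A", "C", "G", "T")
  syn_frac <- function(cod) {
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NTS, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- nt
        if (GC[[alt]] != "*" && GC[[alt]] == GC[[cod]]) s <- s + 1 / 3
      }
    }
    s
  }
  paths <- function(x, y) {
    dp <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(dp)) return(list(c(0, 0)))
    out <- list()
    for (p in dp) {
      mid <- x
      substr(mid, p, p) <- substr(y, p, p)
      if (GC[[mid]] == "*") next
      step <- if (GC[[x]] == GC[[mid]]) c(1, 0) else c(0, 1)
      for (rest in paths(mid, y)) out[[length(out) + 1]] <- step + rest
    }
    out
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(codons_a)) {
    ca <- codons_a[i]; cb <- codons_b[i]
    if (GC[[ca]] == "*" || GC[[cb]] == "*") next
    pw <- paths(ca, cb)
    if (!length(pw)) next
    used <- used + 1
    S <- S + (syn_frac(ca) + syn_frac(cb)) / 2
    N <- N + 3 - (syn_frac(ca) + syn_frac(cb)) / 2
    m <- do.call(rbind, pw)
    Sd <- Sd + mean(m[, 1])
    Nd <- Nd + mean(m[, 2])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = used)
}

random_codons <- function(n, seed) {
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  repeat {
    cod <- paste0(sample(nts, n, TRUE), sample(nts, n, TRUE), sample(nts, n, TRUE))
    if (!any(cod %in% c("TAA", "TAG", "TGA"))) return(cod)
  }
}

## small deterministic annotation for unit tests
toy_annotation <- function(genome_id = "G", n = 20, chrs = c("c1", "c2")) {
  genes <- do.call(rbind, lapply(chrs, function(ch) data.frame(
    gene_id = sprintf("%s_%s_g%02d", genome_id, ch, seq_len(n)),
    chr = ch, start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
    strand = "+", stringsAsFactors = FALSE)))
  genome_annotation(genome_id, genes)
}

## homology table from a bare pair list
toy_homology <- function(q, s, score = 100) {
  homology_table(data.frame(query = as.character(q), subject = as.character(s),
                            pident = rep(90, length(q)),
                            evalue = rep(1e-30, length(q)),
                            score = rep(score, length.out = length(q)),
                            stringsAsFactors = FALSE))
}

## single-WGD history against an undoubled reference outgroup
single_wgd_config <- function(genes_per_chromosome = 500, n_chromosomes = 2,
                              retain = 0.75, p_loss = 0.3, seed = 1,
                              age = 48, retain_beta = NULL, ...) {
  tree <- list(age = 85, rate = 1, children = list(
    list(tip = "V", rate = 1),
    list(tip = "X", rate = 1)))
  events <- list(list(name = "A-alpha", age = age, multiplicity = 2, tag = "a",
                      lineages = "X", retain = retain, p_loss = p_loss))
  history_config(ancestor = list(n_chromosomes = n_chromosomes,
                                 genes_per_chromosome = genes_per_chromosome),
                 root_age = 90, tree = tree, events = events, seed = seed, ...)
}

## two nested WGDs in X against an undoubled reference outgroup
double_wgd_config <- function(genes_per_chromosome = 500, n_chromosomes = 2,
                              retain_beta = 1, retain_alpha = 1,
                              p_loss = 0.3, seed = 1, ...) {
  tree <- list(age = 85, rate = 1, children = list(
    list(tip = "V", rate = 1),
    list(tip = "X", rate = 1)))
  events <- list(
    list(name = "A-beta", age = 58, multiplicity = 2, tag = "b",
         lineages = "X", retain = retain_beta, p_loss = p_loss),
    list(name = "A-alpha", age = 48, multiplicity = 2, tag = "a",
         lineages = "X", retain = retain_alpha, p_loss = p_loss))
  history_config(ancestor = list(n_chromosomes = n_chromosomes,
                                 genes_per_chromosome = genes_per_chromosome),
                 root_age = 90, tree = tree, events = events, seed = seed, ...)
}

## event table for a V-reference / X-target simulated dataset, with columns
## grouped by the simulator's true subgenome labels
build_truth_table <- function(ds, gap_limit = 50, min_anchors = 5) {
  evs <- ds$truth$tip_events$X
  mult <- ds$truth$events$multiplicity[match(evs, ds$truth$events$name)]
  schema <- table_schema("V", integer(0),
                         setNames(list(setNames(as.integer(mult), evs)), "X"))
  hom <- filter_families(ds$homology)
  cs <- chain_blocks(hom, ds$annotations$V, ds$annotations$X,
                     gap_limit, min_anchors, strict = FALSE)
  groups <- list(X = truth_block_groups(ds, cs, "X", schema))
  build_event_table(schema, ds$annotations$V, list(X = cs), groups)
}
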