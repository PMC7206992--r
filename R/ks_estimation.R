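# Nei-Gojobori (1986) estimation of synonymous (Ks) and nonsynonymous (Ka)
# substitution rates for codon-aligned gene pairs.
#
# Conventions (universal genetic code, injectable for testing):
#  * synonymous site fraction of a codon position = (number of the 3 possible
#    single-nucleotide changes that are synonymous) / 3; changes creating a
#    stop codon count as nonsynonymous, so s + n = 3 per codon;
#  * differences are averaged over all minimal substitution pathways between
#    two codons, pathways passing through a stop codon excluded; if every
#    pathway crosses a stop the codon pair is dropped from all counts;
#  * Jukes-Cantor correction K = -3/4 log(1 - 4/3 p); saturated when the log
#    argument is <= 0.

NT <- c("A", "C", "G", "T")

codon_index <- function(codons) {
  # codon string -> 1..64 index (A,C,G,T base-4); NA for codons with N etc.
  m <- match(c(substring(codons, 1, 1), substring(codons, 2, 2), substring(codons, 3, 3)), NT)
  n <- length(codons)
  i1 <- m[seq_len(n)]; i2 <- m[n + seq_len(n)]; i3 <- m[2 * n + seq_len(n)]
  (i1 - 1L) * 16L + (i2 - 1L) * 4L + i3
}

index_codon <- function(idx) {
  i <- idx - 1L
  paste0(NT[i %/% 16 + 1], NT[(i %/% 4) %% 4 + 1], NT[i %% 4 + 1])
}

codon_aa <- function(code = Biostrings::GENETIC_CODE) {
  unname(code[index_codon(1:64)])
}

# Per-codon synonymous site counts and pairwise pathway-averaged difference
# counts, computed once and cached.
ng_tables <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste0("ng_", digest_code(code))
  if (!is.null(.wgdscan_env[[key]])) return(.wgdscan_env[[key]])
  aa <- codon_aa(code)
  stops <- which(aa == "*")

  ## synonymous sites per codon (stop-creating changes are nonsynonymous)
  syn_sites <- rep(NA_real_, 64)
  neighbours <- function(idx, pos) {
    cod <- index_codon(idx)
    cur <- substring(cod, pos, pos)
    vapply(setdiff(NT, cur), function(nt) {
      s <- cod; substring(s, pos, pos) <- nt; codon_index(s)
    }, 1L)
  }
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    s <- 0
    for (pos in 1:3) {
      nb <- neighbours(i, pos)
      s <- s + sum(aa[nb] == aa[i] & aa[nb] != "*") / 3
    }
    syn_sites[i] <- s
  }

  ## pathway-averaged synonymous / nonsynonymous differences per codon pair
  sd_tab <- matrix(0, 64, 64)
  nd_tab <- matrix(0, 64, 64)
  ok_tab <- matrix(TRUE, 64, 64)   # FALSE when all pathways cross a stop
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                           c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(64)) {
    if (aa[i] == "*") { ok_tab[i, ] <- FALSE; next }
    ci <- index_codon(i)
    for (j in seq_len(64)) {
      if (j == i) next
      if (aa[j] == "*") { ok_tab[i, j] <- FALSE; next }
      cj <- index_codon(j)
      diffpos <- which(substring(ci, 1:3, 1:3) != substring(cj, 1:3, 1:3))
      d <- length(diffpos)
      tot_s <- 0; tot_n <- 0; nvalid <- 0
      for (ord in perms[[as.character(d)]]) {
        cur <- ci; s <- 0; n <- 0; valid <- TRUE
        for (p in diffpos[ord]) {
          nxt <- cur
          substring(nxt, p, p) <- substring(cj, p, p)
          a1 <- aa[codon_index(cur)]; a2 <- aa[codon_index(nxt)]
          if (a2 == "*") { valid <- FALSE; break }
          if (a1 == a2) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; nvalid <- nvalid + 1 }
      }
      if (nvalid == 0) ok_tab[i, j] <- FALSE
      else { sd_tab[i, j] <- tot_s / nvalid; nd_tab[i, j] <- tot_n / nvalid }
    }
  }
  out <- list(aa = aa, syn_sites = syn_sites, sd = sd_tab, nd = nd_tab, ok = ok_tab)
  .wgdscan_env[[key]] <- out
  out
}

digest_code <- function(code) paste(code, collapse = "")

#' Codon-align two coding sequences
#'
#' Global protein-level alignment (BLOSUM62, affine gaps) back-translated to
#' codons. Gap columns, codons containing `N`, internal stop codons and final
#' stop codons are dropped.
#'
#' @param cds_a,cds_b coding nucleotide sequences (character or `DNAString`).
#' @return data.frame with columns `codon_a`, `codon_b`.
#' @export
align_codons <- function(cds_a, cds_b) {
  a <- as.character(cds_a); b <- as.character(cds_b)
  cod_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cod_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  if (identical(cod_a, cod_b) || (length(cod_a) == length(cod_b) &&
      mean(cod_a == cod_b) > 0.3)) {
    ## equal-length, clearly homologous in frame: gapless alignment
    ia <- seq_along(cod_a); ib <- seq_along(cod_b)
  } else {
    pa <- suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(c(a, b)), if.fuzzy.codon = "solve"))
    pa <- gsub("\\*$", "X", as.character(pa))
    pa <- chartr("*", "X", pa)
    al <- Biostrings::pairwiseAlignment(pa[1], pa[2], type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- cumsum(pat != "-"); ib <- cumsum(sub != "-")
    keep <- pat != "-" & sub != "-"
    ia <- ia[keep]; ib <- ib[keep]
  }
  ca <- cod_a[ia]; cb <- cod_b[ib]
  stopc <- c("TAA", "TAG", "TGA")
  keep <- !grepl("N", ca) & !grepl("N", cb) & !(ca %in% stopc) & !(cb %in% stopc)
  data.frame(codon_a = ca[keep], codon_b = cb[keep], stringsAsFactors = FALSE)
}

#' Nei-Gojobori Ka/Ks estimate for a codon-aligned pair
#'
#' @param codons data.frame from [align_codons()] (columns `codon_a`,
#'   `codon_b`), or a list of two equal-length codon vectors.
#' @param min_codons minimum aligned codons for an `ok` estimate.
#' @param code genetic code (default universal).
#' @return one-row data.frame: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`,
#'   `n_codons`, `status` (`ok`, `saturated`, `too_short`).
#' @export
nei_gojobori <- function(codons, min_codons = 30L, code = Biostrings::GENETIC_CODE) {
  tab <- ng_tables(code)
  ia <- codon_index(codons[[1]]); ib <- codon_index(codons[[2]])
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  valid <- tab$ok[cbind(ia, ib)] & !is.na(tab$syn_sites[ia]) & !is.na(tab$syn_sites[ib])
  ia <- ia[valid]; ib <- ib[valid]
  n_codons <- length(ia)
  S <- sum((tab$syn_sites[ia] + tab$syn_sites[ib]) / 2)
  N <- 3 * n_codons - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || 1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  status <- if (n_codons < min_codons) "too_short"
            else if (is.na(Ks) || is.na(Ka)) "saturated"
            else "ok"
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, n_codons = n_codons, status = status,
             stringsAsFactors = FALSE)
}

# Nei-Gojobori on pre-indexed codon vectors (internal fast path)
ng_from_indices <- function(ia, ib, min_codons, tab) {
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  valid <- tab$ok[cbind(ia, ib)] & !is.na(tab$syn_sites[ia]) & !is.na(tab$syn_sites[ib])
  ia <- ia[valid]; ib <- ib[valid]
  n_codons <- length(ia)
  S <- sum((tab$syn_sites[ia] + tab$syn_sites[ib]) / 2)
  N <- 3 * n_codons - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || 1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  status <- if (n_codons < min_codons) "too_short"
            else if (is.na(Ks) || is.na(Ka)) "saturated"
            else "ok"
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, n_codons = n_codons, status = status,
             stringsAsFactors = FALSE)
}

#' Ka/Ks for many gene pairs
#'
#' Codon-aligns and estimates every pair. Equal-length, clearly homologous
#' pairs take a gapless fast path; the remainder are protein-aligned in one
#' batched global alignment.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (extra columns are
#'   carried through).
#' @param cds named vector / `DNAStringSet` of CDS covering all genes.
#' @param min_codons minimum aligned codons for `ok` status.
#' @return `pairs` with the Nei-Gojobori columns appended.
#' @export
ks_for_pairs <- function(pairs, cds, min_codons = 30L) {
  seqs <- if (is.character(cds)) cds else as.character(cds)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seqs))
  if (length(missing)) integrity_error("no CDS for gene '%s'", missing[1])
  tab <- ng_tables()
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  idx <- lapply(seqs[genes], function(s) {
    n <- nchar(s)
    codon_index(substring(s, seq(1, n, 3), seq(3, n, 3)))
  })
  n <- nrow(pairs)
  res <- vector("list", n)
  need_align <- logical(n)
  for (i in seq_len(n)) {
    ia <- idx[[pairs$gene_a[i]]]; ib <- idx[[pairs$gene_b[i]]]
    if (length(ia) == length(ib) &&
        mean(ia == ib, na.rm = TRUE) > 0.15) {
      ## gapless in-frame pair: drop stop/N codons, estimate directly
      aa <- tab$aa
      ok <- !is.na(ia) & !is.na(ib) & aa[ia] != "*" & aa[ib] != "*"
      res[[i]] <- ng_from_indices(ia[ok], ib[ok], min_codons, tab)
    } else {
      need_align[i] <- TRUE
    }
  }
  if (any(need_align)) {
    ali <- which(need_align)
    prot <- function(g) {
      p <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAStringSet(seqs[g]), if.fuzzy.codon = "solve")))
      chartr("*", "X", p)
    }
    pa <- Biostrings::AAStringSet(prot(pairs$gene_a[ali]))
    pb <- Biostrings::AAStringSet(prot(pairs$gene_b[ali]))
    al <- Biostrings::pairwiseAlignment(pa, pb, type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    app <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
    aps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
    for (k in seq_along(ali)) {
      i <- ali[k]
      pat <- app[[k]]; sub <- aps[[k]]
      ipa <- cumsum(pat != "-"); ipb <- cumsum(sub != "-")
      keep <- pat != "-" & sub != "-"
      ia <- idx[[pairs$gene_a[i]]][ipa[keep]]
      ib <- idx[[pairs$gene_b[i]]][ipb[keep]]
      aa <- tab$aa
      ok <- !is.na(ia) & !is.na(ib) & aa[ia] != "*" & aa[ib] != "*"
      res[[i]] <- ng_from_indices(ia[ok], ib[ok], min_codons, tab)
    }
  }
  cbind(pairs, do.call(rbind, res))
}

#' Attach Ks medians to colinear blocks
#'
#' The block Ks median (over `ok`-status anchor estimates) is the statistic
#' used to group blocks by polyploidy event. Blocks with no usable anchor
#' estimate keep `ks_median = NA` but are retained.
#'
#' @param blocks a `colinear_set` from [chain_blocks()].
#' @param estimates data.frame with `gene_a`, `gene_b`, `Ks`, `status`
#'   (from [ks_for_pairs()]).
#' @return the `colinear_set` with `ks_median` filled in.
#' @export
block_ks_median <- function(blocks, estimates) {
  ok <- estimates[estimates$status == "ok", c("gene_a", "gene_b", "Ks")]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ksmap <- ok$Ks
  names(ksmap) <- key(ok$gene_a, ok$gene_b)
  anc <- blocks$anchors
  anc_ks <- unname(ksmap[key(anc$gene_a, anc$gene_b)])
  med <- tapply(anc_ks, anc$block_id, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  })
  blocks$blocks$ks_median <- unname(med[as.character(blocks$blocks$block_id)])
  blocks$anchors$ks <- anc_ks
  blocks
}
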