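# Readers and writers for the external formats the pipeline touches.
# Internal coordinates are 1-based inclusive; all colinearity logic downstream
# works on `order_index` (0-based gene rank along a chromosome), not base pairs.

#' Construct a genome annotation
#'
#' The coordinate backbone of all synteny work: an ordered set of gene models.
#' Genes are sorted by (chromosome, start) and assigned a 0-based
#' `order_index`, consecutive within each chromosome.
#'
#' @param genome_id label for the genome.
#' @param genes data.frame with columns `gene_id`, `chr`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes) {
  need <- c("gene_id", "chr", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    format_error("annotation needs columns %s", paste(need, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chr <- as.character(genes$chr)
  if (anyDuplicated(genes$gene_id)) {
    integrity_error("duplicate gene_id in genome '%s': %s", genome_id,
                    genes$gene_id[duplicated(genes$gene_id)][1])
  }
  bad <- which(genes$end < genes$start)
  if (length(bad)) {
    integrity_error("end < start for gene '%s'", genes$gene_id[bad[1]])
  }
  genes <- genes[order(genes$chr, genes$start, genes$gene_id), , drop = FALSE]
  genes$order_index <- unlist(lapply(split(seq_len(nrow(genes)), genes$chr),
                                     function(i) seq_along(i) - 1L), use.names = FALSE)
  ## split() reorders by chr level; realign
  genes$order_index <- stats::ave(genes$start, genes$chr,
                                  FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d chromosomes\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$chr))))
  invisible(x)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) encodings of the same
#' genes yield identical internal annotations. Only `gene` features are used
#' from GFF3; BED uses the `name` column as gene id.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param genome_id genome label; defaults to the file base name.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("gff3", "bed"), genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_wgd("io_error", "file not found: '%s'", path)
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]+$", "", basename(path))
  lines <- readLines(path)
  body <- which(!grepl("^\\s*(#|$)", lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (format == "gff3") {
    bad <- body[nf != 9L]
    if (length(bad)) format_error("line %d of '%s': expected 9 tab-separated fields, got %d",
                                  bad[1], path, nf[which(body == bad[1])])
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    if (!length(gr)) format_error("no gene features in '%s'", path)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    genes <- data.frame(gene_id = ids,
                        chr = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  } else {
    bad <- body[nf < 4L]
    if (length(bad)) format_error("line %d of '%s': BED gene records need >= 4 fields", bad[1], path)
    ## parse directly so that end < start can be reported as an integrity
    ## error rather than a range-construction failure
    f <- strsplit(lines[body], "\t", fixed = TRUE)
    genes <- data.frame(gene_id = vapply(f, `[`, "", 4L),
                        chr = vapply(f, `[`, "", 1L),
                        start = as.numeric(vapply(f, `[`, "", 2L)) + 1L,
                        end = as.numeric(vapply(f, `[`, "", 3L)),
                        strand = vapply(f, function(x) if (length(x) >= 6) x[6] else "+", ""),
                        stringsAsFactors = FALSE)
    if (anyNA(genes$start) || anyNA(genes$end)) {
      format_error("non-numeric coordinate in BED file '%s'", path)
    }
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_annotation(genome_id, genes)
}

#' Write a genome annotation as GFF3
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation <- function(ann, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  g <- ann$genes
  lines <- sprintf("%s\twgdscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   g$chr, as.integer(g$start), as.integer(g$end), g$strand, g$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read an all-vs-all homology table (BLAST tabular, outfmt 6)
#'
#' Self-hits are dropped. Duplicate unordered gene pairs keep the row with
#' the highest alignment score; ties break by lower e-value, then by
#' lexicographic gene ids.
#'
#' @param path 12-column BLAST tabular file.
#' @return data.frame of class `homology_table` with columns `query`,
#'   `subject`, `pident`, `evalue`, `score`.
#' @export
read_homology <- function(path) {
  if (!file.exists(path)) stop_wgd("io_error", "file not found: '%s'", path)
  lines <- readLines(path)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body)) return(homology_table(data.frame(query = character(), subject = character(),
                                                      pident = numeric(), evalue = numeric(),
                                                      score = numeric())))
  f <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    format_error("line %d of '%s': expected 12 columns, got %d", body[i], path, nf[i])
  }
  m <- matrix(unlist(f), ncol = 12, byrow = TRUE)
  pident <- suppressWarnings(as.numeric(m[, 3]))
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  score <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(score) || anyNA(evalue)) {
    i <- which(is.na(score) | is.na(evalue))[1]
    format_error("line %d of '%s': non-numeric score or e-value", body[i], path)
  }
  homology_table(data.frame(query = m[, 1], subject = m[, 2], pident = pident,
                            evalue = evalue, score = score, stringsAsFactors = FALSE))
}

#' Construct a homology table (dedup + self-hit rules applied)
#' @param pairs data.frame with columns `query`, `subject`, `pident`,
#'   `evalue`, `score`.
#' @return data.frame of class `homology_table`.
#' @export
homology_table <- function(pairs) {
  pairs <- pairs[pairs$query != pairs$subject, , drop = FALSE]
  if (nrow(pairs)) {
    a <- pmin(pairs$query, pairs$subject)
    b <- pmax(pairs$query, pairs$subject)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -pairs$score, pairs$evalue, pairs$query, pairs$subject)
    pairs <- pairs[ord, , drop = FALSE]
    pairs <- pairs[!duplicated(key[ord]), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  class(pairs) <- c("homology_table", "data.frame")
  pairs
}

#' Write a homology table as 12-column BLAST tabular
#' @param hom a homology table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_homology <- function(hom, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- sprintf("%s\t%s\t%s\t0\t0\t0\t1\t100\t1\t100\t%s\t%s",
                   hom$query, hom$subject, fmt_num(hom$pident),
                   fmt_num(hom$evalue), fmt_num(hom$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file of in-frame CDS.
#' @param validate check CDS invariants (length divisible by 3, alphabet
#'   ACGTN, no internal stop codons).
#' @return a named `DNAStringSet`.
#' @export
read_cds <- function(path, validate = TRUE) {
  cds <- Biostrings::readDNAStringSet(path)
  names(cds) <- sub("\\s.*$", "", names(cds))
  if (validate) validate_cds(cds)
  cds
}

#' Validate a CDS set against its invariants
#' @param cds a `DNAStringSet` or named character vector.
#' @return the input, invisibly; errors on violation.
#' @export
validate_cds <- function(cds) {
  s <- if (is.character(cds)) cds else as.character(cds)
  if (any(nchar(s) %% 3 != 0)) {
    integrity_error("CDS length not divisible by 3: '%s'", names(s)[nchar(s) %% 3 != 0][1])
  }
  if (any(grepl("[^ACGTN]", s))) {
    integrity_error("CDS with characters outside ACGTN: '%s'", names(s)[grepl("[^ACGTN]", s)][1])
  }
  ## internal stops: check all but the final codon
  has_internal_stop <- vapply(s, function(x) {
    n <- nchar(x)
    if (n < 6) return(FALSE)
    cod <- substring(x, seq(1, n - 3, 3), seq(3, n - 3, 3))
    any(cod %in% c("TAA", "TAG", "TGA"))
  }, TRUE, USE.NAMES = FALSE)
  if (any(has_internal_stop)) {
    integrity_error("internal stop codon in CDS '%s'", names(s)[has_internal_stop][1])
  }
  invisible(cds)
}

#' Write a CDS set as FASTA
#' @param cds named character vector or `DNAStringSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cds <- function(cds, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (!methods::is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(unlist(cds))
  Biostrings::writeXStringSet(cds, path)
  invisible(path)
}

#' Read an expression matrix (TSV of FPKM)
#'
#' First column is the gene id, remaining columns are samples. Every sample
#' must belong to exactly one replicate group.
#'
#' @param path TSV file.
#' @param groups named character vector mapping sample name to replicate-group
#'   (condition) label.
#' @param annotation optional [genome_annotation()]; gene ids absent from it
#'   are retained with a warning.
#' @return an `expression_matrix`: list with `fpkm` (genes x samples matrix)
#'   and `samples` (data.frame sample/group).
#' @export
read_expression <- function(path, groups, annotation = NULL) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nf[nf > 0])) > 1) {
    format_error("ragged rows in '%s': line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, groups, annotation)
}

#' Construct an expression matrix object
#' @param fpkm genes x samples numeric matrix of FPKM values.
#' @param groups named character vector: sample -> replicate group.
#' @param annotation optional annotation to check gene ids against.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, groups, annotation = NULL) {
  if (any(fpkm < 0, na.rm = TRUE)) {
    integrity_error("negative FPKM value for gene '%s'",
                    rownames(fpkm)[which(rowSums(fpkm < 0) > 0)[1]])
  }
  missing_grp <- setdiff(colnames(fpkm), names(groups))
  if (length(missing_grp)) {
    config_error("samples without a replicate group: %s", paste(missing_grp, collapse = ", "))
  }
  if (!is.null(annotation)) {
    unmatched <- setdiff(rownames(fpkm), annotation$genes$gene_id)
    if (length(unmatched)) {
      warning(sprintf("%d expression gene id(s) not in annotation (kept), e.g. '%s'",
                      length(unmatched), unmatched[1]))
    }
  }
  structure(list(fpkm = fpkm,
                 samples = data.frame(sample = colnames(fpkm),
                                      group = unname(groups[colnames(fpkm)]),
                                      stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' Write an expression matrix as TSV
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm, check.names = FALSE)
  write_tsv_file(df, path)
}

#' Per-condition replicate means of an expression matrix
#' @param expr an `expression_matrix`.
#' @return genes x conditions matrix of replicate-mean FPKM.
#' @export
condition_means <- function(expr, ...) {
  grp <- expr$samples$group
  conds <- unique(grp)
  out <- vapply(conds, function(g) rowMeans(expr$fpkm[, grp == g, drop = FALSE]),
                numeric(nrow(expr$fpkm)))
  colnames(out) <- conds
  out
}

#' Write pipeline result objects as deterministic TSV files
#'
#' Serializations use a fixed column order, `'.'` for missing values and six
#' significant digits for floats; each writer has a matching reader that
#' round-trips losslessly at that precision.
#'
#' @param objects named list of objects (`colinear_set`, `event_table`,
#'   `mixture_fit`, or plain data.frames).
#' @param out_dir output directory.
#' @return character vector of paths written.
#' @export
write_tables <- function(objects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    x <- objects[[nm]]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (inherits(x, "colinear_set")) write_blocks(x, p)
    else if (inherits(x, "event_table")) write_event_table(x, p)
    else if (inherits(x, "mixture_fit")) write_mixture(x, p)
    else write_tsv_file(as.data.frame(x), p)
    paths <- c(paths, p)
  }
  paths
}
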