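# Deterministic TSV serializations with matching readers (lossless
# round-trips at 6 significant digits; '.' marks missing cells).

#' Write a colinear block set as TSV
#' @param blocks a `colinear_set`.
#' @param path output path (anchors go to `<path>` with a `#` block header
#'   per block, MCScan-style flat layout: one anchor row per line).
#' @return the path, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  bl <- blocks$blocks
  an <- blocks$anchors
  df <- merge(an, bl[, c("block_id", "genome_a", "genome_b", "chr_a", "chr_b",
                         "orientation", "ks_median")], by = "block_id")
  df <- df[order(df$block_id, df$order_a),
           c("block_id", "genome_a", "genome_b", "chr_a", "chr_b", "orientation",
             "gene_a", "gene_b", "order_a", "order_b", "score", "ks_median")]
  df$score <- fmt_num(df$score)
  df$ks_median <- fmt_num(df$ks_median)
  write_tsv_file(df, path)
}

#' Read a colinear block set written by [write_blocks()]
#' @param path TSV path.
#' @return a `colinear_set`.
#' @export
read_blocks <- function(path) {
  df <- read_tsv_file(path)
  if (!nrow(df)) {
    return(structure(list(blocks = data.frame(), anchors = data.frame(),
                          genome_a = NA, genome_b = NA), class = "colinear_set"))
  }
  df$score <- parse_num(as.character(df$score))
  df$ks_median <- parse_num(as.character(df$ks_median))
  an <- df[, c("block_id", "gene_a", "gene_b", "order_a", "order_b", "score")]
  bl <- do.call(rbind, lapply(split(df, df$block_id), function(b) data.frame(
    block_id = b$block_id[1], genome_a = b$genome_a[1], genome_b = b$genome_b[1],
    chr_a = b$chr_a[1], chr_b = b$chr_b[1], orientation = b$orientation[1],
    n_anchors = nrow(b), score = sum(b$score),
    start_a = min(b$order_a), end_a = max(b$order_a),
    start_b = min(b$order_b), end_b = max(b$order_b),
    ks_median = b$ks_median[1], stringsAsFactors = FALSE)))
  bl <- bl[order(bl$block_id), ]
  rownames(bl) <- rownames(an) <- NULL
  structure(list(blocks = bl, anchors = an,
                 genome_a = bl$genome_a[1], genome_b = bl$genome_b[1]),
            class = "colinear_set")
}

#' Write the composed event table as TSV ('.' for missing cells)
#' @param et an `event_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_event_table <- function(et, path) {
  full <- compose_full_table(et)
  write_tsv_file(full, path)
}

#' Read a composed event table TSV
#' @param path TSV path.
#' @return data.frame with NA for '.' cells.
#' @export
read_event_table_tsv <- function(path) read_tsv_file(path)

#' Write a mixture fit as TSV (component table plus R2 header comment)
#' @param fit a `mixture_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mixture <- function(fit, path) {
  df <- data.frame(component = seq_len(fit$n_components),
                   weight = fmt_num(fit$components$weight),
                   mean = fmt_num(fit$components$mean),
                   sd = fmt_num(fit$components$sd),
                   r2 = fmt_num(fit$r2), stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Read a mixture fit TSV written by [write_mixture()]
#' @param path TSV path.
#' @return a `mixture_fit` (components + r2; window/bandwidth not restored).
#' @export
read_mixture <- function(path) {
  df <- read_tsv_file(path)
  comp <- data.frame(weight = parse_num(as.character(df$weight)),
                     mean = parse_num(as.character(df$mean)),
                     sd = parse_num(as.character(df$sd)))
  structure(list(components = comp, n_components = nrow(comp),
                 r2 = parse_num(as.character(df$r2[1])),
                 principal = which.max(comp$weight),
                 bandwidth = NA_real_, window = c(NA_real_, NA_real_)),
            class = "mixture_fit")
}
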