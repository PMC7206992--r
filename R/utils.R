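# Internal utilities: errors, seeds, formatting, minimal SVG output.

stop_wgd <- function(kind, msg, ...) {
  stop(structure(class = c(paste0("wgdscan_", kind), "wgdscan_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

format_error    <- function(msg, ...) stop_wgd("format_error", msg, ...)
integrity_error <- function(msg, ...) stop_wgd("integrity_error", msg, ...)
config_error    <- function(msg, ...) stop_wgd("config_error", msg, ...)
insufficient_data_error <- function(msg, ...) stop_wgd("insufficient_data", msg, ...)

#' Derive a reproducible component seed from a master seed
#'
#' All stochastic stages draw their RNG state from a single master seed via
#' this hash, so individual stages are reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param tag  character tag naming the component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# fixed-precision float formatting shared by all TSV writers ('.' = missing)
fmt_num <- function(x, digits = 6L) {
  out <- ifelse(is.na(x), ".", formatC(signif(x, digits), format = "g", digits = digits))
  out
}

parse_num <- function(x) {
  x[x == "."] <- NA
  as.numeric(x)
}

write_tsv_file <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_wgd("io_error", "cannot write '%s'", path)
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_wgd("io_error", "file not found: '%s'", path)
  read.delim(path, stringsAsFactors = FALSE, na.strings = ".", check.names = FALSE)
}

## ---- minimal deterministic SVG writer -------------------------------------
## Figures (dot plots, homology circles, retention profiles) are written as
## plain SVG text so that identical inputs give byte-identical files.

svg_new <- function(width, height) {
  list(width = width, height = height,
       body = sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
                      fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height)))
}

svg_add <- function(doc, ...) {
  doc$body <- c(doc$body, unlist(list(...)))
  doc
}

svg_rect <- function(x, y, w, h, fill = "none", stroke = "black", sw = 1) {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
          fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h), fill, stroke, fmt_num(sw))
}

svg_line <- function(x1, y1, x2, y2, stroke = "black", sw = 1) {
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          fmt_num(x1), fmt_num(y1), fmt_num(x2), fmt_num(y2), stroke, fmt_num(sw))
}

svg_circle <- function(cx, cy, r, fill = "black", stroke = "none") {
  sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s"/>',
          fmt_num(cx), fmt_num(cy), fmt_num(r), fill, stroke)
}

svg_text <- function(x, y, label, size = 10, anchor = "middle") {
  sprintf('<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="%s">%s</text>',
          fmt_num(x), fmt_num(y), fmt_num(size), anchor, label)
}

svg_write <- function(doc, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(doc$body, "</svg>"), con, sep = "\n")
  invisible(path)
}
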