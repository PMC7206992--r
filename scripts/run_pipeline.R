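#!/usr/bin/env Rscript
# Thin command-line wrapper over wgdscan::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --config cfg.yaml [--outdir DIR] [--seed N]

suppressMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline configuration (defaults used if absent)"),
  make_option("--outdir", type = "character", default = NULL,
              help = "output directory (overrides config)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides config)"))))

suppressMessages(library(wgdscan))
cfg <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
if (!is.null(opts$seed)) cfg$seed <- opts$seed
invisible(run_pipeline(cfg))
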