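# Pipeline orchestration: declarative config, stage sequencing, manifest.

pipeline_defaults <- function() {
  list(
    outdir = "wgdscan_run",
    seed = 1L,
    gap_limit = 50L, min_anchors = 5L, max_family_size = 30L,
    proximal_window = 10L,
    bandwidth = 0.05, ks_window = c(0, 3), r2_threshold = 0.95,
    fold_threshold = 2, retention_window = 30L, retention_step = 5L,
    ks_max_pairs = 4000L,
    calibration = list(anchor_event = "ECH", anchor_age = 125),
    simulate = TRUE,
    simulation = list(profile = "clade3", genes_per_chromosome = 250L,
                      n_chromosomes = 2L, delta = 2, one_copy_factor = 1),
    inputs = NULL,
    figures = TRUE)
}

#' Three-genome demonstration history
#'
#' Reference outgroup `V` carrying only the ancient shared hexaploidy, and
#' two lineages `D` (faster) and `X` (slower) sharing two nested
#' tetraploidizations before their split.
#'
#' @param genes_per_chromosome,n_chromosomes ancestral genome size.
#' @param seed master seed.
#' @param ... overrides for [history_config()].
#' @return a `history_config`.
#' @export
history_config_clade3 <- function(genes_per_chromosome = 250, n_chromosomes = 2,
                                  seed = 1L, ...) {
  tree <- list(age = 118, rate = 1, children = list(
    list(tip = "V", rate = 1),
    list(age = 26, rate = 1, children = list(
      list(tip = "D", rate = 1.15),
      list(tip = "X", rate = 0.9)))))
  events <- list(
    list(name = "ECH", age = 125, multiplicity = 3, tag = "E",
         lineages = c("D", "V", "X"), retain = 0.55, p_loss = 0.35),
    list(name = "A-beta", age = 58, multiplicity = 2, tag = "b",
         lineages = c("D", "X"), retain = 0.7, p_loss = 0.3),
    list(name = "A-alpha", age = 48, multiplicity = 2, tag = "a",
         lineages = c("D", "X"), retain = 0.65, p_loss = 0.3))
  history_config(ancestor = list(n_chromosomes = n_chromosomes,
                                 genes_per_chromosome = genes_per_chromosome),
                 root_age = 130, tree = tree, events = events, seed = seed, ...)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, reports every problem at once (with field paths) and
#' warns on unknown keys.
#'
#' @param config path to a YAML config file, or a named list.
#' @return normalized config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_wgd("io_error", "config file not found: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    warning(sprintf("unknown config key(s) ignored: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defs, config[names(config) %in% names(defs)])
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$gap_limit) && cfg$gap_limit >= 1, "gap_limit: must be >= 1")
  chk(is.numeric(cfg$min_anchors) && cfg$min_anchors >= 1, "min_anchors: must be >= 1")
  chk(is.numeric(cfg$bandwidth) && cfg$bandwidth > 0, "bandwidth: must be > 0")
  chk(is.numeric(cfg$r2_threshold) && cfg$r2_threshold > 0 && cfg$r2_threshold <= 1,
      "r2_threshold: must be in (0, 1]")
  chk(is.numeric(cfg$fold_threshold) && cfg$fold_threshold > 1,
      "fold_threshold: must be > 1")
  chk(length(cfg$ks_window) == 2 && cfg$ks_window[1] < cfg$ks_window[2],
      "ks_window: must be an increasing pair")
  chk(is.numeric(cfg$seed), "seed: must be an integer")
  if (!cfg$simulate) {
    for (f in c("annotations", "homology", "cds")) {
      if (is.null(cfg$inputs[[f]])) {
        errs <- c(errs, sprintf("inputs.%s: required when simulate is false", f))
      } else {
        missing <- unlist(cfg$inputs[[f]])
        missing <- missing[!file.exists(missing)]
        if (length(missing)) {
          errs <- c(errs, sprintf("inputs.%s: file(s) not found: %s", f,
                                  paste(missing, collapse = ", ")))
        }
      }
    }
  }
  if (length(errs)) config_error("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[wgdscan:%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop_wgd("stage_failure", "stage '%s' failed: %s", stage, conditionMessage(e))
  })
  stage_msg(stage, "done in %.1f s", proc.time()[["elapsed"]] - t0)
  out
}

## deterministic subsample of candidate Ks pairs
subsample_pairs <- function(pairs, n_max, seed, tag) {
  if (nrow(pairs) <= n_max) return(pairs)
  set.seed(derive_seed(seed, paste0("kssub_", tag)))
  pairs[sort(sample.int(nrow(pairs), n_max)), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' colinearity, Ks estimation, peak fitting, rate correction and dating,
#' event table, fractionation, expression bias — writing TSV outputs,
#' figures and a JSON manifest (parameters, seed, output checksums) to the
#' run directory. Identical config and seed give identical manifests.
#'
#' @param config a config path / list accepted by [validate_config()].
#' @return (invisibly) list with the principal result objects.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list(config = cfg)

  dataset <- run_stage("simulate", {
    if (!cfg$simulate) config_error("external-input mode requires per-genome wiring; use simulate = TRUE for the bundled profile")
    prof <- cfg$simulation$profile
    hc <- switch(prof,
                 clade3 = history_config_clade3(cfg$simulation$genes_per_chromosome,
                                                cfg$simulation$n_chromosomes,
                                                seed = cfg$seed),
                 clade5 = history_config_clade5(cfg$simulation$genes_per_chromosome,
                                                cfg$simulation$n_chromosomes,
                                                seed = cfg$seed),
                 config_error("unknown simulation profile '%s'", prof))
    ds <- simulate_gene_orders(hc)
    ds <- realize_sequences(ds)
    simulate_expression(ds, target = "X", delta = cfg$simulation$delta,
                        one_copy_factor = cfg$simulation$one_copy_factor)
  })
  results$dataset <- dataset
  anns <- dataset$annotations
  ref <- "V"
  lineages <- names(anns)
  for (g in lineages) write_annotation(anns[[g]], file.path(outdir, paste0(g, ".gff3")))

  hom <- run_stage("collinearity.filter", {
    filter_families(dataset$homology, cfg$max_family_size)
  })
  blocks <- run_stage("collinearity.chain", {
    out <- list()
    for (g in lineages) {
      out[[paste0(g, "_self")]] <- chain_blocks(hom, anns[[g]], anns[[g]],
                                                cfg$gap_limit, cfg$min_anchors,
                                                strict = FALSE)
    }
    for (g in setdiff(lineages, ref)) {
      out[[paste0(ref, "_", g)]] <- chain_blocks(hom, anns[[ref]], anns[[g]],
                                                 cfg$gap_limit, cfg$min_anchors,
                                                 strict = FALSE)
    }
    out
  })
  results$blocks <- blocks

  ks <- run_stage("ks", {
    out <- list()
    for (nm in names(blocks)) {
      anc <- unique(blocks[[nm]]$anchors[, c("gene_a", "gene_b")])
      if (!nrow(anc)) next
      genome_a <- blocks[[nm]]$genome_a; genome_b <- blocks[[nm]]$genome_b
      cds <- c(as.character(dataset$cds[[genome_a]]),
               if (genome_b != genome_a) as.character(dataset$cds[[genome_b]]))
      anc <- subsample_pairs(anc, cfg$ks_max_pairs, cfg$seed, nm)
      est <- ks_for_pairs(anc, cds)
      out[[nm]] <- est
      blocks[[nm]] <- block_ks_median(blocks[[nm]], est)
    }
    out
  })
  results$ks <- ks

  peaks <- run_stage("peaks", {
    out <- list()
    ## reference first: its oldest-event peak anchors the valley search
    fit_ref <- fit_event_peaks(blocks[[paste0(ref, "_self")]],
                               length(dataset$truth$tip_events[[ref]]),
                               bandwidth = cfg$bandwidth, window = cfg$ks_window)
    out[[ref]] <- assign_events(fit_ref, rev(dataset$truth$tip_events[[ref]]))
    oldest_ref <- fit_ref$components$mean[fit_ref$n_components]
    for (g in setdiff(lineages, ref)) {
      evs <- dataset$truth$tip_events[[g]]
      if (!length(evs)) next
      fit <- fit_event_peaks(blocks[[paste0(g, "_self")]], length(evs),
                             oldest_ref = oldest_ref,
                             bandwidth = cfg$bandwidth, window = cfg$ks_window)
      out[[g]] <- assign_events(fit, rev(evs))  # ascending Ks = youngest first
    }
    out
  })
  results$peaks <- peaks

  correction <- run_stage("correct", {
    lam <- setNames(1, ref)
    assigned_corr <- list()
    assigned_corr[[ref]] <- peaks[[ref]]
    for (g in setdiff(names(peaks), ref)) {
      rf <- estimate_rate_factor(peaks[[g]], peaks[[ref]], "ECH", g, ref)
      lam[g] <- rf$lambda
      assigned_corr[[g]] <- correct_ks(peaks[[g]], lam, g)
    }
    ## second stage: the two lineages sharing the youngest event are
    ## re-aligned, the slower one (larger first-stage lambda) as reference
    shared <- intersect(names(assigned_corr), c("D", "X"))
    if (length(shared) == 2) {
      young <- "A-alpha"
      slow <- shared[which.max(lam[shared])]
      fast <- setdiff(shared, slow)
      upd <- recorrect_pair(assigned_corr[[slow]], assigned_corr[[fast]],
                            young, lam[fast])
      lam[fast] <- upd$lambda
      assigned_corr[[fast]] <- correct_ks(peaks[[fast]], lam, fast)
    }
    list(lambda = lam, assigned = assigned_corr)
  })
  results$correction <- correction

  dates <- run_stage("date", {
    ## global clock: calibrate r_ref on the reference lineage's anchor peak
    cal <- cfg$calibration
    if (is.null(cal$r_ref)) {
      anchor <- correction$assigned[[ref]]
      row <- anchor[anchor$event == cal$anchor_event, , drop = FALSE]
      if (!nrow(row)) stop_wgd("assignment", "anchor event '%s' not fitted for '%s'",
                               cal$anchor_event, ref)
      cal <- list(r_ref = row$mean / (2 * cal$anchor_age))
    }
    out <- list()
    for (g in setdiff(names(correction$assigned), ref)) {
      out[[g]] <- date_events(correction$assigned[[g]], cal)
      out[[g]]$lineage <- g
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  results$dates <- dates
  write_tsv_file(transform(dates, mu = fmt_num(mu), sigma = fmt_num(sigma),
                           T = fmt_num(T), T_lo = fmt_num(T_lo),
                           T_hi = fmt_num(T_hi), r_ref = fmt_num(r_ref)),
                 file.path(outdir, "dates.tsv"))

  et <- run_stage("table", {
    tagmap <- setNames(dataset$truth$events$name, dataset$truth$events$tag)
    tgt <- setdiff(lineages, ref)
    schema_targets <- lapply(tgt, function(g) {
      evs <- setdiff(dataset$truth$tip_events[[g]], dataset$truth$tip_events[[ref]])
      mult <- dataset$truth$events$multiplicity[match(evs, dataset$truth$events$name)]
      setNames(as.integer(mult), evs)
    })
    names(schema_targets) <- tgt
    ref_evs <- dataset$truth$tip_events[[ref]]
    ref_mult <- dataset$truth$events$multiplicity[match(ref_evs, dataset$truth$events$name)]
    schema <- table_schema(ref, setNames(as.integer(ref_mult), ref_evs), schema_targets)
    bl <- list(self = blocks[[paste0(ref, "_self")]])
    groups <- list()
    for (g in tgt) {
      cs <- blocks[[paste0(ref, "_", g)]]
      lab <- block_event_labels(cs, dataset$homology)
      keep <- which(lab == "speciation")
      cs$blocks <- cs$blocks[cs$blocks$block_id %in% keep, , drop = FALSE]
      cs$anchors <- cs$anchors[cs$anchors$block_id %in% keep, , drop = FALSE]
      bl[[g]] <- cs
      groups[[g]] <- truth_block_groups(dataset, cs, g, schema)
    }
    build_event_table(schema, anns[[ref]], bl, groups)
  })
  results$event_table <- et
  write_event_table(et, file.path(outdir, "event_table.tsv"))
  write_tsv_file(retention_stats(et), file.path(outdir, "retention.tsv"))

  frac <- run_stage("fractionate", {
    runs <- extract_runs(et, "X")
    fit <- tryCatch(fit_geometric(runs), wgdscan_insufficient_data = function(e) NULL)
    prof <- retention_profile(et, "X", cfg$retention_window, cfg$retention_step)
    loss <- classify_loss_epochs(et, "X")
    write_tsv_file(runs, file.path(outdir, "deletion_runs.tsv"))
    write_tsv_file(loss$summary, file.path(outdir, "loss_epochs.tsv"))
    list(runs = runs, fit = fit, profile = prof, loss = loss)
  })
  results$fractionation <- frac

  expr_res <- run_stage("expression", {
    pd <- pair_divergence(et, dataset$expression, "X", cfg$fold_threshold)
    dom <- dominance_test(pd$pairs, event = "A-alpha")
    ovt <- one_vs_two_copy_test(et, dataset$expression, "X")
    write_tsv_file(pd$fractions, file.path(outdir, "expression_divergence.tsv"))
    write_tsv_file(dom, file.path(outdir, "dominance.tsv"))
    write_tsv_file(ovt, file.path(outdir, "one_vs_two_copy.tsv"))
    list(divergence = pd, dominance = dom, one_vs_two = ovt)
  })
  results$expression <- expr_res

  if (isTRUE(cfg$figures)) {
    run_stage("figures", {
      render_dotplot(hom, anns[[ref]], anns[["X"]],
                     file.path(outdir, "dotplot_V_X.svg"),
                     blocks = blocks[[paste0(ref, "_X")]])
      render_homology_circles(et, anns, file.path(outdir, "homology_circles.svg"))
    })
  }

  manifest <- run_stage("manifest", {
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    info <- file.info(files)
    empty <- files[info$size == 0]
    if (length(empty)) stop_wgd("stage_failure", "empty output file: %s", empty[1])
    m <- list(package = "wgdscan",
              version = as.character(utils::packageVersion("wgdscan")),
              seed = cfg$seed,
              parameters = cfg[c("gap_limit", "min_anchors", "max_family_size",
                                 "bandwidth", "r2_threshold", "fold_threshold")],
              calibration = cfg$calibration,
              outputs = lapply(setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })
  results$manifest <- manifest
  invisible(results)
}
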