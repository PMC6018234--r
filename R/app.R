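# Workflow plumbing: shared configuration and the design -> predict ->
# simulate -> analyze pipeline, with a manifest so a run is reproducible
# from its output directory alone.

#' Run configuration
#'
#' Collects every tunable the workflow stages share. Defaults are the
#' operating conditions the method is run at in the wet protocol:
#' hybridization at 60 degrees C in 0.5 M monovalent salt, capture probe
#' limiting at a 1:4 probe:precursor ratio.
#'
#' @param temperature_C hybridization temperature.
#' @param salt_M monovalent salt concentration (mol/L).
#' @param barcode_length barcode length B (panel capacity `2^B`).
#' @param iterations Monte Carlo assignment iterations.
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param probe_ratio probe:precursor capacity ratio (default 0.25, i.e.
#'   4x precursor excess).
#' @param n_molecules synthesized molecules per precursor (simulation).
#' @param n_read_pairs read pairs emitted by the simulated run.
#' @param max_cost alignment cost above which a read is unaligned.
#' @param gross_threshold error size at which a read is gross.
#' @param delta per-tag-error capture discrimination factor.
#' @param model an [error_model()].
#' @return list of class `snop_config`.
#' @export
run_config <- function(temperature_C = 60, salt_M = 0.5, barcode_length = 6,
                       iterations = 500, seed = 1, probe_ratio = 0.25,
                       n_molecules = 2000, n_read_pairs = 20000,
                       max_cost = 25, gross_threshold = 6, delta = 0.05,
                       model = error_model()) {
  structure(list(temperature_C = temperature_C, salt_M = salt_M,
                 barcode_length = barcode_length, iterations = iterations,
                 seed = seed, probe_ratio = probe_ratio,
                 n_molecules = n_molecules, n_read_pairs = n_read_pairs,
                 max_cost = max_cost, gross_threshold = gross_threshold,
                 delta = delta, model = model),
            class = "snop_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full workflow on a product panel
#'
#' Designs the panel (barcode assignment + validation), predicts capture
#' stoichiometry at equilibrium, simulates synthesis / capture / cleavage /
#' sequencing, analyzes the simulated reads, and writes every report plus a
#' manifest into `out_dir`. `precursor_bias` lets individual precursors be
#' over-represented in the simulated input pool, emulating grossly biased
#' precursor concentrations.
#'
#' @param products named character vector of product sequences (or a panel
#'   file path readable by [read_panel()]).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param precursor_bias optional named multiplier on the molecule count
#'   of specific precursors (default 1 for all).
#' @return invisibly, a list with the assignment, prediction, molecule
#'   pool summary, analysis, and output paths.
#' @export
run_end_to_end <- function(products, out_dir, config = run_config(),
                           precursor_bias = NULL) {
  if (is.character(products) && length(products) == 1 &&
      file.exists(products)) {
    products <- read_panel(products)
  }
  if (!length(products) || is.null(names(products))) {
    stop("stage design: no valid panel supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- thermo_params(config$temperature_C, config$salt_M)

  stage_msg("design", length(products), " products, B = ",
            config$barcode_length)
  asg <- optimize_assignment(products,
                             barcode_length = config$barcode_length,
                             iterations = config$iterations,
                             seed = config$seed, params = params)
  warn <- validate_panel(products)
  paths <- write_design(asg, out_dir, params)

  stage_msg("predict", "equilibrium stoichiometry at probe ratio ",
            config$probe_ratio)
  bias <- stats::setNames(rep(1, length(products)), names(products))
  if (!is.null(precursor_bias)) {
    bias[names(precursor_bias)] <- precursor_bias
  }
  conc0 <- 1e-8  # 10 pmol in 100 uL scale
  pred <- predicted_stoichiometry(asg, bias * conc0,
                                  conc0 * config$probe_ratio, params)

  stage_msg("simulate", "synthesis + capture + reads")
  mols <- do.call(rbind, lapply(seq_along(asg$precursors), function(i) {
    p <- asg$precursors[[i]]
    synthesize_molecules(p, round(config$n_molecules * bias[[p$oligo_id]]),
                         config$model, seed = config$seed + i)
  }))
  probe_n <- round(config$n_molecules * config$probe_ratio)
  prods <- snop_capture_and_cleave(mols, probe_n, delta = config$delta,
                                   seed = config$seed + 1000L)
  r1 <- file.path(out_dir, "reads_R1.fastq.gz")
  r2 <- file.path(out_dir, "reads_R2.fastq.gz")
  emit_reads(prods, config$n_read_pairs, config$model$seq_error_rate,
             seed = config$seed + 2000L, r1_path = r1, r2_path = r2)

  stage_msg("analyze", "consensus filter + alignment + reports")
  pair <- read_fastq_pair(r1, r2)
  # reference library: reads drawn from the raw precursor product regions
  # with equal per-oligo representation, emulating the nominally equimolar
  # desalted reference pool (independent of any input bias)
  avail <- mols[!is.na(mols$product_seq), c("source_id", "product_seq")]
  per_oligo <- min(table(avail$source_id))
  ref_pool <- do.call(rbind, lapply(split(avail, avail$source_id),
                                    function(d) d[seq_len(per_oligo), ]))
  names(ref_pool) <- c("oligo_id", "sequence")
  ref_reads <- emit_reads(ref_pool, config$n_read_pairs,
                          config$model$seq_error_rate,
                          seed = config$seed + 3000L)
  ref_flt <- consensus_filter(ref_reads$r1, ref_reads$r2)
  ref_al <- align_reads(ref_flt$consensus, products, config$max_cost)
  ref_counts <- table(factor(ref_al$reference_id, levels = names(products)))
  ref_counts <- stats::setNames(as.numeric(ref_counts), names(products))
  ana <- analyze_reads(pair$r1, pair$r2, products, ref_counts,
                       config$max_cost, config$gross_threshold)

  report <- merge(ana$purity$per_oligo,
                  ana$concentration$per_oligo[, c("oligo_id", "rel_conc")],
                  by = "oligo_id", all.x = TRUE)
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ana$concentration$lorenz,
                     file.path(out_dir, "lorenz.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = config[setdiff(names(config), "model")],
    error_model = unclass(config$model),
    seed = config$seed, n_products = length(products),
    design_score = asg$score, panel_warnings = nrow(warn),
    predicted_gini = pred$gini,
    filter = ana$filter,
    median_purity = ana$purity$median_purity,
    median_purity_excluding_gross =
      ana$purity$median_purity_excluding_gross,
    precursor_gini = gini_lorenz(as.numeric(table(mols$source_id)))$gini,
    gini = ana$concentration$gini,
    frac_within_2fold = ana$concentration$frac_within_2fold)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(assignment = asg, prediction = pred, warnings = warn,
                 molecules = mols, products = prods, analysis = ana,
                 manifest = manifest, paths = paths, out_dir = out_dir))
}
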