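#' End-to-end synthetic demonstration
#'
#' Runs the whole pipeline on a toy genome: simulate two replicates with
#' planted pauses, write the dataset, filter to well-expressed genes, call
#' pauses per replicate, assess reproducibility by IDR, compute pause
#' metrics, region pausing indices, splicing indices, antisense matrices,
#' assemble pause features with shuffled controls, and train the classifier.
#' Writes a markdown report and a JSON run manifest under `out_dir`.
#'
#' @param seed integer seed driving every stochastic step.
#' @param out_dir output directory.
#' @param config optional [simulation_config()]; its seed is overridden by
#'   `seed`.
#' @param skip character vector of stage names to skip (currently honors
#'   `"classify"`).
#' @param n_trees forest size for the demo classifier (default 300 to keep
#'   the demonstration quick; the analysis default is 2500).
#' @return Invisibly, a list with the main results (`pauses`, `idr_params`,
#'   `density`, `positional`, `pi_tables`, `auc`).
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("netseq_demo"),
                     config = NULL, skip = character(), n_trees = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- simulation_config(seed = seed)
  else config$seed <- as.integer(seed)

  toy <- generate_toy_genome(config)
  sim <- simulate_occupancy(toy$annotation, config)
  write_simulation(sim, toy$genome, toy$annotation, config, out_dir)

  filt <- select_well_expressed(sim$rep1, sim$rep2, toy$annotation)
  calls1 <- call_pauses(sim$rep1, toy$annotation, filt)
  calls2 <- call_pauses(sim$rep2, toy$annotation, filt)
  matched <- match_pauses(calls1, calls2)
  pairs <- estimate_idr(matched$pairs)
  pauses <- reproducible_pauses(pairs)
  write_pauses_bed(pauses, file.path(out_dir, "reproducible_pauses.bed"))

  expressed <- toy$annotation[toy$annotation$gene_id %in%
                                filt$gene_id[filt$passes], ]
  dens <- pause_density(pauses, sum(tx_length(expressed)))
  posd <- positional_distribution(pauses, toy$annotation)
  scram <- scramble_pauses(pauses, toy$annotation, seed = seed)
  posd_scram <- positional_distribution(scram, toy$annotation)

  merged <- merge_replicates(sim$rep1, sim$rep2)
  pi_tables <- lapply(c("tss", "polya", "ss5", "ss3"), function(r)
    pausing_index(merged, toy$annotation, region = r))
  names(pi_tables) <- c("tss", "polya", "ss5", "ss3")
  anti_ann <- build_antisense_annotation(toy$annotation)
  pi_anti <- antisense_pausing_index(merged, anti_ann)
  meta_tss <- metagene_profile(merged, toy$annotation, anchor = "tss",
                               window = c(-100, 400))
  jx <- simulate_junction_counts(toy$annotation, psi = 0.8, depth = 1000,
                                 seed = seed)
  si <- splicing_index(jx)
  anti_mat <- antisense_log_matrix(merged, toy$annotation,
                                   window = c(-250, 1500))

  auc <- NA_real_
  if (!("classify" %in% skip) && nrow(pauses) >= 40) {
    ctrl <- shuffled_control_loci(pauses, toy$annotation, seed = seed)
    feats <- assemble_features(pauses, ctrl, toy$genome, toy$annotation,
                               shape_table = synthetic_shape_table())
    ev <- train_and_evaluate(feats, classifier_config(n_trees = n_trees,
                                                      seed = seed))
    auc <- ev$auc
    write.table(data.frame(feature = names(ev$importance),
                           importance = ev$importance),
                file.path(out_dir, "importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = seed,
    n_genes = nrow(toy$annotation),
    n_well_expressed = sum(filt$passes),
    calls_rep1 = nrow(calls1), calls_rep2 = nrow(calls2),
    matched_pairs = nrow(pairs), reproducible = nrow(pauses),
    idr_params = attr(pairs, "params"),
    pause_density_per_kb = dens,
    median_si = stats::median(si$si, na.rm = TRUE),
    classifier_auc = auc)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- c(
    "# NET-seq synthetic pipeline report", "",
    sprintf("- seed: %d", seed),
    sprintf("- genes simulated: %d (well-expressed: %d)",
            nrow(toy$annotation), sum(filt$passes)),
    sprintf("- pause calls: %d (rep1), %d (rep2); matched pairs: %d",
            nrow(calls1), nrow(calls2), nrow(pairs)),
    sprintf("- reproducible pauses (IDR < 1%%): %d (%.1f%% of mean per-replicate calls)",
            nrow(pauses),
            100 * nrow(pauses) / mean(c(nrow(calls1), nrow(calls2)))),
    sprintf("- pause density: %.2f per kb of well-expressed gene", dens),
    sprintf("- positional fractions (5'/mid/3'): %.2f / %.2f / %.2f",
            posd$mean[1], posd$mean[2], posd$mean[3]),
    sprintf("- scrambled control fractions:      %.2f / %.2f / %.2f",
            posd_scram$mean[1], posd_scram$mean[2], posd_scram$mean[3]),
    sprintf("- median TSS pausing index: %.2f",
            stats::median(pi_tables$tss$pi, na.rm = TRUE)),
    sprintf("- median splicing index (psi = 0.8): %.2f",
            stats::median(si$si, na.rm = TRUE)),
    if (is.na(auc)) "- classifier: skipped"
    else sprintf("- classifier held-out AUC: %.3f", auc),
    "")
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(pauses = pauses, idr_params = attr(pairs, "params"),
                 density = dens, positional = posd, pi_tables = pi_tables,
                 pi_antisense = pi_anti, metagene = meta_tss,
                 splicing = si, antisense_matrix = anti_mat, auc = auc,
                 out_dir = out_dir))
}
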