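#' Configuration of a full pipeline run
#'
#' Bundles inputs and every stage parameter, with the motivating study's
#' values as defaults (INFO >= 0.9, MAF >= 0.1, selection p < 1e-5, 10 kb
#' gene flanks, 10 Mb / r-squared 0.2 pruning, dependence r-squared 0.2,
#' family-wise rate 0.05, gene-score FDR threshold `fwer / number of traits`,
#' 500 kb haplotype window, 10% haplotype frequency cutoff). Inputs are
#' either a [sim_config()] (the bundled synthetic benchmark) or paths to
#' per-trait summary statistics, a PLINK panel prefix, and a BED-like gene
#' table. Unknown arguments are rejected.
#'
#' @param sim Optional [sim_config()]; when given, inputs are simulated.
#' @param sumstats Named character vector of per-trait summary-statistics
#'   paths (ignored when `sim` is given).
#' @param panel_prefix PLINK 1 fileset prefix (ignored when `sim` is given).
#' @param genes_path BED-like gene table path (ignored when `sim` is given).
#' @param info_min,maf_min QC thresholds ([qc_params()]).
#' @param freq_tol Panel frequency tolerance ([harmonize_to_panel()]).
#' @param p_select,cojo_window_bp,collinearity_r2 Selection parameters
#'   ([cojo_params()]).
#' @param flank_bp Gene flank (bp).
#' @param prune_window_bp,prune_r2 Pruning parameters ([prune_pairwise()]).
#' @param dependence_r2 Scenario LD-dependence threshold.
#' @param fwer Family-wise error rate for the experiment-wide threshold.
#' @param gene_q_thresh Gene-score FDR threshold; `NULL` means
#'   `fwer / number of traits`.
#' @param haplo_window_bp,haplo_freq_min,gamete_freq_min Haplotype-stage
#'   parameters.
#' @param seed Integer seed governing all randomness of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, sumstats = NULL, panel_prefix = NULL,
                       genes_path = NULL,
                       info_min = 0.9, maf_min = 0.1, freq_tol = 0.2,
                       p_select = 1e-5, cojo_window_bp = 1e7,
                       collinearity_r2 = 0.9,
                       flank_bp = 1e4,
                       prune_window_bp = 1e7, prune_r2 = 0.2,
                       dependence_r2 = 0.2, fwer = 0.05,
                       gene_q_thresh = NULL,
                       haplo_window_bp = 5e5, haplo_freq_min = 0.10,
                       gamete_freq_min = 0.01,
                       seed = 1L) {
  if (is.null(sim) &&
      (is.null(sumstats) || is.null(panel_prefix) || is.null(genes_path))) {
    abort("provide either `sim` or all of `sumstats`, `panel_prefix`, `genes_path`.")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(
    list(sim = sim, sumstats = sumstats, panel_prefix = panel_prefix,
         genes_path = genes_path,
         info_min = info_min, maf_min = maf_min, freq_tol = freq_tol,
         p_select = p_select, cojo_window_bp = cojo_window_bp,
         collinearity_r2 = collinearity_r2, flank_bp = flank_bp,
         prune_window_bp = prune_window_bp, prune_r2 = prune_r2,
         dependence_r2 = dependence_r2, fwer = fwer,
         gene_q_thresh = gene_q_thresh,
         haplo_window_bp = haplo_window_bp,
         haplo_freq_min = haplo_freq_min,
         gamete_freq_min = gamete_freq_min,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Validate a plain list as a run configuration
#'
#' Rejects unknown keys before any computation, then dispatches to
#' [run_config()].
#'
#' @param x A named list of [run_config()] arguments.
#' @return A `run_config`.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, x)
}

#' Run the full pleiotropy pipeline
#'
#' Executes simulate/read -> QC -> harmonization -> stepwise signal
#' selection -> gene binning and block merging -> experiment-wide threshold
#' from pruned region markers -> scenario classification and tabulation ->
#' Brown gene scores, within-trait FDR and pleiotropic-gene selection ->
#' haplotype analysis of one LD-dependent cross-trait region, writing every
#' stage table plus a JSON manifest to `outdir`. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [run_config()] (or a plain list, validated first).
#' @param outdir Output directory (created if missing).
#' @return An object of class `pleio_run`: all stage tables plus `$manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  config <- as_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(...) inform(paste0("[pleiogene] ", ...))

  # -- inputs -----------------------------------------------------------
  if (!is.null(config$sim)) {
    stage("simulate: ", length(config$sim$traits), " trait(s)")
    study <- simulate_study(config$sim)
    panel <- study$panel
    genes <- study$genes
    raw <- study$sumstats
    write_plink(panel, file.path(outdir, "panel"))
    readr::write_tsv(study$genes, file.path(outdir, "genes.tsv"))
    readr::write_tsv(study$truth, file.path(outdir, "truth.tsv"))
    for (tr in names(raw)) {
      readr::write_tsv(setNames(raw[[tr]],
                                c("SNP", "CHR", "BP", "A1", "A2", "FREQ",
                                  "BETA", "SE", "P", "N", "INFO")),
                       file.path(outdir, paste0("sumstats_", tr, ".tsv")))
    }
  } else {
    stage("read inputs")
    panel <- read_plink(config$panel_prefix)
    genes <- readr::read_tsv(config$genes_path, col_types = "iiicic",
                             col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                             progress = FALSE)
    raw <- purrr::map(config$sumstats, read_sumstats)
  }

  # -- QC + harmonization ----------------------------------------------
  stage("qc + harmonize")
  qcp <- qc_params(info_min = config$info_min, maf_min = config$maf_min)
  qc <- purrr::map(raw, qc_filter, params = qcp)
  harmonized <- purrr::map(qc, harmonize_to_panel, panel = panel,
                           freq_tol = config$freq_tol)
  qc_report <- purrr::imap_dfr(qc, ~ mutate(.x$report, trait = .y)) %>%
    bind_rows(purrr::imap_dfr(
      harmonized, ~ mutate(attr(.x, "harmonize_report"), trait = .y)))
  readr::write_tsv(qc_report, file.path(outdir, "qc_report.tsv"))

  # -- signal selection -------------------------------------------------
  stage("select signals")
  cp <- cojo_params(p_select = config$p_select,
                    window_bp = config$cojo_window_bp,
                    collinearity_r2 = config$collinearity_r2)
  signals <- select_signals_all(harmonized, panel, cp)
  readr::write_tsv(signals, file.path(outdir, "signals.tsv"))

  # -- gene binning -----------------------------------------------------
  stage("bin genes")
  assignment <- assign_snps_to_genes(signals, genes, config$flank_bp)
  groups <- merge_gene_blocks(assignment, genes)
  readr::write_tsv(groups %>%
                     mutate(snp_ids = purrr::map_chr(.data$snp_ids, paste,
                                                     collapse = ";")) %>%
                     select(-"genes"),
                   file.path(outdir, "gene_groups.tsv"))
  readr::write_tsv(assignment$unannotated,
                   file.path(outdir, "unannotated_signals.tsv"))

  # -- experiment-wide threshold from multi-signal regions --------------
  sig_groups <- groups %>% filter(.data$n_snps >= 2)
  region_snps <- collect_region_snps(groups, harmonized, config$flank_bp)
  multi_snps <- region_snps %>%
    filter(.data$group_id %in% sig_groups$group_id) %>%
    pull("snp_id") %>% unique()
  if (length(multi_snps)) {
    pruned <- prune_pairwise(panel, multi_snps,
                             window_bp = config$prune_window_bp,
                             r2_thresh = config$prune_r2)
    alpha <- compute_experiment_threshold(pruned$n_retained, config$fwer)
  } else {
    pruned <- NULL
    alpha <- config$fwer  # degenerate: no multi-signal region
  }
  stage("experiment-wide alpha = ", signif(alpha, 3),
        " (", if (is.null(pruned)) 0 else pruned$n_retained,
        " pruned markers)")

  # -- scenario classification -----------------------------------------
  stage("classify regions")
  classifications <- classify_regions(signals, groups, panel, alpha,
                                      config$dependence_r2, config$flank_bp)
  readr::write_tsv(classifications %>% select(-"evidence"),
                   file.path(outdir, "classifications.tsv"))
  readr::write_tsv(classifications %>%
                     select("group_id", "evidence") %>%
                     tidyr::unnest("evidence"),
                   file.path(outdir, "classification_evidence.tsv"))
  thresholds <- c(genome_wide = 5e-8, experiment_wide = alpha,
                  selection = config$p_select)
  scenario_table <- tabulate_scenarios(signals, groups, panel, thresholds,
                                       config$dependence_r2, config$flank_bp)
  readr::write_tsv(scenario_table, file.path(outdir, "scenario_counts.tsv"))
  tpm <- trait_pair_matrix(classifications, traits = sort(names(raw)))
  utils::write.table(unclass(tpm), file.path(outdir, "trait_pair_matrix.tsv"),
                     sep = "\t", quote = FALSE)

  # -- gene scores ------------------------------------------------------
  stage("gene scores")
  scores <- score_all_genes(groups, harmonized, panel, config$flank_bp) %>%
    fdr_adjust_within_trait()
  readr::write_tsv(scores, file.path(outdir, "gene_scores.tsv"))
  q_thresh <- config$gene_q_thresh %||% (config$fwer / length(raw))
  selection <- select_pleiotropic_genes(scores, region_snps, panel,
                                        classifications,
                                        q_thresh = q_thresh,
                                        minp_thresh = alpha,
                                        dependence_r2 = config$dependence_r2)
  readr::write_tsv(selection, file.path(outdir, "pleiotropic_genes.tsv"))

  # -- haplotype stage --------------------------------------------------
  haplo <- NULL
  target <- classifications %>%
    filter(.data$scenario %in% c("III", "mixed")) %>%
    arrange(.data$group_id) %>% head(1)
  if (nrow(target) == 1) {
    stage("haplotypes for group ", target$group_name)
    blocks <- four_gamete_blocks(panel, target$chrom,
                                 max(1, target$start - config$flank_bp),
                                 target$end + config$flank_bp,
                                 window_bp = config$haplo_window_bp,
                                 gamete_freq_min = config$gamete_freq_min)
    focal_sig <- signals %>%
      filter(.data$chrom == target$chrom,
             .data$pos >= target$start - config$flank_bp,
             .data$pos <= target$end + config$flank_bp,
             .data$p_j < alpha)
    focal <- focal_sig %>%
      left_join(panel$markers %>%
                  select("snp_id", "allele_a", "allele_b"),
                by = "snp_id") %>%
      mutate(allele = ifelse(.data$beta_j > 0, .data$allele_b,
                             .data$allele_a)) %>%
      select("snp_id", "trait", "allele")
    bid <- purrr::map_lgl(blocks$snp_ids, ~ any(focal$snp_id %in% .x))
    if (any(bid)) {
      blk <- blocks[which(bid)[1], ]
      haplo <- haplotype_report(panel, blk,
                                focal %>%
                                  filter(.data$snp_id %in% blk$snp_ids[[1]]),
                                freq_min = config$haplo_freq_min)
      readr::write_tsv(haplo$haplotypes,
                       file.path(outdir, "haplotype_frequencies.tsv"))
      readr::write_tsv(haplo$focal %>%
                         mutate(haplotypes = purrr::map_chr(
                           .data$haplotypes, paste, collapse = ";")),
                       file.path(outdir, "haplotype_focal.tsv"))
    }
  }

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("pleiogene")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("sim", "sumstats", "panel_prefix",
                                  "genes_path"))],
    n_traits = length(raw),
    rows = list(
      input = purrr::map_int(raw, nrow),
      qc_retained = purrr::map_int(qc, ~ nrow(.x$sumstats)),
      harmonized = purrr::map_int(harmonized, nrow),
      signals = nrow(signals),
      gene_groups = nrow(groups),
      multi_signal_groups = nrow(sig_groups),
      pruned_markers = if (is.null(pruned)) 0L else pruned$n_retained,
      pleiotropic_genes = nrow(selection)
    ),
    experiment_wide_alpha = alpha,
    gene_q_thresh = q_thresh
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(panel = panel, genes = genes, qc = qc, harmonized = harmonized,
         signals = signals, groups = groups, region_snps = region_snps,
         pruned = pruned, alpha = alpha,
         classifications = classifications,
         scenario_table = scenario_table, trait_pairs = tpm,
         scores = scores, selection = selection, haplotypes = haplo,
         manifest = manifest, outdir = outdir,
         truth = if (!is.null(config$sim)) truth_table(config$sim) else NULL),
    class = "pleio_run"
  )
}

#' @export
print.pleio_run <- function(x, ...) {
  cat("<pleio_run> ", x$manifest$n_traits, " trait(s); ",
      x$manifest$rows$signals, " signal(s); ",
      x$manifest$rows$gene_groups, " gene group(s); alpha = ",
      signif(x$alpha, 3), "; ", x$manifest$rows$pleiotropic_genes,
      " pleiotropic gene(s)\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline One-row summary of a pipeline run.
#' @param x A `pleio_run`.
#' @param ... Unused.
#' @export
glance.pleio_run <- function(x, ...) {
  tibble(n_traits = x$manifest$n_traits,
         n_signals = x$manifest$rows$signals,
         n_gene_groups = x$manifest$rows$gene_groups,
         n_multi_signal_groups = x$manifest$rows$multi_signal_groups,
         pruned_markers = x$manifest$rows$pruned_markers,
         experiment_wide_alpha = x$alpha,
         n_pleiotropic_genes = x$manifest$rows$pleiotropic_genes)
}
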