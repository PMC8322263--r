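#' Experiment-wide Bonferroni threshold from a pruned marker count
#'
#' `alpha = 0.05 / pruned_count`, where `pruned_count` is the number of
#' LD-independent markers left after windowed pairwise pruning of all SNPs
#' mapped to the multi-signal regions (see [prune_pairwise()]). With the
#' 8772 independent markers of the motivating analysis this gives 5.70e-6.
#'
#' @param pruned_count Positive count of independent markers.
#' @param fwer Family-wise error rate (default 0.05).
#' @return The experiment-wide significance threshold.
#' @export
compute_experiment_threshold <- function(pruned_count, fwer = 0.05) {
  if (length(pruned_count) != 1 || is.na(pruned_count) || pruned_count < 1) {
    abort("`pruned_count` must be a positive count.")
  }
  fwer / pruned_count
}

#' Classify a multi-signal region into pleiotropy/heterogeneity scenarios
#'
#' Signals (across all traits) falling in one gene group are filtered to
#' joint p-values below the experiment-wide threshold; each unordered pair of
#' the survivors is labelled dependent when its panel r-squared is at least
#' `dependence_r2` (the same SNP selected for two traits is dependent with
#' r-squared 1). With `T` the number of distinct traits:
#' \itemize{
#'   \item fewer than two surviving signals: `"single"`;
#'   \item no cross-trait dependent pair: `"I"` (gene-level pleiotropy) when
#'     `T >= 2`; with one trait, `"II"` (allelic heterogeneity) when some
#'     pair is LD-independent, otherwise `"none"` (within-trait dependence
#'     only);
#'   \item a cross-trait dependent pair and no independent pair among
#'     distinct markers: `"III"` (SNP-level pleiotropy);
#'   \item both a cross-trait dependent pair and an independent pair:
#'     `"mixed"`.
#' }
#' Within-trait dependent pairs never create Scenario III on their own; they
#' are reported in the evidence table.
#'
#' @param signals Tibble of signals in one group (columns `trait`, `snp_id`,
#'   `p_j`; `pos` recommended).
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param alpha Experiment-wide threshold from
#'   [compute_experiment_threshold()].
#' @param dependence_r2 LD-dependence threshold (default 0.2).
#' @return One-row tibble: `scenario`, `n_signals`, `n_traits`, `traits`
#'   (`";"`-joined), `evidence` (list-column of pairwise rows: `snp_i`,
#'   `trait_i`, `snp_j`, `trait_j`, `r2`, `dependent`, `cross_trait`).
#' @export
classify_region <- function(signals, panel, alpha, dependence_r2 = 0.2) {
  sig <- as_tibble(signals) %>% filter(.data$p_j < alpha)
  ev <- tibble(snp_i = character(), trait_i = character(),
               snp_j = character(), trait_j = character(),
               r2 = numeric(), dependent = logical(),
               cross_trait = logical())
  base <- function(scn) {
    tibble(scenario = scn, n_signals = nrow(sig),
           n_traits = dplyr::n_distinct(sig$trait),
           traits = paste(sort(unique(sig$trait)), collapse = ";"),
           evidence = list(ev))
  }
  if (nrow(sig) <= 1) return(base("single"))
  cmb <- utils::combn(nrow(sig), 2)
  rows <- purrr::map_dfr(seq_len(ncol(cmb)), function(q) {
    i <- cmb[1, q]; j <- cmb[2, q]
    r2 <- if (sig$snp_id[i] == sig$snp_id[j]) 1 else
      ld_r2(panel, sig$snp_id[i], sig$snp_id[j])
    tibble(snp_i = sig$snp_id[i], trait_i = sig$trait[i],
           snp_j = sig$snp_id[j], trait_j = sig$trait[j],
           r2 = r2,
           dependent = !is.na(r2) & r2 >= dependence_r2,
           cross_trait = sig$trait[i] != sig$trait[j])
  })
  ev <- rows
  n_traits <- dplyr::n_distinct(sig$trait)
  D <- any(rows$dependent & rows$cross_trait)
  indep <- any(!rows$dependent & rows$snp_i != rows$snp_j)
  scn <- if (!D) {
    if (n_traits >= 2) "I" else if (indep) "II" else "none"
  } else if (!indep) "III" else "mixed"
  out <- base(scn)
  out$evidence <- list(ev)
  out
}

#' Classify every multi-signal gene group of a study
#'
#' Assigns selected signals to gene groups by position (block boundaries plus
#' flank) and classifies each group at the given threshold.
#'
#' @param signals All traits' signals ([select_signals_all()]).
#' @param groups Gene groups from [merge_gene_blocks()].
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param alpha Experiment-wide threshold.
#' @param dependence_r2 LD-dependence threshold (default 0.2).
#' @param flank_bp Flank around block boundaries (default 10 kb).
#' @return One row per group: group columns plus the [classify_region()]
#'   fields.
#' @export
classify_regions <- function(signals, groups, panel, alpha,
                             dependence_r2 = 0.2, flank_bp = 1e4) {
  groups <- as_tibble(groups)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sig <- signals %>%
      filter(.data$chrom == g$chrom,
             .data$pos >= g$start - flank_bp,
             .data$pos <= g$end + flank_bp)
    cls <- classify_region(sig, panel, alpha, dependence_r2)
    bind_cols(g %>% select("group_id", "group_name", "chrom", "start",
                           "end"),
              cls)
  })
}

#' Tabulate scenario counts over a threshold grid
#'
#' Counts of multi-signal gene groups per scenario at each significance
#' threshold (layout of the motivating study's Table 1: the genome-wide
#' 5e-8, the experiment-wide threshold, and the selection threshold 1e-5).
#'
#' @param signals All traits' signals.
#' @param groups Gene groups.
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param thresholds Named numeric vector of p-value thresholds.
#' @param dependence_r2,flank_bp Passed to [classify_regions()].
#' @return A tibble `scenario` x threshold (one column per threshold name)
#'   of group counts, scenarios ordered II, I, III, mixed (then single/none
#'   rows for completeness).
#' @export
tabulate_scenarios <- function(signals, groups, panel,
                               thresholds = c(genome_wide = 5e-8,
                                              experiment_wide = 5.7e-6,
                                              selection = 1e-5),
                               dependence_r2 = 0.2, flank_bp = 1e4) {
  long <- purrr::imap_dfr(thresholds, function(alpha, nm) {
    classify_regions(signals, groups, panel, alpha, dependence_r2,
                     flank_bp) %>%
      count(.data$scenario) %>%
      mutate(threshold = nm)
  })
  lev <- c("II", "I", "III", "mixed", "single", "none")
  long %>%
    mutate(scenario = factor(.data$scenario, levels = lev)) %>%
    tidyr::complete(scenario = factor(lev, levels = lev),
                    threshold = names(thresholds),
                    fill = list(n = 0L)) %>%
    tidyr::pivot_wider(names_from = "threshold", values_from = "n") %>%
    select("scenario", all_of(names(thresholds))) %>%
    arrange(.data$scenario)
}

#' Trait-pair overlap matrix
#'
#' Square matrix over traits: the upper triangle counts gene groups where
#' LD-independent markers associate with the trait pair (Scenario I
#' evidence), the lower triangle groups where the same or LD-dependent
#' markers associate with both traits (Scenario III evidence); mixed groups
#' contribute to both triangles.
#'
#' @param classifications Output of [classify_regions()].
#' @param traits Optional trait universe fixing the matrix order.
#' @return An integer matrix of class `trait_pair_matrix` with trait
#'   dimnames.
#' @export
trait_pair_matrix <- function(classifications, traits = NULL) {
  ev <- classifications %>%
    filter(.data$scenario %in% c("I", "III", "mixed")) %>%
    select("group_id", "evidence") %>%
    tidyr::unnest("evidence") %>%
    filter(.data$cross_trait)
  if (is.null(traits)) {
    traits <- sort(unique(c(ev$trait_i, ev$trait_j,
                            unlist(strsplit(classifications$traits, ";")))))
  }
  M <- matrix(0L, length(traits), length(traits),
              dimnames = list(traits, traits))
  if (nrow(ev)) {
    pairs <- ev %>%
      mutate(t1 = pmin(.data$trait_i, .data$trait_j),
             t2 = pmax(.data$trait_i, .data$trait_j)) %>%
      group_by(.data$group_id, .data$t1, .data$t2) %>%
      summarise(any_dep = any(.data$dependent),
                any_indep = any(!.data$dependent), .groups = "drop")
    for (q in seq_len(nrow(pairs))) {
      t1 <- pairs$t1[q]; t2 <- pairs$t2[q]
      i <- match(t1, traits); j <- match(t2, traits)
      a <- min(i, j); b <- max(i, j)
      if (pairs$any_indep[q]) M[a, b] <- M[a, b] + 1L  # upper: independent
      if (pairs$any_dep[q]) M[b, a] <- M[b, a] + 1L    # lower: dependent
    }
  }
  structure(M, class = c("trait_pair_matrix", "matrix", "array"))
}

#' @export
print.trait_pair_matrix <- function(x, ...) {
  cat("<trait_pair_matrix> upper: LD-independent overlaps;",
      "lower: LD-dependent overlaps\n")
  print(unclass(x))
  invisible(x)
}
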