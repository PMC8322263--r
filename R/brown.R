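#' Brown's combined p-value for correlated tests
#'
#' Fisher's statistic `X = -2 sum(log p)` referred to a scaled chi-square
#' whose scale `c` and effective degrees of freedom `f` are moment-matched
#' to the correlation among tests: `E = 2k`, `Var = 4k + 2 sum_{i<j} cov_ij`
#' with `cov_ij = s(3.263 + 0.710 s + 0.027 s^2)` where `s = r^2` (the
#' Kost-McDermott polynomial approximation to `cov(-2 log p_i, -2 log p_j)`,
#' evaluated at the squared genotype correlation — the adaptation for
#' two-sided association p-values, whose chi-square statistics correlate as
#' `r^2`; this keeps the null combined test calibrated at high LD), then
#' `c = Var / (2E)`, `f = 2 E^2 / Var` and
#' `p = P(chi2_f > X / c)`. With a single test it reduces to that test's
#' p-value; with uncorrelated tests it reduces to Fisher's method.
#'
#' @param pvalues Numeric p-values in (0, 1]; zero is an error (floor before
#'   calling, e.g. at 1e-300).
#' @param R Signed LD correlation matrix matching `pvalues` (only `|r|` is
#'   used, so the result is invariant to sign flips and to reordering applied
#'   consistently to both arguments).
#' @return One-row tibble: `k`, `X`, `c`, `f`, `p_brown`.
#' @export
brown_score <- function(pvalues, R) {
  k <- length(pvalues)
  stopifnot(k >= 1)
  if (any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1]; floor zeros before calling.")
  }
  R <- as.matrix(R)
  stopifnot(all(dim(R) == k))
  X <- -2 * sum(log(pvalues))
  E <- 2 * k
  s <- R[upper.tri(R)]^2
  cov_sum <- sum(s * (3.263 + 0.710 * s + 0.027 * s^2))
  V <- 4 * k + 2 * cov_sum
  cc <- V / (2 * E)
  ff <- 2 * E^2 / V
  tibble(k = k, X = X, c = cc, f = ff,
         p_brown = pchisq(X / cc, df = ff, lower.tail = FALSE))
}

#' LD-corrected Brown gene scores for every gene group and trait
#'
#' Scores each (gene group, trait) over all QC'd SNPs inside the block plus
#' flanking regions that are present and polymorphic in the panel; p-values
#' are floored at 1e-300 before logs. Groups with an empty usable SNP set
#' for a trait yield no row (reported via a message).
#'
#' @param groups Gene groups from [merge_gene_blocks()].
#' @param sumstats_list Named list of harmonized per-trait tables.
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param flank_bp Flank in bp (default 10 kb).
#' @return A tibble: `group_id`, `group_name`, `trait`, `k`, `X`, `c`, `f`,
#'   `p_brown`.
#' @export
score_all_genes <- function(groups, sumstats_list, panel, flank_bp = 1e4) {
  region <- collect_region_snps(groups, sumstats_list, flank_bp)
  usable <- panel$markers$snp_id[!panel$markers$monomorphic]
  dropped <- region %>% filter(!.data$snp_id %in% usable)
  if (nrow(dropped)) {
    inform(paste0(dplyr::n_distinct(dropped$snp_id),
                  " region SNP(s) absent or monomorphic in panel; dropped."))
  }
  region <- region %>% filter(.data$snp_id %in% usable)
  key <- groups %>% select("group_id", "group_name")
  out <- region %>%
    group_by(.data$group_id, .data$trait) %>%
    group_modify(function(d, grp) {
      R <- ld_matrix(panel, d$snp_id, regularize = FALSE)
      brown_score(pmax(d$p, 1e-300), R)
    }) %>%
    ungroup() %>%
    left_join(key, by = "group_id") %>%
    select("group_id", "group_name", "trait", "k", "X", "c", "f", "p_brown")
  empty <- tidyr::expand_grid(group_id = groups$group_id,
                              trait = names(sumstats_list)) %>%
    anti_join(out, by = c("group_id", "trait"))
  if (nrow(empty)) {
    inform(paste0(nrow(empty), " (group, trait) score(s) absent: ",
                  "no usable SNPs."))
  }
  out
}

#' Benjamini-Hochberg adjustment of gene scores within each trait
#'
#' @param scores Output of [score_all_genes()].
#' @return `scores` with a `q` column, adjusted separately per trait over
#'   all scored genes of that trait.
#' @export
fdr_adjust_within_trait <- function(scores) {
  scores %>%
    group_by(.data$trait) %>%
    mutate(q = p.adjust(.data$p_brown, method = "BH")) %>%
    ungroup()
}

#' Select pleiotropic genes from adjusted gene scores
#'
#' Keeps gene groups whose FDR-adjusted Brown score passes `q_thresh` in at
#' least two traits. Groups whose minimal SNP p-value across the qualifying
#' traits exceeds `minp_thresh` (the experiment-wide threshold) are retained
#' with category `"minp_fail"`; survivors are categorised as
#' `"marker_confirmed"` when the marker-based classification already found a
#' cross-trait scenario (I, III or mixed) for the group, otherwise by the LD
#' between the qualifying traits' top SNPs: `"independent_markers"` (all
#' cross-trait pairs r-squared below `dependence_r2`), `"dependent_markers"`
#' (all at or above), or `"mixed"`.
#'
#' @param scores Adjusted scores from [fdr_adjust_within_trait()].
#' @param region_snps SNP-level records per group and trait
#'   ([collect_region_snps()]), used for minimal p-values and top SNPs.
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param classifications Optional [classify_regions()] output for the
#'   marker-confirmed category.
#' @param q_thresh FDR threshold; the motivating analysis used
#'   0.05 / 27 traits = 0.0018.
#' @param minp_thresh Experiment-wide SNP threshold
#'   ([compute_experiment_threshold()]).
#' @param dependence_r2 LD threshold separating the categories (default 0.2).
#' @return A tibble: `group_id`, `group_name`, `traits` (qualifying,
#'   `";"`-joined), `n_traits`, `min_p`, `category`.
#' @export
select_pleiotropic_genes <- function(scores, region_snps, panel,
                                     classifications = NULL,
                                     q_thresh = 0.05 / 27,
                                     minp_thresh = 5.7e-6,
                                     dependence_r2 = 0.2) {
  qual <- scores %>% filter(.data$q < q_thresh)
  cand <- qual %>%
    group_by(.data$group_id, .data$group_name) %>%
    summarise(traits = list(sort(unique(.data$trait))), .groups = "drop") %>%
    filter(lengths(.data$traits) >= 2)
  if (nrow(cand) == 0) {
    return(tibble(group_id = integer(), group_name = character(),
                  traits = character(), n_traits = integer(),
                  min_p = numeric(), category = character()))
  }
  confirmed <- if (!is.null(classifications)) {
    classifications$group_id[classifications$scenario %in%
                               c("I", "III", "mixed")]
  } else integer(0)
  purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    g <- cand[i, ]
    trs <- g$traits[[1]]
    snp <- region_snps %>%
      filter(.data$group_id == g$group_id, .data$trait %in% trs)
    min_p <- min(snp$p)
    cat <- if (min_p > minp_thresh) {
      "minp_fail"
    } else if (g$group_id %in% confirmed) {
      "marker_confirmed"
    } else {
      top <- snp %>%
        group_by(.data$trait) %>%
        slice(which.min(.data$p)) %>%
        ungroup()
      cmb <- utils::combn(nrow(top), 2)
      r2 <- purrr::map_dbl(seq_len(ncol(cmb)), function(q) {
        i1 <- cmb[1, q]; j1 <- cmb[2, q]
        if (top$snp_id[i1] == top$snp_id[j1]) 1 else
          ld_r2(panel, top$snp_id[i1], top$snp_id[j1])
      })
      dep <- !is.na(r2) & r2 >= dependence_r2
      if (all(dep)) "dependent_markers"
      else if (all(!dep)) "independent_markers"
      else "mixed"
    }
    tibble(group_id = g$group_id, group_name = g$group_name,
           traits = paste(trs, collapse = ";"),
           n_traits = length(trs), min_p = min_p, category = cat)
  })
}
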