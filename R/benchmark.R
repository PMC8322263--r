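#' Standard synthetic benchmark configuration
#'
#' Three traits and thirty two-block regions with planted scenarios
#' (8 x gene-level pleiotropy, 7 x allelic heterogeneity, 8 x SNP-level
#' pleiotropy, 7 x mixed), cycling through the trait pairs. Each causal
#' variant has noncentrality `lambda` on the z-scale (default 6, i.e. a
#' clearly genome-wide-significant signal at the default GWAS size of
#' 50,000 per trait); the reference panel holds 1,000 individuals with 15
#' markers per LD block. Used by the recovery benchmarks and the worked
#' examples.
#'
#' @param seed Integer seed.
#' @param lambda Planted noncentrality per causal variant (z-scale).
#' @param gwas_n GWAS sample size per trait.
#' @param n_individuals Reference-panel size.
#' @param n_regions Number of planted regions (default 30; scenario counts
#'   are spread as evenly as 8/7/8/7 over the default).
#' @param decoy_fraction QC decoy fraction (default 0.05).
#' @return A [sim_config()]; the planted truth is available via
#'   [truth_table()].
#' @export
benchmark_config <- function(seed = 1L, lambda = 6, gwas_n = 50000,
                             n_individuals = 1000, n_regions = 30,
                             decoy_fraction = 0.05) {
  traits <- c("T1", "T2", "T3")
  pair_cycle <- list(c("T1", "T2"), c("T2", "T3"), c("T1", "T3"))
  scn <- rep(c("I", "II", "III", "mixed"), length.out = n_regions)
  scn <- scn[order(match(scn, c("I", "II", "III", "mixed")))]
  loci <- vector("list", n_regions)
  for (k in seq_len(n_regions)) {
    b1 <- 2L * k - 1L; b2 <- 2L * k
    s1 <- snp_id_make(b1, 8L); s2 <- snp_id_make(b2, 8L)
    pr <- pair_cycle[[(k - 1) %% 3 + 1]]
    gene <- sprintf("GENE%02d_%s", k, scn[k])
    loci[[k]] <- switch(
      scn[k],
      I = planted_locus("I", gene, tibble(
        snp_id = c(s1, s2), trait = pr, lambda = lambda)),
      II = planted_locus("II", gene, tibble(
        snp_id = c(s1, s2), trait = pr[c(1, 1)], lambda = lambda)),
      III = planted_locus("III", gene, tibble(
        snp_id = c(s1, s1), trait = pr, lambda = lambda),
        blocks = c(b1, b2)),
      mixed = planted_locus("mixed", gene, tibble(
        snp_id = c(s1, s1, s2), trait = c(pr, pr[1]),
        lambda = lambda))
    )
  }
  sim_config(
    n_individuals = n_individuals,
    n_blocks = 2L * n_regions,
    snps_per_block = 15,
    traits = traits,
    gwas_n_per_trait = gwas_n,
    planted_loci = loci,
    decoy_fraction = decoy_fraction,
    seed = seed
  )
}

#' Score recovered scenario classifications against the planted truth
#'
#' Joins pipeline classifications to the truth table by gene name (the
#' antisense twin merged into a block counts as its host gene) and tabulates
#' planted versus recovered scenario per class.
#'
#' @param classifications Output of [classify_regions()] (or
#'   `$classifications` of a [run_pipeline()] result).
#' @param truth A [truth_table()].
#' @return A tibble: `gene_name`, `planted`, `recovered`, `correct`.
#' @export
score_recovery <- function(classifications, truth) {
  planted <- truth %>%
    distinct(.data$gene_name, planted = .data$scenario)
  rec <- classifications %>%
    select("group_name", recovered = "scenario") %>%
    tidyr::separate_rows("group_name", sep = ";") %>%
    rename(gene_name = "group_name")
  planted %>%
    left_join(rec, by = "gene_name") %>%
    mutate(recovered = dplyr::coalesce(.data$recovered, "single"),
           correct = .data$planted == .data$recovered)
}
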