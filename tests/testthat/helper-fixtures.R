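# hand-built panels and tables used across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# panel from an explicit dosage matrix (markers evenly spaced on one chrom
# unless pos given); alleles default A (ref) / G (counted)
toy_panel <- function(G, chrom = 1L, pos = NULL, alleles = NULL,
                      ids = NULL) {
  m <- ncol(G)
  ids <- ids %||% sprintf("snp%02d", seq_len(m))
  pos <- pos %||% (1000L + 1000L * seq_len(m))
  if (is.null(alleles)) alleles <- cbind(rep("A", m), rep("G", m))
  new_genotype_panel(
    tibble::tibble(snp_id = ids, chrom = rep_len(chrom, m), pos = pos,
                   allele_a = alleles[, 1], allele_b = alleles[, 2]),
    G)
}

# diploid panel sampled from explicit haplotype pool (rows = haplotypes)
pool_panel <- function(hap, w, n, seed = 1, ...) {
  set.seed(seed)
  h1 <- sample.int(nrow(hap), n, replace = TRUE, prob = w)
  h2 <- sample.int(nrow(hap), n, replace = TRUE, prob = w)
  toy_panel(hap[h1, , drop = FALSE] + hap[h2, , drop = FALSE], ...)
}

# minimal well-formed sumstats row(s)
toy_sumstats <- function(n = 1, snp_id = sprintf("snp%02d", seq_len(n)),
                         chrom = 1L, pos = 1000L + 1000L * seq_len(n),
                         a1 = "G", a2 = "A", freq = 0.3, beta = 0.01,
                         se = 0.01, p = NULL, N = 10000, info = 0.99) {
  z <- beta / se
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos, a1 = a1,
                 a2 = a2, freq = freq, beta = beta, se = se,
                 p = p %||% pmax(2 * stats::pnorm(-abs(z)), 1e-300),
                 n = N, info = info)
}

# small benchmark-style study cached per session (used by several files)
cached_small_study <- local({
  store <- new.env()
  function(seed = 7) {
    key <- paste0("s", seed)
    if (is.null(store[[key]])) {
      cfg <- sim_config(
        n_individuals = 600, n_blocks = 8, snps_per_block = 10,
        traits = c("T1", "T2"),
        gwas_n_per_trait = 50000,
        planted_loci = list(
          planted_locus("I", "GI", tibble::tibble(
            snp_id = c("b001_s05", "b002_s05"), trait = c("T1", "T2"),
            lambda = 7)),
          planted_locus("III", "GIII", tibble::tibble(
            snp_id = c("b003_s05", "b003_s05"), trait = c("T1", "T2"),
            lambda = 7), blocks = 3:4)
        ),
        decoy_fraction = 0.1, seed = seed)
      store[[key]] <- simulate_study(cfg)
    }
    store[[key]]
  }
})
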