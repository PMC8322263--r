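#' Simulate GWAS summary statistics for one trait
#'
#' Marginal z-scores are drawn chromosome by chromosome from a multivariate
#' normal with mean `R %*% lambda` and covariance `R`, where `R` is the
#' panel's signed genotype correlation matrix over the chromosome's markers
#' (regularised to an eigenvalue floor of 1e-6) and `lambda` the planted
#' noncentrality vector for the trait. This is exactly the model the
#' conditional-selection stage assumes — including the small sample LD the
#' panel shows between blocks — so planted effects propagate to neighbours
#' in proportion to reference LD, as for a real GWAS analysed against a
#' well-matched reference. Effect sizes
#' are recovered as `beta = z * se` with `se = 1 / sqrt(2 f (1-f) n)`;
#' reported frequencies are panel frequencies with a small binomial
#' perturbation; INFO is drawn in [0.9, 1]. Monomorphic panel markers are not
#' reported (a GWAS would not test them).
#'
#' Optionally a set of labelled decoy rows is appended, each failing exactly
#' one QC filter (low INFO, low MAF, strand-ambiguous alleles, indel alleles,
#' non-autosomal chromosome); the labels are returned in the `"decoys"`
#' attribute so QC removals can be asserted exactly.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param truth Truth table from [truth_table()] (rows for other traits are
#'   ignored).
#' @param trait Trait name.
#' @param n GWAS sample size.
#' @param seed Integer seed.
#' @param decoy_fraction Decoy rows as a fraction of the panel marker count.
#' @return A tibble with columns `snp_id, chrom, pos, a1, a2, freq, beta, se,
#'   p, n, info` (`a1` is the effect allele = panel `allele_b`), with
#'   attribute `"decoys"`: a tibble of `snp_id`, `reason`.
#' @export
simulate_sumstats <- function(panel, truth, trait, n, seed,
                              decoy_fraction = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  causal <- truth %>%
    filter(!is.na(.data$snp_id), .data$trait == !!trait)
  unknown <- setdiff(causal$snp_id, panel$markers$snp_id)
  if (length(unknown)) {
    abort(paste0("causal SNP(s) not in panel: ",
                 paste(unknown, collapse = ", ")))
  }
  set.seed(seed)
  mk <- panel$markers %>% filter(!.data$monomorphic)
  lam <- setNames(rep(0, nrow(mk)), mk$snp_id)
  lam[causal$snp_id[causal$snp_id %in% names(lam)]] <-
    causal$lambda[causal$snp_id %in% names(lam)]

  z <- numeric(nrow(mk))
  for (b in unique(mk$chrom)) {
    idx <- which(mk$chrom == b)
    G <- panel$genotypes[, mk$snp_id[idx], drop = FALSE]
    R <- regularize_psd(cor(G))
    ed <- eigen(R, symmetric = TRUE)
    L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nrow(R))
    z[idx] <- as.numeric(R %*% lam[idx] + L %*% rnorm(length(idx)))
  }
  f <- pmin(pmax(rbinom(nrow(mk), size = 2 * round(n),
                        prob = mk$freq_b) / (2 * round(n)),
                 1 / (2 * n)), 1 - 1 / (2 * n))
  se <- 1 / sqrt(2 * f * (1 - f) * n)
  out <- tibble(
    snp_id = mk$snp_id, chrom = mk$chrom, pos = mk$pos,
    a1 = mk$allele_b, a2 = mk$allele_a,
    freq = f, beta = z * se, se = se,
    p = pmax(2 * pnorm(-abs(z)), 1e-300),
    n = n, info = runif(nrow(mk), 0.9, 1)
  )

  n_decoy <- round(decoy_fraction * nrow(mk))
  decoys <- tibble(snp_id = character(), reason = character())
  if (n_decoy > 0) {
    reasons <- rep_len(c("low_info", "low_maf", "ambiguous", "indel",
                         "non_autosome"), n_decoy)
    zd <- rnorm(n_decoy)
    fd <- runif(n_decoy, 0.2, 0.5)
    a1 <- rep("A", n_decoy); a2 <- rep("G", n_decoy)
    info <- runif(n_decoy, 0.91, 1)
    chrom <- sample(unique(mk$chrom), n_decoy, replace = TRUE)
    fd[reasons == "low_maf"] <- runif(sum(reasons == "low_maf"), 0.01, 0.09)
    info[reasons == "low_info"] <- runif(sum(reasons == "low_info"), 0.5, 0.89)
    a1[reasons == "ambiguous"] <- "A"; a2[reasons == "ambiguous"] <- "T"
    a1[reasons == "indel"] <- "AT"; a2[reasons == "indel"] <- "A"
    chrom[reasons == "non_autosome"] <- 23L
    sed <- 1 / sqrt(2 * fd * (1 - fd) * n)
    decoy_tab <- tibble(
      snp_id = sprintf("decoy_%04d", seq_len(n_decoy)),
      chrom = as.integer(chrom),
      pos = sample.int(1000000L, n_decoy),
      a1 = a1, a2 = a2, freq = fd, beta = zd * sed, se = sed,
      p = pmax(2 * pnorm(-abs(zd)), 1e-300), n = n, info = info
    )
    out <- bind_rows(out, decoy_tab)
    decoys <- tibble(snp_id = decoy_tab$snp_id, reason = reasons)
  }
  attr(out, "decoys") <- decoys
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper generating the reference panel, gene annotation, truth
#' table and one summary-statistics table per trait from a single
#' configuration. Per-trait seeds are derived deterministically from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `pleio_study` with elements `panel`, `genes`,
#'   `truth`, `sumstats` (named list of tibbles), `decoys` (tibble with
#'   `trait`, `snp_id`, `reason`), `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_reference_panel(config)
  genes <- simulate_gene_annotation(config, panel)
  truth <- truth_table(config)
  sumstats <- list()
  decoys <- list()
  for (i in seq_along(config$traits)) {
    tr <- config$traits[i]
    ss <- simulate_sumstats(
      panel, truth, tr, n = config$gwas_n_per_trait[[tr]],
      seed = (config$seed + 7919L * i) %% .Machine$integer.max,
      decoy_fraction = config$decoy_fraction
    )
    decoys[[tr]] <- mutate(attr(ss, "decoys"), trait = tr, .before = 1)
    sumstats[[tr]] <- ss
  }
  structure(
    list(panel = panel, genes = genes, truth = truth, sumstats = sumstats,
         decoys = bind_rows(decoys), config = config),
    class = "pleio_study"
  )
}

#' @export
print.pleio_study <- function(x, ...) {
  cat("<pleio_study> ", length(x$sumstats), " trait(s), ",
      nrow(x$panel$markers), " panel markers, ", nrow(x$genes),
      " genes, ", sum(!is.na(x$truth$snp_id)), " planted causal rows\n",
      sep = "")
  invisible(x)
}

# eigenvalue-floor regularisation; rescaled to unit diagonal.
# returns the input unchanged when it is already comfortably PSD.
regularize_psd <- function(R, floor = 1e-6) {
  ed <- eigen(R, symmetric = TRUE, only.values = TRUE)
  if (min(ed$values) >= floor) return(R)
  ed <- eigen(R, symmetric = TRUE)
  d <- pmax(ed$values, floor)
  R2 <- ed$vectors %*% (d * t(ed$vectors))
  stats::cov2cor(R2)
}
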