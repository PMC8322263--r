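# enumerate all two-locus gamete frequencies by EM-free counting when phase
# is unambiguous, and by grid search otherwise

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # at most one heterozygous site per individual -> no ambiguity
  hap <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  G <- rbind(hap[1, ] + hap[1, ], hap[2, ] + hap[2, ],
             hap[1, ] + hap[1, ], hap[2, ] + hap[2, ],
             hap[1, ] + hap[2, ])  # one double-het individual is excluded
  G <- G[1:4, , drop = FALSE]
  panel <- toy_panel(G)
  est <- estimate_haplotypes(panel, panel$markers$snp_id)
  expect_equal(sum(est$frequency), 1)
  expect_setequal(round(est$frequency[est$frequency > 0], 6), 0.5)
  expect_setequal(est$haplotype[est$frequency > 0.4], c("AAA", "GGG"))
})

test_that("two-SNP double-heterozygote EM matches a grid-search maximiser", {
  # individuals: 3 x AB/AB-coupling evidence, 1 x double het (ambiguous),
  # 2 x unambiguous singles
  G <- rbind(c(2, 2), c(2, 2), c(0, 0), c(1, 1), c(1, 1), c(2, 1))
  panel <- toy_panel(G)
  est <- estimate_haplotypes(panel, c("snp01", "snp02"))
  # oracle: haplotypes 11,00,10,01 with freqs (p11,p00,p10,p01);
  # maximise multinomial likelihood over a fine simplex grid
  loglik <- function(f) {
    # f = c(p11, p00, p10, p01); individual likelihoods:
    li <- c(f[1]^2, f[1]^2, f[2]^2,
            2 * f[1] * f[2] + 2 * f[3] * f[4],
            2 * f[1] * f[2] + 2 * f[3] * f[4],
            2 * f[1] * f[3])
    sum(log(pmax(li, 1e-300)))
  }
  grid <- seq(0, 1, by = 0.02)
  best <- NULL; bestll <- -Inf
  for (a in grid) for (b in grid) for (c1 in grid) {
    d <- 1 - a - b - c1
    if (d < -1e-9) next
    ll <- loglik(c(a, b, c1, max(d, 0)))
    if (ll > bestll) { bestll <- ll; best <- c(a, b, c1, max(d, 0)) }
  }
  got <- setNames(rep(0, 4), c("GG", "AA", "GA", "AG"))
  got[est$haplotype] <- est$frequency
  expect_equal(unname(got[c("GG", "AA", "GA", "AG")]), best,
               tolerance = 2e-2)
  # the EM likelihood is at least the grid optimum (finer resolution)
  expect_gte(loglik(unname(got[c("GG", "AA", "GA", "AG")])), bestll - 1e-6)
})

test_that("haplotype frequencies always sum to one", {
  for (s in 1:5) {
    set.seed(s)
    hap <- matrix(rbinom(4 * 5, 1, 0.5), nrow = 4)
    panel <- pool_panel(hap, w = rep(0.25, 4), n = 50, seed = s)
    poly <- panel$markers$snp_id[!panel$markers$monomorphic]
    if (length(poly) < 2) next
    est <- estimate_haplotypes(panel, poly)
    expect_equal(sum(est$frequency), 1, tolerance = 1e-9)
  }
})

test_that("EM matches a brute-force likelihood maximiser on random small instances", {
  # random 3-SNP/40-individual instances; oracle = optim over the simplex of
  # all 8 haplotypes via softmax parameterisation, multi-start
  mult_loglik <- function(f, pairs_list) {
    sum(purrr::map_dbl(pairs_list, function(pp) {
      li <- sum(f[pp[, 1]] * f[pp[, 2]] * ifelse(pp[, 1] == pp[, 2], 1, 2))
      log(max(li, 1e-300))
    }))
  }
  enumerate_pairs <- function(g) {
    # all unordered compatible haplotype index pairs for genotype vector g
    k <- length(g)
    hapmat <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    idx <- seq_len(2^k)
    out <- list()
    for (i in idx) for (j in i:2^k) {
      if (all(hapmat[i, ] + hapmat[j, ] == g)) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
    do.call(rbind, out)
  }
  for (s in 1:6) {
    set.seed(100 + s)
    hap <- matrix(rbinom(3 * 3, 1, 0.5), nrow = 3)
    panel <- pool_panel(hap, w = c(0.5, 0.3, 0.2), n = 40, seed = 100 + s)
    poly <- panel$markers$snp_id[!panel$markers$monomorphic]
    if (length(poly) < 2) next
    G <- panel$genotypes[, poly, drop = FALSE]
    pairs_list <- purrr::map(seq_len(nrow(G)), ~ enumerate_pairs(G[.x, ]))
    k <- length(poly)
    obj <- function(theta) {
      f <- exp(theta) / sum(exp(theta))
      -mult_loglik(f, pairs_list)
    }
    bestll <- -Inf
    for (start in 1:4) {
      set.seed(start)
      o <- optim(rnorm(2^k), obj, method = "BFGS",
                 control = list(maxit = 300))
      bestll <- max(bestll, -o$value)
    }
    est <- estimate_haplotypes(panel, poly)
    # express EM solution over the full 2^k haplotype basis
    hapmat <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    mk <- panel$markers[match(poly, panel$markers$snp_id), ]
    lab <- apply(hapmat, 1, function(h)
      paste(ifelse(h == 1, mk$allele_b, mk$allele_a), collapse = ""))
    f_em <- setNames(rep(0, 2^k), lab)
    f_em[est$haplotype] <- est$frequency
    em_ll <- mult_loglik(unname(f_em), pairs_list)
    expect_gte(em_ll, bestll - 1e-3)  # EM reaches the ML optimum
  }
})

test_that("four-gamete blocks match brute-force adjacent-pair gamete counts", {
  # construct a region with a known recombination point: two independent
  # pools -> all four gametes appear between them
  set.seed(9)
  hapL <- rbind(c(0L, 0L), c(1L, 1L))
  hapR <- rbind(c(0L, 0L), c(1L, 1L))
  n <- 200
  h1L <- sample(1:2, n, TRUE); h2L <- sample(1:2, n, TRUE)
  h1R <- sample(1:2, n, TRUE); h2R <- sample(1:2, n, TRUE)
  G <- cbind(hapL[h1L, ] + hapL[h2L, ], hapR[h1R, ] + hapR[h2R, ])
  panel <- toy_panel(G, pos = c(1000L, 2000L, 3000L, 4000L))
  blocks <- four_gamete_blocks(panel, chrom = 1)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$snp_ids[[1]], c("snp01", "snp02"))
  expect_equal(blocks$snp_ids[[2]], c("snp03", "snp04"))
  # within each pool only 2 gametes -> joined; across: 4 gametes -> split
  est <- estimate_haplotypes(panel, c("snp02", "snp03"))
  expect_gte(sum(est$frequency >= 0.01), 4)
})

test_that("block span never exceeds the window cap", {
  g <- rbinom(100, 2, 0.5)
  panel <- toy_panel(cbind(g, g, g),
                     pos = c(1000L, 200000L, 900000L))
  blocks <- four_gamete_blocks(panel, chrom = 1, window_bp = 5e5)
  expect_true(all(blocks$end - blocks$start <= 5e5))
  expect_equal(nrow(blocks), 2)
})

test_that("haplotype report keeps only common haplotypes and maps focal alleles", {
  # pool with three haplotypes at 60/32/8%: the 8% one must not be reported
  hap <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 0L, 1L))
  panel <- pool_panel(hap, w = c(0.6, 0.32, 0.08), n = 800, seed = 3)
  blk <- panel$markers$snp_id
  rep <- haplotype_report(panel, blk,
                          tibble::tibble(snp_id = "snp02", trait = "T1",
                                         allele = "G"))
  expect_lte(nrow(rep$haplotypes), 2)
  expect_true(all(rep$haplotypes$frequency > 0.10))
  # snp02's G allele rides only on the GGG haplotype
  expect_equal(rep$focal$haplotypes[[1]], "GGG")
})

test_that("alleles planted on different ancestral haplotypes are flagged", {
  hap <- rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L))
  panel <- pool_panel(hap, w = c(0.4, 0.4, 0.2), n = 600, seed = 5)
  focal <- tibble::tibble(snp_id = c("snp01", "snp02"),
                          trait = c("T1", "T2"), allele = "G")
  rep <- haplotype_report(panel, panel$markers$snp_id, focal)
  expect_true(rep$different_haplotypes)
  expect_equal(nrow(rep$disjoint_pairs), 1)
  # single-haplotype population: every focal allele maps to it
  hap1 <- rbind(c(1L, 1L))
  panel1 <- toy_panel(rbind(hap1 + hap1, hap1 + hap1))
  rep1 <- haplotype_report(panel1, panel1$markers$snp_id,
                           tibble::tibble(snp_id = "snp01", trait = "T1",
                                          allele = "G"))
  expect_equal(nrow(rep1$haplotypes), 1)
  expect_equal(rep1$focal$haplotypes[[1]], rep1$haplotypes$haplotype)
  expect_false(rep1$different_haplotypes)
  # focal SNP outside the block is an error
  expect_error(haplotype_report(panel, "snp01",
                                tibble::tibble(snp_id = "snp02",
                                               trait = "T1", allele = "G")),
               "outside")
})
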