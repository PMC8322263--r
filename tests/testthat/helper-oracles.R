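# independent brute-force oracles shared by the unit and acceptance suites

# naive repeated full scan for the leftmost violating pair, recomputing r2
# from scratch each round (windowed pairwise pruning oracle)
prune_oracle <- function(panel, ids, window, thr) {
  mk <- panel$markers[match(ids, panel$markers$snp_id), ]
  mk <- mk[order(mk$chrom, mk$pos), ]
  alive <- mk$snp_id
  repeat {
    worst <- NULL
    for (i in seq_along(alive)) {
      for (j in seq_along(alive)) {
        if (j <= i) next
        a <- alive[i]; b <- alive[j]
        ma <- mk[mk$snp_id == a, ]; mb <- mk[mk$snp_id == b, ]
        if (ma$chrom != mb$chrom) next
        if (abs(ma$pos - mb$pos) > window) next
        if (ld_r2(panel, a, b) <= thr) next
        worst <- c(a, b); break
      }
      if (!is.null(worst)) break
    }
    if (is.null(worst)) return(alive)
    ma <- mk[mk$snp_id == worst[1], ]; mb <- mk[mk$snp_id == worst[2], ]
    maf <- function(m) min(m$freq_b, 1 - m$freq_b)
    drop <- if (maf(mb) < maf(ma) ||
                (maf(mb) == maf(ma) && mb$pos >= ma$pos)) worst[2] else
                  worst[1]
    alive <- setdiff(alive, drop)
  }
}

# maximum-likelihood two-marker haplotype frequencies by vectorised grid
# search over the 4-haplotype simplex (hap order: 11, 10, 01, 00 in
# allele-b dosage)
pair_grid_ml <- function(g1, g2, step = 0.02) {
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  gr <- seq(0, 1, by = step)
  grid <- expand.grid(f11 = gr, f10 = gr, f01 = gr)
  grid <- grid[grid$f11 + grid$f10 + grid$f01 <= 1 + 1e-9, ]
  f11 <- grid$f11; f10 <- grid$f10; f01 <- grid$f01
  f00 <- pmax(1 - f11 - f10 - f01, 0)
  pb <- function(x) pmax(x, 1e-12)
  # genotype-pair probabilities under random mating
  ll <- cnt["0", "0"] * log(pb(f00^2)) +
    cnt["0", "1"] * log(pb(2 * f00 * f01)) +
    cnt["0", "2"] * log(pb(f01^2)) +
    cnt["1", "0"] * log(pb(2 * f00 * f10)) +
    cnt["1", "1"] * log(pb(2 * f00 * f11 + 2 * f10 * f01)) +
    cnt["1", "2"] * log(pb(2 * f01 * f11)) +
    cnt["2", "0"] * log(pb(f10^2)) +
    cnt["2", "1"] * log(pb(2 * f10 * f11)) +
    cnt["2", "2"] * log(pb(f11^2))
  i <- which.max(ll)
  list(freq = c(`11` = f11[i], `10` = f10[i], `01` = f01[i],
                `00` = f00[i]),
       loglik = ll[i])
}

pair_loglik <- function(g1, g2, f) {
  # f named 11, 10, 01, 00
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  pb <- function(x) max(x, 1e-12)
  sum(cnt["0", "0"] * log(pb(f["00"]^2)),
      cnt["0", "1"] * log(pb(2 * f["00"] * f["01"])),
      cnt["0", "2"] * log(pb(f["01"]^2)),
      cnt["1", "0"] * log(pb(2 * f["00"] * f["10"])),
      cnt["1", "1"] * log(pb(2 * f["00"] * f["11"] + 2 * f["10"] * f["01"])),
      cnt["1", "2"] * log(pb(2 * f["01"] * f["11"])),
      cnt["2", "0"] * log(pb(f["10"]^2)),
      cnt["2", "1"] * log(pb(2 * f["10"] * f["11"])),
      cnt["2", "2"] * log(pb(f["11"]^2)))
}

# independent greedy block scan from externally supplied pair decisions
blocks_from_decisions <- function(pos, pass, window_bp) {
  stopifnot(length(pass) == length(pos) - 1)
  blocks <- list(); a <- 1
  for (i in seq_along(pass)) {
    if (!pass[i] || pos[i + 1] - pos[a] > window_bp) {
      blocks[[length(blocks) + 1]] <- a:i
      a <- i + 1
    }
  }
  blocks[[length(blocks) + 1]] <- a:length(pos)
  blocks
}
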