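# individual-level simulation of one LD region: genotypes, phenotype,
# marginal summary statistics, and the exact least-squares oracle

sim_region_individual <- function(n = 5000, m = 10, seed = 1,
                                  n_causal = 2, beta_abs = c(0.08, 0.15)) {
  set.seed(seed)
  # Gaussian-copula AR(1) haplotypes: adjacent-marker LD ~ rho, never
  # collinear, all markers polymorphic at frequency f
  rho <- runif(1, 0.4, 0.7)
  f <- runif(m, 0.15, 0.5)
  draw_hap <- function() {
    e <- matrix(rnorm(n * m), n, m)
    z <- e
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * e[, j]
    sweep(z, 2, qnorm(1 - f), `>`) + 0L
  }
  X <- draw_hap() + draw_hap()
  causal <- sample.int(m, n_causal)
  b <- numeric(m)
  b[causal] <- sample(c(-1, 1), n_causal, TRUE) *
    runif(n_causal, beta_abs[1], beta_abs[2])
  y <- as.numeric(X %*% b + rnorm(n))
  # marginal regressions (closed form)
  xm <- colMeans(X); ym <- mean(y)
  Sxx <- colSums(X^2) - n * xm^2
  Sxy <- as.numeric(crossprod(X, y)) - n * xm * ym
  bm <- Sxy / Sxx
  rss <- sum((y - ym)^2) - bm * Sxy
  se <- sqrt(rss / (n - 2) / Sxx)
  z <- bm / se
  panel <- toy_panel(X)
  ss <- tibble::tibble(
    snp_id = panel$markers$snp_id, chrom = 1L, pos = panel$markers$pos,
    a1 = "G", a2 = "A", freq = xm / 2, beta = bm, se = se,
    p = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n, info = 1)
  list(panel = panel, sumstats = ss, X = X, y = y, b_true = b,
       causal = sort(causal))
}

# exact multiple regression on the individual-level data
exact_joint <- function(reg, ids = NULL) {
  X <- reg$X
  colnames(X) <- reg$panel$markers$snp_id
  if (!is.null(ids)) X <- X[, ids, drop = FALSE]
  fit <- stats::lm(reg$y ~ X)
  co <- summary(fit)$coefficients[-1, , drop = FALSE]
  tibble::tibble(snp_id = sub("^X", "", rownames(co)),
                 beta = co[, 1], se = co[, 2], p = co[, 4])
}

# exhaustive best-subset oracle at a selection threshold: among subsets of
# size <= size_cap whose joint p-values all clear p_select and whose panel
# r-squared stays below the collinearity cap, pick the largest (ties:
# smallest worst joint p, then first in position order)
best_subset_oracle <- function(reg, p_select = 1e-5, size_cap = 5,
                               collinearity_r2 = 0.9) {
  ids <- reg$panel$markers$snp_id
  m <- length(ids)
  R_full <- suppressWarnings(cor(reg$X))
  best <- character(0); best_key <- c(0, Inf)
  for (size in 1:size_cap) {
    for (sub in utils::combn(m, size, simplify = FALSE)) {
      if (size > 1) {
        r2 <- R_full[sub, sub]^2
        if (max(r2[upper.tri(r2)]) >= collinearity_r2) next
      }
      recs <- reg$sumstats[sub, ]
      fit <- tryCatch(
        joint_fit(recs, ld_matrix(reg$panel, ids[sub])),
        error = function(e) NULL)
      if (is.null(fit)) next
      pj <- fit$estimates$p_j
      if (any(pj >= p_select)) next
      key <- c(size, max(pj))
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best <- ids[sub]; best_key <- key
      }
    }
  }
  best
}
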