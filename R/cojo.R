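#' Parameters for conditional-and-joint signal selection
#'
#' @param p_select Selection threshold on the conditional/joint p-value
#'   (default 1e-5, the recommended threshold for reliable independent
#'   signals).
#' @param window_bp Independence horizon: marker pairs farther apart than
#'   this (or on different chromosomes) are treated as uncorrelated
#'   (default 10 Mb).
#' @param collinearity_r2 Candidates with r-squared above this against any
#'   selected signal are flagged collinear and excluded from candidacy
#'   (default 0.9).
#' @param max_iter Cap on stepwise iterations (default 100).
#' @return A list of class `cojo_params`.
#' @export
cojo_params <- function(p_select = 1e-5, window_bp = 1e7,
                        collinearity_r2 = 0.9, max_iter = 100) {
  if (p_select <= 0 || p_select >= 1) abort("`p_select` must be in (0,1).")
  structure(list(p_select = p_select, window_bp = window_bp,
                 collinearity_r2 = collinearity_r2,
                 max_iter = as.integer(max_iter)),
            class = "cojo_params")
}

# per-record diagonal of X'X on the n scale and X'y, reconstructed from
# marginal statistics: D_j = 2 f_j (1 - f_j) n_j, X'y_j = D_j * beta_j
cojo_moments <- function(records) {
  D <- 2 * records$freq * (1 - records$freq) * records$n
  list(D = D, S = sqrt(2 * records$freq * (1 - records$freq)),
       Xy = D * records$beta,
       var_y_j = D * records$se^2 + D * records$beta^2 / records$n)
}

#' Joint multiple-SNP regression from marginal summary statistics
#'
#' Reconstructs multiple-regression coefficients from marginal GWAS effects
#' and a signed LD matrix: with `D = diag(2 f (1-f) n)` and
#' `B[j,k] = r[j,k] * 2 sqrt(f_j(1-f_j) f_k(1-f_k)) * min(n_j, n_k)`, the
#' joint effects are `beta_J = B^{-1} (D beta)`. The phenotypic variance is
#' estimated as the median of `2 f (1-f) (n se^2 + beta^2)` across records;
#' standard errors come from the diagonal of `B^{-1}` times the residual
#' variance; p-values are two-sided normal. Marker pairs farther than
#' `window_bp` apart, or on different chromosomes, are treated as
#' uncorrelated.
#'
#' @param records Tibble of harmonized records (columns `snp_id, chrom, pos,
#'   freq, beta, se, p, n`), one per model term, in the order of `R`.
#' @param R Signed LD correlation matrix matching `records`.
#' @param n_eff Effective sample size for the residual degrees of freedom;
#'   default `min(records$n)` (the conservative choice when per-SNP sample
#'   sizes differ).
#' @param var_y Phenotypic variance; default estimated from `records` as
#'   above (pass the trait-wide median when fitting small models).
#' @param window_bp Independence horizon in bp (default 10 Mb).
#' @return An object of class `cojo_joint`; see [tidy.cojo_joint()].
#' @export
joint_fit <- function(records, R, n_eff = NULL, var_y = NULL,
                      window_bp = 1e7) {
  records <- as_tibble(records)
  k <- nrow(records)
  stopifnot(k >= 1, all(dim(R) == k))
  mom <- cojo_moments(records)
  if (is.null(var_y)) var_y <- median(mom$var_y_j)
  if (is.null(n_eff)) n_eff <- min(records$n)
  R <- as.matrix(R)
  if (all(c("chrom", "pos") %in% names(records)) && k > 1) {
    far <- outer(records$chrom, records$chrom, `!=`) |
      abs(outer(records$pos, records$pos, `-`)) > window_bp
    R[far] <- 0
  }
  diag(R) <- 1
  minn <- outer(records$n, records$n, pmin)
  B <- R * (mom$S %o% mom$S) * minn
  diag(B) <- mom$D
  if (k > 1) {
    rc <- rcond(B)
    if (!is.finite(rc) || rc < 1e-12) {
      off <- abs(R); diag(off) <- 0
      ij <- which(off == max(off), arr.ind = TRUE)[1, ]
      abort(paste0("collinear markers in joint model: ",
                   records$snp_id[ij[1]], " / ", records$snp_id[ij[2]],
                   " (|r| = ", signif(max(off), 3), ")"))
    }
  }
  beta_j <- solve(B, mom$Xy)
  fitted <- sum(beta_j * mom$Xy)
  sigma2 <- (var_y * n_eff - fitted) / (n_eff - k)
  sigma2 <- max(sigma2, var_y * 1e-8)
  se_j <- sqrt(sigma2 * diag(solve(B)))
  p_j <- pmax(2 * pnorm(-abs(beta_j / se_j)), 1e-300)
  est <- records %>%
    mutate(beta_j = as.numeric(beta_j), se_j = se_j, p_j = p_j)
  structure(list(estimates = est, k = k, n_eff = n_eff, var_y = var_y,
                 sigma2 = sigma2),
            class = "cojo_joint")
}

#' @export
print.cojo_joint <- function(x, ...) {
  cat("<cojo_joint> ", x$k, " term(s), n_eff ", x$n_eff, "\n", sep = "")
  print(x$estimates %>% select(dplyr::any_of(
    c("snp_id", "beta", "se", "p", "beta_j", "se_j", "p_j"))))
  invisible(x)
}

#' @describeIn joint_fit Tidy the per-term joint estimates.
#' @param x A `cojo_joint` object.
#' @param ... Unused.
#' @export
tidy.cojo_joint <- function(x, ...) x$estimates

#' @describeIn joint_fit One-row model summary.
#' @export
glance.cojo_joint <- function(x, ...) {
  tibble(k = x$k, n_eff = x$n_eff, var_y = x$var_y, sigma2 = x$sigma2)
}

#' Conditional statistics of a candidate given selected signals
#'
#' The candidate's effect conditioned on the currently selected set, computed
#' as its term in the joint fit of `selected + candidate`. Candidates in high
#' LD with a selected signal (r-squared above the collinearity cap) are
#' flagged and carry no conditional estimate.
#'
#' @param candidate One-row tibble of the candidate's harmonized record.
#' @param selected Tibble of the selected signals' harmonized records (zero
#'   rows allowed: the conditional equals the marginal).
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param params A [cojo_params()].
#' @param var_y Optional trait-wide phenotypic variance.
#' @return One-row tibble: `snp_id`, `beta_c`, `se_c`, `p_c`, `collinear`.
#' @export
conditional_p <- function(candidate, selected, panel,
                          params = cojo_params(), var_y = NULL) {
  candidate <- as_tibble(candidate)
  stopifnot(nrow(candidate) == 1)
  if (nrow(selected) == 0) {
    return(tibble(snp_id = candidate$snp_id, beta_c = candidate$beta,
                  se_c = candidate$se, p_c = candidate$p, collinear = FALSE))
  }
  if (candidate$snp_id %in% selected$snp_id) {
    abort("candidate is already selected.")
  }
  r <- purrr::map_dbl(selected$snp_id, ld_r, panel = panel,
                      snp_j = candidate$snp_id)
  if (any(r^2 > params$collinearity_r2, na.rm = TRUE)) {
    return(tibble(snp_id = candidate$snp_id, beta_c = NA_real_,
                  se_c = NA_real_, p_c = NA_real_, collinear = TRUE))
  }
  recs <- bind_rows(selected, candidate)
  R <- ld_matrix(panel, recs$snp_id)
  fit <- joint_fit(recs, R, var_y = var_y, window_bp = params$window_bp)
  row <- fit$estimates[nrow(recs), ]
  tibble(snp_id = row$snp_id, beta_c = row$beta_j, se_c = row$se_j,
         p_c = row$p_j, collinear = FALSE)
}

#' Stepwise selection of independent association signals for one trait
#'
#' Forward-backward stepwise conditional regression against the LD reference:
#' seed with the genome-wide smallest marginal p-value below `p_select`; then
#' repeatedly add the candidate with the smallest conditional p-value below
#' `p_select` (ties broken by smaller p, then chromosome and position),
#' refitting the joint model after each addition and dropping any selected
#' signal whose joint p-value rises above the threshold. Selection runs per
#' chromosome (equivalent to genome-wide under the 10 Mb independence
#' horizon) and is fully deterministic.
#'
#' @param sumstats Harmonized summary statistics for one trait.
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param params A [cojo_params()].
#' @param trait Optional trait label carried into the output.
#' @return A tibble of signals: `trait, snp_id, chrom, pos, freq, beta, se,
#'   p, n, beta_j, se_j, p_j` (zero rows when nothing passes).
#' @export
select_signals <- function(sumstats, panel, params = cojo_params(),
                           trait = NA_character_) {
  x <- as_tibble(sumstats)
  empty <- tibble(trait = character(), snp_id = character(),
                  chrom = integer(), pos = integer(), freq = numeric(),
                  beta = numeric(), se = numeric(), p = numeric(),
                  n = numeric(), beta_j = numeric(), se_j = numeric(),
                  p_j = numeric())
  if (nrow(x) == 0) return(empty)
  keep <- x$snp_id %in% panel$markers$snp_id[!panel$markers$monomorphic]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0) return(empty)
  var_y <- median(cojo_moments(x)$var_y_j)
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    sel <- cojo_chrom_stepwise(x %>% filter(.data$chrom == ch) %>%
                                 arrange(.data$pos),
                               panel, params, var_y)
    if (!is.null(sel)) out[[length(out) + 1]] <- sel
  }
  if (!length(out)) return(empty)
  bind_rows(out) %>%
    mutate(trait = trait, .before = 1) %>%
    arrange(.data$chrom, .data$pos)
}

# stepwise engine for one chromosome; vectorised conditional p over all
# candidates via the Schur complement of the selected block
cojo_chrom_stepwise <- function(sub, panel, params, var_y) {
  m <- nrow(sub)
  G <- panel$genotypes[, sub$snp_id, drop = FALSE]
  mom <- cojo_moments(sub)
  D <- mom$D; S <- mom$S; Xy <- mom$Xy
  pos <- sub$pos; nvec <- sub$n
  sel <- integer(0)

  seed_pick <- function() {
    ord <- order(sub$p, sub$pos)
    if (sub$p[ord[1]] < params$p_select) ord[1] else NA_integer_
  }
  first <- seed_pick()
  if (is.na(first)) return(NULL)
  sel <- first

  for (iter in seq_len(params$max_iter)) {
    k <- length(sel)
    Rsc <- suppressWarnings(cor(G[, sel, drop = FALSE], G,
                                use = "pairwise.complete.obs"))
    Rsc[is.na(Rsc)] <- 0
    far <- abs(outer(pos[sel], pos, `-`)) > params$window_bp
    Rsc[far] <- 0
    Rss <- Rsc[, sel, drop = FALSE]
    Bss <- Rss * (S[sel] %o% S[sel]) * outer(nvec[sel], nvec[sel], pmin)
    diag(Bss) <- D[sel]
    A <- tryCatch(solve(Bss), error = function(e) NULL)
    if (is.null(A)) break
    AXy <- A %*% Xy[sel]
    fitted0 <- sum(Xy[sel] * AXy)

    cand <- setdiff(seq_len(m), sel)
    collinear <- cand[apply(Rsc[, cand, drop = FALSE]^2, 2, max) >
                        params$collinearity_r2]
    cand <- setdiff(cand, collinear)
    if (!length(cand)) break
    U <- Rsc[, cand, drop = FALSE] *
      (S[sel] %o% S[cand]) *
      outer(nvec[sel], nvec[cand], pmin)
    AU <- A %*% U
    s_c <- D[cand] - colSums(U * AU)
    t_c <- Xy[cand] - as.numeric(crossprod(U, AXy))
    valid <- s_c > 1e-8 * D[cand]
    beta_c <- ifelse(valid, t_c / s_c, NA_real_)
    n_eff <- pmin(min(nvec[sel]), nvec[cand])
    sigma2 <- (var_y * n_eff - fitted0 - beta_c^2 * s_c) / (n_eff - k - 1)
    sigma2 <- pmax(sigma2, var_y * 1e-8)
    se_c <- sqrt(sigma2 / s_c)
    p_c <- 2 * pnorm(-abs(beta_c / se_c))
    p_c[!valid] <- NA_real_
    if (all(is.na(p_c)) || min(p_c, na.rm = TRUE) >= params$p_select) break
    ord <- order(p_c, pos[cand], na.last = TRUE)
    sel <- c(sel, cand[ord[1]])

    # backward step: drop signals whose joint p rose above the threshold
    repeat {
      fit <- joint_fit(sub[sel, , drop = FALSE],
                       chrom_R(G, sel), var_y = var_y,
                       window_bp = params$window_bp)
      pj <- fit$estimates$p_j
      if (length(sel) <= 1 || max(pj) < params$p_select) break
      sel <- sel[-which.max(pj)]
    }
  }

  fit <- joint_fit(sub[sel, , drop = FALSE], chrom_R(G, sel),
                   var_y = var_y, window_bp = params$window_bp)
  fit$estimates %>%
    filter(.data$p_j < params$p_select) %>%
    select("snp_id", "chrom", "pos", "freq", "beta", "se", "p", "n",
           "beta_j", "se_j", "p_j")
}

chrom_R <- function(G, sel) {
  R <- suppressWarnings(cor(G[, sel, drop = FALSE],
                            use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

#' Select signals for every trait of a study
#'
#' @param sumstats_list Named list of harmonized per-trait tables.
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param params A [cojo_params()].
#' @return Signals of all traits, row-bound.
#' @export
select_signals_all <- function(sumstats_list, panel,
                               params = cojo_params()) {
  purrr::imap(sumstats_list,
              ~ select_signals(.x, panel, params, trait = .y)) %>%
    bind_rows()
}
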