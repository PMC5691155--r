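# Shared small synthetic worlds and independent oracles used across the
# suite. Everything is generated in code under fixed seeds.

# A modest causal world: 5 autosomal loci + 1 X locus, strong h2, used by
# several module tests. Built once per test run.
causal_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_individuals = 3000, n_snps_autosomal = 600, n_snps_x = 100,
        ld_block_size = 10, ld_decay = 0.5, n_loci = 5,
        distinct_per_locus = c(1, 3), h2_autosomal = 0.5, h2_x = 0.1,
        prevalence = 0.59,
        pathway_spec = list(
          list(name = "pwA", loci = c(1, 2), slopes = c(t2 = 0.5)),
          list(name = "pwB", loci = c(3, 4), slopes = c(t2 = -0.5))),
        seed = 7)
      panel <- simulate_panel(cfg)
      traits <- simulate_traits(panel, cfg)
      cache <<- list(cfg = cfg, panel = panel,
                     phen = traits$phenotypes, truth = traits$truth,
                     cov = traits$phenotypes[, c("age", "pc1", "pc2")])
    }
    cache
  }
})

# independent brute-force single-linkage clustering of positions by gap
oracle_single_linkage <- function(chr, pos, gap_bp) {
  out <- integer(length(pos))
  nxt <- 0L
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    idx <- idx[order(pos[idx])]
    lab <- integer(length(idx))
    for (i in seq_along(idx)) {
      if (i == 1L || pos[idx[i]] - pos[idx[i - 1L]] > gap_bp) nxt <- nxt + 1L
      lab[i] <- nxt
    }
    out[idx] <- lab
  }
  out
}

# exhaustive all-subsets conditional-selection oracle on a tiny candidate
# set: the subset S such that every SNP in S stays significant conditional
# on the rest of S (plus covariates) and no SNP outside S is significant
# conditional on S. Linear model version (valid for the quantitative toys).
oracle_all_subsets <- function(panel, phenotype, covariates, members, p_gw) {
  n <- length(phenotype)
  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  cond_p <- function(snp, given) {
    X <- cbind(X0, panel$dosage[, given, drop = FALSE],
               panel$dosage[, snp])
    fit <- stats::lm.fit(X, phenotype)
    df <- n - fit$rank
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    se <- sqrt(diag(chol2inv(R)) * sum(fit$residuals^2) / df)
    tv <- fit$coefficients[ncol(X)] / se[length(se)]
    2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  }
  k <- length(members)
  hits <- list()
  for (mask in 0:(2^k - 1)) {
    S <- members[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    inside_ok <- all(vapply(S, function(s) {
      cond_p(s, setdiff(S, s)) < p_gw
    }, logical(1)))
    outside_ok <- all(vapply(setdiff(members, S), function(s) {
      cond_p(s, S) >= p_gw
    }, logical(1)))
    if (inside_ok && outside_ok) hits[[length(hits) + 1L]] <- S
  }
  hits
}

# restricted log-likelihood evaluated from first principles (dense algebra,
# no shared code with the package's REML internals)
oracle_reml_loglik <- function(y, X, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(y) %*% P %*% y))
}
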