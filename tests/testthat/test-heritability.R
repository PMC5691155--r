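# GRM construction, AI-REML variance components, liability transformation,
# variance explained by a score.

test_that("GRM matches the element-wise formula oracle", {
  set.seed(3)
  X <- matrix(rbinom(15, 2, 0.4), 5, 3)
  colnames(X) <- paste0("s", 1:3)
  panel <- genotype_panel(X)
  g <- build_grm(panel)
  p <- colMeans(X) / 2
  A <- matrix(0, 5, 5)
  for (j in 1:5) for (k in 1:5) {
    A[j, k] <- mean((X[j, ] - 2 * p) * (X[k, ] - 2 * p) / (2 * p * (1 - p)))
  }
  expect_equal(unname(g$K), A, tolerance = 1e-12)
  expect_true(isSymmetric(g$K))
})

test_that("GRM: duplicated individuals, monomorphic exclusion, diagonal mean", {
  set.seed(4)
  X <- matrix(rbinom(300, 2, runif(30, 0.1, 0.5)), 10, 30, byrow = TRUE)
  X[2, ] <- X[1, ]                      # identical twins / duplicate sample
  X <- cbind(X, mono = rep(2, 10))      # monomorphic column
  panel <- genotype_panel(X)
  expect_message(g <- build_grm(panel), "monomorphic")
  expect_equal(g$m, 30L)
  expect_equal(g$K[1, 2], g$K[1, 1], tolerance = 1e-12)
  expect_equal(g$K[1, 2], g$K[2, 2], tolerance = 1e-12)

  cfg <- sim_config(n_individuals = 20000, n_snps_autosomal = 300,
                    ld_decay = 0, seed = 6)
  big <- build_grm(simulate_panel(cfg))
  expect_lt(abs(mean(diag(big$K)) - 1), 0.02)
})

test_that("liability transformation has its closed-form multipliers", {
  expect_equal(liability_transform(0, 0.3), 0)
  # K = 0.5: multiplier 0.25 / phi(0)^2 = pi/2
  expect_equal(liability_transform(1, 0.5), pi / 2, tolerance = 1e-12)
  # K = 0.59: frozen from numerical evaluation of t = qnorm(0.41), z = phi(t)
  expect_equal(liability_transform(1, 0.59), 1.6011, tolerance = 1e-3)
  # linearity in h2 and continuity in K
  expect_equal(liability_transform(0.4, 0.59),
               0.4 * liability_transform(1, 0.59), tolerance = 1e-12)
  ks <- seq(0.55, 0.63, by = 0.001)
  mult <- liability_transform(1, 0.59)
  expect_true(all(abs(vapply(ks, liability_transform, 1, h2_observed = 1) -
                        mult) < 0.1))
  expect_error(liability_transform(0.5, 1), "prevalence")
})

test_that("REML on a pure-noise phenotype reports a null genetic fraction", {
  set.seed(12)
  cfg <- sim_config(n_individuals = 1000, n_snps_autosomal = 400,
                    ld_decay = 0, seed = 13)
  panel <- simulate_panel(cfg)
  g <- build_grm(panel)
  fit <- fit_aireml(rnorm(1000), grms = g)
  expect_lt(fit$h2_obs_total, 2 * fit$h2_total_se + 1e-6)
})

test_that("REML maximises the restricted likelihood (grid-search oracle)", {
  set.seed(14)
  n <- 150
  cfg <- sim_config(n_individuals = n, n_snps_autosomal = 200, ld_decay = 0,
                    seed = 15)
  panel <- simulate_panel(cfg)
  Z <- scale(panel$dosage)
  y <- drop(Z %*% rnorm(200, sd = sqrt(0.5 / 200))) + rnorm(n, sd = sqrt(0.5))
  g <- build_grm(panel)
  X <- matrix(1, n, 1)
  fit <- fit_aireml(y, grms = g)
  expect_true(fit$converged)
  # log-likelihood trajectory is non-decreasing, final gradient small
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_lt(fit$gradient_norm, 0.1)
  # brute-force grid on (sigma_g, sigma_e)
  grid <- seq(0.02, 1.2 * var(y), length.out = 30)
  ll <- outer(grid, grid, Vectorize(function(a, b) {
    oracle_reml_loglik(y, X, list(g$K), c(a, b))
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  res <- grid[2] - grid[1]
  expect_lt(abs(fit$vc[1] - grid[best[1]]), res + 1e-9)
  expect_lt(abs(fit$vc[2] - grid[best[2]]), res + 1e-9)
  # and the fitted maximum is at least the grid maximum
  expect_gte(fit$loglik + 1e-6, max(ll))
})

test_that("single-component REML recovers planted h2 (scaled-down sweep)", {
  # 40 replicates at n = 800 / m = 500 keep this inside the suite budget;
  # the asymptotic 2-SE coverage is unchanged by the scale-down.
  reps <- 40
  n <- 800; m <- 500
  hit <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = n, n_snps_autosomal = m, ld_decay = 0,
                      seed = 100 + r)
    panel <- simulate_panel(cfg)
    set.seed(200 + r)
    Z <- scale(panel$dosage)
    yg <- drop(Z %*% rnorm(m, sd = sqrt(0.5 / m)))
    y <- yg + rnorm(n, sd = sqrt(1 - var(yg)))
    h2_real <- var(yg) / var(y)   # realised planted heritability
    fit <- fit_aireml(y, grms = build_grm(panel))
    if (abs(fit$h2_obs_total - h2_real) < 2 * fit$h2_total_se) hit <- hit + 1L
  }
  expect_gte(hit / reps, 0.9)
})

test_that("two-component REML recovers an autosomal/X-like split", {
  reps <- 15
  n <- 700
  hit_a <- 0L; hit_x <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = n, n_snps_autosomal = 300,
                      n_snps_x = 150, ld_decay = 0, seed = 300 + r)
    panel <- simulate_panel(cfg)
    ga <- build_grm(panel, chr = "1")
    gx <- build_grm(panel, chr = "X")
    set.seed(400 + r)
    Za <- scale(panel$dosage[, panel$snp_meta$chr == "1"])
    Zx <- scale(panel$dosage[, panel$snp_meta$chr == "X"])
    ya <- drop(Za %*% rnorm(300, sd = sqrt(0.6 / 300)))
    yx <- drop(Zx %*% rnorm(150, sd = sqrt(0.2 / 150)))
    y <- ya + yx + rnorm(n, sd = sqrt(max(1 - var(ya) - var(yx), 0.05)))
    ha <- var(ya) / var(y); hx <- var(yx) / var(y)
    fit <- fit_aireml(y, grms = list(auto = ga, x = gx))
    if (abs(fit$h2_obs[["auto"]] - ha) < 2 * fit$h2_se[1]) hit_a <- hit_a + 1L
    if (abs(fit$h2_obs[["x"]] - hx) < 2 * fit$h2_se[2]) hit_x <- hit_x + 1L
  }
  expect_gte(hit_a / reps, 0.85)
  expect_gte(hit_x / reps, 0.85)
})

test_that("identity-only GRM split is reported as degenerate, not silent", {
  set.seed(21)
  n <- 300
  g <- structure(list(K = diag(n), m = 1L, ids = paste0("id", 1:n)),
                 class = "grm")
  fit <- fit_aireml(rnorm(n), grms = g)
  # genetic and residual components are unidentifiable; expect a boundary
  # hit or an honestly huge standard error, never a confident split
  expect_true(any(fit$boundary) || all(fit$vc_se > 0.05))
})

test_that("a polygenic score as fixed effect removes its share of h2", {
  set.seed(22)
  n <- 1200; m <- 400
  cfg <- sim_config(n_individuals = n, n_snps_autosomal = m, ld_decay = 0,
                    seed = 23)
  panel <- simulate_panel(cfg)
  Z <- scale(panel$dosage)
  b <- rnorm(m, sd = sqrt(0.5 / m))
  yg <- drop(Z %*% b)
  y <- yg + rnorm(n, sd = sqrt(1 - var(yg)))
  g <- build_grm(panel)

  # oracle score = the full true genetic value: decrease ~ full h2
  sv <- score_variance_explained(y, grms = g, score = yg)
  expect_lt(abs(sv$decrease_obs[["total"]] - sv$fit_without$h2_obs_total),
            2 * sv$fit_without$h2_total_se)

  # independent score: decrease ~ 0
  sv0 <- score_variance_explained(y, grms = g, score = rnorm(n))
  expect_lt(abs(sv0$decrease_obs[["total"]]), 2 * sv0$fit_without$h2_total_se)

  # half the causal variance: decrease ~ half the genetic fraction
  half <- drop(Z[, 1:(m / 2)] %*% b[1:(m / 2)])
  svh <- score_variance_explained(y, grms = g, score = half)
  expect_lt(abs(svh$decrease_obs[["total"]] - 0.5 * sv$fit_without$h2_obs_total),
            0.2)

  # constant score warns and explains nothing
  expect_warning(svc <- score_variance_explained(y, grms = g,
                                                 score = rep(1, n)),
                 "constant")
  expect_equal(unname(svc$decrease_obs[["total"]]), 0)
})

test_that("GRMs round-trip through the TSV triplet format", {
  set.seed(25)
  panel <- genotype_panel(matrix(rbinom(60, 2, 0.4), 6, 10))
  g <- build_grm(panel)
  f <- tempfile(fileext = ".grm.tsv")
  write_grm(g, f)
  back <- read_grm(f)
  expect_equal(back$K[g$ids, g$ids], g$K, tolerance = 1e-6)
  expect_equal(back$m, g$m)
})
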