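# Joint weights, locus/pathway/overall scores, trait scans, q-values.

test_that("joint betas match an independently coded Newton solver", {
  # tiny ten-individual dataset, two SNPs, no separation
  G <- cbind(s1 = c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1),
             s2 = c(1, 0, 1, 2, 0, 2, 1, 1, 0, 2))
  y <- c(0, 0, 1, 1, 1, 1, 0, 1, 0, 0)
  panel <- genotype_panel(G)
  wt <- reestimate_joint_betas(panel, y, snp_ids = c("s1", "s2"))
  # independent Newton-Raphson on the log-likelihood
  X <- cbind(1, G)
  b <- rep(0, 3)
  for (i in 1:50) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    b <- b + solve(t(X) %*% (X * W), t(X) %*% (y - mu))
  }
  expect_equal(wt$beta, unname(b[2:3]), tolerance = 1e-8)

  # duplicated SNP columns abort with names
  pan2 <- genotype_panel(cbind(a = G[, 1], b = G[, 1]))
  expect_error(reestimate_joint_betas(pan2, y, snp_ids = c("a", "b")),
               "collinear")
})

test_that("orthogonal SNPs keep their marginal effects in the joint fit", {
  set.seed(52)
  n <- 5000
  G <- sapply(rep(0.3, 3), function(f) rbinom(n, 2, f))
  colnames(G) <- paste0("s", 1:3)
  eta <- -0.5 + 0.3 * G[, 1] + 0.25 * G[, 2] + 0.2 * G[, 3]
  y <- rbinom(n, 1, plogis(eta))
  panel <- genotype_panel(G)
  wt <- reestimate_joint_betas(panel, y, snp_ids = colnames(G))
  marg <- refit_logistic(panel, y, snp_ids = colnames(G))
  expect_true(all(abs(wt$beta - marg$beta) < 2 * sqrt(wt$se^2 + marg$se^2)))
})

test_that("locus scores are the weighted dosage sums", {
  # one SNP, dosage 2, beta 0.5 -> score 1.0
  panel <- genotype_panel(cbind(s1 = c(2, 0)))
  loci <- data.frame(locus = 1L)
  loci$distinct <- list("s1")
  wt <- data.frame(snp = "s1", beta = 0.5)
  sc <- compute_locus_scores(panel, wt, loci)
  expect_equal(unname(sc[, 1]), c(1, 0))

  # 3-SNP locus on 4 individuals: hand-computed matrix product
  G <- rbind(c(0, 1, 2), c(2, 2, 0), c(1, 0, 1), c(0, 0, 0))
  colnames(G) <- c("a", "b", "c")
  pan <- genotype_panel(G)
  w2 <- data.frame(snp = c("a", "b", "c"), beta = c(0.1, -0.2, 0.3))
  l2 <- data.frame(locus = 1L)
  l2$distinct <- list(c("a", "b", "c"))
  sc2 <- compute_locus_scores(pan, w2, l2)
  expect_equal(unname(sc2[, 1]), drop(G %*% c(0.1, -0.2, 0.3)),
               tolerance = 1e-12)

  # all-zero weights give all-zero scores
  w0 <- data.frame(snp = c("a", "b", "c"), beta = 0)
  expect_true(all(compute_locus_scores(pan, w0, l2) == 0))

  # missing dosages are mean-imputed with a message
  G[1, "a"] <- NA
  expect_message(sc3 <- compute_locus_scores(genotype_panel(G), w2, l2),
                 "mean-imputed")
  expect_false(anyNA(sc3))
})

test_that("aggregation conserves scores and honours merge rules", {
  set.seed(53)
  ls <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, as.character(1:4)))
  pt <- data.frame(pathway = c("P1", "P2", "P3"),
                   loci = c("1;2", "1;2", "3"), stringsAsFactors = FALSE)
  pg_none <- aggregate_scores(ls, pt, merge_rule = "none")
  expect_equal(pg_none$overall, rowSums(ls), tolerance = 1e-9)
  expect_equal(unname(pg_none$pathway[, "P1"]), rowSums(ls[, 1:2]),
               tolerance = 1e-9)
  expect_equal(ncol(pg_none$pathway), 3L)

  pg_exp <- aggregate_scores(ls, pt, merge_rule = "explicit",
                             merge_groups = list(c("P1", "P2")))
  expect_equal(ncol(pg_exp$pathway), 2L)
  expect_true("P1 / P2" %in% colnames(pg_exp$pathway))

  pg_all <- aggregate_scores(ls, pt, merge_rule = "all-identical")
  expect_equal(ncol(pg_all$pathway), 2L)

  # unknown locus id errors
  bad <- data.frame(pathway = "PX", loci = "9")
  expect_error(aggregate_scores(ls, bad), "unknown locus")
  # merging different locus sets errors
  expect_error(aggregate_scores(ls, pt, merge_rule = "explicit",
                                merge_groups = list(c("P1", "P3"))),
               "different locus sets")
})

test_that("score-trait association recovers effects per family", {
  set.seed(54)
  n <- 3000
  score <- rnorm(n)
  cov <- data.frame(age = rnorm(n, 55, 8))

  # quantitative: trait = 2 * score + noise
  aq <- associate_score_with_trait(score, 2 * score + rnorm(n),
                                   "quantitative", cov)
  expect_lt(abs(aq$effect - 2), 2 * aq$se)
  expect_lt(aq$p, 1e-10)

  # binary: log-odds 0.5 per unit score
  yb <- rbinom(n, 1, plogis(-0.3 + 0.5 * score))
  ab <- associate_score_with_trait(score, yb, "binary", cov)
  expect_lt(abs(ab$effect - 0.5), 2.5 * ab$se)

  # parental survival: exponential hazard increasing in score
  time <- rexp(n, rate = exp(0.3 * score) / 50)
  status <- as.integer(time < 80)
  time <- pmin(time, 80)
  as_ <- associate_score_with_trait(score, time, "parental-survival",
                                    status = status)
  expect_lt(abs(as_$effect - 0.3), 2.5 * as_$se)

  expect_error(associate_score_with_trait(score, rep(1, n), "quantitative"),
               "constant")
  expect_error(associate_score_with_trait(score, time, "parental-survival",
                                          status = rep(0L, n)), "events")
})

test_that("null binary association is calibrated", {
  set.seed(55)
  n <- 20000
  score <- rnorm(n)
  z <- replicate(60, {
    y <- rbinom(n, 1, 0.4)
    associate_score_with_trait(score, y, "binary")$z
  })
  expect_gte(mean(abs(z) < 1.96), 0.88)
})

test_that("Storey q-values match the step-down oracle and stay monotone", {
  # hand oracle on 4 sorted p-values with pi0 = 1:
  # q4 = .95; q3 = min(.95, 4*.9/3) = .95; q2 = 4*.02/2 = .04; q1 = .04
  q <- storey_qvalues(c(0.01, 0.02, 0.9, 0.95), pi0 = 1)
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.95, 0.95), tolerance = 1e-12)

  # single p with pi0 = 1: q = p
  expect_equal(as.numeric(storey_qvalues(0.03, pi0 = 1)), 0.03)

  # uniform null: pi0 estimate near 1
  set.seed(56)
  qn <- storey_qvalues(runif(1e4))
  expect_gte(attr(qn, "pi0"), 0.9)
  expect_lte(attr(qn, "pi0"), 1.05)

  # monotone in p after sorting, bounded by 1
  p <- c(runif(500), runif(100, 0, 1e-3))
  qq <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(qq[o]) > -1e-12))
  expect_true(all(qq <= 1))
  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
})

test_that("scan_scores ties families together with q-values", {
  w <- causal_world()
  ss <- run_screen(w$panel, w$phen$mpb, w$cov, mac_min = 20)
  lg <- refit_logistic(w$panel, w$phen$mpb, w$cov, ss$snp[ss$log10p > 5])
  loci <- add_distinct_snps(define_loci(lg), w$panel, w$phen$mpb, w$cov)
  wt <- reestimate_joint_betas(w$panel, w$phen$mpb, w$cov,
                               unlist(loci$distinct))
  ls <- compute_locus_scores(w$panel, wt, loci)
  pt <- data.frame(pathway = "all", loci = paste(loci$locus, collapse = ";"))
  pg <- aggregate_scores(ls, pt, merge_rule = "none")
  res <- scan_scores(pg, list(
    t2 = list(values = w$phen$t2, family = "quantitative"),
    mpb = list(values = w$phen$mpb, family = "binary")),
    covariates = w$cov)
  expect_true(all(c("z", "q") %in% names(res)))
  # q is a non-decreasing function of p within the scan
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) > -1e-12))
  # the overall score is strongly associated with the phenotype it indexes
  expect_lt(res$q[res$score == "overall" & res$trait == "mpb"], 0.05)
})
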