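# Linear screen, logistic refit, meta-analysis, genomic control.

test_that("screen matches the closed-form OLS oracle and handles filters", {
  # printed toy: n=6, x=(0,1,2,0,1,2), y=(0,0,1,0,1,1):
  # slope = Sxy/Sxx = 2/4 = 0.5; RSS = 0.5 -> SE = sqrt((0.5/4)/4) = sqrt(1/32)
  panel <- genotype_panel(cbind(snp1 = c(0, 1, 2, 0, 1, 2)))
  ss <- run_screen(panel, c(0, 0, 1, 0, 1, 1), mac_min = 0)
  expect_equal(ss$beta, 0.5, tolerance = 1e-10)
  expect_equal(ss$se, sqrt(1 / 32), tolerance = 1e-10)

  # perfect fit: phenotype == dosage
  set.seed(1)
  g <- rbinom(200, 2, 0.4)
  p2 <- genotype_panel(cbind(gA = g, gB = rbinom(200, 2, 0.3)))
  ss2 <- run_screen(p2, g, mac_min = 0)
  expect_equal(ss2$beta[ss2$snp == "gA"], 1.0, tolerance = 1e-10)
  expect_gt(ss2$log10p[ss2$snp == "gA"], 100)

  # MAC boundary: carrier count of exactly 99 is filtered at mac_min = 100
  n <- 5000
  g99 <- c(rep(1, 99), rep(0, n - 99))
  g100 <- c(rep(1, 100), rep(0, n - 100))
  p3 <- genotype_panel(cbind(rare99 = g99, rare100 = g100,
                             common = rbinom(n, 2, 0.5)))
  set.seed(2)
  ss3 <- run_screen(p3, rbinom(n, 1, 0.5), mac_min = 100)
  expect_false("rare99" %in% ss3$snp)
  expect_true("rare100" %in% ss3$snp)

  # screen agrees with lm() including covariates
  w <- causal_world()
  snp <- w$truth$causal$snp[1]
  ss4 <- run_screen(w$panel, w$phen$mpb, w$cov, mac_min = 0)
  fit <- lm(w$phen$mpb ~ w$panel$dosage[, snp] + as.matrix(w$cov))
  expect_equal(ss4$beta[ss4$snp == snp], unname(coef(fit)[2]),
               tolerance = 1e-8)
  expect_equal(ss4$se[ss4$snp == snp],
               unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-8)
})

test_that("collinear covariates error with names", {
  panel <- genotype_panel(cbind(s = rbinom(50, 2, 0.3)))
  cov <- data.frame(a = 1:50, b = 2 * (1:50))
  expect_error(run_screen(panel, rnorm(50), cov, mac_min = 0),
               "collinear.*b")
})

test_that("logistic refit recovers the exact 2x2 log odds ratio", {
  # dosage in {0,2}: cases 30 exposed / 10 unexposed, controls 10 / 30
  # per-copy log-OR = log((30*30)/(10*10)) / 2 = log(9)/2
  g <- c(rep(2, 30), rep(0, 10), rep(2, 10), rep(0, 30))
  y <- c(rep(1, 40), rep(0, 40))
  panel <- genotype_panel(cbind(snp = g))
  out <- refit_logistic(panel, y, snp_ids = "snp")
  expect_equal(out$beta, log(9) / 2, tolerance = 1e-8)
  expect_identical(out$flag, "")
})

test_that("logistic refit flags separation and rejects degenerate input", {
  y <- c(rep(0, 20), rep(1, 20))
  g <- c(rep(0, 20), rep(2, 20))  # perfectly separating SNP
  panel <- genotype_panel(cbind(sep = g))
  out <- refit_logistic(panel, y, snp_ids = "sep")
  expect_identical(out$flag, "separation")
  expect_error(refit_logistic(panel, rep(1, 40), snp_ids = "sep"),
               "no variation")
})

test_that("null logistic p-values are uniform (type-I calibration)", {
  set.seed(31)
  n <- 20000
  reps <- 500
  pv <- numeric(reps)
  y <- rbinom(n, 1, 0.59)
  cov <- data.frame(age = rnorm(n))
  for (r in seq_len(reps)) {
    panel <- genotype_panel(cbind(s = rbinom(n, 2, 0.3)))
    pv[r] <- refit_logistic(panel, y, cov, "s")$p
  }
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("screen and logistic refit rank signals identically", {
  w <- causal_world()
  ss <- run_screen(w$panel, w$phen$mpb, w$cov, mac_min = 20)
  top <- ss[ss$log10p > 5, ]
  lg <- refit_logistic(w$panel, w$phen$mpb, w$cov, top$snp)
  expect_gt(cor(top$log10p, lg$log10p, method = "spearman"), 0.99)
})

test_that("inverse-variance meta-analysis matches its oracle and invariants", {
  mk <- function(beta, se, a1 = "A", a2 = "G", cohort = "c") {
    pathpgs:::.new_summary_stats(data.frame(
      snp = paste0("rs", seq_along(beta)), chr = "1",
      bp = seq_along(beta) * 1000L, a1 = a1, a2 = a2, beta = beta, se = se,
      p = 2 * pnorm(-abs(beta / se)),
      log10p = -log10(2 * pnorm(-abs(beta / se))),
      n = 100L, cohort = cohort, stringsAsFactors = FALSE))
  }
  # identity for one cohort
  one <- mk(c(0.1, -0.2), c(0.05, 0.08))
  m1 <- meta_analyse(list(one))
  expect_equal(m1$beta, one$beta)
  expect_equal(m1$se, one$se)

  # symmetric weights: betas 0.1 / 0.3 at equal se 0.1
  m2 <- meta_analyse(list(mk(0.1, 0.1), mk(0.3, 0.1)))
  expect_equal(m2$beta, 0.2, tolerance = 1e-12)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)

  # three cohorts vs direct weighted-mean arithmetic
  b <- c(0.12, 0.05, 0.30); s <- c(0.1, 0.2, 0.4)
  m3 <- meta_analyse(list(mk(b[1], s[1]), mk(b[2], s[2]), mk(b[3], s[3])))
  wgt <- 1 / s^2
  expect_equal(m3$beta, sum(wgt * b) / sum(wgt), tolerance = 1e-12)
  expect_equal(m3$se, 1 / sqrt(sum(wgt)), tolerance = 1e-12)

  # permutation invariance over cohorts
  ca <- mk(c(0.1, 0.2), c(0.1, 0.2)); cb <- mk(c(0.0, 0.1), c(0.2, 0.1))
  cc <- mk(c(-0.1, 0.3), c(0.3, 0.3))
  mA <- meta_analyse(list(ca, cb, cc))
  mB <- meta_analyse(list(cb, cc, ca))
  expect_equal(mA$beta, mB$beta[match(mA$snp, mB$snp)], tolerance = 1e-12)

  # swapped effect/other alleles flip the sign before pooling
  swapped <- mk(-0.1, 0.1, a1 = "G", a2 = "A")
  m4 <- meta_analyse(list(mk(0.1, 0.1), swapped))
  expect_equal(m4$beta, 0.1, tolerance = 1e-12)

  # irreconcilable alleles error, naming the SNP
  clash <- mk(0.1, 0.1, a1 = "C", a2 = "A")
  expect_error(meta_analyse(list(mk(0.1, 0.1), clash)), "rs1")
})

test_that("genomic-control lambda behaves under null and scaling", {
  expect_equal(inflation_lambda(rep(0.5, 11)), 1.0, tolerance = 1e-12)
  set.seed(17)
  p <- runif(1e5)
  expect_equal(inflation_lambda(p), 1.0, tolerance = 0.02)
  # doubling the chi-square statistics doubles lambda
  chi2 <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi2, 1, lower.tail = FALSE)
  expect_equal(inflation_lambda(p2), 2.0, tolerance = 0.05)
  # reorder invariance and empty-input error
  expect_identical(inflation_lambda(p), inflation_lambda(rev(p)))
  expect_error(inflation_lambda(numeric(0)), "no p-values")
})

test_that("summary statistics survive a TSV round trip with exact columns", {
  w <- causal_world()
  ss <- run_screen(w$panel, w$phen$mpb, w$cov, mac_min = 100)
  f <- tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N"))
  back <- read_sumstats(f)
  expect_equal(back$beta, ss$beta, tolerance = 1e-12)
})
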