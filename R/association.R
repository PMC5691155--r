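# Per-SNP association: fast linear screen, logistic refit, inverse-variance
# meta-analysis, genomic-control inflation.

#' @keywords internal
.new_summary_stats <- function(df) {
  needed <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p", "log10p",
              "n", "cohort")
  if (!"flag" %in% names(df)) df$flag <- ""
  stopifnot(all(needed %in% names(df)))
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %d SNPs, cohort(s): %s\n",
              nrow(x), paste(unique(x$cohort), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Fast linear association screen
#'
#' Per-SNP least squares of the phenotype on dosage plus covariates,
#' equivalent for a binary 0/1 outcome to the Armitage trend test. Computed
#' by the Frisch-Waugh projection: phenotype and every dosage column are
#' residualized on the covariates once, so the scan is a handful of matrix
#' products. SNPs below the minor-allele-count threshold or monomorphic in
#' sample are excluded (with a message).
#'
#' @param panel a `genotype_panel`.
#' @param phenotype numeric vector (binary 0/1 or quantitative).
#' @param covariates data.frame/matrix of covariates or NULL.
#' @param mac_min minimum minor allele count (default 100, the usual rare-
#'   variant guard for a biobank-scale screen).
#' @param cohort label stored in the output.
#' @return a `summary_stats` data.frame (one row per retained SNP) with
#'   p-values carried alongside -log10(p) to survive underflow.
#' @export
run_screen <- function(panel, phenotype, covariates = NULL, mac_min = 100,
                       cohort = "discovery") {
  G <- panel$dosage
  n <- nrow(G)
  stopifnot(length(phenotype) == n)
  X <- .design_matrix(covariates, n)
  ac <- colSums(G)
  mac <- pmin(ac, 2 * n - ac)
  keep <- mac >= mac_min
  mono <- (colMeans(G^2) - colMeans(G)^2) < .Machine$double.eps
  if (any(mono & keep)) {
    message(sum(mono & keep), " monomorphic SNP(s) excluded from the screen")
  }
  keep <- keep & !mono
  if (!any(keep)) stop("no SNP passes the minor-allele-count filter")
  Gk <- G[, keep, drop = FALSE]
  qx <- qr(X)
  yr <- qr.resid(qx, phenotype)
  Gr <- qr.resid(qx, Gk)
  gtg <- colSums(Gr^2)
  gty <- drop(crossprod(Gr, yr))
  beta <- gty / gtg
  df <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta^2 * gtg
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / gtg)
  tval <- beta / se
  pp <- .t_to_p(tval, df)
  meta <- panel$snp_meta[keep, , drop = FALSE]
  .new_summary_stats(data.frame(
    snp = meta$id, chr = meta$chr, bp = meta$pos,
    a1 = meta$a1, a2 = meta$a2,
    beta = beta, se = se, p = pp$p, log10p = pp$log10p,
    n = n, cohort = cohort, flag = "",
    stringsAsFactors = FALSE, row.names = NULL))
}

#' Logistic refit of selected SNPs
#'
#' Additive log-odds per effect-allele copy from maximum likelihood
#' (iteratively reweighted least squares), with the same covariates as the
#' screen. Records with fitted probabilities at the 0/1 boundary are flagged
#' `"separation"`; fits hitting the iteration cap are flagged
#' `"nonconverged"` - neither is dropped silently.
#'
#' @inheritParams run_screen
#' @param snp_ids SNP ids to refit (must exist in the panel).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return a `summary_stats` data.frame.
#' @export
refit_logistic <- function(panel, phenotype, covariates = NULL, snp_ids,
                           max_iter = 25, tol = 1e-8, cohort = "discovery") {
  G <- panel$dosage
  n <- nrow(G)
  stopifnot(length(phenotype) == n)
  if (!all(phenotype %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(phenotype)) < 2L) {
    stop("phenotype has no variation (all cases or all controls)")
  }
  miss <- setdiff(snp_ids, colnames(G))
  if (length(miss)) stop("SNPs absent from panel: ", paste(miss, collapse = ", "))
  X0 <- .design_matrix(covariates, n)
  rows <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    g <- G[, snp_ids[i]]
    fit <- suppressWarnings(stats::glm.fit(
      x = cbind(X0, snp = g), y = phenotype,
      family = stats::binomial(),
      control = stats::glm.control(epsilon = tol, maxit = max_iter)))
    w <- .glm_wald(fit)
    k <- length(w$coef)
    flag <- ""
    if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
        !is.finite(w$se[k]) || w$se[k] > 1e3) flag <- "separation"
    if (!fit$converged && flag == "") flag <- "nonconverged"
    z <- w$coef[k] / w$se[k]
    pp <- .z_to_p(z)
    j <- match(snp_ids[i], panel$snp_meta$id)
    rows[[i]] <- data.frame(
      snp = snp_ids[i], chr = panel$snp_meta$chr[j], bp = panel$snp_meta$pos[j],
      a1 = panel$snp_meta$a1[j], a2 = panel$snp_meta$a2[j],
      beta = unname(w$coef[k]), se = unname(w$se[k]),
      p = pp$p, log10p = pp$log10p, n = n, cohort = cohort, flag = flag,
      stringsAsFactors = FALSE)
  }
  .new_summary_stats(do.call(rbind, rows))
}

# Harmonise `other` onto `ref` allele coding. Returns `other` with beta
# flipped where effect/other alleles are swapped; errors on irreconcilable
# allele pairs; strand-ambiguous SNPs (A/T, C/G) pass through with a warning.
#' @keywords internal
.harmonise_alleles <- function(ref, other) {
  idx <- match(other$snp, ref$snp)
  if (anyNA(idx)) stop("SNPs missing from reference cohort: ",
                       paste(other$snp[is.na(idx)], collapse = ", "))
  comp <- function(a) chartr("ACGT", "TGCA", a)
  ambiguous <- (other$a1 == comp(other$a2))
  if (any(ambiguous)) {
    warning(sum(ambiguous), " strand-ambiguous SNP(s) (A/T or C/G) passed through")
  }
  r1 <- ref$a1[idx]; r2 <- ref$a2[idx]
  same <- other$a1 == r1 & other$a2 == r2
  swap <- other$a1 == r2 & other$a2 == r1
  flip_same <- comp(other$a1) == r1 & comp(other$a2) == r2
  flip_swap <- comp(other$a1) == r2 & comp(other$a2) == r1
  ok <- same | swap | flip_same | flip_swap
  if (!all(ok)) {
    stop("allele mismatch not resolvable by strand/swap for: ",
         paste(other$snp[!ok], collapse = ", "))
  }
  do_swap <- (swap | flip_swap) & !same & !flip_same
  other$beta[do_swap] <- -other$beta[do_swap]
  other$a1 <- r1; other$a2 <- r2
  other
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-cohort summary statistics with weights 1/SE^2:
#' `beta = sum(w_i b_i) / sum(w_i)`, `se = 1/sqrt(sum(w_i))`, two-sided
#' normal p-value. Alleles are harmonised to the first cohort (sign flip on
#' swapped coding, strand complement resolved, irreconcilable pairs error).
#' A single cohort is returned unchanged apart from the cohort label.
#'
#' @param stats_list list of `summary_stats`, one per cohort; every cohort
#'   must contain all SNPs of the first.
#' @param label cohort label of the output.
#' @return a `summary_stats` data.frame with one row per SNP.
#' @export
meta_analyse <- function(stats_list, label = "meta") {
  stopifnot(length(stats_list) >= 1L)
  ref <- stats_list[[1]]
  if (length(stats_list) == 1L) {
    ref$cohort <- label
    return(ref)
  }
  others <- lapply(stats_list[-1], .harmonise_alleles, ref = ref)
  w <- 1 / ref$se^2
  num <- w * ref$beta
  ntot <- ref$n
  for (o in others) {
    idx <- match(ref$snp, o$snp)
    wi <- 1 / o$se[idx]^2
    wi[is.na(wi)] <- 0
    bi <- o$beta[idx]; bi[is.na(bi)] <- 0
    w <- w + wi
    num <- num + wi * bi
    nn <- o$n[idx]; nn[is.na(nn)] <- 0
    ntot <- ntot + nn
  }
  beta <- num / w
  se <- 1 / sqrt(w)
  pp <- .z_to_p(beta / se)
  .new_summary_stats(data.frame(
    snp = ref$snp, chr = ref$chr, bp = ref$bp, a1 = ref$a1, a2 = ref$a2,
    beta = beta, se = se, p = pp$p, log10p = pp$log10p,
    n = ntot, cohort = label, flag = "",
    stringsAsFactors = FALSE, row.names = NULL))
}

#' Genomic-control inflation factor
#'
#' Median of the one-degree-of-freedom chi-square statistics implied by the
#' p-values, divided by the null chi-square median (0.4549364).
#'
#' @param stats a `summary_stats` object or a numeric vector of p-values.
#' @return scalar lambda.
#' @export
inflation_lambda <- function(stats) {
  p <- if (inherits(stats, "summary_stats")) stats$p else as.numeric(stats)
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Column names follow the conventional exchange format exactly:
#' SNP, CHR, BP, A1, A2, BETA, SE, P, N.
#' @param stats a `summary_stats` object.
#' @param path file path.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp, CHR = stats$chr, BP = stats$bp,
                    A1 = stats$a1, A2 = stats$a2, BETA = stats$beta,
                    SE = stats$se, P = stats$p, N = stats$n,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param cohort cohort label to attach on read.
#' @export
read_sumstats <- function(path, cohort = "cohort") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
                %in% names(d)))
  lp <- -log10(d$P)
  .new_summary_stats(data.frame(
    snp = d$SNP, chr = as.character(d$CHR), bp = d$BP, a1 = d$A1, a2 = d$A2,
    beta = d$BETA, se = d$SE, p = d$P, log10p = lp, n = d$N,
    cohort = cohort, flag = "", stringsAsFactors = FALSE))
}
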