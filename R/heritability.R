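# Genetic relationship matrices, average-information REML variance
# components, liability-scale conversion, and the variance explained by a
# polygenic score fitted as a fixed effect.

#' Build a genetic relationship matrix
#'
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the m retained SNPs, with `p_i` the sample effect-allele frequency
#' (dosage mean / 2; under the male-X 0/2 dosage-compensated coding the same
#' standardisation applies). Monomorphic SNPs are excluded with a message.
#'
#' @param panel a `genotype_panel`.
#' @param snp_ids SNPs to use (default: all); `chr` instead restricts to a
#'   chromosome set (e.g. `"X"`), matching the two-matrix split of an
#'   autosomal and an X-linked component.
#' @param chr optional chromosome filter.
#' @return a `grm` object: list with `K` (n x n symmetric), `m` (SNPs used)
#'   and `ids`.
#' @export
build_grm <- function(panel, snp_ids = NULL, chr = NULL) {
  meta <- panel$snp_meta
  use <- rep(TRUE, nrow(meta))
  if (!is.null(chr)) use <- use & meta$chr %in% chr
  if (!is.null(snp_ids)) use <- use & meta$id %in% snp_ids
  if (!any(use)) stop("empty SNP subset for GRM")
  X <- panel$dosage[, use, drop = FALSE]
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    message(sum(!poly), " monomorphic SNP(s) excluded from the GRM")
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- ncol(X)
  if (!m) stop("no polymorphic SNPs left for the GRM")
  Z <- sweep(X, 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / m
  structure(list(K = K, m = m, ids = rownames(panel$dosage)),
            class = "grm")
}

#' Liability-scale transformation of heritability
#'
#' Converts observed-scale (0/1) heritability to the liability scale for a
#' population sample analysed at its own prevalence (no ascertainment
#' correction): `h2_liab = h2_obs * K (1 - K) / z^2`, where `z` is the
#' standard normal density at the threshold `qnorm(1 - K)`.
#'
#' @param h2_observed observed-scale heritability (vectorised).
#' @param prevalence case fraction K in (0, 1).
#' @return liability-scale heritability.
#' @export
liability_transform <- function(h2_observed, prevalence) {
  .check_fraction(prevalence, "prevalence")
  z <- stats::dnorm(stats::qnorm(1 - prevalence))
  h2_observed * prevalence * (1 - prevalence) / z^2
}

#' Average-information REML for one or more GRMs
#'
#' Fits `y = X b + sum_k u_k + e`, `u_k ~ N(0, sigma2_k A_k)`, by restricted
#' maximum likelihood with average-information updates, an EM fallback step
#' whenever an AI step leaves the feasible region, and step halving when a
#' step would decrease the restricted likelihood. With a single GRM the
#' problem is rotated to the GRM eigenbasis once, making every iteration
#' linear in n. Start values split the phenotypic variance equally across
#' components. Variance components are kept above a small positive floor;
#' floor hits are reported as boundary components.
#'
#' @param phenotype numeric vector (a binary trait is analysed on the
#'   observed 0/1 scale and transformed afterwards).
#' @param covariates covariate table or NULL (an intercept is always
#'   included).
#' @param grms a `grm`, or a (preferably named) list of `grm` objects.
#' @param prevalence if supplied, liability-scale heritabilities are
#'   reported via [liability_transform()].
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change in restricted log-likelihood.
#' @return a `reml_fit`: variance components (`vc`), their standard errors
#'   (`vc_se`), observed-scale heritability per component and in total
#'   (`h2_obs`, with `h2_se`), optional `h2_liability`, the log-likelihood
#'   trajectory, gradient norm, convergence and boundary flags.
#' @export
fit_aireml <- function(phenotype, covariates = NULL, grms,
                       prevalence = NULL, max_iter = 100, tol = 1e-6) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1L, all(vapply(grms, inherits, TRUE, "grm")))
  if (is.null(names(grms)) || any(!nzchar(names(grms)))) {
    names(grms) <- paste0("G", seq_along(grms))
  }
  y <- as.numeric(phenotype)
  n <- length(y)
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  X <- .design_matrix(covariates, n)
  fit <- if (length(grms) == 1L) {
    .reml_eigen(y, X, grms[[1]]$K, max_iter, tol)
  } else {
    .reml_dense(y, X, lapply(grms, `[[`, "K"), max_iter, tol)
  }
  K <- length(grms)
  vc <- fit$theta
  names(vc) <- c(names(grms), "residual")
  # variance attributable to component k on the phenotypic scale is
  # sigma2_k * mean(diag(A_k)): invariant to any rescaling of the GRM, and
  # the mean diagonal is ~1 for a standard autosomal GRM but ~2 under the
  # male-X 0/2 dosage-compensated coding standardised by 2p(1-p)
  cs <- c(vapply(grms, function(g) mean(diag(g$K)), numeric(1)), 1)
  vattr <- vc * cs
  vtot <- sum(vattr)
  h2 <- vattr[seq_len(K)] / vtot
  # delta-method SEs for the ratios from the AI covariance of the components
  Sigma <- fit$cov
  h2_se <- vapply(seq_len(K), function(k) {
    grad <- -cs[k] * vc[k] * cs / vtot^2
    grad[k] <- grad[k] + cs[k] / vtot
    sqrt(max(drop(t(grad) %*% Sigma %*% grad), 0))
  }, numeric(1))
  gtot <- -sum(vattr[seq_len(K)]) * cs / vtot^2
  gtot[seq_len(K)] <- gtot[seq_len(K)] + cs[seq_len(K)] / vtot
  h2_tot_se <- sqrt(max(drop(t(gtot) %*% Sigma %*% gtot), 0))
  out <- list(vc = vc, vc_se = sqrt(pmax(diag(Sigma), 0)),
              h2_obs = h2, h2_se = h2_se,
              h2_obs_total = sum(h2), h2_total_se = h2_tot_se,
              loglik = fit$loglik, loglik_trace = fit$trace,
              gradient_norm = fit$grad_norm,
              converged = fit$converged, boundary = fit$boundary,
              n = n, prevalence = prevalence)
  if (!is.null(prevalence)) {
    out$h2_liability <- liability_transform(h2, prevalence)
    out$h2_liability_se <- liability_transform(h2_se, prevalence)
    out$h2_liability_total <- liability_transform(sum(h2), prevalence)
  }
  class(out) <- "reml_fit"
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit (n =", x$n, ")\n")
  comp <- data.frame(component = names(x$vc), variance = x$vc, se = x$vc_se)
  print(comp, row.names = FALSE, digits = 4)
  cat(sprintf("observed-scale h2: %s (total %.3f)\n",
              paste(sprintf("%s=%.3f", names(x$h2_obs), x$h2_obs),
                    collapse = ", "), x$h2_obs_total))
  if (!is.null(x$h2_liability)) {
    cat(sprintf("liability-scale h2 (K=%.2f): %s (total %.3f)\n",
                x$prevalence,
                paste(sprintf("%.3f", x$h2_liability), collapse = ", "),
                x$h2_liability_total))
  }
  if (!x$converged) cat("WARNING: not converged\n")
  if (any(x$boundary)) {
    cat("boundary component(s):",
        paste(names(x$vc)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

# Shared AI-REML driver. `ops` abstracts the linear algebra so the same
# update loop serves the dense multi-GRM path and the eigen-rotated
# single-GRM path. `ops$prepare(theta)` returns an environment with
# tr_PA(k), quad(k) = y'P A_k P y, Py, PAPy-based AI entries and loglik.
#' @keywords internal
.reml_loop <- function(theta, n, K, prepare, max_iter, tol, vary) {
  lb <- 1e-6 * vary
  trace <- numeric(0)
  st <- prepare(theta)
  ll <- st$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    trace <- c(trace, ll)
    grad <- -0.5 * (st$trPA - st$quad)
    AI <- 0.5 * st$AI
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    em <- FALSE
    if (is.null(step)) em <- TRUE else {
      prop <- theta + step
      if (any(prop < lb)) em <- TRUE
    }
    if (em) {
      # EM update, guaranteed feasible
      prop <- theta + (theta^2 / n) * (st$quad - st$trPA)
      prop <- pmax(prop, lb)
    }
    st_new <- prepare(prop)
    halve <- 0
    while (st_new$loglik < ll - 1e-10 && halve < 8) {
      prop <- (theta + prop) / 2
      prop <- pmax(prop, lb)
      st_new <- prepare(prop)
      halve <- halve + 1
    }
    if (st_new$loglik < ll - 1e-10) {
      # cannot improve; stop at current estimates
      converged <- TRUE
      break
    }
    dll <- st_new$loglik - ll
    theta <- prop
    st <- st_new
    ll <- st$loglik
    if (dll < tol) {
      converged <- TRUE
      trace <- c(trace, ll)
      break
    }
  }
  grad <- -0.5 * (st$trPA - st$quad)
  AI <- 0.5 * st$AI
  cov <- tryCatch(solve(AI), error = function(e) {
    diag(1e6, K + 1L)
  })
  list(theta = theta, cov = cov, loglik = ll, trace = trace,
       grad_norm = sqrt(sum(grad^2)), converged = converged,
       boundary = theta <= lb * (1 + 1e-8))
}

# Dense path: arbitrary number of GRMs.
#' @keywords internal
.reml_dense <- function(y, X, Ks, max_iter, tol) {
  n <- length(y)
  K <- length(Ks)
  vary <- stats::var(y)
  theta <- rep(vary / (K + 1), K + 1L)
  In <- diag(n)
  comps <- c(Ks, list(In))
  prepare <- function(th) {
    V <- matrix(0, n, n)
    for (k in seq_len(K)) V <- V + th[k] * Ks[[k]]
    diag(V) <- diag(V) + th[K + 1L]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    B <- solve(XtViX)
    Viy <- Vi %*% y
    Py <- Viy - ViX %*% (B %*% crossprod(ViX, y))
    Pmul <- function(u) Vi %*% u - ViX %*% (B %*% crossprod(ViX, u))
    trPA <- numeric(K + 1L)
    quad <- numeric(K + 1L)
    APy <- vector("list", K + 1L)
    for (k in seq_len(K + 1L)) {
      A <- comps[[k]]
      AViX <- A %*% ViX
      trPA[k] <- sum(Vi * A) - sum(B * crossprod(ViX, AViX))
      APy[[k]] <- A %*% Py
      quad[k] <- drop(crossprod(Py, APy[[k]]))
    }
    AI <- matrix(0, K + 1L, K + 1L)
    for (k in seq_len(K + 1L)) {
      PAPy <- Pmul(APy[[k]])
      for (l in k:(K + 1L)) {
        AI[k, l] <- AI[l, k] <- drop(crossprod(APy[[l]], PAPy))
      }
    }
    ldV <- 2 * sum(log(diag(ch)))
    ldX <- determinant(XtViX, logarithm = TRUE)$modulus
    loglik <- -0.5 * (ldV + ldX + drop(crossprod(y, Py)))
    list(loglik = loglik, trPA = trPA, quad = quad, AI = AI)
  }
  .reml_loop(theta, n, K, prepare, max_iter, tol, vary)
}

# Eigen path for a single GRM: rotate once, every iteration O(n p^2).
#' @keywords internal
.reml_eigen <- function(y, X, A, max_iter, tol) {
  n <- length(y)
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  vary <- stats::var(y)
  theta <- rep(vary / 2, 2)
  comps <- list(d, rep(1, n))
  prepare <- function(th) {
    v <- th[1] * d + th[2]
    if (any(v <= 0)) return(list(loglik = -Inf))
    vi <- 1 / v
    ViX <- Xs * vi
    XtViX <- crossprod(Xs, ViX)
    B <- solve(XtViX)
    Py <- ys * vi - ViX %*% (B %*% crossprod(ViX, ys))
    Pmul <- function(u) u * vi - ViX %*% (B %*% crossprod(ViX, u))
    trPA <- numeric(2)
    quad <- numeric(2)
    APy <- vector("list", 2)
    for (k in 1:2) {
      a <- comps[[k]]
      trPA[k] <- sum(vi * a) - sum(B * crossprod(ViX, ViX * a))
      APy[[k]] <- drop(Py) * a
      quad[k] <- sum(drop(Py) * APy[[k]])
    }
    AI <- matrix(0, 2, 2)
    for (k in 1:2) {
      PAPy <- Pmul(APy[[k]])
      for (l in k:2) AI[k, l] <- AI[l, k] <- drop(crossprod(APy[[l]], PAPy))
    }
    loglik <- -0.5 * (sum(log(v)) +
                        determinant(XtViX, logarithm = TRUE)$modulus +
                        sum(ys * drop(Py)))
    list(loglik = as.numeric(loglik), trPA = trPA, quad = quad, AI = AI)
  }
  .reml_loop(theta, n, 1L, prepare, max_iter, tol, vary)
}

#' Heritability explained by a polygenic score
#'
#' Refits the REML model with the score appended to the fixed effects and
#' reports the decrease in the GRM-attributed variance fraction, i.e. the
#' share of heritability captured by the score, on the observed and (when a
#' prevalence is given) liability scales.
#'
#' @inheritParams fit_aireml
#' @param score per-individual polygenic score, aligned with the phenotype.
#' @return list with the two `reml_fit`s (`fit_without`, `fit_with`) and
#'   `decrease_obs` / `decrease_liability` (per component and total).
#' @export
score_variance_explained <- function(phenotype, covariates = NULL, grms,
                                     score, prevalence = NULL, ...) {
  if (length(score) != length(phenotype)) {
    stop("score not aligned with individuals")
  }
  if (stats::var(score) <= .Machine$double.eps) {
    warning("constant score explains nothing")
    fit0 <- fit_aireml(phenotype, covariates, grms, prevalence = prevalence, ...)
    zero <- c(fit0$h2_obs * 0, total = 0)
    return(list(fit_without = fit0, fit_with = fit0,
                decrease_obs = zero,
                decrease_liability = if (is.null(prevalence)) NULL else zero))
  }
  C0 <- if (is.null(covariates)) {
    data.frame(score = score)
  } else {
    cbind(as.data.frame(covariates), score = score)
  }
  fit0 <- fit_aireml(phenotype, covariates, grms, prevalence = prevalence, ...)
  fit1 <- fit_aireml(phenotype, C0, grms, prevalence = prevalence, ...)
  dec <- c(fit0$h2_obs - fit1$h2_obs,
           total = fit0$h2_obs_total - fit1$h2_obs_total)
  out <- list(fit_without = fit0, fit_with = fit1, decrease_obs = dec)
  if (!is.null(prevalence)) {
    out$decrease_liability <- liability_transform(dec, prevalence)
  }
  out
}

#' Write / read a GRM as TSV
#'
#' Plain-text triplet format: one row per pair (i <= j) with ids and the
#' relationship value, plus the SNP count as a comment header.
#' @param grm a `grm` object.
#' @param path file path.
#' @export
write_grm <- function(grm, path) {
  n <- nrow(grm$K)
  idx <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(id1 = grm$ids[idx[, 1]], id2 = grm$ids[idx[, 2]],
                    value = grm$K[idx])
  con <- file(path, "w")
  writeLines(sprintf("# pathpgs GRM, m=%d SNPs, n=%d individuals", grm$m, n),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  first <- readLines(path, n = 1L)
  m <- as.integer(sub(".*m=(\\d+).*", "\\1", first))
  d <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  ids <- unique(c(d$id1, d$id2))
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(d$id1, ids); j <- match(d$id2, ids)
  K[cbind(i, j)] <- d$value
  K[cbind(j, i)] <- d$value
  structure(list(K = K, m = m, ids = ids), class = "grm")
}
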