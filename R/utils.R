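# Internal helpers shared across modules.

#' @keywords internal
.check_fraction <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a single number in %s0,1%s, got %s",
                 name, if (open_lower) "(" else "[",
                 if (open_upper) ")" else "]",
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

# Design matrix from a covariate table (may be NULL). Always includes an
# intercept; errors when columns are collinear, naming the offenders.
#' @keywords internal
.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)")))
  }
  C <- as.matrix(covariates)
  if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
  if (nrow(C) != n) stop("covariate rows do not align with the phenotype vector")
  storage.mode(C) <- "double"
  X <- cbind("(Intercept)" = 1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariate columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X
}

# Two-sided p-value from a z statistic, carried both as p and -log10(p) so
# that extreme associations (the strongest signals in large GWAS underflow
# double precision) survive.
#' @keywords internal
.z_to_p <- function(z) {
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  list(p = exp(lp), log10p = -lp / log(10))
}

#' @keywords internal
.t_to_p <- function(tval, df) {
  lp <- stats::pt(abs(tval), df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  list(p = exp(lp), log10p = -lp / log(10))
}

# Wald statistics from a fitted glm.fit object.
#' @keywords internal
.glm_wald <- function(fit) {
  p <- fit$rank
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- chol2inv(R)
  se <- rep(NA_real_, length(fit$coefficients))
  se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(cov))
  list(coef = fit$coefficients, se = se)
}
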