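# Polygenic risk scores: joint re-estimation of SNP weights, locus /
# overall / pathway scores, score-trait association scans, Storey q-values.

#' Joint re-estimation of distinct-SNP weights
#'
#' One multivariable logistic regression of the binary trait on all distinct
#' SNPs simultaneously plus covariates; the per-SNP joint coefficients
#' become the score weights, so shared signal between SNPs is not double
#' counted. Exactly collinear SNP pairs abort with their names; separation
#' is flagged on the result.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype binary 0/1 vector.
#' @param covariates covariate table or NULL.
#' @param snp_ids distinct SNP ids entering the joint model.
#' @return a `weight_table` data.frame: snp, beta (joint log-odds), se;
#'   attribute `flag` is `"separation"` when any fitted probability hits the
#'   0/1 boundary.
#' @export
reestimate_joint_betas <- function(panel, phenotype, covariates = NULL,
                                   snp_ids) {
  G <- panel$dosage
  miss <- setdiff(snp_ids, colnames(G))
  if (length(miss)) stop("SNPs absent from panel: ", paste(miss, collapse = ", "))
  if (!all(phenotype %in% c(0, 1))) stop("phenotype must be binary 0/1")
  X0 <- .design_matrix(covariates, nrow(G))
  S <- G[, snp_ids, drop = FALSE]
  M <- cbind(X0, S)
  qx <- qr(M)
  if (qx$rank < ncol(M)) {
    bad <- colnames(M)[qx$pivot[(qx$rank + 1L):ncol(M)]]
    bad <- intersect(bad, snp_ids)
    stop("collinear SNPs in the joint model: ", paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = M, y = phenotype, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  w <- .glm_wald(fit)
  sel <- ncol(X0) + seq_along(snp_ids)
  out <- data.frame(snp = snp_ids, beta = unname(w$coef[sel]),
                    se = unname(w$se[sel]), stringsAsFactors = FALSE)
  flag <- ""
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    flag <- "separation"
  }
  attr(out, "flag") <- flag
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Per-locus polygenic scores
#'
#' The score of a locus for an individual is the sum over the locus's
#' distinct SNPs of dosage times joint beta. Missing dosages are
#' mean-imputed (count reported via a message).
#'
#' @param panel a `genotype_panel`.
#' @param weights a `weight_table` (snp, beta) from
#'   [reestimate_joint_betas()], or any data.frame with those columns.
#' @param loci a `locus_table` carrying a `distinct` list-column; every
#'   distinct SNP must have a weight.
#' @return numeric matrix, individuals x loci (columns named by locus id).
#' @export
compute_locus_scores <- function(panel, weights, loci) {
  stopifnot(!is.null(loci$distinct))
  snps <- unique(unlist(loci$distinct))
  miss_w <- setdiff(snps, weights$snp)
  if (length(miss_w)) {
    stop("no weight for distinct SNP(s): ", paste(miss_w, collapse = ", "))
  }
  G <- panel$dosage[, snps, drop = FALSE]
  if (anyNA(G)) {
    n_imp <- sum(is.na(G))
    G <- apply(G, 2, function(g) {
      g[is.na(g)] <- mean(g, na.rm = TRUE); g
    })
    message(n_imp, " missing dosage(s) mean-imputed")
  }
  b <- weights$beta[match(snps, weights$snp)]
  weighted <- sweep(G, 2, b, `*`)
  out <- vapply(seq_len(nrow(loci)), function(i) {
    rowSums(weighted[, loci$distinct[[i]], drop = FALSE])
  }, numeric(nrow(G)))
  colnames(out) <- as.character(loci$locus)
  rownames(out) <- rownames(panel$dosage)
  out
}

#' Aggregate locus scores into overall and pathway scores
#'
#' The overall score is the sum of all locus scores; each pathway score is
#' the sum of the locus scores of the loci containing that pathway's genes.
#' Pathways composed of identical locus sets produce identical scores and
#' can be merged: `merge_rule = "explicit"` merges only the groups named in
#' `merge_groups` (mirroring curated merging), `"all-identical"` merges
#' every group of pathways with the same locus set, `"none"` keeps all.
#' Merged scores are named by concatenating the member names with " / ".
#'
#' @param locus_scores matrix from [compute_locus_scores()].
#' @param pathway_table data.frame with columns `pathway` and `loci`
#'   (either a list-column of integer ids or a ";"-separated string).
#' @param merge_rule one of "explicit", "all-identical", "none".
#' @param merge_groups list of character vectors of pathway names (used
#'   with `merge_rule = "explicit"`).
#' @return a `pgs_set`: list with `locus` (matrix), `overall` (vector),
#'   `pathway` (matrix), `composition` (pathway -> locus ids) and
#'   `merged_from` (pathway -> original names).
#' @export
aggregate_scores <- function(locus_scores, pathway_table,
                             merge_rule = c("explicit", "all-identical", "none"),
                             merge_groups = list()) {
  merge_rule <- match.arg(merge_rule)
  comp <- pathway_table$loci
  if (!is.list(comp)) {
    comp <- lapply(strsplit(as.character(comp), ";", fixed = TRUE),
                   function(x) sort(as.integer(x)))
  } else {
    comp <- lapply(comp, function(x) sort(as.integer(x)))
  }
  names(comp) <- pathway_table$pathway
  known <- colnames(locus_scores)
  for (pw in names(comp)) {
    bad <- setdiff(as.character(comp[[pw]]), known)
    if (length(bad)) {
      stop("pathway '", pw, "' references unknown locus id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  merged_from <- as.list(stats::setNames(names(comp), names(comp)))
  if (merge_rule == "explicit" && length(merge_groups)) {
    for (grp in merge_groups) {
      if (!all(grp %in% names(comp))) {
        stop("merge group names unknown: ",
             paste(setdiff(grp, names(comp)), collapse = ", "))
      }
      sets <- comp[grp]
      if (!all(vapply(sets, identical, TRUE, sets[[1]]))) {
        stop("cannot merge pathways with different locus sets: ",
             paste(grp, collapse = ", "))
      }
      new_name <- paste(grp, collapse = " / ")
      comp <- comp[!(names(comp) %in% grp)]
      comp[[new_name]] <- sets[[1]]
      merged_from <- merged_from[!(names(merged_from) %in% grp)]
      merged_from[[new_name]] <- grp
    }
  } else if (merge_rule == "all-identical") {
    key <- vapply(comp, function(x) paste(x, collapse = ";"), "")
    groups <- split(names(comp), key)
    new_comp <- list()
    new_from <- list()
    for (g in groups) {
      nm <- if (length(g) > 1L) paste(g, collapse = " / ") else g
      new_comp[[nm]] <- comp[[g[1]]]
      new_from[[nm]] <- g
    }
    ord <- order(vapply(new_from, function(g) match(g[1], names(comp)), 0L))
    comp <- new_comp[ord]
    merged_from <- new_from[ord]
  }
  overall <- rowSums(locus_scores)
  pw_mat <- vapply(comp, function(ids) {
    rowSums(locus_scores[, as.character(ids), drop = FALSE])
  }, numeric(nrow(locus_scores)))
  structure(list(locus = locus_scores, overall = overall,
                 pathway = pw_mat, composition = comp,
                 merged_from = merged_from),
            class = "pgs_set")
}

#' @export
print.pgs_set <- function(x, ...) {
  cat(sprintf("pgs_set: %d individuals, %d locus scores, %d pathway scores\n",
              length(x$overall), ncol(x$locus), ncol(x$pathway)))
  invisible(x)
}

#' Association of a polygenic score with a trait
#'
#' Fits the family-appropriate regression of the trait on the score plus
#' covariates: logistic for binary traits, least squares for quantitative
#' traits, and a Cox proportional-hazards model (age as the survival time,
#' alive/dead as status) for parental-survival traits.
#'
#' @param score numeric score vector.
#' @param trait trait vector: 0/1 for binary, numeric for quantitative,
#'   survival time (age) for parental-survival.
#' @param family "binary", "quantitative" or "parental-survival".
#' @param covariates covariate table or NULL.
#' @param status event indicator (1 = dead), required for parental-survival.
#' @param score_name,trait_name labels for the result row.
#' @return a `trait_assoc` data.frame row: score, trait, family, effect,
#'   se, z, p (q-values are attached scan-wide by [storey_qvalues()]).
#' @export
associate_score_with_trait <- function(score, trait,
                                       family = c("quantitative", "binary",
                                                  "parental-survival"),
                                       covariates = NULL, status = NULL,
                                       score_name = "score",
                                       trait_name = "trait") {
  family <- match.arg(family)
  n <- length(score)
  if (family != "parental-survival" &&
      stats::var(as.numeric(trait)) <= .Machine$double.eps) {
    stop("trait is constant")
  }
  if (family == "binary") {
    if (!all(trait %in% c(0, 1))) stop("binary trait must be 0/1")
    X <- cbind(.design_matrix(covariates, n), score = score)
    fit <- suppressWarnings(stats::glm.fit(
      x = X, y = trait, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    w <- .glm_wald(fit)
    k <- length(w$coef)
    eff <- unname(w$coef[k]); se <- unname(w$se[k])
  } else if (family == "quantitative") {
    X <- cbind(.design_matrix(covariates, n), score = score)
    fit <- stats::lm.fit(X, as.numeric(trait))
    df <- n - fit$rank
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- chol2inv(R) * sum(fit$residuals^2) / df
    se_all <- rep(NA_real_, ncol(X))
    se_all[fit$qr$pivot[seq_len(fit$rank)]] <- sqrt(diag(cov))
    eff <- unname(fit$coefficients[ncol(X)]); se <- se_all[ncol(X)]
  } else {
    if (is.null(status)) stop("parental-survival requires a status vector")
    if (sum(status) == 0) stop("no events in survival trait")
    dat <- data.frame(time = as.numeric(trait), status = as.integer(status),
                      score = score)
    form <- survival::Surv(time, status) ~ score
    if (!is.null(covariates)) {
      dat <- cbind(dat, as.data.frame(covariates))
      form <- stats::as.formula(paste(
        "survival::Surv(time, status) ~ score +",
        paste(colnames(as.data.frame(covariates)), collapse = " + ")))
    }
    fit <- survival::coxph(form, data = dat)
    eff <- unname(stats::coef(fit)["score"])
    se <- sqrt(diag(stats::vcov(fit)))[["score"]]
  }
  z <- eff / se
  pp <- .z_to_p(z)
  out <- data.frame(score = score_name, trait = trait_name, family = family,
                    effect = eff, se = se, z = z, p = pp$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("trait_assoc", "data.frame")
  out
}

#' Scan every score in a score set against a set of traits
#'
#' Convenience wrapper running [associate_score_with_trait()] for the
#' overall score, every pathway score and (optionally) every locus score
#' against each trait, then attaching Storey q-values scan-wide.
#'
#' @param pgs a `pgs_set`.
#' @param traits named list; each element is a list with `values`, `family`
#'   and optionally `status`.
#' @param covariates covariate table or NULL.
#' @param include_locus_scores also test the individual locus scores.
#' @return a `trait_assoc` data.frame with a `q` column.
#' @export
scan_scores <- function(pgs, traits, covariates = NULL,
                        include_locus_scores = TRUE) {
  score_mat <- cbind(overall = pgs$overall, pgs$pathway)
  if (include_locus_scores) {
    lm_ <- pgs$locus
    colnames(lm_) <- paste0("locus_", colnames(lm_))
    score_mat <- cbind(score_mat, lm_)
  }
  rows <- list()
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    for (sn in colnames(score_mat)) {
      rows[[length(rows) + 1L]] <- associate_score_with_trait(
        score_mat[, sn], tr$values, family = tr$family,
        covariates = covariates, status = tr$status,
        score_name = sn, trait_name = tn)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- storey_qvalues(out$p)
  class(out) <- c("trait_assoc", "data.frame")
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution (the
#' smoother method over lambda = 0.05, 0.10, ..., 0.95; for fewer than 100
#' tests the estimate falls back to the single point lambda = 0.5) and
#' converts p-values to q-values by the step-down minimum of
#' `pi0 * m * p_(j) / j` over the sorted tail.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optionally force pi0 (e.g. 1 for the Benjamini-Hochberg
#'   limit).
#' @return q-values in input order, with `pi0` as an attribute.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- min(1, mean(p > 0.5) / 0.5)
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(sp, x = max(lam))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
    if (pi0 <= 0) pi0 <- 1
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Export score and association tables
#'
#' @param pgs a `pgs_set`.
#' @param path output TSV.
#' @export
write_score_matrix <- function(pgs, path) {
  lm_ <- pgs$locus
  colnames(lm_) <- paste0("locus_", colnames(lm_))
  out <- data.frame(id = names(pgs$overall) %||% seq_along(pgs$overall),
                    lm_, pgs$pathway, overall = pgs$overall,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_score_matrix
#' @param assoc a `trait_assoc` table.
#' @export
write_association_results <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
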