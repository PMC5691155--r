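# Locus definition (distance-based single linkage), stepwise conditional
# selection of distinct SNPs, replication filtering, locus table I/O.

#' Partition associated SNPs into loci
#'
#' Selects all SNPs with p below `p_select` and single-linkage clusters them
#' along each chromosome: consecutive selected SNPs belong to the same locus
#' unless they are strictly more than `gap_bp` apart (so a gap of exactly
#' 500 kb keeps one locus). Loci are numbered genome-wide in (chromosome,
#' position) order. Coordinates are 1-based inclusive.
#'
#' @param stats a `summary_stats` data.frame.
#' @param p_select selection threshold on -log10 scale via `log10p`
#'   (default 1e-5, the conventional suggestive threshold).
#' @param gap_bp maximum within-locus gap in base pairs (default 500000).
#' @return a `locus_table` data.frame: locus, chr, start, end, n_snps and a
#'   `members` list-column of SNP ids; a `distinct` list-column is added by
#'   [select_distinct_snps()] / [add_distinct_snps()].
#' @export
define_loci <- function(stats, p_select = 1e-5, gap_bp = 500000) {
  sel <- stats[stats$log10p > -log10(p_select), , drop = FALSE]
  if (!nrow(sel)) {
    out <- data.frame(locus = integer(), chr = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("locus_table", "data.frame")
    return(out)
  }
  unsorted <- any(unlist(tapply(sel$bp, sel$chr, is.unsorted)))
  if (unsorted) warning("input not position-sorted; sorting internally")
  sel <- sel[order(.chr_rank(sel$chr), sel$bp), , drop = FALSE]
  rows <- list()
  for (ch in unique(sel$chr)) {
    s <- sel[sel$chr == ch, , drop = FALSE]
    gaps <- diff(s$bp)
    grp <- cumsum(c(1L, as.integer(gaps > gap_bp)))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(chr = ch, start = min(sg$bp),
                                        end = max(sg$bp),
                                        members = sg$snp)
    }
  }
  out <- data.frame(
    locus = seq_along(rows),
    chr = vapply(rows, `[[`, "", "chr"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    n_snps = vapply(rows, function(r) length(r$members), 0L),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  class(out) <- c("locus_table", "data.frame")
  out
}

# numeric chromosome ordering with X last
#' @keywords internal
.chr_rank <- function(chr) {
  v <- suppressWarnings(as.numeric(chr))
  v[chr %in% c("X", "x")] <- 23
  v[is.na(v)] <- 99
  v
}

#' Stepwise conditional selection of distinct SNPs at a locus
#'
#' Refits the association of every member SNP conditional on the SNPs
#' already selected at the locus (logistic regression for a binary
#' phenotype, least squares otherwise), starting from the marginal model.
#' While the best conditional p-value is below `p_gw`, the top SNP (ties
#' broken by smallest p, then smallest position, then id) enters the
#' conditioning set. Candidates whose dosage is predicted from the selected
#' set with r-squared above `r2_guard` are skipped as collinear.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype 0/1 or quantitative vector.
#' @param covariates covariate table or NULL.
#' @param members character vector of candidate SNP ids (a `locus_table`
#'   row's `members` element).
#' @param p_gw genome-wide significance threshold (default 5e-8).
#' @param r2_guard collinearity guard between a candidate and the selected
#'   set (default 0.9, the usual conditional-analysis convention).
#' @return character vector of selected SNP ids in order of entry.
#' @export
select_distinct_snps <- function(panel, phenotype, covariates = NULL,
                                 members, p_gw = 5e-8, r2_guard = 0.9) {
  G <- panel$dosage
  stopifnot(all(members %in% colnames(G)))
  binary <- all(phenotype %in% c(0, 1))
  X0 <- .design_matrix(covariates, nrow(G))
  pos <- panel$snp_meta$pos[match(members, panel$snp_meta$id)]
  selected <- character()
  repeat {
    remaining <- setdiff(members, selected)
    if (!length(remaining)) break
    Xc <- cbind(X0, G[, selected, drop = FALSE])
    # collinearity guard: candidate regressed on intercept + selected set
    if (length(selected)) {
      qc <- qr(Xc)
      usable <- vapply(remaining, function(s) {
        g <- G[, s]
        tss <- sum((g - mean(g))^2)
        if (tss < .Machine$double.eps) return(FALSE)
        r2 <- 1 - sum(qr.resid(qc, g)^2) / tss
        r2 <= r2_guard
      }, logical(1))
      if (any(!usable)) {
        message("skipping ", sum(!usable),
                " candidate(s) collinear with the selected set")
      }
      remaining <- remaining[usable]
      if (!length(remaining)) break
    }
    cond <- .conditional_scan(G, phenotype, Xc, remaining, binary)
    ok <- cond$log10p > -log10(p_gw)
    if (!any(ok)) break
    cand <- which(ok)
    best <- cand[order(-cond$log10p[cand], pos[match(remaining[cand], members)],
                       remaining[cand])][1]
    selected <- c(selected, remaining[best])
  }
  selected
}

# per-SNP association conditional on a fixed design matrix
#' @keywords internal
.conditional_scan <- function(G, phenotype, Xc, snps, binary) {
  n <- nrow(G)
  if (binary) {
    log10p <- vapply(snps, function(s) {
      fit <- suppressWarnings(stats::glm.fit(
        x = cbind(Xc, snp = G[, s]), y = phenotype,
        family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 25)))
      w <- .glm_wald(fit)
      k <- length(w$coef)
      if (!is.finite(w$se[k]) || w$se[k] <= 0) return(0)
      .z_to_p(w$coef[k] / w$se[k])$log10p
    }, numeric(1))
  } else {
    qx <- qr(Xc)
    yr <- qr.resid(qx, phenotype)
    Gr <- qr.resid(qx, G[, snps, drop = FALSE])
    gtg <- colSums(Gr^2)
    beta <- drop(crossprod(Gr, yr)) / gtg
    df <- n - ncol(Xc) - 1L
    sigma2 <- pmax(sum(yr^2) - beta^2 * gtg, 0) / df
    tval <- beta / sqrt(sigma2 / gtg)
    log10p <- .t_to_p(tval, df)$log10p
  }
  list(snp = snps, log10p = unname(log10p))
}

#' Attach distinct SNPs to a locus table and prune empty loci
#'
#' Runs [select_distinct_snps()] on every locus and keeps only loci with at
#' least one distinct SNP (a locus where nothing stays genome-wide
#' significant conditionally is discarded); loci are renumbered.
#'
#' @inheritParams select_distinct_snps
#' @param loci a `locus_table` from [define_loci()].
#' @return the pruned `locus_table` with a `distinct` list-column and an
#'   `n_distinct` column.
#' @export
add_distinct_snps <- function(loci, panel, phenotype, covariates = NULL,
                              p_gw = 5e-8, r2_guard = 0.9) {
  distinct <- lapply(loci$members, function(mem) {
    select_distinct_snps(panel, phenotype, covariates, mem,
                         p_gw = p_gw, r2_guard = r2_guard)
  })
  keep <- lengths(distinct) > 0L
  out <- loci[keep, , drop = FALSE]
  out$distinct <- distinct[keep]
  out$n_distinct <- lengths(out$distinct)
  out$locus <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Merge named loci
#'
#' Same-chromosome loci linked by conditional analysis can be merged via an
#' explicit list (merging is never inferred from distance alone).
#'
#' @param loci a `locus_table`.
#' @param merge_list list of integer vectors of locus ids to merge.
#' @return the merged, renumbered `locus_table`.
#' @export
merge_loci <- function(loci, merge_list) {
  for (grp in merge_list) {
    rows <- match(grp, loci$locus)
    if (anyNA(rows)) stop("unknown locus id in merge list")
    if (length(unique(loci$chr[rows])) != 1L) {
      stop("cannot merge loci on different chromosomes")
    }
    first <- rows[1]
    loci$start[first] <- min(loci$start[rows])
    loci$end[first] <- max(loci$end[rows])
    loci$members[[first]] <- unique(unlist(loci$members[rows]))
    loci$n_snps[first] <- length(loci$members[[first]])
    if (!is.null(loci$distinct)) {
      loci$distinct[[first]] <- unique(unlist(loci$distinct[rows]))
      loci$n_distinct[first] <- length(loci$distinct[[first]])
    }
    loci <- loci[-rows[-1], , drop = FALSE]
  }
  loci <- loci[order(.chr_rank(loci$chr), loci$start), , drop = FALSE]
  loci$locus <- seq_len(nrow(loci))
  rownames(loci) <- NULL
  class(loci) <- c("locus_table", "data.frame")
  loci
}

#' Replication filter
#'
#' Keeps discovery-significant SNPs whose replication meta-analysis p-value
#' is strictly below `p_rep` and (by default) whose effect direction agrees
#' with discovery. SNPs absent from the replication table count as
#' unreplicated and are listed in the result.
#'
#' @param discovery,replication `summary_stats` tables (allele-harmonised).
#' @param p_rep replication threshold (default 0.05, strict `<`).
#' @param require_direction demand sign concordance (default TRUE; set
#'   FALSE for the literal p-value-only rule).
#' @return a `replication_result`: list with `stats` (replicated discovery
#'   rows), `n_discovery`, `n_replicated`, `fraction` (NA for an empty
#'   discovery set) and `missing` (SNP ids absent from replication).
#' @export
replicate_filter <- function(discovery, replication, p_rep = 0.05,
                             require_direction = TRUE) {
  n_disc <- nrow(discovery)
  if (n_disc == 0L) {
    return(structure(list(stats = discovery, n_discovery = 0L,
                          n_replicated = 0L, fraction = NA_real_,
                          missing = character()),
                     class = "replication_result"))
  }
  idx <- match(discovery$snp, replication$snp)
  missing <- discovery$snp[is.na(idx)]
  repl_p <- replication$p[idx]
  repl_b <- replication$beta[idx]
  ok <- !is.na(idx) & repl_p < p_rep
  if (require_direction) ok <- ok & (sign(repl_b) == sign(discovery$beta))
  ok[is.na(ok)] <- FALSE
  kept <- discovery[ok, , drop = FALSE]
  class(kept) <- class(discovery)
  structure(list(stats = kept, n_discovery = n_disc,
                 n_replicated = sum(ok), fraction = sum(ok) / n_disc,
                 missing = missing),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  if (is.na(x$fraction)) {
    cat("replication: not applicable (empty discovery set)\n")
  } else {
    cat(sprintf("replication: %d of %d SNPs replicated (%.1f%%)\n",
                x$n_replicated, x$n_discovery, 100 * x$fraction))
  }
  invisible(x)
}

#' Export a locus table as TSV / BED
#'
#' The TSV mirrors the conventional locus summary (Locus, Chr, Start, End,
#' Replicated, N distinct SNPs, N significant SNPs). BED output converts the
#' internal 1-based inclusive coordinates to 0-based half-open.
#' @param loci a `locus_table`.
#' @param path output file.
#' @param replicated optional logical vector (annotation only).
#' @export
write_locus_table <- function(loci, path, replicated = NULL) {
  out <- data.frame(Locus = loci$locus, Chr = loci$chr, Start = loci$start,
                    End = loci$end,
                    Replicated = if (is.null(replicated)) NA else
                      ifelse(replicated, "Y", "N"),
                    N_distinct_SNPs = if (is.null(loci$n_distinct)) NA else
                      loci$n_distinct,
                    N_significant_SNPs = loci$n_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
write_locus_bed <- function(loci, path) {
  bed <- data.frame(chr = loci$chr, start = loci$start - 1L, end = loci$end,
                    name = paste0("locus_", loci$locus))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
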