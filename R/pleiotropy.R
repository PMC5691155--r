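# Regional genotypic scores and cross-trait score correlation for
# locus-level pleiotropy.

#' Define trait-associated regions from summary statistics
#'
#' Regions are seeded by SNPs with p below `p_seed` (default 1e-7) and grown
#' to include every SNP with p below `p_extend` (default 1e-6) reachable
#' without a gap of `gap_bp` (default 1 Mb) or more between consecutive such
#' SNPs; clusters containing no seed are discarded. Region boundaries are
#' the min/max positions of the included SNPs (no padding). The procedure
#' is idempotent and invariant to SNP input order.
#'
#' @param stats a `summary_stats` table (betas are carried as the region's
#'   SNP weights).
#' @param p_seed,p_extend,gap_bp thresholds as above.
#' @param trait label attached to the regions.
#' @return a `trait_regions` data.frame: trait, chr, start, end, n_snps and
#'   a `members` list-column of data.frames (snp, pos, weight, p).
#' @export
define_trait_regions <- function(stats, p_seed = 1e-7, p_extend = 1e-6,
                                 gap_bp = 1e6, trait = "trait") {
  ext <- stats[stats$log10p > -log10(p_extend), , drop = FALSE]
  rows <- list()
  if (nrow(ext)) {
    ext <- ext[order(.chr_rank(ext$chr), ext$bp), , drop = FALSE]
    for (ch in unique(ext$chr)) {
      s <- ext[ext$chr == ch, , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(diff(s$bp) >= gap_bp)))
      for (g in unique(grp)) {
        sg <- s[grp == g, , drop = FALSE]
        if (!any(sg$log10p > -log10(p_seed))) next
        rows[[length(rows) + 1L]] <- list(
          chr = ch, start = min(sg$bp), end = max(sg$bp),
          members = data.frame(snp = sg$snp, pos = sg$bp, weight = sg$beta,
                               p = sg$p, log10p = sg$log10p,
                               stringsAsFactors = FALSE))
      }
    }
  }
  out <- data.frame(
    trait = rep(trait, length(rows)),
    chr = vapply(rows, `[[`, "", "chr"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    n_snps = vapply(rows, function(r) nrow(r$members), 0L),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  class(out) <- c("trait_regions", "data.frame")
  out
}

#' Regional genotypic scores
#'
#' Per-individual, per-region score: sum over the region's SNPs (filtered
#' at `p_filter`, default 1e-6) of genotype dosage times the effect-size
#' weight. Regions where no SNP survives the filter are dropped with a
#' message.
#'
#' @param panel a `genotype_panel` covering the region SNPs.
#' @param regions a `trait_regions` table.
#' @param p_filter per-SNP p-value filter.
#' @return numeric matrix, individuals x regions, columns named
#'   `trait:chr:start-end`.
#' @export
regional_scores <- function(panel, regions, p_filter = 1e-6) {
  G <- panel$dosage
  cols <- list()
  for (i in seq_len(nrow(regions))) {
    mem <- regions$members[[i]]
    mem <- mem[mem$log10p > -log10(p_filter), , drop = FALSE]
    if (!nrow(mem)) {
      message("region ", i, " dropped: no SNP passes the p-value filter")
      next
    }
    miss <- setdiff(mem$snp, colnames(G))
    if (length(miss)) {
      stop("panel does not cover region SNP(s): ", paste(miss, collapse = ", "))
    }
    nm <- sprintf("%s:%s:%d-%d", regions$trait[i], regions$chr[i],
                  regions$start[i], regions$end[i])
    cols[[nm]] <- drop(G[, mem$snp, drop = FALSE] %*% mem$weight)
  }
  if (!length(cols)) stop("no region survived the p-value filter")
  do.call(cbind, cols)
}

#' Cross-trait correlation of regional scores
#'
#' Pairwise squared Pearson correlations between the columns of two score
#' matrices over shared individuals; pairs at or above `r2_flag` (default
#' 0.5) are flagged. Constant score columns yield NA with a note. Flagging
#' is symmetric by construction.
#'
#' @param scores_a,scores_b score matrices with aligned rows.
#' @param r2_flag flagging threshold on the squared correlation.
#' @return a `score_correlation`: list with `r2` (matrix a x b), `flagged`
#'   (logical matrix), `pairs` (data.frame of flagged pairs) and
#'   `undefined` (names of constant columns).
#' @export
cross_trait_correlation <- function(scores_a, scores_b, r2_flag = 0.5) {
  scores_a <- as.matrix(scores_a)
  scores_b <- as.matrix(scores_b)
  if (nrow(scores_a) != nrow(scores_b)) {
    stop("score matrices do not share individuals")
  }
  sd_a <- apply(scores_a, 2, stats::sd)
  sd_b <- apply(scores_b, 2, stats::sd)
  undefined <- c(colnames(scores_a)[sd_a == 0], colnames(scores_b)[sd_b == 0])
  if (length(undefined)) {
    message("correlation undefined for constant score(s): ",
            paste(undefined, collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(scores_a, scores_b))
  r[!is.finite(r)] <- NA
  r2 <- r^2
  flagged <- !is.na(r2) & r2 >= r2_flag
  idx <- which(flagged, arr.ind = TRUE)
  pairs <- data.frame(
    score_a = colnames(scores_a)[idx[, 1]],
    score_b = colnames(scores_b)[idx[, 2]],
    r2 = r2[idx], stringsAsFactors = FALSE)
  structure(list(r2 = r2, flagged = flagged, pairs = pairs,
                 undefined = undefined),
            class = "score_correlation")
}

#' @export
print.score_correlation <- function(x, ...) {
  cat(sprintf("score_correlation: %d x %d pairs, %d flagged at r2 >= threshold\n",
              nrow(x$r2), ncol(x$r2), nrow(x$pairs)))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a trait-region table as TSV
#' @param regions a `trait_regions` table.
#' @param path output file.
#' @export
write_region_table <- function(regions, path) {
  out <- regions[, c("trait", "chr", "start", "end", "n_snps")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
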