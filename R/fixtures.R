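# Packaged worked-example tables for a large male-pattern-baldness GWAS:
# the published locus summary and the pathway -> locus -> SNP composition
# used to build pathway polygenic risk scores.

#' Published MPB locus summary table
#'
#' 71 replicated susceptibility loci for male-pattern baldness with
#' chromosome, 1-based inclusive interval, novelty flag (replicated = "N"
#' marks loci first described by the source study), the number of
#' conditionally distinct SNPs, the total number of significant replicated
#' SNPs, the prioritised gene and the top p-value (kept as printed, as a
#' string: the strongest locus underflows double precision).
#'
#' @return data.frame with one row per locus.
#' @export
mpb_loci <- function() {
  path <- system.file("extdata", "mpb_loci.tsv", package = "pathpgs")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(top_p = "character", chr = "character"))
}

#' Published pathway composition table
#'
#' 28 enriched pathways with the loci whose genes they contain, the number
#' of distinct SNPs those loci contribute, and the SNP ids; the direct
#' input for pathway polygenic risk scores.
#'
#' @return data.frame: pathway, loci (";"-separated ids), n_snps, snps.
#' @export
mpb_pathways <- function() {
  path <- system.file("extdata", "mpb_pathways.tsv", package = "pathpgs")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The three curated pathway merges
#'
#' Pathway pairs whose locus sets are identical and whose scores were
#' therefore merged in the source analysis; used with
#' [aggregate_scores()]'s `"explicit"` merge rule.
#' @return list of character vectors.
#' @export
mpb_pathway_merges <- function() {
  list(c("Apoptosis", "Apoptotic signalling pathway"),
       c("Wnt signalling pathway", "Wnt signalling pathway and pluripotency"),
       c("WNT ligand biogenesis and trafficking",
         "Wnt signalling in kidney disease"))
}

#' Parse the loci / SNP-list columns of the pathway table
#' @param pathways the [mpb_pathways()] table (or one shaped like it).
#' @return list with `loci` (list of integer vectors) and `snps` (list of
#'   character vectors), both named by pathway.
#' @export
pathway_composition <- function(pathways) {
  loci <- lapply(strsplit(pathways$loci, ";", fixed = TRUE), as.integer)
  snps <- strsplit(pathways$snps, ";", fixed = TRUE)
  names(loci) <- names(snps) <- pathways$pathway
  list(loci = loci, snps = snps)
}
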