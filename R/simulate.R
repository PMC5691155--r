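# Synthetic GWAS world: block-LD genotype panels, a liability-threshold
# binary trait split across an autosome-like and an X-like component, and
# secondary traits whose shared genetic effects are restricted to named
# pathway subsets of loci.

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic GWAS world.
#' The defaults describe a high-prevalence, highly heritable binary trait
#' (prevalence 0.59, liability-scale heritability 0.82 autosomal + 0.12
#' X-linked) screened on a dense biallelic panel with block-wise LD.
#'
#' @param n_individuals number of (male) individuals.
#' @param n_snps_autosomal,n_snps_x SNP counts for the autosome-like and
#'   X-like components.
#' @param maf_range length-2 vector of minor allele frequencies in (0, 0.5];
#'   per-SNP MAFs are drawn uniformly from this range.
#' @param ld_block_size SNPs per LD block; blocks are mutually independent.
#' @param ld_decay AR(1) correlation of the latent Gaussian haplotype process
#'   within a block, in [0, 1).
#' @param n_loci number of causal loci (placed well over 500 kb apart).
#' @param distinct_per_locus length-2 integer range (within 1..5) for the
#'   number of conditionally distinct causal SNPs per locus.
#' @param h2_autosomal,h2_x liability-scale heritability attributed to each
#'   component; their sum must be below 1.
#' @param prevalence population case fraction of the binary trait.
#' @param pathway_spec list of pathway entries, each a list with elements
#'   `name` (character), `loci` (integer locus ids) and `slopes` (named
#'   numeric: per-standard-deviation effect of the pathway genetic value on
#'   each named secondary trait).
#' @param beta_dist distribution of causal effect sizes: `"normal"` (the
#'   default; locus contributions are then chi-square heavy-tailed, as in
#'   real architectures) or `"equal"` (equal magnitude, random sign; gives
#'   every locus the same detection power, which the demonstration
#'   scenarios rely on).
#' @param spacing_bp base-pair spacing between consecutive SNPs.
#' @param seed integer seed; all generators are deterministic given it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       n_snps_autosomal = 500,
                       n_snps_x = 0,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_decay = 0.6,
                       n_loci = 0,
                       distinct_per_locus = c(1L, 1L),
                       h2_autosomal = 0,
                       h2_x = 0,
                       prevalence = 0.59,
                       pathway_spec = list(),
                       beta_dist = c("normal", "equal"),
                       spacing_bp = 10000,
                       seed = 1L) {
  beta_dist <- match.arg(beta_dist)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing pair of frequencies in (0, 0.5]")
  }
  if (ld_block_size < 1L) stop("`ld_block_size` must be at least 1")
  if (ld_decay < 0 || ld_decay >= 1) stop("`ld_decay` must lie in [0, 1)")
  if (h2_autosomal < 0 || h2_x < 0 || h2_autosomal + h2_x >= 1) {
    stop("heritabilities must be non-negative with h2_autosomal + h2_x < 1")
  }
  .check_fraction(prevalence, "prevalence")
  if (length(distinct_per_locus) != 2L ||
      distinct_per_locus[1] < 1L || distinct_per_locus[2] > 5L ||
      distinct_per_locus[1] > distinct_per_locus[2]) {
    stop("`distinct_per_locus` must be a range within 1..5")
  }
  for (pw in pathway_spec) {
    if (!all(c("name", "loci", "slopes") %in% names(pw))) {
      stop("each pathway_spec entry needs `name`, `loci` and `slopes`")
    }
    if (length(pw$loci) && (any(pw$loci < 1L) || any(pw$loci > n_loci))) {
      stop("pathway '", pw$name, "' references locus ids outside 1..n_loci")
    }
  }
  n_loci_x <- if (n_snps_x > 0 && h2_x > 0 && n_loci > 0) 1L else 0L
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps_autosomal = as.integer(n_snps_autosomal),
    n_snps_x = as.integer(n_snps_x),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    ld_decay = as.numeric(ld_decay),
    n_loci = as.integer(n_loci),
    n_loci_x = n_loci_x,
    distinct_per_locus = as.integer(distinct_per_locus),
    h2_autosomal = as.numeric(h2_autosomal),
    h2_x = as.numeric(h2_x),
    prevalence = as.numeric(prevalence),
    pathway_spec = pathway_spec,
    beta_dist = beta_dist,
    spacing_bp = as.integer(spacing_bp),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
#' @keywords internal
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# Latent AR(1) Gaussian haplotype block: n x m matrix, unit marginals,
# corr(z_j, z_{j+1}) = rho.
#' @keywords internal
.ar1_block <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1L) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  z
}

#' Closed-form LD target for the block-copula generator
#'
#' Correlation between the allele indicators of two SNPs whose latent
#' Gaussians have correlation `rho` and whose alleles are defined by
#' thresholding at the (1 - MAF) quantile. Under the generator the genotype
#' (sum of two independent haplotypes) has exactly the same correlation.
#' The orthant probability is evaluated by one-dimensional quadrature.
#'
#' @param maf1,maf2 minor allele frequencies of the two SNPs.
#' @param rho latent correlation (for adjacent SNPs, `ld_decay`).
#' @return Pearson correlation of the two genotype dosages.
#' @export
ld_target_r <- function(maf1, maf2, rho) {
  t1 <- stats::qnorm(1 - maf1)
  t2 <- stats::qnorm(1 - maf2)
  if (abs(rho) < 1e-12) return(0)
  p11 <- stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((rho * z - t2) / sqrt(1 - rho^2))
  }, lower = t1, upper = Inf, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Simulate a genotype panel with block LD
#'
#' Haplotypes are generated from a Gaussian copula: within each block of
#' `ld_block_size` SNPs the latent process is AR(1) with parameter
#' `ld_decay`; alleles arise by thresholding at Hardy-Weinberg frequencies,
#' and genotype dosage is the sum of two independent haplotypes (autosomes)
#' or twice the single haplotype (male X, full dosage compensation, so male
#' X dosages are 0 or 2).
#'
#' @param config a [sim_config()].
#' @return an object of class `genotype_panel`: a list with `dosage`
#'   (individuals x SNPs), `snp_meta` (id, chr, pos, a1 = effect allele,
#'   a2, maf) and `sex` (1 = male; the default world is all-male).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_individuals
    m_a <- config$n_snps_autosomal
    m_x <- config$n_snps_x
    m <- m_a + m_x
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(1 - maf)
    G <- matrix(0, n, m)
    fill <- function(cols, haploid) {
      nb <- length(cols)
      starts <- seq(1L, nb, by = config$ld_block_size)
      for (s in starts) {
        idx <- cols[s:min(s + config$ld_block_size - 1L, nb)]
        mB <- length(idx)
        tB <- matrix(thr[idx], n, mB, byrow = TRUE)
        h1 <- (.ar1_block(n, mB, config$ld_decay) > tB) + 0
        if (haploid) {
          G[, idx] <<- 2 * h1
        } else {
          h2 <- (.ar1_block(n, mB, config$ld_decay) > tB) + 0
          G[, idx] <<- h1 + h2
        }
      }
    }
    if (m_a > 0) fill(seq_len(m_a), haploid = FALSE)
    if (m_x > 0) fill(m_a + seq_len(m_x), haploid = TRUE)
    ids <- paste0("rs", seq_len(m))
    chr <- c(rep("1", m_a), rep("X", m_x))
    pos <- c(seq_len(m_a), seq_len(m_x)) * config$spacing_bp
    dimnames(G) <- list(paste0("id", seq_len(n)), ids)
    structure(list(
      dosage = G,
      snp_meta = data.frame(id = ids, chr = chr, pos = pos,
                            a1 = "A", a2 = "G",
                            maf = maf, stringsAsFactors = FALSE),
      sex = rep(1L, n)
    ), class = "genotype_panel")
  })
}

#' Construct a genotype panel from a dosage matrix
#'
#' Low-level constructor for panels not produced by the simulator (e.g.
#' read from external files or built in tests). Positions must be strictly
#' increasing within a chromosome.
#'
#' @param dosage numeric matrix, individuals x SNPs, values in [0, 2];
#'   column names are the SNP ids (generated when absent).
#' @param chr chromosome label(s), recycled across SNPs.
#' @param pos 1-based positions (default: 10 kb spacing per chromosome).
#' @param a1,a2 effect / other alleles, recycled.
#' @param sex per-individual codes (1 = male), default all male.
#' @return a `genotype_panel`.
#' @export
genotype_panel <- function(dosage, chr = "1", pos = NULL,
                           a1 = "A", a2 = "G", sex = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("rs", seq_len(m))
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  chr <- rep_len(as.character(chr), m)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(m), chr, FUN = seq_along) * 10000L
  }
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  for (ch in unique(chr)) {
    if (is.unsorted(pos[chr == ch], strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(list(
    dosage = dosage,
    snp_meta = data.frame(id = colnames(dosage), chr = chr, pos = as.integer(pos),
                          a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                          maf = pmin(colMeans(dosage, na.rm = TRUE) / 2,
                                     1 - colMeans(dosage, na.rm = TRUE) / 2),
                          stringsAsFactors = FALSE),
    sex = if (is.null(sex)) rep(1L, nrow(dosage)) else as.integer(sex)
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(sprintf("%s: %d", names(table(x$snp_meta$chr)),
                            as.integer(table(x$snp_meta$chr))),
                    collapse = ", ")))
  invisible(x)
}

# Deterministic causal architecture: locus centres evenly spaced, each locus
# containing k conditionally distinct causal SNPs placed in different LD
# blocks (hence nearly orthogonal).
#' @keywords internal
.plan_loci <- function(config) {
  if (config$n_loci == 0L) {
    return(data.frame(locus = integer(), snp_index = integer(),
                      chr = character(), stringsAsFactors = FALSE))
  }
  n_x <- config$n_loci_x
  n_a <- config$n_loci - n_x
  k <- sample(seq(config$distinct_per_locus[1], config$distinct_per_locus[2]),
              config$n_loci, replace = TRUE)
  rows <- list()
  place <- function(locus_ids, offset, m_comp, chr_label) {
    if (!length(locus_ids)) return()
    span <- floor(m_comp / length(locus_ids))
    need <- 5L * config$ld_block_size
    if (span <= need) {
      stop("not enough SNPs to separate ", length(locus_ids),
           " loci on chromosome ", chr_label)
    }
    for (i in seq_along(locus_ids)) {
      centre <- (i - 1L) * span + floor(span / 2)
      ki <- k[locus_ids[i]]
      idx <- offset + centre + (seq_len(ki) - 1L) * config$ld_block_size
      rows[[length(rows) + 1L]] <<- data.frame(
        locus = locus_ids[i], snp_index = idx, chr = chr_label,
        stringsAsFactors = FALSE)
    }
  }
  place(seq_len(n_a), 0L, config$n_snps_autosomal, "1")
  place(if (n_x) n_a + seq_len(n_x) else integer(), config$n_snps_autosomal,
        config$n_snps_x, "X")
  do.call(rbind, rows)
}

#' Simulate liability-threshold and pathway-shared traits
#'
#' The primary binary trait arises from a liability `g_auto + g_x + e`
#' thresholded at the standard-normal quantile of (1 - prevalence); each
#' genetic component is scaled to its configured heritability exactly (in
#' sample), and the noise variance is `1 - h2`. Secondary quantitative
#' traits receive genetic input only through the configured pathways: for
#' each pathway its standardized genetic value (the weighted dosage sum over
#' its loci's causal SNPs) enters with the stated per-SD slope, plus unit
#' normal noise. Opposite-signed slopes on pathways of equal weight
#' therefore cancel in the genome-wide genetic value while remaining fully
#' visible within each pathway.
#'
#' @param panel a `genotype_panel` from [simulate_panel()].
#' @param config the same [sim_config()] used to build the panel.
#' @return list with `phenotypes` (data.frame: id, mpb, one column per
#'   secondary trait, age and two inert covariates) and `truth` (causal
#'   table with liability betas, per-component h2, liability threshold,
#'   pathway slopes, per-pathway standardized genetic values, locus table).
#' @export
simulate_traits <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (nrow(panel$dosage) != config$n_individuals ||
      ncol(panel$dosage) != config$n_snps_autosomal + config$n_snps_x) {
    stop("panel and config dimensions disagree")
  }
  .with_seed(config$seed + 1000L, {
    n <- config$n_individuals
    plan <- .plan_loci(config)
    g_auto <- numeric(n)
    g_x <- numeric(n)
    beta <- numeric(nrow(plan))
    scale_component <- function(idx, h2) {
      if (!length(idx) || h2 <= 0) {
        return(list(g = numeric(n), b = rep(0, length(idx))))
      }
      X <- panel$dosage[, plan$snp_index[idx], drop = FALSE]
      b <- if (identical(config$beta_dist, "equal")) {
        # equal variance explained per causal SNP (random sign): effects
        # inversely proportional to the dosage standard deviation
        sample(c(-1, 1), length(idx), replace = TRUE) /
          pmax(apply(X, 2, stats::sd), 1e-8)
      } else {
        stats::rnorm(length(idx))
      }
      g <- drop(X %*% b)
      g <- g - mean(g)   # liability is defined up to a constant
      v <- stats::var(g)
      if (v < 1e-12) stop("degenerate genetic component")
      b <- b * sqrt(h2 / v)
      list(g = g * sqrt(h2 / v), b = b)
    }
    ia <- which(plan$chr == "1")
    ix <- which(plan$chr == "X")
    ca <- scale_component(ia, config$h2_autosomal)
    cx <- scale_component(ix, config$h2_x)
    g_auto <- ca$g; beta[ia] <- ca$b
    g_x <- cx$g; beta[ix] <- cx$b
    h2 <- config$h2_autosomal + config$h2_x
    e <- stats::rnorm(n, sd = sqrt(1 - h2))
    liab <- g_auto + g_x + e
    thr <- stats::qnorm(1 - config$prevalence)
    mpb <- as.integer(liab > thr)

    # pathway genetic values, standardized to unit sample variance
    pw_g <- list()
    for (pw in config$pathway_spec) {
      idx <- which(plan$locus %in% pw$loci)
      g <- if (length(idx)) {
        drop(panel$dosage[, plan$snp_index[idx], drop = FALSE] %*% beta[idx])
      } else numeric(n)
      s <- stats::sd(g)
      pw_g[[pw$name]] <- if (s > 0) (g - mean(g)) / s else g
    }
    trait_names <- unique(unlist(lapply(config$pathway_spec,
                                        function(pw) names(pw$slopes))))
    secondary <- matrix(0, n, length(trait_names),
                        dimnames = list(NULL, trait_names))
    for (tn in trait_names) secondary[, tn] <- stats::rnorm(n)
    for (pw in config$pathway_spec) {
      for (tn in names(pw$slopes)) {
        secondary[, tn] <- secondary[, tn] + pw$slopes[[tn]] * pw_g[[pw$name]]
      }
    }

    phen <- data.frame(id = rownames(panel$dosage), mpb = mpb,
                       stringsAsFactors = FALSE)
    if (length(trait_names)) phen <- cbind(phen, as.data.frame(secondary))
    phen$age <- round(stats::rnorm(n, 57, 8), 1)
    phen$pc1 <- stats::rnorm(n)
    phen$pc2 <- stats::rnorm(n)

    causal <- data.frame(
      snp = panel$snp_meta$id[plan$snp_index],
      locus = plan$locus,
      chr = plan$chr,
      pos = panel$snp_meta$pos[plan$snp_index],
      beta = beta,
      stringsAsFactors = FALSE)
    truth <- list(
      causal = causal,
      h2 = c(autosomal = config$h2_autosomal, x = config$h2_x),
      prevalence = config$prevalence,
      threshold = thr,
      liability = liab,
      genetic_value = g_auto + g_x,
      genetic_value_autosomal = g_auto,
      genetic_value_x = g_x,
      pathway_genetic = pw_g,
      pathway_slopes = lapply(
        stats::setNames(config$pathway_spec,
                        vapply(config$pathway_spec, `[[`, "", "name")),
        `[[`, "slopes"))
    list(phenotypes = phen, truth = truth)
  })
}

#' Write simulated data as plain-text fixtures
#'
#' Emits a VCF 4.2 genotype file (GT and DS fields), a TSV
#' phenotype/covariate table and a GMT pathway file, all of which round-trip
#' through [read_panel_vcf()], [read_phenotypes()] and [read_gmt()].
#'
#' @param panel a `genotype_panel`.
#' @param phenotypes phenotype data.frame (first column `id`).
#' @param pathways named list: pathway name -> character vector of member
#'   ids; may be empty.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
emit_fixtures <- function(panel, phenotypes, pathways, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- c(genotypes = file.path(out_dir, "genotypes.vcf"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             pathways = file.path(out_dir, "pathways.gmt"))
  write_panel_vcf(panel, paths[["genotypes"]])
  utils::write.table(phenotypes, paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(pathways, paths[["pathways"]])
  invisible(paths)
}

#' Write a genotype panel as VCF 4.2
#'
#' One record per SNP with REF = other allele, ALT = effect allele and both
#' GT and DS per sample; male X genotypes are written as haploid GT with
#' dosage-compensated DS in \{0, 2\}.
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @export
write_panel_vcf <- function(panel, path) {
  meta <- panel$snp_meta
  G <- panel$dosage
  n <- nrow(G)
  male_x <- outer(panel$sex == 1L, meta$chr %in% c("X", "23"), `&`)
  gt <- matrix("", nrow(G), ncol(G))
  gt[G == 0] <- "0/0"; gt[G == 1] <- "0/1"; gt[G == 2] <- "1/1"
  gt[male_x & G == 0] <- "0"
  gt[male_x & G == 2] <- "1"
  field <- matrix(paste0(gt, ":", formatC(G, format = "g", digits = 10)),
                  nrow(G), ncol(G))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pathpgs-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(meta$chr[j], meta$pos[j], meta$id[j], meta$a2[j], meta$a1[j],
            ".", "PASS", ".", "GT:DS", field[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from a VCF written by [write_panel_vcf()]
#'
#' Parses the constrained VCF dialect this package emits (single-ALT
#' records, GT:DS sample fields). The DS field is used when present,
#' otherwise dosage is recovered from GT.
#'
#' @param path VCF file.
#' @param sex optional per-individual sex codes (1 = male); defaults to all
#'   male, matching the simulator.
#' @return a `genotype_panel`.
#' @export
read_panel_vcf <- function(path, sex = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  samples <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]][-(1:9)]
  records <- lines[-seq_len(hdr)]
  records <- records[nzchar(records)]
  parts <- strsplit(records, "\t", fixed = TRUE)
  m <- length(parts)
  n <- length(samples)
  G <- matrix(NA_real_, n, m)
  meta <- data.frame(id = character(m), chr = character(m), pos = integer(m),
                     a1 = character(m), a2 = character(m), maf = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- parts[[j]]
    meta$chr[j] <- f[1]; meta$pos[j] <- as.integer(f[2]); meta$id[j] <- f[3]
    meta$a2[j] <- f[4]; meta$a1[j] <- f[5]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    ds_i <- match("DS", fmt)
    if (!is.na(ds_i)) {
      G[, j] <- as.numeric(vapply(cells, `[[`, "", ds_i))
    } else {
      gt_i <- match("GT", fmt)
      if (is.na(gt_i)) stop("record ", f[3], " carries neither DS nor GT")
      gt <- vapply(cells, `[[`, "", gt_i)
      alt <- vapply(strsplit(gt, "[/|]"), function(a) sum(a == "1"), 0)
      ploidy <- vapply(strsplit(gt, "[/|]"), length, 0L)
      alt[ploidy == 1L] <- 2 * alt[ploidy == 1L]  # haploid male X
      G[, j] <- alt
    }
  }
  meta$maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  dimnames(G) <- list(samples, meta$id)
  structure(list(dosage = G, snp_meta = meta,
                 sex = if (is.null(sex)) rep(1L, n) else as.integer(sex)),
            class = "genotype_panel")
}

#' Read a phenotype/covariate TSV
#' @param path TSV with a header; first column must be `id`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ph)[1] != "id") stop("phenotype table must start with an `id` column")
  ph
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member ids. Duplicate
#' members within a set are dropped with a warning.
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    out[[f[1]]] <- members
  }
  out
}

#' @rdname read_gmt
#' @param sets named list: set name -> member ids.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
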