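#' Genome specification for the simulator
#'
#' @param chromosomes named numeric vector of chromosome lengths in base
#'   pairs, e.g. `c(A01 = 30e6, B06 = 40e6)`. Coordinates throughout the
#'   package are 1-based inclusive (VCF/GFF3 convention).
#' @return a `genome_spec` object.
#' @export
genome_spec <- function(chromosomes) {
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1,
            all(chromosomes > 0))
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)) ||
      any(names(chromosomes) == "")) {
    stop("chromosomes must have unique non-empty names", call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, coordinates = "1-based inclusive"),
            class = "genome_spec")
}

#' Planted-QTL specification
#'
#' @param chrom,pos locus of the causal SNP.
#' @param effect_size proportion of phenotypic variance attributed to the
#'   QTL, in `[0, 1)`.
#' @param affected_trait trait name the QTL acts on.
#' @param affected_treatments character vector of treatment codes under
#'   which the QTL is expressed (default: all).
#' @return a `qtl_spec` object.
#' @export
qtl_spec <- function(chrom, pos, effect_size, affected_trait,
                     affected_treatments = NULL) {
  stopifnot(effect_size >= 0, effect_size < 1, pos >= 1)
  structure(list(chrom = chrom, pos = pos, effect_size = effect_size,
                 affected_trait = affected_trait,
                 affected_treatments = affected_treatments),
            class = "qtl_spec")
}

#' Planted selective-sweep specification
#'
#' @param chrom,start,end region differentiated between the tolerant and
#'   sensitive subpopulations.
#' @param fst_target differentiation level aimed for inside the region,
#'   in `[0, 1]` (expected Weir-Cockerham Fst at the planted allele
#'   frequencies).
#' @return a `sweep_spec` object.
#' @export
sweep_spec <- function(chrom, start, end, fst_target) {
  stopifnot(start < end, fst_target >= 0, fst_target <= 1)
  structure(list(chrom = chrom, start = start, end = end,
                 fst_target = fst_target),
            class = "sweep_spec")
}

#' Planted co-expression module specification
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module genes per planted module (>= 2 when
#'   `n_modules > 0`).
#' @param trait_correlation numeric vector (recycled over modules) of target
#'   correlations between each module's latent factor and its designated
#'   sample covariate; `|r| <= 1`.
#' @param noise_sd gene-level expression noise standard deviation, on the
#'   latent (linear) scale where the factor has unit variance.
#' @param n_background additional independent-noise genes outside any module.
#' @return a `module_spec` object.
#' @export
module_spec <- function(n_modules, genes_per_module,
                        trait_correlation = 0.8, noise_sd = 0.5,
                        n_background = 0) {
  stopifnot(n_modules >= 0, genes_per_module >= 0,
            all(abs(trait_correlation) <= 1), noise_sd >= 0,
            n_background >= 0)
  if (n_modules > 0 && genes_per_module < 2) {
    stop("a planted module needs at least 2 genes", call. = FALSE)
  }
  structure(list(n_modules = n_modules, genes_per_module = genes_per_module,
                 trait_correlation = rep_len(trait_correlation,
                                             max(n_modules, 1)),
                 noise_sd = noise_sd, n_background = n_background),
            class = "module_spec")
}

#' Simulate a panel genotype matrix with LD blocks and a planted sweep
#'
#' Genotypes are generated block-wise: each LD block carries a founder
#' allele frequency, every accession draws two block-level haplotype
#' indicators, and each SNP in the block copies those indicators with a
#' small per-site mutation rate - so markers within a block are in strong
#' LD while blocks are independent. Inside the planted sweep region the two
#' subpopulations (tolerant first, sensitive second, in row order) use
#' divergent allele frequencies chosen so the expected between-group
#' Weir-Cockerham Fst matches `sweep$fst_target`; outside it they share
#' frequencies.
#'
#' @param genome a [genome_spec()].
#' @param n_accessions number of accessions (>= 2).
#' @param n_snps total number of SNPs across the genome (0 allowed).
#' @param maf_range interval of founder minor-allele frequencies, a subset
#'   of (0, 0.5].
#' @param ld_block_len LD block length in base pairs.
#' @param subpop_split integer vector `c(n_tolerant, n_sensitive)`; must sum
#'   to `n_accessions`.
#' @param sweep optional [sweep_spec()]; must lie inside the genome.
#' @param mutation_rate per-site probability that a SNP's allele deviates
#'   from its block haplotype indicator (controls within-block r-squared).
#' @param missing_rate probability an individual genotype call is missing.
#' @param seed integer seed; fixing it fixes every emitted value.
#' @return a [geno_matrix()] with an extra attribute `subpop` (character
#'   vector "tolerant"/"sensitive" per accession, in row order).
#' @export
simulate_genotypes <- function(genome, n_accessions, n_snps,
                               maf_range = c(0.1, 0.5),
                               ld_block_len = 50000,
                               subpop_split = NULL,
                               sweep = NULL,
                               mutation_rate = 0.03,
                               missing_rate = 0.01,
                               seed = 1) {
  stopifnot(inherits(genome, "genome_spec"), n_accessions >= 2, n_snps >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], ld_block_len >= 1,
            mutation_rate >= 0, mutation_rate < 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(subpop_split)) {
    subpop_split <- c(ceiling(n_accessions / 2), floor(n_accessions / 2))
  }
  stopifnot(length(subpop_split) == 2, sum(subpop_split) == n_accessions)
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    chr_len <- genome$chromosomes[sweep$chrom]
    if (is.na(chr_len) || sweep$start < 1 || sweep$end > chr_len) {
      stop("sweep region ", sweep$chrom, ":", sweep$start, "-", sweep$end,
           " lies outside the genome", call. = FALSE)
    }
  }
  set.seed(seed)
  subpop <- rep(c("tolerant", "sensitive"), times = subpop_split)

  chroms <- names(genome$chromosomes)
  lens <- genome$chromosomes
  n_per_chr <- if (n_snps == 0) stats::setNames(rep(0L, length(chroms)), chroms) else {
    alloc <- floor(n_snps * lens / sum(lens))
    rem <- n_snps - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
    stats::setNames(as.integer(alloc), chroms)
  }

  geno <- matrix(integer(0), nrow = n_accessions, ncol = 0)
  map <- data.frame(id = character(), chrom = character(), pos = numeric(),
                    ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  idx_tol <- subpop == "tolerant"

  for (chr in chroms) {
    m <- n_per_chr[[chr]]
    if (m == 0) next
    pos <- sort(sample.int(lens[[chr]], m, replace = FALSE))
    block <- (pos - 1) %/% ld_block_len
    in_sweep <- !is.null(sweep) && chr == sweep$chrom
    gchr <- matrix(0L, nrow = n_accessions, ncol = m)
    for (b in unique(block)) {
      cols <- which(block == b)
      sweep_cols <- if (in_sweep) {
        pos[cols] >= sweep$start & pos[cols] <= sweep$end
      } else rep(FALSE, length(cols))
      q <- stats::runif(1, maf_range[1], maf_range[2])
      # block haplotype indicators, two per accession
      h1 <- stats::rbinom(n_accessions, 1, q)
      h2 <- stats::rbinom(n_accessions, 1, q)
      if (any(sweep_cols)) {
        # divergent frequencies centred on 0.5: for two equal-sized groups
        # the expected Weir-Cockerham ratio at frequency difference d and
        # mean 0.5 is about (d^2/2) / (d^2/4 + 1/4), so d = sqrt(t/(2-t))
        d <- sqrt(sweep$fst_target / (2 - sweep$fst_target))
        qa <- min(0.5 + d / 2, 0.98)
        qb <- max(0.5 - d / 2, 0.02)
        h1s <- ifelse(idx_tol, stats::rbinom(n_accessions, 1, qa),
                      stats::rbinom(n_accessions, 1, qb))
        h2s <- ifelse(idx_tol, stats::rbinom(n_accessions, 1, qa),
                      stats::rbinom(n_accessions, 1, qb))
      }
      for (jj in seq_along(cols)) {
        if (sweep_cols[jj]) { b1 <- h1s; b2 <- h2s } else { b1 <- h1; b2 <- h2 }
        flip1 <- stats::rbinom(n_accessions, 1, mutation_rate)
        flip2 <- stats::rbinom(n_accessions, 1, mutation_rate)
        gchr[, cols[jj]] <- as.integer(abs(b1 - flip1) + abs(b2 - flip2))
      }
    }
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    map <- rbind(map, data.frame(
      id = paste0(chr, "_", pos), chrom = chr, pos = pos,
      ref = ref, alt = alt, stringsAsFactors = FALSE))
    geno <- cbind(geno, gchr)
  }

  if (missing_rate > 0 && length(geno)) {
    drop <- matrix(stats::runif(length(geno)) < missing_rate,
                   nrow = nrow(geno))
    geno[drop] <- NA_integer_
  }
  rownames(geno) <- sprintf("acc%03d", seq_len(n_accessions))
  gm <- geno_matrix(geno, map, contigs = genome$chromosomes)
  attr(gm, "subpop") <- subpop
  gm
}

#' Simulate phenotypes over a treatment x environment x replicate design
#'
#' Each trait value is built multiplicatively around a treatment-specific
#' mean: `value = mean * stress_effect[treatment] * (1 + u + env + e)` where
#' the accession effect `u` is the sum of planted-QTL effects (standardized
#' genotype dosage scaled to explain `effect_size` of phenotypic variance),
#' a polygenic term computed from genome-wide genotypes (so that total
#' genetic variance matches `heritability`), an environment shift and
#' replicate noise. Between-accession variability is expressed as a
#' coefficient of variation `cv` on the relative scale.
#'
#' @param gm a [geno_matrix()] from [simulate_genotypes()].
#' @param qtls list of [qtl_spec()] objects; each locus must exist in `gm`.
#' @param traits character vector of trait names.
#' @param trait_means named numeric vector of control-treatment means per
#'   trait (defaults to 100 for every trait).
#' @param heritability total genetic fraction of phenotypic variance,
#'   in `[0, 1)`. QTL effect sizes are capped by it; the remainder is
#'   polygenic.
#' @param treatments character vector of treatment codes; the first is the
#'   well-watered control.
#' @param environments,replicates numbers of environments and replicates.
#' @param stress_effect named numeric vector of per-treatment multipliers on
#'   the trait mean (control implicitly 1).
#' @param cv between-accession coefficient of variation of the trait on the
#'   relative scale.
#' @param env_sd,res_sd environment-shift and replicate-noise standard
#'   deviations on the relative scale.
#' @param group_effect separation, in accession-effect standard deviations,
#'   between the planted tolerant and sensitive subpopulations under the
#'   stress treatments (uses the `subpop` attribute of `gm`; 0 disables).
#'   The default of 2 reproduces the wide stress-trait dispersion typical
#'   of diversity panels whose subgroups genuinely differ in tolerance.
#' @param seed integer seed.
#' @return a long-format data.frame with columns `accession`, `trait`,
#'   `treatment`, `environment`, `replicate`, `value`.
#' @export
simulate_phenotypes <- function(gm, qtls = list(),
                                traits = c("germination_rate", "shoot_fw",
                                           "root_fw", "chlorophyll", "yield"),
                                trait_means = NULL,
                                heritability = 0.6,
                                treatments = c("CK", "M", "S"),
                                environments = 3, replicates = 3,
                                stress_effect = c(M = 0.7, S = 0.35),
                                cv = 0.2, env_sd = 0.03, res_sd = 0.05,
                                group_effect = 2, seed = 1) {
  stopifnot(inherits(gm, "geno_matrix"), heritability >= 0, heritability < 1,
            length(traits) >= 1, length(treatments) >= 1,
            environments >= 1, replicates >= 1)
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  if (is.null(trait_means)) {
    trait_means <- stats::setNames(rep(100, length(traits)), traits)
  }
  n <- nrow(gm$geno)
  acc <- rownames(gm$geno)
  set.seed(seed)

  # standardized planted-QTL dosages
  qtl_z <- lapply(qtls, function(q) {
    hit <- which(gm$map$chrom == q$chrom & gm$map$pos == q$pos)
    if (!length(hit)) {
      stop("QTL locus ", q$chrom, ":", q$pos,
           " is absent from the genotype map", call. = FALSE)
    }
    g <- gm$geno[, hit[1]]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    s <- stats::sd(g)
    if (s == 0) rep(0, n) else (g - mean(g)) / s
  })

  # polygenic score: random weights over all (mean-imputed, scaled) markers
  poly <- rep(0, n)
  if (ncol(gm$geno) > 0) {
    G <- gm$geno
    cm <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    if (nrow(na_idx)) G[na_idx] <- cm[na_idx[, 2]]
    csd <- apply(G, 2, stats::sd)
    keep <- csd > 0
    if (any(keep)) {
      Z <- scale(G[, keep, drop = FALSE])
      w <- stats::rnorm(ncol(Z))
      poly <- drop(Z %*% w)
      poly <- (poly - mean(poly)) / stats::sd(poly)
    }
  }

  env_shift <- matrix(stats::rnorm(environments * length(traits), 0, env_sd),
                      nrow = environments)
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr_name <- traits[ti]
    qv <- vapply(qtls, function(q) {
      ok_trait <- identical(q$affected_trait, tr_name)
      if (ok_trait) q$effect_size else 0
    }, numeric(1))
    qtl_var <- pmin(qv, heritability)
    poly_var <- max(heritability - sum(qtl_var), 0)
    res_var <- max(1 - sum(qtl_var) - poly_var, 0)

    grid <- expand.grid(accession = acc, treatment = treatments,
                        environment = paste0("E", seq_len(environments)),
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    acc_i <- match(grid$accession, acc)
    env_i <- as.integer(sub("^E", "", grid$environment))
    mult <- ifelse(grid$treatment == treatments[1], 1,
                   stress_effect[grid$treatment])

    u <- rep(0, nrow(grid))
    for (k in seq_along(qtls)) {
      if (qtl_var[k] <= 0) next
      active <- if (is.null(qtls[[k]]$affected_treatments)) TRUE else
        grid$treatment %in% qtls[[k]]$affected_treatments
      u <- u + sqrt(qtl_var[k]) * qtl_z[[k]][acc_i] * as.numeric(active)
    }
    u <- u + sqrt(poly_var) * poly[acc_i]
    subpop <- attr(gm, "subpop")
    if (!is.null(subpop) && group_effect != 0) {
      shift <- ifelse(subpop == "tolerant", group_effect / 2,
                      -group_effect / 2)
      u <- u + shift[acc_i] * as.numeric(grid$treatment != treatments[1])
    }
    rel <- 1 + cv * (u + sqrt(res_var) *
                       stats::rnorm(n)[acc_i]) +
      env_shift[cbind(env_i, ti)] +
      stats::rnorm(nrow(grid), 0, res_sd)
    value <- trait_means[tr_name] * mult * pmax(rel, 0)
    out[[ti]] <- data.frame(accession = grid$accession, trait = tr_name,
                            treatment = grid$treatment,
                            environment = grid$environment,
                            replicate = grid$replicate,
                            value = value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate an FPKM-like expression matrix with planted modules
#'
#' Planted-module genes are linear combinations of one latent factor per
#' module plus independent noise; each latent factor is constructed to have
#' the requested correlation with its designated sample covariate. Genes
#' outside modules are independent noise. Values are shifted to an
#' FPKM-like non-negative scale.
#'
#' @param spec a [module_spec()].
#' @param sample_design data.frame with one row per sample; must contain a
#'   `sample` column plus covariates (e.g. `treatment`, `tissue`, `group`).
#' @param covariates optional character vector naming, per module, the
#'   design column whose (numeric-encoded) values the module factor tracks.
#'   Default: indicator of each non-first treatment level, cycling.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `design` (the sample
#'   design), and `truth` (gene -> planted module label, `"none"` for
#'   background genes).
#' @export
simulate_expression <- function(spec, sample_design, covariates = NULL,
                                seed = 1) {
  stopifnot(inherits(spec, "module_spec"), is.data.frame(sample_design),
            nrow(sample_design) >= 3, "sample" %in% names(sample_design))
  set.seed(seed)
  ns <- nrow(sample_design)
  encode <- function(m) {
    if (is.null(covariates)) {
      lev <- unique(sample_design$treatment)
      tgt <- lev[-1][(m - 1) %% max(length(lev) - 1, 1) + 1]
      as.numeric(sample_design$treatment == tgt)
    } else {
      v <- sample_design[[covariates[(m - 1) %% length(covariates) + 1]]]
      if (is.numeric(v)) v else as.numeric(factor(v))
    }
  }
  n_genes <- spec$n_modules * spec$genes_per_module + spec$n_background
  expr <- matrix(0, nrow = n_genes, ncol = ns)
  truth <- rep("none", n_genes)
  row <- 1
  for (m in seq_len(spec$n_modules)) {
    cvt <- encode(m)
    if (stats::sd(cvt) == 0) stop("module covariate has zero variance",
                                  call. = FALSE)
    z <- stats::rnorm(ns)
    z <- stats::residuals(stats::lm(z ~ cvt))
    z <- z / stats::sd(z)
    rho <- spec$trait_correlation[m]
    f <- rho * scale(cvt)[, 1] + sqrt(1 - rho^2) * z
    for (g in seq_len(spec$genes_per_module)) {
      loading <- stats::runif(1, 0.7, 1.3)
      noise <- if (spec$noise_sd > 0) stats::rnorm(ns, 0, spec$noise_sd) else 0
      expr[row, ] <- loading * f + noise
      truth[row] <- paste0("planted", m)
      row <- row + 1
    }
  }
  if (spec$n_background > 0) {
    expr[row:(row + spec$n_background - 1), ] <-
      matrix(stats::rnorm(spec$n_background * ns), ncol = ns)
  }
  expr <- pmax(10 + 2 * expr, 0)  # FPKM-like, effectively never clipped
  rownames(expr) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(expr) <- sample_design$sample
  list(expr = expr, design = sample_design,
       truth = stats::setNames(truth, rownames(expr)))
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes are placed per chromosome (count proportional to length) by
#' distributing the free space between them uniformly at random, so
#' intervals never overlap and never extend past the chromosome end.
#'
#' @param genome a [genome_spec()].
#' @param n_genes total gene count (>= 0).
#' @param length_range gene length interval in bp (inclusive).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; coordinates 1-based inclusive.
#' @export
simulate_annotation <- function(genome, n_genes, length_range = c(1000, 5000),
                                seed = 1) {
  stopifnot(inherits(genome, "genome_spec"), n_genes >= 0,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  set.seed(seed)
  if (n_genes == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- genome$chromosomes
  alloc <- floor(n_genes * lens / sum(lens))
  rem <- n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  out <- list()
  gid <- 1
  for (chr in names(lens)) {
    k <- alloc[[chr]]
    if (k == 0) next
    glen <- if (length_range[1] == length_range[2]) rep(length_range[1], k) else
      sample(seq(length_range[1], length_range[2]), k, replace = TRUE)
    free <- lens[[chr]] - sum(glen)
    if (free < k) {
      stop("chromosome ", chr, " too small to place ", k,
           " non-overlapping genes of the requested lengths", call. = FALSE)
    }
    # k+1 gaps (>= 1 bp between genes) summing to the free space
    cuts <- sort(sample.int(free - 1, k))
    gaps <- diff(c(0, cuts, free))
    start <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, glen[-k])) + 1
    end <- start + glen - 1
    out[[chr]] <- data.frame(
      gene_id = sprintf("GENE%05d", seq(gid, gid + k - 1)),
      chrom = chr, start = start, end = end,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    gid <- gid + k
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a simulated dataset to standard file formats
#'
#' Serializes genotypes as VCF v4.2, the annotation as GFF3, phenotypes as
#' a long TSV and the expression matrix plus sample design as TSVs - the
#' formats the analysis side of the package reads back.
#'
#' @param dir output directory (created if needed).
#' @param gm optional [geno_matrix()].
#' @param pheno optional phenotype data.frame.
#' @param expr optional result of [simulate_expression()].
#' @param annotation optional annotation data.frame.
#' @return named character vector of files written, invisibly.
#' @export
write_simulation <- function(dir, gm = NULL, pheno = NULL, expr = NULL,
                             annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(gm)) {
    written["vcf"] <- write_vcf_genotypes(gm, file.path(dir, "genotypes.vcf"))
  }
  if (!is.null(pheno)) {
    p <- file.path(dir, "phenotypes.tsv")
    write.table(pheno, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written["phenotypes"] <- p
  }
  if (!is.null(expr)) {
    p <- file.path(dir, "expression.tsv")
    write.table(data.frame(gene = rownames(expr$expr), expr$expr,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    written["expression"] <- p
    d <- file.path(dir, "sample_design.tsv")
    write.table(expr$design, d, sep = "\t", quote = FALSE, row.names = FALSE)
    written["design"] <- d
  }
  if (!is.null(annotation)) {
    written["gff3"] <- write_gff3_annotation(annotation,
                                             file.path(dir, "genes.gff3"))
  }
  invisible(written)
}

#' Read a long-format phenotype table
#'
#' @param path TSV with header `accession trait treatment environment
#'   replicate value`.
#' @return data.frame in the package's phenotype layout.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "trait", "treatment", "environment", "replicate",
            "value")
  if (!all(need %in% names(p))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p
}

#' Read an expression matrix and its sample design
#'
#' @param expr_path TSV with a `gene` column then one column per sample.
#' @param design_path TSV with a `sample` column plus covariates.
#' @return list with `expr` (genes x samples matrix) and `design`.
#' @export
read_expression <- function(expr_path, design_path) {
  e <- utils::read.delim(expr_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(e[, -1, drop = FALSE])
  rownames(m) <- e[[1]]
  d <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(colnames(m) %in% d$sample)) {
    stop("expression columns missing from the sample design", call. = FALSE)
  }
  list(expr = m, design = d[match(colnames(m), d$sample), , drop = FALSE])
}
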