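#' VanRaden genomic relationship (kinship) matrix
#'
#' Mean-imputes missing genotypes, centers each marker by twice its allele
#' frequency, and scales the cross-product by `2 * sum(p * (1 - p))`:
#' `K = W W' / (2 sum p q)` with `W = M - 2p`. The result is the covariance
#' structure of the polygenic random effect in the mixed-model scan.
#'
#' @param gm a [geno_matrix()] with at least one polymorphic SNP.
#' @return n x n symmetric positive semi-definite matrix with accession
#'   dimnames.
#' @export
kinship_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(gm$geno) >= 2)
  G <- gm$geno
  storage.mode(G) <- "double"
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_idx)) G[na_idx] <- cm[na_idx[, 2]]
  p <- cm / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs; kinship undefined", call. = FALSE)
  W <- sweep(G[, poly, drop = FALSE], 2, 2 * p[poly], "-")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(gm$geno), rownames(gm$geno))
  K
}

# Profiled REML log-likelihood in delta = sigma_e^2 / sigma_g^2, using the
# rotated responses (U'y) and design (U'X) and the eigenvalues of K.
reml_loglik <- function(log_delta, yt, Xt, d) {
  delta <- exp(log_delta)
  n <- length(yt)
  q <- ncol(Xt)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt * w, Xt)
  beta <- solve(XtWX, crossprod(Xt * w, yt))
  r <- yt - Xt %*% beta
  R <- sum(w * r^2)
  sg2 <- R / (n - q)
  -0.5 * ((n - q) * log(sg2) + sum(log(d + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus[1])
}

#' Kinship-corrected single-marker association scan
#'
#' Two-stage approximate mixed-model scan in the EMMAX style. Under the
#' null model `y = mu + g + e` with `g ~ N(0, sg2 K)` and
#' `e ~ N(0, se2 I)`, the variance ratio `delta = se2/sg2` is estimated
#' once by REML via the eigen-decomposition of K. Each SNP is then tested
#' by a generalized-least-squares Wald test of its (mean-imputed) dosage
#' holding the variance ratio fixed. SNPs failing the MAF or call-rate
#' filters are reported with `NA` statistics and `filtered = TRUE`.
#'
#' With `K` proportional to the identity the scan reduces exactly to
#' ordinary least-squares regression of the trait on each marker.
#'
#' @param gm a [geno_matrix()].
#' @param trait named numeric vector of per-accession trait values; names
#'   must match accession ids (unnamed vectors are taken in row order).
#' @param K kinship matrix from [kinship_matrix()] (computed from `gm` when
#'   `NULL`).
#' @param min_maf,min_call_rate marker filters (defaults 0.05 and 0.9).
#' @return data.frame (class `assoc_scan`) with columns `id`, `chrom`,
#'   `pos`, `maf`, `call_rate`, `beta`, `se`, `stat`, `p`, `neglog10p`,
#'   `filtered`, plus attributes `delta`, `sigma_g2`, `sigma_e2`, `n`.
#' @export
emmax_scan <- function(gm, trait, K = NULL, min_maf = 0.05,
                       min_call_rate = 0.9) {
  stopifnot(inherits(gm, "geno_matrix"))
  acc <- rownames(gm$geno)
  if (!is.null(names(trait))) {
    if (!all(acc %in% names(trait))) {
      stop("trait values missing for some accessions", call. = FALSE)
    }
    y <- as.numeric(trait[acc])
  } else {
    stopifnot(length(trait) == length(acc))
    y <- as.numeric(trait)
  }
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n <= 3) stop("need more than 3 phenotyped accessions", call. = FALSE)
  if (stats::sd(y) == 0) stop("trait is constant", call. = FALSE)
  if (is.null(K)) K <- kinship_matrix(gm)
  K <- K[keep, keep, drop = FALSE]
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric",
                                      call. = FALSE)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  ones <- matrix(1, n, 1)
  Xt <- crossprod(U, ones)

  opt <- stats::optimize(reml_loglik, interval = c(log(1e-5), log(1e5)),
                         yt = yt, Xt = Xt, d = d, maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)

  # rotate (mean-imputed) genotypes once, then closed-form 2-column GLS
  G <- gm$geno[keep, , drop = FALSE]
  storage.mode(G) <- "double"
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_idx)) G[na_idx] <- cm[na_idx[, 2]]
  Gt <- crossprod(U, G)

  x0 <- drop(Xt)
  a11 <- sum(w * x0^2)
  b1 <- sum(w * x0 * yt)
  syy <- sum(w * yt^2)
  a12 <- drop(crossprod(Gt * w, x0))
  a22 <- colSums(w * Gt^2)
  b2 <- drop(crossprod(Gt * w, yt))
  det2 <- a11 * a22 - a12^2
  det2[det2 <= 0] <- NA_real_
  beta_g <- (a11 * b2 - a12 * b1) / det2
  beta_0 <- (a22 * b1 - a12 * b2) / det2
  rss <- syy - beta_0 * b1 - beta_g * b2
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det2)
  tstat <- beta_g / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  ss <- snp_summary(gm)
  filtered <- is.na(ss$maf) | ss$maf < min_maf | ss$call_rate < min_call_rate |
    !is.finite(p)
  p[filtered] <- NA_real_
  out <- data.frame(id = gm$map$id, chrom = gm$map$chrom, pos = gm$map$pos,
                    maf = ss$maf, call_rate = ss$call_rate,
                    beta = beta_g, se = se, stat = tstat, p = p,
                    neglog10p = -log10(p), filtered = filtered,
                    stringsAsFactors = FALSE)
  sg2 <- sum(w * (yt - x0 * (b1 / a11))^2) / (n - 1)
  attr(out, "delta") <- delta
  attr(out, "sigma_g2") <- sg2
  attr(out, "sigma_e2") <- sg2 * delta
  attr(out, "n") <- n
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Genome-wide significance threshold
#'
#' `"bonferroni"` returns the family-wise cutoff `0.05 / n_snps`;
#' `"suggestive"` returns the fixed cutoff `1e-4`, i.e.
#' `-log10(p) >= 4`, regardless of the number of markers.
#'
#' @param n_snps number of tested SNPs (>= 1).
#' @param mode `"bonferroni"` or `"suggestive"`.
#' @return p-value cutoff.
#' @export
significance_threshold <- function(n_snps, mode = c("bonferroni",
                                                    "suggestive")) {
  mode <- match.arg(mode)
  if (n_snps < 1) stop("n_snps must be at least 1", call. = FALSE)
  switch(mode, bonferroni = 0.05 / n_snps, suggestive = 1e-4)
}

#' SNPs co-detected across environments
#'
#' Given one association scan per environment, returns the SNPs (matched
#' by chromosome and position) that pass the significance cutoff in at
#' least `min_envs` environments, annotated with the environments in which
#' each was detected.
#'
#' @param scans named list of `assoc_scan` data.frames, one per
#'   environment.
#' @param p_cutoff significance cutoff applied within each environment.
#' @param min_envs minimum number of environments (default 2).
#' @return data.frame with columns `id`, `chrom`, `pos`, `n_envs`, `envs`.
#' @export
co_detected <- function(scans, p_cutoff, min_envs = 2) {
  stopifnot(is.list(scans), length(scans) >= 2)
  if (is.null(names(scans))) names(scans) <- paste0("E", seq_along(scans))
  keys <- lapply(scans, function(s) paste(s$chrom, s$pos, sep = ":"))
  shared <- Reduce(intersect, keys)
  if (!length(shared)) {
    stop("association scans share no SNPs (disjoint universes)",
         call. = FALSE)
  }
  hit_env <- lapply(names(scans), function(e) {
    s <- scans[[e]]
    k <- paste(s$chrom, s$pos, sep = ":")
    k[!is.na(s$p) & s$p <= p_cutoff]
  })
  names(hit_env) <- names(scans)
  all_hits <- unique(unlist(hit_env))
  if (!length(all_hits)) {
    return(data.frame(id = character(), chrom = character(), pos = numeric(),
                      n_envs = integer(), envs = character(),
                      stringsAsFactors = FALSE))
  }
  n_in <- vapply(all_hits, function(k) {
    sum(vapply(hit_env, function(h) k %in% h, logical(1)))
  }, integer(1))
  envs <- vapply(all_hits, function(k) {
    paste(names(hit_env)[vapply(hit_env, function(h) k %in% h, logical(1))],
          collapse = ",")
  }, character(1))
  sel <- n_in >= min_envs
  ref <- scans[[1]]
  kref <- paste(ref$chrom, ref$pos, sep = ":")
  idx <- match(all_hits[sel], kref)
  out <- data.frame(id = ref$id[idx], chrom = ref$chrom[idx],
                    pos = ref$pos[idx], n_envs = n_in[sel],
                    envs = envs[sel], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Pairwise LD as genotypic r-squared
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors over
#' pairwise-complete accessions (the composite genotypic r-squared used
#' for unphased data).
#'
#' @param gm a [geno_matrix()].
#' @param snp_a,snp_b SNP ids (or column indices).
#' @return r-squared in `[0, 1]`, or `NA` with a warning when fewer than
#'   3 shared non-missing accessions or either SNP is monomorphic among
#'   them.
#' @export
ld_r2 <- function(gm, snp_a, snp_b) {
  stopifnot(inherits(gm, "geno_matrix"))
  ga <- gm$geno[, snp_a]
  gb <- gm$geno[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 3) {
    warning("fewer than 3 shared non-missing accessions; r2 undefined")
    return(NA_real_)
  }
  if (stats::sd(ga[ok]) == 0 || stats::sd(gb[ok]) == 0) {
    warning("monomorphic SNP among shared accessions; r2 undefined")
    return(NA_real_)
  }
  stats::cor(ga[ok], gb[ok])^2
}

#' Merge significant SNPs into QTL intervals
#'
#' Single-linkage chaining per chromosome: two position-adjacent
#' significant SNPs belong to the same QTL when their distance is at most
#' `max_gap` and their genotypic LD exceeds `min_r2`. Each QTL reports its
#' span (min/max member position), member SNPs, and the peak SNP (smallest
#' p when p-values are supplied, otherwise the first member). Every input
#' SNP lands in exactly one QTL.
#'
#' @param snps data.frame of significant SNPs with columns `id`, `chrom`,
#'   `pos` and optionally `p`.
#' @param gm the [geno_matrix()] the SNPs came from (for LD).
#' @param max_gap maximum distance between chain-adjacent members (bp,
#'   default 100000).
#' @param min_r2 LD threshold between chain-adjacent members
#'   (default 0.35, strict inequality).
#' @return data.frame with one row per QTL: `qtl_id`, `chrom`, `start`,
#'   `end`, `n_snps`, `peak_snp`, `members` (comma-separated ids).
#' @export
merge_snps_to_qtls <- function(snps, gm, max_gap = 100000, min_r2 = 0.35) {
  stopifnot(is.data.frame(snps),
            all(c("id", "chrom", "pos") %in% names(snps)))
  missing_ids <- setdiff(snps$id, gm$map$id)
  if (length(missing_ids)) {
    stop("SNP(s) absent from the genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  qtl <- integer(nrow(snps))
  current <- 0L
  for (i in seq_len(nrow(snps))) {
    new_qtl <- i == 1 ||
      snps$chrom[i] != snps$chrom[i - 1] ||
      (snps$pos[i] - snps$pos[i - 1]) > max_gap ||
      {
        r2 <- ld_r2(gm, snps$id[i - 1], snps$id[i])
        is.na(r2) || r2 <= min_r2
      }
    if (new_qtl) current <- current + 1L
    qtl[i] <- current
  }
  rows <- lapply(split(seq_len(nrow(snps)), qtl), function(ix) {
    sub <- snps[ix, , drop = FALSE]
    peak <- if ("p" %in% names(sub) && !all(is.na(sub$p))) {
      sub$id[which.min(sub$p)]
    } else sub$id[1]
    data.frame(chrom = sub$chrom[1], start = min(sub$pos),
               end = max(sub$pos), n_snps = nrow(sub), peak_snp = peak,
               members = paste(sub$id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(qtl_id = sprintf("QTL%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Candidate-gene windows around significant SNPs
#'
#' For each SNP, builds the window `[pos - flank, pos + flank]`, clipped to
#' `[1, chromosome length]` when contig lengths are known, and lists every
#' annotated gene whose interval overlaps the window by at least 1 bp
#' (1-based inclusive overlap).
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos`.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param flank half-window width in bp (default 100000).
#' @param contigs optional named vector of chromosome lengths used to clip
#'   window ends.
#' @return data.frame with one row per SNP: `id`, `chrom`, `pos`,
#'   `window_start`, `window_end`, `n_genes`, `genes` (comma-separated).
#' @export
candidate_gene_windows <- function(snps, annotation, flank = 100000,
                                   contigs = NULL) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  unknown <- setdiff(snps$chrom, unique(c(annotation$chrom, names(contigs))))
  if (length(unknown)) {
    stop("chromosome(s) unknown to the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ws <- pmax(snps$pos - flank, 1)
  we <- snps$pos + flank
  if (!is.null(contigs)) {
    lim <- contigs[snps$chrom]
    we <- ifelse(is.na(lim), we, pmin(we, lim))
  }
  win <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(ws, we))
  genes <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start,
                                                   annotation$end))
  hits <- GenomicRanges::findOverlaps(win, genes)
  gene_lists <- split(annotation$gene_id[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(snps))))
  data.frame(id = snps$id, chrom = snps$chrom, pos = snps$pos,
             window_start = ws, window_end = we,
             n_genes = lengths(gene_lists),
             genes = vapply(gene_lists, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}
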