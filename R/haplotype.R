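#' Regional pairwise LD matrices
#'
#' For every pair of polymorphic SNPs inside the region: the genotypic
#' r-squared (squared Pearson correlation of dosages, identical to
#' [ld_r2()]) and D-prime computed from two-locus haplotype frequencies
#' estimated by an EM algorithm from the unphased diploid genotypes
#' (iteration cap 100, tolerance 1e-8 on the log-likelihood).
#'
#' @param gm a [geno_matrix()].
#' @param region `"chrom:start-end"` or a list with `chrom`, `start`,
#'   `end`.
#' @return list with `snps` (the regional marker map), `r2` and `dprime`
#'   (symmetric matrices with unit/NA diagonals).
#' @export
regional_ld <- function(gm, region) {
  sub <- subset_region(gm, region)
  poly <- apply(sub$geno, 2, function(g) stats::sd(g, na.rm = TRUE) > 0) &
    colSums(!is.na(sub$geno)) >= 3
  poly[is.na(poly)] <- FALSE
  sub <- geno_matrix(sub$geno[, poly, drop = FALSE],
                     sub$map[poly, , drop = FALSE], contigs = sub$contigs)
  m <- ncol(sub$geno)
  if (m < 2) stop("fewer than 2 polymorphic SNPs in region", call. = FALSE)
  r2 <- matrix(NA_real_, m, m, dimnames = list(sub$map$id, sub$map$id))
  dp <- r2
  diag(r2) <- 1
  diag(dp) <- 1
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r2[i, j] <- r2[j, i] <- ld_r2(sub, i, j)
      em <- em_haplotype_freqs(sub$geno[, i], sub$geno[, j])
      dp[i, j] <- dp[j, i] <- em$dprime
    }
  }
  list(snps = sub$map, r2 = r2, dprime = dp)
}

# Two-SNP haplotype-frequency EM from unphased diploid dosages.
# Haplotypes: 11 (alt-alt), 10, 01, 00 by alt-allele carriage at (a, b).
# Only double heterozygotes are phase-ambiguous. Returns D, D' and the
# log-likelihood trace (non-decreasing).
em_haplotype_freqs <- function(ga, gb, max_iter = 100, tol = 1e-8) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]
  gb <- gb[ok]
  n <- length(ga)
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  # haplotype freqs: h[1]=f(A B), h[2]=f(A b), h[3]=f(a B), h[4]=f(a b)
  # (A = alt at SNP a, B = alt at SNP b); start at linkage equilibrium
  h <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  h <- pmax(h, 1e-12)
  h <- h / sum(h)
  dhet <- ga == 1 & gb == 1
  # every genotype pair except the double heterozygote resolves into a
  # determined pair of haplotypes: min(a,b) copies of AB, a-min of Ab,
  # b-min of aB, 2-max of ab
  a_ <- ga[!dhet]
  b_ <- gb[!dhet]
  fixed <- c(sum(pmin(a_, b_)), sum(a_ - pmin(a_, b_)),
             sum(b_ - pmin(a_, b_)), sum(2 - pmax(a_, b_)))
  nd <- sum(dhet)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step: double hets are AB/ab with prob h1 h4 / (h1 h4 + h2 h3)
    w <- h[1] * h[4] / (h[1] * h[4] + h[2] * h[3])
    cnt <- fixed + nd * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / sum(cnt)
    h_new <- pmax(h_new, 1e-12)
    h_new <- h_new / sum(h_new)
    ll <- sum(fixed * log(h_new)) +
      nd * log(2 * (h_new[1] * h_new[4] + h_new[2] * h_new[3]))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  pa_ <- h[1] + h[2]
  pb_ <- h[1] + h[3]
  D <- h[1] - pa_ * pb_
  dmax <- if (D >= 0) min(pa_ * (1 - pb_), (1 - pa_) * pb_) else
    min(pa_ * pb_, (1 - pa_) * (1 - pb_))
  dprime <- if (dmax <= 0) NA_real_ else max(min(D / dmax, 1), -1)
  list(h = h, D = D, dprime = dprime, loglik = ll_trace)
}

#' Regional single-marker association
#'
#' Per-SNP fixed-effects regression of the trait on the dosage (intercept
#' included, no kinship correction - the regional fine-mapping
#' convention), flagging SNPs with `-log10(p)` at or above the regional
#' threshold (default 2.5).
#'
#' @param gm a [geno_matrix()].
#' @param region region string or list.
#' @param trait named numeric vector of per-accession values.
#' @param threshold_neglog10p flagging threshold (default 2.5).
#' @return data.frame with columns `id`, `chrom`, `pos`, `beta`, `p`,
#'   `neglog10p`, `flagged`.
#' @export
regional_association <- function(gm, region, trait,
                                 threshold_neglog10p = 2.5) {
  sub <- subset_region(gm, region)
  if (ncol(sub$geno) == 0) stop("no SNPs in region", call. = FALSE)
  acc <- rownames(sub$geno)
  y <- if (!is.null(names(trait))) as.numeric(trait[acc]) else {
    stopifnot(length(trait) == length(acc))
    as.numeric(trait)
  }
  res <- lapply(seq_len(ncol(sub$geno)), function(j) {
    g <- sub$geno[, j]
    ok <- !is.na(g) & !is.na(y)
    if (sum(ok) < 4 || stats::sd(g[ok]) == 0) {
      return(c(beta = NA_real_, p = NA_real_))
    }
    fit <- stats::lm(y[ok] ~ g[ok])
    sm <- summary(fit)$coefficients
    c(beta = sm[2, 1], p = sm[2, 4])
  })
  res <- do.call(rbind, res)
  nlp <- -log10(res[, "p"])
  data.frame(id = sub$map$id, chrom = sub$map$chrom, pos = sub$map$pos,
             beta = res[, "beta"], p = res[, "p"], neglog10p = nlp,
             flagged = !is.na(nlp) & nlp >= threshold_neglog10p,
             stringsAsFactors = FALSE)
}

#' Group accessions into regional haplotypes
#'
#' Forms each accession's regional genotype string from the unphased codes
#' `0/0`, `0/1`, `1/1` (and `./.` for missing) across the region's SNPs.
#' Accessions whose missing fraction exceeds `max_missing_frac` are
#' excluded (their ids are reported). Identical strings - missing
#' positions must match exactly, missing is not a wildcard - form one
#' haplotype group; groups are numbered `Hap1, Hap2, ...` by descending
#' carrier count, ties broken by lexicographic genotype string.
#'
#' @param gm a [geno_matrix()].
#' @param region region string or list.
#' @param max_missing_frac per-accession missing-call tolerance
#'   (default 0.1).
#' @return data.frame with columns `haplotype`, `genotype_string`, `n`,
#'   `carriers` (comma-separated accession ids); attribute `excluded`
#'   lists dropped accessions.
#' @export
assign_haplotypes <- function(gm, region, max_missing_frac = 0.1) {
  sub <- subset_region(gm, region)
  if (ncol(sub$geno) == 0) stop("no SNPs in region", call. = FALSE)
  codes <- c("0/0", "0/1", "1/1")
  gs <- apply(sub$geno, 1, function(g) {
    paste(ifelse(is.na(g), "./.", codes[g + 1]), collapse = " ")
  })
  miss_frac <- rowMeans(is.na(sub$geno))
  excluded <- names(gs)[miss_frac > max_missing_frac]
  if (length(excluded)) {
    message(length(excluded),
            " accession(s) excluded for excess missing calls in region")
  }
  gs <- gs[miss_frac <= max_missing_frac]
  groups <- split(names(gs), gs)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  out <- data.frame(haplotype = paste0("Hap", seq_along(groups)),
                    genotype_string = names(groups),
                    n = lengths(groups),
                    carriers = vapply(groups, paste, character(1),
                                      collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "snps") <- sub$map$id
  out
}

#' Haplotype by tolerance-class distribution
#'
#' Cross-tabulates haplotype carriers against tolerance classes, reports
#' per-haplotype percentage composition, and flags haplotypes whose
#' carriers all fall in a single class (exclusivity). Carriers lacking a
#' class label are counted in an `unclassified` column with a warning.
#'
#' @param haps output of [assign_haplotypes()].
#' @param classes named character vector accession -> class label (e.g.
#'   from [classify_accessions()]).
#' @return data.frame with one row per haplotype: counts per class,
#'   `exclusive` (the class name, or `NA`), and percentage columns.
#' @export
haplotype_class_distribution <- function(haps, classes) {
  stopifnot(is.data.frame(haps),
            all(c("haplotype", "carriers", "n") %in% names(haps)))
  lev <- sort(unique(unname(classes)))
  carrier_list <- strsplit(haps$carriers, ",")
  unl <- 0L
  rows <- lapply(seq_len(nrow(haps)), function(i) {
    cl <- classes[carrier_list[[i]]]
    n_unc <- sum(is.na(cl))
    unl <<- unl + n_unc
    cnt <- vapply(lev, function(l) sum(cl == l, na.rm = TRUE), integer(1))
    tot <- sum(cnt) + n_unc
    nonzero <- lev[cnt > 0]
    excl <- if (length(nonzero) == 1 && n_unc == 0) nonzero else NA_character_
    c(as.list(cnt), list(unclassified = n_unc, exclusive = excl,
                         stats::setNames(as.list(round(100 * cnt / tot, 1)),
                                         paste0("pct_", lev))))
  })
  if (unl > 0) warning(unl, " carrier(s) had no class label")
  out <- cbind(haps[, c("haplotype", "n")],
               do.call(rbind, lapply(rows, function(r) {
                 as.data.frame(r, stringsAsFactors = FALSE)
               })))
  rownames(out) <- NULL
  out
}
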