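#' Per-site Weir-Cockerham Fst between two groups
#'
#' Computes, for every SNP, the Weir & Cockerham (1984) variance
#' components for two populations of diploids with unequal sample sizes:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals, from observed heterozygosity). The per-site
#' estimate is `a / (a + b + c)`; it may be negative (an estimator
#' property), and sites monomorphic across both groups carry a zero
#' denominator and are flagged uninformative. Sites where either group has
#' fewer than 2 called genotypes are flagged missing.
#'
#' @param gm a [geno_matrix()].
#' @param group_a,group_b disjoint character vectors of accession ids (or
#'   logical/integer row indices).
#' @return data.frame with columns `id`, `chrom`, `pos`, `a`, `b`, `c`,
#'   `denom` (= a + b + c), `fst`, `informative`.
#' @export
per_site_fst <- function(gm, group_a, group_b) {
  stopifnot(inherits(gm, "geno_matrix"))
  acc <- rownames(gm$geno)
  resolve <- function(g) {
    if (is.character(g)) {
      bad <- setdiff(g, acc)
      if (length(bad)) stop("unknown accession(s): ",
                            paste(utils::head(bad, 5), collapse = ", "),
                            call. = FALSE)
      match(g, acc)
    } else if (is.logical(g)) which(g) else as.integer(g)
  }
  ia <- resolve(group_a)
  ib <- resolve(group_b)
  if (length(intersect(ia, ib))) stop("groups overlap", call. = FALSE)
  Ga <- gm$geno[ia, , drop = FALSE]
  Gb <- gm$geno[ib, , drop = FALSE]

  comp <- wc_components(
    n1 = colSums(!is.na(Ga)), n2 = colSums(!is.na(Gb)),
    p1 = colMeans(Ga, na.rm = TRUE) / 2, p2 = colMeans(Gb, na.rm = TRUE) / 2,
    h1 = colMeans(Ga == 1, na.rm = TRUE), h2 = colMeans(Gb == 1, na.rm = TRUE))

  denom <- comp$a + comp$b + comp$c
  usable <- comp$usable
  informative <- usable & denom != 0 & !is.na(denom)
  fst <- ifelse(informative, comp$a / denom, NA_real_)
  data.frame(id = gm$map$id, chrom = gm$map$chrom, pos = gm$map$pos,
             a = ifelse(usable, comp$a, NA_real_),
             b = ifelse(usable, comp$b, NA_real_),
             c = ifelse(usable, comp$c, NA_real_),
             denom = ifelse(usable, denom, NA_real_),
             fst = fst, informative = informative,
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) variance components for r = 2 populations of
# diploids. Vectorized over sites; inputs are per-group sample sizes
# (called individuals), alternate-allele frequencies and observed
# heterozygote frequencies.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  usable <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, usable = usable)
}

#' Sliding-window Fst scan
#'
#' Aggregates per-site Weir-Cockerham components into windows advancing
#' along each chromosome (default 100 kb windows, 10 kb step, anchored at
#' position 1, 1-based inclusive). The window statistic is the weighted
#' ratio-of-sums `sum(a) / sum(a + b + c)` over informative SNPs in the
#' window; the per-window mean of per-site ratios is also reported.
#' Windows containing no informative SNP are omitted. Negative per-site
#' components are retained in the sums.
#'
#' @param sites output of [per_site_fst()].
#' @param window,step window and step size in bp (defaults 100000, 10000).
#' @param chrom_lengths optional named vector; defaults to the last SNP
#'   position per chromosome.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_snps`,
#'   `fst_weighted`, `fst_mean`.
#' @export
windowed_fst <- function(sites, window = 100000, step = 10000,
                         chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "a", "denom", "fst") %in% names(sites)))
  if (step > window) warning("step exceeds window size; coverage has gaps")
  sites <- sites[sites$informative, , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_snps = integer(), fst_weighted = numeric(),
                      fst_mean = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (chr in unique(sites$chrom)) {
    s <- sites[sites$chrom == chr, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    L <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      chrom_lengths[[chr]]
    } else max(s$pos) + window - 1  # unknown length: cover the last SNP fully
    starts <- seq(1, max(L - window + 1, 1), by = step)
    # assign each SNP to the windows covering it via interval overlap
    win <- IRanges::IRanges(start = starts, width = window)
    snp <- IRanges::IRanges(start = s$pos, width = 1)
    hits <- IRanges::findOverlaps(win, snp)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (!length(qh)) next
    num <- tapply(s$a[sh], qh, sum)
    den <- tapply(s$denom[sh], qh, sum)
    mfst <- tapply(s$fst[sh], qh, mean)
    cnt <- tapply(sh, qh, length)
    wi <- as.integer(names(num))
    keep <- den != 0
    out[[chr]] <- data.frame(chrom = chr, start = starts[wi][keep],
                             end = (starts[wi] + window - 1)[keep],
                             n_snps = as.integer(cnt)[keep],
                             fst_weighted = (num / den)[keep],
                             fst_mean = as.numeric(mfst)[keep],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-fraction sweep regions
#'
#' Ranks windows by weighted Fst (descending), flags the top
#' `ceiling(fraction * N)`, and merges overlapping or book-ended flagged
#' windows into maximal regions. Each region reports its span, the number
#' of merged windows, the peak window's weighted Fst and the peak start.
#'
#' @param windows output of [windowed_fst()].
#' @param fraction top fraction to flag, in (0, 1] (default 0.05).
#' @return data.frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `peak_fst`, `peak_start`.
#' @export
top_regions <- function(windows, fraction = 0.05) {
  stopifnot(nrow(windows) >= 1)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * nrow(windows))
  ord <- order(windows$fst_weighted, decreasing = TRUE)
  flagged <- windows[ord[seq_len(k)], , drop = FALSE]
  gr <- GenomicRanges::GRanges(flagged$chrom,
                               IRanges::IRanges(flagged$start, flagged$end),
                               fst = flagged$fst_weighted)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(red, gr)
  rows <- lapply(seq_along(red), function(i) {
    mem <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    peak <- mem[which.max(flagged$fst_weighted[mem])]
    data.frame(chrom = as.character(GenomicRanges::seqnames(red))[i],
               start = GenomicRanges::start(red)[i],
               end = GenomicRanges::end(red)[i],
               n_windows = length(mem),
               peak_fst = flagged$fst_weighted[peak],
               peak_start = flagged$start[peak],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect sweep regions with GWAS candidate windows
#'
#' Reports every (sweep region, SNP candidate window) pair overlapping by
#' at least 1 bp, together with the genes of the SNP window that lie inside
#' the intersection of the two intervals.
#'
#' @param regions sweep regions from [top_regions()] (columns `chrom`,
#'   `start`, `end`).
#' @param windows candidate windows from [candidate_gene_windows()].
#' @param annotation gene annotation used to place genes inside the
#'   intersection.
#' @return data.frame with one row per overlapping pair: region
#'   coordinates, SNP id, window coordinates, intersection bounds,
#'   `shared_genes` (comma-separated ids inside the intersection).
#' @export
intersect_with_gwas <- function(regions, windows, annotation) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("id", "chrom", "window_start", "window_end") %in%
                  names(windows)))
  if (!any(windows$chrom %in% regions$chrom) && nrow(regions) &&
      nrow(windows)) {
    stop("regions and windows share no chromosome names", call. = FALSE)
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$window_start,
                                                windows$window_end))
  hits <- GenomicRanges::findOverlaps(rg, wg)
  if (!length(hits)) {
    return(data.frame(chrom = character(), region_start = numeric(),
                      region_end = numeric(), snp_id = character(),
                      window_start = numeric(), window_end = numeric(),
                      inter_start = numeric(), inter_end = numeric(),
                      n_shared_genes = integer(), shared_genes = character(),
                      stringsAsFactors = FALSE))
  }
  ri <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  is_ <- pmax(regions$start[ri], windows$window_start[wi])
  ie_ <- pmin(regions$end[ri], windows$window_end[wi])
  genes <- mapply(function(chr, s, e) {
    g <- annotation[annotation$chrom == chr & annotation$start <= e &
                      annotation$end >= s, "gene_id"]
    paste(g, collapse = ",")
  }, regions$chrom[ri], is_, ie_)
  data.frame(chrom = regions$chrom[ri], region_start = regions$start[ri],
             region_end = regions$end[ri], snp_id = windows$id[wi],
             window_start = windows$window_start[wi],
             window_end = windows$window_end[wi],
             inter_start = is_, inter_end = ie_,
             n_shared_genes = ifelse(genes == "", 0L,
                                     lengths(strsplit(genes, ","))),
             shared_genes = genes, stringsAsFactors = FALSE)
}
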