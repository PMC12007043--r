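#' Intersect co-expression modules with GWAS candidate windows
#'
#' Joins the module assignment, the gene annotation and the candidate-gene
#' windows of significant SNPs: one output row per (gene, module, SNP)
#' where the gene's interval lies inside the SNP's window (>= 1 bp
#' overlap), the gene belongs to a non-grey module, and - when
#' `significant_modules` is supplied - that module is in the significant
#' list. Genes hit by several SNP windows appear once per SNP.
#'
#' @param modules named character vector gene -> module label.
#' @param windows candidate windows from [candidate_gene_windows()].
#' @param annotation gene annotation data.frame.
#' @param significant_modules optional character vector of module labels
#'   deemed trait-significant; `NULL` keeps every non-grey module.
#' @return data.frame with columns `gene_id`, `module`, `snp_id`, `chrom`,
#'   `window_start`, `window_end`, `gene_start`, `gene_end`.
#' @export
module_gwas_overlap <- function(modules, windows, annotation,
                                significant_modules = NULL) {
  stopifnot(all(c("id", "chrom", "window_start", "window_end") %in%
                  names(windows)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  shared <- intersect(names(modules), annotation$gene_id)
  if (length(modules) &&
      length(shared) < 0.5 * min(length(modules), nrow(annotation))) {
    stop("more than half of the gene identifiers do not match the ",
         "annotation; wrong annotation?", call. = FALSE)
  }
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$window_start,
                                                windows$window_end))
  gg <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start,
                                                annotation$end))
  hits <- GenomicRanges::findOverlaps(wg, gg)
  wi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  gene <- annotation$gene_id[gi]
  mod <- unname(modules[gene])
  keep <- !is.na(mod) & mod != "grey"
  if (!is.null(significant_modules)) {
    keep <- keep & mod %in% significant_modules
  }
  out <- data.frame(gene_id = gene[keep], module = mod[keep],
                    snp_id = windows$id[wi][keep],
                    chrom = windows$chrom[wi][keep],
                    window_start = windows$window_start[wi][keep],
                    window_end = windows$window_end[wi][keep],
                    gene_start = annotation$start[gi][keep],
                    gene_end = annotation$end[gi][keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$window_start, out$gene_start), , drop = FALSE]
}

#' Allele-class versus phenotype association at one SNP
#'
#' Partitions the panel by genotype class at the SNP (homozygous
#' reference, heterozygous, homozygous alternate; missing calls are
#' reported as their own class but never tested). Classes smaller than
#' `min_class_size` are reported but excluded from testing. With two
#' testable classes a Welch two-sample t-test is used; with three, one-way
#' ANOVA. Class counts always sum to the panel size.
#'
#' @param gm a [geno_matrix()].
#' @param snp_id SNP identifier (or column index).
#' @param trait named numeric vector of per-accession trait values.
#' @param min_class_size smallest class entering the test (default 2).
#' @return list with `snp`, `classes` (data.frame: class, n, mean, sd),
#'   `stat`, `p`, `stars` (`NS`/`*`/`**`/`***`), `test` (`"welch"`,
#'   `"anova"` or `"none"`).
#' @export
allele_phenotype_association <- function(gm, snp_id, trait,
                                         min_class_size = 2) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.character(snp_id) && !snp_id %in% gm$map$id) {
    stop("SNP '", snp_id, "' absent from the genotype matrix", call. = FALSE)
  }
  g <- gm$geno[, snp_id]
  acc <- rownames(gm$geno)
  y <- if (!is.null(names(trait))) as.numeric(trait[acc]) else {
    stopifnot(length(trait) == length(acc))
    as.numeric(trait)
  }
  if (all(is.na(g))) stop("all accessions missing at this SNP", call. = FALSE)
  cls <- factor(ifelse(is.na(g), "missing", c("0/0", "0/1", "1/1")[g + 1]),
                levels = c("0/0", "0/1", "1/1", "missing"))
  tab <- lapply(levels(cls), function(lv) {
    v <- y[cls == lv & !is.na(y)]
    data.frame(class = lv, n = sum(cls == lv),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  testable <- setdiff(levels(cls), "missing")
  testable <- testable[vapply(testable, function(lv) {
    sum(cls == lv & !is.na(y)) >= min_class_size
  }, logical(1))]
  ok <- cls %in% testable & !is.na(y)
  yv <- y[ok]
  cv <- droplevels(cls[ok])
  if (length(testable) < 2) {
    warning("fewer than two testable allele classes; no test performed")
    return(list(snp = snp_id, classes = tab, stat = NA_real_, p = NA_real_,
                stars = "NS", test = "none"))
  }
  res <- if (length(testable) == 2) {
    tt <- tryCatch(stats::t.test(yv ~ cv), error = function(e) NULL)
    if (is.null(tt)) list(stat = NA_real_, p = NA_real_, test = "welch")
    else list(stat = unname(tt$statistic), p = tt$p.value, test = "welch")
  } else {
    an <- stats::anova(stats::aov(yv ~ cv))
    list(stat = an[["F value"]][1], p = an[["Pr(>F)"]][1], test = "anova")
  }
  list(snp = snp_id, classes = tab, stat = res$stat, p = res$p,
       stars = significance_stars(res$p), test = res$test)
}
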