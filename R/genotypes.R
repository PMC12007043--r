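#' Genotype matrix container
#'
#' Bundles an accessions x SNPs dosage matrix (0/1/2 copies of the alternate
#' allele, `NA` for missing calls) with its marker map. This is the genotype
#' container consumed by the association scan, the Fst scan and the regional
#' haplotype tools.
#'
#' @param geno integer/numeric matrix, accessions in rows (rownames are
#'   accession ids), SNPs in columns. Values must be 0, 1, 2 or `NA`.
#' @param map data.frame with one row per SNP and columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`. Rows must match the columns of `geno` in order.
#' @param contigs optional named numeric vector of chromosome lengths
#'   (base pairs); used when exporting VCF headers and clipping windows.
#' @return an object of class `geno_matrix`: a list with elements `geno`,
#'   `map` and `contigs`, SNPs sorted by (chrom, pos).
#' @export
geno_matrix <- function(geno, map, contigs = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(map),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(map)),
            nrow(map) == ncol(geno))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(map$id)) stop("duplicated SNP ids in map", call. = FALSE)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("acc%03d", seq_len(nrow(geno)))
  }
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- map$id
  rownames(map) <- NULL
  structure(list(geno = geno, map = map, contigs = contigs),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "accessions x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Per-SNP minor allele frequency and call rate
#'
#' @param gm a [geno_matrix()].
#' @return data.frame with columns `id`, `maf`, `call_rate`.
#' @export
snp_summary <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_called <- colSums(!is.na(gm$geno))
  p_alt <- colMeans(gm$geno, na.rm = TRUE) / 2
  p_alt[n_called == 0] <- NA_real_
  data.frame(id = gm$map$id,
             maf = pmin(p_alt, 1 - p_alt),
             call_rate = n_called / nrow(gm$geno),
             stringsAsFactors = FALSE)
}

#' Subset a genotype matrix to a genomic region
#'
#' @param gm a [geno_matrix()].
#' @param region either a string `"chrom:start-end"` or a list with elements
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @return a `geno_matrix` restricted to SNPs inside the region.
#' @export
subset_region <- function(gm, region) {
  stopifnot(inherits(gm, "geno_matrix"))
  region <- parse_region(region)
  keep <- gm$map$chrom == region$chrom &
    gm$map$pos >= region$start & gm$map$pos <= region$end
  geno_matrix(gm$geno[, keep, drop = FALSE], gm$map[keep, , drop = FALSE],
              contigs = gm$contigs)
}

#' Write genotypes to a VCF file
#'
#' Serializes a genotype matrix as VCF v4.2 with a GT-only FORMAT field and
#' `##contig` header lines taken from the container's contig lengths.
#' Dosages 0/1/2 become `0/0`, `0/1`, `1/1`; missing becomes `./.`.
#'
#' @param gm a [geno_matrix()].
#' @param path output path; `.gz` is appended if absent (block-gzipped
#'   output, readable by [read_vcf_genotypes()] and standard VCF tools).
#' @return the path written, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  meta <- c("##fileformat=VCFv4.2", "##source=droughtpanel")
  if (!is.null(gm$contigs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(gm$contigs), as.integer(gm$contigs)))
  }
  meta <- c(meta, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fix <- cbind(CHROM = gm$map$chrom,
               POS = format(gm$map$pos, scientific = FALSE, trim = TRUE),
               ID = gm$map$id, REF = gm$map$ref, ALT = gm$map$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  codes <- c("0/0", "0/1", "1/1")
  gt_chr <- matrix("./.", nrow = ncol(gm$geno), ncol = nrow(gm$geno),
                   dimnames = list(NULL, rownames(gm$geno)))
  tg <- t(gm$geno)
  ok <- !is.na(tg)
  gt_chr[ok] <- codes[tg[ok] + 1L]
  gt <- cbind(FORMAT = "GT", gt_chr)
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic SNP genotypes (GT field) into a [geno_matrix()]. Phased
#' separators are accepted; half-missing calls are treated as missing.
#'
#' @param path a VCF or bgzipped VCF file.
#' @return a `geno_matrix` with contig lengths recovered from `##contig`
#'   header lines when present.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  dose[gt == "0/0"] <- 0L
  dose[gt %in% c("0/1", "1/0")] <- 1L
  dose[gt == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(id = ids, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  contig_lines <- grep("^##contig=", v@meta, value = TRUE)
  contigs <- NULL
  if (length(contig_lines)) {
    cid <- sub(".*ID=([^,>]+).*", "\\1", contig_lines)
    clen <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            contig_lines)))
    if (!anyNA(clen)) contigs <- stats::setNames(clen, cid)
  }
  geno_matrix(t(dose), map, contigs = contigs)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive) and optionally `strand`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gff3_annotation <- function(annotation, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  strand <- annotation$strand %||% rep("+", nrow(annotation))
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = strand,
    type = "gene",
    ID = annotation$gene_id,
    Name = annotation$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Keeps `gene` features only and returns plain 1-based inclusive intervals.
#'
#' @param path a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$Name
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
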