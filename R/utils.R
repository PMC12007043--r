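#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor var sd prcomp hclust cutree dist aov anova
#'   t.test p.adjust pt pf qf optimize rnorm runif rbinom setNames
#'   complete.cases quantile
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Significance stars for a vector of p-values
#'
#' Encodes p-values with the conventional star codes used in module-trait
#' and allele-association tables: `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05, `NS` otherwise.
#'
#' @param p numeric vector of p-values.
#' @param ns label used for non-significant entries (default `"NS"`).
#' @return character vector of the same length as `p`.
#' @export
significance_stars <- function(p, ns = "NS") {
  stopifnot(is.numeric(p))
  out <- rep(ns, length(p))
  out[!is.na(p) & p <= 0.05]  <- "*"
  out[!is.na(p) & p <= 0.01]  <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# p-value for a Pearson correlation via the exact t transform, df = n - 2
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Parse "chrom:start-end" into a list(chrom, start, end)
parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    region$start <- as.numeric(region$start)
    region$end <- as.numeric(region$end)
  } else {
    m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4) {
      stop("region must be 'chrom:start-end', got: ", region, call. = FALSE)
    }
    region <- list(chrom = m[2],
                   start = as.numeric(gsub(",", "", m[3])),
                   end   = as.numeric(gsub(",", "", m[4])))
  }
  if (region$start > region$end) stop("region start exceeds end", call. = FALSE)
  region
}
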