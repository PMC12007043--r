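# Small in-code fixtures shared across test files.

# Build a geno_matrix directly from a dosage matrix and positions.
make_gm <- function(mat, chrom = "A01", pos = NULL, contigs = NULL) {
  mat <- as.matrix(mat)
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 1000
  chrom <- rep_len(chrom, ncol(mat))
  map <- data.frame(id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  geno_matrix(mat, map, contigs = contigs)
}

# A tiny balanced phenotype table: one accession effect per row of `values`,
# replicated over the design.
make_pheno <- function(values, trait = "trait1", treatments = c("CK", "M"),
                       environments = 1, replicates = 1,
                       mult = c(CK = 1, M = 0.6)) {
  acc <- names(values) %||% sprintf("acc%02d", seq_along(values))
  grid <- expand.grid(accession = acc, treatment = treatments,
                      environment = paste0("E", seq_len(environments)),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  grid$trait <- trait
  grid$value <- unname(values[grid$accession] * mult[grid$treatment])
  grid[, c("accession", "trait", "treatment", "environment", "replicate",
           "value")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent literal transcription of the two-population diploid
# Weir-Cockerham (1984) variance components, scalar, from genotype counts
# c(n00, n01, n11) per group. Used as the formula oracle.
wc_oracle <- function(counts_a, counts_b) {
  n1 <- sum(counts_a)
  n2 <- sum(counts_b)
  p1 <- (counts_a[2] + 2 * counts_a[3]) / (2 * n1)
  p2 <- (counts_b[2] + 2 * counts_b[3]) / (2 * n2)
  h1 <- counts_a[2] / n1
  h2 <- counts_b[2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = unname(a), b = unname(b), c = unname(cc))
}

# Expand genotype counts c(n00, n01, n11) into a dosage vector.
counts_to_dosage <- function(counts) {
  rep(c(0L, 1L, 2L), times = counts)
}

# Loop transcription of the unsigned topological overlap formula, used as
# the TOM oracle.
tom_oracle <- function(expr, power) {
  cc <- abs(cor(t(expr)))^power
  diag(cc) <- 0
  n <- nrow(cc)
  tom <- diag(n)
  k <- rowSums(cc)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- sum(cc[i, -c(i, j)] * cc[-c(i, j), j])
      tom[i, j] <- tom[j, i] <- (l + cc[i, j]) / (min(k[i], k[j]) + 1 -
                                                    cc[i, j])
    }
  }
  tom
}

# Exhaustive-likelihood grid oracle for the two-SNP haplotype D' (phase
# ambiguity resolved by maximizing the multinomial likelihood over the
# AB-haplotype frequency).
dprime_grid_oracle <- function(ga, gb, grid_n = 20001) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]
  gb <- gb[ok]
  dhet <- ga == 1 & gb == 1
  a_ <- ga[!dhet]
  b_ <- gb[!dhet]
  fixed <- c(sum(pmin(a_, b_)), sum(a_ - pmin(a_, b_)),
             sum(b_ - pmin(a_, b_)), sum(2 - pmax(a_, b_)))
  nd <- sum(dhet)
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  f11 <- seq(lo, hi, length.out = grid_n)
  h1 <- f11
  h2 <- pa - f11
  h3 <- pb - f11
  h4 <- 1 - pa - pb + f11
  eps <- 1e-12
  ll <- fixed[1] * log(pmax(h1, eps)) + fixed[2] * log(pmax(h2, eps)) +
    fixed[3] * log(pmax(h3, eps)) + fixed[4] * log(pmax(h4, eps)) +
    nd * log(pmax(2 * (h1 * h4 + h2 * h3), eps))
  best <- f11[which.max(ll)]
  D <- best - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) NA_real_ else max(min(D / dmax, 1), -1)
}
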