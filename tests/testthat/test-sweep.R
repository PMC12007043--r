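test_that("fixed allele differences give Fst of one", {
  g <- rbind(matrix(0L, 10, 3), matrix(2L, 10, 3))
  gm <- make_gm(g)
  fst <- per_site_fst(gm, 1:10, 11:20)
  expect_equal(fst$fst, rep(1, 3))
})

test_that("identical genotype count tables give non-positive estimates", {
  counts <- c(6, 3, 1)
  g <- cbind(c(counts_to_dosage(counts), counts_to_dosage(counts)))
  gm <- make_gm(g)
  fst <- per_site_fst(gm, 1:10, 11:20)
  expect_lte(fst$a, 0)
  expect_lte(fst$fst, 0)
})

test_that("variance components match the literal 1984 transcription", {
  ca <- c(6, 3, 1)
  cb <- c(1, 4, 5)
  gm <- make_gm(cbind(c(counts_to_dosage(ca), counts_to_dosage(cb))))
  fst <- per_site_fst(gm, 1:10, 11:20)
  oracle <- wc_oracle(ca, cb)
  expect_equal(fst$a, oracle[["a"]], tolerance = 1e-12)
  expect_equal(fst$b, oracle[["b"]], tolerance = 1e-12)
  expect_equal(fst$c, oracle[["c"]], tolerance = 1e-12)

  set.seed(8)
  for (i in 1:200) {
    ca <- rmultinom(1, sample(4:30, 1), runif(3) + 0.05)[, 1]
    cb <- rmultinom(1, sample(4:30, 1), runif(3) + 0.05)[, 1]
    if (sum(ca) < 2 || sum(cb) < 2) next
    gm <- make_gm(cbind(c(counts_to_dosage(ca), counts_to_dosage(cb))))
    fst <- per_site_fst(gm, seq_len(sum(ca)), sum(ca) + seq_len(sum(cb)))
    oracle <- wc_oracle(ca, cb)
    expect_equal(c(fst$a, fst$b, fst$c), unname(oracle), tolerance = 1e-12)
  }
})

test_that("the per-site estimator is symmetric and count-scale invariant", {
  ca <- c(5, 3, 2)
  cb <- c(2, 4, 4)
  gm <- make_gm(cbind(c(counts_to_dosage(ca), counts_to_dosage(cb))))
  f_ab <- per_site_fst(gm, 1:10, 11:20)
  f_ba <- per_site_fst(gm, 11:20, 1:10)
  expect_equal(f_ab$fst, f_ba$fst, tolerance = 1e-12)

  gm2 <- make_gm(cbind(c(counts_to_dosage(2 * ca), counts_to_dosage(2 * cb))))
  f2 <- per_site_fst(gm2, 1:20, 21:40)
  # doubling all counts changes only the finite-sample correction slightly;
  # the ratio built from the same frequency/heterozygosity pattern stays
  # within a small neighbourhood and is identical in the large-n limit.
  expect_equal(sign(f2$fst), sign(f_ab$fst))
  expect_equal(f2$fst, f_ab$fst, tolerance = 0.1)
})

test_that("tiny or monomorphic sites are flagged, never crash", {
  g <- cbind(c(0L, 0L, 0L, 0L), c(0L, NA, 0L, 1L))
  gm <- make_gm(g)
  fst <- per_site_fst(gm, 1:2, 3:4)
  expect_false(fst$informative[1])  # monomorphic: zero denominator
  expect_false(fst$informative[2])  # group with < 2 calls
  expect_error(per_site_fst(gm, 1:2, 2:4), "overlap")
})

test_that("window arithmetic: a SNP at 100 kb lies in exactly 10 windows", {
  sites <- data.frame(id = "s", chrom = "A01", pos = 100000,
                      a = 0.2, b = 0.1, c = 0.1, denom = 0.4, fst = 0.5,
                      informative = TRUE, stringsAsFactors = FALSE)
  w <- windowed_fst(sites)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(1, 90001, by = 10000))
  expect_equal(w$fst_weighted, rep(0.5, 10))
})

test_that("windows with identical per-site components equal that value", {
  pos <- seq(5000, 295000, by = 5000)
  sites <- data.frame(id = paste0("s", seq_along(pos)), chrom = "B01",
                      pos = pos, a = 0.03, b = 0.05, c = 0.02, denom = 0.1,
                      fst = 0.3, informative = TRUE, stringsAsFactors = FALSE)
  w <- windowed_fst(sites)
  expect_true(all(abs(w$fst_weighted - 0.3) < 1e-12))
  expect_true(all(abs(w$fst_mean - 0.3) < 1e-12))
})

test_that("the window count follows the chromosome-length formula", {
  L <- 1e6
  pos <- seq(1000, L, by = 1000)
  sites <- data.frame(id = paste0("s", seq_along(pos)), chrom = "A02",
                      pos = pos, a = 0.1, b = 0.1, c = 0.1, denom = 0.3,
                      fst = 1 / 3, informative = TRUE,
                      stringsAsFactors = FALSE)
  w <- windowed_fst(sites, chrom_lengths = c(A02 = L))
  expect_equal(nrow(w), floor((L - 100000) / 10000) + 1)
})

test_that("empty site lists give empty window tables", {
  empty <- data.frame(id = character(), chrom = character(), pos = numeric(),
                      a = numeric(), b = numeric(), c = numeric(),
                      denom = numeric(), fst = numeric(),
                      informative = logical(), stringsAsFactors = FALSE)
  expect_equal(nrow(windowed_fst(empty)), 0)
  expect_warning(windowed_fst(empty, window = 1000, step = 5000), "gaps")
})

test_that("top regions are counted, merged, and bounded", {
  set.seed(9)
  w <- data.frame(chrom = "A01", start = seq(1, by = 10000, length.out = 100),
                  end = seq(100000, by = 10000, length.out = 100),
                  n_snps = 5, fst_weighted = runif(100, 0, 0.3),
                  fst_mean = runif(100, 0, 0.3), stringsAsFactors = FALSE)
  # plant the top 5 at known, partially overlapping positions
  w$fst_weighted[c(1, 2, 50, 70, 90)] <- c(0.9, 0.8, 0.95, 0.85, 0.99)
  tr <- top_regions(w, 0.05)
  expect_equal(sum(tr$n_windows), 5)
  first <- tr[tr$start == 1, ]
  expect_equal(first$end, 110000)  # windows at 1 and 10001 merged
  expect_error(top_regions(w, 0), "fraction")
  expect_error(top_regions(w, 1.2), "fraction")
})

test_that("sweep regions intersect GWAS windows with shared genes", {
  regions <- data.frame(chrom = "B06", start = 23686061, end = 24177367,
                        stringsAsFactors = FALSE)
  windows <- data.frame(id = "B06_24082156", chrom = "B06",
                        window_start = 23682156, window_end = 24482156,
                        stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("geneA", "geneB"), chrom = "B06",
                    start = c(24083624, 24300000),
                    end = c(24084788, 24310000), stringsAsFactors = FALSE)
  ov <- intersect_with_gwas(regions, windows, ann)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$inter_start, 23686061)
  expect_equal(ov$inter_end, 24177367)
  expect_true(grepl("geneA", ov$shared_genes))
  expect_false(grepl("geneB", ov$shared_genes))  # outside the intersection

  far <- data.frame(id = "x", chrom = "B06", window_start = 1,
                    window_end = 1000, stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_with_gwas(regions, far, ann)), 0)

  same <- data.frame(id = "y", chrom = "B06", window_start = 23686061,
                     window_end = 24177367, stringsAsFactors = FALSE)
  ov2 <- intersect_with_gwas(regions, same, ann)
  expect_equal(c(ov2$inter_start, ov2$inter_end), c(23686061, 24177367))
})

test_that("a planted sweep region is recovered in the top fraction", {
  genome <- genome_spec(c(A01 = 4e6, B06 = 4e6))
  gm <- simulate_genotypes(genome, 100, 1500, subpop_split = c(50, 50),
                           sweep = sweep_spec("B06", 1e6, 1.5e6, 0.6),
                           seed = 3)
  fst <- per_site_fst(gm, 1:50, 51:100)
  w <- windowed_fst(fst, chrom_lengths = genome$chromosomes)
  tr <- top_regions(w, 0.05)
  hit <- any(tr$chrom == "B06" & tr$start <= 1.5e6 & tr$end >= 1e6)
  expect_true(hit)
})
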