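genome <- genome_spec(c(A01 = 4e6, B06 = 4e6))

test_that("genotype simulation honours shape, MAF range and determinism", {
  empty <- simulate_genotypes(genome, 10, 0, seed = 1)
  expect_equal(dim(empty), c(10L, 0L))

  gm1 <- simulate_genotypes(genome, 120, 1000, maf_range = c(0.1, 0.5),
                            seed = 1)
  gm2 <- simulate_genotypes(genome, 120, 1000, maf_range = c(0.1, 0.5),
                            seed = 1)
  expect_identical(gm1$geno, gm2$geno)
  expect_identical(gm1$map, gm2$map)

  ss <- snp_summary(gm1)
  expect_true(all(ss$maf >= 0.05, na.rm = TRUE))
  expect_false(is.unsorted(order(gm1$map$chrom, gm1$map$pos)))
  expect_true(all(gm1$geno %in% c(0L, 1L, 2L, NA)))
})

test_that("planted sweep region raises between-group Fst above background", {
  sw <- sweep_spec("B06", 1e6, 1.5e6, 0.6)
  gm <- simulate_genotypes(genome, 100, 1200, subpop_split = c(50, 50),
                           sweep = sw, seed = 1)
  sp <- attr(gm, "subpop")
  fst <- per_site_fst(gm, which(sp == "tolerant"), which(sp == "sensitive"))
  inside <- fst$chrom == "B06" & fst$pos >= 1e6 & fst$pos <= 1.5e6
  expect_gt(mean(fst$fst[inside], na.rm = TRUE),
            mean(fst$fst[!inside], na.rm = TRUE))
  expect_gt(mean(fst$fst[inside], na.rm = TRUE), 0.4)
})

test_that("realized sweep Fst is monotone in the target level", {
  levels <- c(0.2, 0.5, 0.8)
  realized <- sapply(levels, function(t) {
    mean(sapply(1:3, function(s) {
      gm <- simulate_genotypes(genome, 80, 600, subpop_split = c(40, 40),
                               sweep = sweep_spec("B06", 1e6, 1.5e6, t),
                               seed = s)
      f <- per_site_fst(gm, 1:40, 41:80)
      inside <- f$chrom == "B06" & f$pos >= 1e6 & f$pos <= 1.5e6
      mean(f$fst[inside], na.rm = TRUE)
    }))
  })
  expect_true(all(diff(realized) > 0))
})

test_that("a sweep region outside the genome is rejected", {
  expect_error(
    simulate_genotypes(genome, 10, 100,
                       sweep = sweep_spec("B06", 1e6, 9e6, 0.5), seed = 1),
    "outside the genome")
  expect_error(
    simulate_genotypes(genome, 10, 100,
                       sweep = sweep_spec("C99", 1e6, 2e6, 0.5), seed = 1),
    "outside the genome")
})

test_that("nearby markers inside an LD block are correlated", {
  gm <- simulate_genotypes(genome, 150, 800, ld_block_len = 100000,
                           missing_rate = 0, seed = 3)
  blk <- (gm$map$pos - 1) %/% 100000
  same_block <- which(gm$map$chrom[-1] == head(gm$map$chrom, -1) &
                        blk[-1] == head(blk, -1))
  r2 <- sapply(head(same_block, 50), function(i) ld_r2(gm, i, i + 1))
  expect_gt(mean(r2, na.rm = TRUE), 0.5)
})

test_that("phenotype simulation follows the design arithmetic", {
  gm <- simulate_genotypes(genome, 40, 200, seed = 2)
  ph <- simulate_phenotypes(gm, traits = c("germination_rate", "yield"),
                            environments = 3, replicates = 3, seed = 5)
  expect_equal(nrow(ph), 40 * 3 * 3 * 3 * 2)
  expect_identical(sort(unique(ph$treatment)), c("CK", "M", "S"))
  # stress multipliers below 1 depress yield-like means relative to control
  m <- tapply(ph$value[ph$trait == "yield"],
              ph$treatment[ph$trait == "yield"], mean)
  expect_gt(m[["CK"]], m[["M"]])
  expect_gt(m[["M"]], m[["S"]])
  # and the panel-mean relative trait tracks the multiplier
  tr <- relative_trait(ph)
  expect_equal(mean(tr$TR[tr$treatment == "M"]), 0.7, tolerance = 0.05)
})

test_that("zero heritability decouples the planted QTL from the trait", {
  gm <- simulate_genotypes(genome, 200, 300, missing_rate = 0, seed = 7)
  pos <- gm$map$pos[100]
  chr <- gm$map$chrom[100]
  q <- qtl_spec(chr, pos, effect_size = 0.3,
                affected_trait = "germination_rate")
  ph <- simulate_phenotypes(gm, list(q), heritability = 0, group_effect = 0,
                            seed = 7)
  acc_mean <- tapply(ph$value[ph$trait == "germination_rate" &
                                ph$treatment == "M"],
                     ph$accession[ph$trait == "germination_rate" &
                                    ph$treatment == "M"], mean)
  g <- gm$geno[names(acc_mean), 100]
  expect_lt(abs(cor(g, acc_mean)), 0.15)
})

test_that("a QTL at an unknown locus is rejected by name", {
  gm <- simulate_genotypes(genome, 10, 50, seed = 1)
  q <- qtl_spec("A01", 999, 0.2, "yield")
  expect_error(simulate_phenotypes(gm, list(q), seed = 1), "A01:999")
})

test_that("expression simulation plants factor-driven modules", {
  design <- data.frame(sample = sprintf("s%02d", 1:12),
                       treatment = rep(c("CK", "M", "S"), each = 4),
                       stringsAsFactors = FALSE)
  sim <- simulate_expression(module_spec(2, 20, noise_sd = 0.5,
                                         n_background = 10),
                             design, seed = 3)
  expect_equal(ncol(sim$expr), 12)
  expect_equal(nrow(sim$expr), 2 * 20 + 10)
  expect_true(all(sim$expr >= 0))
  expect_identical(sim$expr,
                   simulate_expression(module_spec(2, 20, noise_sd = 0.5,
                                                   n_background = 10),
                                       design, seed = 3)$expr)

  noiseless <- simulate_expression(module_spec(1, 10, noise_sd = 0),
                                   design, seed = 1)
  cc <- cor(t(noiseless$expr))
  expect_equal(abs(cc[upper.tri(cc)]), rep(1, sum(upper.tri(cc))),
               tolerance = 1e-12)
})

test_that("a one-gene module specification is rejected", {
  expect_error(module_spec(1, 1), "at least 2 genes")
})

test_that("annotation simulation places disjoint in-bounds genes", {
  expect_equal(nrow(simulate_annotation(genome, 0, seed = 1)), 0)

  ann <- simulate_annotation(genome_spec(c(A01 = 10e6)), 500, seed = 2)
  expect_equal(nrow(ann), 500)
  expect_true(all(ann$end <= 10e6 & ann$start >= 1))
  ord <- ann[order(ann$start), ]
  expect_true(all(ord$start[-1] > head(ord$end, -1)))

  fixed <- simulate_annotation(genome, 50, length_range = c(300, 300),
                               seed = 3)
  expect_true(all(fixed$end - fixed$start + 1 == 300))

  expect_error(simulate_annotation(genome_spec(c(A01 = 1e4)), 50,
                                   length_range = c(500, 500), seed = 1),
               "too small")
})

test_that("written datasets round-trip through VCF, GFF3 and TSV", {
  dir <- withr::local_tempdir()
  gm <- simulate_genotypes(genome, 25, 150, seed = 4)
  ph <- simulate_phenotypes(gm, traits = "yield", seed = 4)
  design <- data.frame(sample = sprintf("s%02d", 1:9),
                       treatment = rep(c("CK", "M", "S"), each = 3),
                       stringsAsFactors = FALSE)
  ex <- simulate_expression(module_spec(1, 5, n_background = 5), design,
                            seed = 4)
  ann <- simulate_annotation(genome, 30, seed = 4)
  files <- write_simulation(dir, gm = gm, pheno = ph, expr = ex,
                            annotation = ann)
  expect_true(all(file.exists(files)))

  gm2 <- read_vcf_genotypes(files[["vcf"]])
  expect_equal(unname(gm2$geno), unname(gm$geno))
  expect_equal(gm2$map$pos, gm$map$pos)
  expect_equal(gm2$contigs, genome$chromosomes)

  ann2 <- read_gff3_annotation(files[["gff3"]])
  expect_equal(ann2$start, ann$start)
  expect_equal(ann2$gene_id, ann$gene_id)

  ph2 <- read_phenotypes(files[["phenotypes"]])
  expect_equal(nrow(ph2), nrow(ph))
  expect_equal(sum(ph2$value), sum(ph$value))

  ex2 <- read_expression(files[["expression"]], files[["design"]])
  expect_equal(unname(ex2$expr), unname(ex$expr), tolerance = 1e-8)
})
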