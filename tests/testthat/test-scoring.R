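test_that("relative traits are stress/control ratios of replicate means", {
  ph <- rbind(
    make_pheno(c(a1 = 100), mult = c(CK = 1, M = 0.55)),
    make_pheno(c(a2 = 80), mult = c(CK = 1, M = 1)))
  tr <- relative_trait(ph)
  expect_equal(tr$TR[tr$accession == "a1"], 0.55)
  expect_equal(tr$TR[tr$accession == "a2"], 1)
})

test_that("a zero control mean is flagged undefined, not propagated", {
  ph <- make_pheno(c(a1 = 100, a2 = 50), mult = c(CK = 1, M = 0.5))
  ph$value[ph$accession == "a2" & ph$treatment == "CK"] <- 0
  expect_message(tr <- relative_trait(ph), "zero control mean")
  expect_true(tr$undefined[tr$accession == "a2"])
  expect_true(is.na(tr$TR[tr$accession == "a2"]))
  expect_equal(tr$TR[tr$accession == "a1"], 0.5)
})

test_that("the drought tolerance index matches hand arithmetic", {
  ph <- data.frame(accession = rep(c("a1", "a2", "a3"), each = 2),
                   trait = "yield",
                   treatment = rep(c("S", "CK"), 3),
                   environment = "E1", replicate = 1,
                   value = c(2, 4, 4, 4, 6, 6), stringsAsFactors = FALSE)
  di <- drought_tolerance_index(ph)
  # YD = (2,4,6), YP = (4,4,6), mean YD = 4
  expect_equal(di$DI, c(0.25, 1.0, 1.5))
  lit <- drought_tolerance_index(ph, di_formula = "literal")
  expect_equal(lit$DI, c(2 / 4, 4 / 4, 6 / 6) * 4)

  # homogeneous panel: YD = YP = mean(YD) for everyone -> DI = 1
  ph$value <- 5
  expect_equal(drought_tolerance_index(ph)$DI, rep(1, 3))

  # zero drought yield -> DI = 0; zero control yield -> flagged
  ph$value <- c(0, 4, 4, 4, 6, 0)
  di <- drought_tolerance_index(ph)
  expect_equal(di$DI[1], 0)
  expect_true(di$undefined[3])
  expect_true(is.na(di$DI[3]))
})

test_that("PCA factor weights equal explained-variance ratios", {
  set.seed(42)
  X <- matrix(rnorm(250), 50, 5)
  cw <- composite_weights(X, cum_var = 0.999)
  # independent eigen-decomposition oracle on the correlation matrix
  ev <- eigen(cor(X), symmetric = TRUE)$values
  k <- length(cw$weights)
  expect_equal(cw$weights, (ev / sum(ev))[1:k] / sum((ev / sum(ev))[1:k]),
               tolerance = 1e-8)
  expect_equal(sum(cw$weights), 1, tolerance = 1e-10)

  # perfectly collinear indicators collapse to a single component
  Y <- cbind(a = X[, 1], b = 2 * X[, 1] + 3, c = -X[, 1])
  cw1 <- composite_weights(Y)
  expect_equal(unname(cw1$weights), 1)

  expect_error(composite_weights(cbind(X, const = 1)), "constant")
})

test_that("membership attains both bounds and is linear between them", {
  x <- matrix(c(2, 5, 8), dimnames = list(NULL, "i1"))
  mu <- membership(x)
  expect_equal(as.numeric(mu), c(0, 0.5, 1))
  expect_error(membership(matrix(rep(3, 4), dimnames = list(NULL, "flat"))),
               "max == min")
})

test_that("D values are weighted membership sums with exact arithmetic", {
  expect_equal(unname(d_value(matrix(c(1, 0), 1), c(0.6, 0.4))), 0.6)
  expect_equal(unname(d_value(matrix(1, 2, 3), c(0.2, 0.3, 0.5))), c(1, 1))
  expect_equal(unname(d_value(matrix(c(0.2, 0.8, 0.5), 1),
                              c(0.5, 0.3, 0.2))), 0.44)
  expect_error(d_value(matrix(0.5, 1, 2), c(1)), "mismatch")
  expect_error(d_value(matrix(0.5, 1, 2), c(0.6, 0.2)), "sum to 1")
})

test_that("d_value is linear in the membership matrix", {
  set.seed(1)
  w <- c(0.5, 0.3, 0.2)
  m1 <- matrix(runif(30), 10, 3)
  m2 <- matrix(runif(30), 10, 3)
  for (alpha in c(0.2, 0.5, 0.9)) {
    expect_equal(d_value(alpha * m1 + (1 - alpha) * m2, w),
                 alpha * d_value(m1, w) + (1 - alpha) * d_value(m2, w),
                 tolerance = 1e-12)
  }
})

test_that("classification recovers separated D bands and ranks them", {
  set.seed(3)
  mu <- rbind(matrix(0.9 + runif(20, -0.01, 0.01), 10, 2),
              matrix(0.5 + runif(20, -0.01, 0.01), 10, 2),
              matrix(0.1 + runif(20, -0.01, 0.01), 10, 2))
  rownames(mu) <- sprintf("a%02d", 1:30)
  d <- rowMeans(mu)
  cls <- classify_accessions(mu, d, k = 3)
  expect_equal(cls$class, rep(c("tolerant", "medium", "sensitive"),
                              each = 10))
})

test_that("classification is invariant to accession order", {
  set.seed(4)
  mu <- matrix(runif(60), 30, 2,
               dimnames = list(sprintf("a%02d", 1:30), NULL))
  d <- rowMeans(mu)
  cls <- classify_accessions(mu, d)
  perm <- sample(30)
  cls_p <- classify_accessions(mu[perm, ], d[perm])
  expect_equal(cls_p$class[match(cls$accession, cls_p$accession)], cls$class)
})

test_that("an all-tied D vector is flagged degenerate, not an error", {
  mu <- matrix(0.5, 5, 2, dimnames = list(letters[1:5], NULL))
  mu[, 1] <- c(0.1, 0.3, 0.5, 0.7, 0.9)  # memberships differ, D ties
  expect_warning(cls <- classify_accessions(mu, rep(0.5, 5), k = 3),
                 "degenerate")
  expect_equal(nrow(cls), 5)
})

test_that("descriptive statistics match the adjusted sample formulas", {
  ph <- data.frame(accession = letters[1:5], trait = "t", treatment = "M",
                   environment = "E1", replicate = 1,
                   value = c(1, 2, 3, 4, 5), stringsAsFactors = FALSE)
  st <- descriptive_stats(ph)
  expect_equal(st$skewness, 0)
  expect_equal(st$cv, 100 * sd(1:5) / 3)

  # brute-force transcription of the adjusted Fisher-Pearson formulas
  v <- c(1, 1, 1, 10)
  n <- 4
  z <- (v - mean(v)) / sd(v)
  sk_expect <- n / ((n - 1) * (n - 2)) * sum(z^3)
  ku_expect <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  ph2 <- data.frame(accession = letters[1:4], trait = "t", treatment = "M",
                    environment = "E1", replicate = 1, value = v,
                    stringsAsFactors = FALSE)
  st2 <- descriptive_stats(ph2)
  expect_equal(st2$skewness, sk_expect, tolerance = 1e-10)
  expect_equal(st2$kurtosis, ku_expect, tolerance = 1e-10)

  cst <- descriptive_stats(transform(ph, value = 7))
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv, 0)

  expect_warning(tiny <- descriptive_stats(ph2[1:2, ]), "< 3 observations")
  expect_true(is.na(tiny$skewness))
})

test_that("the scoring pipeline recovers planted tolerant and sensitive extremes", {
  genome <- genome_spec(c(A01 = 4e6, B06 = 4e6))
  gm <- simulate_genotypes(genome, 100, 800, subpop_split = c(50, 50),
                           sweep = sweep_spec("B06", 1e6, 1.5e6, 0.8),
                           seed = 11)
  ph <- simulate_phenotypes(gm, seed = 11)
  sc <- score_drought_tolerance(ph)
  expect_equal(sum(sc$pca$weights), 1, tolerance = 1e-10)
  expect_true(all(sc$scores$D >= 0 & sc$scores$D <= 1))
  sp <- setNames(attr(gm, "subpop"), rownames(gm$geno))[sc$scores$accession]
  # no planted extreme lands in the opposite class, and at least 90% of
  # each assigned extreme class matches its planted subgroup
  expect_equal(sum(sp == "tolerant" & sc$scores$class == "sensitive"), 0)
  expect_equal(sum(sp == "sensitive" & sc$scores$class == "tolerant"), 0)
  expect_gte(mean(sp[sc$scores$class == "tolerant"] == "tolerant"), 0.9)
  expect_gte(mean(sp[sc$scores$class == "sensitive"] == "sensitive"), 0.9)
})
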