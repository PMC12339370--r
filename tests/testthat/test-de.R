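test_that("prefilter keeps features with enough well-covered samples", {
  m <- rbind(a = c(12, 11, 0, 3), b = c(9, 9, 9, 9))
  expect_equal(prefilter(m, smallest_group_size = 2), "a")

  toy <- rbind(f1 = c(10, 10, 10, 0), f2 = c(10, 10, 0, 0),
               f3 = c(50, 0, 0, 0),  f4 = c(9, 9, 9, 9),
               f5 = c(100, 100, 100, 100), f6 = c(0, 0, 0, 0))
  expect_equal(prefilter(toy, smallest_group_size = 2),
               c("f1", "f2", "f5"))
  expect_equal(prefilter(toy, smallest_group_size = 3), c("f1", "f5"))
  expect_error(prefilter(toy, smallest_group_size = 5), "exceeds")
})

test_that("median-of-ratios size factors recover library scale", {
  a <- c(10, 20, 40, 100)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("f", 1:4)
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  m3 <- cbind(s1 = a, s2 = a, s3 = a)
  expect_equal(unname(size_factors(m3)), rep(1, 3), tolerance = 1e-12)

  zero <- cbind(s1 = c(0, 5), s2 = c(5, 0))
  expect_error(size_factors(zero), "median-of-ratios is undefined")
})

test_that("size factors track true library multipliers on NB data", {
  catalog <- simulate_catalog(10, 5000, seed = 20)
  sim <- simulate_counts(catalog, cohort_design(3, 3, 3, 3), NULL, seed = 21,
                         mean_range = c(20, 2000))
  sf <- size_factors(sim$counts)
  truth <- sim$size_factors_true
  # both are defined up to a common scale; compare after geometric centring
  ratio <- (sf / exp(mean(log(sf)))) / (truth / exp(mean(log(truth))))
  expect_true(all(abs(ratio - 1) < 0.02))
})

test_that("BH adjustment matches a literal step-up oracle", {
  set.seed(33)
  for (m in c(1, 7, 100, 1000)) {
    p <- runif(m)
    expect_equal(stats::p.adjust(p, method = "BH"), bh_stepup(p),
                 tolerance = 1e-12)
  }
})

test_that("planted fold changes are recovered with correct sign and scale", {
  # plant a small fraction of features so normalisation stays anchored by
  # the unchanged majority (median-of-ratios absorbs very dense effects)
  catalog <- simulate_catalog(40, 2000, seed = 22)
  idx <- build_family_index(catalog)
  fam <- idx$families$family[which(idx$families$size >= 50)][1]
  eff <- effect_spec(fam, fraction_down = 1.0, log2fc = 2, subgroup = "all")
  sim <- simulate_counts(catalog, cohort_design(6, 6, 6, 6), eff, seed = 23)
  de <- nb_wald_de(sim$counts, sim$metadata, "all")
  planted <- sim$truth$id[sim$truth$true_log2fc_all == -2]
  expect_gte(length(planted), 50)
  est <- de$log2FC[match(planted, de$id)]
  expect_gte(mean(est < 0), 48 / 50)
  expect_lt(abs(mean(est) - (-2)), 0.3)
})

test_that("null simulation gives calibrated Wald p-values", {
  catalog <- simulate_catalog(45, 5000, seed = 24)
  sim <- simulate_counts(catalog, cohort_design(6, 6, 6, 6), NULL, seed = 25)
  de <- nb_wald_de(sim$counts, sim$metadata, "all")
  frac <- mean(de$pvalue <= 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("identical groups give exactly zero log2 fold change", {
  set.seed(26)
  base <- matrix(rnbinom(100 * 6, mu = 50, size = 5), nrow = 100)
  counts <- cbind(base, base)  # stress samples literally copy control samples
  rownames(counts) <- paste0("f", 1:100)
  colnames(counts) <- paste0("s", 1:12)
  meta <- data.frame(sample_id = colnames(counts), cohort = "newborn",
                     group = rep(c("control", "stress"), each = 6),
                     sex = "F", birth_type = "vaginal", pss = 1)
  keep <- prefilter(counts, 2)
  de <- nb_wald_de(counts[keep, ], meta, "all")
  expect_true(all(abs(de$log2FC) < 1e-8))
})

test_that("scaling one sample's counts rescales its size factor and leaves noiseless log2FC alone", {
  # noiseless counts: every sample sits exactly on its group mean x size
  # factor; only two of five features change, so the unchanged majority
  # anchors the median-of-ratios normalisation
  mu <- c(40, 100, 400, 1000, 250)
  fc <- c(2, 2, 1, 1, 1)               # stress doubles features 1-2
  sf_true <- c(1, 2, 1, 2, 1, 2, 1, 2)
  x <- rep(c(0, 1), each = 4)
  counts <- sapply(seq_along(sf_true), function(j) mu * fc^x[j] * sf_true[j])
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("f", seq_along(mu))
  colnames(counts) <- paste0("s", 1:8)
  meta <- data.frame(sample_id = colnames(counts), cohort = "newborn",
                     group = rep(c("control", "stress"), each = 4),
                     sex = "F", birth_type = "vaginal", pss = 1)
  de1 <- nb_wald_de(counts, meta, "all")
  expect_equal(de1$log2FC, c(1, 1, 0, 0, 0), tolerance = 1e-6)

  scaled <- counts
  scaled[, 1] <- scaled[, 1] * 2L
  # size factors are defined up to a common scale (the geometric reference
  # itself moves when a sample is rescaled): the invariant is the factor
  # relative to any other sample
  sf0 <- size_factors(counts); sf2 <- size_factors(scaled)
  expect_equal(unname((sf2[1] / sf2[2]) / (sf0[1] / sf0[2])), 2,
               tolerance = 1e-12)
  de2 <- nb_wald_de(scaled, meta, "all")
  expect_equal(de2$log2FC, de1$log2FC, tolerance = 1e-6)
})

test_that("degenerate contrasts and missing levels raise errors", {
  counts <- matrix(10L, 4, 4, dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), cohort = "newborn",
                     group = "stress", sex = "F", birth_type = "vaginal", pss = 20)
  expect_error(nb_wald_de(counts, meta, "all"), "at least 2 samples")
})

test_that("external DE tables load through the same schema", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b"), baseMean = c(10, 20), log2FC = c(-1, 2),
                   stat = c(-2, 3), pvalue = c(0.04, 0.01), padj = c(0.04, 0.02))
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  de <- read_de_table(tmp)
  expect_s3_class(de, "de_result")
  expect_equal(de$significant, c(TRUE, TRUE))
  expect_error(read_de_table(textConnection("id\tfoo\n1\t2")), "missing column")
})
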