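make_de <- function(ids, lfc) {
  structure(data.frame(id = ids, baseMean = 10, log2FC = lfc, lfcSE = 1,
                       stat = lfc, pvalue = 0.5, padj = 0.5,
                       significant = FALSE, flagged = FALSE,
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

make_index <- function(ids, families, min_size = 2) {
  ann <- data.frame(id = ids, length = 20L,
                    genome_origin = sub("-.*", "", families),
                    amino_acid = sub("^[^-]+-([^-]+)-.*$", "\\1", families),
                    anticodon = "AGC",
                    cleavage_type = sub("^[^-]+-[^-]+-", "", families),
                    stringsAsFactors = FALSE)
  build_family_index(ann, min_size = min_size)
}

test_that("direction counts use only finite nonzero fold changes", {
  ids <- paste0("t", 1:7)
  fams <- c(rep("MT-Gly-i-tRF", 4), rep("Nuc-Asp-i-tRF", 3))
  de <- make_de(ids, c(-1, -2, -0.1, 0.3, 0, NA, -1))
  idx <- make_index(ids, fams)
  fc <- family_direction_counts(de, idx)
  mt <- fc[fc$family == "MT-Gly-i-tRF", ]
  expect_equal(c(mt$n, mt$k_down), c(4L, 3L))
  nuc <- fc[fc$family == "Nuc-Asp-i-tRF", ]
  expect_equal(c(nuc$n, nuc$k_down, nuc$n_excluded), c(1L, 1L, 2L))

  expect_error(family_direction_counts(make_de("zz", -1), idx), "absent")
})

test_that("exact binomial p matches closed forms and the enumeration oracle", {
  expect_equal(exact_binomial_test(4, 4), 0.125, tolerance = 1e-15)
  expect_equal(exact_binomial_test(10, 8), 0.109375, tolerance = 1e-15)
  expect_equal(exact_binomial_test(29, 29), 2 * 0.5^29, tolerance = 1e-15)
  expect_equal(exact_binomial_test(1, 0), 1)

  for (n in 1:12) {
    for (k in 0:n) {
      expect_equal(exact_binomial_test(n, k), enum_binom_p(n, k),
                   tolerance = 1e-12)
    }
  }

  # independent reference implementation agrees (symmetric null)
  for (n in c(5, 17, 40)) {
    for (k in c(0, 2, n %/% 2, n)) {
      expect_equal(exact_binomial_test(n, k),
                   stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
    }
  }

  expect_error(exact_binomial_test(0, 0), "n = 0")
  expect_error(exact_binomial_test(4, 5), "0 <= k <= n")
})

test_that("binomial test is symmetric in k and n - k up to n = 200", {
  for (n in c(1, 2, 7, 50, 200)) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n - 1, n))) {
      expect_equal(exact_binomial_test(n, k), exact_binomial_test(n, n - k),
                   tolerance = 1e-14)
    }
  }
  expect_equal(exact_binomial_test(200, 200), 2 * 0.5^200, tolerance = 1e-15)
  expect_equal(exact_binomial_test(150, 0), 2 * 0.5^150, tolerance = 1e-15)
})

test_that("family trend table applies BH across testable families and calls direction", {
  ids <- paste0("t", 1:4)
  de <- make_de(ids, c(-1, -2, -3, -4))
  idx <- make_index(ids, rep("MT-Gly-i-tRF", 4))
  ft <- family_trend_table(de, idx)
  expect_equal(ft$pvalue, 0.125)   # single family: FDR equals p
  expect_equal(ft$padj, 0.125)
  expect_equal(ft$direction, "none")

  # BH step-up arithmetic over three families (p = 0.01, 0.02, 0.04)
  # exact binomial p for (n, k): (7,7)->0.015625, (9,8)->0.0390625, (12,11)->0.punted
  ids2 <- c(sprintf("a%d", 1:7), sprintf("b%d", 1:9), sprintf("c%d", 1:12))
  fams2 <- c(rep("MT-Ala-i-tRF", 7), rep("MT-Gly-i-tRF", 9), rep("Nuc-Asp-i-tRF", 12))
  lfc2 <- c(rep(-1, 7), rep(-1, 8), 1, rep(-1, 11), 1)
  ft2 <- family_trend_table(make_de(ids2, lfc2), make_index(ids2, fams2))
  p_expect <- c(exact_binomial_test(12, 11), exact_binomial_test(7, 7),
                exact_binomial_test(9, 8))  # index order: Nuc-Asp, MT-Ala, MT-Gly
  expect_equal(ft2$pvalue[match(c("Nuc-Asp-i-tRF", "MT-Ala-i-tRF", "MT-Gly-i-tRF"),
                                ft2$family)], p_expect)
  expect_equal(sort(ft2$padj), sort(bh_stepup(p_expect)), tolerance = 1e-12)
  expect_true(all(ft2$direction == "down"))
  expect_equal(ft2$signed_size, -ft2$n)

  # families below min_size are reported but not tested
  ids3 <- c("x1", "y1", "y2")
  ft3 <- family_trend_table(make_de(ids3, c(-1, -1, -1)),
                            make_index(ids3, c("MT-Phe-i-tRF", "MT-Gly-i-tRF",
                                               "MT-Gly-i-tRF")))
  expect_true(is.na(ft3$pvalue[ft3$family == "MT-Phe-i-tRF"]))
  expect_false(is.na(ft3$pvalue[ft3$family == "MT-Gly-i-tRF"]))
})

test_that("a planted down-trending family is detected against null families", {
  catalog <- simulate_catalog(45, 565, seed = 30)
  idx <- build_family_index(catalog)
  big <- idx$families$family[idx$families$size >= 40][1]
  eff <- effect_spec(big, fraction_down = 0.9, log2fc = 1, subgroup = "all")
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_counts(catalog, cohort_design(), eff, seed = 100 + s)
    de <- nb_wald_de(sim$counts, sim$metadata, "all")
    ft <- family_trend_table(de, idx)
    if (ft$direction[ft$family == big] == "down") hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.9)
})

test_that("superfamily trends aggregate by origin, cleavage and amino acid", {
  ids <- paste0("t", 1:10)
  ann <- data.frame(id = ids, length = 20L,
                    genome_origin = rep(c("MT", "Nuc"), each = 5),
                    amino_acid = rep(c("Gly", "Asp"), each = 5),
                    anticodon = "AGC",
                    cleavage_type = rep(c("i-tRF", "3p-tRF"), 5),
                    stringsAsFactors = FALSE)
  de <- make_de(ids, c(rep(-1, 5), rep(1, 5)))
  by_origin <- superfamily_trend_table(de, ann, by = "genome_origin")
  expect_equal(by_origin$k_down[by_origin$group == "MT"], 5L)
  expect_equal(by_origin$k_down[by_origin$group == "Nuc"], 0L)
  expect_equal(by_origin$pvalue, rep(exact_binomial_test(5, 5), 2))
  by_cleave <- superfamily_trend_table(de, ann, by = "cleavage_type")
  expect_equal(sum(by_cleave$n), 10L)
})

test_that("length profiles concentrate where the expression is", {
  ids <- c("a", "b", "c")
  ann <- data.frame(id = ids, length = c(20L, 20L, 20L), genome_origin = "Nuc",
                    amino_acid = "Ala", anticodon = "AGC",
                    cleavage_type = "i-tRF", stringsAsFactors = FALSE)
  m <- matrix(5, 3, 4, dimnames = list(ids, paste0("s", 1:4)))
  prof <- mean_length_profile(m, ann, rep("g1", 4))
  expect_equal(prof$profile$g1[prof$profile$length == 20], 15)
  expect_equal(sum(prof$profile$g1), 15)
  expect_equal(unname(prof$mir_window_fraction["g1"]), 1)

  # two identical groups -> identical profiles
  prof2 <- mean_length_profile(m, ann, rep(c("g1", "g2"), each = 2))
  expect_equal(prof2$profile$g1, prof2$profile$g2)

  # planted 36-nt peak dominates the profile argmax
  catalog <- simulate_catalog(10, 150, seed = 31)
  sim <- simulate_counts(catalog, cohort_design(3, 3, 3, 3), NULL, seed = 32)
  norm <- normalize_counts(sim$counts)
  boost <- rownames(norm) %in% catalog$id[catalog$length == 36]
  expect_gt(sum(boost), 0)   # the catalog's 3'-half mode sits at 36 nt
  norm[boost, ] <- norm[boost, ] + 5000
  prof3 <- mean_length_profile(norm, catalog, sim$metadata$group)
  expect_equal(prof3$profile$length[which.max(prof3$profile$stress)], 36)
})

test_that("Kruskal-Wallis family length statistics match the rank formula", {
  # family of two members (lengths 20 and 30); counts tuned to produce a
  # hand-made 3-per-group x 4-group table of weighted mean lengths
  w <- c(21, 22, 23, 24, 25, 26, 27, 28, 29, 21.5, 22.5, 23.5)
  a <- (30 - w) / 10  # member-1 weight fraction giving weighted length w
  counts <- rbind(m1 = 100 * a, m2 = 100 * (1 - a))
  colnames(counts) <- paste0("s", 1:12)
  ann <- data.frame(id = c("m1", "m2"), length = c(20L, 30L),
                    genome_origin = "Nuc", amino_acid = "Ala",
                    anticodon = "AGC", cleavage_type = "i-tRF",
                    stringsAsFactors = FALSE)
  idx <- build_family_index(ann)
  groups <- rep(c("fs", "ms", "fc", "mc"), each = 3)
  wml <- weighted_family_length(counts, ann, idx)
  expect_equal(unname(wml[1, ]), w, tolerance = 1e-12)

  kw <- kw_family_length(counts, ann, idx, groups)
  r <- rank(w)
  N <- length(w)
  rbar <- tapply(r, groups, mean)
  H_oracle <- 12 / (N * (N + 1)) * sum(3 * (rbar - (N + 1) / 2)^2)
  expect_equal(kw$H, H_oracle, tolerance = 1e-12)

  # four identical groups -> H = 0, p = 1
  counts_tied <- rbind(m1 = rep(50, 12), m2 = rep(50, 12))
  colnames(counts_tied) <- paste0("s", 1:12)
  kw_tied <- kw_family_length(counts_tied, ann, idx, groups)
  expect_equal(kw_tied$H, 0)
  expect_equal(kw_tied$pvalue, 1)
})

test_that("a shifted length distribution in one group is detected", {
  ann <- data.frame(id = c("short", "long"), length = c(20L, 30L),
                    genome_origin = "MT", amino_acid = "Gln",
                    anticodon = "AGC", cleavage_type = "3p-tRF",
                    stringsAsFactors = FALSE)
  idx <- build_family_index(ann)
  set.seed(40)
  n_per <- 10
  groups <- rep(c("fs", "ms", "fc", "mc"), each = n_per)
  # control groups weight the short member, the fs group the long one (+6 nt)
  short_w <- ifelse(groups == "fs", 0.2, 0.8) + rnorm(length(groups), 0, 0.03)
  counts <- rbind(short = 1000 * short_w, long = 1000 * (1 - short_w))
  colnames(counts) <- paste0("s", seq_along(groups))
  kw <- kw_family_length(counts, ann, idx, groups)
  expect_lt(kw$pvalue, 0.01)
})
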