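gl_example <- data.frame(
  gene = c("ACHE", "CHAT", "IL6", "CHKB", "NGF", "TNF", "BDNF", "FOS", "JUN"),
  tier = c("core", "core", rep("peripheral", 7)),
  stringsAsFactors = FALSE
)

test_that("candidate filtering applies the length and score gates after collapsing", {
  lens <- data.frame(id = c("r17", "r21", "r28", "r36", "r16"),
                     length = c(17L, 21L, 28L, 36L, 16L))
  pred <- data.frame(
    rna_id = c("r17", "r21", "r28", "r36", "r16", "r21", "r21"),
    gene = c("ACHE", "IL6", "TNF", "ACHE", "ACHE", "NGF", "NGF"),
    score = c(80, 85, 79.9, 95, 95, 70, 83)
  )
  q <- filter_candidates(lens, pred)
  # r17/ACHE at exactly 80 and length 17 kept; r28 at 79.9 dropped; r36 and
  # r16 outside the length window; duplicate r21/NGF collapses to max 83
  expect_setequal(paste(q$rna_id, q$gene),
                  c("r17 ACHE", "r21 IL6", "r21 NGF"))
  expect_equal(q$score[q$rna_id == "r21" & q$gene == "NGF"], 83)

  expect_message(
    q2 <- filter_candidates(lens, data.frame(rna_id = "ghost", gene = "ACHE",
                                             score = 99)),
    "unknown RNA"
  )
  expect_equal(nrow(q2), 0)

  # boundary: length 28 kept when score passes
  q3 <- filter_candidates(lens, data.frame(rna_id = "r28", gene = "ACHE",
                                           score = 80))
  expect_equal(nrow(q3), 1)
})

test_that("cholinergic scores follow the 5/1 weighting and designation rule", {
  qual <- data.frame(rna_id = "r1", gene = c("ACHE", "IL6", "CHKB"),
                     score = c(90, 85, 82))
  s <- cholinergic_scores(qual, gl_example)
  expect_equal(s$score, 7)           # 5 + 1 + 1
  expect_equal(c(s$n_core, s$n_peripheral), c(1L, 2L))
  expect_true(s$is_cholino)

  four <- data.frame(rna_id = "r2", gene = c("IL6", "CHKB", "NGF", "TNF"),
                     score = 90)
  s4 <- cholinergic_scores(four, gl_example)
  expect_equal(s4$score, 4)
  expect_false(s4$is_cholino)        # rule (b) needs five peripherals

  five <- data.frame(rna_id = "r3",
                     gene = c("IL6", "CHKB", "NGF", "TNF", "BDNF"), score = 90)
  s5 <- cholinergic_scores(five, gl_example)
  expect_equal(s5$score, 5)
  expect_true(s5$is_cholino)

  # genes outside the list contribute nothing
  outside <- data.frame(rna_id = "r4", gene = c("ACHE", "NOTAGENE"), score = 90)
  so <- cholinergic_scores(outside, gl_example)
  expect_equal(so$score, 5)
  expect_equal(so$n_peripheral, 0L)

  # RNAs with no qualifying targets report zero scores when asked for
  s0 <- cholinergic_scores(qual, gl_example, rna_ids = c("r1", "rEmpty"))
  expect_equal(s0$score[s0$rna_id == "rEmpty"], 0)
  expect_false(s0$is_cholino[s0$rna_id == "rEmpty"])
})

test_that("designation is monotone: adding a listed target never revokes it", {
  set.seed(70)
  genes <- gl_example$gene
  for (i in 1:30) {
    base_genes <- sample(genes, sample(1:6, 1))
    qual <- data.frame(rna_id = "r", gene = base_genes,
                       score = rep(90, length(base_genes)))
    s_before <- cholinergic_scores(qual, gl_example, rna_ids = "r")
    extra <- sample(genes, 1)
    qual2 <- rbind(qual, data.frame(rna_id = "r", gene = extra, score = 90))
    s_after <- cholinergic_scores(qual2, gl_example, rna_ids = "r")
    expect_gte(s_after$score, s_before$score)
    if (s_before$is_cholino) expect_true(s_after$is_cholino)
  }
})

test_that("RNA class is inferred from identifier conventions", {
  qual <- data.frame(rna_id = c("tDR-1:20-Ala-AGC-1", "hsa-miR-132-3p"),
                     gene = "ACHE", score = 90)
  s <- cholinergic_scores(qual, gl_example)
  expect_equal(s$class[s$rna_id == "tDR-1:20-Ala-AGC-1"], "tRF")
  expect_equal(s$class[s$rna_id == "hsa-miR-132-3p"], "miR")
})

test_that("planted cholinergic RNAs in synthetic tables are recovered exactly", {
  uni <- simulate_gene_universe(seed = 71)
  catalog <- simulate_catalog(10, 80, seed = 72)
  short <- catalog$id[catalog$length >= 17 & catalog$length <= 28]
  planted <- short[seq_len(min(8, length(short)))]
  pred <- simulate_prediction_table(catalog$id, uni$universe, uni$gene_list,
                                    planted_cholino = planted, seed = 73)
  qual <- filter_candidates(catalog, pred)
  s <- cholinergic_scores(qual, uni$gene_list, rna_ids = catalog$id)
  expect_true(all(s$is_cholino[s$rna_id %in% planted]))
  # designation is exactly the rule applied to the qualifying table
  recompute <- vapply(catalog$id, function(r) {
    g <- qual$gene[qual$rna_id == r]
    tier <- uni$gene_list$tier[match(g, uni$gene_list$gene)]
    sum(tier == "core", na.rm = TRUE) >= 1 || sum(tier == "peripheral", na.rm = TRUE) >= 5
  }, logical(1))
  expect_equal(s$is_cholino, unname(recompute[s$rna_id]))
})

test_that("Fisher origin enrichment matches hypergeometric enumeration", {
  flags <- rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 1, 1, 3))
  origin <- rep(c("MT", "Nuc"), each = 4)
  f <- fisher_origin_enrichment(flags, origin)
  expect_equal(f$p, 34 / 70, tolerance = 1e-12)
  expect_equal(f$odds_ratio, 9)

  flags2 <- rep(c(TRUE, FALSE), each = 5)
  origin2 <- rep(c("MT", "Nuc"), each = 5)
  f2 <- fisher_origin_enrichment(flags2, origin2)
  expect_equal(f2$p, 2 / 252, tolerance = 1e-12)

  # zero margin: no information
  f3 <- fisher_origin_enrichment(rep(TRUE, 4), rep(c("MT", "Nuc"), 2))
  expect_equal(f3$p, 1)
  expect_true(is.na(f3$odds_ratio))

  # enumeration oracle over all small tables
  set.seed(74)
  for (i in 1:200) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d <- sample(0:6, 1)
    tab <- matrix(c(a, c_, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    flags_i <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d))
    origin_i <- rep(c("MT", "MT", "Nuc", "Nuc"), c(a, b, c_, d))
    expect_equal(fisher_origin_enrichment(flags_i, origin_i)$p,
                 enum_fisher_p(tab), tolerance = 1e-9)
  }
})

test_that("hypergeometric target enrichment equals direct summation", {
  expect_equal(hypergeom_target_enrichment(100, 10, 10, 5),
               enum_hyper_tail(100, 10, 10, 5), tolerance = 1e-12)
  expect_equal(hypergeom_target_enrichment(100, 10, 10, 0), 1)
  expect_equal(hypergeom_target_enrichment(50, 50, 50, 50), 1)
  set.seed(75)
  for (i in 1:50) {
    u <- sample(20:200, 1)
    nc <- sample(1:(u %/% 2), 1)
    nd <- sample(1:(u %/% 2), 1)
    k <- sample(0:min(nc, nd), 1)
    expect_equal(hypergeom_target_enrichment(u, nc, nd, k),
                 enum_hyper_tail(u, nc, nd, k), tolerance = 1e-10)
  }
  expect_error(hypergeom_target_enrichment(10, 5, 5, 6), "inconsistent")
})

test_that("the shipped example gene list loads and matches the panel scale", {
  path <- system.file("extdata", "cholinergic_genes_example.csv",
                      package = "trfam")
  gl <- read_gene_list(path)
  expect_equal(nrow(gl), 102)
  expect_equal(sum(gl$weight == 5), sum(gl$tier == "core"))
  expect_true(all(c("ACHE", "BCHE", "CHAT") %in% gl$gene[gl$tier == "core"]))
  expect_true(all(c("IL6", "CHKB") %in% gl$gene[gl$tier == "peripheral"]))
})
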