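test_that("fractional counting splits multi-mapped reads and conserves mass", {
  feats <- data.frame(feature_id = paste0("TE", 1:4),
                      chrom = "chr1",
                      start = c(1000, 3000, 5000, 7000),
                      end = c(1999, 3999, 5999, 7999))
  # one read, 4 equally best loci, one inside each TE -> 0.25 each
  pl <- data.frame(read_id = "r1", chrom = "chr1",
                   start = c(1100, 3100, 5100, 7100),
                   end = c(1199, 3199, 5199, 7199))
  expect_equal(unname(fractional_counts(pl, feats)), rep(0.25, 4))

  # unique read -> 1.0; read outside all features -> nothing
  pl2 <- data.frame(read_id = c("r1", "r2"), chrom = "chr1",
                    start = c(1100, 20000), end = c(1199, 20099))
  expect_equal(unname(fractional_counts(pl2, feats)), c(1, 0, 0, 0))

  # largest-overlap assignment, ties split equally
  feats2 <- data.frame(feature_id = c("A", "B"), chrom = "chr1",
                       start = c(100, 180), end = c(199, 300))
  hit_a <- data.frame(read_id = "r1", chrom = "chr1", start = 150,
                      end = 249)  # 50 bp in A, 70 bp in B
  expect_equal(unname(fractional_counts(hit_a, feats2)), c(0, 1))
  tie <- data.frame(read_id = "r1", chrom = "chr1", start = 160,
                    end = 219)    # 40 bp in each
  expect_equal(unname(fractional_counts(tie, feats2)), c(0.5, 0.5))

  expect_error(fractional_counts(pl, transform(feats, end = start - 1)),
               "length")
})

test_that("fractional counting conserves total read mass on simulated placements", {
  cfg <- sim_config(seed = 9, n_genes = 30, n_tes = 80)
  ann <- gen_annotation(cfg)
  n_reads <- 400
  pl <- gen_placements(cfg, ann, n_reads = n_reads)
  feats <- data.frame(feature_id = ann$tes$te_id, chrom = ann$tes$chrom,
                      start = ann$tes$start, end = ann$tes$end)
  counts <- fractional_counts(pl, feats)
  expect_lte(sum(counts), n_reads + 1e-9)
  # reads fully inside TEs contribute their whole weight
  expect_gt(sum(counts), 0.5 * n_reads)
  # all-unique placements give integer counts
  uni <- pl[!duplicated(pl$read_id) & !(pl$read_id %in%
              pl$read_id[duplicated(pl$read_id)]), ]
  cu <- fractional_counts(uni, feats)
  expect_true(all(abs(cu - round(cu)) < 1e-9))
})

test_that("size factors follow median-of-ratios with geometric mean one", {
  m <- matrix(c(10, 20, 100, 200, 1000, 2000), 3, 2, byrow = TRUE)
  rownames(m) <- paste0("f", 1:3)
  expect_equal(size_factors(m), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(size_factors(cbind(m[, 1], m[, 1])), c(1, 1))
  m2 <- cbind(m[, 1], 2 * m[, 1])
  expect_equal(size_factors(m2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(size_factors(m)))), 1, tolerance = 1e-12)
  # no common feature -> library-size fallback
  m3 <- matrix(c(5, 0, 0, 7), 2, 2)
  rownames(m3) <- c("a", "b")
  expect_warning(sf <- size_factors(m3), "library-size")
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("NB differential expression controls the null and recovers planted signal", {
  set.seed(101)
  mu <- exp(rnorm(2000, log(50), 1))
  null_vals <- sapply(1:8, function(j) rnbinom(2000, mu = mu, size = 10))
  de0 <- nb_differential(make_cm(null_vals, 4), "A", "B")
  expect_lt(mean(de0$p_value < 0.05, na.rm = TRUE), 0.08)
  expect_lt(mean(de0$p_adjusted < 0.05, na.rm = TRUE), 0.05)

  muB <- mu; muB[1:200] <- mu[1:200] * 4
  vals <- cbind(sapply(1:4, function(j) rnbinom(2000, mu = mu, size = 10)),
                sapply(1:4, function(j) rnbinom(2000, mu = muB, size = 10)))
  de <- nb_differential(make_cm(vals, 4), "A", "B")
  expect_gte(mean(de$direction[1:200] == "up", na.rm = TRUE), 0.9)
  expect_equal(median(de$log2_fold_change[1:200]), 2, tolerance = 0.3)

  # features identical in every sample are ns with log2FC exactly 0
  const <- matrix(rep(c(50, 120, 7, 300), each = 8), 4, 8, byrow = TRUE)
  de2 <- nb_differential(make_cm(const, 4), "A", "B")
  expect_equal(de2$log2_fold_change, rep(0, 4))
  expect_equal(de2$direction, rep("ns", 4))

  # low-coverage features carry NA p (independent filtering)
  low <- rbind(matrix(0, 1, 8), vals[301:350, ])
  de3 <- nb_differential(make_cm(low, 4), "A", "B")
  expect_true(is.na(de3$p_value[1]))
  expect_true(is.na(de3$direction[1]))

  five <- vals[, 1:5]
  rownames(five) <- sprintf("f%04d", seq_len(nrow(five)))
  cm5 <- count_matrix(five, data.frame(
    sample_id = paste0("s", 1:5), tissue = c("A", "A", "A", "A", "B"),
    replicate = c(1:4, 1)))
  expect_error(nb_differential(cm5, "A", "B"), "replicates")
})

test_that("NB differential type-I error stays near alpha across seeds", {
  fr <- sapply(1:8, function(s) {
    set.seed(200 + s)
    mu <- exp(rnorm(800, log(50), 1))
    vals <- sapply(1:8, function(j) rnbinom(800, mu = mu, size = 10))
    de <- nb_differential(make_cm(vals, 4), "A", "B")
    mean(de$p_value < 0.05, na.rm = TRUE)
  })
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.08)
})

test_that("TE categorization applies the documented precedence", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 12000)
  tes <- data.frame(
    te_id = c("near", "lowcount", "dyn", "stat", "untested", "absent"),
    chrom = "chr1",
    start = c(12500, 30000, 40000, 50000, 60000, 70000),
    end = c(12900, 30400, 40400, 50400, 60400, 70400),
    family = "RLG")
  ann <- genome_annotation(genes, tes)
  vals <- rbind(near = c(50, 50), lowcount = c(4, 5), dyn = c(60, 70),
                stat = c(40, 45), untested = c(30, 35), absent = c(0, 0))
  cm <- count_matrix(vals[-6, , drop = FALSE],
                     data.frame(sample_id = c("s1", "s2"),
                                tissue = c("seedling", "pollen"),
                                replicate = c(1, 1)))
  de <- data.frame(feature_id = c("near", "dyn", "stat", "untested"),
                   p_adjusted = c(0.001, 0.01, 0.5, NA))
  cats <- categorize_tes(ann, cm, list(pollen = de))
  got <- setNames(cats$category, cats$te_id)
  expect_equal(got[["near"]], "near_genes")      # proximity beats DE
  expect_equal(got[["lowcount"]], "not_covered") # 9 < 10 total
  expect_equal(got[["dyn"]], "dynamic")
  expect_equal(got[["stat"]], "static")
  expect_equal(got[["untested"]], "not_covered") # NA padj everywhere
  expect_equal(got[["absent"]], "not_covered")   # zero counts
  # the partition covers every annotated TE exactly once
  expect_setequal(cats$te_id, ann$tes$te_id)
  expect_equal(sum(table(cats$category)), nrow(ann$tes))
})

test_that("family enrichment is zero on self and log2-linear in proportion", {
  bg <- data.frame(family = rep(c("RLG", "DTM", "RST"), c(50, 30, 20)))
  fe <- family_enrichment(bg, bg)
  expect_true(all(fe$log2_ratio == 0))
  # family at twice its background proportion
  cat2 <- data.frame(family = rep(c("RLG", "DTM"), c(50, 15)))
  fe2 <- family_enrichment(cat2, bg)
  expect_equal(fe2$log2_ratio[fe2$family == "RLG"],
               log2((50 / 65) / 0.5), tolerance = 1e-12)
  expect_true(is.na(fe2$log2_ratio[fe2$family == "RST"]))
  # random subsets match direct recomputation
  set.seed(7)
  sub <- bg[sample(100, 40), , drop = FALSE]
  fe3 <- family_enrichment(sub, bg)
  for (i in seq_len(nrow(fe3))) {
    o <- mean(sub$family == fe3$family[i])
    e <- mean(bg$family == fe3$family[i])
    if (o > 0) expect_equal(fe3$log2_ratio[i], log2(o / e))
  }
  expect_error(family_enrichment(bg, bg[0, , drop = FALSE]), "non-empty")
})

test_that("stage set persistence and overlap match enumeration", {
  up <- list(micro = c("a", "b", "c", "d"))
  ex <- list(micro = letters[1:6], pollen = c("a", "b"),
             sperm = letters[1:10])
  uni <- letters[1:12]
  res <- stage_set_analysis(up, ex, uni)
  pers <- res$persistence
  expect_equal(pers$fraction[pers$to == "pollen"], 0.5)
  expect_equal(pers$fraction[pers$to == "sperm"], 1)
  # hypergeometric tail equals explicit enumeration on the tiny universe
  ov <- res$overlap_tests
  for (i in seq_len(nrow(ov)))
    expect_equal(ov$p_value[i],
                 overlap_oracle(ov$n_overlap[i], ov$n_a[i], ov$n_b[i],
                                length(uni)), tolerance = 1e-12)
  # identical sets over the whole universe: p = 1
  expect_equal(overlap_hyper_p(12, 12, 12, 12), 1)
  # exclusive sets
  expect_setequal(res$exclusive$sperm, c("g", "h", "i", "j"))
  expect_error(stage_set_analysis(up, ex, letters[1:3]), "universe")
})
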