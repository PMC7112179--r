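make_ears <- function(marked, totals, allele = "al1", plant = NULL,
                      direction = "male", class = "vegetative_cell",
                      log2_fpkm = 9) {
  k <- length(marked)
  if (is.null(plant)) plant <- paste0(allele, "_p", rep(1:2, length.out = k))
  data.frame(allele_id = allele, gene_id = paste0("g_", allele),
             expression_class = class, log2_fpkm = log2_fpkm,
             plant_id = plant, ear_id = paste0(allele, "_e", seq_len(k)),
             direction = direction, marker = "GFP",
             n_marked = marked, n_total = totals)
}

test_that("QC excludes double-insertion ears and under-replicated alleles", {
  ears <- rbind(
    make_ears(c(150, 100, 95, 105), c(200, 200, 200, 200), "al1"),
    make_ears(c(105, 98, 101), c(200, 200, 200), "al2"),
    make_ears(c(100, 102), c(200, 200), "al3"),                 # 2 ears
    make_ears(c(99, 101, 100), c(200, 200, 200), "al4",
              plant = rep("al4_p1", 3)))                        # 1 plant
  qc <- qc_ears(ears)
  # 150/200 = 75% and binomially incompatible with 0.5 -> excluded
  expect_true(any(qc$report$reason == "double_insertion" &
                  qc$report$ear_id == "al1_e1"))
  expect_false("al1_e1" %in% qc$ears$ear_id)
  # al1 still has 3 ears from 2 plants -> retained
  expect_true("al1" %in% qc$ears$allele_id)
  expect_true("al2" %in% qc$ears$allele_id)
  expect_false("al3" %in% qc$ears$allele_id)
  expect_false("al4" %in% qc$ears$allele_id)
  expect_true(all(qc$report$reason[qc$report$allele_id %in%
                                   c("al3", "al4")] ==
                  "insufficient_replication"))
  # a high-ish fraction on a small ear is NOT excluded (no binomial evidence)
  small <- make_ears(c(8, 100, 100), c(11, 200, 200), "al5")
  qc2 <- qc_ears(small)
  expect_true("al5_e1" %in% qc2$ears$ear_id)
  # 52.5% retained
  qc3 <- qc_ears(make_ears(c(105, 100, 98), c(200, 200, 200), "al6"))
  expect_equal(nrow(qc3$report), 0)
})

test_that("transmission rate is the seeds-weighted pooled estimate", {
  ears <- make_ears(c(30, 60, 45), c(100, 150, 100), "al1")
  res <- test_all_alleles(ears, phi_pooling = "per_allele")
  expect_equal(res$transmission_rate, (30 + 60 + 45) / 350)
  expect_equal(res$n_seeds, 350)
  # removing an ear whose rate equals the pooled rate leaves it unchanged
  pooled <- 135 / 350
  extra <- rbind(ears, make_ears(round(pooled * 1000), 1000, "al1")[1, ])
  extra$ear_id <- paste0("al1_e", 1:4)
  res2 <- test_all_alleles(extra, phi_pooling = "per_allele")
  expect_equal(res2$transmission_rate, res$transmission_rate,
               tolerance = 1e-3)
  # every ear exactly at 50%: rate 0.5, p = 1
  res3 <- test_all_alleles(make_ears(c(100, 100, 100), c(200, 200, 200)),
                           phi_pooling = "per_allele")
  expect_equal(res3$transmission_rate, 0.5)
  expect_equal(res3$p_value, 1)
})

test_that("per-class dispersion pooling shares phi within a class", {
  ears <- rbind(make_ears(c(95, 105, 100, 98), rep(200, 4), "al1"),
                make_ears(c(90, 110, 99, 103), rep(200, 4), "al2"),
                make_ears(c(60, 70, 64, 66), rep(130, 4), "al3",
                          class = "sperm_cell"))
  res <- test_all_alleles(ears, phi_pooling = "per_class")
  expect_equal(res$dispersion_phi[res$allele_id == "al1"],
               res$dispersion_phi[res$allele_id == "al2"])
  # pooled phi equals the sum of contributions over (ears - alleles)
  vc <- ears[ears$expression_class == "vegetative_cell", ]
  contrib <- sum(sapply(split(vc, vc$allele_id), function(d) {
    mu <- sum(d$n_marked) / sum(d$n_total)
    sum((d$n_marked - d$n_total * mu)^2 / (d$n_total * mu * (1 - mu)))
  }))
  expect_equal(res$dispersion_phi[res$allele_id == "al1"],
               contrib / (8 - 2), tolerance = 1e-12)
})

test_that("null-simulated alleles are rarely flagged; planted defects are found", {
  # null calibration at the study design (56 alleles, phi ~ 1.8)
  fr <- sapply(1:5, function(s) {
    ears <- gen_ear_counts(sim_config(seed = s))
    mean(test_all_alleles(qc_ears(ears)$ears)$significant)
  })
  expect_lte(mean(fr), 0.07)
  # a planted rate-0.30 allele is flagged
  hits <- sapply(1:10, function(s) {
    cfg <- sim_config(seed = 400 + s, true_rates = c(allele01 = 0.30))
    res <- test_all_alleles(qc_ears(gen_ear_counts(cfg))$ears)
    res$significant[res$allele_id == "allele01"]
  })
  expect_true(all(hits))
  # planted rates are recovered near their truth
  cfg <- sim_config(seed = 77, true_rates = c(allele01 = 0.30,
                                              allele02 = 0.23))
  res <- test_all_alleles(gen_ear_counts(cfg))
  expect_equal(res$transmission_rate[res$allele_id == "allele01"], 0.30,
               tolerance = 0.05)
  expect_equal(res$transmission_rate[res$allele_id == "allele02"], 0.23,
               tolerance = 0.05)
})

test_that("female-direction null data stay clean under the mirror analysis", {
  runs <- sapply(1:25, function(s) {
    ears <- gen_ear_counts(sim_config(seed = s), direction = "female")
    res <- test_all_alleles(ears, direction = "female",
                            bh_scope = "global")
    c(none = sum(res$significant) == 0, frac = mean(res$significant))
  })
  expect_lte(mean(runs["frac", ]), 0.02)
  expect_gte(mean(runs["none", ]), 0.8)
})

test_that("class defect comparisons rebuild the printed contingency tables", {
  # 12 high-expression genes with 6 defective, 20 low with 1 defective
  res <- data.frame(
    allele_id = sprintf("a%02d", 1:32), gene_id = sprintf("g%02d", 1:32),
    expression_class = "vegetative_cell",
    log2_fpkm = c(rep(9, 12), rep(5, 20)),
    direction = "male", n_ears = 4, n_seeds = 2800,
    transmission_rate = 0.45, dispersion_phi = 1.8,
    p_value = 0.5, p_adjusted = 0.5,
    significant = c(rep(TRUE, 6), rep(FALSE, 6),
                    TRUE, rep(FALSE, 19)))
  class(res) <- c("transmission_results", "data.frame")
  cmp <- class_defect_comparison(res, split_log2fpkm = 8)
  hl <- cmp$high_vs_low_expression
  expect_equal(unname(hl$table), matrix(c(6, 6, 1, 19), 2, byrow = TRUE))
  expect_equal(hl$test$p_value, 0.00572, tolerance = 1.5e-3)
  # identical defect proportions across classes give p = 1
  res2 <- res
  res2$expression_class <- rep(c("vegetative_cell", "sperm_cell"), 16)
  res2$significant <- rep(c(TRUE, FALSE), each = 16)[order(rep(1:16, 2))]
  res2$significant <- rep(c(TRUE, TRUE, FALSE, FALSE), 8)
  cmp2 <- class_defect_comparison(res2)
  pair <- grep("_vs_", names(cmp2), value = TRUE)[1]
  expect_equal(cmp2[[pair]]$test$p_value, 1, tolerance = 1e-9)
  # gene-level flag: a gene is defective if any allele is significant
  res3 <- res[1:2, ]
  res3$gene_id <- "shared"
  res3$significant <- c(TRUE, FALSE)
  res3$log2_fpkm <- c(9, 9)
  cmp3 <- class_defect_comparison(res3)
  expect_equal(unname(cmp3$high_vs_low_expression$table[1, ]), c(1, 0))
})

test_that("expression-fitness regressions return both responses", {
  res <- data.frame(
    allele_id = sprintf("a%02d", 1:20), gene_id = sprintf("g%02d", 1:20),
    expression_class = "vegetative_cell",
    log2_fpkm = seq(3, 12, length.out = 20),
    direction = "male", n_ears = 4, n_seeds = 2800,
    transmission_rate = 0.55 - 0.01 * seq(3, 12, length.out = 20),
    dispersion_phi = 1.8,
    p_value = 10^(-seq(0.1, 3, length.out = 20)),
    p_adjusted = NA, significant = FALSE)
  class(res) <- c("transmission_results", "data.frame")
  reg <- suppressWarnings(expression_fitness_regression(res))
  expect_equal(reg$rate_vs_log2fpkm$slope, -0.01, tolerance = 1e-10)
  expect_equal(reg$rate_vs_log2fpkm$r2_adjusted, 1, tolerance = 1e-9)
  expect_gt(reg$neglog10p_vs_log2fpkm$slope, 0)
  expect_error(expression_fitness_regression(res[1:2, ]), ">= 3")
})

test_that("ear table TSV round-trips", {
  ears <- gen_ear_counts(sim_config(seed = 12))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_ear_tsv(ears, tmp)
  back <- read_ear_tsv(tmp)
  expect_equal(back$n_marked, ears$n_marked)
  expect_equal(back$allele_id, ears$allele_id)
})
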