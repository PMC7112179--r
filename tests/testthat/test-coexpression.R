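small_coexpr_fixture <- function(seed = 1, n_genes = 50, n_tes = 30) {
  set.seed(seed)
  tm <- matrix(rexp(n_genes * 2, rate = 0.01), n_genes, 2,
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               c("pollen", "seedling")))
  te_ids <- sprintf("t%03d", seq_len(n_tes))
  prox <- lapply(rownames(tm), function(g) {
    k <- rpois(1, 1.2)
    if (k == 0) character(0) else sample(te_ids, min(k, n_tes))
  })
  names(prox) <- rownames(tm)
  de <- data.frame(feature_id = te_ids,
                   direction = sample(c("up", "down", "ns"), n_tes, TRUE))
  list(tm = tm, prox = prox, de = de)
}

test_that("bin profile counts equal a brute-force nested-loop recount", {
  fx <- small_coexpr_fixture()
  prof <- bin_and_count(fx$tm, "pollen", fx$de, fx$prox,
                        n_top = 50, bin_size = 10)
  expect_equal(nrow(prof), 5)
  expect_equal(prof$n_features, rep(10L, 5))
  up_set <- fx$de$feature_id[fx$de$direction == "up"]
  down_set <- fx$de$feature_id[fx$de$direction == "down"]
  ord <- order(-fx$tm[, "pollen"], rownames(fx$tm))
  ranked <- rownames(fx$tm)[ord]
  for (b in 1:5) {
    members <- ranked[((b - 1) * 10 + 1):(b * 10)]
    n_up <- sum(sapply(members, function(g) sum(fx$prox[[g]] %in% up_set)))
    n_gup <- sum(sapply(members, function(g) any(fx$prox[[g]] %in% up_set)))
    n_down <- sum(sapply(members, function(g)
      sum(fx$prox[[g]] %in% down_set)))
    expect_equal(prof$n_up_te[b], n_up)
    expect_equal(prof$n_genes_with_up_te[b], n_gup)
    expect_equal(prof$n_down_te[b], n_down)
    expect_equal(prof$median_expression[b],
                 median(fx$tm[members, "pollen"]))
  }
  # per-gene indicator never exceeds the bin size; totals bounded by n_top
  expect_true(all(prof$n_genes_with_up_te <= prof$n_features))
  expect_lte(sum(prof$n_genes_with_up_te), 50)
})

test_that("bin profile is invariant to input feature order", {
  fx <- small_coexpr_fixture(seed = 2)
  prof <- bin_and_count(fx$tm, "pollen", fx$de, fx$prox, 50, 10)
  shuf <- sample(nrow(fx$tm))
  prof2 <- bin_and_count(fx$tm[shuf, ], "pollen", fx$de, fx$prox[shuf],
                         50, 10)
  expect_equal(as.data.frame(prof), as.data.frame(prof2))
})

test_that("short final bin is kept and flagged; empty DE gives zero counts", {
  fx <- small_coexpr_fixture(seed = 3)
  prof <- bin_and_count(fx$tm, "pollen", fx$de, fx$prox, 45, 10)
  expect_equal(prof$n_features, c(10L, 10L, 10L, 10L, 5L))
  expect_true(isTRUE(attr(prof, "short_last_bin")))
  expect_warning(
    prof2 <- bin_and_count(fx$tm, "pollen", fx$de, fx$prox, 500, 10),
    "fewer than n_top")
  de0 <- transform(fx$de, direction = "ns")
  prof3 <- bin_and_count(fx$tm, "pollen", de0, fx$prox, 50, 10)
  expect_true(all(prof3$n_up_te == 0) && all(prof3$n_down_te == 0))
})

test_that("bin association reports signed tau against median expression", {
  prof <- structure(
    data.frame(bin_index = 1:3, n_features = 10,
               median_expression = c(100, 10, 1),
               n_up_te = c(5L, 3L, 1L), n_down_te = c(1L, 3L, 5L),
               n_genes_with_up_te = c(4L, 2L, 1L),
               n_genes_with_down_te = c(1L, 2L, 4L)),
    tissue = "pollen", class = c("bin_profile", "data.frame"))
  assoc <- bin_association(prof)
  expect_equal(assoc$tau[assoc$direction == "up" &
                         assoc$count_type == "n_tes"], 1)
  expect_equal(assoc$tau[assoc$direction == "down" &
                         assoc$count_type == "n_tes"], -1)
  # constant count series is flagged NA
  prof$n_up_te <- rep(2L, 3)
  assoc2 <- bin_association(prof)
  expect_true(is.na(assoc2$tau[assoc2$direction == "up" &
                               assoc2$count_type == "n_tes"]))
})

test_that("cross-tissue control filters on strictly greater expression", {
  fx <- small_coexpr_fixture(seed = 4)
  tm <- fx$tm
  tm[1:10, "seedling"] <- tm[1:10, "pollen"]       # ties -> excluded
  tm[11:20, "seedling"] <- tm[11:20, "pollen"] + 1 # lower in pollen
  keep_expected <- rownames(tm)[tm[, "pollen"] > tm[, "seedling"]]
  prof <- crosstissue_control(tm, "pollen", "seedling", fx$de, fx$prox,
                              n_top = length(keep_expected), bin_size = 5)
  expect_setequal(unlist(attr(prof, "members")), keep_expected)
  # all features higher in A than B -> identical to unfiltered profile
  tm2 <- fx$tm; tm2[, "seedling"] <- 0
  prof_f <- crosstissue_control(tm2, "pollen", "seedling", fx$de, fx$prox,
                                n_top = 50, bin_size = 10)
  prof_u <- bin_and_count(tm2, "pollen", fx$de, fx$prox, 50, 10)
  expect_equal(as.data.frame(prof_f), as.data.frame(prof_u))
  tm3 <- fx$tm; tm3[, "pollen"] <- 0
  expect_error(crosstissue_control(tm3, "pollen", "seedling", fx$de,
                                   fx$prox), "strictly higher")
})

test_that("planted coupling yields positive up-TE association; null is centered", {
  run_tau <- function(seed, kappa) {
    cfg <- sim_config(seed = seed, n_genes = 600, n_tes = 1800,
                      coupling_kappa = kappa, proximity_fraction = 0.5,
                      te_silent_fraction = 0.3,
                      tissue_design = data.frame(
                        tissue = c("seedling", "pollen"),
                        n_replicates = 3L),
                      te_activation = list(
                        pollen = c(fraction = 0.2, log2_effect = 2.5)))
    ann <- gen_annotation(cfg)
    gc <- gen_counts(cfg, ann)
    prox <- classify_proximity(ann)
    de <- nb_differential(gc$counts, "seedling", "pollen")
    lens <- setNames(ann$transcripts$transcript_length_bp,
                     ann$transcripts$gene_id)
    em <- fpkm_matrix(count_matrix(
      gc$counts$values[ann$genes$gene_id, ], gc$counts$samples), lens)
    prof <- bin_and_count(em, "pollen", de, prox$gene_te_map,
                          n_top = 600, bin_size = 10)
    a <- bin_association(prof)
    unlist(a[a$direction == "up" & a$count_type == "n_tes",
             c("tau", "p_value")])
  }
  planted <- t(sapply(1:10, run_tau, kappa = 2))
  expect_gte(mean(planted[, "tau"] > 0 & planted[, "p_value"] < 0.05), 0.9)
  null <- sapply(1:10, function(s) run_tau(50 + s, 0)["tau"])
  expect_lt(mean(abs(null), na.rm = TRUE), 0.15)
})
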