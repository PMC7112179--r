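# TE expression quantification and classification.
#
# The differential-expression step here is a deliberately simple,
# documented negative-binomial Wald test (median-of-ratios size factors +
# method-of-moments dispersion). It is a stand-in for a full shrinkage
# estimator such as DESeq2, not a reimplementation of one; its null
# behaviour and power are characterized by the simulation tests that ship
# with the package.

#' Fractionally weighted read counting over features
#'
#' Multi-mapped reads are counted fractionally: a read with `k` equally
#' best-scoring candidate loci contributes weight `1/k` at each locus (a
#' read mapping to 4 TE locations equally well gives each TE 0.25 of a
#' read). Each locus passes its weight to the feature with the largest
#' overlap; when two features tie for the largest overlap the weight is
#' split equally between them. Loci overlapping no feature contribute
#' nothing, so the total assigned count never exceeds the number of reads.
#'
#' @param placements data.frame with columns `read_id`, `chrom`, `start`,
#'   `end`; one row per candidate locus.
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive; zero-length features are an error).
#'
#' @return Named numeric vector of weighted counts, one entry per feature
#'   (zeros included).
#' @export
fractional_counts <- function(placements, features) {
  stopifnot(all(c("read_id", "chrom", "start", "end") %in% names(placements)),
            all(c("feature_id", "chrom", "start", "end") %in% names(features)))
  if (any(features$end < features$start))
    stop("zero- or negative-length feature interval")
  counts <- stats::setNames(numeric(nrow(features)), features$feature_id)
  if (nrow(placements) == 0) return(counts)

  multiplicity <- table(placements$read_id)
  loc_weight <- 1 / as.numeric(multiplicity[placements$read_id])

  loc_gr <- GenomicRanges::GRanges(
    placements$chrom, IRanges::IRanges(placements$start, placements$end))
  feat_gr <- as_granges(features, "feature_id")
  hits <- GenomicRanges::findOverlaps(loc_gr, feat_gr)
  if (length(hits) == 0) return(counts)

  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(loc_gr[q], feat_gr[s]))

  # keep, per locus, only the feature(s) with the largest overlap;
  # split the locus weight equally among ties
  best <- tapply(ov, q, max)[as.character(q)]
  keep <- ov == best
  q <- q[keep]; s <- s[keep]
  ties <- table(q)
  w <- loc_weight[q] / as.numeric(ties[as.character(q)])
  agg <- tapply(w, s, sum)
  counts[as.integer(names(agg))] <- counts[as.integer(names(agg))] + agg
  counts
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across features of the
#' ratio of each sample's count to the per-feature geometric mean, computed
#' over features with nonzero counts in every sample, then rescaled so the
#' factors have geometric mean 1. If no feature is expressed in all
#' samples, falls back to library-size ratios with a warning.
#'
#' @param values non-negative numeric matrix (features x samples) or a
#'   [count_matrix].
#' @return Positive numeric vector of per-sample factors (geometric mean 1).
#' @export
size_factors <- function(values) {
  if (inherits(values, "count_matrix")) values <- values$values
  values <- as.matrix(values)
  ok <- rowSums(values > 0) == ncol(values)
  if (!any(ok)) {
    warning("no feature expressed in all samples; using library-size ratios")
    sf <- colSums(values)
  } else {
    v <- values[ok, , drop = FALSE]
    geo <- exp(rowMeans(log(v)))
    sf <- apply(v / geo, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Negative-binomial Wald differential expression (two tissues)
#'
#' Tests each feature for differential abundance between a target tissue
#' and the reference tissue. Counts are rounded to integers at entry,
#' normalized by [size_factors()] computed on the two tissues' samples, and
#' a per-feature NB dispersion is estimated by the method of moments within
#' each group (so the estimate is not biased by a true expression
#' difference), pooled by degrees of freedom, and moderated toward the
#' across-feature median with `dispersion_prior_df` pseudo-degrees of
#' freedom — a moderation in the spirit of empirical-Bayes variance
#' shrinkage, which stabilizes the very noisy 3-4 replicate estimates. The
#' Wald statistic on the log fold change is referred to a t distribution
#' whose degrees of freedom are the residual plus prior degrees of freedom.
#'
#' Features whose mean normalized count falls below `filter_min_mean` are
#' not tested and carry `NA` p-values (independent filtering); features
#' with a group at zero get a pseudo-fraction added in the reported log2
#' fold change only. BH adjustment is applied over tested features.
#'
#' @param cm a [count_matrix] containing both tissues.
#' @param reference_tissue,target_tissue tissue labels in `cm$samples$tissue`.
#' @param alpha adjusted-p threshold for the up/down direction call.
#' @param filter_min_mean independent-filtering threshold on the mean
#'   normalized count (default 1).
#' @param dispersion_prior_df pseudo-degrees of freedom of the moderation
#'   toward the median dispersion (default 4).
#' @param drop_samples optional sample ids to exclude (e.g. an aberrant
#'   replicate).
#'
#' @return data.frame with columns `feature_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `direction`
#'   (`"up"`/`"down"`/`"ns"`/`NA`).
#' @export
nb_differential <- function(cm, reference_tissue, target_tissue,
                            alpha = 0.05, filter_min_mean = 1,
                            dispersion_prior_df = 4,
                            drop_samples = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- cm$samples$tissue %in% c(reference_tissue, target_tissue)
  if (!is.null(drop_samples))
    keep <- keep & !(cm$samples$sample_id %in% drop_samples)
  samples <- cm$samples[keep, , drop = FALSE]
  grp <- samples$tissue == target_tissue
  if (sum(grp) < 2 || sum(!grp) < 2)
    stop("need >= 2 replicates in both tissues")
  counts <- round(cm$values[, keep, drop = FALSE])

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, !grp, drop = FALSE]   # reference
  b <- norm[, grp, drop = FALSE]    # target
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  base_mean <- rowMeans(norm)

  # per-group method-of-moments NB dispersion, pooled by df, then
  # moderated toward the across-feature median
  var_a <- apply(a, 1, stats::var); var_b <- apply(b, 1, stats::var)
  s_inv_a <- mean(1 / sf[!grp]); s_inv_b <- mean(1 / sf[grp])
  disp_a <- (var_a - mu_a * s_inv_a) / pmax(mu_a, 0.5)^2
  disp_b <- (var_b - mu_b * s_inv_b) / pmax(mu_b, 0.5)^2
  disp <- pmax(((na - 1) * disp_a + (nb - 1) * disp_b) / (na + nb - 2), 0)
  resid_df <- na + nb - 2
  tested0 <- base_mean >= filter_min_mean
  disp_prior <- stats::median(disp[tested0], na.rm = TRUE)
  if (!is.finite(disp_prior)) disp_prior <- 0
  disp <- pmax((dispersion_prior_df * disp_prior + resid_df * disp) /
                 (dispersion_prior_df + resid_df), 1e-8)

  pseudo <- 0.5
  l2fc <- log2((mu_b + pseudo) / (mu_a + pseudo))

  mu_a_s <- pmax(mu_a, pseudo); mu_b_s <- pmax(mu_b, pseudo)
  # delta-method variance of log(mean normalized count) per group
  v_log_a <- (mu_a_s * s_inv_a + disp * mu_a_s^2) / (na * mu_a_s^2)
  v_log_b <- (mu_b_s * s_inv_b + disp * mu_b_s^2) / (nb * mu_b_s^2)
  z <- (log(mu_b_s) - log(mu_a_s)) / sqrt(v_log_a + v_log_b)
  p <- 2 * stats::pt(-abs(z), df = resid_df + dispersion_prior_df)

  tested <- base_mean >= filter_min_mean
  p[!tested] <- NA_real_
  padj <- benjamini_hochberg(p)

  direction <- rep("ns", length(p))
  direction[!is.na(padj) & padj < alpha & l2fc > 0] <- "up"
  direction[!is.na(padj) & padj < alpha & l2fc < 0] <- "down"
  direction[is.na(p)] <- NA_character_

  data.frame(feature_id = rownames(counts), base_mean = base_mean,
             log2_fold_change = l2fc, p_value = p, p_adjusted = padj,
             direction = direction, row.names = NULL)
}

#' Four-way TE category assignment
#'
#' Partitions every annotated TE into exactly one of four categories, in
#' order of precedence:
#' 1. `near_genes` -- within the proximity threshold of a gene;
#' 2. `not_covered` -- distal, but with a summed raw count below
#'    `min_total` across all samples, or an `NA` adjusted p-value in every
#'    tissue comparison (no power to call differential expression);
#' 3. `dynamic` -- adjusted p below `alpha` in at least one tissue versus
#'    the reference;
#' 4. `static` -- covered but never differentially expressed.
#'
#' TEs present in the annotation but absent from the count matrix are
#' treated as zero counts (hence `not_covered`).
#'
#' @param annotation a [genome_annotation].
#' @param cm [count_matrix] of TE counts across all samples.
#' @param de_by_tissue named list of [nb_differential()] results, one per
#'   non-reference tissue, computed on the distal TE set.
#' @param min_total minimum summed raw count, default 10.
#' @param alpha significance threshold on adjusted p, default 0.05.
#' @param proximity optional precomputed [classify_proximity()] result.
#'
#' @return data.frame with columns `te_id`, `category`.
#' @export
categorize_tes <- function(annotation, cm, de_by_tissue, min_total = 10,
                           alpha = 0.05, proximity = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(proximity)) proximity <- classify_proximity(annotation)
  te_ids <- annotation$tes$te_id

  totals <- stats::setNames(numeric(length(te_ids)), te_ids)
  in_cm <- intersect(te_ids, rownames(cm$values))
  totals[in_cm] <- rowSums(round(cm$values[in_cm, , drop = FALSE]))

  padj_min <- stats::setNames(rep(NA_real_, length(te_ids)), te_ids)
  any_tested <- stats::setNames(rep(FALSE, length(te_ids)), te_ids)
  for (de in de_by_tissue) {
    idx <- match(de$feature_id, te_ids)
    ok <- !is.na(idx) & !is.na(de$p_adjusted)
    any_tested[idx[ok]] <- TRUE
    padj_min[idx[ok]] <- pmin(padj_min[idx[ok]], de$p_adjusted[ok],
                              na.rm = TRUE)
  }

  category <- rep("static", length(te_ids))
  category[!any_tested | totals < min_total] <- "not_covered"
  category[any_tested & totals >= min_total &
           !is.na(padj_min) & padj_min < alpha] <- "dynamic"
  category[proximity$te_category[te_ids] == "near_gene"] <- "near_genes"
  data.frame(te_id = te_ids, category = category, row.names = NULL)
}

#' Observed/expected TE family enrichment
#'
#' For each family, the log2 ratio of its proportion within a TE category
#' to its proportion in a background set. The ratio is `NA` ("no data")
#' when the family is absent from either set.
#'
#' @param category_members data.frame of TEs in the category (needs a
#'   `family` column), or a character vector of family labels.
#' @param background same, for the background set (non-empty).
#'
#' @return data.frame with `family`, `observed_fraction`,
#'   `expected_fraction`, `log2_ratio`.
#' @export
family_enrichment <- function(category_members, background) {
  fam_of <- function(x) if (is.data.frame(x)) as.character(x$family)
                        else as.character(x)
  obs <- fam_of(category_members); bg <- fam_of(background)
  if (length(bg) == 0) stop("background must be non-empty")
  fams <- sort(unique(c(obs, bg)))
  n_obs <- as.numeric(table(factor(obs, levels = fams)))
  n_bg <- as.numeric(table(factor(bg, levels = fams)))
  of <- if (length(obs)) n_obs / length(obs) else rep(0, length(fams))
  ef <- n_bg / length(bg)
  lr <- ifelse(n_obs > 0 & n_bg > 0, log2(of / ef), NA_real_)
  data.frame(family = fams, observed_fraction = of, expected_fraction = ef,
             log2_ratio = lr, row.names = NULL)
}

#' Persistence and overlap analysis of stage-wise TE sets
#'
#' Given per-stage sets of up-regulated and expressed TE ids over a common
#' universe, computes (i) persistence fractions: the fraction of TEs
#' up-regulated at stage A that are still expressed at stage B; (ii)
#' pairwise overlap significance between expressed sets by the
#' hypergeometric upper tail on the universe; (iii) exclusive sets:
#' elements expressed at a stage but at no other stage.
#'
#' @param up_sets named list stage -> character vector of up-regulated ids.
#' @param expressed_sets named list stage -> character vector of expressed
#'   ids.
#' @param universe character vector containing every id in the sets.
#'
#' @return A list with `persistence` (data.frame `from`, `to`, `n_up`,
#'   `n_persisting`, `fraction`), `overlap_tests` (data.frame with
#'   hypergeometric p per pair of expressed sets), `exclusive` (named list).
#' @export
stage_set_analysis <- function(up_sets, expressed_sets, universe) {
  all_ids <- unique(unlist(c(up_sets, expressed_sets)))
  if (!all(all_ids %in% universe))
    stop("all sets must be subsets of the universe")
  stages_up <- names(up_sets); stages_ex <- names(expressed_sets)
  pers <- do.call(rbind, lapply(stages_up, function(a) {
    do.call(rbind, lapply(setdiff(stages_ex, a), function(b) {
      n_up <- length(up_sets[[a]])
      n_per <- length(intersect(up_sets[[a]], expressed_sets[[b]]))
      data.frame(from = a, to = b, n_up = n_up, n_persisting = n_per,
                 fraction = if (n_up > 0) n_per / n_up else NA_real_)
    }))
  }))
  pairs <- utils::combn(stages_ex, 2, simplify = FALSE)
  ov <- do.call(rbind, lapply(pairs, function(pr) {
    a <- expressed_sets[[pr[1]]]; b <- expressed_sets[[pr[2]]]
    k <- length(intersect(a, b))
    p <- overlap_hyper_p(k, length(a), length(b), length(universe))
    data.frame(set_a = pr[1], set_b = pr[2], n_a = length(a),
               n_b = length(b), n_overlap = k, p_value = p)
  }))
  excl <- lapply(stages_ex, function(a) {
    others <- unlist(expressed_sets[setdiff(stages_ex, a)])
    setdiff(expressed_sets[[a]], others)
  })
  names(excl) <- stages_ex
  list(persistence = pers, overlap_tests = ov, exclusive = excl)
}

#' Hypergeometric upper-tail overlap p-value
#'
#' Probability of observing at least `k` common elements between a set of
#' size `n_a` and a set of size `n_b` drawn independently from a universe
#' of size `n_universe`.
#'
#' @param k observed overlap; `n_a`, `n_b` set sizes; `n_universe` universe
#'   size.
#' @return p-value.
#' @export
overlap_hyper_p <- function(k, n_a, n_b, n_universe) {
  stopifnot(n_a <= n_universe, n_b <= n_universe, k <= min(n_a, n_b))
  stats::phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}
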