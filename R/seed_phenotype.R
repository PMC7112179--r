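# Post-fertilization phenotype statistics: small/aborted seed censuses,
# seedless-area comparisons, the fertilization-outcome contingency test at
# 4 days after pollination, and the small-seed genotype test.

#' Pairwise seed-census comparisons against control groups
#'
#' Compares per-ear small-seed fractions `n_small / (n_small + n_normal)`
#' (or `seedless_area_pct`) of each treatment group against each control
#' group with a Welch two-sample t-test. Every compared group must have at
#' least 2 ears.
#'
#' @param censuses data.frame with `ear_id`, `genotype_group`, `n_small`,
#'   `n_normal`, and optionally `seedless_area_pct`.
#' @param treatment_groups,control_groups character vectors of
#'   `genotype_group` labels.
#' @param measure `"small_fraction"` (default) or `"seedless_area"`.
#'
#' @return data.frame with one row per treatment x control pair:
#'   `treatment`, `control`, `mean_treatment`, `mean_control`, `statistic`,
#'   `p_value`.
#' @export
census_tests <- function(censuses, treatment_groups, control_groups,
                         measure = c("small_fraction", "seedless_area")) {
  measure <- match.arg(measure)
  stopifnot(all(c("genotype_group", "n_small", "n_normal") %in%
                names(censuses)))
  value_of <- function(d) {
    if (measure == "small_fraction") {
      if (any(d$n_small + d$n_normal <= 0)) stop("empty ear census")
      d$n_small / (d$n_small + d$n_normal)
    } else {
      if (is.null(d$seedless_area_pct) || anyNA(d$seedless_area_pct))
        stop("seedless_area_pct missing for group ", d$genotype_group[1L])
      d$seedless_area_pct
    }
  }
  groups <- split(censuses, censuses$genotype_group)
  for (g in c(treatment_groups, control_groups)) {
    if (is.null(groups[[g]])) stop("unknown group: ", g)
    if (nrow(groups[[g]]) < 2)
      stop("group '", g, "' has fewer than 2 ears")
  }
  out <- expand.grid(treatment = treatment_groups,
                     control = control_groups,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    x <- value_of(groups[[out$treatment[i]]])
    y <- value_of(groups[[out$control[i]]])
    tt <- auxiliary_test("welch_t", x = x, y = y)
    data.frame(mean_treatment = mean(x), mean_control = mean(y),
               statistic = tt$statistic, p_value = tt$p_value)
  })
  cbind(out, do.call(rbind, res))
}

#' Fertilization-outcome contingency test
#'
#' Classifies ovules assessed a few days after pollination as *normal*
#' (exactly one synergid penetrated by a pollen tube, and both embryo and
#' endosperm developing) or *abnormal* (single fertilization of either
#' product, or both synergids penetrated), then tests the two pollen-parent
#' groups with a two-sided Fisher exact test.
#'
#' @param table data.frame with a `group` column and the six outcome
#'   columns `one_syn_both`, `one_syn_endosperm_only`,
#'   `one_syn_embryo_only`, `both_syn_both`, `both_syn_endosperm_only`,
#'   `both_syn_embryo_only`.
#' @param group_a,group_b labels present in `table$group`.
#'
#' @return A list with `classification` (data.frame `group`, `n_normal`,
#'   `n_abnormal`, `n_ovules`) and `test` (a [test_result]).
#' @export
fertilization_outcome_test <- function(table, group_a, group_b) {
  cols <- c("one_syn_both", "one_syn_endosperm_only", "one_syn_embryo_only",
            "both_syn_both", "both_syn_endosperm_only",
            "both_syn_embryo_only")
  stopifnot(all(c("group", cols) %in% names(table)))
  rows <- lapply(c(group_a, group_b), function(g) {
    d <- table[table$group == g, , drop = FALSE]
    if (nrow(d) != 1) stop("group not found (or duplicated): ", g)
    counts <- as.numeric(d[1, cols])
    if (sum(counts) == 0) stop("zero ovules assessed in group ", g)
    data.frame(group = g, n_normal = counts[1],
               n_abnormal = sum(counts[-1]), n_ovules = sum(counts))
  })
  cls <- do.call(rbind, rows)
  tab <- matrix(c(cls$n_normal[1], cls$n_abnormal[1],
                  cls$n_normal[2], cls$n_abnormal[2]), 2, byrow = TRUE,
                dimnames = list(cls$group, c("normal", "abnormal")))
  list(classification = cls,
       test = fisher_exact_2x2(tab, alternative = "two.sided"))
}

#' Exact binomial test of small-seed genotype enrichment
#'
#' Tests whether the fraction of genotyped small seeds carrying the mutant
#' allele deviates from the Mendelian sampling expectation of 0.5, using an
#' exact two-sided binomial test.
#'
#' @param n_mutant number of small seeds genotyped as mutant.
#' @param n_typed number of small seeds genotyped, `> 0`.
#' @return A [test_result]; its `estimate` is the mutant fraction.
#' @examples
#' small_seed_genotype_test(19, 24)
#' @export
small_seed_genotype_test <- function(n_mutant, n_typed) {
  if (n_typed <= 0) stop("n_typed must be positive")
  stopifnot(n_mutant >= 0, n_mutant <= n_typed)
  auxiliary_test("exact_binomial", k = n_mutant, n = n_typed, p0 = 0.5)
}
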