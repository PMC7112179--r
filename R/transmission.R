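# Marker-transmission fitness analysis. Input is a per-ear table of
# marked/total seed counts for heterozygous insertion alleles outcrossed
# through the male or female; the workflow is QC -> per-allele
# quasi-binomial test against Mendelian 0.5 -> BH correction within an
# expression class -> class-level Fisher comparisons and
# expression-fitness regressions.

EAR_COLUMNS <- c("allele_id", "plant_id", "ear_id", "direction", "marker",
                 "n_marked", "n_total")

validate_ears <- function(ears) {
  miss <- setdiff(EAR_COLUMNS, names(ears))
  if (length(miss))
    stop("ear table is missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(ears$n_total > 0), all(ears$n_marked >= 0),
            all(ears$n_marked <= ears$n_total))
  invisible(ears)
}

#' Quality control of per-ear seed counts
#'
#' Two exclusion rules, applied in order:
#' 1. *Double insertion*: an ear whose marked fraction exceeds
#'    `double_insertion_rate` (default 0.70, operationalizing the ~75%
#'    transmission expected from two unlinked insertions) *and* whose
#'    exact-binomial p-value against 0.5 (one-sided, greater) is below
#'    `binom_alpha` is excluded. Both conditions are required so that a
#'    small ear with a noisy high fraction is not discarded.
#' 2. *Replication*: an allele is dropped entirely unless, after rule 1,
#'    it retains at least `min_male_ears` male-direction ears from at least
#'    `min_plants` distinct plants.
#'
#' @param ears data.frame with columns `allele_id`, `plant_id`, `ear_id`,
#'   `direction` (`"male"`/`"female"`), `marker`, `n_marked`, `n_total`
#'   (plus any metadata columns, carried through).
#' @param min_male_ears minimum male ears per allele, default 3.
#' @param min_plants minimum distinct plants per allele, default 2.
#' @param double_insertion_rate marked-fraction threshold, default 0.70.
#' @param binom_alpha one-sided binomial threshold for rule 1, default 0.01.
#'
#' @return A list with `ears` (the retained rows) and `report` (data.frame
#'   `allele_id`, `ear_id`, `reason` for every exclusion).
#' @export
qc_ears <- function(ears, min_male_ears = 3L, min_plants = 2L,
                    double_insertion_rate = 0.70, binom_alpha = 0.01) {
  validate_ears(ears)
  report <- ears[0, c("allele_id", "ear_id")]
  report$reason <- character(0)

  frac <- ears$n_marked / ears$n_total
  suspect <- frac > double_insertion_rate
  if (any(suspect)) {
    pgt <- vapply(which(suspect), function(i)
      stats::binom.test(ears$n_marked[i], ears$n_total[i], 0.5,
                        alternative = "greater")$p.value, 0)
    double <- which(suspect)[pgt < binom_alpha]
    if (length(double)) {
      report <- rbind(report, data.frame(
        allele_id = ears$allele_id[double], ear_id = ears$ear_id[double],
        reason = "double_insertion"))
      ears <- ears[-double, , drop = FALSE]
    }
  }

  male <- ears[ears$direction == "male", , drop = FALSE]
  by_allele <- split(male, male$allele_id)
  bad <- names(by_allele)[vapply(by_allele, function(d)
    nrow(d) < min_male_ears ||
      length(unique(d$plant_id)) < min_plants, TRUE)]
  # alleles with no male ears at all also fail the replication rule
  bad <- union(bad, setdiff(unique(ears$allele_id), male$allele_id))
  if (length(bad)) {
    drop_rows <- ears$allele_id %in% bad
    report <- rbind(report, data.frame(
      allele_id = ears$allele_id[drop_rows],
      ear_id = ears$ear_id[drop_rows],
      reason = "insufficient_replication"))
    ears <- ears[!drop_rows, , drop = FALSE]
  }
  list(ears = ears, report = report)
}

#' Per-allele transmission tests with pooled overdispersion
#'
#' For each allele, pools seeds over its QC-passing ears in the given cross
#' direction (transmission rate = total marked / total seeds) and tests the
#' rate against Mendelian 0.5 with [quasibinomial_test()]. The Pearson
#' dispersion is pooled over a scope: with `phi_pooling = "per_class"`
#' (default) the squared Pearson residuals of all ears in an expression
#' class are summed and divided by (ears in scope - alleles in scope),
#' giving every allele of the class the same, better-estimated dispersion;
#' `"per_allele"` estimates dispersion from each allele's own ears. BH
#' correction is applied within expression class x direction by default
#' (`bh_scope = "per_class"`), or over all alleles of the direction at once
#' (`bh_scope = "global"`).
#'
#' @param ears QC-passed ear table (see [qc_ears()]); optional metadata
#'   columns `gene_id`, `expression_class`, `log2_fpkm` are carried into
#'   the result.
#' @param direction `"male"` (default) or `"female"`.
#' @param phi_pooling `"per_class"` or `"per_allele"`.
#' @param bh_scope `"per_class"` (default) or `"global"` multiple-testing
#'   family.
#' @param alpha adjusted-p significance threshold, default 0.05.
#' @param null_rate Mendelian expectation, default 0.5.
#'
#' @return data.frame of class `"transmission_results"` with one row per
#'   allele: `allele_id`, `gene_id`, `expression_class`, `log2_fpkm`,
#'   `direction`, `n_ears`, `n_seeds`, `transmission_rate`,
#'   `dispersion_phi`, `p_value`, `p_adjusted`, `significant`.
#' @export
test_all_alleles <- function(ears, direction = "male",
                             phi_pooling = c("per_class", "per_allele"),
                             bh_scope = c("per_class", "global"),
                             alpha = 0.05, null_rate = 0.5) {
  phi_pooling <- match.arg(phi_pooling)
  bh_scope <- match.arg(bh_scope)
  validate_ears(ears)
  ears <- ears[ears$direction == direction, , drop = FALSE]
  if (nrow(ears) == 0) stop("no ears in direction ", direction)
  if (is.null(ears$expression_class)) ears$expression_class <- "all"
  if (is.null(ears$gene_id)) ears$gene_id <- ears$allele_id
  if (is.null(ears$log2_fpkm)) ears$log2_fpkm <- NA_real_

  pearson_contrib <- function(d) {
    mu <- sum(d$n_marked) / sum(d$n_total)
    mu <- min(max(mu, 1e-8), 1 - 1e-8)
    sum((d$n_marked - d$n_total * mu)^2 / (d$n_total * mu * (1 - mu)))
  }

  scope_of <- if (phi_pooling == "per_class") ears$expression_class
              else ears$allele_id
  out <- do.call(rbind, lapply(split(ears, scope_of), function(sc) {
    by_allele <- split(sc, sc$allele_id)
    df_phi <- nrow(sc) - length(by_allele)
    if (df_phi < 1)
      stop("zero residual degrees of freedom in a pooling scope; ",
           "more ears per allele are required")
    phi <- sum(vapply(by_allele, pearson_contrib, 0)) / df_phi
    phi <- max(phi, 1e-8)
    res <- do.call(rbind, lapply(by_allele, function(d) {
      qb <- quasibinomial_test(d$n_marked, d$n_total, null_rate = null_rate,
                               phi_override = phi, phi_df = df_phi)
      data.frame(allele_id = d$allele_id[1L], gene_id = d$gene_id[1L],
                 expression_class = d$expression_class[1L],
                 log2_fpkm = d$log2_fpkm[1L], direction = direction,
                 n_ears = nrow(d), n_seeds = sum(d$n_total),
                 transmission_rate = qb$fit$fitted_rate,
                 dispersion_phi = phi, p_value = qb$test$p_value,
                 row.names = NULL)
    }))
    res
  }))
  rownames(out) <- NULL
  out$p_adjusted <- if (bh_scope == "global") {
    benjamini_hochberg(out$p_value)
  } else {
    stats::ave(out$p_value, out$expression_class,
               FUN = benjamini_hochberg)
  }
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("transmission_results", "data.frame")
  out
}

#' @export
print.transmission_results <- function(x, ...) {
  cat("transmission_results:", nrow(x), "alleles,",
      sum(x$significant), "significant at BH", "\n")
  print.data.frame(utils::head(as.data.frame(
    x[order(x$p_adjusted), c("allele_id", "expression_class",
                             "transmission_rate", "p_value",
                             "p_adjusted")]), 10))
  invisible(x)
}

#' Fisher comparisons of transmission-defect proportions
#'
#' A gene is *defective* if any of its alleles is BH-significant. Builds
#' 2x2 defective/non-defective tables for every pair of expression classes
#' and, within the vegetative cell class, for genes above versus below a
#' log2(FPKM) threshold (default 8, the very-high expression split), and
#' tests each with [fisher_exact_2x2()].
#'
#' @param results a [test_all_alleles()] result carrying `gene_id`,
#'   `expression_class` and `log2_fpkm`.
#' @param split_log2fpkm expression split within `split_class`, default 8.
#' @param split_class class for the high/low split, default
#'   `"vegetative_cell"`.
#' @param alternative passed to [fisher_exact_2x2()].
#'
#' @return A list of comparisons, each with `comparison`, `table` (2x2)
#'   and `test` (a [test_result]).
#' @export
class_defect_comparison <- function(results, split_log2fpkm = 8,
                                    split_class = "vegetative_cell",
                                    alternative = "two.sided") {
  genes <- do.call(rbind, lapply(split(results, results$gene_id),
    function(d) data.frame(
      gene_id = d$gene_id[1L], expression_class = d$expression_class[1L],
      log2_fpkm = suppressWarnings(max(d$log2_fpkm)),
      defective = any(d$significant))))
  out <- list()
  classes <- unique(genes$expression_class)
  if (length(classes) >= 2) {
    for (pr in utils::combn(classes, 2, simplify = FALSE)) {
      a <- genes[genes$expression_class == pr[1], ]
      b <- genes[genes$expression_class == pr[2], ]
      if (nrow(a) == 0 || nrow(b) == 0) {
        warning("empty class in comparison ", paste(pr, collapse = " vs "))
        next
      }
      tab <- matrix(c(sum(a$defective), sum(!a$defective),
                      sum(b$defective), sum(!b$defective)), 2, byrow = TRUE,
                    dimnames = list(pr, c("defective", "mendelian")))
      out[[paste(pr, collapse = "_vs_")]] <- list(
        comparison = paste(pr, collapse = " vs "), table = tab,
        test = fisher_exact_2x2(tab, alternative = alternative))
    }
  }
  vc <- genes[genes$expression_class == split_class &
              is.finite(genes$log2_fpkm), ]
  if (nrow(vc)) {
    hi <- vc$log2_fpkm > split_log2fpkm
    tab <- matrix(c(sum(vc$defective[hi]), sum(!vc$defective[hi]),
                    sum(vc$defective[!hi]), sum(!vc$defective[!hi])),
                  2, byrow = TRUE,
                  dimnames = list(c("high", "low"),
                                  c("defective", "mendelian")))
    out[["high_vs_low_expression"]] <- list(
      comparison = sprintf("%s: log2(FPKM) > %g vs <= %g", split_class,
                           split_log2fpkm, split_log2fpkm),
      table = tab, test = fisher_exact_2x2(tab, alternative = alternative))
  }
  out
}

#' Expression-fitness regressions within a class
#'
#' Two ordinary least-squares regressions over the alleles of one
#' expression class: (1) transmission rate on log2(FPKM); (2)
#' -log10(raw p-value) on log2(FPKM). A negative slope in (1) and a
#' positive slope in (2) indicate that higher expression predicts a larger
#' fitness cost when the gene is mutated.
#'
#' @param results a [test_all_alleles()] result.
#' @param class expression class to regress within, default
#'   `"vegetative_cell"`.
#' @return A list with `rate_vs_log2fpkm` and `neglog10p_vs_log2fpkm`
#'   (each a [linear_regression] result).
#' @export
expression_fitness_regression <- function(results,
                                          class = "vegetative_cell") {
  d <- results[results$expression_class == class &
               is.finite(results$log2_fpkm), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 alleles with log2_fpkm in class ", class)
  list(
    rate_vs_log2fpkm =
      linear_regression(d$log2_fpkm, d$transmission_rate),
    neglog10p_vs_log2fpkm =
      linear_regression(d$log2_fpkm, -log10(pmax(d$p_value, 1e-300))))
}

#' Read / write the per-ear seed count table
#'
#' TSV with columns `allele_id`, `gene_id`, `expression_class`,
#' `log2_fpkm`, `plant_id`, `ear_id`, `direction`, `marker`, `n_marked`,
#' `n_total` (metadata columns optional on read).
#'
#' @param path file path.
#' @return data.frame of ear observations.
#' @export
read_ear_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  validate_ears(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_ear_tsv
#' @param ears ear table to write.
#' @export
write_ear_tsv <- function(ears, path) {
  utils::write.table(ears, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
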