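# Binned gene-TE neighborhood coexpression statistic: rank genes by
# expression in a tissue, bin them (default: top 20,000 in bins of 200),
# and count differentially expressed TEs within 2 kb of each bin's genes.

#' Bin top-expressed features and count nearby differentially expressed TEs
#'
#' Features are ranked in descending order of tissue-mean expression (ties
#' broken by feature id), the top `n_top` are split into consecutive bins
#' of `bin_size` (bin 1 = most highly expressed; a short final bin is
#' kept and flagged). For each bin, the number of up- and down-regulated
#' TEs within the proximity threshold of the bin's features is summed — a
#' TE near `k` binned features contributes `k` times — and the number of
#' features with at least one up-/down-regulated TE is counted once per
#' feature.
#'
#' @param expr an [expression_matrix] or tissue-mean matrix.
#' @param tissue tissue whose expression defines the ranking.
#' @param de_results [nb_differential()] result for the TEs of that tissue
#'   (needs `feature_id`, `direction`).
#' @param proximity_map named list feature_id -> character vector of nearby
#'   te_ids (from [classify_proximity()]).
#' @param n_top number of top features to bin, default 20000.
#' @param bin_size features per bin, default 200.
#' @param feature_subset optional character vector restricting the ranked
#'   universe (used by the cross-tissue contamination control).
#'
#' @return An object of class `"bin_profile"`: a data.frame with
#'   `bin_index`, `n_features`, `median_expression`, `n_up_te`,
#'   `n_down_te`, `n_genes_with_up_te`, `n_genes_with_down_te`, plus
#'   attributes `tissue` and `members` (list of per-bin feature ids).
#' @export
bin_and_count <- function(expr, tissue, de_results, proximity_map,
                          n_top = 20000L, bin_size = 200L,
                          feature_subset = NULL) {
  tm <- if (inherits(expr, "expression_matrix")) tissue_means(expr)
        else as.matrix(expr)
  stopifnot(tissue %in% colnames(tm), bin_size >= 1)
  v <- tm[, tissue]
  ids <- rownames(tm)
  if (!is.null(feature_subset)) {
    keep <- ids %in% feature_subset
    v <- v[keep]; ids <- ids[keep]
  }
  if (length(ids) < n_top) {
    warning("fewer than n_top features available (", length(ids),
            "); using all")
    n_top <- length(ids)
  }
  ord <- order(-v, ids)
  ids <- ids[ord][seq_len(n_top)]
  v <- v[ord][seq_len(n_top)]
  bin <- ceiling(seq_len(n_top) / bin_size)

  up_set <- de_results$feature_id[!is.na(de_results$direction) &
                                  de_results$direction == "up"]
  down_set <- de_results$feature_id[!is.na(de_results$direction) &
                                    de_results$direction == "down"]
  near <- proximity_map[ids]
  near[vapply(near, is.null, TRUE)] <- list(character(0))
  n_up_per_gene <- vapply(near, function(t) sum(t %in% up_set), 0L)
  n_down_per_gene <- vapply(near, function(t) sum(t %in% down_set), 0L)

  prof <- data.frame(
    bin_index = sort(unique(bin)),
    n_features = as.integer(table(bin)),
    median_expression = as.numeric(tapply(v, bin, stats::median)),
    n_up_te = as.integer(tapply(n_up_per_gene, bin, sum)),
    n_down_te = as.integer(tapply(n_down_per_gene, bin, sum)),
    n_genes_with_up_te = as.integer(tapply(n_up_per_gene > 0, bin, sum)),
    n_genes_with_down_te = as.integer(tapply(n_down_per_gene > 0, bin, sum)),
    row.names = NULL)
  if (prof$n_features[nrow(prof)] < bin_size)
    attr(prof, "short_last_bin") <- TRUE
  attr(prof, "tissue") <- tissue
  attr(prof, "members") <- split(ids, bin)
  class(prof) <- c("bin_profile", "data.frame")
  prof
}

#' @export
print.bin_profile <- function(x, ...) {
  cat("bin_profile:", nrow(x), "bins of tissue", attr(x, "tissue"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Monotone association between bin expression and nearby-TE counts
#'
#' Kendall tau-b between per-bin median expression and each of the four
#' count series (up/down x TEs/genes). Positive tau means higher expression
#' associates with larger counts. Constant count series give a flagged `NA`.
#'
#' @param profile a [bin_and_count()] result with at least 3 bins.
#' @return data.frame with `tissue`, `direction`, `count_type`, `tau`,
#'   `p_value`.
#' @export
bin_association <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"), nrow(profile) >= 3)
  series <- list(
    c("up", "n_tes", "n_up_te"),
    c("down", "n_tes", "n_down_te"),
    c("up", "n_genes", "n_genes_with_up_te"),
    c("down", "n_genes", "n_genes_with_down_te"))
  do.call(rbind, lapply(series, function(s) {
    res <- kendall_tau_b(profile$median_expression, profile[[s[3]]])
    data.frame(tissue = attr(profile, "tissue"), direction = s[1],
               count_type = s[2], tau = res$estimate,
               p_value = res$p_value, row.names = NULL)
  }))
}

#' Cross-tissue contamination control profile
#'
#' Restricts the ranked universe to features with tissue-mean expression
#' strictly greater in `tissue_a` than in `tissue_b` before binning; if the
#' gene-TE association survives this filter it cannot be driven by
#' cross-contamination of the two samples. Otherwise identical to
#' [bin_and_count()].
#'
#' @inheritParams bin_and_count
#' @param tissue_a tissue whose expression defines the ranking (features
#'   kept must exceed their `tissue_b` mean).
#' @param tissue_b comparison tissue for the strict filter.
#' @return A `"bin_profile"` over the filtered universe.
#' @export
crosstissue_control <- function(expr, tissue_a, tissue_b, de_results,
                                proximity_map, n_top = 20000L,
                                bin_size = 200L) {
  tm <- if (inherits(expr, "expression_matrix")) tissue_means(expr)
        else as.matrix(expr)
  stopifnot(all(c(tissue_a, tissue_b) %in% colnames(tm)))
  keep <- rownames(tm)[tm[, tissue_a] > tm[, tissue_b]]
  if (length(keep) == 0)
    stop("no feature expressed strictly higher in ", tissue_a,
         " than in ", tissue_b)
  bin_and_count(tm, tissue_a, de_results, proximity_map,
                n_top = min(n_top, length(keep)), bin_size = bin_size,
                feature_subset = keep)
}

#' Plot a bin profile
#'
#' Grey bars: per-bin counts of nearby up-regulated TEs; black dots: per-bin
#' number of genes with at least one up-regulated TE. Bins run from the
#' most highly expressed (left) to the least.
#'
#' @param x a `"bin_profile"`.
#' @param direction `"up"` (default) or `"down"`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.bin_profile <- function(x, direction = c("up", "down"), ...) {
  direction <- match.arg(direction)
  bars <- if (direction == "up") x$n_up_te else x$n_down_te
  dots <- if (direction == "up") x$n_genes_with_up_te
          else x$n_genes_with_down_te
  mids <- graphics::barplot(bars, border = NA, col = "grey70",
                            xlab = "expression bin (high to low)",
                            ylab = paste0("# ", direction, "-regulated TEs < 2 kb"),
                            ...)
  graphics::points(mids, dots, pch = 16, cex = 0.6)
  invisible(x)
}
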