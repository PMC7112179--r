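# Gene/isoform abundance and the mutually exclusive expression classes
# used to choose insertion alleles for the transmission assay.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fragments / ((transcript_length_bp / 1e3) * (total_mapped_fragments / 1e6))`.
#' Vectorized over features.
#'
#' @param fragments assigned fragment counts (may be fractional), `>= 0`.
#' @param transcript_length_bp transcript lengths, `> 0`.
#' @param total_mapped_fragments per-sample mapped totals, `> 0`.
#' @return Numeric FPKM values.
#' @examples
#' fpkm(1000, 1000, 1e6) # 1000
#' @export
fpkm <- function(fragments, transcript_length_bp, total_mapped_fragments) {
  stopifnot(all(transcript_length_bp > 0), all(total_mapped_fragments > 0))
  if (any(fragments < 0)) stop("negative fragment counts")
  fragments / ((transcript_length_bp / 1e3) * (total_mapped_fragments / 1e6))
}

#' FPKM matrix from a count matrix and transcript lengths
#'
#' Applies [fpkm()] column-wise, using each sample's `library_size` as the
#' mapped-fragment total.
#'
#' @param cm a [count_matrix].
#' @param transcript_lengths named vector of transcript lengths covering
#'   the features of `cm`.
#' @return An [expression_matrix].
#' @export
fpkm_matrix <- function(cm, transcript_lengths) {
  len <- transcript_lengths[rownames(cm$values)]
  if (anyNA(len)) stop("missing transcript length for some features")
  vals <- vapply(seq_len(ncol(cm$values)), function(j)
    fpkm(cm$values[, j], len, cm$samples$library_size[j]),
    numeric(nrow(cm$values)))
  rownames(vals) <- rownames(cm$values)
  expression_matrix(vals, cm$samples)
}

#' Mutually exclusive expression-class assignment
#'
#' Assigns genes to one of three classes from tissue-mean FPKM:
#' * `vegetative_cell`: in the top quantile of mature pollen (MP) *and*
#'   FPKM greater in MP than in sperm cells (SC);
#' * `sperm_cell`: in the top quantile of SC *and* FPKM greater in SC than
#'   in MP;
#' * `seedling`: in the top quantile of seedling and in the top quantile of
#'   neither MP nor SC.
#'
#' The top quantile (default 20%) is computed per tissue among genes with
#' nonzero tissue-mean FPKM (`universe = "expressed"`) or among all genes.
#' A gene in the top quantile of both MP and SC with exactly equal FPKM is
#' left `unclassified` with a warning. Genes whose class-tissue
#' `log2(FPKM)` exceeds `high_threshold_log2` are flagged as very highly
#' expressed.
#'
#' @param expr an [expression_matrix] (gene level), or a matrix of
#'   tissue-mean FPKM with tissues in columns.
#' @param quantile top fraction defining "highly expressed", default 0.20.
#' @param high_threshold_log2 threshold on log2(FPKM) for the very-high
#'   flag, default 8.
#' @param tissues named character vector mapping the roles `mp`, `sc`,
#'   `seedling` to tissue labels in the data.
#' @param universe `"expressed"` (default) or `"all"`.
#'
#' @return data.frame with `gene_id`, `class`, `fpkm_mp`, `fpkm_sc`,
#'   `fpkm_seedling`, `high_expression`.
#' @export
assign_classes <- function(expr, quantile = 0.20, high_threshold_log2 = 8,
                           tissues = c(mp = "pollen", sc = "sperm_cell",
                                       seedling = "seedling"),
                           universe = c("expressed", "all")) {
  universe <- match.arg(universe)
  tm <- if (inherits(expr, "expression_matrix")) tissue_means(expr)
        else as.matrix(expr)
  miss <- setdiff(unname(tissues), colnames(tm))
  if (length(miss)) stop("tissues absent from data: ",
                         paste(miss, collapse = ", "))
  ids <- rownames(tm)
  v_mp <- tm[, tissues[["mp"]]]
  v_sc <- tm[, tissues[["sc"]]]
  v_sl <- tm[, tissues[["seedling"]]]

  top_set <- function(v) {
    use <- if (universe == "expressed") v > 0 else rep(TRUE, length(v))
    n_top <- ceiling(sum(use) * quantile)
    if (n_top == 0) return(character(0))
    # rank descending; ties at the boundary broken by feature id
    ord <- order(-v[use], ids[use])
    ids[use][ord][seq_len(n_top)]
  }
  top_mp <- top_set(v_mp); top_sc <- top_set(v_sc); top_sl <- top_set(v_sl)

  class <- rep("unclassified", length(ids))
  tie <- ids %in% top_mp & ids %in% top_sc & v_mp == v_sc
  if (any(tie))
    warning(sum(tie), " gene(s) tied between MP and SC FPKM; unclassified")
  class[ids %in% top_mp & v_mp > v_sc] <- "vegetative_cell"
  class[ids %in% top_sc & v_sc > v_mp] <- "sperm_cell"
  class[ids %in% top_sl & !(ids %in% top_mp) & !(ids %in% top_sc)] <-
    "seedling"

  class_fpkm <- ifelse(class == "vegetative_cell", v_mp,
                ifelse(class == "sperm_cell", v_sc,
                ifelse(class == "seedling", v_sl, NA_real_)))
  high <- !is.na(class_fpkm) & log2(pmax(class_fpkm, .Machine$double.xmin)) >
    high_threshold_log2
  data.frame(gene_id = ids, class = class, fpkm_mp = unname(v_mp),
             fpkm_sc = unname(v_sc), fpkm_seedling = unname(v_sl),
             high_expression = high, row.names = NULL)
}

#' Multiplicity histogram of top-expressed feature sets across tissues
#'
#' For each tissue, the `top_n` features by tissue-mean expression are
#' identified (ties broken by feature id); each top feature's multiplicity
#' is the number of tissues in whose top set it appears. Returns per-tissue
#' and global multiplicity histograms — a multiplicity-1 fraction near 1
#' means top expression is tissue-exclusive.
#'
#' @param expr an [expression_matrix] or tissue-mean matrix.
#' @param tissues tissue labels to compare.
#' @param top_n number of top features per tissue.
#'
#' @return A list with `per_tissue` (matrix tissues x multiplicity) and
#'   `global` (named vector over the union of top sets).
#' @export
top_set_overlap_summary <- function(expr, tissues, top_n) {
  tm <- if (inherits(expr, "expression_matrix")) tissue_means(expr)
        else as.matrix(expr)
  stopifnot(top_n <= nrow(tm), all(tissues %in% colnames(tm)))
  ids <- rownames(tm)
  tops <- lapply(tissues, function(t) {
    ord <- order(-tm[, t], ids)
    ids[ord][seq_len(top_n)]
  })
  names(tops) <- tissues
  all_top <- unique(unlist(tops))
  mult <- rowSums(vapply(tops, function(s) all_top %in% s,
                         logical(length(all_top))))
  names(mult) <- all_top
  levs <- seq_along(tissues)
  per_tissue <- t(vapply(tops, function(s)
    as.numeric(table(factor(mult[s], levels = levs))), numeric(length(levs))))
  colnames(per_tissue) <- levs
  global <- as.numeric(table(factor(mult, levels = levs)))
  names(global) <- levs
  list(per_tissue = per_tissue, global = global)
}
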