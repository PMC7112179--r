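# Genome annotation data model. Coordinates are 1-based inclusive (GFF3
# dialect) everywhere; all distance arithmetic below states and assumes
# that convention.

#' Assemble a genome annotation object
#'
#' Bundles gene intervals, TE intervals with family labels, centromere
#' positions and chromosome lengths into the container consumed by the
#' proximity and expression analyses.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param tes data.frame with columns `te_id`, `chrom`, `start`, `end`,
#'   `strand`, `family`, `superfamily`.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`.
#' @param chrom_lengths named integer vector of chromosome lengths. If
#'   `NULL`, taken as the maximum annotated end per chromosome.
#' @param transcripts optional data.frame with columns `gene_id`,
#'   `isoform_id`, `transcript_length_bp` (used by FPKM computation).
#'
#' @return An object of class `"genome_annotation"`.
#' @export
genome_annotation <- function(genes, tes, centromeres = NULL,
                              chrom_lengths = NULL, transcripts = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "chrom", "start", "end"), "genes")
  need(tes, c("te_id", "chrom", "start", "end", "family"), "tes")
  if (is.null(genes$strand)) genes$strand <- rep(".", nrow(genes))
  if (is.null(tes$strand)) tes$strand <- rep(".", nrow(tes))
  if (is.null(tes$superfamily)) tes$superfamily <- rep("other", nrow(tes))
  check_iv <- function(df, what) {
    if (any(df$start < 1) || any(df$start > df$end))
      stop(what, ": intervals must satisfy 1 <= start <= end")
  }
  check_iv(genes, "genes"); check_iv(tes, "tes")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(tes$te_id)) stop("duplicate TE ids")
  tes$length_bp <- tes$end - tes$start + 1L
  if (is.null(chrom_lengths)) {
    ends <- c(tapply(genes$end, genes$chrom, max),
              tapply(tes$end, tes$chrom, max))
    if (!is.null(centromeres))
      ends <- c(ends, stats::setNames(centromeres$end, centromeres$chrom))
    chrom_lengths <- tapply(ends, names(ends), max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  } else {
    over <- function(df) any(df$end > chrom_lengths[as.character(df$chrom)],
                             na.rm = FALSE)
    if (over(genes) || over(tes))
      stop("features extend beyond chrom_lengths")
  }
  structure(
    list(genes = as.data.frame(genes), tes = as.data.frame(tes),
         centromeres = if (is.null(centromeres)) NULL
                       else as.data.frame(centromeres),
         chrom_lengths = chrom_lengths,
         transcripts = if (is.null(transcripts)) NULL
                       else as.data.frame(transcripts)),
    class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$tes),
      "TEs on", length(x$chrom_lengths), "chromosomes\n")
  if (!is.null(x$centromeres))
    cat("  centromeres annotated for", nrow(x$centromeres), "chromosomes\n")
  invisible(x)
}

as_granges <- function(df, id_col) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    feature_id = df[[id_col]])
}

#' Gap distance between two genomic intervals
#'
#' Number of bases strictly between two 1-based inclusive intervals: 0 when
#' they overlap or abut, `NA` when they lie on different chromosomes.
#' Vectorized over rows.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycled).
#' @param chrom_b,start_b,end_b second interval.
#'
#' @return Integer vector of gap distances (`NA` across chromosomes).
#' @examples
#' gap_distance("chr1", 100, 200, "chr1", 401, 500) # 200
#' @export
gap_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  gap <- pmax(pmax(start_a, start_b) - pmin(end_a, end_b) - 1, 0)
  gap[as.character(chrom_a) != as.character(chrom_b)] <- NA_integer_
  as.integer(gap)
}

#' Partition TEs by proximity to genes
#'
#' A TE is `near_gene` when its gap distance (edge to edge, strand-agnostic)
#' to any gene is strictly less than `threshold_bp`; overlap counts as near.
#' A gap of exactly `threshold_bp` is distal: the distal analysis set is
#' defined as elements *more* than the threshold away from genes. Also
#' returns the inverse relation, mapping each gene to the TEs within the
#' threshold.
#'
#' @param annotation a [genome_annotation].
#' @param threshold_bp positive integer, default 2000.
#'
#' @return A list with `te_category` (named character vector, values
#'   `"near_gene"`/`"distal"`), `gene_te_map` (named list gene_id ->
#'   character vector of te_ids), and `threshold_bp`.
#' @export
classify_proximity <- function(annotation, threshold_bp = 2000L) {
  stopifnot(inherits(annotation, "genome_annotation"), threshold_bp > 0)
  tes <- annotation$tes
  genes <- annotation$genes
  cat_vec <- stats::setNames(rep("distal", nrow(tes)), tes$te_id)
  gene_map <- stats::setNames(
    rep(list(character(0)), nrow(genes)), genes$gene_id)
  if (nrow(genes) == 0) {
    warning("no genes in annotation; all TEs classified distal")
    return(list(te_category = cat_vec, gene_te_map = gene_map,
                threshold_bp = threshold_bp))
  }
  te_gr <- as_granges(tes, "te_id")
  gene_gr <- as_granges(genes, "gene_id")
  # gap < threshold  <=>  findOverlaps with maxgap = threshold - 1
  hits <- GenomicRanges::findOverlaps(gene_gr, te_gr,
                                      maxgap = threshold_bp - 1L)
  if (length(hits)) {
    near_idx <- unique(S4Vectors::subjectHits(hits))
    cat_vec[near_idx] <- "near_gene"
    by_gene <- split(tes$te_id[S4Vectors::subjectHits(hits)],
                     genes$gene_id[S4Vectors::queryHits(hits)])
    gene_map[names(by_gene)] <- by_gene
  }
  list(te_category = cat_vec, gene_te_map = gene_map,
       threshold_bp = threshold_bp)
}

#' Distance from TEs to the annotated centromere
#'
#' Gap distance between each TE and the centromere interval of its
#' chromosome; 0 for TEs inside the centromere.
#'
#' @param annotation a [genome_annotation] with centromeres.
#' @param te_ids optional subset of TE ids (default: all).
#'
#' @return Named integer vector of distances in bp.
#' @export
distance_to_centromere <- function(annotation, te_ids = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(annotation$centromeres))
    stop("annotation has no centromere table")
  tes <- annotation$tes
  if (!is.null(te_ids)) tes <- tes[tes$te_id %in% te_ids, , drop = FALSE]
  cen <- annotation$centromeres
  idx <- match(as.character(tes$chrom), as.character(cen$chrom))
  if (anyNA(idx))
    stop("missing centromere for chromosome(s): ",
         paste(unique(tes$chrom[is.na(idx)]), collapse = ", "))
  d <- gap_distance(tes$chrom, tes$start, tes$end,
                    cen$chrom[idx], cen$start[idx], cen$end[idx])
  stats::setNames(d, tes$te_id)
}
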