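# Annotation input/output: GFF3 for genes and TEs (via rtracklayer), a
# plain TSV for centromere positions, and BED6 export of TE categories.

#' Read gene and TE annotation from GFF3
#'
#' Genes are taken from features of type `gene`; isoform transcript lengths
#' are summed from `exon` features grouped by their `Parent` mRNA when
#' present. TE family labels are read from the attribute named by
#' `family_attr` (different TE annotation dialects use `Classification`,
#' `family`, or similar).
#'
#' @param gene_gff3 path to the gene annotation GFF3.
#' @param te_gff3 path to the TE annotation GFF3.
#' @param centromere_tsv optional TSV with columns `chrom`, `start`, `end`.
#' @param family_attr attribute holding the TE family label; the first of
#'   the given names that exists is used. Default
#'   `c("Classification", "family")`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#'
#' @return A [genome_annotation].
#' @export
read_annotation_gff3 <- function(gene_gff3, te_gff3, centromere_tsv = NULL,
                                 family_attr = c("Classification", "family"),
                                 chrom_lengths = NULL) {
  for (f in c(gene_gff3, te_gff3))
    if (!file.exists(f)) stop("annotation file not found: ", f)
  g <- rtracklayer::import(gene_gff3, format = "gff3")
  gg <- g[g$type == "gene"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)))
  transcripts <- NULL
  ex <- g[g$type == "exon"]
  if (length(ex)) {
    parent <- vapply(ex$Parent, function(p) as.character(p)[1L], "")
    tl <- tapply(GenomicRanges::width(ex), parent, sum)
    mr <- g[g$type == "mRNA"]
    if (length(mr)) {
      gene_of <- stats::setNames(
        vapply(mr$Parent, function(p) as.character(p)[1L], ""),
        as.character(mr$ID))
      transcripts <- data.frame(
        gene_id = unname(gene_of[names(tl)]),
        isoform_id = names(tl),
        transcript_length_bp = as.integer(tl))
    }
  }
  t_gr <- rtracklayer::import(te_gff3, format = "gff3")
  attr_use <- intersect(family_attr, names(S4Vectors::mcols(t_gr)))
  fam <- if (length(attr_use)) as.character(S4Vectors::mcols(t_gr)[[attr_use[1L]]])
         else rep(NA_character_, length(t_gr))
  ids <- if (!is.null(t_gr$ID)) as.character(t_gr$ID)
         else paste0("TE", seq_along(t_gr))
  tes <- data.frame(
    te_id = ids,
    chrom = as.character(GenomicRanges::seqnames(t_gr)),
    start = GenomicRanges::start(t_gr), end = GenomicRanges::end(t_gr),
    strand = as.character(GenomicRanges::strand(t_gr)),
    family = fam,
    superfamily = te_superfamily(fam))
  cen <- NULL
  if (!is.null(centromere_tsv)) {
    cen <- utils::read.delim(centromere_tsv, stringsAsFactors = FALSE)
    names(cen)[1:3] <- c("chrom", "start", "end")
  }
  genome_annotation(genes, tes, centromeres = cen,
                    chrom_lengths = chrom_lengths,
                    transcripts = transcripts)
}

#' Map TE family labels to superfamily classes
#'
#' Uses the three-letter TE code convention (`RL*` = LTR retrotransposon,
#' `RI*`/`LINE*` = LINE, `RS*`/`SINE*` = SINE, `D**` = DNA transposon);
#' anything unrecognized is `"other"`.
#'
#' @param family character vector of family labels.
#' @return Character vector in `{"LTR", "DNA", "LINE", "SINE", "other"}`.
#' @export
te_superfamily <- function(family) {
  out <- rep("other", length(family))
  f <- toupper(as.character(family))
  out[startsWith(f, "RL") | grepl("^LTR", f)] <- "LTR"
  out[startsWith(f, "RI") | grepl("^LINE", f)] <- "LINE"
  out[startsWith(f, "RS") | grepl("^SINE", f)] <- "SINE"
  out[startsWith(f, "D")] <- "DNA"
  out[is.na(family)] <- "other"
  out
}

#' Write TE category assignments as BED6
#'
#' One BED record per TE with the category in the name column
#' (`te_id|category`), score 0. BED is 0-based half-open; the conversion
#' from the package's 1-based inclusive coordinates is done here.
#'
#' @param annotation a [genome_annotation].
#' @param categories named character vector te_id -> category.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_category_bed6 <- function(annotation, categories, path) {
  tes <- annotation$tes
  idx <- match(tes$te_id, names(categories))
  df <- data.frame(
    chrom = tes$chrom,
    start = tes$start - 1L,          # BED 0-based
    end = tes$end,
    name = paste0(tes$te_id, "|", unname(categories[idx])),
    score = 0L,
    strand = ifelse(tes$strand %in% c("+", "-"), tes$strand, "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome annotation as a pair of GFF3 files
#'
#' Deterministic, minimal GFF3 writer used by the synthetic-data generator
#' so that generated annotations can be re-read through
#' [read_annotation_gff3()]. Gene records carry one mRNA and one exon per
#' isoform; TE records carry the family in a `Classification` attribute.
#'
#' @param annotation a [genome_annotation].
#' @param gene_gff3,te_gff3 output paths.
#' @param centromere_tsv optional output path for the centromere table.
#' @return Invisibly, the paths written.
#' @export
write_annotation_gff3 <- function(annotation, gene_gff3, te_gff3,
                                  centromere_tsv = NULL) {
  g <- annotation$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], "synthetic", "gene", g$start[i],
                            g$end[i], ".", g$strand[i], ".",
                            paste0("ID=", g$gene_id[i]), sep = "\t"))
    tr <- annotation$transcripts
    if (!is.null(tr)) {
      tri <- tr[tr$gene_id == g$gene_id[i], , drop = FALSE]
      for (j in seq_len(nrow(tri))) {
        mid <- tri$isoform_id[j]
        len <- tri$transcript_length_bp[j]
        lines <- c(lines,
          paste(g$chrom[i], "synthetic", "mRNA", g$start[i], g$end[i], ".",
                g$strand[i], ".",
                paste0("ID=", mid, ";Parent=", g$gene_id[i]), sep = "\t"),
          paste(g$chrom[i], "synthetic", "exon", g$start[i],
                g$start[i] + len - 1L, ".", g$strand[i], ".",
                paste0("ID=", mid, ".e1;Parent=", mid), sep = "\t"))
      }
    }
  }
  writeLines(lines, gene_gff3)
  t <- annotation$tes
  tlines <- c("##gff-version 3",
    paste(t$chrom, "synthetic", "transposable_element", t$start, t$end, ".",
          t$strand, ".",
          paste0("ID=", t$te_id, ";Classification=", t$family), sep = "\t"))
  writeLines(tlines, te_gff3)
  if (!is.null(centromere_tsv) && !is.null(annotation$centromeres))
    utils::write.table(annotation$centromeres, centromere_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(gene_gff3, te_gff3))
}
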