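# Simplified genomic-feature annotation: each region is assigned exactly one
# category by a fixed precedence, mirroring the usual peak-annotation
# convention (Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream >
# Distal Intergenic).

FEATURE_LEVELS <- c("Promoter", "5' UTR", "3' UTR", "Exon", "Intron",
                    "Downstream", "Distal Intergenic")

#' Build an annotation model from feature tables
#'
#' @param transcripts Interval data.frame with a `strand` column (`+`/`-`)
#'   and optionally `gene_id`.
#' @param exons,five_utr,three_utr Optional interval data.frames.
#' @return List of class `annotation_model`.
#' @export
annotation_model <- function(transcripts, exons = NULL, five_utr = NULL,
                             three_utr = NULL) {
  stopifnot(!is.null(transcripts$strand))
  empty <- intervals()
  structure(list(transcripts = transcripts,
                 exons = if (is.null(exons)) empty else exons,
                 five_utr = if (is.null(five_utr)) empty else five_utr,
                 three_utr = if (is.null(three_utr)) empty else three_utr),
            class = "annotation_model")
}

#' Read an annotation model from a GFF3/GTF file
#'
#' Keeps transcript-level records (types transcript/mRNA, or gene when no
#' transcripts are present), exons, and UTRs. Parsed with a plain
#' tab-delimited reader; coordinates converted to 0-based half-open.
#'
#' @param path GFF3 or GTF file path.
#' @return An `annotation_model`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 8) stop(sprintf("malformed GFF '%s'", path))
  type <- raw[[3]]
  grab <- function(types) {
    sel <- type %in% types
    if (!any(sel)) return(intervals())
    intervals(seqid = raw[[1]][sel], start = raw[[4]][sel] - 1L,
              end = raw[[5]][sel], strand = raw[[7]][sel])
  }
  tx <- grab(c("transcript", "mRNA"))
  if (nrow(tx) == 0) tx <- grab("gene")
  if (nrow(tx) == 0) stop(sprintf("no transcript/mRNA/gene records in '%s'", path))
  annotation_model(tx,
                   exons = grab(c("exon", "CDS")),
                   five_utr = grab(c("five_prime_UTR", "5UTR")),
                   three_utr = grab(c("three_prime_UTR", "3UTR")))
}

.tss_of <- function(tx) ifelse(tx$strand == "-", tx$end - 1L, tx$start)
.tes_of <- function(tx) ifelse(tx$strand == "-", tx$start, tx$end - 1L)

.any_overlap <- function(region, feats) {
  f <- feats[feats$seqid == region$seqid, , drop = FALSE]
  nrow(f) > 0 && any(.overlap_widths(region$start, region$end,
                                     f$start, f$end) > 0)
}

#' Annotate regions with genomic feature categories
#'
#' Categories in precedence order: Promoter (region overlaps TSS +/-
#' `promoter_window`), 5' UTR, 3' UTR, Exon, Intron (inside a transcript but
#' not exonic), Downstream (within `downstream_window` past the transcript
#' 3' end), Distal Intergenic.
#'
#' @param regions Interval data.frame.
#' @param annotation An `annotation_model`.
#' @param promoter_window Promoter half-width around the TSS in bp
#'   (default 3000).
#' @param downstream_window Downstream window in bp (default 3000).
#' @return List with `category` (factor per region, levels in precedence
#'   order) and `distribution` (data.frame of category, n, percent; percents
#'   sum to 100).
#' @export
annotate_features <- function(regions, annotation, promoter_window = 3000,
                              downstream_window = 3000) {
  if (!inherits(annotation, "annotation_model"))
    stop("'annotation' must be an annotation_model")
  tx <- annotation$transcripts
  tss <- .tss_of(tx)
  prom <- intervals(tx$seqid, pmax(0L, tss - as.integer(promoter_window)),
                    tss + as.integer(promoter_window) + 1L)
  tes <- .tes_of(tx)
  down_start <- ifelse(tx$strand == "-",
                       pmax(0L, tx$start - as.integer(downstream_window)),
                       tx$end)
  down_end <- ifelse(tx$strand == "-", tx$start,
                     tx$end + as.integer(downstream_window))
  keep <- down_end > down_start
  down <- intervals(tx$seqid[keep], down_start[keep], down_end[keep])
  cats <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (.any_overlap(r, prom)) return("Promoter")
    if (.any_overlap(r, annotation$five_utr)) return("5' UTR")
    if (.any_overlap(r, annotation$three_utr)) return("3' UTR")
    if (.any_overlap(r, annotation$exons)) return("Exon")
    if (.any_overlap(r, tx)) return("Intron")
    if (nrow(down) && .any_overlap(r, down)) return("Downstream")
    "Distal Intergenic"
  }, character(1))
  category <- factor(cats, levels = FEATURE_LEVELS)
  n <- as.integer(table(category))
  dist <- data.frame(category = FEATURE_LEVELS, n = n,
                     percent = if (sum(n)) 100 * n / sum(n) else rep(0, 7),
                     stringsAsFactors = FALSE)
  list(category = category, distribution = dist)
}
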