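# Genomic intervals are carried as plain data.frames in BED convention:
# 0-based half-open [start, end), columns seqid/start/end (+ extras).
# IRanges is used for set algebra; the helpers below do the 0/1-based bridge.

#' Create an interval table
#'
#' @param seqid Character vector of sequence names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param ... Further columns (name, score, strand, ...), recycled.
#' @return A data.frame with class `c("bed_df", "data.frame")`.
#' @export
intervals <- function(seqid = character(), start = integer(),
                      end = integer(), ...) {
  df <- data.frame(seqid = as.character(seqid),
                   start = as.integer(start), end = as.integer(end),
                   ..., stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start))
    stop("intervals must satisfy end > start (0-based half-open)")
  class(df) <- c("bed_df", "data.frame")
  df
}

.as_bed <- function(df) {
  class(df) <- c("bed_df", "data.frame")
  df
}

.bed_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

.gr_to_bed <- function(gr) {
  intervals(seqid = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::end(gr))
}

#' Sort intervals by (seqid, start, end)
#' @param df Interval data.frame.
#' @return Sorted data.frame.
#' @export
sort_intervals <- function(df) {
  .as_bed(df[order(df$seqid, df$start, df$end), , drop = FALSE])
}

#' Merge overlapping or bookended intervals
#'
#' @param df Interval data.frame.
#' @return Sorted, disjoint interval data.frame.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(intervals())
  .gr_to_bed(GenomicRanges::reduce(.bed_to_gr(df)))
}

#' Read a BED file (3-6 columns)
#'
#' @param path File path.
#' @return Interval data.frame with any of name/score/strand present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop(sprintf("malformed BED '%s': %s", path, conditionMessage(e)))
    })
  if (nrow(raw) == 0) return(intervals())
  if (ncol(raw) < 3) stop(sprintf("malformed BED '%s': fewer than 3 columns", path))
  bad <- which(!grepl("^[0-9]+$", as.character(raw[[2]])) |
                 !grepl("^[0-9]+$", as.character(raw[[3]])))
  if (length(bad))
    stop(sprintf("malformed BED '%s': non-integer coordinates at line %d",
                 path, bad[1]))
  df <- intervals(seqid = raw[[1]], start = as.integer(raw[[2]]),
                  end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) df$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) df$score <- raw[[5]]
  if (ncol(raw) >= 6) df$strand <- as.character(raw[[6]])
  df
}

#' Write intervals as BED
#'
#' Writes 3 to 6 columns depending on which of name/score/strand exist.
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$seqid, df$start, df$end)
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) {
      cols <- c(cols, list(df$score))
      if (!is.null(df$strand)) cols <- c(cols, list(df$strand))
    }
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA index (.fai) into named sequence lengths
#'
#' @param path Path to a samtools-style `.fai` (first two columns used).
#' @return Named integer vector of sequence lengths.
#' @export
read_fai <- function(path) {
  if (!file.exists(path)) stop(sprintf("fai file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

# overlap width of one interval against a table (same seqid assumed filtered)
.overlap_widths <- function(ref_start, ref_end, starts, ends) {
  pmax(0L, pmin(ref_end, ends) - pmax(ref_start, starts))
}
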