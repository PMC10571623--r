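# Sequences are held as integer code vectors (A=1, C=2, G=3, T=4, NA for
# ambiguous bases); scanning is vectorized per motif column, O(n * L).

.encode_seq <- function(seq_chr) {
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  match(chars, DNA_BASES)
}

.decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok]]
  paste(out, collapse = "")
}

#' Read a multi-record FASTA into character sequences
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# score every window start for one strand matrix of log-odds (4 x L);
# returns numeric vector length n - L + 1 with NA where a window spans non-ACGT
.window_scores <- function(codes, logodds) {
  L <- ncol(logodds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  total <- numeric(nw)
  for (j in seq_len(L)) {
    colscore <- logodds[, j][codes[j:(j + nw - 1L)]]  # NA codes index -> NA
    colscore[is.na(codes[j:(j + nw - 1L)])] <- NA_real_
    total <- total + colscore
  }
  total
}

#' Find all binding sites of a PWM in one sequence
#'
#' Scans every window on both strands; a window is a site when its log-odds
#' score reaches `threshold` and it contains no ambiguous base. Minus-strand
#' windows are scored on the reverse complement but reported in forward
#' coordinates (BED convention).
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive), or an
#'   integer code vector as produced internally.
#' @param pwm A [pwm()] object.
#' @param threshold Minimum score (nats). Use [default_threshold()] for the
#'   information-content based automatic cutoff.
#' @param seqid Sequence name recorded in the output (default "seq").
#' @return Interval data.frame with columns seqid, start, end, name (pwm id),
#'   score, strand, sorted by (start, strand, name). 0-based half-open.
#' @export
find_sites <- function(sequence, pwm, threshold, seqid = "seq") {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold))
  codes <- if (is.character(sequence)) .encode_seq(sequence) else sequence
  L <- pwm_length(pwm)
  if (length(codes) < L)
    return(intervals(character(), integer(), integer(),
                     name = character(), score = numeric(),
                     strand = character()))
  fwd <- .window_scores(codes, pwm_logodds(pwm))
  rev <- .window_scores(codes, pwm_logodds(pwm_revcomp(pwm)))
  hit_f <- which(!is.na(fwd) & fwd >= threshold)
  hit_r <- which(!is.na(rev) & rev >= threshold)
  df <- data.frame(
    seqid = rep(seqid, length(hit_f) + length(hit_r)),
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + L,
    name = rep(pwm$id, length(hit_f) + length(hit_r)),
    score = c(fwd[hit_f], rev[hit_r]),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand, df$name), , drop = FALSE]
  rownames(df) <- NULL
  .as_bed(df)
}

#' Scan one sequence with a PWM library
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param pwms List of `pwm` objects.
#' @param thresholds Named numeric vector of score cutoffs per pwm id; when
#'   `NULL`, [default_threshold()] is computed for each motif.
#' @param seqid Sequence name for the output.
#' @return Combined site interval data.frame, sorted by (start, strand, name).
#' @export
scan_sequence <- function(sequence, pwms, thresholds = NULL, seqid = "seq") {
  codes <- .encode_seq(sequence)
  if (is.null(thresholds)) {
    thresholds <- vapply(pwms, default_threshold, numeric(1))
    names(thresholds) <- vapply(pwms, function(p) p$id, character(1))
  }
  pieces <- lapply(pwms, function(p) {
    thr <- thresholds[[p$id]]
    if (is.null(thr) || is.na(thr))
      stop(sprintf("no threshold for motif '%s'", p$id))
    find_sites(codes, p, thr, seqid = seqid)
  })
  df <- do.call(rbind, pieces)
  df <- df[order(df$start, df$strand, df$name), , drop = FALSE]
  rownames(df) <- NULL
  .as_bed(df)
}

#' Per-position binding-site coverage track
#'
#' `counts[i]` is the number of reported sites whose footprint covers
#' position `i` (0-based). Positions under the N mask always carry zero
#' coverage since no site may span an ambiguous base.
#'
#' @param sites Site interval data.frame (as from [find_sites()]).
#' @param seq_length Sequence length.
#' @param n_mask Logical vector of length `seq_length`, TRUE at non-ACGT
#'   positions; default all FALSE.
#' @param count_mode `"coverage"` (default; a site adds 1 to every position
#'   it spans) or `"starts"` (a site adds 1 only at its start).
#' @return List of class `coverage_track`: `counts` (integer), `n_mask`
#'   (logical), `seq_length`.
#' @export
build_coverage <- function(sites, seq_length, n_mask = NULL,
                           count_mode = c("coverage", "starts")) {
  count_mode <- match.arg(count_mode)
  seq_length <- as.integer(seq_length)
  if (is.null(n_mask)) n_mask <- rep(FALSE, seq_length)
  stopifnot(length(n_mask) == seq_length)
  counts <- integer(seq_length)
  if (nrow(sites)) {
    bad <- which(sites$start < 0 | sites$end > seq_length)
    if (length(bad))
      stop(sprintf("site out of bounds: %s:[%d,%d)", sites$seqid[bad[1]],
                   sites$start[bad[1]], sites$end[bad[1]]))
    if (count_mode == "coverage") {
      # difference-array accumulation
      delta <- tabulate(sites$start + 1L, seq_length + 1L) -
        tabulate(sites$end + 1L, seq_length + 1L)
      counts <- cumsum(delta[seq_len(seq_length)])
    } else {
      tab <- table(sites$start + 1L)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  structure(list(counts = as.integer(counts), n_mask = n_mask,
                 seq_length = seq_length),
            class = "coverage_track")
}

#' Export a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param seqid Sequence name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, seqid, path) {
  v <- track$counts
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  writeLines(sprintf("%s\t%d\t%d\t%g", seqid, starts[keep], ends[keep],
                     r$values[keep]), path)
  invisible(path)
}
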