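#' Standardize a coverage track to per-position Z-scores
#'
#' The mean and population standard deviation of the per-position site count
#' are taken over non-N positions of the sequence (a whole-chromosome census,
#' hence the divide-by-n SD). `Z(i) = (counts(i) - mu) / sigma`; Z is NA at
#' masked positions.
#'
#' @param track A `coverage_track` from [build_coverage()].
#' @return List of class `z_track`: `z` (numeric, NA at masked positions),
#'   `stats` (list mu, sigma, n_positions), `n_mask`.
#' @export
compute_z <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  ok <- !track$n_mask
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-N positions to standardize")
  x <- as.numeric(track$counts[ok])
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))      # population SD
  if (sigma == 0)
    stop("degenerate track: constant site count, Z undefined")
  z <- rep(NA_real_, track$seq_length)
  z[ok] <- (track$counts[ok] - mu) / sigma
  structure(list(z = z, stats = list(mu = mu, sigma = sigma,
                                     n_positions = n),
                 n_mask = track$n_mask),
            class = "z_track")
}

#' Call CRMs from a Z-score track by seeded, gap-limited extension
#'
#' Positions with `Z > z_seed` are seeds. A seed is extended in both
#' directions along "stepping stone" positions with `Z > 0`: the boundary
#' jumps to the next such position whenever it is fewer than `max_gap` bases
#' away and no masked (N) position intervenes, repeatedly. Final boundaries
#' are the outermost `Z > 0` positions reached, so the flanking positions
#' have `Z <= 0` (the zero-crossing boundary rule). Seeds swallowed by an
#' earlier extension do not start a new call; overlapping or bookended calls
#' are merged.
#'
#' Equivalently: partition the `Z > 0` positions into chains in which
#' consecutive members are < `max_gap` apart with no N between them; every
#' chain holding at least one seed becomes one CRM spanning the chain.
#'
#' @param z_track A `z_track` from [compute_z()].
#' @param z_seed Seed threshold (default 2.33, the one-tailed 0.01 quantile
#'   of the standard normal).
#' @param max_gap Maximum hop distance in bases (default 30, the longest
#'   motif length in the library).
#' @param seqid Sequence name for the output.
#' @return Interval data.frame with columns seqid, start, end, max_z,
#'   n_seeds; sorted, non-overlapping, 0-based half-open.
#' @export
call_crms <- function(z_track, z_seed = 2.33, max_gap = 30, seqid = "seq") {
  stopifnot(inherits(z_track, "z_track"), z_seed > 0, max_gap >= 1)
  z <- z_track$z
  pos <- which(!is.na(z) & z > 0)          # 1-based positions with Z > 0
  empty <- intervals(character(), integer(), integer(),
                     max_z = numeric(), n_seeds = integer())
  if (length(pos) == 0L) return(empty)
  # chain break between consecutive Z>0 positions: distance >= max_gap,
  # or any masked position in between
  if (length(pos) > 1L) {
    gap_too_far <- diff(pos) >= max_gap
    n_before <- cumsum(z_track$n_mask)
    n_between <- n_before[pos[-1L] - 1L] - n_before[pos[-length(pos)]]
    breaks <- gap_too_far | (n_between > 0L)
    chain <- cumsum(c(1L, as.integer(breaks)))
  } else chain <- 1L
  seed <- !is.na(z[pos]) & z[pos] > z_seed
  keep_chain <- unique(chain[seed])
  if (length(keep_chain) == 0L) return(empty)
  out <- lapply(sort(keep_chain), function(ch) {
    members <- pos[chain == ch]
    data.frame(seqid = seqid,
               start = members[1L] - 1L,
               end = members[length(members)],
               max_z = max(z[members]),
               n_seeds = sum(z[members] > z_seed),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  # merge overlapping/bookended calls (possible only at tiny max_gap)
  if (nrow(df) > 1L) {
    grp <- cumsum(c(1L, as.integer(df$start[-1L] > df$end[-nrow(df)])))
    if (any(duplicated(grp))) {
      df <- do.call(rbind, lapply(split(df, grp), function(g) {
        data.frame(seqid = g$seqid[1L], start = min(g$start),
                   end = max(g$end), max_z = max(g$max_z),
                   n_seeds = sum(g$n_seeds), stringsAsFactors = FALSE)
      }))
    }
  }
  rownames(df) <- NULL
  .as_bed(df)
}

#' Run the full CRM detection pipeline on a FASTA
#'
#' For each record: scan with every motif at its threshold, accumulate the
#' per-position coverage track, standardize to Z, and call CRMs. Records
#' whose track is degenerate (constant count, e.g. no sites at all) yield
#' zero CRMs with a warning. Per-record summaries are reported via
#' `message()`.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param pwms List of `pwm` objects.
#' @param z_seed,max_gap See [call_crms()].
#' @param thresholds Optional named numeric score cutoffs; defaults to
#'   [default_threshold()] per motif.
#' @param count_mode Passed to [build_coverage()].
#' @param verbose Emit per-record summary messages (default TRUE).
#' @return List with `crms` (interval data.frame with name and score
#'   columns, BED6-ready), `sites` (all binding sites), `stats` (per-record
#'   data.frame).
#' @export
run_crm_caller <- function(fasta, pwms, z_seed = 2.33, max_gap = 30,
                           thresholds = NULL, count_mode = "coverage",
                           verbose = TRUE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (is.null(thresholds)) {
    thresholds <- vapply(pwms, default_threshold, numeric(1))
    names(thresholds) <- vapply(pwms, function(p) p$id, character(1))
  }
  all_crms <- list(); all_sites <- list(); stats <- list()
  for (sid in names(seqs)) {
    codes <- .encode_seq(seqs[[sid]])
    n_mask <- is.na(codes)
    sites <- scan_sequence(seqs[[sid]], pwms, thresholds, seqid = sid)
    track <- build_coverage(sites, length(codes), n_mask,
                            count_mode = count_mode)
    res <- tryCatch({
      zt <- compute_z(track)
      call_crms(zt, z_seed = z_seed, max_gap = max_gap, seqid = sid)
    }, error = function(e) {
      warning(sprintf("record '%s': %s; emitting zero CRMs", sid,
                      conditionMessage(e)), call. = FALSE)
      intervals(character(), integer(), integer(),
                max_z = numeric(), n_seeds = integer())
    })
    stats[[sid]] <- data.frame(
      seqid = sid, n_sites = nrow(sites),
      mu = if (sum(!n_mask)) mean(track$counts[!n_mask]) else NA_real_,
      sigma = if (sum(!n_mask))
        sqrt(mean((track$counts[!n_mask] -
                     mean(track$counts[!n_mask]))^2)) else NA_real_,
      n_crms = nrow(res),
      mean_crm_len = if (nrow(res)) mean(res$end - res$start) else NA_real_,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf(
        "[%s] %d sites, mu=%.4f sigma=%.4f -> %d CRMs (mean %.0f bp)",
        sid, nrow(sites), stats[[sid]]$mu, stats[[sid]]$sigma,
        nrow(res), ifelse(nrow(res), stats[[sid]]$mean_crm_len, 0)))
    all_sites[[sid]] <- sites
    all_crms[[sid]] <- res
  }
  crms <- do.call(rbind, all_crms)
  if (is.null(crms)) crms <- intervals(character(), integer(), integer(),
                                       max_z = numeric(), n_seeds = integer())
  rownames(crms) <- NULL
  if (nrow(crms)) {
    crms$name <- sprintf("CRM_%s_%d", crms$seqid,
                         stats::ave(seq_len(nrow(crms)), crms$seqid,
                                    FUN = seq_along))
    crms$score <- pmin(1000, round(100 * crms$max_z))
    crms$strand <- "."
  }
  sites <- do.call(rbind, all_sites)
  if (is.null(sites)) sites <- intervals()
  rownames(sites) <- NULL
  list(crms = .as_bed(crms), sites = .as_bed(sites),
       stats = do.call(rbind, c(stats, list(make.row.names = FALSE))))
}
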