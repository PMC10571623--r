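# Control regions: carve predicted-non-functional intervals whose length
# multiset exactly matches the sub-cap CRM subset, from the CRM complement
# after N-exclusion, short-gap filtering, and end-trimming.

#' Complement of the CRM set over each sequence
#'
#' Returns the regions not covered by any CRM, per sequence, excluding
#' complement regions whose ambiguous-base (N) fraction exceeds 50%.
#'
#' @param crms CRM interval data.frame.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param n_runs Optional interval data.frame of N runs.
#' @return Interval data.frame, sorted.
#' @export
complement_regions <- function(crms, seq_lengths, n_runs = NULL) {
  if (nrow(crms)) {
    bad <- which(!(crms$seqid %in% names(seq_lengths)) |
                   crms$end > seq_lengths[crms$seqid])
    if (length(bad))
      stop(sprintf("CRM beyond sequence end: %s:[%d,%d)",
                   crms$seqid[bad[1]], crms$start[bad[1]], crms$end[bad[1]]))
  }
  merged <- merge_intervals(crms)
  out <- list()
  for (sid in names(seq_lengths)) {
    len <- seq_lengths[[sid]]
    sub <- merged[merged$seqid == sid, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[sid]] <- intervals(sid, 0L, len)
      next
    }
    starts <- c(0L, sub$end)
    ends <- c(sub$start, len)
    keep <- ends > starts
    if (any(keep))
      out[[sid]] <- intervals(rep(sid, sum(keep)), starts[keep], ends[keep])
  }
  comp <- do.call(rbind, out)
  if (is.null(comp)) return(intervals())
  rownames(comp) <- NULL
  comp <- .as_bed(comp)
  if (!is.null(n_runs) && nrow(n_runs) && nrow(comp)) {
    nfrac <- vapply(seq_len(nrow(comp)), function(i) {
      nr <- n_runs[n_runs$seqid == comp$seqid[i], , drop = FALSE]
      if (nrow(nr) == 0) return(0)
      sum(.overlap_widths(comp$start[i], comp$end[i], nr$start, nr$end)) /
        (comp$end[i] - comp$start[i])
    }, numeric(1))
    comp <- comp[nfrac <= 0.5, , drop = FALSE]
  }
  sort_intervals(comp)
}

#' Drop short complement regions wedged between two CRMs
#'
#' Complement regions flanked by CRMs on both sides and shorter than
#' `min_len` are removed, since such slivers may belong to the neighbouring
#' CRMs. Terminal regions touching a sequence end are always kept.
#'
#' @param complement Interval data.frame from [complement_regions()].
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param min_len Minimum length for a between-CRM region (default 400;
#'   regions of exactly `min_len` are kept).
#' @return Filtered interval data.frame.
#' @export
filter_short_gaps <- function(complement, seq_lengths, min_len = 400) {
  if (nrow(complement) == 0) return(complement)
  terminal <- complement$start == 0L |
    complement$end == seq_lengths[complement$seqid]
  short <- (complement$end - complement$start) < min_len
  .as_bed(complement[terminal | !short, , drop = FALSE])
}

#' Select the sub-cap CRM subset (CRMsub)
#'
#' Keeps CRMs strictly shorter than `length_cap`. When `candidates` are
#' supplied, the cap is lowered in steps of `step` until the candidate space
#' (after trimming) can host the resulting length multiset; the attained cap
#' is returned alongside.
#'
#' @param crms CRM interval data.frame.
#' @param length_cap Initial cap in bp (default 250, strict `<`).
#' @param candidates Optional candidate interval data.frame used for the
#'   feasibility check.
#' @param trim,pad Packing overheads used in the feasibility check (see
#'   [carve_controls()]).
#' @param step Cap decrement when infeasible (default 10).
#' @return List with `crmsub` (interval data.frame) and `cap` (the final
#'   cap used).
#' @export
select_crmsub <- function(crms, length_cap = 250, candidates = NULL,
                          trim = 40, pad = 5, step = 10) {
  cap <- length_cap
  repeat {
    sub <- .as_bed(crms[(crms$end - crms$start) < cap, , drop = FALSE])
    if (is.null(candidates) || .packing_feasible(candidates,
                                                 sort(sub$end - sub$start,
                                                      decreasing = TRUE),
                                                 trim, pad))
      return(list(crmsub = sub, cap = cap))
    cap <- cap - step
    if (cap <= 0)
      stop("control capacity error: candidate space cannot host any CRM subset")
  }
}

# first-fit-decreasing packing check: lengths into candidate capacities
.packing_feasible <- function(candidates, lengths, trim, pad) {
  caps <- pmax(0, (candidates$end - candidates$start) - 2 * trim)
  for (len in lengths) {
    # cost is len for an empty candidate, len + pad otherwise; model by
    # charging pad up-front and refunding it on first use
    i <- which.max(caps)
    if (length(i) == 0 || caps[i] < len) return(FALSE)
    caps[i] <- caps[i] - len - pad
  }
  TRUE
}

#' Carve control regions matching a length multiset
#'
#' Each candidate region is shrunk by `trim` bases at both ends; the
#' requested lengths are then placed longest-first, each into the candidate
#' with the largest remaining capacity, separated by `pad` bases within a
#' candidate. Placement within a candidate is left-packed after a uniform
#' random start jitter drawn once per candidate under `seed`, so reruns with
#' one seed are identical and the emitted length multiset never changes.
#'
#' @param candidates Candidate interval data.frame (non-CRM space after
#'   filtering).
#' @param lengths Integer vector: the CRMsub length multiset to replicate.
#' @param trim End-trim in bp (default 40).
#' @param pad Minimum separation between fragments in one candidate
#'   (default 5).
#' @param seed Integer seed for placement jitter.
#' @return List of class `control_plan`: `controls` (interval data.frame),
#'   `candidates`, `lengths`, `trim`, `pad`, `seed`.
#' @export
carve_controls <- function(candidates, lengths, trim = 40, pad = 5,
                           seed = 1L) {
  lengths <- sort(as.integer(lengths), decreasing = TRUE)
  trim <- as.integer(trim); pad <- as.integer(pad)
  usable <- pmax(0L, (candidates$end - candidates$start) - 2L * trim)
  caps <- usable
  assigned <- vector("list", nrow(candidates))
  for (len in lengths) {
    i <- which.max(caps)
    if (length(i) == 0 || caps[i] < len) {
      deficit <- sum(lengths) - (sum(usable) - sum(caps))
      stop(sprintf(
        "control capacity shortfall: %d bp of requested length cannot be placed",
        max(1L, deficit)))
    }
    assigned[[i]] <- c(assigned[[i]], len)
    caps[i] <- caps[i] - len - pad
  }
  used <- which(!vapply(assigned, is.null, logical(1)))
  slacks <- vapply(used, function(i) {
    frag <- assigned[[i]]
    (candidates$end[i] - candidates$start[i] - 2 * trim) -
      (sum(frag) + pad * (length(frag) - 1L))
  }, numeric(1))
  jitters <- .with_seed(.derive_seed(seed, "carve_controls"),
                        vapply(slacks, function(s)
                          if (s > 0) sample.int(s + 1L, 1L) - 1L else 0L,
                          integer(1)))
  ctrl <- list()
  for (u in seq_along(used)) {
    i <- used[u]
    frag <- assigned[[i]]
    cursor <- candidates$start[i] + trim + jitters[u]
    for (len in frag) {
      ctrl[[length(ctrl) + 1L]] <- data.frame(
        seqid = candidates$seqid[i], start = cursor, end = cursor + len,
        stringsAsFactors = FALSE)
      cursor <- cursor + len + pad
    }
  }
  controls <- if (length(ctrl)) sort_intervals(do.call(rbind, ctrl)) else
    intervals()
  rownames(controls) <- NULL
  structure(list(controls = controls, candidates = candidates,
                 lengths = lengths, trim = trim, pad = pad, seed = seed),
            class = "control_plan")
}

#' Build a complete control plan from CRM calls
#'
#' Orchestrates [complement_regions()], [filter_short_gaps()],
#' [select_crmsub()] (with feasibility-driven cap lowering) and
#' [carve_controls()] into one `control_plan`, guaranteeing exact
#' length-multiset equality between controls and CRMsub and zero overlap
#' between controls and the full CRM set.
#'
#' @param crms Full CRM interval data.frame (CRMfull).
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param n_runs Optional N-run interval data.frame.
#' @param length_cap,min_gap,trim,pad Scheme constants (defaults 250, 400,
#'   40, 5 bp).
#' @param seed Integer seed for placement jitter.
#' @return A `control_plan` with added elements `crmsub` and `cap`.
#' @export
build_control_plan <- function(crms, seq_lengths, n_runs = NULL,
                               length_cap = 250, min_gap = 400, trim = 40,
                               pad = 5, seed = 1L) {
  comp <- complement_regions(crms, seq_lengths, n_runs)
  cand <- filter_short_gaps(comp, seq_lengths, min_len = min_gap)
  sel <- select_crmsub(crms, length_cap, candidates = cand,
                       trim = trim, pad = pad)
  plan <- carve_controls(cand, sel$crmsub$end - sel$crmsub$start,
                         trim = trim, pad = pad, seed = seed)
  plan$crmsub <- sel$crmsub
  plan$cap <- sel$cap
  plan
}
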