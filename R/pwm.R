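DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' A PWM models the binding specificity of a transcription factor as a
#' per-position base count (or frequency) profile over A/C/G/T. Scoring a
#' sequence window returns the log-likelihood ratio (in nats) of the window
#' under the smoothed motif model versus an i.i.d. background model.
#'
#' Counts are smoothed with a background-proportional pseudocount:
#' `f_i(b) = (counts_i(b) + pseudocount * q_b) / (N_i + pseudocount)`,
#' so every smoothed frequency is strictly inside (0, 1) whenever
#' `pseudocount > 0`.
#'
#' @param id Motif identifier (non-empty string).
#' @param counts Numeric 4 x L matrix of nonnegative base counts; rows must be
#'   A, C, G, T (rownames optional, assumed in that order if absent).
#' @param background Base probabilities (length 4, summing to 1). Default
#'   uniform.
#' @param pseudocount Nonnegative smoothing mass distributed in proportion to
#'   the background. Default 0.375 (the classic Patser convention).
#' @param total_score Importance score used to order motifs during greedy
#'   consolidation. Defaults to `IC * L` (information content in bits times
#'   motif length) when not supplied.
#' @return An object of class `pwm`.
#' @export
#' @examples
#' m <- pwm("toy", matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4))
#' pwm_ic(m)
pwm <- function(id, counts, background = rep(0.25, 4), pseudocount = 0.375,
                total_score = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("'counts' must have 4 rows (A, C, G, T)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and nonnegative")
  rownames(counts) <- DNA_BASES
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("'background' must be 4 positive probabilities summing to 1")
  names(background) <- DNA_BASES
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("'pseudocount' must be a single nonnegative number")
  totals <- colSums(counts)
  if (any(totals + pseudocount <= 0))
    stop("each column needs positive total count (or a positive pseudocount)")
  obj <- structure(
    list(id = id, counts = counts, background = background,
         pseudocount = pseudocount, total_score = NA_real_),
    class = "pwm")
  obj$total_score <- if (is.null(total_score))
    pwm_ic(obj) * ncol(counts) else as.numeric(total_score)
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d columns, IC = %.2f bits, total_score = %.2f\n",
              x$id, ncol(x$counts), pwm_ic(x), x$total_score))
  invisible(x)
}

#' Motif length (number of columns)
#' @param x A `pwm` object.
#' @return Integer number of positions.
#' @export
pwm_length <- function(x) ncol(x$counts)

#' Smoothed per-position base frequencies
#'
#' @param x A `pwm` object.
#' @return 4 x L matrix of smoothed frequencies; columns sum to 1.
#' @export
pwm_freq <- function(x) {
  totals <- colSums(x$counts)
  sweep(x$counts + x$pseudocount * x$background,
        2, totals + x$pseudocount, "/")
}

#' Per-position log-odds matrix (nats)
#'
#' @param x A `pwm` object.
#' @return 4 x L matrix of `log(f_i(b) / q_b)`.
#' @export
pwm_logodds <- function(x) log(pwm_freq(x) / x$background)

#' Information content of a PWM
#'
#' `IC = sum_i sum_b f_i(b) * log(f_i(b)/q_b)`, the Kullback-Leibler
#' divergence of the smoothed motif model from the background, summed over
#' positions. Nonnegative; zero iff every column equals the background.
#'
#' @param x A `pwm` object.
#' @param base Logarithm base: 2 for bits (default), `exp(1)` for nats.
#' @return Nonnegative scalar.
#' @export
pwm_ic <- function(x, base = 2) {
  f <- pwm_freq(x)
  sum(f * log(f / x$background, base = base))
}

#' Reverse complement of a PWM
#'
#' Columns are reversed and the A/T and C/G rows swapped, so that scoring the
#' result on the forward strand equals scoring the original on the reverse
#' strand.
#'
#' @param x A `pwm` object.
#' @return A `pwm` object.
#' @export
pwm_revcomp <- function(x) {
  counts <- x$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(x$counts))),
                     drop = FALSE]
  rownames(counts) <- DNA_BASES
  bg <- x$background[c("T", "G", "C", "A")]
  names(bg) <- DNA_BASES
  pwm(paste0(x$id, "_rc"), counts, background = bg,
      pseudocount = x$pseudocount, total_score = x$total_score)
}

#' Score one sequence window against a PWM
#'
#' Computes the Patser-style log-likelihood ratio
#' `sum_i log(f_i(x_i) / q(x_i))` in nats. Windows containing any non-ACGT
#' character have no defined score and return `NA`.
#'
#' @param pwm A `pwm` object.
#' @param window Character scalar of length `pwm_length(pwm)` over
#'   A/C/G/T/N (case-insensitive).
#' @return Numeric score in nats, or `NA_real_` for windows containing
#'   ambiguous bases.
#' @export
score_window <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  chars <- strsplit(toupper(window), "")[[1]]
  L <- pwm_length(pwm)
  if (length(chars) != L)
    stop(sprintf("window length %d does not match motif length %d",
                 length(chars), L))
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  lo <- pwm_logodds(pwm)
  sum(lo[cbind(idx, seq_len(L))])
}

#' Exact score distribution of a PWM under the background model
#'
#' Discretizes each column's four log-odds values onto an integer lattice of
#' width `bin_width` and convolves the columns, yielding the exact
#' distribution of the window score for an i.i.d. background sequence
#' (the classic dynamic programme used to translate score cutoffs into
#' p-values). The discretization error contributed by each column is at most
#' `bin_width / 2`.
#'
#' @param pwm A `pwm` object.
#' @param bin_width Lattice resolution in nats (> 0). Default 0.01.
#' @return An object of class `score_distribution` with elements `pwm_id`,
#'   `bin_width`, `k` (integer lattice coordinates), `prob`, `min_score`,
#'   `max_score`.
#' @export
score_distribution <- function(pwm, bin_width = 0.01) {
  stopifnot(inherits(pwm, "pwm"), bin_width > 0)
  lo <- pwm_logodds(pwm)
  kmat <- round(lo / bin_width)      # 4 x L integer lattice scores
  # zero smoothed frequency (pseudocount 0) gives -Inf log-odds; represent
  # such impossible-under-motif outcomes by a sentinel lattice value below
  # every achievable finite sum so the survival function stays exact at all
  # finite thresholds
  if (any(!is.finite(kmat))) {
    span_tot <- sum(apply(kmat, 2, function(k) {
      kf <- k[is.finite(k)]
      if (length(kf)) diff(range(kf)) else 0
    }))
    for (j in seq_len(ncol(kmat))) {
      kj <- kmat[, j]
      if (any(!is.finite(kj))) {
        base <- if (any(is.finite(kj))) min(kj[is.finite(kj)]) else 0
        kmat[!is.finite(kj), j] <- base - span_tot - 1
      }
    }
  }
  q <- pwm$background
  L <- ncol(kmat)
  # iterative convolution over columns; dist[i] = P(sum = done_lo + i - 1)
  dist <- 1
  done_lo <- 0L
  for (j in seq_len(L)) {
    kj <- kmat[, j]
    kj_min <- min(kj)
    out <- numeric(length(dist) + (max(kj) - kj_min))
    for (b in 1:4) {
      idx <- seq_along(dist) + (kj[b] - kj_min)
      out[idx] <- out[idx] + q[b] * dist
    }
    dist <- out
    done_lo <- done_lo + kj_min
  }
  k <- done_lo + seq_along(dist) - 1L
  keep <- dist > 0
  structure(
    list(pwm_id = pwm$id, bin_width = bin_width,
         k = k[keep], prob = dist[keep],
         min_score = min(k[keep]) * bin_width,
         max_score = max(k[keep]) * bin_width),
    class = "score_distribution")
}

#' Survival function of a score distribution
#'
#' @param dist A `score_distribution`.
#' @param s Numeric vector of scores (nats).
#' @return `P(S >= s)` for each element of `s`.
#' @export
score_survival <- function(dist, s) {
  surv <- rev(cumsum(rev(dist$prob)))      # P(S >= k * bw)
  vapply(s, function(si) {
    sum_idx <- which(dist$k * dist$bin_width >= si - 1e-12)
    if (length(sum_idx) == 0L) 0 else surv[sum_idx[1L]]
  }, numeric(1))
}

#' Patser-style automatic score cutoff
#'
#' Returns the smallest lattice score `s` whose background tail probability
#' satisfies `ln P(S >= s) <= -IC`, with IC the motif's information content
#' in nats. Sharper motifs (higher IC) therefore demand rarer scores. A
#' degenerate motif with IC = 0 yields the minimum score (every window
#' passes) with a warning.
#'
#' @param pwm A `pwm` object.
#' @param bin_width Lattice resolution passed to [score_distribution()].
#' @return Numeric threshold in nats.
#' @export
default_threshold <- function(pwm, bin_width = 0.01) {
  ic <- pwm_ic(pwm, base = exp(1))
  dist <- score_distribution(pwm, bin_width)
  if (ic <= .Machine$double.eps * 100) {
    warning(sprintf("PWM '%s' has zero information content; threshold = min score",
                    pwm$id))
    return(dist$min_score)
  }
  surv <- rev(cumsum(rev(dist$prob)))      # survival at support points
  bound <- exp(-ic)
  viol <- which(surv > bound)
  # the lattice survival is flat between support points, so the smallest
  # lattice score meeting the bound is one step above the last violating
  # support point (or the minimum score when nothing violates)
  if (length(viol) == 0L) return(dist$min_score)
  (dist$k[max(viol)] + 1) * dist$bin_width
}

#' Average log-likelihood ratio (ALLR) between two PWM columns
#'
#' `ALLR = [ sum_b n2_b log(p1_b/q_b) + sum_b n1_b log(p2_b/q_b) ] /
#'  (n1 + n2)` where `p` are pseudocount-smoothed frequencies. Symmetric in
#' its arguments; may be negative for dissimilar columns.
#'
#' @param c1,c2 Numeric length-4 count vectors (A, C, G, T) with positive
#'   totals.
#' @param background Base probabilities.
#' @param pseudocount Smoothing mass (see [pwm()]).
#' @return Scalar ALLR in nats.
#' @export
allr <- function(c1, c2, background = rep(0.25, 4), pseudocount = 0.375) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 <= 0 || n2 <= 0) stop("ALLR requires positive column totals")
  q <- background / sum(background)
  p1 <- (c1 + pseudocount * q) / (n1 + pseudocount)
  p2 <- (c2 + pseudocount * q) / (n2 + pseudocount)
  # a zero count contributes nothing even when the matching smoothed
  # frequency is zero (0 * log 0 = 0 by convention)
  xlogy <- function(x, y) sum(x[x > 0] * log(y[x > 0]))
  (xlogy(c2, p1 / q) + xlogy(c1, p2 / q)) / (n1 + n2)
}

# ALLR summed over an ungapped alignment at a given offset.
# offset d: column j of m2 aligns with column j + d of m1.
.allr_at_offset <- function(counts1, counts2, d, background, pseudocount) {
  L1 <- ncol(counts1); L2 <- ncol(counts2)
  j2 <- seq_len(L2)
  j1 <- j2 + d
  keep <- j1 >= 1 & j1 <= L1
  j1 <- j1[keep]; j2 <- j2[keep]
  total <- 0
  for (i in seq_along(j1))
    total <- total + allr(counts1[, j1[i]], counts2[, j2[i]],
                          background, pseudocount)
  list(allr = total, n_aligned = length(j1))
}

#' Best ungapped alignment of two PWMs
#'
#' Slides `p2` against `p1` over every ungapped offset in both orientations
#' (forward and reverse complement), requiring at least `min_overlap` aligned
#' columns, and returns the alignment maximizing the summed column ALLR.
#' The OLAP score is the aligned-column count as a percentage of the shorter
#' motif's length.
#'
#' @param p1,p2 `pwm` objects.
#' @param min_overlap Minimum aligned columns (default 5, the shortest motif
#'   length admitted to the library).
#' @param pseudocount Smoothing used for column ALLR terms.
#' @return List with `allr_total`, `olap_percent`, `offset`, `orientation`
#'   (`"forward"` or `"revcomp"`), and `n_aligned`.
#' @export
align_pwms <- function(p1, p2, min_overlap = 5,
                       pseudocount = p1$pseudocount) {
  stopifnot(inherits(p1, "pwm"), inherits(p2, "pwm"))
  L1 <- pwm_length(p1); L2 <- pwm_length(p2)
  eff_min <- min_overlap
  bg <- p1$background
  best <- NULL
  for (orient in c("forward", "revcomp")) {
    c2 <- if (orient == "forward") p2$counts else
      pwm_revcomp(p2)$counts
    for (d in seq(-(L2 - 1L), L1 - 1L)) {
      n_al <- min(L1, d + L2) - max(0L, d)
      if (n_al < eff_min) next
      res <- .allr_at_offset(p1$counts, c2, d, bg, pseudocount)
      if (is.null(best) || res$allr > best$allr_total + 1e-12) {
        best <- list(allr_total = res$allr,
                     olap_percent = 100 * res$n_aligned / min(L1, L2),
                     offset = d, orientation = orient,
                     n_aligned = res$n_aligned)
      }
    }
  }
  if (is.null(best)) stop("no offset satisfies the minimum overlap")
  best
}

#' Greedy consolidation of a redundant PWM library
#'
#' Motifs are ranked by `total_score` (ties broken by id). The top-ranked
#' motif is kept and every remaining motif redundant to it — best alignment
#' with `allr_total > allr_threshold` AND `olap_percent > olap_threshold` —
#' is removed; the procedure repeats on the remainder until exhausted.
#'
#' @param pwms List of `pwm` objects.
#' @param allr_threshold Redundancy cutoff on the summed ALLR (default 6.57).
#' @param olap_threshold Redundancy cutoff on percent overlap (default 68.1).
#' @param min_overlap Minimum aligned columns considered (default 5).
#' @return List with `kept` (list of `pwm`) and `decisions` (data.frame of
#'   kept_id, removed_id, allr_score, olap_percent, offset, orientation).
#' @export
consolidate_pwms <- function(pwms, allr_threshold = 6.57,
                             olap_threshold = 68.1, min_overlap = 5) {
  stopifnot(length(pwms) > 0)
  ids <- vapply(pwms, function(p) p$id, character(1))
  scores <- vapply(pwms, function(p) p$total_score, numeric(1))
  ord <- order(-scores, ids)
  remaining <- pwms[ord]
  kept <- list()
  dec <- list()
  while (length(remaining) > 0) {
    top <- remaining[[1L]]
    kept[[length(kept) + 1L]] <- top
    remaining <- remaining[-1L]
    if (length(remaining) == 0) break
    redundant <- logical(length(remaining))
    for (i in seq_along(remaining)) {
      al <- tryCatch(align_pwms(top, remaining[[i]], min_overlap),
                     error = function(e) NULL)
      if (!is.null(al) && al$allr_total > allr_threshold &&
          al$olap_percent > olap_threshold) {
        redundant[i] <- TRUE
        dec[[length(dec) + 1L]] <- data.frame(
          kept_id = top$id, removed_id = remaining[[i]]$id,
          allr_score = al$allr_total, olap_percent = al$olap_percent,
          offset = al$offset, orientation = al$orientation,
          stringsAsFactors = FALSE)
      }
    }
    remaining <- remaining[!redundant]
  }
  decisions <- if (length(dec)) do.call(rbind, dec) else
    data.frame(kept_id = character(), removed_id = character(),
               allr_score = numeric(), olap_percent = numeric(),
               offset = integer(), orientation = character(),
               stringsAsFactors = FALSE)
  list(kept = kept, decisions = decisions)
}
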