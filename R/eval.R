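# Statistical comparison of predicted CRMs and controls against reference
# region sets: hit calling at two overlap cutoffs, 2x2 odds-ratio tables,
# positional-shuffle nulls, feature annotation, gene-set enrichment, and the
# CRM x TF abundance matrix.

#' Prepare a reference region set
#'
#' Merges overlapping/bookended peaks and drops merged intervals longer than
#' `max_len` (large fragments likely harbour several elements plus linker).
#'
#' @param peaks Interval data.frame.
#' @param max_len Maximum merged length in bp (default 2500; strictly longer
#'   intervals are dropped).
#' @return Sorted, disjoint interval data.frame.
#' @export
prepare_reference <- function(peaks, max_len = 2500) {
  merged <- merge_intervals(peaks)
  .as_bed(merged[(merged$end - merged$start) <= max_len, , drop = FALSE])
}

#' Hit call for one reference region
#'
#' Under policy `"one_bp"` a reference is hit when any query overlaps it by
#' at least 1 bp; under `"half_shorter"` the overlap must reach 50% of the
#' shorter of the two fragments.
#'
#' @param ref Single-row interval data.frame (or list with seqid/start/end).
#' @param queries Interval data.frame.
#' @param policy `"one_bp"` or `"half_shorter"`.
#' @return Logical scalar.
#' @export
is_hit <- function(ref, queries, policy = c("one_bp", "half_shorter")) {
  policy <- match.arg(policy)
  q <- queries[queries$seqid == ref$seqid, , drop = FALSE]
  if (nrow(q) == 0) return(FALSE)
  ov <- .overlap_widths(ref$start, ref$end, q$start, q$end)
  if (policy == "one_bp") return(any(ov >= 1))
  shorter <- pmin(ref$end - ref$start, q$end - q$start)
  any(ov >= 0.5 * shorter)
}

.hit_vector <- function(refs, queries, policy) {
  vapply(seq_len(nrow(refs)), function(i)
    is_hit(refs[i, ], queries, policy), logical(1))
}

#' Evaluate predictions and controls against a reference set
#'
#' Builds the 2x2 detection table: `a` references hit by the prediction set,
#' `b` missed; `c` hit by the control set, `d` missed. The odds ratio is
#' `ad/bc` (Haldane-Anscombe +0.5 on all cells iff any cell is zero), the CI
#' is the 95% Woolf log-normal interval, and the p-value is the Pearson
#' chi-square test on the table without continuity correction.
#'
#' @param refs Prepared reference interval data.frame.
#' @param predictions,controls Interval data.frames.
#' @param policy Overlap policy, see [is_hit()].
#' @return List of class `eval_result`: a, b, c, d, sensitivity_pred,
#'   sensitivity_ctrl, odds_ratio, ci_low, ci_high, p_chi2, policy.
#' @export
evaluate_overlap <- function(refs, predictions, controls,
                             policy = c("one_bp", "half_shorter")) {
  policy <- match.arg(policy)
  if (nrow(refs) == 0) stop("no reference regions to evaluate")
  hit_p <- .hit_vector(refs, predictions, policy)
  hit_c <- .hit_vector(refs, controls, policy)
  eval_from_counts(a = sum(hit_p), b = sum(!hit_p),
                   c = sum(hit_c), d = sum(!hit_c), policy = policy)
}

#' Evaluation statistics from 2x2 counts
#'
#' @param a,b Reference regions hit / missed by the prediction set.
#' @param c,d Reference regions hit / missed by the control set.
#' @param policy Label recorded in the result.
#' @return An `eval_result` list; see [evaluate_overlap()].
#' @export
eval_from_counts <- function(a, b, c, d, policy = "one_bp") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b == c + d, a + b > 0)
  cells <- c(a, b, c, d)
  adj <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  se <- sqrt(sum(1 / adj))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  structure(list(a = a, b = b, c = c, d = d,
                 sensitivity_pred = a / (a + b),
                 sensitivity_ctrl = c / (c + d),
                 odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
                 p_chi2 = p, policy = policy),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "2x2 evaluation (%s): a=%d b=%d c=%d d=%d\n  sensitivity pred %.1f%%, ctrl %.1f%%\n  OR = %.2f [%.2f, %.2f], chi-square p = %.3g\n",
    x$policy, x$a, x$b, x$c, x$d, 100 * x$sensitivity_pred,
    100 * x$sensitivity_ctrl, x$odds_ratio, x$ci_low, x$ci_high, x$p_chi2))
  invisible(x)
}

#' Write an evaluation result as a one-row TSV
#'
#' @param res An `eval_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_tsv <- function(res, path) {
  df <- data.frame(a = res$a, b = res$b, c = res$c, d = res$d,
                   sensitivity_pred = res$sensitivity_pred,
                   sensitivity_ctrl = res$sensitivity_ctrl,
                   odds_ratio = res$odds_ratio, ci_low = res$ci_low,
                   ci_high = res$ci_high, p_chi2 = res$p_chi2,
                   policy = res$policy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positional-shuffle null for detection sensitivity
#'
#' Repeatedly repositions every prediction at a uniform random start within
#' its own sequence (lengths preserved; shuffled intervals may overlap each
#' other) and records the reference detection sensitivity of each replicate.
#' The empirical p-value uses the add-one rule
#' `(1 + #[null >= observed]) / (n_reps + 1)`.
#'
#' @param refs Prepared reference interval data.frame.
#' @param predictions Interval data.frame.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param policy Overlap policy, see [is_hit()].
#' @param n_reps Number of replicates (default 10000).
#' @param seed Integer seed.
#' @param observed Optional observed sensitivity; defaults to the
#'   sensitivity of `predictions` themselves.
#' @return List of class `null_summary`: n_reps, mean_sensitivity,
#'   sd_sensitivity (population), p_empirical, observed.
#' @export
shuffle_null <- function(refs, predictions, seq_lengths,
                         policy = c("one_bp", "half_shorter"),
                         n_reps = 10000, seed = 1L, observed = NULL) {
  policy <- match.arg(policy)
  if (nrow(refs) == 0) stop("no reference regions")
  lens <- predictions$end - predictions$start
  room <- seq_lengths[predictions$seqid] - lens
  if (any(room < 0))
    stop("prediction longer than its sequence; cannot shuffle")
  if (is.null(observed))
    observed <- mean(.hit_vector(refs, predictions, policy))
  nref <- nrow(refs)
  npred <- nrow(predictions)
  sens <- .with_seed(.derive_seed(seed, "shuffle_null"), {
    vapply(seq_len(n_reps), function(r) {
      starts <- as.integer(floor(stats::runif(npred) * (room + 1)))
      shuf <- data.frame(seqid = predictions$seqid, start = starts,
                         end = starts + lens, stringsAsFactors = FALSE)
      hits <- 0L
      for (i in seq_len(nref)) {
        q <- shuf[shuf$seqid == refs$seqid[i], , drop = FALSE]
        if (nrow(q) == 0) next
        ov <- .overlap_widths(refs$start[i], refs$end[i], q$start, q$end)
        hit <- if (policy == "one_bp") any(ov >= 1) else
          any(ov >= 0.5 * pmin(refs$end[i] - refs$start[i],
                               q$end - q$start))
        hits <- hits + as.integer(hit)
      }
      hits / nref
    }, numeric(1))
  })
  structure(list(n_reps = n_reps,
                 mean_sensitivity = mean(sens),
                 sd_sensitivity = sqrt(mean((sens - mean(sens))^2)),
                 p_empirical = (1 + sum(sens >= observed)) / (n_reps + 1),
                 observed = observed),
            class = "null_summary")
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each named gene set, tests over-representation of `query_genes` by
#' the upper-tail hypergeometric probability `P(X >= k)` with population
#' size `N`, set size `K` (after intersecting with the population) and draw
#' size `n = |query|`; p-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param query_genes Character vector (subset of `population`).
#' @param gene_sets Named list of character vectors.
#' @param population Character vector: the gene universe.
#' @param fdr Significance cutoff on the adjusted p-value (default 0.05).
#' @return data.frame with set, set_size, overlap, p, q, significant.
#' @export
hypergeom_enrich <- function(query_genes, gene_sets, population, fdr = 0.05) {
  population <- unique(population)
  if (length(population) == 0) stop("empty gene population")
  query <- unique(intersect(query_genes, population))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], population))
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), length(population) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (set name, description, genes...; tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' CRM x TF binding-site abundance matrix
#'
#' Entry `(m, t)` counts the binding sites of transcription factor `t` whose
#' midpoint falls inside CRM `m` (midpoint containment avoids double
#' counting across adjacent CRMs). Sites whose motif id has no TF mapping
#' are skipped with a warning.
#'
#' @param crms CRM interval data.frame (row order preserved).
#' @param sites Site interval data.frame with a `name` column of motif ids.
#' @param pwm_to_tf Named character vector mapping motif id to TF name; by
#'   default the motif ids themselves.
#' @return Sparse `dgCMatrix` with CRM names as rows and TFs as columns;
#'   attribute `n_skipped` counts unmapped sites.
#' @export
build_tf_matrix <- function(crms, sites, pwm_to_tf = NULL) {
  crm_names <- if (!is.null(crms$name)) crms$name else
    sprintf("CRM_%s_%d", crms$seqid, seq_len(nrow(crms)))
  if (is.null(pwm_to_tf)) {
    ids <- unique(sites$name)
    pwm_to_tf <- stats::setNames(ids, ids)
  }
  tf <- unname(pwm_to_tf[sites$name])
  n_skipped <- sum(is.na(tf))
  if (n_skipped > 0)
    warning(sprintf("%d sites with unmapped motif ids skipped", n_skipped))
  tfs <- sort(unique(stats::na.omit(unname(pwm_to_tf))))
  mat <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(),
    dims = c(nrow(crms), length(tfs)),
    dimnames = list(crm_names, tfs))
  keep <- !is.na(tf)
  if (any(keep) && nrow(crms)) {
    mid <- (sites$start + sites$end) %/% 2L
    s <- sites[keep, , drop = FALSE]
    midk <- mid[keep]
    tfk <- tf[keep]
    ii <- integer(0); jj <- integer(0)
    for (sid in unique(crms$seqid)) {
      ci <- which(crms$seqid == sid)
      si <- which(s$seqid == sid)
      if (!length(ci) || !length(si)) next
      # assign each midpoint to the CRM containing it (CRMs may overlap in
      # general input; first containing row wins by findInterval on sorted)
      for (c0 in ci) {
        inside <- si[midk[si] >= crms$start[c0] & midk[si] < crms$end[c0]]
        if (length(inside)) {
          ii <- c(ii, rep(c0, length(inside)))
          jj <- c(jj, match(tfk[inside], tfs))
        }
      }
    }
    if (length(ii))
      mat <- mat + Matrix::sparseMatrix(i = ii, j = jj,
                                        x = rep(1, length(ii)),
                                        dims = dim(mat),
                                        dimnames = dimnames(mat))
  }
  attr(mat, "n_skipped") <- n_skipped
  mat
}

#' Write a sparse matrix in Matrix Market format with name sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.rownames.txt`, `<prefix>.colnames.txt`.
#'
#' @param mat A sparse Matrix.
#' @param prefix Output path prefix.
#' @return Invisibly, the `.mtx` path.
#' @export
write_tf_matrix <- function(mat, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), mtx)
  writeLines(rownames(mat), paste0(prefix, ".rownames.txt"))
  writeLines(colnames(mat), paste0(prefix, ".colnames.txt"))
  invisible(mtx)
}

#' Read a sparse matrix written by [write_tf_matrix()]
#'
#' @param prefix Path prefix used when writing.
#' @return Sparse matrix with dimnames restored.
#' @export
read_tf_matrix <- function(prefix) {
  mat <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(mat) <- list(readLines(paste0(prefix, ".rownames.txt")),
                        readLines(paste0(prefix, ".colnames.txt")))
  mat
}
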