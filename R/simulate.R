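# Synthetic fixture generator: i.i.d. background sequence with implanted
# clusters of motif binding sites plus ground-truth BED, so the scanner,
# caller, control builder and evaluation can be exercised without any
# external genome.

#' Simulation configuration
#'
#' @param seq_length Sequence length in bp.
#' @param n_clusters Number of implanted site clusters.
#' @param cluster_len_range Length range (min, max) of a cluster in bp.
#' @param sites_per_cluster_range Range (min, max) of sites per cluster.
#' @param motif_ids Motif ids drawn from when implanting sites.
#' @param background Base probabilities for the i.i.d. background.
#' @param n_run_spec Optional list of `c(start, len)` N runs (0-based).
#' @param min_separation Minimum distance between clusters (default 200 bp).
#' @param seed Integer seed; the whole fixture is deterministic given it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seq_length = 100000, n_clusters = 20,
                       cluster_len_range = c(150, 250),
                       sites_per_cluster_range = c(6, 12),
                       motif_ids = "sim_motif",
                       background = rep(0.25, 4),
                       n_run_spec = NULL, min_separation = 200,
                       seed = 1L) {
  stopifnot(seq_length > 0, n_clusters >= 0,
            cluster_len_range[1] <= cluster_len_range[2],
            sites_per_cluster_range[1] <= sites_per_cluster_range[2],
            length(background) == 4, all(background > 0))
  structure(list(seq_length = as.integer(seq_length),
                 n_clusters = as.integer(n_clusters),
                 cluster_len_range = as.integer(cluster_len_range),
                 sites_per_cluster_range = as.integer(sites_per_cluster_range),
                 motif_ids = motif_ids,
                 background = background / sum(background),
                 n_run_spec = n_run_spec,
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample one site sequence from a PWM's smoothed frequency model
.sample_site <- function(pwm) {
  f <- pwm_freq(pwm)
  idx <- apply(f, 2, function(p) sample.int(4, 1, prob = p))
  paste(DNA_BASES[idx], collapse = "")
}

#' Generate a synthetic sequence with implanted motif clusters
#'
#' Background bases are drawn i.i.d. from the configured composition.
#' Cluster anchors are placed so clusters fit in the sequence and are
#' pairwise separated by at least `min_separation` bp. Each cluster receives
#' a uniform random number of sites, each sampled from its motif's smoothed
#' frequency model, placed without overlap on a random strand inside the
#' cluster. Optional N runs are written last (and may hide sites). Fully
#' deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param pwms List of `pwm` objects covering `config$motif_ids`.
#' @param seq_name Name of the emitted record (default "sim1").
#' @return List with `sequence` (named character), `truth` (cluster interval
#'   data.frame), `sites` (implanted site interval data.frame with name =
#'   motif id, strand).
#' @export
simulate_genome <- function(config, pwms, seq_name = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  ids <- vapply(pwms, function(p) p$id, character(1))
  if (!all(config$motif_ids %in% ids))
    stop("motif_ids not all present in the pwm library")
  maxL <- max(vapply(pwms[match(config$motif_ids, ids)], pwm_length,
                     numeric(1)))
  .with_seed(.derive_seed(config$seed, "simulate_genome"), {
    bases <- sample(DNA_BASES, config$seq_length, replace = TRUE,
                    prob = config$background)
    # place cluster anchors by rejection, enforcing pairwise separation
    clens <- if (config$n_clusters > 0)
      sample(config$cluster_len_range[1]:config$cluster_len_range[2],
             config$n_clusters, replace = TRUE) else integer(0)
    starts <- integer(0)
    guard <- 0L
    while (length(starts) < config$n_clusters) {
      k <- length(starts) + 1L
      cand <- sample.int(config$seq_length - clens[k] + 1L, 1L) - 1L
      ok <- all(abs(cand - starts) >= config$min_separation +
                  pmax(clens[seq_along(starts)], clens[k]))
      if (ok) starts <- c(starts, cand)
      guard <- guard + 1L
      if (guard > 10000L * max(1L, config$n_clusters))
        stop("cannot place clusters with the requested separation")
    }
    truth <- if (config$n_clusters > 0)
      sort_intervals(intervals(rep(seq_name, config$n_clusters),
                               starts, starts + clens,
                               name = sprintf("cluster_%d",
                                              seq_len(config$n_clusters))))
    else intervals()
    site_rows <- list()
    for (k in seq_len(config$n_clusters)) {
      n_sites <- sample(config$sites_per_cluster_range[1]:
                          config$sites_per_cluster_range[2], 1L)
      mids <- sample(config$motif_ids, n_sites, replace = TRUE)
      plist <- pwms[match(mids, ids)]
      sitelens <- vapply(plist, pwm_length, numeric(1))
      free <- clens[k] - sum(sitelens)
      if (free < 0)
        stop(sprintf("cluster %d cannot host %d sites of total length %d",
                     k, n_sites, sum(sitelens)))
      # non-overlapping placement via random gap partition (stars and bars)
      cuts <- sort(stats::runif(n_sites, 0, free))
      gaps <- floor(c(cuts[1], diff(cuts)))
      s0s <- starts[k] + cumsum(gaps) +
        c(0, cumsum(sitelens[-n_sites]))
      for (j in seq_len(n_sites)) {
        p <- plist[[j]]
        L <- pwm_length(p)
        s0 <- as.integer(s0s[j])
        strand <- sample(c("+", "-"), 1L)
        site_seq <- .sample_site(p)
        if (strand == "-")
          site_seq <- .decode_seq(rev(5L - .encode_seq(site_seq)))
        bases[(s0 + 1L):(s0 + L)] <- strsplit(site_seq, "")[[1]]
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          seqid = seq_name, start = s0, end = s0 + L, name = mids[j],
          score = 0, strand = strand, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(config$n_run_spec)) {
      for (run in config$n_run_spec) {
        idx <- (run[1] + 1L):(run[1] + run[2])
        bases[idx] <- "N"
      }
    }
    sites <- if (length(site_rows))
      sort_intervals(do.call(rbind, site_rows)) else
        intervals(character(), integer(), integer(), name = character(),
                  score = numeric(), strand = character())
    rownames(sites) <- NULL
    list(sequence = stats::setNames(paste(bases, collapse = ""), seq_name),
         truth = truth, sites = .as_bed(sites))
  })
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Returns a shuffled copy with exactly the same mono- and dinucleotide
#' counts (Altschul-Erickson Eulerian walk), destroying any implanted
#' clusters while preserving composition; useful as a matched negative.
#' Deterministic under `seed`.
#'
#' @param sequence Character scalar (A/C/G/T; N not supported here).
#' @param seed Integer seed.
#' @return Shuffled character scalar of identical length.
#' @export
dinuc_shuffle <- function(sequence, seed = 1L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 3) return(sequence)
  if (any(!chars %in% DNA_BASES))
    stop("dinuc_shuffle supports plain A/C/G/T sequences only")
  .with_seed(.derive_seed(seed, "dinuc_shuffle"), {
    # multigraph: edge for each dinucleotide; find a random Eulerian path
    # from chars[1] to chars[n] (Altschul & Erickson 1985)
    from <- chars[-n]
    to <- chars[-1]
    edges <- split(seq_len(n - 1L), from)       # outgoing edge ids per vertex
    repeat {
      # choose a random "last edge" tree pointing toward the end vertex,
      # then verify connectivity (rejection sampling)
      last_edge <- vapply(DNA_BASES, function(v) {
        e <- edges[[v]]
        if (is.null(e) || v == chars[n]) return(NA_integer_)
        e[sample.int(length(e), 1L)]
      }, integer(1))
      # the chosen last edges must lead toward chars[n] in the tree sense:
      # walk from each vertex along last edges; must reach chars[n]
      ok <- TRUE
      for (v in DNA_BASES) {
        if (is.na(last_edge[[v]])) next
        cur <- v
        steps <- 0L
        while (cur != chars[n] && steps <= 4L) {
          e <- last_edge[[cur]]
          if (is.na(e)) break
          cur <- to[e]
          steps <- steps + 1L
        }
        if (cur != chars[n]) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # shuffle the remaining edges; last edges go last
    ordered <- lapply(DNA_BASES, function(v) {
      e <- edges[[v]]
      if (is.null(e)) return(integer(0))
      le <- last_edge[[v]]
      rest <- if (!is.na(le)) setdiff(e, le) else e
      rest <- if (length(rest) > 1L) sample(rest) else rest
      c(rest, if (!is.na(le)) le)
    })
    names(ordered) <- DNA_BASES
    ptr <- stats::setNames(rep(1L, 4), DNA_BASES)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      e <- ordered[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      cur <- to[e]
      out[i] <- cur
    }
    paste(out, collapse = "")
  })
}
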