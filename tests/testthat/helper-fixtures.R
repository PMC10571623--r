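# Shared fixtures and independent oracles. Oracles are deliberately written
# in the most literal style possible (enumeration, direct simulation) and
# never call the code paths they check.

uniform_pwm <- function(L = 2, id = "uni") {
  pwm(id, matrix(1, nrow = 4, ncol = L), pseudocount = 0)
}

# 1-column A-biased motif: counts (3,1,0,0), score("A") = ln 3
a_rich_pwm <- function(id = "m1") {
  pwm(id, matrix(c(3, 1, 0, 0), nrow = 4), pseudocount = 0)
}

# sharply peaked motifs like real library PWMs: one consensus base per
# column holds most of the mass
random_pwm <- function(id, L, seed, nsites = 20, pseudocount = 0.375) {
  set.seed(seed)
  counts <- matrix(0, nrow = 4, ncol = L)
  for (j in seq_len(L)) {
    col <- c(0.9, 0.05, 0.025, 0.025) * nsites
    counts[, j] <- col[order(sample.int(4))]
  }
  pwm(id, counts, pseudocount = pseudocount)
}

# diffuse multinomial motifs (wider score spread, for distribution tests)
diffuse_pwm <- function(id, L, seed, nsites = 20, pseudocount = 0.375) {
  set.seed(seed)
  counts <- matrix(0, nrow = 4, ncol = L)
  for (j in seq_len(L))
    counts[, j] <- as.vector(stats::rmultinom(1, nsites, runif(4)))
  pwm(id, counts, pseudocount = pseudocount)
}

random_seq <- function(n, seed, n_frac = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, n, replace = TRUE)
  if (n_frac > 0) {
    k <- ceiling(n * n_frac)
    s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# enumeration oracle: exact score distribution over all 4^L windows
enumerate_scores <- function(p) {
  L <- pwm_length(p)
  grids <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  apply(grids, 1, function(row)
    score_window(p, paste(row, collapse = "")))
}

# literal window-by-window scanner oracle
brute_find_sites <- function(seq_chr, p, threshold, seqid = "seq") {
  L <- pwm_length(p)
  n <- nchar(seq_chr)
  rows <- list()
  if (n >= L) {
    for (s in 1:(n - L + 1)) {
      w <- substr(seq_chr, s, s + L - 1)
      sc <- score_window(p, w)
      if (!is.na(sc) && sc >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = seqid, start = s - 1L, end = s - 1L + L, name = p$id,
          score = sc, strand = "+", stringsAsFactors = FALSE)
      wrc <- revcomp_chr2(w)
      sc2 <- if (grepl("N", w)) NA_real_ else score_window(p, wrc)
      if (!is.na(sc2) && sc2 >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = seqid, start = s - 1L, end = s - 1L + L, name = p$id,
          score = sc2, strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand, df$name), ]
  rownames(df) <- NULL
  df
}

# revcomp for windows that may contain N (oracle-local, no Biostrings)
revcomp_chr2 <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# literal simulation of the seed/extension rule (caller oracle)
oracle_call_crms <- function(z, z_seed = 2.33, max_gap = 30) {
  n <- length(z)
  zz <- ifelse(is.na(z), -Inf, z)
  masked <- is.na(z)
  seeds <- which(zz > z_seed)
  res <- list()
  consumed <- rep(FALSE, n)
  step_to <- function(from, dir) {
    # next Z>0 position strictly less than max_gap away in direction dir,
    # with no masked position in between; NA if none
    if (max_gap < 2 || (dir > 0 && from >= n) || (dir < 0 && from <= 1))
      return(NA_integer_)
    rng <- if (dir > 0) seq(from + 1, min(n, from + max_gap - 1)) else
      seq(max(1, from - max_gap + 1), from - 1)
    cand <- rng[zz[rng] > 0]
    if (dir < 0) cand <- rev(cand)
    if (length(cand) == 0) return(NA_integer_)
    nxt <- cand[1]
    between <- if (dir > 0) seq(from + 1, nxt - 1) else seq(nxt + 1, from - 1)
    between <- between[between >= 1 & between <= n & between != nxt]
    if (length(between) && any(masked[between])) return(NA_integer_)
    nxt
  }
  for (s in seeds) {
    if (consumed[s]) next
    left <- s; right <- s
    repeat {
      nxt <- step_to(right, +1)
      if (is.na(nxt)) break
      right <- nxt
    }
    repeat {
      nxt <- step_to(left, -1)
      if (is.na(nxt)) break
      left <- nxt
    }
    consumed[left:right] <- TRUE
    res[[length(res) + 1L]] <- c(left - 1L, right)
  }
  if (length(res) == 0)
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, res)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df <- df[order(df$start), , drop = FALSE]
  # merge overlapping or bookended
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], df$end[i])
    } else out <- rbind(out, df[i, ])
  }
  rownames(out) <- NULL
  out
}

random_z_track <- function(n, seed, mask_frac = 0.02) {
  set.seed(seed)
  z <- rnorm(n, mean = -0.2, sd = 1.2)
  if (mask_frac > 0) z[sample.int(n, ceiling(n * mask_frac))] <- NA
  z
}

# wrap a raw z vector as a z_track for call_crms
as_z_track <- function(z) {
  structure(list(z = z,
                 stats = list(mu = 0, sigma = 1, n_positions = sum(!is.na(z))),
                 n_mask = is.na(z)),
            class = "z_track")
}

# standard end-to-end fixture used across modules (matches the documented
# generator defaults; seed 1)
standard_fixture <- function(seed = 1L) {
  motif <- demo_cluster_motif()
  cfg <- sim_config(seq_length = 100000, n_clusters = 20,
                    cluster_len_range = c(150, 250),
                    sites_per_cluster_range = c(6, 12),
                    motif_ids = motif$id, seed = seed)
  sim <- simulate_genome(cfg, list(motif))
  list(cfg = cfg, sim = sim, motif = motif)
}
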