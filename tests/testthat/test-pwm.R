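# PWM representation, scoring, exact score distributions, thresholds,
# ALLR similarity and greedy consolidation.

test_that("score_window matches hand arithmetic and the degenerate rules", {
  u <- uniform_pwm(2)
  expect_equal(score_window(u, "AC"), 0)
  expect_equal(score_window(u, "tg"), 0)          # case-insensitive

  m1 <- a_rich_pwm()
  expect_equal(score_window(m1, "A"), log(3))
  expect_equal(score_window(m1, "C"), log(1 / 0.25 * 0.25))  # ln(0.25/0.25)=0
  expect_identical(score_window(m1, "G"), -Inf)   # zero count, no pseudocount

  expect_true(is.na(score_window(uniform_pwm(3), "ANA")))
  expect_error(score_window(m1, "AA"), "length")
})

test_that("pwm validation and invariants hold", {
  expect_error(pwm("x", matrix(1, nrow = 3, ncol = 2)), "4 rows")
  expect_error(pwm("x", matrix(-1, nrow = 4, ncol = 1)), "nonnegative")
  expect_error(pwm("x", matrix(1, nrow = 4), background = c(1, 1, 1, 1)),
               "summing to 1")
  # smoothed frequencies strictly in (0,1) with positive pseudocount
  p <- pwm("x", matrix(c(5, 0, 0, 0), nrow = 4))
  f <- pwm_freq(p)
  expect_true(all(f > 0 & f < 1))
  expect_equal(colSums(f), 1, ignore_attr = TRUE)
  # IC nonnegative, zero iff background
  expect_equal(pwm_ic(uniform_pwm(4)), 0)
  expect_gt(pwm_ic(p), 0)
})

test_that("score_distribution equals brute-force enumeration for L <= 4", {
  for (cfg in list(list(L = 1, seed = 11), list(L = 2, seed = 12),
                   list(L = 3, seed = 13), list(L = 4, seed = 14))) {
    p <- diffuse_pwm(sprintf("r%d", cfg$L), cfg$L, cfg$seed)
    d <- score_distribution(p, bin_width = 0.01)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    scores <- enumerate_scores(p)
    # each enumerated score carries probability prod(background) = 4^-L
    for (s in unique(round(scores, 3))) {
      exact <- mean(scores >= s - 1e-9)
      lattice <- score_survival(d, s - cfg$L * 0.01 / 2)
      lattice_hi <- score_survival(d, s + cfg$L * 0.01 / 2)
      expect_true(exact <= lattice + 1e-9 && exact >= lattice_hi - 1e-9,
                  label = sprintf("survival bracket at %.3f (L=%d)", s, cfg$L))
    }
  }
})

test_that("single-column distributions are exact", {
  u <- uniform_pwm(1)
  d <- score_distribution(u)
  expect_equal(length(d$prob), 1L)
  expect_equal(d$prob, 1)
  expect_equal(d$min_score, 0)
  expect_equal(score_survival(d, d$min_score), 1)
})

test_that("default_threshold obeys the ln-p <= -IC rule with minimality", {
  # hand-checkable 1-column case: pseudocount 0.4 on counts (1,0,0,0)
  p <- pwm("a1", matrix(c(1, 0, 0, 0), nrow = 4), pseudocount = 0.4)
  thr <- default_threshold(p)
  ic <- pwm_ic(p, base = exp(1))
  d <- score_distribution(p)
  # brute force over the 4 outcomes
  sc <- vapply(c("A", "C", "G", "T"), function(b) score_window(p, b),
               numeric(1))
  surv_at <- function(s) mean(sc >= s - 1e-9)
  expect_lte(log(surv_at(thr)), -ic)
  # next-lower lattice score fails the bound (half-bin slack because exact
  # scores sit up to bin_width/2 off their lattice point)
  expect_gt(log(surv_at(thr - 0.01 - 0.005)), -ic)
  # only the A outcome passes the threshold
  expect_identical(sc >= thr, c(A = TRUE, C = FALSE, G = FALSE, T = FALSE))

  # degenerate: IC = 0 -> threshold = min score, warning
  expect_warning(t0 <- default_threshold(uniform_pwm(2)), "information")
  expect_equal(t0, 0)
})

test_that("default_threshold minimality holds on random motifs (property)", {
  for (seed in 1:6) {
    p <- diffuse_pwm(sprintf("p%d", seed), L = sample(2:5, 1), seed = seed)
    thr <- default_threshold(p)
    ic <- pwm_ic(p, base = exp(1))
    d <- score_distribution(p)
    expect_lte(log(max(score_survival(d, thr), .Machine$double.xmin)), -ic)
    expect_gt(log(score_survival(d, thr - d$bin_width)), -ic)
  }
})

test_that("allr matches hand arithmetic and is symmetric", {
  # both columns equal background composition -> 0
  expect_equal(allr(c(1, 1, 1, 1), c(2, 2, 2, 2), pseudocount = 0), 0)
  # identical concentrated columns
  expect_equal(allr(c(10, 0, 0, 0), c(10, 0, 0, 0), pseudocount = 0), log(4))
  # symmetry on random columns
  set.seed(42)
  for (i in 1:10) {
    c1 <- rmultinom(1, 20, runif(4))[, 1]
    c2 <- rmultinom(1, 15, runif(4))[, 1]
    expect_equal(allr(c1, c2), allr(c2, c1))
  }
  expect_error(allr(c(0, 0, 0, 0), c(1, 0, 0, 0)), "positive")
})

test_that("self-ALLR dominates ALLR against a background column", {
  set.seed(7)
  for (i in 1:10) {
    c1 <- rmultinom(1, 20, runif(4))[, 1]
    bgcol <- rep(5, 4)
    expect_gte(allr(c1, c1) + 1e-12, allr(c1, bgcol))
  }
})

test_that("align_pwms finds self, padded, and reverse-complement optima", {
  p1 <- random_pwm("p1", 8, seed = 21, nsites = 30, pseudocount = 0.375)
  self <- align_pwms(p1, p1)
  expect_equal(self$offset, 0L)
  expect_equal(self$orientation, "forward")
  expect_equal(self$olap_percent, 100)
  expect_gt(self$allr_total, 0)

  # p2 = p1 with 2 uniform flanking columns each side; expect offset 2 and
  # 100% overlap measured against the shorter matrix
  pad <- matrix(7.5, nrow = 4, ncol = 2)
  p2 <- pwm("p2", cbind(pad, p1$counts, pad))
  al <- align_pwms(p1, p2)
  expect_equal(al$offset, -2L)
  expect_equal(al$olap_percent, 100)

  # reverse complement orientation recovers the self-alignment score
  p3 <- pwm_revcomp(p1)
  al3 <- align_pwms(p1, p3)
  expect_equal(al3$orientation, "revcomp")
  expect_equal(al3$allr_total, self$allr_total, tolerance = 1e-9)

  expect_error(align_pwms(p1, p3, min_overlap = 20), "overlap")
})

test_that("consolidate keeps the strongest and removes redundancy", {
  base <- random_pwm("dup_a", 8, seed = 31, nsites = 40)
  twin <- pwm("dup_b", base$counts, total_score = base$total_score - 1)
  res <- consolidate_pwms(list(base, twin))
  expect_length(res$kept, 1L)
  expect_equal(res$kept[[1]]$id, "dup_a")
  expect_equal(nrow(res$decisions), 1L)
  expect_equal(res$decisions$removed_id, "dup_b")

  # {A, B, C}: B redundant to A, C unrelated
  A <- random_pwm("A", 8, seed = 32, nsites = 50)
  B <- pwm("B", A$counts + matrix(rpois(32, 0.2), nrow = 4),
           total_score = A$total_score - 5)
  C <- random_pwm("C", 6, seed = 99, nsites = 30)
  al_ab <- align_pwms(A, B)
  expect_gt(al_ab$allr_total, 6.57)   # fixture sanity: A/B are redundant
  res2 <- consolidate_pwms(list(C, A, B))
  kept_ids <- vapply(res2$kept, function(p) p$id, character(1))
  expect_true("A" %in% kept_ids)
  expect_false("B" %in% kept_ids)

  # all dissimilar: nothing removed; idempotence
  lib <- list(random_pwm("x1", 7, 41), random_pwm("x2", 7, 4242),
              random_pwm("x3", 9, 43))
  r1 <- consolidate_pwms(lib)
  r2 <- consolidate_pwms(r1$kept)
  expect_length(r2$kept, length(r1$kept))
  expect_equal(nrow(r2$decisions), 0L)
})

test_that("JASPAR and MEME round trips preserve the model", {
  pwms <- list(random_pwm("MA0001.1", 6, 61, nsites = 24),
               random_pwm("MA0002.1", 9, 62, nsites = 24))
  jf <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, jf)
  back <- read_jaspar(jf)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$counts, pwms[[1]]$counts, ignore_attr = TRUE)
  expect_equal(back[[2]]$id, "MA0002.1")

  mf <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, mf)
  back2 <- read_meme(mf)
  expect_equal(length(back2), 2L)
  # the smoothed model survives the round trip (MEME stores probabilities,
  # so re-smoothing on read perturbs frequencies by O(pseudocount/nsites))
  expect_equal(pwm_freq(back2[[1]]), pwm_freq(pwms[[1]]),
               tolerance = 2e-2, ignore_attr = TRUE)
  # dialect sniffing
  expect_equal(length(read_motifs(jf)), 2L)
  expect_equal(length(read_motifs(mf)), 2L)
})
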