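# Reference preparation, overlap policies, 2x2 statistics, shuffle null,
# enrichment, annotation, and the CRM x TF matrix.

test_that("prepare_reference merges then filters long modules", {
  peaks <- intervals(c("c1", "c1"), c(0, 900), c(1000, 2000))
  ref <- prepare_reference(peaks)
  expect_equal(nrow(ref), 1L)
  expect_equal(c(ref$start, ref$end), c(0L, 2000L))
  # merged length 2600 dropped
  peaks2 <- intervals(c("c1", "c1"), c(0, 1200), c(1300, 2600))
  expect_equal(nrow(prepare_reference(peaks2)), 0L)
  expect_equal(nrow(prepare_reference(intervals())), 0L)
})

test_that("is_hit implements both overlap cutoffs", {
  ref <- intervals("c1", 0, 100)
  q1 <- intervals("c1", 99, 200)           # 1 bp overlap
  expect_true(is_hit(ref[1, ], q1, "one_bp"))
  expect_false(is_hit(ref[1, ], q1, "half_shorter"))
  expect_true(is_hit(ref[1, ], ref, "half_shorter"))   # identical
  q2 <- intervals("c1", 40, 200)           # overlap 60 >= 0.5*min(100,160)
  expect_true(is_hit(ref[1, ], q2, "half_shorter"))
  # different sequence never hits
  expect_false(is_hit(ref[1, ], intervals("c2", 0, 100), "one_bp"))
  # half_shorter hits are a subset of one_bp hits (property)
  set.seed(31)
  for (i in 1:25) {
    r <- intervals("x", 500, 500 + sample(50:300, 1))
    q <- intervals("x", sample(300:800, 3), sample(850:1200, 3))
    if (is_hit(r[1, ], q, "half_shorter"))
      expect_true(is_hit(r[1, ], q, "one_bp"))
  }
})

test_that("evaluate reproduces the published 2x2 statistics", {
  mouse <- eval_from_counts(77, 20, 26, 71)
  expect_equal(mouse$odds_ratio, 10.51, tolerance = 0.001)
  expect_lte(mouse$p_chi2, 2.5e-13)
  expect_true(mouse$ci_low <= mouse$odds_ratio &
                mouse$odds_ratio <= mouse$ci_high)

  human <- eval_from_counts(34, 26, 12, 48)
  expect_equal(human$odds_ratio, 5.23, tolerance = 0.001)
  expect_lte(human$p_chi2, 3.9e-05)

  # independence: equal rows give OR 1, p 1
  ind <- eval_from_counts(30, 20, 30, 20)
  expect_equal(ind$odds_ratio, 1)
  expect_equal(ind$p_chi2, 1)

  # zero cell triggers the Haldane-Anscombe correction
  z <- eval_from_counts(50, 0, 25, 25)
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio > 1)
  expect_error(eval_from_counts(1, 1, 2, 1), "a \\+ b == c \\+ d")
})

test_that("evaluate_overlap fills the table from interval hit calls", {
  refs <- intervals(rep("c1", 4), c(0, 200, 400, 600), c(100, 300, 500, 700))
  preds <- intervals(rep("c1", 2), c(50, 250), c(150, 280))
  ctrls <- intervals("c1", 650, 660)
  res <- evaluate_overlap(refs, preds, ctrls, "one_bp")
  expect_equal(c(res$a, res$b, res$c, res$d), c(2L, 2L, 1L, 3L))
  expect_equal(res$sensitivity_pred, 0.5)
  expect_error(evaluate_overlap(intervals(), preds, ctrls), "no reference")
})

test_that("shuffle_null trivial cases behave as stated", {
  lens <- c(s1 = 1000L)
  refs <- intervals("s1", 450, 550)
  # prediction covering the whole sequence: no freedom, SD 0
  whole <- intervals("s1", 0, 1000)
  ns <- shuffle_null(refs, whole, lens, "one_bp", n_reps = 50, seed = 5)
  expect_equal(ns$sd_sensitivity, 0)
  expect_equal(ns$mean_sensitivity, 1)
  # predictions confined to another sequence: sensitivity 0
  lens2 <- c(s1 = 1000L, s2 = 1000L)
  other <- intervals("s2", 0, 100)
  ns2 <- shuffle_null(refs, other, lens2, "one_bp", n_reps = 50, seed = 5)
  expect_equal(ns2$mean_sensitivity, 0)
  expect_error(shuffle_null(refs, intervals("s1", 0, 1500), lens),
               "longer than its sequence")
})

test_that("shuffle_null matches the closed-form overlap probability", {
  # one 100 bp interval shuffled in 1000 bp vs a central 100 bp reference:
  # P(overlap >= 1) = 199/901
  lens <- c(s1 = 1000L)
  refs <- intervals("s1", 450, 550)
  pred <- intervals("s1", 0, 100)
  ns <- shuffle_null(refs, pred, lens, "one_bp", n_reps = 4000, seed = 7)
  p0 <- 199 / 901
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(ns$mean_sensitivity - p0), 3 * se)
  expect_gt(ns$p_empirical, 0)
  expect_lte(ns$p_empirical, 1)
})

test_that("hypergeom_enrich matches hand combinatorics and BH rules", {
  pop <- sprintf("g%02d", 1:10)
  sets <- list(hit_set = pop[1:5], null_set = pop[6:10])
  # query of 4 genes all inside hit_set: p = C(5,4)C(5,0)/C(10,4) = 5/210
  tab <- hypergeom_enrich(pop[1:4], sets["hit_set"], pop)
  expect_equal(tab$p, 5 / 210, tolerance = 1e-12)
  expect_equal(tab$q, tab$p)                      # single test: q = p
  # zero overlap: p = 1
  tab2 <- hypergeom_enrich(pop[1:4], sets["null_set"], pop)
  expect_equal(tab2$p, stats::phyper(-1, 5, 5, 4, lower.tail = FALSE))
  expect_equal(tab2$p, 1)
  expect_error(hypergeom_enrich("g01", sets, character(0)), "empty")
  # BH across both sets
  tab3 <- hypergeom_enrich(pop[1:4], sets, pop)
  expect_equal(tab3$q, stats::p.adjust(tab3$p, "BH"))
})

test_that("GMT round trip works", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g4")
})

test_that("build_tf_matrix counts site midpoints per CRM", {
  crms <- intervals(c("c1", "c1"), c(0, 200), c(100, 300),
                    name = c("crm1", "crm2"))
  sites <- intervals(rep("c1", 3), c(10, 40, 70), c(20, 50, 80),
                     name = rep("X", 3), score = 1, strand = "+")
  mat <- build_tf_matrix(crms, sites)
  expect_equal(dim(mat), c(2L, 1L))
  expect_equal(as.numeric(mat["crm1", "X"]), 3)
  expect_equal(as.numeric(mat["crm2", "X"]), 0)
  # unmapped ids: warning + skip
  expect_warning(
    mat2 <- build_tf_matrix(crms, sites, pwm_to_tf = c(Y = "TF_Y")),
    "unmapped")
  expect_equal(sum(mat2), 0)
  expect_equal(attr(mat2, "n_skipped"), 3L)
  # empty sites: zero matrix of correct shape
  empty_sites <- intervals(character(), integer(), integer(),
                           name = character())
  mat3 <- build_tf_matrix(crms, empty_sites, pwm_to_tf = c(X = "X"))
  expect_equal(dim(mat3), c(2L, 1L))
  expect_equal(sum(mat3), 0)
})

test_that("Matrix Market round trip is exact", {
  crms <- intervals(rep("c1", 3), c(0, 200, 400), c(100, 300, 500),
                    name = sprintf("m%d", 1:3))
  set.seed(8)
  starts <- sample(0:490, 20)
  sites <- intervals(rep("c1", 20), starts, starts + 10L,
                     name = sample(c("tf1", "tf2"), 20, replace = TRUE))
  mat <- build_tf_matrix(crms, sites)
  prefix <- file.path(withr::local_tempdir(), "tfmat")
  write_tf_matrix(mat, prefix)
  back <- read_tf_matrix(prefix)
  expect_equal(as.matrix(back), as.matrix(mat))
})

test_that("annotate_features applies the precedence ladder", {
  # two genes: g1 on [10000, 20000) + with exon [10000,11000) and
  # intron beyond; g2 TSS at 26000 (+)
  tx <- intervals(c("g", "g"), c(10000, 26000), c(20000, 30000),
                  strand = c("+", "+"))
  ex <- intervals(c("g", "g"), c(10000, 26000), c(11000, 26500))
  ann <- annotation_model(tx, exons = ex)
  regions <- intervals(
    rep("g", 5),
    c(9900,   15000, 24000, 31500, 50000),
    c(10100,  15100, 24100, 31600, 50100))
  got <- annotate_features(regions, ann)
  expect_equal(as.character(got$category),
               c("Promoter",            # straddles g1 TSS
                 "Intron",              # inside g1, not exonic
                 "Promoter",            # within 3 kb of g2 TSS (precedence)
                 "Downstream",          # 1.5 kb past g2 end
                 "Distal Intergenic"))
  # intronic region within 3 kb of ANOTHER gene TSS is Promoter
  r2 <- intervals("g", 18500, 18600)    # inside g1 but far from TSSs
  expect_equal(as.character(annotate_features(r2, ann)$category), "Intron")
  r3 <- intervals("g", 23500, 23600)    # intergenic, 2.4 kb from g2 TSS
  expect_equal(as.character(annotate_features(r3, ann)$category), "Promoter")
  # distribution sums to 100
  expect_equal(sum(got$distribution$percent), 100, tolerance = 0.1)
})
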