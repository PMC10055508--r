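test_that("discriminant is the configured combination and order-preserving", {
  ps <- toy_psms(disc = c(1.5, 2.5, 0.5))
  ps$xcorr <- c(2, 4, 8)
  ps$deltacn <- c(0.1, 0.2, 0.3)

  expect_equal(discriminant_score(ps, c(disc = 1)), ps$disc)
  expect_equal(discriminant_score(ps, c(disc = 0, xcorr = 0)), c(0, 0, 0))
  expect_equal(
    discriminant_score(ps, c(xcorr = 1, deltacn = 4),
                       log_transform = "xcorr"),
    log(ps$xcorr) + 4 * ps$deltacn)

  # higher raw score with positive weight -> higher discriminant
  two <- ps[c(1, 1), ]
  two$xcorr <- c(2, 3)
  d <- discriminant_score(two, c(xcorr = 2, deltacn = 1))
  expect_gt(d[2], d[1])

  expect_error(discriminant_score(ps, c(nope = 1)), "missing score")
})

test_that("threshold FDR is the capped decoy/target ratio", {
  ps <- toy_psms(disc = c(rep(5, 100), 5, rep(-1, 20)),
                 is_decoy = c(rep(FALSE, 100), TRUE, rep(TRUE, 20)))
  expect_equal(fdr_at_threshold(ps, 0), 1 / 100)
  eq <- toy_psms(disc = rep(3, 10), is_decoy = rep(c(TRUE, FALSE), 5))
  expect_equal(fdr_at_threshold(eq, 0), 1)  # capped
  only_dec <- toy_psms(disc = c(5, -5), is_decoy = c(TRUE, FALSE))
  expect_error(fdr_at_threshold(only_dec, 4),
               class = "spcenrich_undefined_fdr")
})

test_that("FDR curves are non-increasing in the threshold after monotonization", {
  set.seed(21)
  ps <- toy_psms(disc = c(rnorm(400, 2), rnorm(200)),
                 is_decoy = c(rep(FALSE, 400), rep(TRUE, 200)))
  h <- build_score_histograms(ps, bin_width = 0.1, min_decoys = 10)
  cv <- fdr_curve(h$pooled)
  expect_true(all(diff(cv$fdr) <= 1e-12))
  expect_true(all(cv$fdr <= cv$fdr_raw + 1e-12))
  # totals per subclass equal the histogram mass
  sc <- h$subclasses[[1]]
  expect_equal(sum(sc$target_counts) + sum(sc$decoy_counts),
               sum(!ps$is_decoy) + sum(ps$is_decoy))
})

test_that("single-subclass threshold equals the exhaustive bin-edge scan", {
  set.seed(22)
  ps <- toy_psms(disc = c(rnorm(2000, 3), rnorm(1000)),
                 is_decoy = c(rep(FALSE, 2000), rep(TRUE, 1000)))
  h <- build_score_histograms(ps, bin_width = 0.1, min_decoys = 10)
  thr <- threshold_search(h, target_fdr = 0.01)

  # oracle: smallest edge whose decoy/target ratio above it is <= 1%
  edges <- h$bin_edges[-length(h$bin_edges)]
  ok <- vapply(edges, function(t) {
    nt <- sum(ps$disc >= t & !ps$is_decoy)
    nd <- sum(ps$disc >= t & ps$is_decoy)
    nt > 0 && nd / nt <= 0.01
  }, TRUE)
  expect_equal(unname(thr[[1]]), min(edges[ok]))
  expect_lte(attr(thr, "pooled_fdr"), 0.01)
})

test_that("threshold search is permissive when decoys never outrank targets", {
  ps <- toy_psms(disc = c(rnorm(500, 10), rnorm(300, -10)),
                 is_decoy = c(rep(FALSE, 500), rep(TRUE, 300)))
  h <- build_score_histograms(ps, min_decoys = 10)
  thr <- threshold_search(h, target_fdr = 0.01)
  acc <- filter_psms(ps, thr, min_length = 1)
  expect_equal(sum(!acc$is_decoy), 500)
  expect_equal(attr(thr, "pooled_fdr"), 0)
})

test_that("accepted set shrinks as the FDR target tightens", {
  set.seed(23)
  ps <- toy_psms(disc = c(rnorm(2000, 2.5), rnorm(1000)),
                 is_decoy = c(rep(FALSE, 2000), rep(TRUE, 1000)))
  h <- build_score_histograms(ps, min_decoys = 10)
  sizes <- vapply(c(0.10, 0.05, 0.01, 1e-6), function(q)
    nrow(filter_psms(ps, threshold_search(h, q), min_length = 1)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("filtering enforces the minimum peptide length and subclass coverage", {
  ps <- toy_psms(disc = c(100, 5), peptide = c("SHORTK", "LONGPEPTIDEK"))
  ps$is_decoy <- c(FALSE, FALSE)
  h <- build_score_histograms(
    toy_psms(disc = c(ps$disc, -1), is_decoy = c(FALSE, FALSE, TRUE)),
    min_decoys = 1)
  thr <- threshold_search(h, 0.5)
  acc <- filter_psms(ps, thr, min_length = 7)
  expect_equal(acc$peptide, "LONGPEPTIDEK")   # length-6 top scorer excluded

  expect_equal(nrow(filter_psms(ps[0, ], thr)), 0)

  other <- toy_psms(disc = 5, charge = 4L, mod_state = "oxidized")
  named_only <- setNames(1, spcenrich:::subclass_key(2L, "unmodified", 0L))
  expect_error(filter_psms(other, named_only), "cover all subclasses")
  with_pooled <- c(named_only, pooled = 1)
  expect_equal(nrow(filter_psms(other, with_pooled)), 1)
})

test_that("sparse-decoy subclasses fall back to the pooled histogram", {
  set.seed(24)
  main <- toy_psms(disc = c(rnorm(1000, 3), rnorm(500)),
                   is_decoy = c(rep(FALSE, 1000), rep(TRUE, 500)))
  rare <- toy_psms(disc = c(rnorm(30, 3), rnorm(5)), charge = 4L,
                   is_decoy = c(rep(FALSE, 30), rep(TRUE, 5)))
  ps <- rbind(main, rare)
  h <- build_score_histograms(ps, min_decoys = 50)
  expect_false(h$subclasses[[spcenrich:::subclass_key(2L, "unmodified", 0L)]]$fallback)
  expect_true(h$subclasses[[spcenrich:::subclass_key(4L, "unmodified", 0L)]]$fallback)
  thr <- threshold_search(h, 0.01)
  expect_lte(attr(thr, "pooled_fdr"), 0.01)
})

test_that("PSM tables and threshold reports round-trip through TSV", {
  db <- make_database(30, 1, length_range = c(40, 80), seed = 31)
  sim <- simulate_psms(db, 300, p_correct = 0.6, seed = 32)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(sim$psms, path)
  back <- read_psm_table(path)
  expect_equal(back$peptide, sim$psms$peptide)
  expect_equal(back$disc, sim$psms$disc, tolerance = 1e-12)
  expect_equal(back$is_decoy, sim$psms$is_decoy)

  res <- filter_psms_fdr(sim$psms, target_fdr = 0.05, min_decoys = 10)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_thresholds(res$thresholds, tpath)
  rep <- read.delim(tpath)
  expect_setequal(rep$subclass, names(res$thresholds))
})
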