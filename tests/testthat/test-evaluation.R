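# Protocols, threshold selection, error rates and SVM score fusion.

mk_manifest <- function(n_subj = 10, n_samp = 5, hand = "LH",
                        incomplete = integer(0)) {
  m <- expand.grid(sample_index = 0:(n_samp - 1), subject_id = sprintf("S%02d", 1:n_subj),
                   stringsAsFactors = FALSE)
  data.frame(subject_id = m$subject_id, hand = hand,
             sample_index = m$sample_index,
             complete = !(seq_len(nrow(m)) %in% incomplete))
}

test_that("a 10x5 manifest yields 10 enrolments, 40 probes, 160 comparisons", {
  bp <- build_protocol(mk_manifest(), protocol_def("LH"), seed = 1)
  expect_equal(nrow(bp$enrolled), 10)
  expect_equal(nrow(bp$probes), 40)
  expect_equal(nrow(bp$comparisons), 160)
  expect_equal(sum(bp$comparisons$is_genuine), 40)
  # every probe gets 3 distinct ZEI identities, none its own
  zei <- bp$comparisons[!bp$comparisons$is_genuine, ]
  by_probe <- split(zei$enrolled_subject, paste(zei$probe_subject, zei$probe_sample))
  expect_true(all(vapply(by_probe, function(x) length(unique(x)) == 3, logical(1))))
  expect_false(any(zei$enrolled_subject == zei$probe_subject))
})

test_that("the comparison list is reproducible under the same seed", {
  a <- build_protocol(mk_manifest(), protocol_def("LH"), seed = 42)
  b <- build_protocol(mk_manifest(), protocol_def("LH"), seed = 42)
  expect_identical(a$comparisons, b$comparisons)
  c <- build_protocol(mk_manifest(), protocol_def("LH"), seed = 43)
  expect_false(identical(a$comparisons, c$comparisons))
})

test_that("incomplete samples are excluded and small pools rejected", {
  mf <- mk_manifest(incomplete = c(1, 7, 12))   # 3 samples marked incomplete
  bp <- build_protocol(mf, protocol_def("LH"), seed = 1)
  expect_equal(nrow(bp$enrolled) + nrow(bp$probes), 47)
  expect_error(build_protocol(mk_manifest(n_subj = 3), protocol_def("LH")),
               "ZEI")
  expect_error(build_protocol(mk_manifest(hand = "RH"), protocol_def("LH")),
               "no usable samples")
})

test_that("threshold_at_fmr matches an exhaustive sweep on random score sets", {
  for (i in 1:100) {
    sc <- with_seed_test(i, data.frame(
      score = c(runif(60), runif(25, 0.4, 1.4)),
      is_genuine = c(rep(FALSE, 60), rep(TRUE, 25))))
    target <- with_seed_test(1000 + i, sample(c(0.5, 2, 5, 10, 25), 1))
    thr <- threshold_at_fmr(sc, target)
    imp <- sc$score[!sc$is_genuine]
    # oracle: sweep every candidate threshold in the impostor grid
    cands <- sort(unique(imp))
    ok <- cands[vapply(cands, function(t) 100 * mean(imp >= t) <= target, logical(1))]
    if (length(ok)) expect_equal(thr, ok[1]) else expect_gt(thr, max(imp))
    expect_lte(100 * mean(imp >= thr), target)
    # no smaller admissible threshold exists on the grid
    smaller <- cands[cands < thr]
    if (length(smaller))
      expect_true(all(vapply(smaller, function(t) 100 * mean(imp >= t),
                             numeric(1)) > target))
  }
})

test_that("impostor grid: target 10% on a 10-point grid admits exactly one", {
  sc <- data.frame(score = c(seq(0.1, 1, 0.1), 1.5), is_genuine = c(rep(FALSE, 10), TRUE))
  thr <- threshold_at_fmr(sc, 10)
  imp <- sc$score[!sc$is_genuine]
  expect_equal(sum(imp >= thr), 1)
})

test_that("below-resolution targets give FMR 0 with a threshold above all impostors", {
  sc <- data.frame(score = c(runif(20, 0, 0.5), 0.9, 0.95),
                   is_genuine = c(rep(FALSE, 20), TRUE, TRUE))
  thr <- threshold_at_fmr(sc, 0)
  expect_gt(thr, max(sc$score[!sc$is_genuine]))
  expect_equal(evaluate_scores(sc, thr)$fmr_pct, 0)
  # all impostor scores equal: rates can only jump 0 <-> 100
  sc2 <- data.frame(score = c(rep(0.5, 10), 0.8), is_genuine = c(rep(FALSE, 10), TRUE))
  expect_gt(threshold_at_fmr(sc2, 50), 0.5)   # <= 50% forces the 0% side
  expect_equal(threshold_at_fmr(sc2, 100), 0.5)
  expect_error(threshold_at_fmr(data.frame(score = 1, is_genuine = TRUE), 1),
               "no impostor")
})

test_that("evaluate_scores computes FMR/FNMR/HTER with the accept-at rule", {
  sc <- data.frame(score = c(0.2, 0.4, 0.6, 0.8, 0.5, 0.7),
                   is_genuine = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  ev <- evaluate_scores(sc, 0.6)
  expect_equal(ev$fmr_pct, 50)    # 0.6 and 0.8 accepted
  expect_equal(ev$fnmr_pct, 50)   # 0.5 rejected, 0.7 accepted
  expect_equal(ev$hter_pct, 50)
  perfect <- evaluate_scores(data.frame(score = c(0.1, 0.9),
                                        is_genuine = c(FALSE, TRUE)), 0.5)
  expect_equal(c(perfect$fmr_pct, perfect$fnmr_pct, perfect$hter_pct), c(0, 0, 0))
  expect_error(evaluate_scores(data.frame(score = 1, is_genuine = TRUE), 0.5),
               "undefined-rate")
})

test_that("the HTER identity holds to machine precision on random rates", {
  for (i in 1:50) {
    sc <- with_seed_test(i, data.frame(score = runif(40),
                                       is_genuine = rep(c(TRUE, FALSE), 20)))
    thr <- with_seed_test(i + 1, runif(1))
    ev <- evaluate_scores(sc, thr)
    expect_equal(ev$hter_pct, 0.5 * (ev$fmr_pct + ev$fnmr_pct), tolerance = 1e-12)
    expect_equal(hter(ev$fmr_pct, ev$fnmr_pct), ev$hter_pct, tolerance = 1e-12)
  }
})

test_that("raising the threshold never raises FMR nor lowers FNMR", {
  sc <- with_seed_test(3, data.frame(score = runif(100),
                                     is_genuine = rep(c(TRUE, FALSE), 50)))
  ths <- seq(0, 1, 0.05)
  evs <- lapply(ths, function(t) evaluate_scores(sc, t))
  fmr <- vapply(evs, `[[`, numeric(1), "fmr_pct")
  fnmr <- vapply(evs, `[[`, numeric(1), "fnmr_pct")
  expect_true(all(diff(fmr) <= 0))
  expect_true(all(diff(fnmr) >= 0))
})

test_that("fusion vectors require all three finger scores", {
  st <- score_table(rep(c("p1", "p2"), each = 3), rep("e1", 6),
                    rep(c("index", "middle", "ring"), 2), "P1",
                    seq(0.1, 0.6, 0.1), rep(c(TRUE, FALSE), each = 3))
  fv <- fusion_vectors(st)
  expect_equal(nrow(fv), 2)
  # drop one finger of p2 -> p2 excluded
  fv2 <- fusion_vectors(st[-4, ])
  expect_equal(nrow(fv2), 1)
  expect_equal(fv2$probe_id, "p1")
})

test_that("SVM fusion separates well-separated clouds with eval HTER <= 1%", {
  mk_cloud <- function(n, mu, seed) with_seed_test(seed, data.frame(
    probe_id = sprintf("p%d", 1:n), enrolled_id = "e",
    s_index = rnorm(n, mu, 0.05), s_middle = rnorm(n, mu, 0.05),
    s_ring = rnorm(n, mu, 0.05), is_genuine = mu > 0.5))
  dev <- rbind(mk_cloud(200, 0.8, 1), mk_cloud(200, 0.3, 2))
  evl <- rbind(mk_cloud(200, 0.8, 3), mk_cloud(200, 0.3, 4))
  dev$probe_id <- sprintf("p%d", seq_len(nrow(dev)))
  evl$probe_id <- sprintf("q%d", seq_len(nrow(evl)))
  fu <- fuse_fingers(dev, evl, target_fmr_pct = 0.1, seed = 5)
  expect_lte(fu$eval$hter_pct, 1)
  # brute-force linear threshold oracle on the mean score confirms separability
  mean_dev <- rowMeans(dev[, c("s_index", "s_middle", "s_ring")])
  best <- min(vapply(sort(mean_dev), function(t) {
    fm <- mean(rowMeans(evl[!evl$is_genuine, 3:5]) >= t)
    fn <- mean(rowMeans(evl[evl$is_genuine, 3:5]) < t)
    50 * (fm + fn)
  }, numeric(1)))
  expect_lte(best, 1)   # the construction is separable; SVM matches it
})

test_that("fusion is deterministic and rejects single-class dev sets", {
  dev <- with_seed_test(6, data.frame(
    probe_id = sprintf("p%d", 1:60), enrolled_id = "e",
    s_index = runif(60), s_middle = runif(60), s_ring = runif(60),
    is_genuine = rep(c(TRUE, FALSE), 30)))
  f1 <- fuse_fingers(dev, dev, seed = 9)
  f2 <- fuse_fingers(dev, dev, seed = 9)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$eval$hter_pct, f2$eval$hter_pct)
  bad <- dev; bad$is_genuine <- TRUE
  expect_error(fuse_fingers(bad, dev), "single class")
})
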