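test_that("dice and jaccard follow the empty-set convention and formulas", {
  e <- matrix(FALSE, 4, 4)
  expect_identical(dice(e, e), 1)
  expect_identical(jaccard(e, e), 1)
  m <- matrix(TRUE, 4, 4)
  expect_equal(dice(m, m), 1)
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE   # |A|=|B|=4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(jaccard(a, !a & m), 0)
  expect_error(dice(a, matrix(FALSE, 3, 3)), "dimensions")
})

test_that("D = 2J/(1+J) holds across random mask pairs", {
  set.seed(13)
  for (i in 1:300) {
    a <- random_mask(12, 9, runif(1, 0, 1))
    b <- random_mask(12, 9, runif(1, 0, 1))
    J <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("count-based summary metrics match direct formula evaluation", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0.5, 0.5), 0.5)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(round(f_measure(0.979, 0.953), 4), 0.9658)
  expect_equal(accuracy(confusion_counts(tp = 1, tn = 1)), 1)
  expect_equal(accuracy(confusion_counts(tp = 1, fp = 1)), 0.5)
  expect_equal(accuracy(confusion_counts(tp = 217, fp = 13, fn = 71)),
               217 / 301)
  expect_equal(mcc(confusion_counts(tp = 5, tn = 7)), 1)
  expect_equal(mcc(confusion_counts(tp = 1, tn = 1, fp = 1, fn = 1)), 0)
  expect_equal(mcc(confusion_counts(fn = 3, tn = 2)), 0)  # degenerate
})

test_that("hausdorff equals the brute-force max-min over point pairs", {
  p <- rbind(c(0, 0))
  expect_equal(hausdorff(p, p), 0)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  brute <- function(a, b) {
    d <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)),
                                      nrow(a) + seq_len(nrow(b)),
                                      drop = FALSE]
    max(max(apply(d, 1, min)), max(apply(d, 2, min)))
  }
  set.seed(17)
  for (i in 1:20) {
    a <- matrix(runif(20, 0, 50), ncol = 2)
    b <- matrix(runif(2 * sample(5:200, 1), 0, 50), ncol = 2)
    expect_equal(hausdorff(a, b), brute(a, b), tolerance = 1e-12)
  }
  expect_error(hausdorff(matrix(numeric(), 0, 2), p), "nonempty")
})

test_that("identical predictions match all instances at Dice 1", {
  scn <- small_scene(seed = 3, n_ftu = 3)
  tab <- match_instances(scn$truth_labels, scn$truth_labels)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$category == "TP"))
  expect_true(all(tab$dice == 1))
})

test_that("drops and additions land in FN and FP", {
  scn <- small_scene(seed = 9, n_ftu = 3)
  scn <- perturb(scn, perturb_spec(drop_n = 1, add_n = 1, seed = 2))
  tab <- match_instances(scn$truth_labels,
                         label_components(scn$prediction, 8))
  cc <- match_counts(tab)
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(2, 1, 1))
})

test_that("a sub-threshold overlap yields one FN and one FP", {
  gt <- matrix(0L, 10, 10); gt[1:5, 1:4] <- 1L          # 20 px
  pr <- matrix(0L, 10, 10); pr[1:5, 3:6] <- 1L          # 20 px, overlap 10
  # dice = 2*10/40 = 0.5 -> TP at threshold 0.5
  tab <- match_instances(gt, pr)
  expect_equal(tab$category, "TP")
  # shrink overlap to 8 px: dice 0.4 -> FN + FP
  pr2 <- matrix(0L, 10, 10); pr2[1:4, 3:7] <- 1L        # 20 px, overlap 8
  tab2 <- match_instances(gt, pr2)
  expect_setequal(tab2$category, c("FN", "FP"))
  expect_equal(tab2$dice[tab2$category == "FN"], 0.4)
})

test_that("every instance appears exactly once in the match table", {
  set.seed(29)
  for (i in 1:10) {
    gt <- label_components(random_mask(25, 25, 0.35), 4)
    pr <- label_components(random_mask(25, 25, 0.35), 4)
    tab <- match_instances(gt, pr)
    cc <- match_counts(tab)
    expect_equal(cc$tp + cc$fn, max(gt))
    expect_equal(cc$tp + cc$fp, max(pr))
    expect_equal(sort(tab$gt_id[!is.na(tab$gt_id)]), seq_len(max(gt)))
    expect_equal(sort(tab$pred_id[!is.na(tab$pred_id)]), seq_len(max(pr)))
  }
})

test_that("raising the match threshold never increases TP", {
  set.seed(43)
  gt <- label_components(random_mask(30, 30, 0.4), 4)
  pr <- label_components(random_mask(30, 30, 0.4), 4)
  tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    match_counts(match_instances(gt, pr, th))$tp, integer(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("per-WSI rows reproduce printed precision and recall tables", {
  # kidney, 2038 glomeruli: precision from 95 FN / 41 FP
  r <- wsi_metrics(confusion_counts(tp = 2038 - 95, fp = 41, fn = 95))
  expect_equal(round(r$precision, 3), 0.979)
  # kidney recall from 63 FN
  r <- wsi_metrics(confusion_counts(tp = 2038 - 63, fp = 70, fn = 63))
  expect_equal(round(r$recall, 3), 0.969)
  # colon, 160 crypts, 26 FN / 11 FP
  r <- wsi_metrics(confusion_counts(tp = 160 - 26, fp = 11, fn = 26))
  expect_equal(round(r$recall, 2), 0.84)
  expect_equal(round(r$precision, 2), 0.92)
  # empty-vs-empty convention
  r <- wsi_metrics(confusion_counts())
  expect_equal(c(r$precision, r$recall), c(1, 1))
  e <- matrix(0L, 3, 3)
  r <- wsi_metrics(match_instances(e, e), e, e)
  expect_equal(r$pixel_dice, 1)
})

test_that("competition mean factors missing WSIs in as zero", {
  expect_equal(competition_mean_dice(list(A = 1.0, B = 0.5),
                                     c("A", "B", "C")), 0.5)
  expect_equal(competition_mean_dice(list(A = 0.7, B = 0.7), c("A", "B")),
               0.7)
  expect_error(competition_mean_dice(list(), character()), "nonempty")
})

test_that("half-up rounding matches printed-table arithmetic", {
  expect_equal(round_half_up(20124.5), 20125)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.8375, 2), 0.84)
})
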