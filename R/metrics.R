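#' Pixel-overlap metrics between two binary masks
#'
#' `dice()` is `2|A n B| / (|A| + |B|)`; `jaccard()` (intersection over
#' union) is `|A n B| / |A u B|`. Both are defined to be 1 when both
#' masks are empty, and satisfy `D = 2J / (1 + J)`.
#'
#' @param a,b logical matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- assert_binary_mask(a); b <- assert_binary_mask(b)
  assert_same_shape(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  a <- assert_binary_mask(a); b <- assert_binary_mask(b)
  assert_same_shape(a, b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Confusion counts over FTU instances
#'
#' @param tp,fp,fn,tn non-negative integer counts of true-positive,
#'   false-positive, false-negative and (pixel-mode only) true-negative
#'   instances.
#' @return A list of class `ftu_confusion`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "ftu_confusion")
}

#' Summary metrics from precision/recall or confusion counts
#'
#' `f_measure()` is the harmonic mean of precision and recall (0 when
#' both are 0). `accuracy()` is `(TP + TN) / (TP + TN + FP + FN)`.
#' `mcc()` is the Matthews correlation coefficient, with the usual
#' convention of 0 when any denominator factor vanishes.
#'
#' @param precision,recall numbers in `[0, 1]`.
#' @return A number.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @rdname f_measure
#' @param counts a [confusion_counts()] object.
#' @export
accuracy <- function(counts) {
  with(counts, {
    den <- tp + tn + fp + fn
    if (den == 0) return(1)
    (tp + tn) / den
  })
}

#' @rdname f_measure
#' @export
mcc <- function(counts) {
  with(counts, {
    f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
    if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) /
      sqrt(as.numeric(f1) * f2 * f3 * f4)
  })
}

#' Hausdorff distance between two point sets
#'
#' The symmetric Hausdorff distance: the larger of the two directed
#' distances, where the directed distance from A to B is the maximum
#' over points of A of the Euclidean distance to the nearest point of
#' B. Typically applied to object edge points.
#'
#' @param a,b numeric matrices of points (one point per row), both
#'   nonempty, with equal column count.
#' @return A non-negative number, 0 iff the two sets are equal.
#' @export
hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b))
    stop("hausdorff distance requires two nonempty point sets",
         call. = FALSE)
  if (ncol(a) != ncol(b))
    stop("point sets must have the same dimensionality", call. = FALSE)
  directed <- function(p, q) {
    # min distance from each row of p to q, computed in blocks
    mins <- vapply(seq_len(nrow(p)), function(i) {
      d2 <- rowSums(sweep(q, 2L, p[i, ])^2)
      min(d2)
    }, numeric(1L))
    sqrt(max(mins))
  }
  max(directed(a, b), directed(b, a))
}

#' Match predicted to ground-truth instances by per-object Dice
#'
#' Candidate pairs are (ground truth label, predicted label) sharing at
#' least one pixel. Pairs are accepted greedily in descending pairwise
#' Dice order (ties broken by ascending gt then pred label), one-to-one.
#' Accepted pairs with Dice at or above `match_threshold` are true
#' positives; every unmatched (or sub-threshold) prediction is a false
#' positive and every unmatched ground truth a false negative.
#'
#' @param gt,pred integer label matrices of identical shape.
#' @param match_threshold per-object Dice threshold (default 0.5).
#' @return A data.frame of class `ftu_match_table` with columns
#'   `gt_id`, `pred_id`, `dice`, `category`; each ground-truth and each
#'   predicted label appears in exactly one row.
#' @export
match_instances <- function(gt, pred, match_threshold = 0.5) {
  gt <- assert_label_image(gt); pred <- assert_label_image(pred)
  assert_same_shape(gt, pred)
  ng <- max(gt, 0L); np <- max(pred, 0L)
  area_g <- tabulate(gt[gt > 0L], nbins = ng)
  area_p <- tabulate(pred[pred > 0L], nbins = np)
  ov <- cpp_overlap_counts(gt, pred)
  pair_dice <- if (nrow(ov))
    2 * ov[, 3L] / (area_g[ov[, 1L]] + area_p[ov[, 2L]]) else numeric()
  o <- order(-pair_dice, ov[, 1L], ov[, 2L])
  g_taken <- logical(ng); p_taken <- logical(np)
  rows <- vector("list", length(o))
  for (i in o) {
    g <- ov[i, 1L]; p <- ov[i, 2L]
    if (g_taken[g] || p_taken[p]) next
    g_taken[g] <- TRUE; p_taken[p] <- TRUE
    d <- pair_dice[i]
    rows[[i]] <- if (d >= match_threshold)
      data.frame(gt_id = g, pred_id = p, dice = d, category = "TP")
    else
      rbind(data.frame(gt_id = g, pred_id = NA_integer_, dice = d,
                       category = "FN"),
            data.frame(gt_id = NA_integer_, pred_id = p, dice = d,
                       category = "FP"))
  }
  unmatched_g <- which(!g_taken & area_g > 0L)
  unmatched_p <- which(!p_taken & area_p > 0L)
  tab <- do.call(rbind, c(
    rows[!vapply(rows, is.null, TRUE)],
    if (length(unmatched_g))
      list(data.frame(gt_id = unmatched_g, pred_id = NA_integer_,
                      dice = 0, category = "FN")),
    if (length(unmatched_p))
      list(data.frame(gt_id = NA_integer_, pred_id = unmatched_p,
                      dice = 0, category = "FP"))))
  if (is.null(tab))
    tab <- data.frame(gt_id = integer(), pred_id = integer(),
                      dice = numeric(), category = character())
  tab <- tab[order(tab$category, tab$gt_id, tab$pred_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "match_threshold") <- match_threshold
  class(tab) <- c("ftu_match_table", "data.frame")
  tab
}

#' Tally a match table into confusion counts
#' @param table an `ftu_match_table`.
#' @return A [confusion_counts()] object.
#' @export
match_counts <- function(table) {
  confusion_counts(tp = sum(table$category == "TP"),
                   fp = sum(table$category == "FP"),
                   fn = sum(table$category == "FN"))
}

#' Per-WSI metrics row
#'
#' Aggregates a match table (and optionally the underlying label
#' images) into the row format of the per-WSI performance tables:
#' object-level precision `TP/(TP+FP)` and recall `TP/(TP+FN)`, the
#' mean per-instance Dice over all TP/FP/FN rows (an instance with no
#' overlapping partner contributes 0), and the pixel-level Dice of the
#' union masks (leaderboard semantics). When one of (predictions,
#' ground truth) is empty, precision and recall are 1 if the other is
#' empty too, else 0 — the empty-set convention of the Dice
#' coefficient carried over.
#'
#' @param table an `ftu_match_table` (or a [confusion_counts()] object
#'   for count-only use).
#' @param gt,pred optional label images for the pixel-level Dice.
#' @param wsi_id identifier stored in the row.
#' @return A one-row data.frame with columns `wsi_id`, `n_gt`, `tp`,
#'   `fp`, `fn`, `mean_instance_dice`, `pixel_dice`, `precision`,
#'   `recall`.
#' @export
wsi_metrics <- function(table, gt = NULL, pred = NULL, wsi_id = NA_character_) {
  if (inherits(table, "ftu_confusion")) {
    counts <- table
    mean_dice <- NA_real_
  } else {
    counts <- match_counts(table)
    mean_dice <- if (nrow(table)) mean(table$dice) else NA_real_
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(tp + fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(tp + fp == 0)
  pixel_dice <- if (!is.null(gt) && !is.null(pred)) dice(gt > 0, pred > 0)
                else NA_real_
  data.frame(wsi_id = wsi_id, n_gt = tp + fn, tp = tp, fp = fp, fn = fn,
             mean_instance_dice = mean_dice, pixel_dice = pixel_dice,
             precision = precision, recall = recall)
}

#' Competition-style mean Dice over a set of WSIs
#'
#' The leaderboard score: the mean of per-WSI (pixel) Dice
#' coefficients over all listed WSIs, where a WSI with no prediction at
#' all is factored into the mean as a zero.
#'
#' @param per_wsi named numeric vector or list of per-WSI Dice values.
#' @param wsi_ids the full roster of WSIs being scored.
#' @return The mean Dice.
#' @export
competition_mean_dice <- function(per_wsi, wsi_ids) {
  if (!length(wsi_ids)) stop("wsi_ids must be nonempty", call. = FALSE)
  vals <- vapply(wsi_ids, function(id) {
    v <- per_wsi[[id]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }, numeric(1L))
  mean(vals)
}

#' Round half away from zero
#'
#' Printed-table style rounding (5 always rounds up in magnitude),
#' unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
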