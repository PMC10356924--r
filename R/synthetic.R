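# Synthetic WSI-like scenes with known ground truth
# --------------------------------------------------
# The generator emulates the geometry of the datasets this package
# evaluates: roughly circular glomeruli 100-350 um in diameter, or
# elongated crypts with a ~73.5 um cross-section, packed without
# overlap inside a cortex region, at a stated physical resolution.
# The default canvas is a 2048 x 2048 px "downscaled WSI" at 4 um/px
# so a glomerulus spans roughly 25-88 px; the full 0.5 um/px
# resolution of the source imagery is supported but not the default.

# derived per-subtask RNG stream so adding one perturbation never
# shifts the draws of another subtask; values stay below 2^31
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1e6) * 1009 + k * 9176 + 17) %% 2147483647
}

with_stream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, k))
  force(expr)
}

#' Specification of a synthetic WSI-like scene
#'
#' @param n_ftu number of FTU instances to plant.
#' @param ftu_kind `"glomerulus"` (quasi-circular, diameter drawn
#'   uniformly from `diameter_range_um`) or `"crypt"` (elongated,
#'   cross-section diameter drawn from a normal distribution).
#' @param image_shape canvas `(rows, cols)` in pixels.
#' @param pixel_size_um physical pixel size; the default 4 um/px keeps
#'   scenes desk-sized while preserving object geometry.
#' @param diameter_range_um for glomeruli, `c(min, max)` diameter in um
#'   (default 100-350); for crypts, `c(mean, sd)` of the cross-section
#'   diameter (default 73.5, 3.4).
#' @param cortex_fraction fraction of the canvas covered by the cortex
#'   band in which FTUs are placed.
#' @param min_gap_px minimum gap between instance boundaries.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return A list of class `ftu_scene_spec`.
#' @export
scene_spec <- function(n_ftu = 40, ftu_kind = c("glomerulus", "crypt"),
                       image_shape = c(2048, 2048), pixel_size_um = 4,
                       diameter_range_um = NULL, cortex_fraction = 0.55,
                       min_gap_px = 2, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory", call. = FALSE)
  ftu_kind <- match.arg(ftu_kind)
  if (is.null(diameter_range_um))
    diameter_range_um <- if (ftu_kind == "glomerulus") c(100, 350)
                         else c(73.5, 3.4)
  if (any(diameter_range_um <= 0))
    stop("diameter parameters must be positive", call. = FALSE)
  if (n_ftu < 0) stop("n_ftu must be >= 0", call. = FALSE)
  structure(list(n_ftu = as.integer(n_ftu), ftu_kind = ftu_kind,
                 image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 diameter_range_um = diameter_range_um,
                 cortex_fraction = cortex_fraction,
                 min_gap_px = min_gap_px, seed = as.integer(seed)),
            class = "ftu_scene_spec")
}

# quasi-elliptical ring: axis ratio in [0.8, 1] ("roughly spherical")
# for glomeruli, ~0.17 for crypts (73.5 um wide, ~433 um long), plus
# low-amplitude radial noise so shapes are not trivially circular
ftu_ring <- function(kind, d_um, pixel_size_um, n_vertices = 64) {
  d_px <- d_um / pixel_size_um
  if (kind == "glomerulus") {
    ratio <- runif(1, 0.8, 1)
    a <- (d_px / 2) / sqrt(ratio)
    b <- (d_px / 2) * sqrt(ratio)
  } else {
    b <- d_px / 2
    a <- (d_px / 0.17) / 2
  }
  amp <- 0.02
  kf <- sample(3:6, 1L)
  ph <- runif(1, 0, 2 * pi)
  th <- runif(1, 0, pi)
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  noise <- 1 + amp * sin(kf * phi + ph)
  ex <- a * cos(phi) * noise
  ey <- b * sin(phi) * noise
  cbind(x = ex * cos(th) - ey * sin(th),
        y = ex * sin(th) + ey * cos(th))
}

#' Generate the ground-truth portion of a synthetic scene
#'
#' Plants exactly `n_ftu` non-overlapping quasi-elliptical instances
#' inside a cortex band, producing a label image and the matching
#' polygon annotation set (FTU polygons plus one cortex polygon). The
#' label image is the rasterization of the polygons, so the two truth
#' representations are mutually consistent by construction. Fully
#' deterministic for a fixed seed.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `ftu_scene` with elements `truth_labels`
#'   (integer matrix), `annotations` ([annotation_set()]), `spec`, and
#'   placeholders `prediction`/`expected` filled by [perturb()].
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "ftu_scene_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  h <- nr * spec$cortex_fraction
  y0 <- (nr - h) / 2; y1 <- y0 + h
  cortex_ring <- cbind(x = c(0, nc, nc, 0), y = c(y0, y0, y1, y1))

  shapes <- with_stream(spec$seed, 1L, lapply(seq_len(spec$n_ftu),
    function(i) {
      d_um <- if (spec$ftu_kind == "glomerulus")
        runif(1, spec$diameter_range_um[1L], spec$diameter_range_um[2L])
      else
        max(rnorm(1, spec$diameter_range_um[1L], spec$diameter_range_um[2L]),
            spec$diameter_range_um[1L] / 2)
      ftu_ring(spec$ftu_kind, d_um, spec$pixel_size_um)
    }))
  rb <- vapply(shapes, function(rg) max(sqrt(rowSums(rg^2))), numeric(1L))

  centers <- with_stream(spec$seed, 2L, {
    cx <- numeric(0); cy <- numeric(0)
    for (i in seq_len(spec$n_ftu)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        pad <- rb[i] + spec$min_gap_px + 1
        if (nc - 2 * pad <= 0 || y1 - y0 - 2 * pad <= 0) break
        x <- runif(1, pad, nc - pad)
        y <- runif(1, y0 + pad, y1 - pad)
        if (length(cx)) {
          dd <- sqrt((cx - x)^2 + (cy - y)^2)
          if (any(dd < rb[i] + rb[seq_along(cx)] + spec$min_gap_px)) next
        }
        cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste("could not place instance %d of %d without",
                           "overlap; reduce n_ftu or enlarge the canvas"),
                     i, spec$n_ftu), call. = FALSE)
    }
    cbind(cx, cy)
  })

  anns <- vector("list", spec$n_ftu + 1L)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(spec$n_ftu)) {
    ring <- sweep(shapes[[i]], 2L, -centers[i, ])
    anns[[i]] <- annotation(id = i, category = spec$ftu_kind, ring = ring)
    lab[rasterize(anns[[i]], c(nr, nc))] <- i
  }
  anns[[spec$n_ftu + 1L]] <- annotation(id = "cortex-1", category = "cortex",
                                        ring = cortex_ring)
  structure(list(
    truth_labels = lab,
    annotations = annotation_set(sprintf("synthetic-%d", spec$seed),
                                 c(nr, nc), spec$pixel_size_um, anns),
    prediction = NULL, expected = NULL, spec = spec),
    class = "ftu_scene")
}

#' Specification of prediction perturbations
#'
#' @param drop_n ground-truth instances omitted from the prediction
#'   (become false negatives).
#' @param add_n spurious blobs disjoint from all ground truth (become
#'   false positives).
#' @param merge_pairs pairs of nearby instances bridged into a single
#'   predicted component; watershed separation restores them.
#' @param jitter_px dilate/erode magnitude applied per instance.
#' @param seed mandatory integer seed.
#' @return A list of class `ftu_perturb_spec`.
#' @export
perturb_spec <- function(drop_n = 0, add_n = 0, merge_pairs = 0,
                         jitter_px = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  v <- c(drop_n, add_n, merge_pairs, jitter_px)
  if (any(v < 0)) stop("perturbation counts must be non-negative",
                       call. = FALSE)
  structure(list(drop_n = as.integer(drop_n), add_n = as.integer(add_n),
                 merge_pairs = as.integer(merge_pairs),
                 jitter_px = as.integer(jitter_px), seed = as.integer(seed)),
            class = "ftu_perturb_spec")
}

#' Perturb a scene's truth into a prediction with known confusion counts
#'
#' Builds the prediction mask by dropping `drop_n` instances, adding
#' `add_n` disjoint spurious blobs, bridging `merge_pairs` nearby
#' instance pairs with a thin neck, and dilating/eroding instance
#' boundaries by `jitter_px`. The expected object-level counts are
#' `tp = n_ftu - drop_n`, `fn = drop_n`, `fp = add_n`; they are exact
#' whenever the jitter leaves every surviving pairwise Dice at or above
#' the matching threshold, and merged pairs require
#' [watershed_separate()] before matching.
#'
#' @param scene an `ftu_scene` from [generate_scene()].
#' @param pspec a [perturb_spec()].
#' @return The scene with `prediction` (logical matrix), `expected`
#'   ([confusion_counts()]), and bookkeeping fields `dropped`, `merged`.
#' @export
perturb <- function(scene, pspec) {
  stopifnot(inherits(scene, "ftu_scene"), inherits(pspec, "ftu_perturb_spec"))
  lab <- scene$truth_labels
  K <- max(lab, 0L)
  if (pspec$drop_n > K)
    stop("drop_n exceeds the number of planted instances", call. = FALSE)
  nr <- nrow(lab); nc <- ncol(lab)

  dropped <- with_stream(pspec$seed, 11L,
                         sort(sample(seq_len(K), pspec$drop_n)))
  kept <- setdiff(seq_len(K), dropped)
  pred_lab <- lab
  pred_lab[pred_lab %in% dropped] <- 0L

  # per-instance boundary jitter: dilate or erode on a padded crop
  if (pspec$jitter_px > 0L && length(kept)) {
    signs <- with_stream(pspec$seed, 12L,
                         sample(c(-1L, 1L), length(kept), replace = TRUE))
    brush <- EBImage::makeBrush(2L * pspec$jitter_px + 1L, shape = "disc")
    out <- matrix(0L, nr, nc)
    for (j in seq_along(kept)) {
      k <- kept[j]
      idx <- which(pred_lab == k, arr.ind = TRUE)
      m <- pspec$jitter_px + 1L
      r0 <- max(1L, min(idx[, 1L]) - m); r1 <- min(nr, max(idx[, 1L]) + m)
      c0 <- max(1L, min(idx[, 2L]) - m); c1 <- min(nc, max(idx[, 2L]) + m)
      crop <- pred_lab[r0:r1, c0:c1] == k
      crop <- if (signs[j] > 0) EBImage::dilate(crop * 1, brush)
              else EBImage::erode(crop * 1, brush)
      sub <- out[r0:r1, c0:c1]
      sub[crop > 0] <- k
      out[r0:r1, c0:c1] <- sub
    }
    keep_other <- pred_lab != 0L & out == 0L &
      !(pred_lab %in% kept)  # nothing else exists yet, but be safe
    out[keep_other] <- pred_lab[keep_other]
    pred_lab <- out
  }
  pred <- pred_lab > 0L

  merged <- NULL
  if (pspec$merge_pairs > 0L) {
    if (length(kept) < 2L * pspec$merge_pairs)
      stop("not enough surviving instances to merge", call. = FALSE)
    cen <- t(vapply(kept, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(mean(idx[, 2L]), mean(idx[, 1L]))     # (x, y)
    }, numeric(2L)))
    avail <- rep(TRUE, length(kept))
    merged <- matrix(integer(), 0L, 2L)
    for (p in seq_len(pspec$merge_pairs)) {
      ii <- which(avail)
      if (length(ii) < 2L) stop("ran out of mergeable pairs", call. = FALSE)
      dmat <- as.matrix(dist(cen[ii, , drop = FALSE]))
      diag(dmat) <- Inf
      w <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
      a <- ii[w[1L]]; b <- ii[w[2L]]
      avail[c(a, b)] <- FALSE
      merged <- rbind(merged, c(kept[a], kept[b]))
      pred <- pred | bridge_mask(cen[a, ], cen[b, ], width = 3, nr, nc)
    }
  }

  if (pspec$add_n > 0L) {
    rb_all <- vapply(seq_len(K), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      cx <- mean(idx[, 2L]); cy <- mean(idx[, 1L])
      max(sqrt((idx[, 2L] - cx)^2 + (idx[, 1L] - cy)^2))
    }, numeric(1L))
    cen_all <- t(vapply(seq_len(K), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(mean(idx[, 2L]), mean(idx[, 1L]))
    }, numeric(2L)))
    with_stream(pspec$seed, 13L, {
      placed <- 0L
      bx <- numeric(0); by <- numeric(0); brad <- numeric(0)
      guard <- 0L
      while (placed < pspec$add_n) {
        if ((guard <- guard + 1L) > 2000L * pspec$add_n)
          stop("could not place spurious blobs disjoint from the truth",
               call. = FALSE)
        d_um <- 0.6 * mean(scene$spec$diameter_range_um[1L])
        ring <- ftu_ring("glomerulus", d_um, scene$spec$pixel_size_um)
        r <- max(sqrt(rowSums(ring^2)))
        x <- runif(1, r + 2, nc - r - 2)
        y <- runif(1, r + 2, nr - r - 2)
        ok <- TRUE
        if (K > 0) {
          dd <- sqrt((cen_all[, 1L] - x)^2 + (cen_all[, 2L] - y)^2)
          ok <- all(dd > rb_all + r + 2)
        }
        if (ok && length(bx)) {
          dd <- sqrt((bx - x)^2 + (by - y)^2)
          ok <- all(dd > brad + r + 2)
        }
        if (!ok) next
        ring <- sweep(ring, 2L, -c(x, y))
        pred <- pred | cpp_polygon_fill(list(ring), nr, nc)
        bx <- c(bx, x); by <- c(by, y); brad <- c(brad, r)
        placed <- placed + 1L
      }
    })
  }

  scene$prediction <- pred
  scene$expected <- confusion_counts(tp = K - pspec$drop_n,
                                     fn = pspec$drop_n, fp = pspec$add_n)
  scene$dropped <- dropped
  scene$merged <- merged
  scene$perturb <- pspec
  scene
}

# thin rectangle of the given width along the segment a-b ((x, y))
bridge_mask <- function(a, b, width, nr, nc) {
  v <- b - a
  len <- sqrt(sum(v^2))
  if (len == 0) return(matrix(FALSE, nr, nc))
  u <- v / len
  n <- c(-u[2L], u[1L]) * (width / 2)
  ring <- rbind(a + n, b + n, b - n, a - n)
  cpp_polygon_fill(list(ring), nr, nc)
}

#' Generate a synthetic donor cohort with planted FTU densities
#'
#' Each donor receives a planted glomerulus density drawn uniformly
#' from `density_range` (FTUs per mm^2 of cortex) plus metadata (sex,
#' age, BMI, vertical tissue-block position). Each of the donor's
#' scenes plants `round(density * cortex_area_mm2)` instances, so the
#' density recovered from the scene's annotations matches the planted
#' value up to that rounding.
#'
#' @param n_donors,scenes_per_donor cohort dimensions.
#' @param density_range `c(min, max)` planted density in FTUs/mm^2.
#' @param seed mandatory integer seed.
#' @param image_shape,pixel_size_um,cortex_fraction forwarded to
#'   [scene_spec()]; the defaults keep cohort scenes desk-sized.
#' @return List of entries, each with `scene`, `donor` (one-row
#'   data.frame: `donor_id`, `sex`, `age`, `bmi`, `y_position`) and
#'   `planted_density`.
#' @export
generate_cohort <- function(n_donors = 4, scenes_per_donor = 2,
                            density_range = c(3, 6), seed,
                            image_shape = c(1024, 1024), pixel_size_um = 4,
                            cortex_fraction = 0.55) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_donors < 1) stop("n_donors must be >= 1", call. = FALSE)
  meta <- with_stream(seed, 21L, data.frame(
    donor_id = sprintf("donor-%02d", seq_len(n_donors)),
    sex = sample(c("F", "M"), n_donors, replace = TRUE),
    age = sample(25:75, n_donors, replace = TRUE),
    bmi = round(rnorm(n_donors, 27, 4), 1),
    y_base = runif(n_donors, 0, 100),
    density = runif(n_donors, density_range[1L], density_range[2L])))
  cortex_mm2 <- (image_shape[1L] * cortex_fraction) * image_shape[2L] *
    pixel_size_um^2 / 1e6
  out <- list()
  for (i in seq_len(n_donors)) {
    for (s in seq_len(scenes_per_donor)) {
      n <- max(1L, as.integer(round(meta$density[i] * cortex_mm2)))
      sp <- scene_spec(n_ftu = n, ftu_kind = "glomerulus",
                       image_shape = image_shape,
                       pixel_size_um = pixel_size_um,
                       cortex_fraction = cortex_fraction,
                       seed = derive_seed(seed, 100L + i * 17L + s))
      scn <- generate_scene(sp)
      scn$annotations$wsi_id <- sprintf("%s-wsi-%d", meta$donor_id[i], s)
      donor <- data.frame(donor_id = meta$donor_id[i], sex = meta$sex[i],
                          age = meta$age[i], bmi = meta$bmi[i],
                          y_position = meta$y_base[i] + s * 0.1)
      out[[length(out) + 1L]] <- list(scene = scn, donor = donor,
                                      planted_density = meta$density[i])
    }
  }
  out
}
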