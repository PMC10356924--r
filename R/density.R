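#' Shoelace area of a polygon annotation, in square pixels
#'
#' Area is positive regardless of vertex orientation; interior rings
#' (holes) are subtracted.
#'
#' @param ann an [annotation()] or a bare two-column ring matrix.
#' @return Area in px^2.
#' @export
polygon_area_px <- function(ann) {
  shoelace <- function(rg) {
    x <- rg[, 1L]; y <- rg[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    abs(sum(x * yn - xn * y)) / 2
  }
  rings <- if (inherits(ann, "ftu_annotation")) c(list(ann$ring), ann$holes)
           else list(as_ring(ann))
  if (nrow(unique(rings[[1L]])) < 3L)
    stop("degenerate polygon: a ring needs at least 3 distinct vertices",
         call. = FALSE)
  a <- shoelace(rings[[1L]])
  if (length(rings) > 1L)
    a <- a - sum(vapply(rings[-1L], shoelace, numeric(1L)))
  a
}

#' Convert a pixel area to square micrometers
#'
#' @param area_px area in px^2.
#' @param pixel_size_um physical edge length of one pixel in um
#'   (0.5 for the kidney WSIs modeled here).
#' @return Area in um^2 (`area_px * pixel_size_um^2`).
#' @export
px_area_to_um2 <- function(area_px, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || any(pixel_size_um <= 0))
    stop("pixel_size_um must be positive", call. = FALSE)
  area_px * pixel_size_um^2
}

#' FTU density of one WSI
#'
#' Counts the FTU annotations, computes their mean area (px^2 converted
#' to um^2), sums the areas of all cortex polygons (the sum, not their
#' union: overlapping cortex polygons double-count, which reproduces the
#' conventional bookkeeping; set `cortex_union = TRUE` for the union
#' area instead), converts to mm^2, and reports density as FTUs per
#' mm^2 of cortex.
#'
#' @param aset an [annotation_set()] containing at least one cortex
#'   polygon.
#' @param donor optional list/row with donor metadata (`sex`, `age`,
#'   `bmi`, `y_position`).
#' @param cortex_union use the union area of cortex polygons instead of
#'   their sum.
#' @return A one-row data.frame of class `ftu_density_record` with
#'   columns `wsi_id`, `n_ftu`, `mean_ftu_area_um2`, `cortex_area_mm2`,
#'   `density_per_mm2`, `sex`, `age`, `bmi`, `y_position`.
#' @export
ftu_density <- function(aset, donor = NULL, cortex_union = FALSE) {
  stopifnot(inherits(aset, "ftu_annotation_set"))
  cats <- vapply(aset$annotations, `[[`, "", "category")
  ftus <- aset$annotations[cats %in% ftu_kinds()]
  cortex <- aset$annotations[cats == "cortex"]
  if (!length(cortex))
    stop("undefined density: the annotation set has no cortex polygon",
         call. = FALSE)
  cortex_px2 <- if (cortex_union) {
    u <- Reduce(`|`, lapply(cortex, rasterize, shape = aset$image_shape))
    sum(u)
  } else {
    sum(vapply(cortex, polygon_area_px, numeric(1L)))
  }
  cortex_mm2 <- px_area_to_um2(cortex_px2, aset$pixel_size_um) / 1e6
  if (cortex_mm2 <= 0)
    stop("undefined density: cortex area is zero", call. = FALSE)
  n_ftu <- length(ftus)
  mean_area <- if (n_ftu)
    mean(vapply(ftus, function(a)
      px_area_to_um2(polygon_area_px(a), aset$pixel_size_um), numeric(1L)))
  else NA_real_
  rec <- data.frame(
    wsi_id = aset$wsi_id, n_ftu = n_ftu,
    mean_ftu_area_um2 = mean_area,
    cortex_area_mm2 = cortex_mm2,
    density_per_mm2 = n_ftu / cortex_mm2,
    sex = if (!is.null(donor$sex)) donor$sex else NA_character_,
    age = if (!is.null(donor$age)) donor$age else NA_real_,
    bmi = if (!is.null(donor$bmi)) donor$bmi else NA_real_,
    y_position = if (!is.null(donor$y_position)) donor$y_position
                 else NA_real_)
  class(rec) <- c("ftu_density_record", "data.frame")
  rec
}

#' Cohort table of density records
#'
#' Binds per-WSI density records and orders them top-down by the
#' vertical position of the tissue block (descending `y_position`,
#' stable for ties), the layout used when comparing FTU density along
#' an organ axis across donors.
#'
#' @param records list of [ftu_density()] rows (or a bound data.frame).
#' @return A data.frame sorted by descending `y_position`.
#' @export
cohort_table <- function(records) {
  df <- if (is.data.frame(records)) records else do.call(rbind, records)
  key <- df$y_position
  key[is.na(key)] <- -Inf
  df <- df[order(-key), , drop = FALSE]   # order() is a stable sort
  rownames(df) <- NULL
  df
}
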