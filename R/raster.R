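#' Rasterize a polygon annotation onto a pixel grid
#'
#' A pixel is set if and only if its center lies inside the polygon
#' under the even-odd rule; a center lying exactly on the boundary
#' counts as inside. Interior rings (holes) are subtracted by the same
#' even-odd rule. The rule is deterministic and consistent across
#' resolutions.
#'
#' @param ann an [annotation()] (or a bare two-column ring matrix).
#' @param shape image shape `(rows, cols)` in pixels.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize <- function(ann, shape) {
  rings <- if (inherits(ann, "ftu_annotation")) c(list(ann$ring), ann$holes)
           else list(as_ring(ann))
  if (nrow(unique(rings[[1L]])) < 3L)
    stop("degenerate polygon: a ring needs at least 3 distinct vertices",
         call. = FALSE)
  shape <- as.integer(shape)
  cpp_polygon_fill(rings, shape[1L], shape[2L])
}

#' Rasterize a whole annotation set into a label image
#'
#' Each FTU annotation becomes one instance label, in annotation order;
#' region annotations (cortex, medulla, ...) are skipped unless
#' `categories` says otherwise.
#'
#' @param aset an [annotation_set()].
#' @param categories which categories become instances.
#' @return Integer label matrix (0 background, 1..K instances).
#' @export
rasterize_set <- function(aset, categories = ftu_kinds()) {
  stopifnot(inherits(aset, "ftu_annotation_set"))
  lab <- matrix(0L, aset$image_shape[1L], aset$image_shape[2L])
  k <- 0L
  for (a in aset$annotations) {
    if (!a$category %in% categories) next
    k <- k + 1L
    lab[rasterize(a, aset$image_shape)] <- k
  }
  lab
}

#' Convert a label image into one polygon per instance
#'
#' Traces the outer boundary of each label along pixel edges, so that
#' rasterizing the resulting polygon reproduces the label's pixel set
#' exactly for solid 4-connected blobs (interior holes are filled).
#'
#' @param lm integer label matrix.
#' @param category category assigned to the produced annotations.
#' @return List of [annotation()] objects, one per label `1..K`.
#' @export
vectorize <- function(lm, category = "glomerulus") {
  lm <- assert_label_image(lm)
  labs <- sort(unique(lm[lm > 0L]))
  lapply(labs, function(k) {
    idx <- which(lm == k, arr.ind = TRUE)
    r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
    c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
    sub <- lm[r0:r1, c0:c1, drop = FALSE] == k
    ring <- cpp_trace_outer(sub)
    # shift crop-local corner coordinates back to image coordinates
    ring[, 1L] <- ring[, 1L] + (c0 - 1L)
    ring[, 2L] <- ring[, 2L] + (r0 - 1L)
    annotation(id = as.integer(k), category = category, ring = ring)
  })
}

#' Read and write label images as 16-bit TIFF
#'
#' Labels are stored as 16-bit unsigned samples (up to 65535 instances
#' per image; thousands of glomeruli occur on real WSIs, so 8 bits would
#' not do).
#'
#' @param path TIFF file.
#' @return `read_label_tiff()`: integer label matrix.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' @rdname read_label_tiff
#' @param lm integer label matrix (values 0..65535).
#' @export
write_label_tiff <- function(lm, path) {
  lm <- assert_label_image(lm)
  if (any(lm > 65535L))
    stop("more than 65535 labels cannot be stored in 16-bit TIFF",
         call. = FALSE)
  tiff::writeTIFF(lm / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
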