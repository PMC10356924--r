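#' Named minimum-distance presets for watershed separation
#'
#' The marker exclusion radius is the one tunable of the separation
#' step. The presets encode the values used for the datasets this
#' package models: 30 px for the HuBMAP kidney WSIs, 60 px for HuBMAP
#' colon, 80 px for the HPA immunohistochemistry WSIs.
#'
#' @param name `"kidney-hubmap"`, `"colon-hubmap"` or `"hpa"`, or a
#'   positive integer passed through unchanged.
#' @return Integer minimum distance in pixels.
#' @export
min_distance_preset <- function(name) {
  if (is.character(name) && grepl("^[0-9]+$", name)) name <- as.numeric(name)
  if (is.numeric(name)) {
    md <- as.integer(name)
    if (md < 1L) stop("min_distance must be >= 1", call. = FALSE)
    return(md)
  }
  presets <- c("kidney-hubmap" = 30L, "colon-hubmap" = 60L, "hpa" = 80L)
  name <- match.arg(name, names(presets))
  presets[[name]]
}

#' Label connected components of a binary mask
#'
#' Maximal connected components are labeled 1..K, in deterministic
#' row-major first-encounter order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + corner).
#' @return Integer label matrix.
#' @export
label_components <- function(mask, connectivity = 4) {
  mask <- assert_binary_mask(mask)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  cpp_label_components(mask, as.integer(connectivity))
}

#' Separation parameters
#'
#' @param min_distance_px marker exclusion radius (peak-to-peak), in
#'   pixels; see [min_distance_preset()].
#' @param connectivity 4 or 8.
#' @return A list of class `ftu_separation_params`.
#' @export
separation_params <- function(min_distance_px = 30, connectivity = 8) {
  md <- min_distance_preset(min_distance_px)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(min_distance_px = md,
                 connectivity = as.integer(connectivity)),
            class = "ftu_separation_params")
}

# Local maxima of the distance map subject to a minimum pairwise
# separation. Candidates are pixels >= all neighbors within the 3x3
# window; a connected candidate plateau contributes one marker at its
# highest then first row-major pixel. Candidates are accepted greedily
# in decreasing distance (ties by row-major order), rejecting any
# candidate within min_distance of an accepted one.
distance_peaks <- function(d, min_distance_px) {
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- d
  nbmax <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbmax <- pmax(nbmax, pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  cand <- d > 0 & d >= nbmax
  if (!any(cand)) return(NULL)
  # collapse plateaus: one representative per connected candidate patch
  plab <- cpp_label_components(cand, 8L)
  idx <- which(cand)
  reps <- vapply(split(idx, plab[idx]), function(ii) {
    best <- ii[d[ii] == max(d[ii])]
    rw <- (best - 1L) %% nr; cl <- (best - 1L) %/% nr
    best[order(rw, cl)][1L]
  }, integer(1L))
  rw <- (reps - 1L) %% nr; cl <- (reps - 1L) %/% nr
  o <- order(-d[reps], rw, cl)
  reps <- reps[o]; rw <- rw[o]; cl <- cl[o]
  keep <- logical(length(reps))
  for (i in seq_along(reps)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    js <- which(keep[seq_len(i - 1L)])
    dd <- sqrt((rw[i] - rw[js])^2 + (cl[i] - cl[js])^2)
    keep[i] <- all(dd >= min_distance_px)
  }
  cbind(row = rw[keep] + 1L, col = cl[keep] + 1L)
}

#' Separate merged FTUs by marker-controlled watershed
#'
#' Computes the Euclidean distance transform of the foreground, detects
#' its local maxima with no two markers closer than
#' `params$min_distance_px`, and floods the negated distance map from
#' those markers so that every foreground pixel is assigned to exactly
#' one marker. The foreground pixel set is preserved exactly and the
#' labeling is deterministic for a fixed input.
#'
#' @param mask logical matrix.
#' @param params a [separation_params()] object.
#' @return Integer label matrix with labels 1..K in row-major
#'   first-encounter order.
#' @export
watershed_separate <- function(mask, params = separation_params()) {
  mask <- assert_binary_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask))
  peaks <- distance_peaks(d, params$min_distance_px)
  markers <- matrix(0L, nrow(mask), ncol(mask))
  markers[peaks] <- seq_len(nrow(peaks))
  lab <- cpp_watershed_flood(d, markers, mask, params$connectivity)
  # isolated foreground pixels unreachable from any marker (possible
  # only with connectivity 4 across diagonal necks) fall back to their
  # own component labels
  if (any(lab == 0L & mask)) {
    extra <- cpp_label_components(lab == 0L & mask, params$connectivity)
    lab[extra > 0L] <- extra[extra > 0L] + max(lab)
  }
  relabel_scan_order(lab)
}

# renumber labels 1..K by first-encounter position in row-major order
relabel_scan_order <- function(lab) {
  pos <- which(t(lab) > 0L)                     # row-major positions
  if (!length(pos)) return(lab)
  vals <- t(lab)[pos]
  first <- vals[!duplicated(vals)]
  map <- integer(max(lab))
  map[first] <- seq_along(first)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Cut a mask along manual split lines
#'
#' Mirrors the manual-correction workflow in which adjacent FTUs merged
#' in a predicted mask are separated by drawing a line between them:
#' pixels under the 1-px-wide rasterized polylines are cleared to
#' background; everything else is untouched. Apply before
#' [label_components()].
#'
#' @param mask logical matrix.
#' @param lines list of polylines, each a numeric matrix with columns
#'   `(x, y)` and at least 2 vertices.
#' @return Logical matrix.
#' @export
apply_split_lines <- function(mask, lines) {
  mask <- assert_binary_mask(mask)
  for (ln in lines) {
    ln <- as.matrix(ln)
    if (ncol(ln) != 2L || nrow(ln) < 2L)
      stop("each split line needs >= 2 (x, y) vertices", call. = FALSE)
    for (i in seq_len(nrow(ln) - 1L)) {
      px <- bresenham_pixels(ln[i, ], ln[i + 1L, ],
                             nrow(mask), ncol(mask))
      mask[px] <- FALSE
    }
  }
  mask
}

# pixels of the 1-px line segment from a to b ((x, y) coordinates);
# supercover stepping in the dominant direction
bresenham_pixels <- function(a, b, nr, nc) {
  n <- max(abs(b - a)) + 1
  steps <- max(2L, ceiling(n) * 2L)
  t <- seq(0, 1, length.out = steps)
  x <- a[1L] + t * (b[1L] - a[1L])
  y <- a[2L] + t * (b[2L] - a[2L])
  cl <- pmin(pmax(floor(x), 0), nc - 1L) + 1L
  rw <- pmin(pmax(floor(y), 0), nr - 1L) + 1L
  unique(cbind(row = rw, col = cl))
}
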