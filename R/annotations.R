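#' Polygon annotation of a single structure
#'
#' An annotation is one simple closed polygon outlining a functional
#' tissue unit (glomerulus, crypt) or an anatomical region (cortex,
#' medulla, ...) on a whole-slide image, in pixel coordinates.
#'
#' @param id unique identifier (character or integer scalar).
#' @param category one of `"glomerulus"`, `"crypt"`, `"cortex"`,
#'   `"medulla"`, `"background"`, `"other"`.
#' @param ring numeric matrix with two columns `(x, y)` of polygon
#'   vertices in pixel coordinates (x along columns, y down rows). The
#'   ring is closed implicitly; do not repeat the first vertex.
#' @param holes optional list of interior rings (same format) subtracted
#'   at rasterization.
#' @return An object of class `ftu_annotation`.
#' @export
annotation <- function(id, category, ring, holes = list()) {
  category <- match.arg(category, ftu_categories())
  ring <- as_ring(ring)
  if (nrow(unique(ring)) < 3L)
    stop("degenerate polygon: a ring needs at least 3 distinct vertices",
         call. = FALSE)
  holes <- lapply(holes, as_ring)
  structure(list(id = id, category = category, ring = ring, holes = holes),
            class = "ftu_annotation")
}

ftu_categories <- function() {
  c("glomerulus", "crypt", "cortex", "medulla", "background", "other")
}

#' Categories counted as functional tissue units
#' @return Character vector of FTU category names.
#' @export
ftu_kinds <- function() c("glomerulus", "crypt")

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || !is.numeric(ring))
    stop("a ring must be a numeric matrix with columns (x, y)", call. = FALSE)
  storage.mode(ring) <- "double"
  dimnames(ring) <- list(NULL, c("x", "y"))
  # drop a duplicated closing vertex if present
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

#' Per-WSI collection of polygon annotations
#'
#' @param wsi_id text identifier of the whole-slide image.
#' @param image_shape integer `(rows, cols)` extent in pixels.
#' @param pixel_size_um physical edge length of one pixel in micrometers
#'   (0.5 for the kidney WSIs this package models by default).
#' @param annotations list of [annotation()] objects.
#' @return An object of class `ftu_annotation_set`.
#' @export
annotation_set <- function(wsi_id, image_shape, pixel_size_um,
                           annotations = list()) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0L))
    stop("image_shape must be two positive integers (rows, cols)",
         call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive", call. = FALSE)
  for (a in annotations) {
    if (!inherits(a, "ftu_annotation"))
      stop("annotations must be a list of ftu_annotation objects",
           call. = FALSE)
    if (any(a$ring[, 1] < 0) || any(a$ring[, 1] > image_shape[2L]) ||
        any(a$ring[, 2] < 0) || any(a$ring[, 2] > image_shape[1L]))
      stop(sprintf("annotation '%s' has vertices outside the image extent",
                   a$id), call. = FALSE)
  }
  structure(list(wsi_id = as.character(wsi_id), image_shape = image_shape,
                 pixel_size_um = pixel_size_um, annotations = annotations),
            class = "ftu_annotation_set")
}

#' @export
print.ftu_annotation_set <- function(x, ...) {
  cats <- table(vapply(x$annotations, `[[`, "", "category"))
  cat(sprintf("<ftu_annotation_set> %s: %d x %d px @ %g um/px, %d annotations\n",
              x$wsi_id, x$image_shape[1L], x$image_shape[2L],
              x$pixel_size_um, length(x$annotations)))
  if (length(cats))
    cat("  ", paste(sprintf("%s: %d", names(cats), cats), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
print.ftu_annotation <- function(x, ...) {
  cat(sprintf("<ftu_annotation> id=%s category=%s vertices=%d holes=%d\n",
              x$id, x$category, nrow(x$ring), length(x$holes)))
  invisible(x)
}

#' Read polygon annotations from a GeoJSON-style file
#'
#' Reads a FeatureCollection of Polygon features, as written by pathology
#' annotation tools (QuPath-style exports). The feature's classification
#' property (`properties$classification$name`, or `properties$category`)
#' is mapped to the annotation category; unrecognized names map to
#' `"other"`. Image shape and pixel size are taken from top-level
#' `image_shape` / `pixel_size_um` members when present, else from the
#' arguments.
#'
#' @param path file to read.
#' @param image_shape,pixel_size_um fallbacks when absent from the file.
#' @param wsi_id fallback WSI identifier (defaults to the file name).
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, image_shape = NULL, pixel_size_um = NULL,
                             wsi_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$type) || !identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  anns <- lapply(seq_along(doc$features), function(i) {
    ft <- doc$features[[i]]
    geom <- ft$geometry
    if (is.null(geom$type) || !identical(geom$type, "Polygon"))
      stop(sprintf("unsupported geometry '%s' in feature %d (only Polygon is supported)",
                   if (is.null(geom$type)) "<none>" else geom$type, i),
           call. = FALSE)
    rings <- lapply(geom$coordinates, function(rg)
      do.call(rbind, lapply(rg, function(p) c(p[[1L]], p[[2L]]))))
    cat_name <- ft$properties$classification$name
    if (is.null(cat_name)) cat_name <- ft$properties$category
    if (is.null(cat_name)) cat_name <- "other"
    cat_name <- tolower(as.character(cat_name))
    if (!cat_name %in% ftu_categories()) cat_name <- "other"
    id <- ft$id
    if (is.null(id)) id <- ft$properties$id
    if (is.null(id)) id <- i
    annotation(id = id, category = cat_name, ring = rings[[1L]],
               holes = if (length(rings) > 1L) rings[-1L] else list())
  })
  shp <- if (!is.null(doc$image_shape))
    unlist(doc$image_shape) else image_shape
  psz <- if (!is.null(doc$pixel_size_um))
    doc$pixel_size_um else pixel_size_um
  wid <- if (!is.null(doc$wsi_id)) doc$wsi_id
         else if (!is.null(wsi_id)) wsi_id
         else sub("\\.[^.]*$", "", basename(path))
  if (is.null(shp)) {
    # smallest extent containing every vertex
    allv <- do.call(rbind, lapply(anns, `[[`, "ring"))
    shp <- if (is.null(allv)) c(1L, 1L)
           else ceiling(c(max(allv[, 2]), max(allv[, 1])))
  }
  if (is.null(psz)) psz <- 0.5
  annotation_set(wid, shp, psz, anns)
}

#' Write polygon annotations to a GeoJSON-style file
#'
#' Writes a FeatureCollection readable by [read_annotations()]; the
#' round-trip preserves every vertex exactly. Image shape, pixel size and
#' WSI id are stored as top-level members alongside the features.
#'
#' @param aset an [annotation_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(aset, path) {
  stopifnot(inherits(aset, "ftu_annotation_set"))
  ring_to_coords <- function(rg) {
    closed <- rbind(rg, rg[1L, , drop = FALSE])
    lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
  }
  features <- lapply(aset$annotations, function(a) {
    list(type = "Feature", id = a$id,
         properties = list(classification = list(name = a$category)),
         geometry = list(type = "Polygon",
                         coordinates = c(list(ring_to_coords(a$ring)),
                                         lapply(a$holes, ring_to_coords))))
  })
  doc <- list(type = "FeatureCollection",
              wsi_id = aset$wsi_id,
              image_shape = aset$image_shape,
              pixel_size_um = aset$pixel_size_um,
              features = features)
  # digits = I(17): significant-digit precision sufficient to make the
  # double -> decimal -> double round trip bit-exact
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}
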