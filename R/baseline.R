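#' Baseline threshold-plus-watershed segmenter
#'
#' A classical end-to-end demonstrator for flat-shaded or
#' well-contrasted images: intensity threshold, hole filling, removal
#' of specks below `min_size_px`, then marker-controlled watershed
#' separation. It stands at the start of the evaluation pipeline where
#' a learned model's prediction would normally enter.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param intensity_threshold foreground threshold.
#' @param params a [separation_params()].
#' @param invert set when objects are darker than the background, so
#'   pixels below the threshold are foreground.
#' @param min_size_px components smaller than this are discarded as
#'   specks.
#' @return Integer label matrix.
#' @export
baseline_segment <- function(image, intensity_threshold = 0.5,
                             params = separation_params(),
                             invert = FALSE, min_size_px = 20) {
  stopifnot(is.matrix(image), is.numeric(image))
  fg <- if (invert) image < intensity_threshold
        else image > intensity_threshold
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  fg <- EBImage::fillHull(fg * 1) > 0
  comp <- label_components(fg, connectivity = 8)
  sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
  small <- which(sizes < min_size_px)
  if (length(small)) fg[comp %in% small] <- FALSE
  watershed_separate(fg, params)
}
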