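#' Run-length encode a binary mask
#'
#' Encodes in the submission dialect of the Kaggle platform: pixels are
#' numbered 1-based in column-major order (top to bottom within a
#' column, then the next column to the right) and each maximal run of
#' foreground pixels becomes a `(start, length)` pair. Column-major
#' numbering coincides with R's native matrix storage order.
#'
#' @param mask logical matrix.
#' @param wsi_id optional identifier carried along with the record.
#' @return A list of class `ftu_rle` with `wsi_id`, `shape` and an
#'   integer matrix `runs` with columns `start`, `length`.
#' @export
rle_encode <- function(mask, wsi_id = NA_character_) {
  mask <- assert_binary_mask(mask)
  v <- as.vector(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- cbind(start = starts[keep], length = r$lengths[keep])
  if (!nrow(runs)) runs <- matrix(integer(), 0L, 2L,
                                  dimnames = list(NULL, c("start", "length")))
  structure(list(wsi_id = wsi_id, shape = dim(mask), runs = runs),
            class = "ftu_rle")
}

#' Decode a run-length record back into a binary mask
#'
#' Exact inverse of [rle_encode()]. Runs must be strictly increasing,
#' non-overlapping, and lie within `prod(shape)`.
#'
#' @param rec an `ftu_rle` object, or a list with `shape` and `runs`.
#' @return Logical matrix of dimension `rec$shape`.
#' @export
rle_decode <- function(rec) {
  shape <- as.integer(rec$shape)
  runs <- rec$runs
  npx <- prod(shape)
  m <- logical(npx)
  if (length(runs) && nrow(runs)) {
    starts <- as.numeric(runs[, 1L]); lens <- as.numeric(runs[, 2L])
    if (any(starts < 1) || any(lens < 1))
      stop("runs must have positive start and length", call. = FALSE)
    ends <- starts + lens - 1
    if (any(ends > npx))
      stop("run exceeds the image extent (rows x cols)", call. = FALSE)
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] <= ends[-length(ends)]))
      stop("runs overlap or are not strictly increasing", call. = FALSE)
    idx <- sequence(lens, from = starts)
    m[idx] <- TRUE
  }
  matrix(m, shape[1L], shape[2L])
}

#' Parse a run-length string of the submission format
#'
#' @param s space-separated alternating starts and lengths, e.g.
#'   `"1 3 10 5"`; empty or `NA` means an empty mask.
#' @param shape image shape `(rows, cols)`.
#' @param wsi_id optional identifier.
#' @return An `ftu_rle` record.
#' @export
rle_from_string <- function(s, shape, wsi_id = NA_character_) {
  nums <- if (is.na(s) || !nzchar(trimws(s))) integer()
          else as.integer(strsplit(trimws(s), "\\s+")[[1L]])
  if (length(nums) %% 2L != 0L)
    stop("run-length string must contain start/length pairs", call. = FALSE)
  runs <- matrix(nums, ncol = 2L, byrow = TRUE,
                 dimnames = list(NULL, c("start", "length")))
  structure(list(wsi_id = wsi_id, shape = as.integer(shape), runs = runs),
            class = "ftu_rle")
}

#' @rdname rle_from_string
#' @param rec an `ftu_rle` record to format.
#' @return `rle_to_string()`: the space-separated encoding string.
#' @export
rle_to_string <- function(rec) {
  if (!nrow(rec$runs)) return("")
  paste(as.vector(t(rec$runs)), collapse = " ")
}

#' Read and write prediction CSVs of (wsi_id, rle) rows
#'
#' The CSV holds one row per WSI with the run-length string of its
#' predicted foreground, the interchange format for predicted masks.
#' Shapes are supplied externally (they are a property of each WSI).
#'
#' @param path CSV file.
#' @param shapes named list mapping wsi_id to `(rows, cols)`.
#' @return A named list of `ftu_rle` records.
#' @export
read_rle_csv <- function(path, shapes) {
  df <- read.csv(path, colClasses = "character")
  if (!all(c("wsi_id", "rle") %in% names(df)))
    stop("prediction CSV needs columns (wsi_id, rle)", call. = FALSE)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    id <- df$wsi_id[i]
    if (is.null(shapes[[id]]))
      stop(sprintf("no image shape known for wsi_id '%s'", id), call. = FALSE)
    rle_from_string(df$rle[i], shapes[[id]], wsi_id = id)
  })
  setNames(recs, df$wsi_id)
}

#' @rdname read_rle_csv
#' @param recs list of `ftu_rle` records to write.
#' @export
write_rle_csv <- function(recs, path) {
  df <- data.frame(wsi_id = vapply(recs, `[[`, "", "wsi_id"),
                   rle = vapply(recs, rle_to_string, ""))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
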