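## Shared data types and raster/score/config I/O.
##
## Masks are integer matrices (0-based labels, background = 0) carrying a "K"
## attribute; probability maps are H x W x K arrays. Files: single-channel
## TIFF/PNG for masks, multipage TIFF (one page per class, page order = class
## index) for probability stacks, CSV for scores, JSON for configuration.

#' Construct and validate a label mask
#'
#' @param labels integer matrix with values in \code{0..K-1}.
#' @param K number of classes; defaults to \code{max(labels) + 1}.
#' @return integer matrix of class \code{label_mask} with attribute \code{K}.
#' @export
label_mask <- function(labels, K = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (any(!is.finite(labels))) stop("mask contains non-finite values")
  if (any(labels != round(labels))) stop("mask contains non-integer values")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (is.null(K)) K <- max(labels, 1L) + 1L
  K <- as.integer(K)
  if (any(labels < 0L) || any(labels >= K))
    stop("mask labels must lie in 0..K-1 (K = ", K, ")")
  structure(labels, K = K, class = c("label_mask", class(labels)))
}

#' Number of classes of a mask or probability map
#' @param x a \code{label_mask} or \code{H x W x K} array.
#' @return integer class count.
#' @export
n_classes <- function(x) {
  if (!is.null(attr(x, "K"))) return(attr(x, "K"))
  if (is.array(x) && length(dim(x)) == 3L) return(dim(x)[3L])
  stop("cannot determine class count")
}

#' Validate a probability map
#'
#' Checks that `probs` is an \code{H x W x K} array of values in \code{[0, 1]}
#' whose per-pixel class probabilities sum to one within `tol`.
#'
#' @param probs numeric array \code{H x W x K}.
#' @param tol tolerance on the per-pixel sum (default \code{1e-6}).
#' @return the validated array (invisibly unchanged).
#' @export
probability_map <- function(probs, tol = 1e-6) {
  if (!is.array(probs) || length(dim(probs)) != 3L)
    stop("probability map must be an H x W x K array")
  if (any(!is.finite(probs))) stop("probability map contains non-finite values")
  if (any(probs < -tol) || any(probs > 1 + tol))
    stop("probabilities outside [0, 1]")
  s <- apply(probs, c(1L, 2L), sum)
  if (any(abs(s - 1) > tol))
    stop("per-pixel class probabilities do not sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  probs
}

#' Read an integer label mask from TIFF or PNG
#'
#' @param path single-channel TIFF or PNG file.
#' @param expected_K if given, values must be < `expected_K` (after optional
#'   remapping).
#' @param remap if \code{TRUE}, observed values are remapped to contiguous
#'   0-based labels; otherwise they are validated as already in range.
#' @return a [label_mask()].
#' @export
read_mask <- function(path, expected_K = NULL, remap = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    ## PNG values arrive rescaled to [0, 1]; undo the 8/16-bit scaling.
    raw <- raw * if (max(raw) <= 1 && any(raw * 255 != round(raw * 255))) 65535 else 255
  } else stop("unsupported mask format: .", ext)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] != 1L) stop("mask must be single-channel")
    raw <- raw[, , 1L]
  }
  if (any(abs(raw - round(raw)) > 1e-6)) stop("non-integer pixel values in mask")
  raw <- round(raw)
  if (remap) {
    vals <- sort(unique(as.vector(raw)))
    raw <- matrix(match(raw, vals) - 1L, nrow(raw), ncol(raw))
  }
  if (!is.null(expected_K) && max(raw) >= expected_K)
    stop("mask contains label ", max(raw), " >= expected_K = ", expected_K)
  label_mask(raw, K = if (is.null(expected_K)) NULL else expected_K)
}

#' Write a label mask to TIFF or PNG
#'
#' Stored as an 8-bit (K <= 256) or 16-bit raster.
#'
#' @param mask a [label_mask()] or integer matrix.
#' @param path output path (.tif/.tiff/.png).
#' @export
write_mask <- function(mask, path) {
  K <- max(n_classes(mask), max(mask) + 1L)
  denom <- if (K <= 256L) 255 else 65535
  img <- unclass(mask) / denom
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = if (denom == 255) 8L else 16L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' Read a class-probability stack from a multipage TIFF
#'
#' One page per class, page order = class index. Per-pixel sums deviating
#' from 1 by at most `renorm_tol` are renormalised; larger deviations error.
#'
#' @param path multipage TIFF.
#' @param renorm_tol maximum tolerated per-pixel sum deviation (default 1e-3).
#' @return \code{H x W x K} probability array.
#' @export
read_probability_stack <- function(path, renorm_tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  probs <- simplify2array(pages)
  if (length(dim(probs)) != 3L) stop("probability stack must have K 2D pages")
  if (any(probs < 0)) stop("negative values in probability stack")
  s <- apply(probs, c(1L, 2L), sum)
  if (any(abs(s - 1) > renorm_tol))
    stop("per-pixel sums deviate from 1 by more than ", renorm_tol,
         " (max deviation ", format(max(abs(s - 1))), ")")
  probs <- sweep(probs, c(1L, 2L), s, "/")
  probability_map(probs)
}

#' Write a class-probability stack to a multipage TIFF
#'
#' @param probs \code{H x W x K} probability array.
#' @param path output .tif path; pages are written as 32-bit floats.
#' @export
write_probability_stack <- function(probs, path) {
  probs <- probability_map(probs)
  pages <- lapply(seq_len(dim(probs)[3L]), function(k) probs[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multichannel image (TIFF or PNG)
#'
#' @param path image file; values are returned as stored (TIFF) or in
#'   \code{[0, 1]} (PNG).
#' @return \code{H x W x c} numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.list(pages)) simplify2array(pages) else pages
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (any(!is.finite(img))) stop("image contains non-finite values")
  img
}

#' Write an image to TIFF
#' @param img \code{H x W} matrix or \code{H x W x c} array in \code{[0, 1]}.
#' @param path output .tif path.
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img <- pmin(pmax(img, 0), 1)
  if (length(dim(img)) == 3L) {
    tiff::writeTIFF(lapply(seq_len(dim(img)[3L]), function(k) img[, , k]),
                    path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Assemble a score table
#'
#' @param image_id,entity_id,metric,value equal-length vectors; `entity_id`
#'   names the rater or model the row refers to.
#' @param extras optional data frame of additional columns.
#' @return data frame with fixed leading column order
#'   \code{image_id, entity_id, metric, value}.
#' @export
score_table <- function(image_id, entity_id, metric, value, extras = NULL) {
  df <- data.frame(image_id = as.character(image_id),
                   entity_id = as.character(entity_id),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (!is.null(extras)) df <- cbind(df, extras)
  if (anyDuplicated(df[, c("image_id", "entity_id", "metric")]))
    stop("duplicate (image, entity, metric) rows in score table")
  df
}

#' Write a score table to CSV
#'
#' UTF-8, '.' decimal separator, stable column order.
#'
#' @param table data frame as produced by [score_table()]; must be non-empty.
#' @param path output .csv path.
#' @export
write_scores <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("score table must be a non-empty data frame")
  lead <- c("image_id", "entity_id", "metric", "value")
  if (!all(lead %in% names(table)))
    stop("score table must contain columns: ", paste(lead, collapse = ", "))
  table <- table[, c(lead, setdiff(names(table), lead)), drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a score table from CSV
#' @param path .csv written by [write_scores()].
#' @return data frame.
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
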