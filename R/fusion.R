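## Ensemble / test-time-augmentation fusion: the ensemble is treated as a
## uniformly weighted mixture over M models and T deterministic views, with
## Gaussian-weighted sliding-window tiled inference for large images.

#' The deterministic test-time augmentation views
#'
#' Four self-inverse dihedral transforms: identity, horizontal flip, vertical
#' flip, and 180-degree rotation. Each is its own inverse, so the set is valid
#' for non-square tiles.
#'
#' @return character vector of view identifiers, in deterministic order.
#' @export
tta_views <- function() c("identity", "hflip", "vflip", "rot180")

#' Apply a test-time augmentation view to an image or probability map
#'
#' Transforms the first two (spatial) dimensions; trailing channel/class
#' dimensions are untouched. All views are involutions, so [invert_view()]
#' is the same operation.
#'
#' @param x matrix or H x W x c array.
#' @param view one of [tta_views()].
#' @return transformed array of the same shape.
#' @export
apply_view <- function(x, view) {
  if (!view %in% tta_views()) stop("unknown view id: ", view)
  if (view == "identity") return(x)
  d <- dim(x)
  ri <- if (view %in% c("vflip", "rot180")) rev(seq_len(d[1L])) else seq_len(d[1L])
  ci <- if (view %in% c("hflip", "rot180")) rev(seq_len(d[2L])) else seq_len(d[2L])
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' @rdname apply_view
#' @export
invert_view <- function(x, view) apply_view(x, view)

#' Gaussian importance weight map for tile stitching
#'
#' Separable Gaussian centred on the tile centre with per-axis
#' \eqn{\sigma = \mathrm{dim} \times \mathtt{sigma\_scale}}, normalised so the
#' maximum sampled weight is 1 and floored at 1e-8. Predictions near tile
#' borders thereby contribute less where tiles overlap.
#'
#' @param tile_shape integer vector \code{c(h, w)}.
#' @param sigma_scale sigma as a fraction of the tile dimension (default 1/8).
#' @return \code{h x w} weight matrix with values in \code{(0, 1]}.
#' @export
gaussian_weight_map <- function(tile_shape, sigma_scale = 1 / 8) {
  if (sigma_scale <= 0) stop("`sigma_scale` must be positive")
  if (any(tile_shape < 1L)) stop("tile dimensions must be >= 1")
  axis_weights <- function(n) {
    c0 <- (n + 1) / 2
    w <- exp(-((seq_len(n) - c0)^2) / (2 * (n * sigma_scale)^2))
    w / max(w)
  }
  w <- outer(axis_weights(tile_shape[1L]), axis_weights(tile_shape[2L]))
  pmax(w, 1e-8)
}

#' Plan sliding-window tiles over an image
#'
#' Windows of `tile_shape` with stride \code{tile * (1 - overlap)}; the last
#' row/column of windows is shifted inward so no window exceeds the image.
#' Every pixel is covered at least once.
#'
#' @param image_shape integer \code{c(H, W)}; must be >= `tile_shape`
#'   (pad smaller images first, see [pad_reflect()]).
#' @param tile_shape integer \code{c(h, w)}.
#' @param overlap overlap fraction in \code{[0, 0.9]} (default 0.5).
#' @return data frame of 1-based inclusive windows
#'   (\code{r0, r1, c0, c1}).
#' @export
tile_plan <- function(image_shape, tile_shape, overlap = 0.5) {
  if (any(image_shape < 1L)) stop("zero-size image")
  if (overlap < 0 || overlap > 0.9) stop("`overlap` must be in [0, 0.9]")
  if (any(tile_shape > image_shape))
    stop("tile exceeds image; pad the image first")
  starts <- function(len, tile) {
    stride <- max(1L, as.integer(round(tile * (1 - overlap))))
    s <- seq.int(1L, max(1L, len - tile + 1L), by = stride)
    if (s[length(s)] + tile - 1L < len) s <- c(s, len - tile + 1L)
    s
  }
  rs <- starts(image_shape[1L], tile_shape[1L])
  cs <- starts(image_shape[2L], tile_shape[2L])
  grid <- expand.grid(r0 = rs, c0 = cs, KEEP.OUT.ATTRS = FALSE)
  data.frame(r0 = grid$r0, r1 = grid$r0 + tile_shape[1L] - 1L,
             c0 = grid$c0, c1 = grid$c0 + tile_shape[2L] - 1L)
}

#' Pad an array to a minimum shape by symmetric reflection
#'
#' @param x matrix or H x W x c array.
#' @param target_shape minimum \code{c(H, W)} after padding.
#' @return padded array; original content sits at the top-left.
#' @export
pad_reflect <- function(x, target_shape) {
  d <- dim(x)
  mirror_idx <- function(n, target) {
    if (target <= n) return(seq_len(max(n, target)))
    idx <- seq_len(n)
    while (length(idx) < target) idx <- c(idx, rev(idx))[seq_len(min(2L * length(idx), target))]
    idx[seq_len(target)]
  }
  ri <- mirror_idx(d[1L], target_shape[1L])
  ci <- mirror_idx(d[2L], target_shape[2L])
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Stitch overlapping tile predictions with Gaussian weights
#'
#' Per pixel, the weighted average of all overlapping tile predictions using
#' the tile-local Gaussian weights, renormalised by the accumulated weight.
#'
#' @param tile_maps list of \code{h x w x K} probability arrays, one per
#'   window.
#' @param windows data frame from [tile_plan()].
#' @param weight_map \code{h x w} weights from [gaussian_weight_map()].
#' @param image_shape output \code{c(H, W)}.
#' @return \code{H x W x K} probability array.
#' @export
stitch <- function(tile_maps, windows, weight_map, image_shape) {
  stopifnot(length(tile_maps) == nrow(windows))
  K <- dim(tile_maps[[1L]])[3L]
  acc <- array(0, dim = c(image_shape, K))
  wacc <- matrix(0, image_shape[1L], image_shape[2L])
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    wm <- weight_map
    acc[w$r0:w$r1, w$c0:w$c1, ] <-
      acc[w$r0:w$r1, w$c0:w$c1, , drop = FALSE] +
      tile_maps[[i]] * as.vector(wm)
    wacc[w$r0:w$r1, w$c0:w$c1] <- wacc[w$r0:w$r1, w$c0:w$c1] + wm
  }
  if (any(wacc == 0)) stop("tile windows do not cover the image")
  p <- sweep(acc, c(1L, 2L), wacc, "/")
  s <- apply(p, c(1L, 2L), sum)
  probability_map(sweep(p, c(1L, 2L), s, "/"))
}

#' Construct an ensemble output container
#'
#' Holds one probability map per (model m, view t), all aligned to the same
#' pixel frame.
#'
#' @param maps nested list: \code{maps[[m]][[t]]} is an \code{H x W x K}
#'   probability array.
#' @param view_ids view identifiers, defaults to [tta_views()] truncated to T.
#' @return object of class \code{ensemble_output} with fields \code{maps},
#'   \code{M}, \code{T}, \code{view_ids}.
#' @export
ensemble_output <- function(maps, view_ids = NULL) {
  if (!is.list(maps) || length(maps) == 0L || !is.list(maps[[1L]]))
    stop("`maps` must be a nested list maps[[m]][[t]]")
  M <- length(maps)
  T_ <- length(maps[[1L]])
  d <- dim(maps[[1L]][[1L]])
  for (m in seq_len(M)) {
    if (length(maps[[m]]) != T_) stop("all models must have the same view count")
    for (t in seq_len(T_))
      if (!identical(dim(maps[[m]][[t]]), d)) stop("ensemble maps differ in shape")
  }
  if (is.null(view_ids)) view_ids <- tta_views()[seq_len(min(T_, 4L))]
  structure(list(maps = maps, M = M, T = T_, view_ids = view_ids),
            class = "ensemble_output")
}

#' @export
print.ensemble_output <- function(x, ...) {
  d <- dim(x$maps[[1L]][[1L]])
  cat("ensemble_output: M =", x$M, "models x T =", x$T, "views,",
      d[1L], "x", d[2L], "pixels,", d[3L], "classes\n")
  invisible(x)
}

#' Fuse an ensemble into the uniformly weighted mixture prediction
#'
#' The fused probability is the plain average over all M x T member maps
#' (a uniformly weighted mixture over models and views); the predicted
#' segmentation is the per-pixel argmax with ties resolved to the lowest
#' class index (background-favouring).
#'
#' @param ensemble an [ensemble_output()] with maps aligned to the original
#'   pixel frame (views already inverted).
#' @return object of class \code{fused_prediction}: list with \code{p}
#'   (H x W x K mixture) and \code{yhat} ([label_mask()]).
#' @export
fuse <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_output"))
  d <- dim(ensemble$maps[[1L]][[1L]])
  acc <- array(0, dim = d)
  for (m in seq_len(ensemble$M))
    for (t in seq_len(ensemble$T))
      acc <- acc + ensemble$maps[[m]][[t]]
  p <- acc / (ensemble$M * ensemble$T)
  flat <- matrix(p, nrow = d[1L] * d[2L], ncol = d[3L])
  yhat <- label_mask(matrix(max.col(flat, ties.method = "first") - 1L,
                            d[1L], d[2L]), K = d[3L])
  structure(list(p = probability_map(p), yhat = yhat),
            class = "fused_prediction")
}

#' @export
print.fused_prediction <- function(x, ...) {
  d <- dim(x$p)
  cat("fused_prediction:", d[1L], "x", d[2L], "pixels,", d[3L], "classes;",
      sum(x$yhat > 0L), "foreground pixels\n")
  invisible(x)
}

#' Tiled, test-time-augmented ensemble prediction of one image
#'
#' Orchestrates the full inference geometry: for each view, the transformed
#' image is cut into overlapping tiles (reflection-padded when smaller than
#' a tile), each ensemble member predicts every tile, tiles are stitched
#' with Gaussian importance weights, the view geometry is inverted, and the
#' M x T maps are fused into the mixture prediction.
#'
#' @param predictor function \code{(member, tile)} returning an
#'   \code{h x w x K} probability array; must be deterministic given
#'   (member, tile).
#' @param image \code{H x W x c} array (or matrix).
#' @param M number of ensemble members (default 5).
#' @param tile_shape tile size (default \code{c(512, 512)}).
#' @param overlap tile overlap fraction (default 0.5).
#' @param sigma_scale Gaussian weight sigma as fraction of tile size.
#' @param tta use all four views (default) or identity only.
#' @return list with \code{ensemble} ([ensemble_output()], original frame)
#'   and \code{fused} ([fuse()] result).
#' @export
predict_image <- function(predictor, image, M = 5L,
                          tile_shape = c(512L, 512L), overlap = 0.5,
                          sigma_scale = 1 / 8, tta = TRUE) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)[1:2]
  views <- if (tta) tta_views() else "identity"
  pad_shape <- pmax(d, tile_shape)
  windows <- tile_plan(pad_shape, tile_shape, overlap)
  wm <- gaussian_weight_map(tile_shape, sigma_scale)

  maps <- lapply(seq_len(M), function(m) vector("list", length(views)))
  for (ti in seq_along(views)) {
    vimg <- pad_reflect(apply_view(image, views[ti]), pad_shape)
    for (m in seq_len(M)) {
      tile_maps <- lapply(seq_len(nrow(windows)), function(i) {
        w <- windows[i, ]
        out <- predictor(m, vimg[w$r0:w$r1, w$c0:w$c1, , drop = FALSE])
        probability_map(out)
      })
      full <- stitch(tile_maps, windows, wm, pad_shape)
      full <- full[seq_len(d[1L]), seq_len(d[2L]), , drop = FALSE]
      maps[[m]][[ti]] <- invert_view(full, views[ti])
    }
  }
  ens <- ensemble_output(maps, view_ids = views)
  list(ensemble = ens, fused = fuse(ens))
}
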