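## Instance derivation from semantic predictions: per-class connected
## components (4- or 8-connectivity), optional marker-based watershed
## splitting of touching objects on the distance transform, minimum-size
## filtering, and semantic<->instance consistency accounting.

#' Construct an instance label map
#'
#' @param instances integer matrix; 0 = background, positive integers are
#'   instance ids (contiguous from 1).
#' @param class_of integer vector mapping instance id -> semantic class.
#' @param min_size_applied the minimum-size filter already applied (0 = none).
#' @return object of class \code{instance_map}.
#' @export
instance_map <- function(instances, class_of = NULL, min_size_applied = 0L) {
  if (!is.matrix(instances)) stop("`instances` must be a matrix")
  instances <- matrix(as.integer(instances), nrow(instances), ncol(instances))
  n <- max(instances, 0L)
  if (n > 0L && !setequal(setdiff(unique(as.vector(instances)), 0L), seq_len(n)))
    stop("instance ids must be contiguous positive integers")
  if (is.null(class_of)) class_of <- rep(1L, n)
  if (length(class_of) != n) stop("`class_of` must have one entry per instance")
  structure(list(instances = instances, class_of = as.integer(class_of),
                 min_size_applied = as.integer(min_size_applied)),
            class = "instance_map")
}

#' @export
print.instance_map <- function(x, ...) {
  cat("instance_map:", nrow(x$instances), "x", ncol(x$instances), "pixels,",
      max(x$instances, 0L), "instances",
      if (x$min_size_applied > 0L) paste0("(min size ", x$min_size_applied, ")") else "",
      "\n")
  invisible(x)
}

## Connected-component labelling of a logical matrix under 4- or
## 8-connectivity. Components are numbered in raster-scan order (row-major,
## top-left origin) of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)  # column-major linear indices
  out <- matrix(0L, H, W)
  if (length(fg) == 0L) return(out)
  node <- integer(H * W)
  node[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% H) + 1L
  cc <- ((fg - 1L) %/% H) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (s in shifts) {
    rr <- r + s[1L]; cn <- cc + s[2L]
    ok <- rr >= 1L & rr <= H & cn >= 1L & cn <= W
    nb <- (cn[ok] - 1L) * H + rr[ok]
    both <- node[nb] > 0L
    if (any(both))
      edges[[length(edges) + 1L]] <- cbind(node[fg[ok]][both], node[nb][both])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  ## renumber components by raster-scan (row-major) order of first pixel
  rowmajor <- (r - 1L) * W + cc
  first <- tapply(rowmajor, comp, min)
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  out[fg] <- relabel[comp]
  out
}

#' Derive instances from a semantic segmentation
#'
#' Per non-background class, connected components of the class mask become
#' instances. With \code{split = "watershed"}, touching objects are
#' subdivided by flooding the negated Euclidean distance transform, with
#' \code{min_distance} as the neighbourhood radius used to detect distinct
#' basins. Instances never span classes; ids are assigned in raster-scan
#' order of each component's first pixel, classes in ascending order.
#'
#' @param yhat [label_mask()] prediction.
#' @param connectivity 4 or 8 (default 8).
#' @param split \code{"none"} (default) or \code{"watershed"}.
#' @param min_distance minimum basin separation in pixels for watershed
#'   splitting (default 5).
#' @return an [instance_map()].
#' @export
derive_instances <- function(yhat, connectivity = 8L,
                             split = c("none", "watershed"),
                             min_distance = 5L) {
  split <- match.arg(split)
  K <- n_classes(yhat)
  m <- unclass(yhat)
  out <- matrix(0L, nrow(m), ncol(m))
  class_of <- integer(0)
  next_id <- 0L
  for (k in seq_len(K - 1L)) {
    mask <- m == k
    if (!any(mask)) next
    lab <- if (split == "watershed") {
      d <- EBImage::distmap(mask * 1)
      w <- EBImage::watershed(d, tolerance = 1, ext = as.integer(min_distance))
      relabel_raster_order(matrix(as.integer(w), nrow(m), ncol(m)))
    } else {
      label_components(mask, connectivity)
    }
    n_k <- max(lab)
    out[lab > 0L] <- lab[lab > 0L] + next_id
    class_of <- c(class_of, rep(k, n_k))
    next_id <- next_id + n_k
  }
  instance_map(out, class_of)
}

## Renumber positive labels of a matrix in raster-scan order of first pixel.
relabel_raster_order <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pos <- which(lab > 0L)
  r <- ((pos - 1L) %% H) + 1L
  cc <- ((pos - 1L) %/% H) + 1L
  rowmajor <- (r - 1L) * W + cc
  first <- tapply(rowmajor, lab[pos], min)
  ord <- order(first)
  relabel <- integer(max(ids))
  relabel[as.integer(names(first))[ord]] <- seq_along(ids)
  lab[pos] <- relabel[lab[pos]]
  lab
}

#' Remove instances below a minimum size
#'
#' Instances with strictly fewer than `min_size` pixels are removed (their
#' pixels become background); instances of exactly `min_size` pixels are
#' retained. Surviving ids are recompacted, preserving order. Idempotent.
#'
#' @param imap an [instance_map()].
#' @param min_size minimum viable instance area in pixels (>= 0).
#' @return filtered [instance_map()] with \code{min_size_applied} recorded.
#' @export
size_filter <- function(imap, min_size) {
  stopifnot(inherits(imap, "instance_map"), min_size >= 0)
  n <- max(imap$instances, 0L)
  if (n == 0L || min_size == 0L) {
    imap$min_size_applied <- max(imap$min_size_applied, as.integer(min_size))
    return(imap)
  }
  sizes <- tabulate(imap$instances[imap$instances > 0L], nbins = n)
  keep <- sizes >= min_size
  relabel <- integer(n)
  relabel[keep] <- seq_len(sum(keep))
  inst <- imap$instances
  pos <- inst > 0L
  inst[pos] <- relabel[inst[pos]]
  instance_map(inst, imap$class_of[keep],
               min_size_applied = max(imap$min_size_applied, as.integer(min_size)))
}

#' Report pixels dropped between semantic and instance segmentation
#'
#' Counts foreground pixels of the semantic prediction that are background
#' in the derived (possibly size-filtered) instance map — a consistency
#' check between the two representations.
#'
#' @param yhat semantic [label_mask()].
#' @param imap derived [instance_map()].
#' @return list with \code{removed_pixels} and \code{removed_fraction}
#'   (0 when the prediction has no foreground).
#' @export
instance_consistency_report <- function(yhat, imap) {
  if (!identical(dim(unclass(yhat)), dim(imap$instances)))
    stop("shapes differ")
  fg <- unclass(yhat) > 0L
  n_fg <- sum(fg)
  removed <- sum(fg & imap$instances == 0L)
  list(removed_pixels = removed,
       removed_fraction = if (n_fg > 0L) removed / n_fg else 0)
}

#' Mean uncertainty per instance
#'
#' Averages the aggregated uncertainty map over each instance's pixels;
#' rows are sorted by decreasing mean uncertainty so the most doubtful
#' objects come first for review.
#'
#' @param imap an [instance_map()].
#' @param aggregated \code{H x W} map from [aggregate_uncertainty()].
#' @return data frame (\code{instance, class, size, mean_uncertainty}),
#'   sorted by decreasing mean uncertainty.
#' @export
per_instance_uncertainty <- function(imap, aggregated) {
  if (!identical(dim(imap$instances), dim(aggregated))) stop("shapes differ")
  n <- max(imap$instances, 0L)
  if (n == 0L)
    return(data.frame(instance = integer(0), class = integer(0),
                      size = integer(0), mean_uncertainty = numeric(0)))
  pos <- imap$instances > 0L
  ids <- imap$instances[pos]
  sizes <- tabulate(ids, nbins = n)
  means <- as.vector(tapply(aggregated[pos], ids, mean))
  df <- data.frame(instance = seq_len(n), class = imap$class_of,
                   size = sizes, mean_uncertainty = means)
  df[order(-df$mean_uncertainty, df$instance), , drop = FALSE]
}
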