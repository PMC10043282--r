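## Moment-based uncertainty of an ensemble prediction: per-class variance
## maps split into an epistemic and an aleatoric term, a scaled aggregate
## across classes, and the scalar foreground uncertainty score U used for
## quality assurance.

#' Per-class epistemic/aleatoric variance maps of an ensemble
#'
#' For each class k, averaging over all M x T member maps p:
#' \deqn{\mathrm{epistemic}_k = \mathrm{mean}(p - p^2), \quad
#'       \mathrm{aleatoric}_k = \mathrm{mean}((p - \bar p_k)^2),}
#' where \eqn{\bar p_k} is the fused mixture probability of class k. The
#' total per-class variance is their sum and is bounded by 0.25 at every
#' pixel for any admissible ensemble.
#'
#' @param ensemble an [ensemble_output()], maps aligned to the original frame.
#' @param fused optional [fuse()] result; recomputed when missing.
#' @return list with \code{epistemic}, \code{aleatoric}, \code{total}
#'   (each \code{H x W x K}) and the \code{fused} prediction used.
#' @export
classwise_variance <- function(ensemble, fused = NULL) {
  stopifnot(inherits(ensemble, "ensemble_output"))
  if (is.null(fused)) fused <- fuse(ensemble)
  d <- dim(fused$p)
  if (!identical(dim(ensemble$maps[[1L]][[1L]]), d))
    stop("ensemble and fused prediction shapes differ")
  epi <- array(0, d); ale <- array(0, d)
  n <- ensemble$M * ensemble$T
  for (m in seq_len(ensemble$M)) {
    for (t in seq_len(ensemble$T)) {
      p <- ensemble$maps[[m]][[t]]
      epi <- epi + (p - p^2)
      ale <- ale + (p - fused$p)^2
    }
  }
  epi <- epi / n
  ale <- ale / n
  list(epistemic = epi, aleatoric = ale, total = epi + ale, fused = fused)
}

#' Aggregate per-class variances into one uncertainty map
#'
#' \deqn{\mathrm{agg} = (\zeta / K) \sum_k \mathrm{total}_k.}
#' With the default \eqn{\zeta = 4} and K = 2 the theoretical per-pixel
#' maximum is exactly 1.
#'
#' @param total \code{H x W x K} per-class total variance array (from
#'   [classwise_variance()]).
#' @param zeta positive scaling factor (default 4).
#' @return \code{H x W} aggregated uncertainty matrix.
#' @export
aggregate_uncertainty <- function(total, zeta = 4) {
  if (zeta <= 0) stop("`zeta` must be positive")
  K <- dim(total)[3L]
  if (is.null(K) || K < 2L) stop("aggregation requires K >= 2 class maps")
  (zeta / K) * apply(total, c(1L, 2L), sum)
}

#' Scalar foreground uncertainty score U
#'
#' The mean aggregated uncertainty over predicted foreground pixels
#' (label > 0). When the prediction contains no foreground, U falls back to
#' the global mean and the record is flagged \code{"no_foreground"} so the
#' quality-assurance step never silently drops such images.
#'
#' @param aggregated \code{H x W} map from [aggregate_uncertainty()].
#' @param yhat predicted [label_mask()].
#' @return list with \code{U} (scalar), \code{n_foreground}, \code{flags}
#'   (character vector, possibly empty).
#' @export
foreground_uncertainty_score <- function(aggregated, yhat) {
  if (!identical(dim(aggregated), dim(unclass(yhat))[1:2]))
    stop("aggregated map and prediction shapes differ")
  fg <- unclass(yhat) > 0L
  if (any(fg)) {
    list(U = mean(aggregated[fg]), n_foreground = sum(fg), flags = character(0))
  } else {
    list(U = mean(aggregated), n_foreground = 0L, flags = "no_foreground")
  }
}

#' Full uncertainty quantification of an ensemble prediction
#'
#' Convenience wrapper: per-class variance decomposition, aggregation, and
#' the foreground score in one call.
#'
#' @inheritParams classwise_variance
#' @param zeta aggregation scaling factor (default 4).
#' @return object of class \code{uncertainty_result}: list with
#'   \code{epistemic}, \code{aleatoric}, \code{total} (H x W x K),
#'   \code{aggregated} (H x W), \code{zeta}, \code{U}, \code{n_foreground},
#'   \code{flags}, and the \code{fused} prediction.
#' @export
uncertainty_maps <- function(ensemble, fused = NULL, zeta = 4) {
  cv <- classwise_variance(ensemble, fused)
  agg <- aggregate_uncertainty(cv$total, zeta = zeta)
  sc <- foreground_uncertainty_score(agg, cv$fused$yhat)
  structure(c(cv, list(aggregated = agg, zeta = zeta, U = sc$U,
                       n_foreground = sc$n_foreground, flags = sc$flags)),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat("uncertainty_result: U =", format(round(x$U, 4)),
      "| foreground pixels:", x$n_foreground,
      if (length(x$flags)) paste("| flags:", paste(x$flags, collapse = ",")) else "",
      "\n")
  invisible(x)
}
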