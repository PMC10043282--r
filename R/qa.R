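## Uncertainty-driven quality assurance: rank predictions by the foreground
## uncertainty score U, derive the review threshold U_min from a labelled
## hold-out set, flag images for manual verification, and quantify the
## U-vs-score relationship.

check_records <- function(records, need_S = FALSE) {
  if (!is.data.frame(records) || !all(c("image_id", "U") %in% names(records)))
    stop("records must be a data frame with columns image_id, U")
  if (need_S && (!"S" %in% names(records) || any(is.na(records$S))))
    stop("labelled records with a score column S are required")
  records
}

#' Rank predictions by decreasing uncertainty
#'
#' Rank 1 is the most uncertain prediction; ties are broken by image id.
#' Reviewing from rank 1 downwards inspects the most doubtful (and likely
#' out-of-distribution) images first.
#'
#' @param records data frame with columns \code{image_id}, \code{U} (and
#'   optionally more).
#' @return the records ordered by decreasing U with a \code{rank} column.
#' @export
rank_by_uncertainty <- function(records) {
  records <- check_records(records)
  ord <- order(-records$U, records$image_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Derive the review threshold U_min from a labelled test set
#'
#' Selects the test records whose quality score falls below `tau` and takes
#' the minimum uncertainty among them: any new prediction with a higher
#' uncertainty may be of inadequate quality and should be verified. When no
#' test record fails, the conservative fallback U_min = max observed U is
#' used and flagged, so review is never silently disabled.
#'
#' @param test_records data frame with columns \code{image_id}, \code{U},
#'   \code{S} (quality metric in \code{[0, 1]}, e.g. Dice or mAP).
#' @param tau quality requirement in \code{[0, 1]}; records with
#'   \code{S < tau} count as failures.
#' @param metric name of the quality metric (bookkeeping only).
#' @return object of class \code{qa_threshold}: list with \code{U_min},
#'   \code{tau}, \code{metric}, \code{n_failures}, \code{fallback_used}.
#' @export
compute_u_min <- function(test_records, tau, metric = "DS") {
  test_records <- check_records(test_records, need_S = TRUE)
  if (nrow(test_records) == 0L) stop("test records must be non-empty")
  if (tau < 0 || tau > 1) stop("`tau` must be in [0, 1]")
  fail <- test_records$S < tau
  if (any(fail)) {
    u_min <- min(test_records$U[fail]); fallback <- FALSE
  } else {
    u_min <- max(test_records$U); fallback <- TRUE
  }
  structure(list(U_min = u_min, tau = tau, metric = metric,
                 n_failures = sum(fail), fallback_used = fallback),
            class = "qa_threshold")
}

#' @export
print.qa_threshold <- function(x, ...) {
  cat("qa_threshold: U_min =", format(round(x$U_min, 5)),
      "| tau =", x$tau, "(", x$metric, ")",
      "| failures:", x$n_failures,
      if (x$fallback_used) "| fallback: max-U used" else "", "\n")
  invisible(x)
}

#' Flag predictions for manual review
#'
#' Returns the records whose uncertainty exceeds \code{U_min}, sorted by
#' decreasing U. Records flagged \code{no_foreground} (empty predicted
#' foreground) are always included regardless of their U.
#'
#' @param records data frame with columns \code{image_id}, \code{U}, and
#'   optionally \code{flags} (character).
#' @param threshold a [compute_u_min()] result.
#' @return subset of `records`, ordered by decreasing U, with \code{rank}.
#' @export
flag_for_review <- function(records, threshold) {
  records <- check_records(records)
  stopifnot(inherits(threshold, "qa_threshold"))
  always <- if ("flags" %in% names(records))
    grepl("no_foreground", records$flags) else rep(FALSE, nrow(records))
  sel <- records$U > threshold$U_min | always
  rank_by_uncertainty(records[sel, , drop = FALSE])
}

#' Correlation between uncertainty score and quality score
#'
#' Pearson correlation (with the standard t-based two-tailed p-value)
#' between U and the quality metric S on a labelled set. A strongly
#' negative r indicates that U is a useful proxy for expected quality on
#' unlabelled data.
#'
#' @param test_records data frame with columns \code{U}, \code{S}; at least
#'   3 rows.
#' @return list with \code{r} and \code{p}.
#' @export
uncertainty_score_correlation <- function(test_records) {
  test_records <- check_records(test_records, need_S = TRUE)
  if (nrow(test_records) < 3L) stop("need at least 3 labelled records")
  if (stats::var(test_records$U) == 0 || stats::var(test_records$S) == 0)
    stop("zero variance in U or S; correlation undefined")
  ct <- stats::cor.test(test_records$U, test_records$S, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
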