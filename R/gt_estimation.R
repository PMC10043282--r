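## Consensus ground-truth estimation from multiple expert annotations:
## majority voting, binary STAPLE EM (Warfield-style sensitivity/specificity
## model), a one-vs-rest multiclass STAPLE with an explicit undecided-pixel
## rule, and inter-rater similarity scoring.

check_annotations <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("`masks` must be a non-empty list of label masks")
  d <- dim(masks[[1L]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("rater masks differ in shape")
  masks
}

#' Majority vote consensus of rater masks
#'
#' Per pixel, the class chosen by the most raters. Ties are resolved by
#' `tie_policy`: \code{"lowest"} (default, background-favouring since
#' background is class 0) or \code{"highest"}.
#'
#' @param masks list of [label_mask()] objects, one per rater, same shape.
#' @param tie_policy \code{"lowest"} or \code{"highest"} class index on ties.
#' @return consensus [label_mask()].
#' @export
majority_vote <- function(masks, tie_policy = c("lowest", "highest")) {
  tie_policy <- match.arg(tie_policy)
  masks <- check_annotations(masks)
  K <- max(vapply(masks, function(m) max(n_classes(m), max(m) + 1L), integer(1)))
  d <- dim(masks[[1L]])
  votes <- matrix(0L, prod(d), K)
  for (m in masks) {
    idx <- cbind(seq_len(prod(d)), as.vector(unclass(m)) + 1L)
    votes[idx] <- votes[idx] + 1L
  }
  if (tie_policy == "highest") votes <- votes[, K:1, drop = FALSE]
  win <- max.col(votes, ties.method = "first")
  if (tie_policy == "highest") win <- K + 1L - win
  label_mask(matrix(win - 1L, d[1L], d[2L]), K = K)
}

## One E-step of the binary STAPLE model: posterior foreground weight per
## pixel given rater decisions D (N x R), sensitivities p, specificities q,
## and a per-pixel (or scalar) foreground prior f. Also returns the observed
## log-likelihood of the current parameters.
staple_e_step <- function(D, p, q, f) {
  log_a <- log(f) + D %*% log(p) + (1 - D) %*% log(1 - p)
  log_b <- log(1 - f) + D %*% log(1 - q) + (1 - D) %*% log(q)
  mx <- pmax(log_a, log_b)
  denom <- mx + log(exp(log_a - mx) + exp(log_b - mx))
  list(W = as.vector(exp(log_a - denom)), loglik = sum(denom))
}

#' Binary STAPLE: simultaneous truth and performance level estimation
#'
#' Expectation-maximisation over a latent binary true segmentation and
#' per-rater sensitivity \eqn{p_r} / specificity \eqn{q_r}. The E-step
#' computes the per-pixel posterior probability of foreground from the
#' current parameters and prior; the M-step re-estimates \eqn{(p_r, q_r)}
#' from the posterior weights. The consensus is posterior >= 0.5.
#'
#' @param masks list of binary [label_mask()] objects (values 0/1).
#' @param prior \code{"consensus"} (default): a scalar global foreground
#'   prior set to the prevalence of the majority-vote consensus, which keeps
#'   the EM anchored when foreground is sparse; \code{"rater-mean"}: a
#'   per-pixel prior equal to the mean of the rater foreground indicators
#'   (clipped away from 0/1); or a numeric scalar in (0, 1). The per-pixel
#'   prior re-uses the votes that also enter the likelihood and can absorb
#'   coincident false positives on sparse images — see the methods vignette.
#' @param init_p,init_q initial sensitivity/specificity (default 0.99).
#' @param tol convergence tolerance on the maximum absolute parameter change
#'   (default 1e-7).
#' @param max_iter maximum EM iterations (default 200). \code{max_iter = 0}
#'   returns the posterior of a single E-step at the initial parameters.
#' @return object of class \code{staple_estimate}: list with \code{gt}
#'   (consensus mask), \code{posterior} (H x W x 2 probability array),
#'   \code{p}, \code{q} (per-rater), \code{iterations}, \code{converged},
#'   \code{loglik} (trajectory, non-decreasing), \code{undecided_pixels}.
#' @export
staple_binary <- function(masks, prior = "consensus",
                          init_p = 0.99, init_q = 0.99,
                          tol = 1e-7, max_iter = 200L) {
  masks <- check_annotations(masks)
  R <- length(masks)
  for (m in masks) if (max(m) > 1L) stop("staple_binary requires binary masks")
  d <- dim(masks[[1L]])
  D <- vapply(masks, function(m) as.numeric(as.vector(unclass(m))), numeric(prod(d)))
  D <- matrix(D, nrow = prod(d), ncol = R)

  f <- if (identical(prior, "consensus")) {
    rep(pmin(pmax(mean(majority_vote(masks) > 0L), 1e-6), 1 - 1e-6), prod(d))
  } else if (identical(prior, "rater-mean")) {
    pmin(pmax(rowMeans(D), 1e-6), 1 - 1e-6)
  } else {
    if (!is.numeric(prior) || prior <= 0 || prior >= 1)
      stop("`prior` must be \"consensus\", \"rater-mean\", or a scalar in (0, 1)")
    rep(prior, prod(d))
  }

  clip <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)
  p <- rep(clip(init_p), R); q <- rep(clip(init_q), R)
  loglik <- numeric(0)
  iter <- 0L; converged <- FALSE
  es <- staple_e_step(D, p, q, f)
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- es$W
    loglik <- c(loglik, es$loglik)
    sw <- sum(W); swc <- length(W) - sw
    p_new <- clip(as.vector(crossprod(D, W)) / sw)
    q_new <- clip(as.vector(crossprod(1 - D, 1 - W)) / swc)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    es <- staple_e_step(D, p, q, f)
    if (delta < tol) { converged <- TRUE; break }
  }
  W <- es$W
  loglik <- c(loglik, es$loglik)

  posterior <- array(c(1 - W, W), dim = c(d, 2L))
  gt <- label_mask(matrix(as.integer(W >= 0.5), d[1L], d[2L]), K = 2L)
  structure(list(gt = gt, posterior = posterior, p = p, q = q,
                 iterations = iter, converged = converged,
                 loglik = loglik, undecided_pixels = 0L),
            class = "staple_estimate")
}

#' Multiclass STAPLE via one-vs-rest binary estimation
#'
#' Runs a binary STAPLE per non-background class (class vs rest). Each pixel
#' is assigned the class with the highest posterior among classes whose
#' posterior reaches 0.5; when no class reaches 0.5 the pixel is background
#' (the "rest" side won every one-vs-rest round, so K = 2 reduces exactly to
#' [staple_binary()]). Pixels where the best posterior is exactly tied
#' between foreground classes are "undecided" and resolved by
#' `undecided_policy`.
#'
#' @param masks list of [label_mask()] objects with values in \code{0..K-1}.
#' @param K class count; defaults to the maximum over masks.
#' @param undecided_policy \code{"rater"} (default: copy the label of the
#'   rater with the highest `rater_scores`; falls back to background when no
#'   scores are given) or \code{"background"}.
#' @param rater_scores optional numeric vector, one score per rater, used by
#'   the \code{"rater"} policy. When omitted under the \code{"rater"} policy,
#'   each rater's mean Dice similarity to the pre-tie-break consensus is used.
#' @param ... passed to [staple_binary()] (prior, tolerances, ...).
#' @return \code{staple_estimate} with per-class \code{p}, \code{q} matrices
#'   (raters x non-background classes), posterior (H x W x K, renormalised
#'   one-vs-rest posteriors), and \code{undecided_pixels}.
#' @export
staple_multiclass <- function(masks, K = NULL,
                              undecided_policy = c("rater", "background"),
                              rater_scores = NULL, ...) {
  undecided_policy <- match.arg(undecided_policy)
  masks <- check_annotations(masks)
  R <- length(masks)
  if (!is.null(rater_scores) && length(rater_scores) != R)
    stop("`rater_scores` must have one entry per rater")
  if (is.null(K))
    K <- max(vapply(masks, function(m) max(n_classes(m), max(m) + 1L), integer(1)))
  d <- dim(masks[[1L]])

  fits <- vector("list", K - 1L)
  post <- array(0, dim = c(d, K))
  for (k in seq_len(K - 1L)) {
    bin <- lapply(masks, function(m) label_mask(matrix(as.integer(unclass(m) == k), d[1L], d[2L]), K = 2L))
    fits[[k]] <- staple_binary(bin, ...)
    post[, , k + 1L] <- fits[[k]]$posterior[, , 2L]
  }

  fg <- post[, , -1L, drop = FALSE]
  fg_flat <- matrix(fg, nrow = prod(d), ncol = K - 1L)
  best <- apply(fg_flat, 1L, max)
  ## ties: more than one class attains the best posterior
  n_best <- rowSums(abs(fg_flat - best) < .Machine$double.eps * 4)
  winner <- max.col(fg_flat, ties.method = "first")
  decided <- best >= 0.5 & n_best == 1L
  labels <- integer(prod(d))
  labels[decided] <- winner[decided]
  ## a pixel with no foreground posterior >= 0.5 is a background decision
  ## (the "rest" side won every one-vs-rest round); undecided pixels are
  ## exact posterior ties between foreground classes
  undecided <- which(!decided & best >= 0.5)

  if (length(undecided) > 0L) {
    if (undecided_policy == "rater") {
      if (is.null(rater_scores)) {
        consensus0 <- label_mask(matrix(labels, d[1L], d[2L]), K = K)
        rater_scores <- vapply(masks, function(m)
          dice_score(m, consensus0, K = K, average = "macro"), numeric(1))
      }
      ref <- masks[[which.max(rater_scores)]]
      labels[undecided] <- as.vector(unclass(ref))[undecided]
    } ## "background": leave at 0
  }

  post[, , 1L] <- 1 - apply(fg, c(1L, 2L), sum)
  ## one-vs-rest posteriors need not sum to one; renormalise for reporting
  post[, , 1L][post[, , 1L] < 0] <- 0
  s <- apply(post, c(1L, 2L), sum)
  s[s == 0] <- 1
  post <- sweep(post, c(1L, 2L), s, "/")

  structure(list(gt = label_mask(matrix(labels, d[1L], d[2L]), K = K),
                 posterior = post,
                 p = vapply(fits, function(f) f$p, numeric(R)),
                 q = vapply(fits, function(f) f$q, numeric(R)),
                 iterations = max(vapply(fits, function(f) f$iterations, integer(1))),
                 converged = all(vapply(fits, function(f) f$converged, logical(1))),
                 loglik = lapply(fits, function(f) f$loglik),
                 undecided_pixels = length(undecided)),
            class = "staple_estimate")
}

#' @export
print.staple_estimate <- function(x, ...) {
  cat("STAPLE estimate:", nrow(x$gt), "x", ncol(x$gt),
      "| iterations:", x$iterations,
      "| converged:", x$converged,
      "| undecided pixels:", x$undecided_pixels, "\n")
  cat("sensitivity p:", format(round(x$p, 4)), "\n")
  cat("specificity q:", format(round(x$q, 4)), "\n")
  invisible(x)
}

#' Per-rater similarity to an estimated ground truth
#'
#' Scores each expert against the consensus: Dice score for semantic tasks,
#' mean average precision for instance tasks. The (min, max) over raters is
#' the inter-expert range used as a data-ambiguity proxy.
#'
#' @param masks list of rater [label_mask()]s (semantic) or instance maps
#'   (instance task).
#' @param gt consensus [label_mask()] (semantic) or [instance_map] (instance).
#' @param task \code{"semantic"} (Dice) or \code{"instance"} (mAP).
#' @param rater_ids optional character vector of rater names.
#' @param image_id image identifier for the score table.
#' @return list with \code{scores} (a [score_table()]) and \code{range}
#'   (named vector \code{min}, \code{max}).
#' @export
inter_rater_scores <- function(masks, gt, task = c("semantic", "instance"),
                               rater_ids = NULL, image_id = "image") {
  task <- match.arg(task)
  if (is.null(rater_ids)) rater_ids <- sprintf("rater%02d", seq_along(masks))
  vals <- vapply(seq_along(masks), function(r) {
    if (task == "semantic") {
      dice_score(masks[[r]], gt)
    } else {
      if (!inherits(gt, "instance_map")) stop("instance task requires an instance_map gt")
      imap_r <- if (inherits(masks[[r]], "instance_map")) masks[[r]] else derive_instances(masks[[r]])
      mean_average_precision(gt, imap_r)$mAP
    }
  }, numeric(1))
  metric <- if (task == "semantic") "DS" else "mAP"
  list(scores = score_table(image_id, rater_ids, metric, vals),
       range = c(min = min(vals), max = max(vals)))
}
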