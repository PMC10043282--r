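## Evaluation metrics: Dice score (binary and macro multiclass), IoU,
## one-to-one instance matching at IoU thresholds, average precision and
## mAP over the COCO-style threshold grid, and classification of model
## scores relative to the inter-expert range.

#' Dice score between two segmentation masks
#'
#' Binary Dice \eqn{DS = 2TP / (2TP + FP + FN)} per class; multiclass scores
#' are the unweighted (macro) mean over the selected classes. A class empty
#' in both masks scores 1 (perfect agreement on absence).
#'
#' @param y_a,y_b [label_mask()] objects of identical shape.
#' @param K class count; defaults to the maximum over both masks.
#' @param classes classes to score; default all non-background classes
#'   (set `include_background = TRUE` for challenge-style reporting).
#' @param average \code{"macro"} (scalar) or \code{"per-class"} (named vector).
#' @param include_background include class 0 in the default selection.
#' @return scalar macro Dice, or a named per-class vector.
#' @export
dice_score <- function(y_a, y_b, K = NULL, classes = NULL,
                       average = c("macro", "per-class"),
                       include_background = FALSE) {
  average <- match.arg(average)
  if (!identical(dim(unclass(y_a)), dim(unclass(y_b)))) stop("mask shapes differ")
  if (is.null(K))
    K <- max(n_classes(y_a), n_classes(y_b), max(y_a) + 1L, max(y_b) + 1L)
  if (is.null(classes))
    classes <- if (include_background) 0:(K - 1L) else seq_len(K - 1L)
  if (length(classes) == 0L) stop("empty class selection")
  a <- unclass(y_a); b <- unclass(y_b)
  ds <- vapply(classes, function(k) {
    in_a <- a == k; in_b <- b == k
    tp <- sum(in_a & in_b)
    fp <- sum(in_a & !in_b)
    fn <- sum(!in_a & in_b)
    if (2L * tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  names(ds) <- paste0("class", classes)
  if (average == "macro") mean(ds) else ds
}

#' Intersection over union of two pixel sets
#'
#' @param set_a,set_b integer vectors of pixel indices.
#' @return \eqn{|A \cap B| / |A \cup B|}; both sets empty is an error
#'   (the ratio is undefined).
#' @export
iou <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0L) stop("IoU undefined for two empty sets")
  length(intersect(set_a, set_b)) / u
}

## Pairwise IoU table between instances of two maps, from the joint label
## histogram. Returns a data frame (a, b, iou) for overlapping pairs only.
pairwise_iou <- function(gt, pred) {
  ga <- gt$instances; pb <- pred$instances
  na <- max(ga, 0L); nb <- max(pb, 0L)
  size_a <- if (na > 0L) tabulate(ga[ga > 0L], nbins = na) else integer(0)
  size_b <- if (nb > 0L) tabulate(pb[pb > 0L], nbins = nb) else integer(0)
  both <- ga > 0L & pb > 0L
  if (!any(both))
    return(data.frame(a = integer(0), b = integer(0), iou = numeric(0)))
  key <- (as.integer(ga[both]) - 1L) * nb + as.integer(pb[both])
  tab <- table(key)
  k <- as.integer(names(tab))
  a <- ((k - 1L) %/% nb) + 1L
  b <- ((k - 1L) %% nb) + 1L
  inter <- as.integer(tab)
  data.frame(a = a, b = b, iou = inter / (size_a[a] + size_b[b] - inter))
}

#' Match instances of two maps at an IoU threshold
#'
#' Candidate pairs with IoU >= `eta` are matched one-to-one greedily in
#' descending IoU (ties broken by lower reference id, then lower prediction
#' id). Unmatched prediction instances are false positives, unmatched
#' reference instances false negatives.
#'
#' @param gt reference [instance_map()].
#' @param pred predicted [instance_map()].
#' @param eta IoU threshold in \code{(0, 1]}.
#' @return list with \code{tp}, \code{fp}, \code{fn} and \code{matches}
#'   (data frame \code{a, b, iou} of matched pairs).
#' @export
match_instances <- function(gt, pred, eta) {
  if (eta <= 0 || eta > 1) stop("`eta` must be in (0, 1]")
  na <- max(gt$instances, 0L); nb <- max(pred$instances, 0L)
  cand <- pairwise_iou(gt, pred)
  cand <- cand[cand$iou >= eta, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$a, cand$b), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_a[cand$a[i]] && !used_b[cand$b[i]]) {
      keep[i] <- TRUE
      used_a[cand$a[i]] <- TRUE
      used_b[cand$b[i]] <- TRUE
    }
  }
  matches <- cand[keep, , drop = FALSE]
  rownames(matches) <- NULL
  list(tp = nrow(matches), fp = nb - nrow(matches), fn = na - nrow(matches),
       matches = matches)
}

#' Default IoU threshold grid
#'
#' Ten thresholds from 0.50 to 0.95 in steps of 0.05, as used by the COCO
#' object-detection benchmark.
#'
#' @return numeric vector of length 10.
#' @export
default_iou_thresholds <- function() (50 + 5 * (0:9)) / 100

#' Mean average precision over IoU thresholds
#'
#' At each threshold, \eqn{AP_\eta = TP / (TP + FN + FP)}; mAP is the
#' unweighted mean over the grid. In multiclass maps, matching is performed
#' per class and AP is macro-averaged before the threshold mean. When both
#' maps contain no instances of a class, that class scores AP = 1.
#'
#' @param gt reference [instance_map()].
#' @param pred predicted [instance_map()].
#' @param thresholds IoU grid, default [default_iou_thresholds()].
#' @return object of class \code{match_table}: list with \code{per_threshold}
#'   (data frame \code{eta, tp, fp, fn, ap}; summed over classes) and
#'   \code{mAP}.
#' @export
mean_average_precision <- function(gt, pred, thresholds = default_iou_thresholds()) {
  if (length(thresholds) == 0L) stop("`thresholds` must be non-empty")
  classes <- sort(union(unique(gt$class_of), unique(pred$class_of)))
  split_class <- function(imap, k) {
    ids <- which(imap$class_of == k)
    inst <- imap$instances
    inst[!(inst %in% ids)] <- 0L
    instance_map(relabel_raster_order(inst), rep(k, length(ids)))
  }
  rows <- lapply(thresholds, function(eta) {
    if (length(classes) == 0L)
      return(data.frame(eta = eta, tp = 0L, fp = 0L, fn = 0L, ap = 1))
    per_class <- lapply(classes, function(k) {
      mm <- match_instances(split_class(gt, k), split_class(pred, k), eta)
      ap <- if (mm$tp + mm$fp + mm$fn == 0L) 1 else mm$tp / (mm$tp + mm$fp + mm$fn)
      c(tp = mm$tp, fp = mm$fp, fn = mm$fn, ap = ap)
    })
    agg <- Reduce(`+`, per_class)
    data.frame(eta = eta, tp = agg[["tp"]], fp = agg[["fp"]], fn = agg[["fn"]],
               ap = mean(vapply(per_class, `[[`, numeric(1), "ap")))
  })
  per_threshold <- do.call(rbind, rows)
  structure(list(per_threshold = per_threshold, mAP = mean(per_threshold$ap)),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("match_table over", nrow(x$per_threshold), "IoU thresholds; mAP =",
      format(round(x$mAP, 4)), "\n")
  invisible(x)
}

#' Classify model scores relative to the inter-expert range
#'
#' Compares each image's model score to the [min, max] of that image's
#' expert scores: below the worst expert, within the expert range (boundary
#' equality counts as in range), or above the best expert.
#'
#' @param model_scores named numeric vector (names = image ids) or data
#'   frame with columns \code{image_id}, \code{score}.
#' @param expert_scores data frame with columns \code{image_id},
#'   \code{score} (one row per expert per image).
#' @return list with \code{labels} (data frame \code{image_id, label}) and
#'   \code{shares} (named vector over the three categories).
#' @export
expert_range_classification <- function(model_scores, expert_scores) {
  if (is.data.frame(model_scores))
    model_scores <- setNames(model_scores$score, model_scores$image_id)
  ids <- names(model_scores)
  if (is.null(ids)) stop("`model_scores` must be named by image id")
  labels <- vapply(ids, function(id) {
    es <- expert_scores$score[expert_scores$image_id == id]
    if (length(es) == 0L) stop("no expert scores for image ", id)
    s <- model_scores[[id]]
    if (s < min(es)) "below_worst"
    else if (s > max(es)) "above_best"
    else "in_range"
  }, character(1))
  lv <- c("below_worst", "in_range", "above_best")
  shares <- table(factor(labels, levels = lv)) / length(labels)
  list(labels = data.frame(image_id = ids, label = unname(labels),
                           stringsAsFactors = FALSE),
       shares = setNames(as.numeric(shares), lv))
}
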