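## End-to-end orchestration of the two workflows: training-side evaluation
## (ground-truth estimation -> fusion -> two-step evaluation) and
## application-side quality assurance (uncertainty -> ranking -> review
## list), plus JSON run configuration and a synthetic workspace writer.

run_config_fields <- function() {
  c("images", "masks", "probs", "out", "gt_method", "task", "zeta",
    "min_size", "tau", "seed", "test_scores", "apply_to")
}

#' Create a run configuration
#'
#' @param images,masks,probs,out directory paths (see Details for layout).
#' @param gt_method \code{"staple"} (default) or \code{"majority"}.
#' @param task \code{"semantic"} (default) or \code{"instance"}.
#' @param zeta uncertainty aggregation scale (default 4).
#' @param min_size minimum instance size in pixels (default 0).
#' @param tau quality-assurance score threshold (default 0.8).
#' @param seed integer seed (default 1).
#' @param test_scores,apply_to CSV paths for [run_qa()].
#'
#' @details Directory layout: \code{images/<image_id>.tif},
#' \code{masks/<rater_id>/<image_id>.(tif|png)},
#' \code{probs/<model_id>/<view_id>/<image_id>.tif} with probability stacks
#' stored in the original (inverted) pixel frame.
#'
#' @return list of class \code{run_config}.
#' @export
run_config <- function(images = NULL, masks = NULL, probs = NULL, out = NULL,
                       gt_method = "staple", task = "semantic", zeta = 4,
                       min_size = 0L, tau = 0.8, seed = 1L,
                       test_scores = NULL, apply_to = NULL) {
  cfg <- list(images = images, masks = masks, probs = probs, out = out,
              gt_method = match.arg(gt_method, c("staple", "majority")),
              task = match.arg(task, c("semantic", "instance")),
              zeta = zeta, min_size = as.integer(min_size), tau = tau,
              seed = as.integer(seed),
              test_scores = test_scores, apply_to = apply_to)
  structure(cfg[!vapply(cfg, is.null, logical(1))], class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected so typos never silently change a run.
#'
#' @param path JSON file written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), run_config_fields())
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#' @param config a [run_config()].
#' @param path output .json path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

list_image_ids <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE))
  if (length(files) == 0L) stop("no images found in ", dir)
  unique(tools::file_path_sans_ext(files))
}

find_raster <- function(dir, id) {
  for (ext in c("tif", "tiff", "png")) {
    p <- file.path(dir, paste0(id, ".", ext))
    if (file.exists(p)) return(p)
  }
  stop("no raster for image '", id, "' in ", dir)
}

## Load the per-(model, view) probability stacks of one image into an
## ensemble_output. Stacks are stored in the original pixel frame.
read_ensemble <- function(probs_dir, id) {
  models <- sort(list.dirs(probs_dir, recursive = FALSE, full.names = FALSE))
  if (length(models) == 0L) stop("no model directories under ", probs_dir)
  maps <- lapply(models, function(mdl) {
    views <- sort(list.dirs(file.path(probs_dir, mdl), recursive = FALSE,
                            full.names = FALSE))
    if (length(views) == 0L) stop("no view directories under ", file.path(probs_dir, mdl))
    lapply(views, function(v)
      read_probability_stack(find_raster(file.path(probs_dir, mdl, v), id)))
  })
  ensemble_output(maps)
}

#' Training-side evaluation: ground truth, fusion, two-step scores
#'
#' For every image: estimates the consensus ground truth from the expert
#' masks, fuses the stored per-(model, view) probability stacks, scores the
#' prediction and each expert against the consensus (absolute performance),
#' classifies the model against the inter-expert range (relative
#' performance), and computes the foreground uncertainty score U. Missing
#' inputs are enumerated before any computation. All outputs go to
#' \code{config$out}: \code{scores.csv}, \code{summary.json}, and estimated
#' ground-truth masks under \code{gt/}.
#'
#' @param config a [run_config()] with `images`, `masks`, `probs`, `out` set.
#' @return invisibly, a list with \code{scores} (data frame),
#'   \code{expert_range} (classification result), \code{summary} (list).
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (fld in c("images", "masks", "probs", "out"))
    if (is.null(config[[fld]])) stop("config field '", fld, "' is required")
  ids <- list_image_ids(config$images)
  raters <- sort(list.dirs(config$masks, recursive = FALSE, full.names = FALSE))
  if (length(raters) == 0L) stop("no rater directories under ", config$masks)
  missing <- character(0)
  for (id in ids) {
    for (r in raters) {
      ok <- tryCatch({ find_raster(file.path(config$masks, r), id); TRUE },
                     error = function(e) FALSE)
      if (!ok) missing <- c(missing, file.path(config$masks, r, id))
    }
  }
  if (length(missing) > 0L)
    stop("missing expert masks:\n  ", paste(missing, collapse = "\n  "))

  dir.create(file.path(config$out, "gt"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  model_scores <- numeric(0)
  expert_scores <- data.frame(image_id = character(0), score = numeric(0))
  u_records <- data.frame(image_id = character(0), U = numeric(0),
                          S = numeric(0), flags = character(0))
  metric_name <- if (config$task == "semantic") "DS" else "mAP"

  for (id in ids) {
    masks <- lapply(raters, function(r)
      read_mask(find_raster(file.path(config$masks, r), id)))
    est <- if (config$gt_method == "staple") {
      K <- max(vapply(masks, max, integer(1))) + 1L
      if (K <= 2L) staple_binary(masks) else staple_multiclass(masks, K = K)
    } else {
      list(gt = majority_vote(masks), undecided_pixels = 0L)
    }
    gt <- est$gt
    write_mask(gt, file.path(config$out, "gt", paste0(id, ".tif")))

    ens <- read_ensemble(config$probs, id)
    unc <- uncertainty_maps(ens, zeta = config$zeta)
    yhat <- unc$fused$yhat

    if (config$task == "semantic") {
      model_s <- dice_score(yhat, gt)
      rater_s <- vapply(masks, function(m) dice_score(m, gt), numeric(1))
    } else {
      gt_inst <- size_filter(derive_instances(gt), config$min_size)
      pred_inst <- size_filter(derive_instances(yhat), config$min_size)
      cons <- instance_consistency_report(yhat, pred_inst)
      rows[[length(rows) + 1L]] <-
        score_table(id, "model", "removed_pixels", cons$removed_pixels)
      model_s <- mean_average_precision(gt_inst, pred_inst)$mAP
      rater_s <- vapply(masks, function(m)
        mean_average_precision(gt_inst, size_filter(derive_instances(m),
                                                    config$min_size))$mAP,
        numeric(1))
    }
    model_scores[id] <- model_s
    expert_scores <- rbind(expert_scores,
                           data.frame(image_id = id, score = rater_s))
    rows[[length(rows) + 1L]] <- score_table(id, "model", metric_name, model_s)
    rows[[length(rows) + 1L]] <- score_table(id, raters, metric_name, rater_s)
    rows[[length(rows) + 1L]] <- score_table(id, "model", "U", unc$U)
    if (!is.null(est$undecided_pixels))
      rows[[length(rows) + 1L]] <-
        score_table(id, "consensus", "undecided_pixels", est$undecided_pixels)
    u_records <- rbind(u_records,
                       data.frame(image_id = id, U = unc$U, S = model_s,
                                  flags = paste(unc$flags, collapse = ";")))
  }

  scores <- do.call(rbind, rows)
  erc <- expert_range_classification(model_scores, expert_scores)
  write_scores(scores, file.path(config$out, "scores.csv"))
  utils::write.csv(u_records, file.path(config$out, "test_records.csv"),
                   row.names = FALSE)
  summary <- list(n_images = length(ids), n_raters = length(raters),
                  task = config$task, gt_method = config$gt_method,
                  metric = metric_name,
                  mean_model_score = mean(model_scores),
                  expert_range_shares = as.list(erc$shares))
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, expert_range = erc, summary = summary,
                 records = u_records))
}

#' Application-side quality assurance
#'
#' Derives U_min from the labelled hold-out records, ranks the new
#' predictions by decreasing uncertainty, and writes the review list.
#'
#' @param config a [run_config()] with `test_scores` (CSV with columns
#'   \code{image_id, U, S}), `apply_to` (CSV with \code{image_id, U}),
#'   `tau`, and `out` set.
#' @return invisibly, a list with \code{threshold} ([compute_u_min()]
#'   result), \code{ranked} (all new records, ranked), \code{review}
#'   (flagged subset).
#' @export
run_qa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$tau)) stop("config field 'tau' is required")
  for (fld in c("test_scores", "apply_to", "out"))
    if (is.null(config[[fld]])) stop("config field '", fld, "' is required")
  test_records <- utils::read.csv(config$test_scores, stringsAsFactors = FALSE)
  new_records <- utils::read.csv(config$apply_to, stringsAsFactors = FALSE)
  thr <- compute_u_min(test_records, tau = config$tau)
  ranked <- rank_by_uncertainty(new_records)
  review <- flag_for_review(new_records, thr)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(review, file.path(config$out, "review_list.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(U_min = thr$U_min, tau = thr$tau,
                            n_failures = thr$n_failures,
                            fallback_used = thr$fallback_used,
                            n_flagged = nrow(review)),
                       file.path(config$out, "qa_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(threshold = thr, ranked = ranked, review = review))
}

#' Write a synthetic workspace to disk
#'
#' Generates scenes, simulated expert masks, and mock-ensemble probability
#' stacks in the directory layout consumed by [run_evaluation()]. Useful for
#' demonstrations and end-to-end tests.
#'
#' @param dir target directory (created if needed).
#' @param n_images number of scenes (default 3).
#' @param config a [synthetic_config()].
#' @param raters rater parameter data frame (see [simulate_raters()]).
#' @param M,T ensemble model/view counts for the mock predictor.
#' @param seed integer seed.
#' @return invisibly, the vector of image ids written.
#' @export
simulate_workspace <- function(dir, n_images = 3L,
                               config = synthetic_config(),
                               raters = data.frame(sensitivity = rep(0.9, 3),
                                                   specificity = rep(0.97, 3),
                                                   jitter = rep(0L, 3)),
                               M = 3L, T = 4L, seed = 1L) {
  ids <- sprintf("img%02d", seq_len(n_images))
  rater_ids <- sprintf("rater%02d", seq_len(nrow(raters)))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (r in rater_ids)
    dir.create(file.path(dir, "masks", r), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(config, seed = seed * 100L + i)
    write_image(sc$image, file.path(dir, "images", paste0(ids[i], ".tif")))
    rmasks <- simulate_raters(sc$mask, raters, seed = seed * 100L + i)
    for (r in seq_along(rmasks))
      write_mask(rmasks[[r]], file.path(dir, "masks", rater_ids[r],
                                        paste0(ids[i], ".tif")))
    ens <- mock_ensemble_from_image(sc$image, M = M, T = T,
                                    seed = seed * 100L + i)
    for (m in seq_len(M)) {
      for (t in seq_len(T)) {
        vdir <- file.path(dir, "probs", sprintf("model%02d", m),
                          ens$view_ids[t])
        dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
        write_probability_stack(ens$maps[[m]][[t]],
                                file.path(vdir, paste0(ids[i], ".tif")))
      }
    }
  }
  invisible(ids)
}
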