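## Synthetic blob-world generator: fluorescence-like scenes with known
## semantic/instance ground truth, simulated expert raters with known
## sensitivity/specificity and boundary jitter, simulated ensembles with
## controlled epistemic/aleatoric structure, an intensity-based mock
## predictor, and a tiered out-of-distribution benchmark. Every output is a
## pure function of (config, seed).

#' Synthetic scene configuration
#'
#' Defaults emulate sparse bright elliptical objects (somata/nuclei-like) on
#' a dim noisy background: background intensity 0.1, foreground class
#' intensities from 0.6 upwards, additive Gaussian pixel noise.
#'
#' @param image_shape \code{c(H, W)} (default 128 x 128).
#' @param K class count incl. background (default 2).
#' @param objects_per_class inclusive range of object counts per class.
#' @param radius inclusive range of ellipse semi-axes in pixels.
#' @param background intensity of the background (default 0.1).
#' @param intensities per-foreground-class intensities; default spaced from
#'   0.6 to 0.9.
#' @param noise_sd additive Gaussian noise sd (default 0.05).
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(image_shape = c(128L, 128L), K = 2L,
                             objects_per_class = c(5L, 10L),
                             radius = c(4L, 9L),
                             background = 0.1,
                             intensities = NULL,
                             noise_sd = 0.05) {
  if (is.null(intensities))
    intensities <- if (K == 2L) 0.6 else seq(0.6, 0.9, length.out = K - 1L)
  if (length(intensities) != K - 1L)
    stop("`intensities` must have one entry per foreground class")
  structure(list(image_shape = as.integer(image_shape), K = as.integer(K),
                 objects_per_class = as.integer(objects_per_class),
                 radius = radius, background = background,
                 intensities = intensities, noise_sd = noise_sd),
            class = "synthetic_config")
}

## Smooth random field: coarse white noise bilinearly upsampled to H x W.
smooth_field <- function(shape, coarse = 8L) {
  ch <- max(2L, ceiling(shape[1L] / coarse))
  cw <- max(2L, ceiling(shape[2L] / coarse))
  m <- matrix(rnorm(ch * cw), ch, cw)
  out <- EBImage::resize(m, w = shape[1L], h = shape[2L])
  matrix(as.numeric(out), shape[1L], shape[2L])
}

#' Generate a synthetic scene with known ground truth
#'
#' Places non-overlapping random ellipses per foreground class on a noisy
#' background; the image is the per-class intensity plus Gaussian noise.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return list with \code{image} (\code{H x W x 1} array), \code{mask}
#'   ([label_mask()]), and \code{instances} ([instance_map()]).
#' @export
generate_scene <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  d <- config$image_shape
  H <- d[1L]; W <- d[2L]
  mask <- matrix(0L, H, W)
  inst <- matrix(0L, H, W)
  class_of <- integer(0)
  placed <- data.frame(r = numeric(0), c = numeric(0), rad = numeric(0))
  next_id <- 0L
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  for (k in seq_len(config$K - 1L)) {
    lo <- config$objects_per_class[1L]; hi <- config$objects_per_class[2L]
    n_obj <- if (lo == hi) lo else sample(lo:hi, 1L)
    for (j in seq_len(n_obj)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, config$radius[1L], config$radius[2L])
        b <- runif(1, config$radius[1L], config$radius[2L])
        th <- runif(1, 0, pi)
        r0 <- runif(1, max(a, b) + 1, H - max(a, b) - 1)
        c0 <- runif(1, max(a, b) + 1, W - max(a, b) - 1)
        if (nrow(placed) > 0L) {
          dist <- sqrt((placed$r - r0)^2 + (placed$c - c0)^2)
          if (any(dist < placed$rad + max(a, b) + 2)) next
        }
        dx <- rr - r0; dy <- cc - c0
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        sel <- u^2 + v^2 <= 1
        next_id <- next_id + 1L
        mask[sel] <- k
        inst[sel] <- next_id
        class_of <- c(class_of, k)
        placed <- rbind(placed, data.frame(r = r0, c = c0, rad = max(a, b)))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible object packing: could not place object ", j,
                    " of class ", k)
    }
  }
  img <- matrix(config$background, H, W)
  for (k in seq_len(config$K - 1L)) img[mask == k] <- config$intensities[k]
  img <- img + matrix(rnorm(H * W, sd = config$noise_sd), H, W)
  inst <- relabel_raster_order(inst)
  ## class_of follows the raster relabelling
  ord_class <- integer(max(inst, 0L))
  if (max(inst) > 0L) {
    pos <- inst > 0L
    for (id in seq_len(max(inst))) {
      k_here <- mask[pos & inst == id][1L]
      ord_class[id] <- k_here
    }
  }
  list(image = array(img, dim = c(H, W, 1L)),
       mask = label_mask(mask, K = config$K),
       instances = instance_map(inst, ord_class))
}

#' Simulate expert raters with known error parameters
#'
#' Each rater's mask is the true mask with independent per-pixel flips —
#' foreground pixels are kept with probability `sensitivity` (else set to
#' background), background pixels are kept with probability `specificity`
#' (else set to a foreground class) — optionally followed by morphological
#' boundary jitter (random dilation or erosion by up to `jitter` pixels).
#'
#' @param true_mask [label_mask()].
#' @param raters data frame with one row per rater and columns
#'   \code{sensitivity}, \code{specificity} in (0.5, 1], and \code{jitter}
#'   (pixels, >= 0).
#' @param seed integer seed.
#' @return list of rater [label_mask()]s.
#' @export
simulate_raters <- function(true_mask,
                            raters = data.frame(sensitivity = rep(0.9, 5),
                                                specificity = rep(0.95, 5),
                                                jitter = rep(0L, 5)),
                            seed = 1L) {
  stopifnot(all(raters$sensitivity > 0.5), all(raters$sensitivity <= 1),
            all(raters$specificity > 0.5), all(raters$specificity <= 1))
  set.seed(seed)
  K <- n_classes(true_mask)
  m <- unclass(true_mask)
  lapply(seq_len(nrow(raters)), function(r) {
    sens <- raters$sensitivity[r]; spec <- raters$specificity[r]
    jit <- raters$jitter[r]
    out <- m
    fg <- which(m > 0L)
    drop <- fg[runif(length(fg)) > sens]
    out[drop] <- 0L
    bg <- which(m == 0L)
    add <- bg[runif(length(bg)) > spec]
    out[add] <- if (K == 2L) 1L else sample(seq_len(K - 1L), length(add), replace = TRUE)
    if (jit > 0L) {
      rad <- sample(seq_len(jit), 1L)
      brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
      for (k in seq_len(K - 1L)) {
        ck <- (out == k) * 1
        ck <- if (runif(1) < 0.5) EBImage::dilate(ck, brush) else EBImage::erode(ck, brush)
        out[out == k] <- 0L
        out[ck > 0] <- k
      }
    }
    label_mask(out, K = K)
  })
}

#' Simulate an ensemble with controlled uncertainty structure
#'
#' Member probability maps are softmaxed logits
#' \code{alpha * onehot(truth) + shared view field * aleatoric_scale +
#' member field * epistemic_scale}. The shared smooth field varies across
#' views but not across models (view-to-view variation), the member field is
#' independent per (model, view) (model disagreement). Both scales at 0
#' give an ensemble of identical, saturated members with zero uncertainty.
#'
#' @param true_mask [label_mask()].
#' @param M,T model and view counts (defaults 5 and 4).
#' @param epistemic_scale,aleatoric_scale noise scales (>= 0).
#' @param alpha logit sharpness of the truth signal (default 6).
#' @param seed integer seed.
#' @return an [ensemble_output()] of \code{M x T} probability maps.
#' @export
simulate_ensemble <- function(true_mask, M = 5L, T = 4L,
                              epistemic_scale = 0.5, aleatoric_scale = 0.5,
                              alpha = 6, seed = 1L) {
  stopifnot(M >= 1L, T >= 1L, epistemic_scale >= 0, aleatoric_scale >= 0)
  set.seed(seed)
  K <- n_classes(true_mask)
  d <- dim(unclass(true_mask))
  onehot <- array(0, dim = c(d, K))
  for (k in 0:(K - 1L)) onehot[, , k + 1L][unclass(true_mask) == k] <- 1
  shared <- lapply(seq_len(T), function(t)
    lapply(seq_len(K), function(k) smooth_field(d)))
  maps <- lapply(seq_len(M), function(m) {
    lapply(seq_len(T), function(t) {
      if (epistemic_scale == 0 && aleatoric_scale == 0) return(onehot)
      logits <- alpha * onehot
      for (k in seq_len(K)) {
        logits[, , k] <- logits[, , k] +
          aleatoric_scale * shared[[t]][[k]] +
          epistemic_scale * smooth_field(d)
      }
      e <- exp(sweep(logits, c(1L, 2L), apply(logits, c(1L, 2L), max)))
      sweep(e, c(1L, 2L), apply(e, c(1L, 2L), sum), "/")
    })
  })
  ## member noise above was drawn inside lapply in (m, t) order; output is a
  ## pure function of (arguments, seed)
  ensemble_output(maps, view_ids = tta_views()[seq_len(min(T, 4L))])
}

#' Intensity-based mock ensemble predictor
#'
#' A binary logistic "predictor" over blurred pixel intensity, calibrated to
#' the nominal scene statistics: logits are
#' \code{gain * (blur(image) - threshold)} plus small member-, view-, and
#' pixel-level perturbations. On nominal scenes (background 0.1, foreground
#' 0.6) it is confident; on content whose intensity sits near `threshold`
#' its probabilities approach 0.5, so uncertainty rises — emulating how a
#' trained ensemble reacts to out-of-distribution inputs.
#'
#' @param image \code{H x W (x 1)} array.
#' @param M,T model and view counts.
#' @param threshold decision intensity (default 0.35, the nominal midpoint).
#' @param gain logit gain (default 25).
#' @param member_sd,view_sd,pixel_sd perturbation scales.
#' @param seed integer seed.
#' @return an [ensemble_output()] with K = 2.
#' @export
mock_ensemble_from_image <- function(image, M = 5L, T = 4L,
                                     threshold = 0.35, gain = 25,
                                     member_sd = 1, view_sd = 0.5,
                                     pixel_sd = 0.5, seed = 1L) {
  set.seed(seed)
  if (length(dim(image)) == 3L) image <- image[, , 1L]
  d <- dim(image)
  base <- gain * (EBImage::gblur(image, sigma = 1) - threshold)
  m_off <- rnorm(M, sd = member_sd)
  t_off <- rnorm(T, sd = view_sd)
  maps <- lapply(seq_len(M), function(m) {
    lapply(seq_len(T), function(t) {
      L <- base + m_off[m] + t_off[t] + pixel_sd * smooth_field(d)
      p1 <- stats::plogis(L)
      array(c(1 - p1, p1), dim = c(d, 2L))
    })
  })
  ensemble_output(maps, view_ids = tta_views()[seq_len(min(T, 4L))])
}

#' Degrade a nominal scene image
#'
#' Blends the image towards the mock predictor's decision intensity and adds
#' noise; `level` = 0 leaves the image untouched, `level` = 1 destroys the
#' object/background contrast entirely. Used for the uncertainty-vs-quality
#' sweeps.
#'
#' @param image \code{H x W (x 1)} array.
#' @param level degradation level in \code{[0, 1]}.
#' @param midpoint intensity towards which the image is blended.
#' @param noise_sd noise amplitude at full degradation.
#' @param seed integer seed.
#' @return degraded image of the same shape.
#' @export
degrade_image <- function(image, level, midpoint = 0.35, noise_sd = 0.2,
                          seed = 1L) {
  stopifnot(level >= 0, level <= 1)
  set.seed(seed)
  d <- dim(image)
  noise <- array(rnorm(prod(d), sd = noise_sd * level), dim = d)
  (1 - level) * image + level * midpoint + noise
}

#' Tiered out-of-distribution benchmark
#'
#' Builds labelled scenes in three tiers: \code{"in"} (nominal scenes),
#' \code{"partial"} (nominal scenes plus foreign structures — an elongated
#' tube and bright speckles at ambiguous intensities, analogues of blood
#' vessels and fluorescent particles), and \code{"full"} (structure-free
#' textured images with entirely different statistics, centred on the mock
#' predictor's decision intensity).
#'
#' @param n_in,n_partial,n_full scene counts per tier (defaults 8, 4, 4).
#' @param config nominal [synthetic_config()]; defaults to a 64 x 64 scaled
#'   scene (3–6 objects of radius 3–6).
#' @param seed integer seed.
#' @return list of records: each has \code{id}, \code{tier}, \code{image},
#'   \code{mask} (all-background for the full tier).
#' @export
make_ood_benchmark <- function(n_in = 8L, n_partial = 4L, n_full = 4L,
                               config = NULL, seed = 1L) {
  stopifnot(n_in >= 1L, n_partial >= 1L, n_full >= 1L)
  if (is.null(config))
    config <- synthetic_config(image_shape = c(64L, 64L),
                               objects_per_class = c(3L, 6L),
                               radius = c(3L, 6L))
  d <- config$image_shape
  records <- list()
  idx <- 0L
  add <- function(records, tier, image, mask) {
    idx <<- idx + 1L
    records[[idx]] <- list(id = sprintf("%s_%02d", tier, idx), tier = tier,
                           image = image, mask = mask)
    records
  }
  for (i in seq_len(n_in)) {
    sc <- generate_scene(config, seed = seed * 1000L + i)
    records <- add(records, "in", sc$image, sc$mask)
  }
  for (i in seq_len(n_partial)) {
    sc <- generate_scene(config, seed = seed * 1000L + 100L + i)
    set.seed(seed * 1000L + 200L + i)
    img <- sc$image[, , 1L]
    ## elongated tube at ambiguous intensity (blood-vessel analogue)
    r0 <- runif(1, 10, d[1L] - 10); slope <- runif(1, -0.5, 0.5)
    for (cc in seq_len(d[2L])) {
      rline <- round(r0 + slope * cc)
      rows <- intersect(seq(rline - 1L, rline + 1L), seq_len(d[1L]))
      img[rows, cc] <- 0.4
    }
    ## bright speckles at mid intensity (fluorescent-particle analogue)
    ns <- sample(4:8, 1L)
    pr <- sample(seq_len(d[1L]), ns); pc <- sample(seq_len(d[2L]), ns)
    for (j in seq_len(ns)) {
      rows <- intersect(seq(pr[j] - 1L, pr[j] + 1L), seq_len(d[1L]))
      cols <- intersect(seq(pc[j] - 1L, pc[j] + 1L), seq_len(d[2L]))
      img[rows, cols] <- 0.45
    }
    records <- add(records, "partial", array(img, dim = c(d, 1L)), sc$mask)
  }
  for (i in seq_len(n_full)) {
    set.seed(seed * 1000L + 300L + i)
    img <- 0.35 + 0.12 * smooth_field(d) +
      matrix(rnorm(prod(d), sd = 0.05), d[1L], d[2L])
    records <- add(records, "full", array(img, dim = c(d, 1L)),
                   label_mask(matrix(0L, d[1L], d[2L]), K = 2L))
  }
  records
}
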