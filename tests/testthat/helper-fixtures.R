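## Shared fixture builders and independent oracles for the test suite.
## Everything is generated in code; no binary fixtures.

## Binary mask from a 0/1 matrix.
mk_mask <- function(m, K = NULL) label_mask(matrix(as.integer(m), nrow(m), ncol(m)), K = K)

## Ensemble of K = 2 maps from a list of foreground-probability matrices,
## arranged as M x T (filled model-major).
mk_ensemble <- function(fg_probs, M = length(fg_probs), T = 1L) {
  stopifnot(length(fg_probs) == M * T)
  i <- 0L
  maps <- lapply(seq_len(M), function(m) {
    lapply(seq_len(T), function(t) {
      i <<- i + 1L
      p <- fg_probs[[i]]
      array(c(1 - p, p), dim = c(dim(p), 2L))
    })
  })
  ensemble_output(maps, view_ids = tta_views()[seq_len(min(T, 4L))])
}

## Constant-probability ensemble: every member emits foreground prob `p`
## everywhere on an h x w image.
mk_const_ensemble <- function(p_values, h = 2L, w = 2L, M = length(p_values), T = 1L) {
  mk_ensemble(lapply(p_values, function(p) matrix(p, h, w)), M = M, T = T)
}

## Exhaustive optimal one-to-one instance matching (oracle for the greedy
## matcher): maximises the number of matched pairs with IoU >= eta.
brute_force_match <- function(gt, pred, eta) {
  cand <- ambiseg:::pairwise_iou(gt, pred)
  cand <- cand[cand$iou >= eta, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (count + (nrow(cand) - i + 1L) <= best) return()
    if (i > nrow(cand)) { best <<- max(best, count); return() }
    ## skip candidate i
    recurse(i + 1L, used_b, count)
    ## take candidate i if free
    a <- cand$a[i]; b <- cand$b[i]
    taken_a <- attr(used_b, "a")
    if (!(a %in% taken_a) && !(b %in% used_b)) {
      ub <- c(used_b, b); attr(ub, "a") <- c(taken_a, a)
      recurse(i + 1L, ub, count + 1L)
    }
  }
  u0 <- integer(0); attr(u0, "a") <- integer(0)
  recurse(1L, u0, 0L)
  best
}

## Random instance map with at most `max_n` blocky instances on a small grid.
random_instance_map <- function(h = 16L, w = 16L, max_n = 6L) {
  inst <- matrix(0L, h, w)
  n <- sample.int(max_n, 1L)
  for (id in seq_len(n)) {
    r0 <- sample.int(h - 3L, 1L); c0 <- sample.int(w - 3L, 1L)
    dr <- sample(2:4, 1L); dc <- sample(2:4, 1L)
    inst[r0:min(h, r0 + dr), c0:min(w, c0 + dc)] <- id
  }
  ## relabel to contiguous ids (instances may be fully overwritten)
  ids <- setdiff(sort(unique(as.vector(inst))), 0L)
  inst <- matrix(match(inst, c(0L, ids), nomatch = 1L) - 1L, h, w)
  instance_map(inst)
}

## Small nominal scene configuration used across tests; object size scales
## down with the canvas so packing stays feasible.
test_scene_config <- function(shape = c(64L, 64L)) {
  if (min(shape) < 48L) {
    synthetic_config(image_shape = shape, objects_per_class = c(2L, 4L),
                     radius = c(2L, 4L))
  } else {
    synthetic_config(image_shape = shape, objects_per_class = c(3L, 6L),
                     radius = c(3L, 6L))
  }
}
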