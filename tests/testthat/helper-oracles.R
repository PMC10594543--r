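# Independent brute-force oracles and fixture builders. The oracles are
# deliberately naive (per-pixel loops, BFS flood fill) and share no code with
# the implementation they check.

# flood-fill connected components; returns count and sorted areas
oracle_flood_fill <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  nb <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  areas <- integer(0)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && jj >= 1 && ii <= h && jj <= w &&
            mask[ii, jj] != 0 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    areas <- c(areas, area)
  }
  list(count = length(areas), areas = sort(areas))
}

# per-pixel argmin-G loop (earliest tie) composite
oracle_composite <- function(frames) {
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  out <- array(0L, c(h, w, 3))
  idx <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gvals <- vapply(frames, function(f) f[i, j, 2], numeric(1))
    k <- which.min(gvals)  # which.min returns the first minimum
    out[i, j, ] <- frames[[k]][i, j, ]
    idx[i, j] <- k
  }
  list(image = out, index = idx)
}

# per-pixel confusion loop
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0; g <- gt[i, j] > 0
    if (p && g) tp <- tp + 1L
    else if (!p && !g) tn <- tn + 1L
    else if (p && !g) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

random_mask <- function(h, w, p = 0.3) {
  m <- matrix(0L, h, w)
  m[matrix(runif(h * w), h, w) < p] <- 255L
  m
}

random_frame <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# binary dilation by a 3x3 square, repeated `iter` times
dilate_mask <- function(mask, iter = 1) {
  h <- nrow(mask); w <- ncol(mask)
  for (it in seq_len(iter)) {
    fg <- mask > 0
    out <- fg
    out[-1, ] <- out[-1, ] | fg[-h, ]
    out[-h, ] <- out[-h, ] | fg[-1, ]
    out[, -1] <- out[, -1] | fg[, -w]
    out[, -w] <- out[, -w] | fg[, -1]
    mask <- matrix(0L, h, w); mask[out] <- 255L
  }
  mask
}

# training patches for the learnable toy task: bimodal G, mask = G < 128
toy_threshold_patch <- function(h = 32, w = 32) {
  low <- sample(60:95, h * w, replace = TRUE)
  high <- sample(160:200, h * w, replace = TRUE)
  pick <- runif(h * w) < 0.4
  g <- matrix(ifelse(pick, low, high), h, w)
  img <- array(0L, c(h, w, 3))
  img[, , 1] <- matrix(sample(0:255, h * w, TRUE), h, w)
  img[, , 2] <- g
  img[, , 3] <- matrix(sample(0:255, h * w, TRUE), h, w)
  storage.mode(img) <- "integer"
  list(image = img, mask = matrix(ifelse(g < 128, 255L, 0L), h, w))
}

# static textured scene (no vessels, no vignette) with known jitter,
# for exact stabilization-recovery checks
jittered_texture_stack <- function(seed, jitter_max = 6, width = 160,
                                   height = 140, n_frames = 4) {
  generate_scene(scene_config(
    width_px = width, height_px = height, n_frames = n_frames,
    n_capillaries = 0, n_distractors = 4, vignette_strength = 0,
    jitter_max_px = jitter_max, seed = seed))
}
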