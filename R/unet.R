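# Convolutional encoder/decoder segmentation network (U-Net) implemented on
# top of the package's im2col/GEMM kernels: size-preserving 3x3 convolutions,
# 2x2 max pooling, nearest-neighbor upsampling with skip concatenation, a
# 1x1 output head, BCE / soft-Dice losses, Adam, and full backpropagation.
# This keeps training reproducible (single-threaded, seeded R RNG) and
# desk-scale networks fast enough for CPU use.

#' Training configuration
#'
#' Defaults mirror the reference workflow: 512 x 512 patches sampled at
#' random positions from annotated stills, 150 patches, batch size 16,
#' 50 epochs. The optimizer (Adam) and learning rate are this package's
#' choices; reduce `depth`/`base_channels`/`epochs` for desk-scale runs.
#'
#' @param patch_size_px square patch edge (default 512).
#' @param n_patches number of patches to sample (default 150).
#' @param batch_size gradient-accumulation batch (default 16).
#' @param epochs training epochs (default 50).
#' @param seed RNG seed for sampling, initialization and shuffling.
#' @param loss "bce", "dice" or "bce_dice".
#' @param learning_rate Adam step size.
#' @param depth number of resolution levels (default 4).
#' @param base_channels channels at the top level, doubled per level
#'   (default 16).
#' @return a `train_config` list.
#' @export
train_config <- function(patch_size_px = 512, n_patches = 150,
                         batch_size = 16, epochs = 50, seed = 1L,
                         loss = c("bce", "dice", "bce_dice"),
                         learning_rate = 1e-3,
                         depth = 4, base_channels = 16) {
  loss <- match.arg(loss)
  stopifnot(patch_size_px >= 1, n_patches >= 1, batch_size >= 1,
            epochs >= 1, learning_rate > 0, depth >= 1, base_channels >= 1)
  if (n_patches < batch_size) stop("n_patches must be >= batch_size")
  if (patch_size_px %% 2^(depth - 1) != 0)
    stop("patch_size_px must be divisible by 2^(depth - 1)")
  list(patch_size_px = as.integer(patch_size_px),
       n_patches = as.integer(n_patches),
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       seed = as.integer(seed), loss = loss,
       learning_rate = learning_rate,
       depth = as.integer(depth), base_channels = as.integer(base_channels))
}

#' Tiled-inference configuration
#'
#' @param window_px sliding-window edge (default 512).
#' @param stride_px step between windows in both axes (default 50).
#' @param merge how overlapping window predictions combine: "mean" or "max".
#' @param threshold probability cut for binarization, in (0, 1); pixels with
#'   merged probability >= threshold become foreground (255).
#' @return a `tile_config` list.
#' @export
tile_config <- function(window_px = 512, stride_px = 50,
                        merge = c("mean", "max"), threshold = 0.5) {
  merge <- match.arg(merge)
  stopifnot(window_px >= 1, stride_px >= 1)
  if (stride_px > window_px) stop("stride must be <= window")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  list(window_px = as.integer(window_px), stride_px = as.integer(stride_px),
       merge = merge, threshold = threshold)
}

#' Sample congruent image/mask patches from annotated pairs
#'
#' Draws `cfg$n_patches` square patches: for each, a source pair is chosen
#' uniformly, then a valid top-left corner uniformly; image and mask are cut
#' congruently. Fully seeded, so two calls with the same inputs and config
#' return identical patch sets.
#'
#' @param pairs list of annotation pairs, each a list with `image`
#'   (8-bit RGB) and `mask` (H x W, {0, 255}) on the same grid.
#' @param cfg a [train_config()].
#' @return list of patches, each a list with `image`, `mask`, `source`
#'   (pair index) and `offset` (0-based x, y of the crop).
#' @export
sample_patches <- function(pairs, cfg = train_config()) {
  p <- cfg$patch_size_px
  for (i in seq_along(pairs)) {
    di <- dim(pairs[[i]]$image)
    if (!identical(di[1:2], dim(pairs[[i]]$mask)))
      stop(sprintf("pair %d: image and mask grids differ", i))
    assert_binary_mask(pairs[[i]]$mask, sprintf("pair %d mask", i))
    if (di[1] < p || di[2] < p)
      stop(sprintf("pair %d image (%d x %d) is smaller than the %d px patch",
                   i, di[2], di[1], p))
  }
  withr::local_seed(cfg$seed)
  lapply(seq_len(cfg$n_patches), function(n) {
    src <- sample.int(length(pairs), 1)
    d <- dim(pairs[[src]]$image)
    y0 <- sample.int(d[1] - p + 1, 1) - 1L
    x0 <- sample.int(d[2] - p + 1, 1) - 1L
    list(image = pairs[[src]]$image[(y0 + 1):(y0 + p), (x0 + 1):(x0 + p), , drop = FALSE],
         mask = pairs[[src]]$mask[(y0 + 1):(y0 + p), (x0 + 1):(x0 + p), drop = FALSE],
         source = src, offset = c(x = x0, y = y0))
  })
}

# ---- network internals -----------------------------------------------------

# layer spec: list of conv layers in forward order with in/out channels
unet_layer_spec <- function(depth, base, in_channels = 3) {
  ch <- base * 2^(seq_len(depth) - 1)
  spec <- list()
  cin <- in_channels
  for (i in seq_len(depth)) {
    spec[[paste0("enc", i, "a")]] <- list(cin = cin, cout = ch[i], k = 3L)
    spec[[paste0("enc", i, "b")]] <- list(cin = ch[i], cout = ch[i], k = 3L)
    cin <- ch[i]
  }
  if (depth > 1) {
    for (i in seq(depth - 1, 1)) {
      spec[[paste0("dec", i, "a")]] <- list(cin = ch[i + 1] + ch[i], cout = ch[i], k = 3L)
      spec[[paste0("dec", i, "b")]] <- list(cin = ch[i], cout = ch[i], k = 3L)
    }
  }
  spec[["out"]] <- list(cin = ch[1], cout = 1L, k = 1L)
  spec
}

unet_init_params <- function(spec) {
  lapply(spec, function(s) {
    fan_in <- s$k * s$k * s$cin
    list(W = matrix(rnorm(s$cout * fan_in, 0, sqrt(2 / fan_in)), s$cout, fan_in),
         b = rep(0, s$cout), k = s$k, cin = s$cin)
  })
}

conv_relu <- function(params, name, x, caches, relu = TRUE) {
  p <- params[[name]]
  f <- cpp_conv2d_forward(x, p$W, p$b, p$k)
  y <- f$y
  if (relu) y <- pmax(y, 0)
  caches[[name]] <- list(xcol = f$xcol, act = if (relu) y else NULL)
  list(y = y, caches = caches)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

downsum2 <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  dy[io, jo, , drop = FALSE] + dy[io + 1, jo, , drop = FALSE] +
    dy[io, jo + 1, , drop = FALSE] + dy[io + 1, jo + 1, , drop = FALSE]
}

concat3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

unet_forward <- function(params, x, depth) {
  caches <- list()
  skips <- list()
  a <- x
  for (i in seq_len(depth)) {
    r <- conv_relu(params, paste0("enc", i, "a"), a, caches); a <- r$y; caches <- r$caches
    r <- conv_relu(params, paste0("enc", i, "b"), a, caches); a <- r$y; caches <- r$caches
    if (i < depth) {
      skips[[i]] <- a
      mp <- cpp_maxpool2_forward(a)
      caches[[paste0("pool", i)]] <- mp$idx
      a <- mp$y
    }
  }
  if (depth > 1) {
    for (i in seq(depth - 1, 1)) {
      up <- upsample2(a)
      caches[[paste0("cat", i)]] <- c(dim(skips[[i]])[3], dim(up)[3])
      a <- concat3(skips[[i]], up)
      r <- conv_relu(params, paste0("dec", i, "a"), a, caches); a <- r$y; caches <- r$caches
      r <- conv_relu(params, paste0("dec", i, "b"), a, caches); a <- r$y; caches <- r$caches
    }
  }
  r <- conv_relu(params, "out", a, caches, relu = FALSE)
  list(z = r$y[, , 1], caches = r$caches)
}

conv_back <- function(params, name, caches, dy, relu = TRUE) {
  p <- params[[name]]
  cc <- caches[[name]]
  if (relu) dy <- dy * (cc$act > 0)
  cpp_conv2d_backward(dy, p$W, cc$xcol, p$k, p$cin)
}

unet_backward <- function(params, caches, dz, depth) {
  grads <- list()
  dz3 <- array(dz, dim = c(dim(dz), 1L))
  bk <- conv_back(params, "out", caches, dz3, relu = FALSE)
  grads[["out"]] <- bk[c("dW", "db")]
  da <- bk$dx
  if (depth > 1) {
    dskip <- vector("list", depth - 1)
    for (i in seq(1, depth - 1)) {   # reverse of forward decoder order
      bk <- conv_back(params, paste0("dec", i, "b"), caches, da)
      grads[[paste0("dec", i, "b")]] <- bk[c("dW", "db")]
      bk <- conv_back(params, paste0("dec", i, "a"), caches, bk$dx)
      grads[[paste0("dec", i, "a")]] <- bk[c("dW", "db")]
      nch <- caches[[paste0("cat", i)]]
      dskip[[i]] <- bk$dx[, , seq_len(nch[1]), drop = FALSE]
      da <- downsum2(bk$dx[, , nch[1] + seq_len(nch[2]), drop = FALSE])
    }
  }
  for (i in seq(depth, 1)) {
    if (i < depth) {
      da <- cpp_maxpool2_backward(da, caches[[paste0("pool", i)]])
      da <- da + dskip[[i]]
    }
    bk <- conv_back(params, paste0("enc", i, "b"), caches, da)
    grads[[paste0("enc", i, "b")]] <- bk[c("dW", "db")]
    bk <- conv_back(params, paste0("enc", i, "a"), caches, bk$dx)
    grads[[paste0("enc", i, "a")]] <- bk[c("dW", "db")]
    da <- bk$dx
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# loss value and gradient wrt logits z; y in {0,1}
seg_loss <- function(z, y, kind) {
  n <- length(z)
  p <- sigmoid(z)
  val <- 0; dz <- 0
  if (kind %in% c("bce", "bce_dice")) {
    # stable BCE: softplus(z) - y*z
    sp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    val <- val + sum(sp - y * z) / n
    dz <- dz + (p - y) / n
  }
  if (kind %in% c("dice", "bce_dice")) {
    eps <- 1
    S <- sum(p) + sum(y) + eps
    Tn <- sum(p * y)
    val <- val + (1 - (2 * Tn + eps) / S)
    # d(1 - (2T+eps)/S)/dp = -(2y*S - (2T+eps))/S^2
    dp <- -(2 * y * S - (2 * Tn + eps)) / S^2
    dz <- dz + dp * p * (1 - p)
  }
  list(value = val, dz = dz)
}

adam_step <- function(params, grads, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    for (s in c("W", "b")) {
      g <- grads[[nm]][[paste0("d", s)]]
      if (s == "b") g <- as.numeric(g)
      key <- paste0(nm, ".", s)
      if (is.null(state[[key]])) state[[key]] <- list(m = g * 0, v = g * 0)
      st <- state[[key]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t); vhat <- st$v / (1 - b2^t)
      params[[nm]][[s]] <- params[[nm]][[s]] - lr * mhat / (sqrt(vhat) + eps)
      state[[key]] <- st
    }
  }
  list(params = params, state = state)
}

patch_to_input <- function(image) {
  x <- image / 255
  storage.mode(x) <- "double"
  x
}

#' Train the segmentation network
#'
#' Mini-batch training with gradient accumulation and Adam on image/mask
#' patches (see [sample_patches()]). Inputs are scaled to `[0, 1]` by /255;
#' masks are taken as {0, 255} and trained against as {0, 1}. Training is
#' fully seeded (initialization and epoch shuffling) and aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param patches list of patches with `image` and `mask` entries.
#' @param cfg a [train_config()].
#' @return a `segmenter_model`: trained parameters, architecture descriptor,
#'   the config, and a per-epoch `train_log` tibble (epoch, loss).
#' @export
train_segmenter <- function(patches, cfg = train_config()) {
  if (length(patches) < 1) stop("empty patch list")
  if (length(patches) < cfg$batch_size)
    stop("need at least one full batch of patches")
  for (i in seq_along(patches))
    assert_binary_mask(patches[[i]]$mask, sprintf("patch %d mask", i))
  d <- dim(patches[[1]]$image)
  if (d[1] %% 2^(cfg$depth - 1) != 0 || d[2] %% 2^(cfg$depth - 1) != 0)
    stop("patch dimensions must be divisible by 2^(depth - 1)")
  spec <- unet_layer_spec(cfg$depth, cfg$base_channels)
  withr::local_seed(cfg$seed)
  params <- unet_init_params(spec)
  xs <- lapply(patches, function(p) patch_to_input(p$image))
  ys <- lapply(patches, function(p) (p$mask > 0) * 1.0)
  state <- list()
  t_step <- 0
  log_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(patches))
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        fw <- unet_forward(params, xs[[i]], cfg$depth)
        ls <- seg_loss(fw$z, ys[[i]], cfg$loss)
        if (!is.finite(ls$value))
          stop(sprintf("non-finite loss at epoch %d (diverged); lower the learning rate", ep))
        bl <- bl + ls$value
        gr <- unet_backward(params, fw$caches, ls$dz, cfg$depth)
        if (is.null(acc)) acc <- gr else
          for (nm in names(gr)) {
            acc[[nm]]$dW <- acc[[nm]]$dW + gr[[nm]]$dW
            acc[[nm]]$db <- acc[[nm]]$db + gr[[nm]]$db
          }
      }
      for (nm in names(acc)) {
        acc[[nm]]$dW <- acc[[nm]]$dW / length(idx)
        acc[[nm]]$db <- acc[[nm]]$db / length(idx)
      }
      t_step <- t_step + 1
      upd <- adam_step(params, acc, state, cfg$learning_rate, t_step)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl / length(idx)
      nb <- nb + 1
    }
    log_loss[ep] <- ep_loss / nb
  }
  structure(list(
    params = params,
    architecture = list(depth = cfg$depth, base_channels = cfg$base_channels,
                        in_channels = 3L, kernel = 3L),
    config = cfg,
    train_log = tibble::tibble(epoch = seq_len(cfg$epochs), loss = log_loss)
  ), class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("<segmenter_model> depth %d, base %d channels, final loss %.4f\n",
              x$architecture$depth, x$architecture$base_channels,
              utils::tail(x$train_log$loss, 1)))
  invisible(x)
}

#' Per-pixel probabilities for one window
#'
#' @param model a `segmenter_model` (or, for testing, any function mapping an
#'   H x W x 3 array in `[0, 1]` to an H x W probability matrix).
#' @param image 8-bit RGB array whose dimensions are divisible by
#'   `2^(depth - 1)`.
#' @return matrix of probabilities in `[0, 1]`.
#' @export
predict_window <- function(model, image) {
  x <- patch_to_input(image)
  if (is.function(model)) return(model(x))
  stopifnot(inherits(model, "segmenter_model"))
  sigmoid(unet_forward(model$params, x, model$architecture$depth)$z)
}

#' Sliding-window tiled inference
#'
#' Windows of `cfg$window_px` tile the image row-major with `cfg$stride_px`
#' spacing; the final window of each row/column is clamped to the image edge
#' so every pixel is covered. Overlapping window predictions are merged
#' per-pixel (mean by default, optionally max), and the merged probability
#' map is binarized at `cfg$threshold` (>= threshold is capillary, 255).
#'
#' @param model a `segmenter_model` or a stub function (see
#'   [predict_window()]).
#' @param image 8-bit RGB still, at least `window_px` in both dimensions.
#' @param cfg a [tile_config()].
#' @return list with `probability` (H x W matrix in `[0, 1]`) and `mask`
#'   (H x W matrix, {0, 255}).
#' @export
predict_tiled <- function(model, image, cfg = tile_config()) {
  assert_rgb8(image)
  d <- dim(image)
  w <- cfg$window_px
  if (d[1] < w || d[2] < w)
    stop(sprintf("image (%d x %d) smaller than the %d px window; pad the image first",
                 d[2], d[1], w))
  starts <- function(n) {
    s <- seq(0L, n - w, by = cfg$stride_px)
    if (s[length(s)] != n - w) s <- c(s, n - w)
    s
  }
  ys <- starts(d[1]); xs <- starts(d[2])
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (y0 in ys) for (x0 in xs) {
    ri <- (y0 + 1):(y0 + w); ci <- (x0 + 1):(x0 + w)
    p <- predict_window(model, image[ri, ci, , drop = FALSE])
    if (cfg$merge == "mean") {
      acc[ri, ci] <- acc[ri, ci] + p
    } else {
      acc[ri, ci] <- pmax(acc[ri, ci], p)
    }
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  prob <- if (cfg$merge == "mean") acc / cnt else acc
  mask <- matrix(0L, d[1], d[2])
  mask[prob >= cfg$threshold] <- 255L
  list(probability = prob, mask = mask)
}

#' Save / load a trained segmenter
#'
#' The checkpoint is R's native serialization of the model object, written
#' alongside a JSON sidecar describing the architecture so checkpoints are
#' self-describing. A reloaded checkpoint reproduces predictions bit-exactly.
#'
#' @param model a `segmenter_model`.
#' @param path checkpoint path (e.g. `model.rds`); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `save_segmenter` returns `path` invisibly; `load_segmenter`
#'   returns the model.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "segmenter_model"))
  saveRDS(model, path)
  jsonlite::write_json(model$architecture, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "segmenter_model"))
  model
}

#' Training-curve plot
#'
#' @param object a `segmenter_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.segmenter_model <- function(object, ...) {
  ggplot2::ggplot(object$train_log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "training loss")
}
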