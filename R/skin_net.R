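#' Configuration of the skin-detection network
#'
#' A small convolutional encoder-decoder for per-pixel skin probability on
#' low-resolution grayscale frames: eight 3 x 3 convolution stages with
#' rectified-linear activations and three 2 x 2 max-pools in the encoder
#' (spatial bottleneck at 1/8 of the input on each axis), six 3 x 3 stages
#' with three nearest-neighbour upsamplings in the decoder, and a sigmoid
#' head so every output lies in [0, 1]. Channel widths are deliberately
#' modest so the network trains in minutes on one CPU core.
#'
#' @param encoder_channels Output channels of the 8 encoder convolutions.
#' @param pool_after Encoder stages followed by a 2 x 2 max-pool (3 of them).
#' @param decoder_channels Output channels of the 6 decoder convolutions;
#'   the last must be 1 (the probability map).
#' @param upsample_before Decoder stages preceded by a 2x nearest-neighbour
#'   upsampling (3 of them).
#' @param alpha Asymmetry weight of the training loss, in (0, 0.5)
#'   (default 0.4); see [asymmetric_loss()].
#' @param threshold Binarization cut in (0, 1) (default 0.5).
#' @param epochs Training epochs (default 30).
#' @param lr Learning rate of the momentum-SGD optimizer (default 1e-3).
#' @param momentum Momentum coefficient (default 0.9).
#' @param clip_norm Global gradient-norm clip (default 5). Clipping caps the
#'   very large early gradients that would otherwise inflate the decoder
#'   activations and drive the sigmoid head into saturation, from which the
#'   squared loss cannot recover; once gradients are moderate the steps are
#'   plain momentum SGD and shrink with the gradient.
#' @param batch_size Mini-batch size (default 10).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `skin_net_config`.
#' @export
skin_net_config <- function(encoder_channels = c(8, 8, 16, 16, 32, 32, 64, 64),
                            pool_after = c(2, 4, 6),
                            decoder_channels = c(32, 32, 16, 16, 8, 1),
                            upsample_before = c(1, 3, 5),
                            alpha = 0.4, threshold = 0.5,
                            epochs = 30, lr = 1e-3, momentum = 0.9,
                            clip_norm = 5, batch_size = 10, seed = 42L) {
  stopifnot(length(encoder_channels) == 8L, length(decoder_channels) == 6L,
            length(pool_after) == 3L, length(upsample_before) == 3L,
            all(encoder_channels >= 1), all(decoder_channels >= 1),
            decoder_channels[6] == 1L || decoder_channels[6] == 1,
            alpha > 0, alpha < 0.5,
            threshold > 0, threshold < 1,
            epochs >= 1, lr > 0, momentum >= 0, momentum < 1,
            clip_norm > 0, batch_size >= 1)
  structure(list(encoder_channels = encoder_channels,
                 pool_after = as.integer(pool_after),
                 decoder_channels = decoder_channels,
                 upsample_before = as.integer(upsample_before),
                 alpha = alpha, threshold = threshold,
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 clip_norm = clip_norm,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "skin_net_config")
}

# ---- index caches -----------------------------------------------------
# Feature maps live as (B*H*W) x C matrices, positions column-major per
# image. Index tables for convolution, pooling and upsampling depend only
# on (H, W, B) and are cached.

.shape_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, B) {
  key <- paste("c", H, W, B, sep = "_")
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- H * W
  r <- ((seq_len(N) - 1L) %% H) + 1L
  c <- ((seq_len(N) - 1L) %/% H) + 1L
  off <- expand.grid(dr = -1:1, dc = -1:1)
  idx1 <- matrix(N + 1L, N, 9L)  # N+1 marks out-of-frame (zero padding)
  for (o in seq_len(9L)) {
    rn <- r + off$dr[o]; cn <- c + off$dc[o]
    ok <- rn >= 1L & rn <= H & cn >= 1L & cn <= W
    idx1[ok, o] <- rn[ok] + (cn[ok] - 1L) * H
  }
  idx <- matrix(B * N + 1L, B * N, 9L)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * N + seq_len(N)
    blk <- idx1
    inside <- blk <= N
    blk[inside] <- blk[inside] + (b - 1L) * N
    blk[!inside] <- B * N + 1L
    idx[rows, ] <- blk
  }
  .shape_cache[[key]] <- idx
  idx
}

pool_indices <- function(H, W, B) {
  key <- paste("p", H, W, B, sep = "_")
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  N <- H * W; N2 <- H2 * W2
  r2 <- ((seq_len(N2) - 1L) %% H2) + 1L
  c2 <- ((seq_len(N2) - 1L) %/% H2) + 1L
  lin <- function(r, c) r + (c - 1L) * H
  idx1 <- cbind(lin(2L * r2 - 1L, 2L * c2 - 1L),
                lin(2L * r2,      2L * c2 - 1L),
                lin(2L * r2 - 1L, 2L * c2),
                lin(2L * r2,      2L * c2))
  idx <- matrix(0L, B * N2, 4L)
  for (b in seq_len(B))
    idx[(b - 1L) * N2 + seq_len(N2), ] <- idx1 + (b - 1L) * N
  .shape_cache[[key]] <- idx
  idx
}

upsample_indices <- function(H, W, B) {
  # maps positions of the (2H x 2W) output to their (H x W) source
  key <- paste("u", H, W, B, sep = "_")
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- 2L * H; W2 <- 2L * W
  N <- H * W; N2 <- H2 * W2
  r <- ((seq_len(N2) - 1L) %% H2) + 1L
  c <- ((seq_len(N2) - 1L) %/% H2) + 1L
  idx1 <- ((r + 1L) %/% 2L) + (((c + 1L) %/% 2L) - 1L) * H
  idx <- integer(B * N2)
  for (b in seq_len(B))
    idx[(b - 1L) * N2 + seq_len(N2)] <- idx1 + (b - 1L) * N
  .shape_cache[[key]] <- idx
  idx
}

# ---- network construction ---------------------------------------------

#' Build an (untrained) skin-detection network
#'
#' Instantiates the layer stack of [skin_net_config()] for a given frame
#' shape with deterministic He-scaled initialization. The returned model is
#' a callable contract: [predict.skin_net()] maps grayscale frames (scaled
#' to [0, 1]) to probability maps of the same shape.
#'
#' @param config A `skin_net_config`.
#' @param rows,cols Input frame shape; both must be divisible by 8
#'   (defaults 32, 64).
#' @return An object of class `skin_net`.
#' @export
build_network <- function(config = skin_net_config(), rows = 32, cols = 64) {
  stopifnot(inherits(config, "skin_net_config"))
  if (rows %% 8L != 0L || cols %% 8L != 0L)
    stop("input shape must be divisible by 8 on both axes")
  plan <- list()
  cin <- 1L
  for (j in seq_len(8L)) {
    cout <- config$encoder_channels[j]
    plan[[length(plan) + 1L]] <- list(type = "conv", cin = cin, cout = cout,
                                      act = "relu")
    if (j %in% config$pool_after)
      plan[[length(plan) + 1L]] <- list(type = "pool")
    cin <- cout
  }
  for (j in seq_len(6L)) {
    if (j %in% config$upsample_before)
      plan[[length(plan) + 1L]] <- list(type = "up")
    cout <- config$decoder_channels[j]
    plan[[length(plan) + 1L]] <- list(type = "conv", cin = cin, cout = cout,
                                      act = if (j == 6L) "sigmoid" else "relu")
    cin <- cout
  }
  layers <- with_seed(config$seed, lapply(plan, function(ly) {
    if (ly$type == "conv") {
      fan_in <- 9L * ly$cin
      ly$W <- matrix(stats::rnorm(fan_in * ly$cout, 0, sqrt(2 / fan_in)),
                     fan_in, ly$cout)
      ly$b <- numeric(ly$cout)
    }
    ly
  }))
  structure(list(config = config, layers = layers, rows = rows, cols = cols,
                 trained = FALSE, loss_history = numeric(0)),
            class = "skin_net")
}

#' Number of trainable parameters of a skin network
#' @param model A `skin_net`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "skin_net"))
  sum(vapply(model$layers, function(ly)
    if (ly$type == "conv") length(ly$W) + length(ly$b) else 0L, numeric(1)))
}

# Forward pass on a batch. X: (B*rows*cols) x 1 matrix. Returns the output
# column and, if keep = TRUE, the per-layer cache needed for backprop.
net_forward <- function(model, X, B, keep = FALSE) {
  H <- model$rows; W <- model$cols
  cache <- if (keep) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      idx <- conv_indices(H, W, B)
      Xa <- rbind(X, 0)
      col <- matrix(0, nrow(X), 9L * ly$cin)
      for (o in seq_len(9L))
        col[, ((o - 1L) * ly$cin + 1L):(o * ly$cin)] <- Xa[idx[, o], , drop = FALSE]
      Y <- col %*% ly$W
      Y <- sweep(Y, 2L, ly$b, `+`)
      r <- NULL
      if (ly$act == "relu") {
        Y[Y < 0] <- 0
        # parameter-free per-image RMS normalization: keeps activation
        # magnitudes bounded through the depth of the unnormalized stack
        N <- H * W
        r <- sqrt(rowsum(rowSums(Y^2), rep(seq_len(B), each = N),
                         reorder = TRUE)[, 1L] / (N * ncol(Y)) + 1e-8)
        Y <- Y / r[rep(seq_len(B), each = N)]
      } else {
        Y <- 1 / (1 + exp(-Y))
      }
      if (keep) cache[[li]] <- list(col = col, out = Y, H = H, W = W, r = r)
      X <- Y
    } else if (ly$type == "pool") {
      idx4 <- pool_indices(H, W, B)
      A <- X[idx4[, 1L], , drop = FALSE]
      sel <- matrix(1L, nrow(A), ncol(A))
      for (k in 2L:4L) {
        Ak <- X[idx4[, k], , drop = FALSE]
        upd <- Ak > A
        A[upd] <- Ak[upd]
        sel[upd] <- k
      }
      if (keep) cache[[li]] <- list(sel = sel, H = H, W = W, n_in = nrow(X))
      X <- A
      H <- H %/% 2L; W <- W %/% 2L
    } else {  # upsample
      upidx <- upsample_indices(H, W, B)
      if (keep) cache[[li]] <- list(H = H, W = W)
      X <- X[upidx, , drop = FALSE]
      H <- 2L * H; W <- 2L * W
    }
  }
  list(out = X, cache = cache)
}

# Backward pass; dOut is the gradient at the network output. Returns the
# list of per-layer gradients (dW, db) for conv layers.
net_backward <- function(model, cache, dOut, B) {
  grads <- vector("list", length(model$layers))
  dY <- dOut
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- cache[[li]]
    if (ly$type == "conv") {
      Y <- cc$out
      if (ly$act == "relu") {
        # back through the per-image RMS norm, then the ReLU
        N <- cc$H * cc$W
        img <- rep(seq_len(B), each = N)
        mdyy <- rowsum(rowSums(dY * Y), img, reorder = TRUE)[, 1L] /
          (N * ncol(Y))
        dPre <- ((dY - Y * mdyy[img]) / cc$r[img]) * (Y > 0)
      } else {
        dPre <- dY * Y * (1 - Y)
      }
      grads[[li]] <- list(dW = crossprod(cc$col, dPre), db = colSums(dPre))
      dCol <- dPre %*% t(ly$W)
      idx <- conv_indices(cc$H, cc$W, B)
      dXa <- matrix(0, nrow(dY) + 1L, ly$cin)
      for (o in seq_len(9L)) {
        blk <- dCol[, ((o - 1L) * ly$cin + 1L):(o * ly$cin), drop = FALSE]
        rows <- idx[, o]
        # per offset each interior target row is unique; only the padding
        # row repeats and it is discarded below
        dXa[rows, ] <- dXa[rows, , drop = FALSE] + blk
      }
      dY <- dXa[seq_len(nrow(dY)), , drop = FALSE]
    } else if (ly$type == "pool") {
      idx4 <- pool_indices(cc$H, cc$W, B)
      dX <- matrix(0, cc$n_in, ncol(dY))
      for (k in 1L:4L) {
        contrib <- dY * (cc$sel == k)
        rows <- idx4[, k]
        dX[rows, ] <- dX[rows, , drop = FALSE] + contrib
      }
      dY <- dX
    } else {  # upsample: sum gradients of the 4 replicated outputs
      upidx <- upsample_indices(cc$H, cc$W, B)
      dY <- rowsum(dY, upidx, reorder = TRUE)
    }
  }
  grads
}

# scale a raw frame to [0, 1] by its own maximum (exposure-invariant)
normalize_frame <- function(frame) {
  m <- max(frame)
  if (m > 0) frame / m else frame
}

frames_to_batch <- function(frames, rows, cols) {
  lst <- if (is.list(frames)) frames
  else if (is.matrix(frames)) list(frames)
  else lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  stopifnot(all(vapply(lst, function(f)
    all(dim(f) == c(rows, cols)), logical(1))))
  X <- matrix(0, length(lst) * rows * cols, 1L)
  for (b in seq_along(lst))
    X[(b - 1L) * rows * cols + seq_len(rows * cols), 1L] <-
      as.numeric(normalize_frame(lst[[b]]))
  list(X = X, B = length(lst))
}

#' Predict skin probability maps
#'
#' @param object A `skin_net`.
#' @param frames A single matrix, a list of matrices, or a 3D array
#'   (n x rows x cols) of grayscale frames (raw counts are rescaled to
#'   [0, 1] internally).
#' @param ... Unused.
#' @return A probability-map matrix, or a list of them when several frames
#'   are given.
#' @export
predict.skin_net <- function(object, frames, ...) {
  single <- is.matrix(frames)
  bt <- frames_to_batch(frames, object$rows, object$cols)
  out <- net_forward(object, bt$X, bt$B)$out
  N <- object$rows * object$cols
  maps <- lapply(seq_len(bt$B), function(b)
    matrix(out[(b - 1L) * N + seq_len(N), 1L], object$rows, object$cols))
  if (single) maps[[1L]] else maps
}

#' Train the skin-detection network
#'
#' Mini-batch Adam on the asymmetric squared loss against simulator
#' ground-truth masks. Training is deterministic given the config seed.
#'
#' @param pairs List of `list(frame, mask)` training pairs (matrices of the
#'   same shape; masks logical).
#' @param config A `skin_net_config`.
#' @param model Optional pre-built `skin_net` to continue training.
#' @param verbose Print the per-epoch loss.
#' @return A trained `skin_net` with `loss_history` (mean per-image loss
#'   per epoch, with the pre-training loss as its first element).
#' @export
train_skin_network <- function(pairs, config = skin_net_config(),
                               model = NULL, verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty training set")
  rows <- nrow(pairs[[1L]]$frame); cols <- ncol(pairs[[1L]]$frame)
  if (is.null(model)) model <- build_network(config, rows, cols)
  else model$config <- config  # architecture kept, training knobs updated
  N <- rows * cols
  n <- length(pairs)
  Y <- matrix(0, n * N, 1L)
  Xall <- matrix(0, n * N, 1L)
  for (b in seq_len(n)) {
    Xall[(b - 1L) * N + seq_len(N), 1L] <-
      as.numeric(normalize_frame(pairs[[b]]$frame))
    Y[(b - 1L) * N + seq_len(N), 1L] <- as.numeric(pairs[[b]]$mask)
  }
  alpha <- config$alpha
  mean_loss <- function() {
    tot <- 0
    bs <- 50L
    for (s in seq(1L, n, by = bs)) {
      ib <- s:min(n, s + bs - 1L)
      rowsel <- as.vector(outer(seq_len(N), (ib - 1L) * N, `+`))
      p <- net_forward(model, Xall[rowsel, , drop = FALSE], length(ib))$out
      y <- Y[rowsel, , drop = FALSE]
      tot <- tot + sum((y - p)^2 * (alpha * y + (1 - alpha) * (1 - y)))
    }
    tot / n
  }
  vel <- lapply(model$layers, function(ly)
    if (ly$type == "conv") list(W = ly$W * 0, b = ly$b * 0) else NULL)
  history <- mean_loss()
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + epoch, sample.int(n))
    ep_loss <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      ib <- ord[s:min(n, s + config$batch_size - 1L)]
      B <- length(ib)
      rowsel <- as.vector(outer(seq_len(N), (ib - 1L) * N, `+`))
      Xb <- Xall[rowsel, , drop = FALSE]
      Yb <- Y[rowsel, , drop = FALSE]
      fw <- net_forward(model, Xb, B, keep = TRUE)
      p <- fw$out
      wgt <- alpha * Yb + (1 - alpha) * (1 - Yb)
      ep_loss <- ep_loss + sum((Yb - p)^2 * wgt)
      dOut <- (-2 * (Yb - p) * wgt) / B
      grads <- net_backward(model, fw$cache, dOut, B)
      gnorm <- sqrt(sum(vapply(grads, function(g)
        if (is.null(g)) 0 else sum(g$dW^2) + sum(g$db^2), numeric(1))))
      sc <- min(1, config$clip_norm / gnorm)
      for (li in seq_along(model$layers)) {
        if (model$layers[[li]]$type != "conv") next
        g <- grads[[li]]
        vel[[li]]$W <- config$momentum * vel[[li]]$W - config$lr * sc * g$dW
        vel[[li]]$b <- config$momentum * vel[[li]]$b - config$lr * sc * g$db
        model$layers[[li]]$W <- model$layers[[li]]$W + vel[[li]]$W
        model$layers[[li]]$b <- model$layers[[li]]$b + vel[[li]]$b
      }
    }
    history <- c(history, ep_loss / n)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, config$epochs,
                      ep_loss / n))
  }
  model$trained <- TRUE
  model$loss_history <- history
  model
}

#' @export
print.skin_net <- function(x, ...) {
  nconv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  cat(sprintf("Skin-detection network (%d conv stages, %d parameters, %s)\n",
              nconv, n_parameters(x),
              if (x$trained) "trained" else "untrained"))
  if (x$trained)
    cat(sprintf("  final training loss %.4f (from %.4f)\n",
                utils::tail(x$loss_history, 1), x$loss_history[1]))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#' @param a,b Logical matrices of identical shape.
#' @return Scalar in [0, 1] (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Save / load a skin network checkpoint
#'
#' The checkpoint embeds the full configuration alongside the weights.
#' @param model A `skin_net`.
#' @param path Checkpoint file path.
#' @return `save_skin_net()` returns `path` invisibly; `load_skin_net()`
#'   the restored `skin_net`.
#' @export
save_skin_net <- function(model, path) {
  stopifnot(inherits(model, "skin_net"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_skin_net
#' @export
load_skin_net <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "skin_net")) stop("not a skin_net checkpoint")
  model
}
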