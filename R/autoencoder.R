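#' Model architecture configuration
#'
#' The network is a skip-connection-free convolutional autoencoder.  The
#' encoder applies `n_blocks` 3x3 conv + ReLU blocks with 2x2 max-pooling
#' after the first `n_blocks - 1`; channels double per block but freeze at
#' the last block, so the full-scale preset contracts 512x512 inputs to a
#' 32x32x256 volume (262,144 values).  That volume is flattened through a
#' dense hierarchy down to a `latent_dim`-wide linear bottleneck — the deep
#' radiomic vector — and mirrored back up; the final 1-channel conv carries
#' a sigmoid so the output is a lesion probability map.
#'
#' @param preset `"full"` (512px input, 32 base filters — the full-scale
#'   clinical architecture) or `"desk"` (64px input, 8 base filters —
#'   CPU-trainable).
#' @param input_size input side length; must be divisible by
#'   `pool_size^n_blocks`.
#' @param n_blocks number of conv blocks in the encoder (decoder mirrors).
#' @param base_filters channels in the first block.
#' @param max_channels channel cap.
#' @param latent_dim bottleneck width (the deep radiomic dimension).
#' @param hidden width of the dense layer between flatten and bottleneck.
#' @param kernel_size,pool_size fixed at 3 and 2 by the architecture.
#' @param use_skip_connections must remain `FALSE`: the dual-output design
#'   forces all information through the bottleneck.
#' @return an object of class `dual_ae_config`.
#' @export
model_config <- function(preset = c("desk", "full"),
                         input_size = NULL, n_blocks = 5L,
                         base_filters = NULL, max_channels = 512L,
                         latent_dim = 16L, hidden = 256L,
                         kernel_size = 3L, pool_size = 2L,
                         use_skip_connections = FALSE) {
  preset <- match.arg(preset)
  if (is.null(input_size)) input_size <- if (preset == "full") 512L else 64L
  if (is.null(base_filters)) base_filters <- if (preset == "full") 32L else 8L
  if (kernel_size != 3L || pool_size != 2L)
    stop("model_config: kernel_size 3 and pool_size 2 are the architecture")
  if (isTRUE(use_skip_connections))
    stop("model_config: skip connections are not part of this architecture")
  if (input_size %% pool_size^n_blocks != 0L)
    stop("model_config: input_size must be divisible by pool_size^n_blocks")
  if (latent_dim < 1L) stop("model_config: latent_dim must be >= 1")
  cfg <- list(preset = preset, input_size = as.integer(input_size),
              n_blocks = as.integer(n_blocks),
              base_filters = as.integer(base_filters),
              max_channels = as.integer(max_channels),
              latent_dim = as.integer(latent_dim),
              hidden = as.integer(hidden),
              kernel_size = 3L, pool_size = 2L,
              use_skip_connections = FALSE)
  class(cfg) <- "dual_ae_config"
  cfg
}

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size samples per optimisation step.
#' @param lr_start,lr_end Adam learning rate, cosine-decayed from
#'   `lr_start` to `lr_end` over the epoch budget.  The full-scale defaults
#'   are 2e-4 to 1e-6 over 150 epochs with batches of 8.
#' @param seed integer seed controlling weight initialisation and shuffling.
#' @param smooth Dice smoothing constant added to numerator and denominator
#'   of the loss (keeps the empty-vs-empty case and its gradient defined).
#' @return an object of class `dual_ae_train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 8L,
                         lr_start = 2e-4, lr_end = 1e-6, seed = 1L,
                         smooth = 1) {
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (!(lr_end > 0 && lr_end <= lr_start))
    stop("train_config: need 0 < lr_end <= lr_start")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end,
                 seed = as.integer(seed), smooth = smooth),
            class = "dual_ae_train_config")
}

ae_channels <- function(cfg) {
  ch <- integer(cfg$n_blocks + 1L)
  ch[1] <- 1L
  for (i in seq_len(cfg$n_blocks - 1L))
    ch[i + 1L] <- min(cfg$base_filters * 2L^(i - 1L), cfg$max_channels)
  ch[cfg$n_blocks + 1L] <- ch[cfg$n_blocks]
  ch
}

ae_meta <- function(cfg) {
  list(n_blocks = cfg$n_blocks, input_size = cfg$input_size,
       base_filters = cfg$base_filters, max_channels = cfg$max_channels,
       hidden = cfg$hidden, latent_dim = cfg$latent_dim)
}

#' Flattened bottleneck size and trainable-parameter count (analytic)
#'
#' Computed from the configuration without allocating any weights, so the
#' full-scale architecture can be inspected cheaply.
#'
#' @param cfg a [model_config()].
#' @return list with `flatten_size`, `n_parameters`, `channels`,
#'   `bottom_spatial`.
#' @export
dual_ae_dimensions <- function(cfg) {
  ch <- ae_channels(cfg)
  sb <- cfg$input_size / 2L^(cfg$n_blocks - 1L)
  Fl <- sb * sb * ch[cfg$n_blocks + 1L]
  n <- 0
  for (i in seq_len(cfg$n_blocks)) # encoder convs + norm scale/shift
    n <- n + 9 * ch[i] * ch[i + 1L] + 3L * ch[i + 1L]
  for (i in 2:cfg$n_blocks)        # decoder convs (mirror)
    n <- n + 9 * ch[i + 1L] * ch[i] + 3L * ch[i]
  n <- n + 9 * ch[2] * 1 + 1       # output conv
  n <- n + Fl * cfg$hidden + cfg$hidden          # fc1
  n <- n + cfg$hidden * cfg$latent_dim + cfg$latent_dim
  n <- n + cfg$latent_dim * cfg$hidden + cfg$hidden
  n <- n + cfg$hidden * Fl + Fl                  # fc4
  list(flatten_size = Fl, n_parameters = n, channels = ch,
       bottom_spatial = sb)
}

ae_init_params <- function(cfg, seed) {
  set.seed(seed)
  ch <- ae_channels(cfg)
  dims <- dual_ae_dimensions(cfg)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  p <- list()
  for (i in seq_len(cfg$n_blocks)) {
    p[[sprintf("enc_W%d", i)]] <- he(9L * ch[i], ch[i + 1L])
    p[[sprintf("enc_b%d", i)]] <- numeric(ch[i + 1L])
    p[[sprintf("enc_g%d", i)]] <- rep(1, ch[i + 1L]) # norm scale
    p[[sprintf("enc_h%d", i)]] <- numeric(ch[i + 1L]) # norm shift
  }
  p[["fc1_W"]] <- he(dims$flatten_size, cfg$hidden)
  p[["fc1_b"]] <- numeric(cfg$hidden)
  p[["fc2_W"]] <- he(cfg$hidden, cfg$latent_dim)
  p[["fc2_b"]] <- numeric(cfg$latent_dim)
  p[["fc3_W"]] <- he(cfg$latent_dim, cfg$hidden)
  p[["fc3_b"]] <- numeric(cfg$hidden)
  p[["fc4_W"]] <- he(cfg$hidden, dims$flatten_size)
  p[["fc4_b"]] <- numeric(dims$flatten_size)
  for (i in cfg$n_blocks:2) {
    p[[sprintf("dec_W%d", i)]] <- he(9L * ch[i + 1L], ch[i])
    p[[sprintf("dec_b%d", i)]] <- numeric(ch[i])
    p[[sprintf("dec_g%d", i)]] <- rep(1, ch[i])
    p[[sprintf("dec_h%d", i)]] <- numeric(ch[i])
  }
  p[["out_W"]] <- matrix(stats::rnorm(9L * ch[2], sd = 0.01), 9L * ch[2], 1L)
  p[["out_b"]] <- 0
  p
}

cosine_lr <- function(epoch, epochs, lr_start, lr_end) {
  if (epochs == 1L) return(lr_start)
  lr_end + 0.5 * (lr_start - lr_end) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

sample_matrices <- function(samples, what = "image") {
  lapply(samples, function(s) if (is.list(s)) s[[what]] else s)
}

#' Fit the dual-output segmentation autoencoder
#'
#' Trains the network to minimise the mean soft-Dice loss
#' `1 - (2*sum(p*g) + s) / (sum(p^2) + sum(g^2) + s)` over each batch using
#' Adam with a cosine learning-rate decay.  Only lesion-bearing (abnormal)
#' samples are used for the segmentation objective by default: all-zero
#' masks make the Dice target degenerate.
#'
#' @param samples training samples (list of `ultrasound_sample`); images
#'   must match `model$input_size`.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param val optional validation samples for the held-out Dice curve.
#' @param include_normal also train on all-zero-mask samples.
#' @param verbose print per-epoch Dice.
#' @return an object of class `dual_ae` with elements `params`, `config`,
#'   `train_config`, `history` (data.frame epoch/train_dice/val_dice),
#'   `n_parameters`.
#' @export
dual_autoencoder <- function(samples, model = model_config("desk"),
                             train = train_config(), val = NULL,
                             include_normal = FALSE, verbose = FALSE) {
  if (!include_normal)
    samples <- Filter(function(s) sum(s$mask) > 0, samples)
  if (length(samples) == 0L)
    stop("dual_autoencoder: no abnormal (lesion-bearing) training samples")
  for (s in samples)
    if (!all(dim(s$image) == model$input_size))
      stop("dual_autoencoder: sample '", s$id, "' does not match input_size")
  meta <- ae_meta(model)
  params <- ae_init_params(model, train$seed)
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  step <- 0L
  imgs <- sample_matrices(samples, "image")
  msks <- lapply(samples, function(s) s$mask * 1.0)
  n <- length(imgs)
  set.seed(train$seed + 1L)
  history <- data.frame(epoch = integer(0), train_dice = numeric(0),
                        val_dice = numeric(0))
  for (epoch in seq_len(train$epochs)) {
    lr <- cosine_lr(epoch, train$epochs, train$lr_start, train$lr_end)
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
    dice_acc <- 0
    for (b in batches) {
      res <- ae_grad_batch_cpp(params, meta, imgs[b], msks[b], train$smooth)
      step <- step + 1L
      g <- res$grads
      for (nm in names(params)) {
        adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * g[[nm]]
        adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * g[[nm]]^2
        mh <- adam_m[[nm]] / (1 - 0.9^step)
        vh <- adam_v[[nm]] / (1 - 0.999^step)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
      }
      dice_acc <- dice_acc + res$dice * length(b)
    }
    train_dice <- dice_acc / n
    val_dice <- NA_real_
    if (!is.null(val) && length(val)) {
      vd <- vapply(val, function(s) {
        pr <- ae_forward_cpp(params, meta, s$image)$prob
        dice_coefficient(pr, s$mask, smooth = train$smooth)
      }, 0)
      val_dice <- mean(vd)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_dice = train_dice,
                                         val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train dice %.4f  val dice %s",
                      epoch, lr, train_dice,
                      ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
  }
  structure(list(params = params, config = model, train_config = train,
                 history = history,
                 n_parameters = dual_ae_dimensions(model)$n_parameters),
            class = "dual_ae")
}

#' Predict segmentation map and latent radiomics for an image
#'
#' One forward pass yields both outputs: the lesion probability map and the
#' bottleneck activation (the deep radiomic vector).
#'
#' @param object a fitted `dual_ae`.
#' @param newdata a matrix image matching the model input size, an
#'   `ultrasound_sample`, or a list of either.
#' @param ... unused.
#' @return for a single input, a list with `prob_map` and `latent`; for a
#'   list input, a list of such results.
#' @export
predict.dual_ae <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata) &&
      !inherits(newdata, "ultrasound_sample"))
    return(lapply(newdata, function(x) predict.dual_ae(object, x)))
  img <- if (inherits(newdata, "ultrasound_sample")) newdata$image else newdata
  if (!is.matrix(img) || !all(dim(img) == object$config$input_size))
    stop("predict.dual_ae: image does not match model input size ",
         object$config$input_size)
  out <- ae_forward_cpp(object$params, ae_meta(object$config), img)
  list(prob_map = out$prob, latent = as.numeric(out$latent))
}

#' Encoder-only forward pass (bottleneck activation)
#' @inheritParams predict.dual_ae
#' @param model a fitted `dual_ae`.
#' @param image matrix image or `ultrasound_sample`.
#' @return numeric latent vector of length `latent_dim`.
#' @export
encode <- function(model, image) {
  predict.dual_ae(model, image)$latent
}

#' Threshold a probability map into a binary mask
#' @param prob_map matrix of probabilities in \[0,1\].
#' @param threshold decision threshold; pixels with `prob >= threshold`
#'   become lesion.
#' @return integer 0/1 matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  (prob_map >= threshold) * 1L
}

#' Dice similarity coefficient with squared denominator terms
#'
#' `DSC = (2 * sum(p*g) + s) / (sum(p^2) + sum(g^2) + s)` where `s` is the
#' `smooth` constant.  With `smooth = 0` this is the raw similarity (the
#' empty-vs-empty case returns 1 by convention); the training loss uses
#' `smooth = 1` to keep gradients stable.
#'
#' @param p probability raster/vector, elementwise in \[0,1\].
#' @param g binary raster/vector of the same shape.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar in \[0,1\].
#' @export
dice_coefficient <- function(p, g, smooth = 0) {
  if (length(p) != length(g))
    stop("dice_coefficient: shape mismatch")
  if (any(p < 0 | p > 1)) stop("dice_coefficient: p outside [0,1]")
  if (!all(g %in% c(0, 1))) stop("dice_coefficient: g must be binary")
  num <- 2 * sum(p * g) + smooth
  den <- sum(p^2) + sum(g^2) + smooth
  if (den == 0) return(1) # both empty, raw convention
  num / den
}

#' Dice loss (1 - smoothed DSC); batch loss is the mean over samples
#' @inheritParams dice_coefficient
#' @export
dice_loss <- function(p, g, smooth = 1) {
  1 - dice_coefficient(p, g, smooth = smooth)
}

#' Select informative latent features
#'
#' Drops bottleneck columns that are exactly zero across all cases, then
#' keeps the `k` highest-variance remaining columns (ties broken toward
#' the lower column index).
#'
#' @param latent_matrix cases x latent_dim matrix.
#' @param k number of features to retain (default 4).
#' @return list with `indices` (ascending) and `reduced` matrix.
#' @export
filter_latent <- function(latent_matrix, k = 4L) {
  if (!is.matrix(latent_matrix) || nrow(latent_matrix) < 2L)
    stop("filter_latent: need a matrix with at least 2 rows")
  nonzero <- which(colSums(latent_matrix != 0) > 0)
  if (length(nonzero) < k) {
    warning("filter_latent: only ", length(nonzero),
            " nonzero columns; keeping all of them")
    idx <- nonzero
  } else {
    v <- apply(latent_matrix[, nonzero, drop = FALSE], 2, stats::var)
    # order by variance desc, ties by lower original index
    ord <- nonzero[order(-v, nonzero)]
    idx <- sort(ord[seq_len(k)])
  }
  list(indices = idx, reduced = latent_matrix[, idx, drop = FALSE])
}

#' @export
print.dual_ae <- function(x, ...) {
  d <- dual_ae_dimensions(x$config)
  cat("Dual-output convolutional autoencoder\n")
  cat(sprintf("  preset: %s  input: %dx%d  blocks: %d  latent: %d\n",
              x$config$preset, x$config$input_size, x$config$input_size,
              x$config$n_blocks, x$config$latent_dim))
  cat(sprintf("  flatten: %s  parameters: %s\n",
              format(d$flatten_size, big.mark = ","),
              format(x$n_parameters, big.mark = ",")))
  h <- x$history
  if (nrow(h))
    cat(sprintf("  trained %d epochs; final train Dice %.3f%s\n", nrow(h),
                h$train_dice[nrow(h)],
                if (!is.na(h$val_dice[nrow(h)]))
                  sprintf(", val Dice %.3f", h$val_dice[nrow(h)]) else ""))
  invisible(x)
}

#' @export
summary.dual_ae <- function(object, ...) {
  print(object)
  invisible(object$history)
}

#' Plot the training history (train/validation Dice per epoch)
#' @param x a fitted `dual_ae`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dual_ae <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_dice, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "Dice", ...)
  if (any(!is.na(h$val_dice)))
    graphics::lines(h$epoch, h$val_dice, lty = 2)
  graphics::legend("bottomright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(h)
}
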