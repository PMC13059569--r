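# Small residual CNN for two-class epigenetic-state classification.
#
# The default architecture ("9conv_1f") is a 9-convolution residual network:
# a 7x7 stride-2 stem followed by four residual blocks of two 3x3
# convolutions each, batch normalization after every convolution, and a
# single fully connected layer producing one logit. Shortcuts are
# parameter-free (identity, or stride-2 subsampling with zero-padded
# channels where the shape changes), keeping the convolution census at
# exactly nine. Variants add global average pooling ("9conv_gap_1f") or
# double the block count ("17conv_gap_1f").

#' Model specification
#'
#' @param architecture one of `"9conv_1f"` (default), `"9conv_gap_1f"`,
#'   `"17conv_gap_1f"`.
#' @param input_size input side length in px (default 600; the network is
#'   fully convolutional up to the FC layer, whose input dimension adapts).
#' @param width base channel count of the stem (doubled at each
#'   downsampling stage).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("9conv_1f", "9conv_gap_1f", "17conv_gap_1f"),
                       input_size = 600L, width = 8L) {
  architecture <- match.arg(architecture)
  layout <- switch(architecture,
    "9conv_1f"     = list(strides = c(1L, 2L, 2L, 2L), mult = c(1L, 2L, 4L, 8L), gap = FALSE),
    "9conv_gap_1f" = list(strides = c(1L, 2L, 2L, 2L), mult = c(1L, 2L, 4L, 8L), gap = TRUE),
    "17conv_gap_1f" = list(strides = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L),
                           mult = c(1L, 1L, 2L, 2L, 4L, 4L, 8L, 8L), gap = TRUE))
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 width = as.integer(width),
                 first_kernel = 7L,
                 strides = layout$strides, mult = layout$mult, gap = layout$gap,
                 n_conv = 1L + 2L * length(layout$strides)),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults follow the reference regimen: Adam, binary cross-entropy,
#' initial learning rate 1e-4 decayed (cosine) to 1e-6, batch size 128,
#' 300 epochs, stratified 80:20 train/validation split. All values scale
#' down for desk-scale experiments.
#'
#' @param lr_start,lr_end learning-rate schedule endpoints.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param split training fraction of the stratified split.
#' @param seed RNG seed controlling split, shuffling and initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr_start = 1e-4, lr_end = 1e-6, batch_size = 128L,
                         epochs = 300L, split = 0.8, seed = 1L) {
  stopifnot(lr_end <= lr_start, split > 0, split < 1)
  structure(list(lr_start = lr_start, lr_end = lr_end,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Duplicate a single-channel image into pseudo-RGB
#'
#' @param single_channel 2D numeric matrix.
#' @return H x W x 3 array with three identical planes.
#' @export
to_pseudo_rgb <- function(single_channel) {
  if (!is.matrix(single_channel))
    stop("to_pseudo_rgb: input is already multi-channel (expected a 2D matrix)")
  array(single_channel, dim = c(dim(single_channel), 3L))
}

# ---- layer primitives ------------------------------------------------------

bcast_ch <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

bn_forward <- function(x, p, s, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]; m <- d[1] * d[2] * d[4]
  if (training) {
    cm <- matrix(colMeans(matrix(x, d[1] * d[2], C * d[4])), C, d[4])
    mu <- rowMeans(cm)
    cm2 <- matrix(colMeans(matrix(x * x, d[1] * d[2], C * d[4])), C, d[4])
    var_ <- rowMeans(cm2) - mu^2
    s$rm <- (1 - momentum) * s$rm + momentum * mu
    s$rv <- (1 - momentum) * s$rv + momentum * var_ * m / max(1, m - 1)
  } else {
    mu <- s$rm; var_ <- s$rv
  }
  ivar <- 1 / sqrt(var_ + eps)
  xhat <- (x - bcast_ch(mu, d)) * bcast_ch(ivar, d)
  y <- xhat * bcast_ch(p$g, d) + bcast_ch(p$b, d)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, g = p$g, d = d), stats = s)
}

bn_backward <- function(dy, cache) {
  d <- cache$d; m <- d[1] * d[2] * d[4]; C <- d[3]
  per_ch_sum <- function(a) rowSums(matrix(colSums(matrix(a, d[1] * d[2], C * d[4])), C, d[4]))
  dg <- per_ch_sum(dy * cache$xhat)
  db <- per_ch_sum(dy)
  dxhat <- dy * bcast_ch(cache$g, d)
  s1 <- per_ch_sum(dxhat); s2 <- per_ch_sum(dxhat * cache$xhat)
  dx <- bcast_ch(cache$ivar / m, d) *
    (m * dxhat - bcast_ch(s1, d) - cache$xhat * bcast_ch(s2, d))
  list(dx = dx, dg = dg, db = db)
}

# parameter-free shortcut: identity, or stride-2 subsample + zero-pad channels
shortcut_forward <- function(x, cout, stride) {
  d <- dim(x)
  if (stride == 1L && d[3] == cout) return(x)
  xs <- x[seq(1, d[1], by = stride), seq(1, d[2], by = stride), , , drop = FALSE]
  ds <- dim(xs)
  if (ds[3] < cout) {
    out <- array(0, dim = c(ds[1], ds[2], cout, ds[4]))
    out[, , seq_len(ds[3]), ] <- xs
    out
  } else xs
}

shortcut_backward <- function(dy, din, cout, stride) {
  if (stride == 1L && din[3] == cout) return(dy)
  dx <- array(0, dim = din)
  dx[seq(1, din[1], by = stride), seq(1, din[2], by = stride), , ] <-
    dy[, , seq_len(din[3]), , drop = FALSE]
  dx
}

# ---- model construction ----------------------------------------------------

#' Build a residual classifier with deterministic initialization
#'
#' He-normal initialization for convolution weights, unit-gamma/zero-beta
#' batch norms, and a zero-initialized FC layer; identical `(spec, seed)`
#' give identical initial parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return object of class `nucleo_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    w <- spec$width
    params <- list(); stats <- list()
    he <- function(kh, kw, cin, cout)
      array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
            dim = c(kh, kw, cin, cout))
    add_conv <- function(name, kh, cin, cout) {
      params[[paste0(name, "_w")]] <<- he(kh, kh, cin, cout)
      params[[paste0(name, "_b")]] <<- numeric(cout)
      params[[paste0("bn_", name)]] <<- list(g = rep(1, cout), b = numeric(cout))
      stats[[paste0("bn_", name)]] <<- list(rm = numeric(cout), rv = rep(1, cout))
    }
    add_conv("conv1", spec$first_kernel, 3L, w)
    cin <- w
    for (i in seq_along(spec$strides)) {
      cout <- w * spec$mult[i]
      add_conv(sprintf("b%da", i), 3L, cin, cout)
      add_conv(sprintf("b%db", i), 3L, cout, cout)
      cin <- cout
    }
    sp <- spec$input_size
    sp <- (sp + 2 * 3 - 7) %/% 2 + 1
    for (s in spec$strides) if (s == 2L) sp <- (sp + 2 - 3) %/% 2 + 1
    fc_in <- if (spec$gap) cin else sp * sp * cin
    params$fc_w <- numeric(fc_in)
    params$fc_b <- 0
    structure(list(spec = spec, params = params, stats = stats,
                   fc_in = fc_in, final_spatial = sp, final_channels = cin,
                   input_scale = 1),
              class = "nucleo_model")
  })
}

#' @export
print.nucleo_model <- function(x, ...) {
  cat(sprintf("nucleo_model: %s, input %dx%dx3, %d conv + %d BN + 1 FC\n",
              x$spec$architecture, x$spec$input_size, x$spec$input_size,
              x$spec$n_conv, x$spec$n_conv))
  invisible(x)
}

#' Count layers of a built model
#' @param model a `nucleo_model`.
#' @return named integer vector with `conv`, `batch_norm`, `fc` counts.
#' @export
layer_census <- function(model) {
  p <- names(model$params)
  c(conv = sum(grepl("_w$", p) & !grepl("^fc", p)),
    batch_norm = sum(grepl("^bn_", p)),
    fc = 1L)
}

# forward pass; x is (H, W, 3, N); returns logits and optional caches or a
# captured post-ReLU stage activation ("conv1", "block1".."blockB", or
# "last_conv" for the final block)
nn_forward <- function(model, x, training = FALSE, capture = NULL) {
  p <- model$params; st <- model$stats; spec <- model$spec
  caches <- if (training) list() else NULL
  captured <- NULL
  nb <- length(spec$strides)
  if (identical(capture, "last_conv")) capture <- paste0("block", nb)

  run_bn <- function(name, z) {
    r <- bn_forward(z, p[[paste0("bn_", name)]], st[[paste0("bn_", name)]], training)
    if (training) { caches[[paste0("bn_", name)]] <<- r$cache; st[[paste0("bn_", name)]] <<- r$stats }
    r$y
  }
  z <- .conv_fwd(x, p$conv1_w, p$conv1_b, 2L, 3L)
  if (training) caches$x <- x
  a <- run_bn("conv1", z)
  t_ <- a * (a > 0)
  if (training) caches$conv1 <- list(a = a)
  if (identical(capture, "conv1")) captured <- t_

  for (i in seq_len(nb)) {
    na <- sprintf("b%da", i); nbm <- sprintf("b%db", i)
    stride <- spec$strides[i]; cout <- dim(p[[paste0(na, "_w")]])[4]
    za <- .conv_fwd(t_, p[[paste0(na, "_w")]], p[[paste0(na, "_b")]], stride, 1L)
    aa <- run_bn(na, za)
    ra <- aa * (aa > 0)
    zb <- .conv_fwd(ra, p[[paste0(nbm, "_w")]], p[[paste0(nbm, "_b")]], 1L, 1L)
    ab <- run_bn(nbm, zb)
    sc <- shortcut_forward(t_, cout, stride)
    sum_ <- ab + sc
    out <- sum_ * (sum_ > 0)
    if (training)
      caches[[paste0("block", i)]] <- list(tin = t_, aa = aa, ra = ra,
                                           sum = sum_, stride = stride, cout = cout)
    t_ <- out
    if (identical(capture, paste0("block", i))) captured <- t_
  }

  d <- dim(t_)
  if (spec$gap) {
    feat <- matrix(colMeans(matrix(t_, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  } else {
    feat <- matrix(t_, d[1] * d[2] * d[3], d[4])
  }
  logits <- as.vector(crossprod(feat, p$fc_w)) + p$fc_b
  if (training) { caches$feat <- feat; caches$final_dim <- d }
  list(logits = logits, caches = caches, stats = st, captured = captured)
}

nn_backward <- function(model, fwd, dlogits) {
  p <- model$params; spec <- model$spec
  caches <- fwd$caches
  grads <- list()
  d <- caches$final_dim
  grads$fc_w <- as.vector(caches$feat %*% dlogits)
  grads$fc_b <- sum(dlogits)
  if (spec$gap) {
    dfeat <- outer(p$fc_w, dlogits)                       # C x N
    dt <- array(rep(dfeat, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  } else {
    dt <- array(outer(p$fc_w, dlogits), dim = d)
  }
  nb <- length(spec$strides)
  for (i in rev(seq_len(nb))) {
    cb <- caches[[paste0("block", i)]]
    na <- sprintf("b%da", i); nbm <- sprintf("b%db", i)
    dsum <- dt * (cb$sum > 0)
    dsc <- shortcut_backward(dsum, dim(cb$tin), cb$cout, cb$stride)
    bb <- bn_backward(dsum, caches[[paste0("bn_", nbm)]])
    grads[[paste0("bn_", nbm)]] <- list(g = bb$dg, b = bb$db)
    cvb <- .conv_bwd(cb$ra, p[[paste0(nbm, "_w")]], bb$dx, 1L, 1L)
    grads[[paste0(nbm, "_w")]] <- cvb$dw; grads[[paste0(nbm, "_b")]] <- cvb$db
    dra <- cvb$dx * (cb$aa > 0)
    ba <- bn_backward(dra, caches[[paste0("bn_", na)]])
    grads[[paste0("bn_", na)]] <- list(g = ba$dg, b = ba$db)
    cva <- .conv_bwd(cb$tin, p[[paste0(na, "_w")]], ba$dx, cb$stride, 1L)
    grads[[paste0(na, "_w")]] <- cva$dw; grads[[paste0(na, "_b")]] <- cva$db
    dt <- cva$dx + dsc
  }
  dt <- dt * (caches$conv1$a > 0)
  b1 <- bn_backward(dt, caches$bn_conv1)
  grads$bn_conv1 <- list(g = b1$dg, b = b1$db)
  cv1 <- .conv_bwd(caches$x, p$conv1_w, b1$dx, 2L, 3L)
  grads$conv1_w <- cv1$dw; grads$conv1_b <- cv1$db
  grads
}

# ---- training --------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_with_logits <- function(logits, y) {
  # stable softplus
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  list(loss = mean(sp - y * logits), dlogits = (sigmoid(logits) - y) / length(y))
}

adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(upd, p, g, m, v)
      return(list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
                  v = lapply(r, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t); vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in names(params)) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# assemble a (H, W, 3, B) batch from a list of images (2D -> pseudo-RGB)
assemble_batch <- function(images, scale = 1) {
  xs <- lapply(images, function(m) if (is.matrix(m)) to_pseudo_rgb(m) else m)
  d <- dim(xs[[1]])
  x <- array(0, dim = c(d[1], d[2], 3L, length(xs)))
  for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
  x / scale
}

#' Train the classifier and evaluate on a held-out split
#'
#' Stratified 80:20 (configurable) split, Adam with binary cross-entropy on
#' a single sigmoid logit, cosine learning-rate decay from `lr_start` to
#' `lr_end` over the configured epochs. Inputs are scaled by the maximum
#' intensity of the training set (stored in the model for inference).
#'
#' @param dataset list of elements with `x` (H x W matrix or H x W x 3
#'   array) and `label` (0/1).
#' @param spec a [model_spec()] matching the image size.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return list with `model`, `report` (class `eval_report`: accuracy,
#'   precision, auc, confusion counts) and `history` (per-epoch mean loss).
#' @export
train_and_evaluate <- function(dataset, spec, cfg = train_config(), verbose = FALSE) {
  labels <- vapply(dataset, function(d) as.integer(d$label), 1L)
  if (length(unique(labels)) < 2)
    stop("train_and_evaluate: dataset must contain two classes")
  with_seed(cfg$seed, {
    idx0 <- which(labels == 0L); idx1 <- which(labels == 1L)
    tr <- c(sample(idx0, round(cfg$split * length(idx0))),
            sample(idx1, round(cfg$split * length(idx1))))
    va <- setdiff(seq_along(dataset), tr)
    model <- build_model(spec, seed = sample.int(1e6, 1))
    model$input_scale <- max(1e-12, max(vapply(dataset[tr], function(d) max(d$x), 1)))
    opt <- adam_init(model$params)
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$lr_end + (cfg$lr_start - cfg$lr_end) *
        (1 + cos(pi * (ep - 1) / max(1, cfg$epochs - 1))) / 2
      ord <- sample(tr)
      losses <- c()
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        x <- assemble_batch(lapply(dataset[bi], `[[`, "x"), model$input_scale)
        y <- labels[bi]
        fwd <- nn_forward(model, x, training = TRUE)
        model$stats <- fwd$stats
        lo <- bce_with_logits(fwd$logits, y)
        grads <- nn_backward(model, fwd, lo$dlogits)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params; opt <- st$state
        losses <- c(losses, lo$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f  lr %.2e",
                                   ep, cfg$epochs, history[ep], lr))
    }
    probs <- predict_model(model, lapply(dataset[va], `[[`, "x"))
    report <- eval_report(labels[va], probs)
    list(model = model, report = report, history = history,
         train_idx = tr, val_idx = va)
  })
}

#' Predict class-1 probabilities for a list of images
#' @param model a trained `nucleo_model`.
#' @param images list of H x W matrices or H x W x 3 arrays.
#' @param batch_size forward-pass batch size.
#' @return numeric vector of probabilities.
#' @export
predict_model <- function(model, images, batch_size = 32L) {
  out <- numeric(length(images))
  for (b0 in seq(1, length(images), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1, length(images))
    x <- assemble_batch(images[bi], model$input_scale)
    out[bi] <- sigmoid(nn_forward(model, x)$logits)
  }
  out
}

#' Evaluation report from labels and predicted probabilities
#' @param labels true 0/1 labels.
#' @param probs predicted class-1 probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `eval_report`.
#' @export
eval_report <- function(labels, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 > 0 && n0 > 0)
    (sum(rank(probs)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  else NA_real_
  structure(list(accuracy = acc, precision = prec, auc = auc,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f, precision %s, AUC %.3f (tp %d fp %d tn %d fn %d)\n",
              x$accuracy, ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              x$auc, x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}
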