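# Optic-disc localizer: a U-Net variant whose convolutions are
# depthwise-separable, whose encoder/decoder stages are recurrent-residual
# blocks, and whose skip connections pass through additive attention gates.
# Trained with soft Dice loss and RMSprop.

# --- functional layer ops (plain arrays in, plain arrays out) -----------------

#' Depthwise-separable convolution
#'
#' Applies one k x k spatial kernel per input channel (`O_i = K_i (*) I_i`),
#' then mixes channels with a pointwise 1x1 convolution. Same padding,
#' stride 1, so spatial dimensions are preserved.
#'
#' @param input feature map, array (row, col, channel)
#' @param depthwise_kernels array (kh, kw, channels) - one kernel per channel
#' @param pointwise_weights channel-mixing weights: matrix (C_in x C_out) or
#'   array (1, 1, C_in, C_out)
#' @param depthwise_bias,pointwise_bias optional biases (default zero)
#' @return feature map array (row, col, C_out)
#' @export
depthwise_separable_conv <- function(input, depthwise_kernels, pointwise_weights,
                                     depthwise_bias = NULL, pointwise_bias = NULL) {
  if (length(dim(input)) != 3) stop_contract("input must be (row, col, channel)")
  C <- dim(input)[3]
  if (dim(depthwise_kernels)[3] != C)
    stop_contract("need one depthwise kernel per input channel (%d != %d)",
                  dim(depthwise_kernels)[3], C)
  pw <- as_pointwise(pointwise_weights)
  if (dim(pw)[3] != C) stop_contract("pointwise weights expect %d channels, input has %d",
                                     dim(pw)[3], C)
  db <- depthwise_bias %||% numeric(C)
  pb <- pointwise_bias %||% numeric(dim(pw)[4])
  y <- .cpp_dwconv2d_fwd(input, depthwise_kernels, db)
  .cpp_conv2d_fwd(y, pw, pb)
}

# accept (Cin x Cout) matrix or (1,1,Cin,Cout) array for 1x1 mixing weights
as_pointwise <- function(w) {
  if (is.matrix(w)) array(w, dim = c(1, 1, nrow(w), ncol(w)))
  else if (length(dim(w)) == 4 && dim(w)[1] == 1 && dim(w)[2] == 1) w
  else stop_contract("pointwise weights must be (Cin x Cout) or (1,1,Cin,Cout)")
}

#' Additive attention gate
#'
#' Computes a per-pixel attention coefficient
#' `alpha = sigmoid(psi(ReLU(W_u u + W_g g + b_g)) + b_psi)` (one channel)
#' and returns `alpha * u_l` broadcast over channels. If the gating signal is
#' at half resolution it is upsampled (nearest-neighbour) first.
#'
#' @param u_l skip-connection feature map (row, col, C_u)
#' @param g_l gating feature map, same grid as `u_l` or one level coarser
#' @param params list with `W_u`, `W_g` (1x1 channel-mixing weights to a
#'   common intermediate width), `b_g` (intermediate bias), `psi` (1x1
#'   projection to one channel) and `b_psi` (scalar bias)
#' @return list with `output` (gated feature map) and `alpha` (row, col, 1)
#' @export
attention_gate <- function(u_l, g_l, params) {
  psi <- params$psi
  if (is.null(dim(psi)) || length(dim(psi)) != 4)
    psi <- array(psi, dim = c(1, 1, length(psi), 1))
  params <- list(W_u = as_pointwise(params$W_u), W_g = as_pointwise(params$W_g),
                 b_g = params$b_g, psi = psi, b_psi = params$b_psi)
  r <- attention_gate_nodes(as_node(u_l), as_node(g_l),
                            lapply(params, as_node))
  list(output = r$output$value, alpha = r$alpha$value)
}

# params must already be nodes holding (1,1,Cin,Cout)-shaped weights
attention_gate_nodes <- function(u, g, params) {
  du <- dim(u$value); dg <- dim(g$value)
  if (all(dg[1:2] * 2L == du[1:2])) g <- ad_upsample2(g)
  else if (!all(dg[1:2] == du[1:2]))
    stop_contract("gating signal %dx%d cannot be aligned to %dx%d",
                  dg[1], dg[2], du[1], du[2])
  cint <- dim(params$W_u$value)[4]
  q <- ad_relu(ad_add(ad_conv2d(u, params$W_u, numeric(cint)),
                      ad_conv2d(g, params$W_g, params$b_g)))
  alpha <- ad_sigmoid(ad_conv2d(q, params$psi, params$b_psi))
  list(output = ad_mul_bcast_channel(alpha, u), alpha = alpha)
}

#' Recurrent-residual block
#'
#' One depthwise-separable convolution layer `g` (+ReLU) applied recurrently
#' with shared weights: `z0 = g(x)`, `zs = g(x + z(s-1))` for `s = 1..t`, and
#' a residual output `x' + zt`. When the block changes the channel width, `x`
#' is first projected by a 1x1 convolution (`params$proj`) and the recurrence
#' runs at the output width; with matching widths the projection is the
#' identity and the formula applies to `x` literally.
#'
#' @param x feature map (row, col, channel)
#' @param params list with `dw` (depthwise kernels), `dw_b`, `pw` (pointwise
#'   weights), `pw_b`, and optionally `proj = list(w, b)`
#' @param t number of recurrent applications (t = 0 gives plain conv + residual)
#' @return feature map array
#' @export
recurrent_residual_block <- function(x, params, t = 1L) {
  params$pw <- as_pointwise(params$pw)
  C <- dim(params$pw)[3]
  params$dw_b <- params$dw_b %||% numeric(C)
  params$pw_b <- params$pw_b %||% numeric(dim(params$pw)[4])
  if (!is.null(params$proj)) params$proj$w <- as_pointwise(params$proj$w)
  params <- rapply(params, as_node, how = "replace",
                   classes = c("numeric", "array", "matrix", "integer"))
  rr_nodes(as_node(x), params, t)$value
}

# params must already be nodes with pointwise weights in (1,1,Cin,Cout) form
rr_nodes <- function(x, params, t, norm = NULL) {
  xp <- if (!is.null(params$proj))
    ad_conv2d(x, params$proj$w, params$proj$b)
  else x
  g <- function(inp) {
    h <- ad_dwconv2d(inp, params$dw, params$dw_b)
    h <- ad_conv2d(h, params$pw, params$pw_b)
    if (!is.null(norm)) h <- norm(h)
    ad_relu(h)
  }
  z <- g(xp)
  s <- 0L
  while (s < t) {
    z <- g(ad_add(xp, z))
    s <- s + 1L
  }
  ad_add(xp, z)
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`; symmetric in its
#' arguments and bounded in \[0,1\].
#'
#' @param pred probability grid in \[0,1\]
#' @param target binary mask of the same shape
#' @param eps smoothing constant
#' @return scalar loss
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) &&
      !identical(length(pred), length(target)))
    stop_contract("pred and target shapes differ")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# --- model --------------------------------------------------------------------

#' Localizer configuration
#'
#' Training-protocol defaults (learning rate 0.003, batch size 6, 100 epochs,
#' RMSprop, Dice loss) follow the published protocol; the architectural
#' defaults (`depth`, `base_filters`) are desk-scale choices, configurable up
#' to the full-scale model.
#'
#' @param depth number of resolution levels (>= 2)
#' @param base_filters channels at the first level, doubled per level
#' @param recurrence_steps recurrent applications `t` in each block
#' @param input_size square network input resolution in pixels
#' @param in_channels input channels (1 = grayscale, 3 = RGB)
#' @param learning_rate RMSprop learning rate
#' @param batch_size training batch size
#' @param epochs training epochs
#' @param seed integer seed for initialization and training
#' @return a `localizer_config`
#' @export
localizer_config <- function(depth = 3, base_filters = 8, recurrence_steps = 1,
                             input_size = 64, in_channels = 1,
                             learning_rate = 0.003, batch_size = 6,
                             epochs = 15, seed = 1L) {
  if (depth < 2) stop_data("depth must be >= 2")
  if (recurrence_steps < 0) stop_data("recurrence_steps must be >= 0")
  if (learning_rate <= 0) stop_data("learning_rate must be positive")
  if (input_size %% 2^(depth - 1) != 0)
    stop_data("input_size %d is not divisible by 2^(depth-1) = %d",
              input_size, 2^(depth - 1))
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 recurrence_steps = as.integer(recurrence_steps),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "localizer_config")
}

make_rr_params <- function(store, pfx, cin, cout, k = 3L) {
  if (cin != cout) {
    make_param(store, paste0(pfx, ".proj.w"), c(1, 1, cin, cout), fan_in = cin)
    make_param(store, paste0(pfx, ".proj.b"), cout, value = numeric(cout))
  }
  make_param(store, paste0(pfx, ".dw.w"), c(k, k, cout), fan_in = k * k)
  make_param(store, paste0(pfx, ".dw.b"), cout, value = numeric(cout))
  make_param(store, paste0(pfx, ".pw.w"), c(1, 1, cout, cout), fan_in = cout)
  make_param(store, paste0(pfx, ".pw.b"), cout, value = numeric(cout))
  make_norm_params(store, paste0(pfx, ".norm"), cout)
}

rr_forward <- function(store, pfx, x, t) {
  gp <- function(nm) get(paste0(pfx, ".", nm), envir = store)
  params <- list(dw = gp("dw.w"), dw_b = gp("dw.b"),
                 pw = gp("pw.w"), pw_b = gp("pw.b"))
  if (exists(paste0(pfx, ".proj.w"), envir = store))
    params$proj <- list(w = gp("proj.w"), b = gp("proj.b"))
  rr_nodes(x, params, t, norm = function(h) norm_fw(store, paste0(pfx, ".norm"), h))
}

make_gate_params <- function(store, pfx, cu, cg) {
  cint <- max(cu %/% 2L, 1L)
  make_param(store, paste0(pfx, ".wu"), c(1, 1, cu, cint), fan_in = cu)
  make_param(store, paste0(pfx, ".wg"), c(1, 1, cg, cint), fan_in = cg)
  make_param(store, paste0(pfx, ".bg"), cint, value = numeric(cint))
  make_param(store, paste0(pfx, ".psi"), c(1, 1, cint, 1), fan_in = cint)
  make_param(store, paste0(pfx, ".bpsi"), 1, value = 0)
}

gate_forward <- function(store, pfx, u, g) {
  gp <- function(nm) get(paste0(pfx, ".", nm), envir = store)
  attention_gate_nodes(u, g, list(W_u = gp("wu"), W_g = gp("wg"), b_g = gp("bg"),
                                  psi = gp("psi"), b_psi = gp("bpsi")))$output
}

#' Build the optic-disc localizer model
#'
#' Encoder of `depth` recurrent-residual stages with 2x2 max pooling between,
#' a mirrored decoder (nearest-neighbour upsampling + 1x1 channel-halving
#' convolution), attention-gated skip concatenations, and a 1x1 convolution +
#' sigmoid head producing a one-channel probability map at full input
#' resolution.
#'
#' @param config a [localizer_config()]
#' @return an object of class `svpnet_localizer`
#' @export
build_localizer <- function(config) {
  stopifnot(inherits(config, "localizer_config"))
  D <- config$depth; F0 <- config$base_filters; tr <- config$recurrence_steps
  store <- new_param_store()
  with_seed(config$seed, {
    cin <- config$in_channels
    for (i in seq_len(D)) {
      make_rr_params(store, paste0("enc", i), cin, F0 * 2^(i - 1))
      cin <- F0 * 2^(i - 1)
    }
    for (i in seq.int(D - 1, 1)) {
      cdeep <- F0 * 2^i; chalf <- F0 * 2^(i - 1)
      make_param(store, paste0("up", i, ".w"), c(1, 1, cdeep, chalf), fan_in = cdeep)
      make_param(store, paste0("up", i, ".b"), chalf, value = numeric(chalf))
      make_gate_params(store, paste0("att", i), chalf, chalf)
      make_rr_params(store, paste0("dec", i), 2 * chalf, chalf)
    }
    make_param(store, "head.w", c(1, 1, F0, 1), fan_in = F0)
    make_param(store, "head.b", 1, value = 0)
  })
  forward <- function(x, training = FALSE) {
    x <- as_node(x)
    enc <- vector("list", D)
    cur <- x
    for (i in seq_len(D)) {
      cur <- rr_forward(store, paste0("enc", i), cur, tr)
      enc[[i]] <- cur
      if (i < D) cur <- ad_maxpool2d(cur)
    }
    dec <- enc[[D]]
    for (i in seq.int(D - 1, 1)) {
      up <- ad_conv2d(ad_upsample2(dec),
                      get(paste0("up", i, ".w"), envir = store),
                      get(paste0("up", i, ".b"), envir = store))
      gated <- gate_forward(store, paste0("att", i), enc[[i]], up)
      dec <- rr_forward(store, paste0("dec", i), ad_concat_c(gated, up), tr)
    }
    ad_sigmoid(ad_conv2d(dec, get("head.w", envir = store),
                         get("head.b", envir = store)))
  }
  structure(list(config = config, store = store, forward = forward),
            class = "svpnet_localizer")
}

#' @export
print.svpnet_localizer <- function(x, ...) {
  np <- sum(vapply(param_list(x$store), function(p) length(p$value), 0))
  cat(sprintf("<svpnet_localizer> depth %d, base filters %d, input %dx%d, %d parameters\n",
              x$config$depth, x$config$base_filters, x$config$input_size,
              x$config$input_size, np))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' @param model a localizer or classifier model
#' @return integer parameter count
#' @export
count_params <- function(model) {
  sum(vapply(param_list(model$store), function(p) length(p$value), 0))
}

# frame (matrix or (H,W,C) array) -> (size,size,in_channels) network input
prepare_localizer_input <- function(frame, config) {
  if (is.matrix(frame)) frame <- array(frame, dim = c(dim(frame), 1))
  C <- dim(frame)[3]
  if (C == 3 && config$in_channels == 1) {
    lum <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    frame <- array(lum, dim = c(dim(lum), 1))
    C <- 1
  }
  if (C != config$in_channels)
    stop_contract("frame has %d channels, model expects %d", C, config$in_channels)
  s <- config$input_size
  out <- array(0, dim = c(s, s, C))
  for (c in seq_len(C)) out[, , c] <- resize_bilinear(frame[, , c], s, s)
  out
}

#' Predict the disc probability map for one frame
#'
#' @param model an `svpnet_localizer`
#' @param frame grayscale matrix or (row, col, channel) array in \[0,1\]
#' @return probability matrix at the original frame resolution
#' @export
predict_prob <- function(model, frame) {
  if (is.matrix(frame)) od <- dim(frame) else od <- dim(frame)[1:2]
  x <- prepare_localizer_input(frame, model$config)
  p <- model$forward(x)$value[, , 1]
  resize_bilinear(p, od[1], od[2])
}

#' Predict a binary optic-disc mask for one frame
#'
#' The frame is resized to the network input size, passed through the model,
#' thresholded at 0.5 (ties count as foreground: the rule is `>= 0.5`), and
#' the mask is mapped back to the original resolution by nearest neighbour.
#'
#' @param model an `svpnet_localizer`
#' @param frame grayscale matrix or (row, col, channel) array in \[0,1\]
#' @return binary matrix of the frame's original size
#' @export
predict_mask <- function(model, frame) {
  if (!(is.matrix(frame) || length(dim(frame)) == 3))
    stop_contract("frame must be 2-D (or 2-D with channels)")
  if (is.matrix(frame)) od <- dim(frame) else od <- dim(frame)[1:2]
  x <- prepare_localizer_input(frame, model$config)
  p <- model$forward(x)$value[, , 1]
  m <- (p >= 0.5) + 0
  resize_nearest(m, od[1], od[2])
}

#' Train the optic-disc localizer
#'
#' Shuffles with the config seed, splits 75/20/5 (floor rounding, remainder
#' to training), optimizes the soft Dice loss with RMSprop, and keeps the
#' parameters of the epoch with the best validation loss.
#'
#' @param data list of `labeled_image` objects (see [make_disc_image()])
#' @param config a [localizer_config()]
#' @return list with `model`, `history` (per-epoch train/validation loss) and
#'   `split` (train/validation/test indices)
#' @export
train_localizer <- function(data, config) {
  n <- length(data)
  n_val <- floor(0.20 * n); n_test <- floor(0.05 * n)
  n_train <- n - n_val - n_test
  if (n_train <= 0 || n_val <= 0)
    stop_data("too few images (%d) to form non-empty train/validation splits", n)
  if (n_train < config$batch_size)
    stop_data("need at least batch_size = %d training samples, have %d",
              config$batch_size, n_train)
  s <- config$input_size
  xs <- lapply(data, function(d) prepare_localizer_input(d$frame, config))
  ys <- lapply(data, function(d) resize_nearest(d$mask, s, s))
  model <- build_localizer(config)
  params <- param_list(model$store)
  res <- with_seed(config$seed + 1L, {
    idx <- sample.int(n)
    tr_i <- idx[seq_len(n_train)]
    va_i <- idx[n_train + seq_len(n_val)]
    te_i <- if (n_test > 0) idx[n_train + n_val + seq_len(n_test)] else integer(0)
    opt <- make_optimizer("rmsprop", params, lr = config$learning_rate)
    loss_fn <- function(i) {
      k <- tr_i[i]
      ad_dice_loss_node(model$forward(xs[[k]], training = TRUE), ys[[k]])
    }
    best <- Inf; best_snap <- NULL
    eval_fn <- function() {
      v <- mean(vapply(va_i, function(k)
        dice_loss(model$forward(xs[[k]])$value[, , 1], ys[[k]]), 0))
      if (v < best) { best <<- v; best_snap <<- deep_copy_params(params) }
      v
    }
    hist <- sgd_train(params, loss_fn, length(tr_i), config$epochs,
                      config$batch_size, opt, eval_fn = eval_fn)
    if (!is.null(best_snap)) restore_params(params, best_snap)
    list(history = hist,
         split = list(train = tr_i, validation = va_i, test = te_i))
  })
  list(model = model, history = res$history, split = res$split)
}
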