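# SVP video classifiers: 3D Inception, 3D Dense-ResNet, 3D ResNet, LRCN and
# ConvLSTM, sharing one input contract (30 frames x 64 x 64 x 1 channel) and
# a two-class softmax head. The ConvLSTM cell implements the peephole
# formulation in which the output gate peeks at the *current* cell state; a
# switch restores the conventional previous-state variant.

SVP_CLASSES <- c("absent", "present")

#' Classifier configuration
#'
#' Learning-rate defaults per architecture (0.0003, 0.0028, 0.002, 0.0029,
#' 0.004 for inception3d, dense_resnet3d, resnet3d, lrcn, convlstm), batch
#' size 30, 100 epochs and the Adam optimizer follow the published training
#' characteristics. The `"small"` preset shrinks widths and resolution for
#' desk-scale training; `"paper"` keeps full-scale widths.
#'
#' @param architecture one of `"inception3d"`, `"dense_resnet3d"`,
#'   `"resnet3d"`, `"lrcn"`, `"convlstm"`
#' @param preset `"small"` or `"paper"`
#' @param batch_size samples per gradient update
#' @param epochs training epochs
#' @param learning_rate Adam learning rate (default per architecture)
#' @param optimizer `"adam"` (default) or `"rmsprop"`
#' @param dropout dropout fraction on dense/conv stacks
#' @param peephole_on_previous use `C_{t-1}` rather than `C_t` in the
#'   ConvLSTM output-gate peephole
#' @param seed integer seed
#' @return a `classifier_config`
#' @export
classifier_config <- function(architecture = c("convlstm", "inception3d",
                                               "dense_resnet3d", "resnet3d",
                                               "lrcn"),
                              preset = c("small", "paper"),
                              batch_size = 30, epochs = 100,
                              learning_rate = NULL, optimizer = "adam",
                              dropout = NULL, peephole_on_previous = FALSE,
                              seed = 1L) {
  architecture <- match.arg(architecture)
  preset <- match.arg(preset)
  if (is.null(learning_rate))
    learning_rate <- switch(architecture, inception3d = 0.0003,
                            dense_resnet3d = 0.0028, resnet3d = 0.002,
                            lrcn = 0.0029, convlstm = 0.004)
  if (is.null(dropout)) dropout <- if (preset == "paper") 0.5 else 0
  if (learning_rate <= 0) stop_data("learning_rate must be positive")
  if (batch_size < 1) stop_data("batch_size must be >= 1")
  structure(list(architecture = architecture, preset = preset,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 dropout = dropout, peephole_on_previous = peephole_on_previous,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# ------------------------------------------------------------ ConvLSTM cell ----

#' One ConvLSTM cell step
#'
#' Gates are computed with same-padded convolutions and elementwise peephole
#' weights:
#' \deqn{f_t = \sigma(W_{Xf}*X_t + W_{Hf}*H_{t-1} + W_{cf} \odot C_{t-1} + b_f)}
#' \deqn{i_t = \sigma(W_{Xi}*X_t + W_{Hi}*H_{t-1} + W_{ci} \odot C_{t-1} + b_{Hi})}
#' \deqn{g_t = \tanh(W_{Xg}*X_t + W_{Hg}*H_{t-1} + b_{hg})}
#' \deqn{C_t = f_t \odot C_{t-1} + i_t \odot g_t}
#' \deqn{O_t = \sigma(W_{Xo}*X_t + W_{Ho}*H_{t-1} + W_{Co} \odot C_t + b_{ho})}
#' \deqn{H_t = O_t \odot \tanh(C_t)}
#' Note the output gate peeks at the current cell state \eqn{C_t}; set
#' `peephole_on_previous = TRUE` for the conventional \eqn{C_{t-1}} variant.
#'
#' @param x_t input feature map (row, col, C_in)
#' @param state list with `H` and `C`, arrays (row, col, C_hidden)
#' @param w list of weights: convolution kernels `W_Xf`, `W_Hf`, `W_Xi`,
#'   `W_Hi`, `W_Xg`, `W_Hg`, `W_Xo`, `W_Ho` (shape (k, k, C, C_hidden));
#'   elementwise peephole weights `W_cf`, `W_ci`, `W_Co` (state-shaped);
#'   biases `b_f`, `b_Hi`, `b_hg`, `b_ho` (length C_hidden)
#' @param peephole_on_previous see above
#' @return list with the new `H` and `C`
#' @export
convlstm_step <- function(x_t, state, w, peephole_on_previous = FALSE) {
  wn <- rapply(w, as_node, how = "replace",
               classes = c("numeric", "array", "matrix", "integer"))
  st <- convlstm_step_nodes(as_node(x_t),
                            list(H = as_node(state$H), C = as_node(state$C)),
                            wn, peephole_on_previous)
  list(H = st$H$value, C = st$C$value)
}

convlstm_step_nodes <- function(x, state, w, peephole_on_previous = FALSE) {
  gate_pre <- function(wx, wh, b) ad_add(ad_conv2d(x, wx, b),
                                         ad_conv2d(state$H, wh,
                                                   numeric(length(ad_value(b)))))
  f <- ad_sigmoid(ad_add(gate_pre(w$W_Xf, w$W_Hf, w$b_f),
                         ad_mul(w$W_cf, state$C)))
  i <- ad_sigmoid(ad_add(gate_pre(w$W_Xi, w$W_Hi, w$b_Hi),
                         ad_mul(w$W_ci, state$C)))
  g <- ad_tanh(gate_pre(w$W_Xg, w$W_Hg, w$b_hg))
  Cn <- ad_add(ad_mul(f, state$C), ad_mul(i, g))
  peek <- if (peephole_on_previous) state$C else Cn
  o <- ad_sigmoid(ad_add(gate_pre(w$W_Xo, w$W_Ho, w$b_ho),
                         ad_mul(w$W_Co, peek)))
  list(H = ad_mul(o, ad_tanh(Cn)), C = Cn)
}

make_convlstm_params <- function(store, pfx, cin, chid, hs, ws, k = 3L) {
  for (nm in c("W_Xf", "W_Xi", "W_Xg", "W_Xo"))
    make_param(store, paste0(pfx, ".", nm), c(k, k, cin, chid), fan_in = k * k * cin)
  for (nm in c("W_Hf", "W_Hi", "W_Hg", "W_Ho"))
    make_param(store, paste0(pfx, ".", nm), c(k, k, chid, chid), fan_in = k * k * chid)
  for (nm in c("W_cf", "W_ci", "W_Co"))
    make_param(store, paste0(pfx, ".", nm), c(hs, ws, chid), value = array(0, c(hs, ws, chid)))
  make_param(store, paste0(pfx, ".b_f"), chid, value = rep(1, chid))  # open forget gate
  for (nm in c("b_Hi", "b_hg", "b_ho"))
    make_param(store, paste0(pfx, ".", nm), chid, value = numeric(chid))
}

convlstm_layer_forward <- function(store, pfx, x, chid, peephole_on_previous) {
  gp <- function(nm) get(paste0(pfx, ".", nm), envir = store)
  w <- setNames(lapply(c("W_Xf", "W_Hf", "W_Xi", "W_Hi", "W_Xg", "W_Hg",
                         "W_Xo", "W_Ho", "W_cf", "W_ci", "W_Co",
                         "b_f", "b_Hi", "b_hg", "b_ho"), gp),
                c("W_Xf", "W_Hf", "W_Xi", "W_Hi", "W_Xg", "W_Hg",
                  "W_Xo", "W_Ho", "W_cf", "W_ci", "W_Co",
                  "b_f", "b_Hi", "b_hg", "b_ho"))
  d <- dim(x$value)
  zero <- array(0, dim = c(d[2], d[3], chid))
  state <- list(H = as_node(zero), C = as_node(zero))
  hs <- vector("list", d[1])
  for (t in seq_len(d[1])) {
    state <- convlstm_step_nodes(ad_frame(x, t), state, w, peephole_on_previous)
    hs[[t]] <- state$H
  }
  ad_stack_frames(hs)
}

# -------------------------------------------------- shared building helpers ----

make_conv3d_params <- function(store, pfx, cin, cout, k = c(3L, 3L, 3L)) {
  make_param(store, paste0(pfx, ".w"), c(k, cin, cout), fan_in = prod(k) * cin)
  make_param(store, paste0(pfx, ".b"), cout, value = numeric(cout))
}

make_norm_params <- function(store, pfx, c) {
  make_param(store, paste0(pfx, ".g"), c, value = rep(1, c))
  make_param(store, paste0(pfx, ".b"), c, value = numeric(c))
}

conv3d_fw <- function(store, pfx, x)
  ad_conv3d(x, get(paste0(pfx, ".w"), envir = store),
            get(paste0(pfx, ".b"), envir = store))

# normalization over the sample's own extent (instance normalization): batch
# statistics are unavailable with sample-at-a-time training
norm_fw <- function(store, pfx, x)
  ad_norm_channels(x, get(paste0(pfx, ".g"), envir = store),
                   get(paste0(pfx, ".b"), envir = store))

cnr3d <- function(store, pfx, x) ad_relu(norm_fw(store, paste0(pfx, ".n"),
                                                 conv3d_fw(store, pfx, x)))

make_dense_params <- function(store, pfx, cin, cout) {
  make_param(store, paste0(pfx, ".w"), c(cout, cin), fan_in = cin)
  make_param(store, paste0(pfx, ".b"), cout, value = numeric(cout))
}

dense_fw <- function(store, pfx, x)
  ad_dense(x, get(paste0(pfx, ".w"), envir = store),
           get(paste0(pfx, ".b"), envir = store))

# residual block of two 3x3x3 convs (with channel-matching 1x1x1 projection)
make_resblock3d_params <- function(store, pfx, cin, cout) {
  make_conv3d_params(store, paste0(pfx, ".c1"), cin, cout)
  make_norm_params(store, paste0(pfx, ".c1.n"), cout)
  make_conv3d_params(store, paste0(pfx, ".c2"), cout, cout)
  make_norm_params(store, paste0(pfx, ".c2.n"), cout)
  if (cin != cout)
    make_conv3d_params(store, paste0(pfx, ".proj"), cin, cout, k = c(1L, 1L, 1L))
}

resblock3d_fw <- function(store, pfx, x) {
  h <- cnr3d(store, paste0(pfx, ".c1"), x)
  h <- norm_fw(store, paste0(pfx, ".c2.n"), conv3d_fw(store, paste0(pfx, ".c2"), h))
  sk <- if (exists(paste0(pfx, ".proj.w"), envir = store))
    conv3d_fw(store, paste0(pfx, ".proj"), x)
  else x
  ad_relu(ad_add(sk, h))
}


# classifier head: the paper-scale presets use global average pooling as
# printed; the small presets flatten instead, giving the linear head direct
# access to spatially localized motion features (a global average dilutes
# the few vein-column cells that carry the pulsation signal)
head_features <- function(cfg, shape) {
  if (cfg$preset == "small") prod(shape) else shape[length(shape)]
}

head_fw <- function(cfg, h) {
  if (cfg$preset == "small") ad_flatten(h) else ad_global_avgpool(h)
}

# ---------------------------------------------------------------- builders ----

arch_widths <- function(cfg) {
  small <- cfg$preset == "small"
  switch(cfg$architecture,
    convlstm = if (small) list(pool0 = 4L, hidden = c(8L))
               else list(pool0 = 1L, hidden = c(16L, 32L)),
    inception3d = if (small)
      list(pool0 = 4L, stem = 6L, modules = list(c(4L, 4L, 2L, 2L)))
    else list(pool0 = 1L, stem = 16L,
              modules = list(c(8L, 12L, 4L, 4L), c(16L, 24L, 8L, 8L))),
    resnet3d = if (small) list(pool0 = 4L, stem = 8L, blocks = c(8L))
               else list(pool0 = 1L, stem = 16L, blocks = c(16L, 32L)),
    dense_resnet3d = if (small) list(pool0 = 4L, stem = 4L, units = 2L, growth = 4L)
                     else list(pool0 = 1L, stem = 16L, units = 3L, growth = 16L),
    lrcn = if (small) list(pool0 = 4L, convs = c(8L), lstm = 16L)
           else list(pool0 = 1L, convs = c(16L, 32L, 64L), lstm = 64L))
}

#' Build an SVP classifier
#'
#' All architectures accept the classifier input contract - an array of shape
#' (30, 64, 64, 1) with values in \[0,1\] - and emit two-class logits whose
#' softmax gives P(absent), P(present).
#'
#' @param cfg a [classifier_config()]
#' @return an object of class `svpnet_classifier`
#' @export
build_classifier <- function(cfg) {
  stopifnot(inherits(cfg, "classifier_config"))
  aw <- arch_widths(cfg)
  store <- new_param_store()
  builder <- switch(cfg$architecture,
                    convlstm = build_convlstm_arch,
                    inception3d = build_inception_arch,
                    resnet3d = build_resnet_arch,
                    dense_resnet3d = build_dense_resnet_arch,
                    lrcn = build_lrcn_arch)
  forward <- with_seed(cfg$seed, builder(store, cfg, aw))
  structure(list(config = cfg, store = store, forward = forward),
            class = "svpnet_classifier")
}

#' @export
print.svpnet_classifier <- function(x, ...) {
  cat(sprintf("<svpnet_classifier> %s (%s preset), %d parameters\n",
              x$config$architecture, x$config$preset,
              count_params(x)))
  invisible(x)
}

stem_pool <- function(x, pool0) if (pool0 > 1L) ad_avgpool3d(x, 1L, pool0, pool0) else x

build_convlstm_arch <- function(store, cfg, aw) {
  s <- 64L %/% aw$pool0
  cin <- 1L
  for (li in seq_along(aw$hidden)) {
    make_convlstm_params(store, paste0("cl", li), cin, aw$hidden[li], s, s)
    make_norm_params(store, paste0("cl", li, ".n"), aw$hidden[li])
    cin <- aw$hidden[li]
    s <- s %/% 2L
  }
  # flatten -> dense head; the small preset averages space per frame first,
  # which keeps the temporal pulsation signal while shrinking the head (a
  # full global average would be exactly zero after the zero-mean
  # normalization, so time must stay unpooled)
  spatial_gap <- cfg$preset == "small"
  make_dense_params(store, "fc", if (spatial_gap) 30L * cin else 30L * s * s * cin, 2L)
  function(x, training = FALSE) {
    h <- stem_pool(as_node(x), aw$pool0)
    for (li in seq_along(aw$hidden)) {
      h <- convlstm_layer_forward(store, paste0("cl", li), h, aw$hidden[li],
                                  cfg$peephole_on_previous)
      h <- norm_fw(store, paste0("cl", li, ".n"), ad_maxpool3d(h, 1L, 2L, 2L))
    }
    if (spatial_gap) {
      d <- dim(h$value)
      h <- ad_avgpool3d(h, 1L, d[2], d[3])
    }
    h <- ad_dropout(ad_flatten(h), cfg$dropout, training)
    dense_fw(store, "fc", h)
  }
}

# one 3-D inception module: parallel 1x1x1, 3x3x3, 5x5x5 and
# pool(3x3x3, stride 1) -> 1x1x1 projection branches, channel-concatenated;
# every convolution is followed by normalization + ReLU
make_inception_module <- function(store, pfx, cin, widths) {
  make_conv3d_params(store, paste0(pfx, ".b1"), cin, widths[1], k = c(1L, 1L, 1L))
  make_norm_params(store, paste0(pfx, ".b1.n"), widths[1])
  make_conv3d_params(store, paste0(pfx, ".b2"), cin, widths[2])
  make_norm_params(store, paste0(pfx, ".b2.n"), widths[2])
  make_conv3d_params(store, paste0(pfx, ".b3"), cin, widths[3], k = c(5L, 5L, 5L))
  make_norm_params(store, paste0(pfx, ".b3.n"), widths[3])
  make_conv3d_params(store, paste0(pfx, ".b4"), cin, widths[4], k = c(1L, 1L, 1L))
  make_norm_params(store, paste0(pfx, ".b4.n"), widths[4])
}

inception_module_fw <- function(store, pfx, x) {
  b1 <- cnr3d(store, paste0(pfx, ".b1"), x)
  b2 <- cnr3d(store, paste0(pfx, ".b2"), x)
  b3 <- cnr3d(store, paste0(pfx, ".b3"), x)
  b4 <- cnr3d(store, paste0(pfx, ".b4"), ad_maxpool3d_s1(x))
  ad_concat_c(ad_concat_c(b1, b2), ad_concat_c(b3, b4))
}

build_inception_arch <- function(store, cfg, aw) {
  make_conv3d_params(store, "stem", 1L, aw$stem)
  make_norm_params(store, "stem.n", aw$stem)
  cin <- aw$stem
  for (mi in seq_along(aw$modules)) {
    make_inception_module(store, paste0("m", mi), cin, aw$modules[[mi]])
    cin <- sum(aw$modules[[mi]])
  }
  sh <- 64L %/% aw$pool0 %/% 2L %/% 2L^(length(aw$modules) - 1L)
  make_dense_params(store, "fc", head_features(cfg, c(15L, sh, sh, cin)), 2L)
  function(x, training = FALSE) {
    h <- stem_pool(as_node(x), aw$pool0)
    h <- ad_maxpool3d(cnr3d(store, "stem", h), 2L, 2L, 2L)
    for (mi in seq_along(aw$modules)) {
      h <- inception_module_fw(store, paste0("m", mi), h)
      if (mi < length(aw$modules)) h <- ad_maxpool3d(h, 1L, 2L, 2L)
    }
    h <- ad_dropout(head_fw(cfg, h), cfg$dropout, training)
    dense_fw(store, "fc", h)
  }
}

build_resnet_arch <- function(store, cfg, aw) {
  make_conv3d_params(store, "stem", 1L, aw$stem)
  make_norm_params(store, "stem.n", aw$stem)
  cin <- aw$stem
  for (bi in seq_along(aw$blocks)) {
    make_resblock3d_params(store, paste0("rb", bi), cin, aw$blocks[bi])
    cin <- aw$blocks[bi]
  }
  sh <- 64L %/% aw$pool0 %/% 2L
  make_dense_params(store, "fc", head_features(cfg, c(15L, sh, sh, cin)), 2L)
  function(x, training = FALSE) {
    h <- stem_pool(as_node(x), aw$pool0)
    h <- ad_relu(norm_fw(store, "stem.n",
                         ad_maxpool3d(conv3d_fw(store, "stem", h), 2L, 2L, 2L)))
    for (bi in seq_along(aw$blocks))
      h <- resblock3d_fw(store, paste0("rb", bi), h)
    h <- ad_dropout(head_fw(cfg, h), cfg$dropout, training)
    dense_fw(store, "fc", h)
  }
}

build_dense_resnet_arch <- function(store, cfg, aw) {
  make_conv3d_params(store, "stem", 1L, aw$stem)
  make_norm_params(store, "stem.n", aw$stem)
  cin <- aw$stem
  for (u in seq_len(aw$units)) {
    # each dense-block unit sees the concatenation of the stem output and all
    # previous unit outputs; a 1x1x1 convolution compresses to the growth
    # width before the residual block
    make_conv3d_params(store, paste0("u", u, ".cmp"), cin, aw$growth,
                       k = c(1L, 1L, 1L))
    make_norm_params(store, paste0("u", u, ".cmp.n"), aw$growth)
    make_resblock3d_params(store, paste0("u", u, ".rb"), aw$growth, aw$growth)
    cin <- cin + aw$growth
  }
  sh <- 64L %/% aw$pool0 %/% 2L
  make_dense_params(store, "fc", head_features(cfg, c(15L, sh, sh, cin)), 2L)
  function(x, training = FALSE) {
    h <- stem_pool(as_node(x), aw$pool0)
    h <- ad_relu(norm_fw(store, "stem.n",
                         ad_maxpool3d(conv3d_fw(store, "stem", h), 2L, 2L, 2L)))
    acc <- h
    for (u in seq_len(aw$units)) {
      z <- cnr3d(store, paste0("u", u, ".cmp"), acc)
      z <- resblock3d_fw(store, paste0("u", u, ".rb"), z)
      acc <- ad_concat_c(acc, z)
    }
    h <- ad_dropout(head_fw(cfg, acc), cfg$dropout, training)
    dense_fw(store, "fc", h)
  }
}

build_lrcn_arch <- function(store, cfg, aw) {
  s <- 64L %/% aw$pool0
  cin <- 1L
  for (ci in seq_along(aw$convs)) {
    make_param(store, paste0("c", ci, ".w"), c(3L, 3L, cin, aw$convs[ci]),
               fan_in = 9 * cin)
    make_param(store, paste0("c", ci, ".b"), aw$convs[ci],
               value = numeric(aw$convs[ci]))
    cin <- aw$convs[ci]
    s <- s %/% 2L
  }
  feat <- s * s * cin
  hid <- aw$lstm
  for (gate in c("i", "f", "g", "o")) {
    make_dense_params(store, paste0("lstm.W", gate), feat, hid)
    make_dense_params(store, paste0("lstm.U", gate), hid, hid)
  }
  # open the forget gate at initialization
  fb <- get("lstm.Wf.b", envir = store)
  fb$value <- rep(1, hid)
  make_dense_params(store, "fc", hid, 2L)
  function(x, training = FALSE) {
    h4 <- stem_pool(as_node(x), aw$pool0)
    T <- dim(h4$value)[1]
    feats <- vector("list", T)
    for (t in seq_len(T)) {
      # the same convolutional stack is applied to every frame (shared weights)
      f <- ad_frame(h4, t)
      for (ci in seq_along(aw$convs)) {
        f <- ad_relu(ad_conv2d(f, get(paste0("c", ci, ".w"), envir = store),
                               get(paste0("c", ci, ".b"), envir = store)))
        f <- ad_maxpool2d(f, 2L, 2L)
      }
      feats[[t]] <- ad_flatten(ad_dropout(f, cfg$dropout, training))
    }
    hz <- as_node(numeric(hid)); cz <- as_node(numeric(hid))
    for (t in seq_len(T)) {
      xt <- feats[[t]]
      gi <- ad_sigmoid(ad_add(dense_fw(store, "lstm.Wi", xt),
                              dense_fw(store, "lstm.Ui", hz)))
      gf <- ad_sigmoid(ad_add(dense_fw(store, "lstm.Wf", xt),
                              dense_fw(store, "lstm.Uf", hz)))
      gg <- ad_tanh(ad_add(dense_fw(store, "lstm.Wg", xt),
                           dense_fw(store, "lstm.Ug", hz)))
      go <- ad_sigmoid(ad_add(dense_fw(store, "lstm.Wo", xt),
                              dense_fw(store, "lstm.Uo", hz)))
      cz <- ad_add(ad_mul(gf, cz), ad_mul(gi, gg))
      hz <- ad_mul(go, ad_tanh(cz))
    }
    dense_fw(store, "fc", hz)
  }
}

#' @rdname build_classifier
#' @export
build_convlstm_classifier <- function(cfg = classifier_config("convlstm")) {
  cfg$architecture <- "convlstm"; build_classifier(cfg)
}

#' @rdname build_classifier
#' @export
build_inception3d <- function(cfg = classifier_config("inception3d")) {
  cfg$architecture <- "inception3d"; build_classifier(cfg)
}

#' @rdname build_classifier
#' @export
build_resnet3d <- function(cfg = classifier_config("resnet3d")) {
  cfg$architecture <- "resnet3d"; build_classifier(cfg)
}

#' @rdname build_classifier
#' @export
build_dense_resnet3d <- function(cfg = classifier_config("dense_resnet3d")) {
  cfg$architecture <- "dense_resnet3d"; build_classifier(cfg)
}

#' @rdname build_classifier
#' @export
build_lrcn <- function(cfg = classifier_config("lrcn")) {
  cfg$architecture <- "lrcn"; build_classifier(cfg)
}

check_classifier_input <- function(clip) {
  d <- dim(clip)
  if (is.null(d) || length(d) != 4 || !all(d == c(30, 64, 64, 1)))
    stop_contract("classifier input must be (30, 64, 64, 1), got (%s)",
                  paste(d, collapse = ", "))
  invisible(clip)
}

#' Train an SVP classifier
#'
#' Two-class cross-entropy on the softmax head, optimized with Adam (or
#' RMSprop) at the configured learning rate, samples shuffled each epoch with
#' the config seed.
#'
#' @param model an `svpnet_classifier`
#' @param inputs list of classifier input arrays (30, 64, 64, 1)
#' @param labels character vector of `"present"` / `"absent"`
#' @param cfg optional [classifier_config()] override (defaults to the
#'   model's own config)
#' @param val_inputs,val_labels optional held-out set; accuracy on it is
#'   recorded per epoch
#' @return list with `model` and `history`
#' @export
train_classifier <- function(model, inputs, labels, cfg = model$config,
                             val_inputs = NULL, val_labels = NULL) {
  stopifnot(inherits(model, "svpnet_classifier"))
  lapply(inputs, check_classifier_input)
  if (length(inputs) < cfg$batch_size)
    stop_data("need at least batch_size = %d samples, have %d",
              cfg$batch_size, length(inputs))
  targets <- match(labels, SVP_CLASSES)
  if (anyNA(targets)) stop_data("labels must be 'present' or 'absent'")
  if (length(unique(targets)) < 2)
    warning("training set contains a single class; proceeding anyway")
  params <- param_list(model$store)
  history <- with_seed(cfg$seed + 1L, {
    opt <- make_optimizer(cfg$optimizer, params, lr = cfg$learning_rate)
    loss_fn <- function(i)
      ad_softmax_ce(model$forward(inputs[[i]], training = TRUE), targets[[i]])
    eval_fn <- if (!is.null(val_inputs)) function() {
      preds <- vapply(val_inputs, function(cl)
        predict_svp(model, cl)$label, "")
      mean(preds == val_labels)
    } else NULL
    sgd_train(params, loss_fn, length(inputs), cfg$epochs, cfg$batch_size, opt,
              eval_fn = eval_fn)
  })
  if (!is.null(history$val_loss)) names(history)[2] <- "val_accuracy"
  list(model = model, history = history)
}

#' Classify SVP presence in one clip
#'
#' @param model a trained `svpnet_classifier`
#' @param clip classifier input array (30, 64, 64, 1)
#' @return list with `label` (`"present"` iff P(present) >= 0.5) and
#'   `probability` (P(present))
#' @export
predict_svp <- function(model, clip) {
  check_classifier_input(clip)
  probs <- softmax_probs(model$forward(clip)$value)
  p <- probs[2]
  list(label = if (p >= 0.5) "present" else "absent", probability = p)
}
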