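# Independent scalar-loop oracles used across the suite. These deliberately
# avoid the package's compiled kernels and graph machinery: plain R loops
# over the defining formulas.

# full 2-D convolution, same padding, by quadruple loop
oracle_conv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  ph <- kh %/% 2; pw <- kw %/% 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
      is <- i + dh - 1 - ph; js <- j + dw - 1 - pw
      if (is >= 1 && is <= H && js >= 1 && js <= W)
        acc <- acc + w[dh, dw, ci, co] * x[is, js, ci]
    }
    y[i, j, co] <- acc
  }
  y
}

# depthwise separable convolution: per-channel 2-D convolution then per-pixel
# channel mixing
oracle_dsconv <- function(x, dw, pw, db = NULL, pb = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(dw)[1]; kw <- dim(dw)[2]
  ph <- kh %/% 2; pwp <- kw %/% 2
  if (is.null(db)) db <- numeric(C)
  if (is.null(pb)) pb <- numeric(ncol(pw))
  mid <- array(0, dim(x))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- db[c]
    for (dh in seq_len(kh)) for (dd in seq_len(kw)) {
      is <- i + dh - 1 - ph; js <- j + dd - 1 - pwp
      if (is >= 1 && is <= H && js >= 1 && js <= W)
        acc <- acc + dw[dh, dd, c] * x[is, js, c]
    }
    mid[i, j, c] <- acc
  }
  Cout <- ncol(pw)
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W))
    y[i, j, co] <- sum(mid[i, j, ] * pw[, co]) + pb[co]
  y
}

# attention gate evaluated pixel by pixel
oracle_attention <- function(u, g, W_u, W_g, b_g, psi, b_psi) {
  H <- dim(u)[1]; W <- dim(u)[2]
  alpha <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    q <- pmax(as.vector(t(W_u) %*% u[i, j, ]) +
                as.vector(t(W_g) %*% g[i, j, ]) + b_g, 0)
    alpha[i, j] <- 1 / (1 + exp(-(sum(psi * q) + b_psi)))
  }
  out <- u
  for (c in seq_len(dim(u)[3])) out[, , c] <- u[, , c] * alpha
  list(alpha = alpha, output = out)
}

# dense peephole LSTM step (scalars/vectors), the 1x1-grid reduction of the
# ConvLSTM equations; peephole on the current cell state in the output gate
oracle_dense_lstm_step <- function(x, h, c, w, peephole_on_previous = FALSE) {
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(w$W_Xf %*% x + w$W_Hf %*% h + w$W_cf * c + w$b_f)
  i <- sig(w$W_Xi %*% x + w$W_Hi %*% h + w$W_ci * c + w$b_Hi)
  g <- tanh(w$W_Xg %*% x + w$W_Hg %*% h + w$b_hg)
  cn <- f * c + i * g
  peek <- if (peephole_on_previous) c else cn
  o <- sig(w$W_Xo %*% x + w$W_Ho %*% h + w$W_Co * peek + w$b_ho)
  list(H = as.vector(o * tanh(cn)), C = as.vector(cn))
}

# vein caliber measured from a rendered frame: anti-aliased coverage summed
# along the horizontal profile through the disc center
oracle_vein_width <- function(frame, spec) {
  r <- round(spec$disc_center[1]) + 1L
  c0 <- round(spec$disc_center[2]) + 1L
  half <- max(8L, ceiling(spec$vessel_base_width * 2))
  prof <- frame[r, (c0 - half):(c0 + half)]
  delta <- spec$background_intensity - spec$vessel_intensity
  sum((spec$disc_intensity - prof) / delta)
}

# soft Dice between a probability map and a binary mask
soft_dice <- function(p, m) 2 * sum(p * m) / (sum(p) + sum(m))

# random binary mask helper
random_mask <- function(h, w, p = 0.3) matrix(rbinom(h * w, 1, p), h, w)

# largest 4-connected component bounding box by brute-force flood fill
oracle_largest_component_bbox <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  best <- NULL; best_n <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1 || seen[i, j]) next
    comp <- matrix(FALSE, H, W)
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      comp[p[1], p[2]] <- TRUE
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] == 1 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    n <- sum(comp)
    if (n > best_n) {
      best_n <- n
      px <- which(comp, arr.ind = TRUE)
      best <- c(min(px[, 1]) - 1L, max(px[, 1]), min(px[, 2]) - 1L, max(px[, 2]))
    }
  }
  best  # (row_start, row_end, col_start, col_end), 0-based half-open
}

# phantom spec matching the classifier's post-crop geometry (64x64 frames,
# disc filling most of the view)
clip_phantom_spec <- function(...) {
  phantom_spec(image_height = 64, image_width = 64, disc_center = c(32, 32),
               disc_radii = c(14, 17), vessel_base_width = 4, ...)
}

clips_to_classifier_inputs <- function(clips) {
  lapply(clips, function(lc)
    crop_clip(lc$clip, bounding_region(0, 64, 0, 64)))
}
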