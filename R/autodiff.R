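# Minimal reverse-mode automatic differentiation over R arrays.
#
# Nodes are environments carrying a value, an accumulated gradient, parent
# references and a backward closure. Ops executed while a tape is active are
# recorded in creation order, which is a valid topological order, so backward
# is a single reverse sweep. Parameters live outside tapes and keep their
# gradients until explicitly zeroed, which lets a training step accumulate
# gradients over a batch processed sample by sample.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

tape_start <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .ad$tape <- tp
  invisible(tp)
}

tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

tape_record <- function(nd) {
  tp <- .ad$tape
  if (is.null(tp)) return(invisible(nd))
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  invisible(nd)
}

ad_node <- function(value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  class(nd) <- "ad_node"
  tape_record(nd)
  nd
}

is_node <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_node(x)) x$value else x

as_node <- function(x) if (is_node(x)) x else ad_node(x)

# Parameter: a leaf node never recorded on a tape (created between tapes).
ad_param <- function(value) {
  stopifnot(is.null(.ad$tape))
  ad_node(value)
}

acc_grad <- function(nd, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node.
ad_backward <- function(loss) {
  tp <- .ad$tape
  if (is.null(tp)) stop("ad_backward() requires an active tape")
  acc_grad(loss, 1)
  for (k in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) acc_grad(ps[[j]], gs[[j]])
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ------------------------------------------------------------ elementwise ----

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, k) {
  a <- as_node(a)
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_relu <- function(a) {
  a <- as_node(a)
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  a <- as_node(a)
  y <- tanh(a$value)
  ad_node(y, list(a), function(g) list(g * (1 - y * y)))
}

# multiply a one-channel map (H,W,1) across all channels of u (H,W,C)
ad_mul_bcast_channel <- function(alpha, u) {
  alpha <- as_node(alpha); u <- as_node(u)
  av <- alpha$value; uv <- u$value
  d <- dim(uv)
  val <- uv * as.vector(av)  # column-major recycling over channels
  ad_node(val, list(alpha, u), function(g) {
    ga <- array(rowSums(matrix(g * uv, nrow = d[1] * d[2])), dim = dim(av))
    list(ga, g * as.vector(av))
  })
}

ad_concat_c <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$value); db <- dim(b$value)
  nd <- length(da)
  val <- array(c(a$value, b$value), dim = c(da[-nd], da[nd] + db[nd]))
  ad_node(val, list(a, b), function(g) {
    na <- prod(da)
    list(array(g[seq_len(na)], dim = da),
         array(g[-seq_len(na)], dim = db))
  })
}

# ----------------------------------------------------------- convolutions ----

ad_conv2d <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- .cpp_conv2d_fwd(xv, wv, b$value)
  ad_node(y, list(x, w, b), function(g) {
    gr <- .cpp_conv2d_bwd(xv, wv, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

ad_dwconv2d <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- .cpp_dwconv2d_fwd(xv, wv, b$value)
  ad_node(y, list(x, w, b), function(g) {
    gr <- .cpp_dwconv2d_bwd(xv, wv, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

ad_conv3d <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  y <- .cpp_conv3d_fwd(xv, wv, b$value)
  ad_node(y, list(x, w, b), function(g) {
    gr <- .cpp_conv3d_bwd(xv, wv, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

# --------------------------------------------------------------- pooling ----

ad_maxpool2d <- function(x, ph = 2L, pw = ph) {
  x <- as_node(x)
  xd <- dim(x$value)
  r <- .cpp_maxpool2d_fwd(x$value, as.integer(ph), as.integer(pw))
  ad_node(r$y, list(x), function(g) list(.cpp_pool_bwd(g, r$idx, as.integer(xd))))
}

ad_maxpool3d <- function(x, pt = 1L, ph = 2L, pw = ph) {
  x <- as_node(x)
  xd <- dim(x$value)
  r <- .cpp_maxpool3d_fwd(x$value, as.integer(pt), as.integer(ph), as.integer(pw))
  ad_node(r$y, list(x), function(g) list(.cpp_pool_bwd(g, r$idx, as.integer(xd))))
}

ad_maxpool3d_s1 <- function(x, kt = 3L, kh = 3L, kw = 3L) {
  x <- as_node(x)
  xd <- dim(x$value)
  r <- .cpp_maxpool3d_s1_fwd(x$value, as.integer(kt), as.integer(kh), as.integer(kw))
  ad_node(r$y, list(x), function(g) list(.cpp_pool_bwd(g, r$idx, as.integer(xd))))
}

ad_avgpool3d <- function(x, pt = 1L, ph = 2L, pw = ph) {
  x <- as_node(x)
  xd <- dim(x$value)
  y <- .cpp_avgpool3d_fwd(x$value, as.integer(pt), as.integer(ph), as.integer(pw))
  ad_node(y, list(x), function(g)
    list(.cpp_avgpool3d_bwd(g, as.integer(xd), as.integer(pt), as.integer(ph),
                            as.integer(pw))))
}

# mean over every dimension except the last (channel)
ad_global_avgpool <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  nd <- length(d)
  nspat <- prod(d[-nd])
  m <- matrix(x$value, nrow = nspat)
  ad_node(colMeans(m), list(x), function(g) {
    list(array(rep(g / nspat, each = nspat), dim = d))
  })
}

# nearest-neighbour 2x upsampling of (H,W,C)
ad_upsample2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  val <- x$value[ri, ci, , drop = FALSE]
  ad_node(val, list(x), function(g) {
    gx <- g[seq(1, 2 * d[1], by = 2), seq(1, 2 * d[2], by = 2), , drop = FALSE] +
      g[seq(2, 2 * d[1], by = 2), seq(1, 2 * d[2], by = 2), , drop = FALSE] +
      g[seq(1, 2 * d[1], by = 2), seq(2, 2 * d[2], by = 2), , drop = FALSE] +
      g[seq(2, 2 * d[1], by = 2), seq(2, 2 * d[2], by = 2), , drop = FALSE]
    list(gx)
  })
}

# ------------------------------------------------- dense / shape plumbing ----

ad_dense <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- as.vector(x$value); wv <- w$value
  xd <- dim(x$value)
  ad_node(as.vector(wv %*% xv) + as.vector(b$value), list(x, w, b), function(g) {
    gx <- as.vector(crossprod(wv, g))
    if (!is.null(xd)) gx <- array(gx, dim = xd)
    list(gx, tcrossprod(g, xv), g)
  })
}

ad_flatten <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  ad_node(as.vector(x$value), list(x), function(g) list(array(g, dim = d)))
}

# extract frame t from a (T,H,W,C) clip as (H,W,C)
ad_frame <- function(x, t) {
  x <- as_node(x)
  d <- dim(x$value)
  val <- array(x$value[t, , , , drop = FALSE], dim = d[2:4])
  ad_node(val, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[t, , , ] <- g
    list(gx)
  })
}

# stack T nodes of shape (H,W,C) into (T,H,W,C)
ad_stack_frames <- function(frames) {
  d <- dim(frames[[1]]$value)
  T <- length(frames)
  val <- array(0, dim = c(T, d))
  for (t in seq_len(T)) val[t, , , ] <- frames[[t]]$value
  ad_node(val, frames, function(g) {
    lapply(seq_len(T), function(t) array(g[t, , , , drop = FALSE], dim = d))
  })
}

# ------------------------------------------------------------- normalize ----

# Per-channel normalization with externally supplied (constant) statistics:
# y = gamma * (x - mean)/sqrt(var + eps) + beta. Used as batch normalization
# with running statistics - normalizing by dataset-level rather than
# per-sample statistics preserves each sample's own activation scale, which
# for motion-rectified features is the class signal.
ad_norm_const <- function(x, gamma, beta, mean_c, var_c, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  nd <- length(d)
  C <- d[nd]
  n <- prod(d[-nd])
  sdv <- sqrt(var_c + eps)
  xm <- matrix(x$value, nrow = n)
  xhat <- sweep(sweep(xm, 2, mean_c), 2, sdv, "/")
  ym <- sweep(sweep(xhat, 2, as.vector(gamma$value), "*"), 2,
              as.vector(beta$value), "+")
  ad_node(array(ym, dim = d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n)
    dx <- sweep(sweep(gm, 2, as.vector(gamma$value), "*"), 2, sdv, "/")
    list(array(dx, dim = d), colSums(gm * xhat), colSums(gm))
  })
}

# Per-channel normalization over the sample's own spatial/temporal extent
# (instance normalization); gamma/beta are per-channel learned parameters.
ad_norm_channels <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  nd <- length(d)
  C <- d[nd]
  n <- prod(d[-nd])
  xm <- matrix(x$value, nrow = n)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  sdv <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sdv, "/")
  ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  ad_node(array(ym, dim = d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gamma$value, "*")
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- sweep(
      dxhat - matrix(s1 / n, n, C, byrow = TRUE) -
        xhat * matrix(s2 / n, n, C, byrow = TRUE),
      2, sdv, "/")
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

ad_dropout <- function(x, rate, training = TRUE) {
  x <- as_node(x)
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  ad_node(x$value * keep, list(x), function(g) list(g * keep))
}

# ---------------------------------------------------------------- losses ----

# 2-class softmax cross-entropy from logits; target is class index (1 or 2)
ad_softmax_ce <- function(logits, target) {
  logits <- as_node(logits)
  z <- logits$value
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  loss <- -log(max(p[target], 1e-12))
  ad_node(loss, list(logits), function(g) {
    gz <- p
    gz[target] <- gz[target] - 1
    list(g * gz)
  })
}

softmax_probs <- function(logits) {
  z <- logits - max(logits)
  exp(z) / sum(exp(z))
}

# soft Dice loss between a probability grid and a binary mask
ad_dice_loss_node <- function(pred, target, eps = 1e-6) {
  pred <- as_node(pred)
  pv <- pred$value
  tv <- ad_value(target)
  if (length(tv) != length(pv)) stop_contract("pred and target shapes differ")
  dim(tv) <- dim(pv)
  inter <- sum(pv * tv)
  denom <- sum(pv) + sum(tv)
  loss <- 1 - (2 * inter + eps) / (denom + eps)
  ad_node(loss, list(pred), function(g) {
    gp <- -(2 * tv * (denom + eps) - (2 * inter + eps)) / (denom + eps)^2
    list(g * gp)
  })
}

# ------------------------------------------------------- initialization ----

# He-uniform initialization; fan_in from kernel geometry
init_weight <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

new_param_store <- function() new.env(parent = emptyenv())

make_param <- function(store, name, dims, fan_in = NULL, value = NULL) {
  if (is.null(value)) {
    if (is.null(fan_in)) fan_in <- prod(dims[-length(dims)])
    value <- init_weight(dims, fan_in)
  }
  p <- ad_param(value)
  assign(name, p, envir = store)
  p
}

param_list <- function(store) {
  nm <- sort(ls(store))
  setNames(lapply(nm, function(n) get(n, envir = store)), nm)
}
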