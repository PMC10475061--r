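# Optimizers and the shared sample-at-a-time training loop.
#
# Gradients are accumulated across the samples of a batch (parameters keep
# their grads between backward sweeps), then averaged and applied in a single
# update, emulating mini-batch SGD at desk scale.

make_optimizer <- function(type = c("rmsprop", "adam"), params, lr,
                           rho = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  type <- match.arg(type)
  st <- new.env(parent = emptyenv())
  st$cache <- lapply(params, function(p) p$value * 0)
  st$m <- st$cache
  st$t <- 0L
  step <- function(scale = 1) {
    st$t <- st$t + 1L
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p$grad)) next
      g <- p$grad * scale
      if (type == "rmsprop") {
        st$cache[[i]] <- rho * st$cache[[i]] + (1 - rho) * g * g
        p$value <- p$value - lr * g / (sqrt(st$cache[[i]]) + eps)
      } else {
        st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
        st$cache[[i]] <- beta2 * st$cache[[i]] + (1 - beta2) * g * g
        mh <- st$m[[i]] / (1 - beta1^st$t)
        vh <- st$cache[[i]] / (1 - beta2^st$t)
        p$value <- p$value - lr * mh / (sqrt(vh) + eps)
      }
    }
    invisible(NULL)
  }
  list(step = step, type = type, lr = lr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Generic epoch loop. `loss_fn(i)` must build the forward graph for sample i
# on the active tape and return a scalar loss node. `eval_fn()` (optional)
# returns a validation loss after each epoch.
sgd_train <- function(params, loss_fn, n_samples, epochs, batch_size, optimizer,
                      eval_fn = NULL, verbose = FALSE) {
  hist_train <- numeric(epochs)
  hist_val <- if (is.null(eval_fn)) NULL else numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_samples)
    ep_loss <- 0
    done <- 0L
    while (done < n_samples) {
      batch <- ord[(done + 1L):min(done + batch_size, n_samples)]
      zero_grads(params)
      for (i in batch) {
        tape_start()
        l <- loss_fn(i)
        ad_backward(l)
        tape_end()
        ep_loss <- ep_loss + l$value
      }
      optimizer$step(scale = 1 / length(batch))
      done <- done + length(batch)
    }
    hist_train[ep] <- ep_loss / n_samples
    if (!is.null(eval_fn)) hist_val[ep] <- eval_fn()
    if (verbose)
      message(sprintf("epoch %d/%d train %.4f%s", ep, epochs, hist_train[ep],
                      if (is.null(eval_fn)) "" else sprintf(" val %.4f", hist_val[ep])))
  }
  list(train_loss = hist_train, val_loss = hist_val)
}
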