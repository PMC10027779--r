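# Minimal dense neural-network engine: branch encoders merged by
# concatenation into a sigmoid output head, trained with class-weighted
# binary cross-entropy and Adam. Written against base matrix algebra so
# the full training loop is deterministic on CPU under a seed.

new_dense <- function(d_in, d_out, activation = "relu") {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = matrix(0, 1, d_out),
       activation = activation)
}

act_fwd <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), linear = z,
         abort("unknown activation: ", activation))
}

act_grad <- function(z, activation) {
  switch(activation, relu = (z > 0) * 1, linear = array(1, dim = dim(z)))
}

stack_forward <- function(layers, x) {
  cache <- vector("list", length(layers))
  a <- x
  for (i in seq_along(layers)) {
    z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    cache[[i]] <- list(a_in = a, z = z)
    a <- act_fwd(z, layers[[i]]$activation)
  }
  list(out = a, cache = cache)
}

stack_backward <- function(layers, cache, d_out) {
  grads <- vector("list", length(layers))
  da <- d_out
  for (i in rev(seq_along(layers))) {
    dz <- da * act_grad(cache[[i]]$z, layers[[i]]$activation)
    grads[[i]] <- list(W = crossprod(cache[[i]]$a_in, dz),
                       b = matrix(colSums(dz), 1))
    da <- dz %*% t(layers[[i]]$W)
  }
  list(grads = grads, d_in = da)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Class-weighted binary cross-entropy
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary labels.
#' @param w per-observation weights (see [class_weights()]).
#' @return mean weighted cross-entropy.
#' @export
weighted_bce <- function(p, y, w = rep(1, length(y))) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}

# Forward pass over named branch inputs; returns probabilities and caches.
nn_forward <- function(net, inputs) {
  bout <- lapply(names(net$branches), function(nm)
    stack_forward(net$branches[[nm]], inputs[[nm]]))
  names(bout) <- names(net$branches)
  h <- do.call(cbind, lapply(bout, `[[`, "out"))
  hd <- stack_forward(net$head, h)
  list(prob = as.vector(sigmoid(hd$out)), branch = bout, head = hd, h = h)
}

# Backward pass for sigmoid + weighted BCE; returns gradients mirroring
# the network structure.
nn_backward <- function(net, fw, y, w) {
  n <- length(y)
  dz <- matrix(w * (fw$prob - y) / n, n, 1)
  hb <- stack_backward(net$head, fw$head$cache, dz)
  widths <- vapply(fw$branch, function(b) ncol(b$out), numeric(1))
  offsets <- cumsum(c(0, widths))
  bgrads <- list()
  for (i in seq_along(net$branches)) {
    cols <- (offsets[i] + 1):offsets[i + 1]
    bgrads[[names(net$branches)[i]]] <-
      stack_backward(net$branches[[i]], fw$branch[[i]]$cache,
                     hb$d_in[, cols, drop = FALSE])$grads
  }
  list(branches = bgrads, head = hb$grads)
}

adam_state <- function(net) {
  zero_like <- function(layers) lapply(layers, function(l)
    list(W = list(m = l$W * 0, v = l$W * 0), b = list(m = l$b * 0, v = l$b * 0)))
  list(branches = lapply(net$branches, zero_like), head = zero_like(net$head),
       t = 0L)
}

adam_update <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd_layer <- function(layer, grad, st) {
    for (p in c("W", "b")) {
      st[[p]]$m <- beta1 * st[[p]]$m + (1 - beta1) * grad[[p]]
      st[[p]]$v <- beta2 * st[[p]]$v + (1 - beta2) * grad[[p]]^2
      mh <- st[[p]]$m / (1 - beta1^t)
      vh <- st[[p]]$v / (1 - beta2^t)
      layer[[p]] <- layer[[p]] - lr * mh / (sqrt(vh) + eps)
    }
    list(layer = layer, st = st)
  }
  for (nm in names(net$branches)) {
    for (i in seq_along(net$branches[[nm]])) {
      u <- upd_layer(net$branches[[nm]][[i]], grads$branches[[nm]][[i]],
                     state$branches[[nm]][[i]])
      net$branches[[nm]][[i]] <- u$layer
      state$branches[[nm]][[i]] <- u$st
    }
  }
  for (i in seq_along(net$head)) {
    u <- upd_layer(net$head[[i]], grads$head[[i]], state$head[[i]])
    net$head[[i]] <- u$layer
    state$head[[i]] <- u$st
  }
  list(net = net, state = state)
}
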