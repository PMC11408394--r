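# A compact 3D convolutional network engine: networks are ordered graphs of
# primitive nodes (convolution, instance norm, activations, dropout,
# additive joins, 2x up/down sampling, softmax) executed forward over R
# arrays (X, Y, Z, C) with C++ kernels, and differentiated by a hand-rolled
# reverse sweep. Deliberately minimal: batch size 1, CPU only,
# deterministic given the R RNG state.

# ---- graph construction ----------------------------------------------------

.graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$channels <- integer()   # output channels per node
  env$add <- function(op, inputs = integer(), p = NULL, Co = NA_integer_,
                      k = 3L, stride = 1L, dil = 1L, slope = 0.01,
                      rate = 0.2) {
    id <- length(env$nodes) + 1L
    if (is.na(Co) && length(inputs)) Co <- env$channels[inputs[1]]
    env$nodes[[id]] <- list(op = op, inputs = as.integer(inputs), p = p,
                            Co = as.integer(Co), k = as.integer(k),
                            stride = as.integer(stride),
                            dil = as.integer(dil), slope = slope,
                            rate = rate)
    env$channels[id] <- as.integer(Co)
    id
  }
  env
}

# parameter shapes implied by the graph; conv/upconv need input channels
.param_shapes <- function(nodes, channels) {
  shapes <- list()
  for (nd in nodes) {
    if (is.null(nd$p)) next
    ci <- channels[nd$inputs[1]]
    if (nd$op == "conv") {
      shapes[[paste0(nd$p, ".W")]] <- c(nd$k, nd$k, nd$k, ci, nd$Co)
      shapes[[paste0(nd$p, ".b")]] <- nd$Co
    } else if (nd$op == "upconv") {
      shapes[[paste0(nd$p, ".W")]] <- c(2L, 2L, 2L, ci, nd$Co)
      shapes[[paste0(nd$p, ".b")]] <- nd$Co
    } else if (nd$op == "inorm") {
      shapes[[paste0(nd$p, ".gamma")]] <- nd$Co
      shapes[[paste0(nd$p, ".beta")]] <- nd$Co
    }
  }
  shapes
}

# variance-scaling (fan-in) initialisation; biases/betas 0, gammas 1
.init_params <- function(shapes) {
  P <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    if (endsWith(nm, ".W")) {
      fan_in <- prod(sh[-length(sh)])
      P[[nm]] <- array(stats::rnorm(prod(sh), sd = sqrt(2 / fan_in)),
                       dim = sh)
    } else if (endsWith(nm, ".gamma")) {
      P[[nm]] <- rep(1, sh)
    } else {
      P[[nm]] <- rep(0, sh)
    }
  }
  P
}

# ---- forward / backward ----------------------------------------------------

.inorm_fwd <- function(x, gamma, beta) {
  r <- .inorm_fwd_c(x, dim(x), gamma, beta)
  list(y = r$y, xhat = r$xhat, istd = r$istd)
}

.inorm_bwd <- function(dy, cache, gamma) {
  .inorm_bwd_c(dy, dim(dy), cache$xhat, cache$istd, gamma)
}

.softmax_fwd <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  m <- matrix(x, n, d[4])
  mx <- m[, 1]
  for (c_ in seq_len(d[4])[-1]) mx <- pmax(mx, m[, c_])
  e <- exp(m - mx)
  q <- e / rowSums(e)
  array(q, dim = d)
}

.softmax_bwd <- function(dy, q) {
  d <- dim(dy)
  n <- prod(d[1:3])
  dym <- matrix(dy, n, d[4])
  qm <- matrix(q, n, d[4])
  s <- rowSums(dym * qm)
  array(qm * (dym - s), dim = d)
}

.wmat <- function(W) {
  sh <- dim(W)
  matrix(W, nrow = prod(sh[-length(sh)]), ncol = sh[length(sh)])
}

# forward pass; returns node values and per-node caches
.net_forward <- function(net, image, classvol = NULL, training = FALSE) {
  nodes <- net@nodes
  P <- net@params
  vals <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    x <- if (length(nd$inputs)) vals[[nd$inputs[1]]]
    vals[[i]] <- switch(nd$op,
      image = {
        d <- dim(image)
        if (length(d) == 3L) dim(image) <- c(d, 1L)
        image
      },
      classvol = {
        if (is.null(classvol))
          stop("this network requires a class-label volume input")
        classvol
      },
      conv = .conv3d_fwd(x, dim(x), .wmat(P[[paste0(nd$p, ".W")]]),
                         P[[paste0(nd$p, ".b")]], nd$k, nd$stride, nd$dil),
      upconv = .upconv_fwd(x, dim(x), P[[paste0(nd$p, ".W")]],
                           P[[paste0(nd$p, ".b")]]),
      avgpool = .avgpool_fwd(x, dim(x)),
      inorm = {
        r <- .inorm_fwd(x, P[[paste0(nd$p, ".gamma")]],
                        P[[paste0(nd$p, ".beta")]])
        caches[[i]] <- r[c("xhat", "istd")]
        r$y
      },
      relu = pmax(x, 0),
      lrelu = ifelse(x > 0, x, nd$slope * x),
      dropout = {
        if (training && nd$rate > 0) {
          mask <- array((stats::runif(length(x)) >= nd$rate) /
                          (1 - nd$rate), dim = dim(x))
          caches[[i]] <- mask
          x * mask
        } else x
      },
      add = {
        v <- vals[[nd$inputs[1]]]
        for (j in nd$inputs[-1]) v <- v + vals[[j]]
        v
      },
      softmax = {
        q <- .softmax_fwd(x)
        caches[[i]] <- q
        q
      },
      stop("unknown op ", nd$op))
  }
  list(vals = vals, caches = caches)
}

# reverse sweep from the final node; dOut = dL/d(output of last node)
.net_backward <- function(net, fw, dOut) {
  nodes <- net@nodes
  P <- net@params
  vals <- fw$vals
  caches <- fw$caches
  g <- vector("list", length(nodes))
  g[[length(nodes)]] <- dOut
  G <- list()
  acc <- function(nm, v) G[[nm]] <<- if (is.null(G[[nm]])) v else G[[nm]] + v
  accg <- function(id, v)
    g[[id]] <<- if (is.null(g[[id]])) v else g[[id]] + v
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- g[[i]]
    if (is.null(dy)) next
    x <- if (length(nd$inputs)) vals[[nd$inputs[1]]]
    switch(nd$op,
      image = NULL,
      classvol = NULL,
      conv = {
        src <- nodes[[nd$inputs[1]]]$op %in% c("image", "classvol")
        r <- .conv3d_bwd(x, dim(x), .wmat(P[[paste0(nd$p, ".W")]]), dy,
                         nd$k, nd$stride, nd$dil, !src)
        acc(paste0(nd$p, ".W"), array(r$dW,
            dim = dim(P[[paste0(nd$p, ".W")]])))
        acc(paste0(nd$p, ".b"), r$db)
        if (!src) accg(nd$inputs[1], r$dx)
      },
      upconv = {
        r <- .upconv_bwd(x, dim(x), P[[paste0(nd$p, ".W")]], dy, nd$Co)
        acc(paste0(nd$p, ".W"), array(r$dW,
            dim = dim(P[[paste0(nd$p, ".W")]])))
        acc(paste0(nd$p, ".b"), r$db)
        accg(nd$inputs[1], r$dx)
      },
      avgpool = accg(nd$inputs[1], .avgpool_bwd(dy, dim(x))),
      inorm = {
        r <- .inorm_bwd(dy, caches[[i]], P[[paste0(nd$p, ".gamma")]])
        acc(paste0(nd$p, ".gamma"), r$dgamma)
        acc(paste0(nd$p, ".beta"), r$dbeta)
        accg(nd$inputs[1], r$dx)
      },
      relu = accg(nd$inputs[1], dy * (x > 0)),
      lrelu = accg(nd$inputs[1], dy * ifelse(x > 0, 1, nd$slope)),
      dropout = accg(nd$inputs[1],
                     if (is.null(caches[[i]])) dy else dy * caches[[i]]),
      add = for (j in nd$inputs) accg(j, dy),
      softmax = accg(nd$inputs[1], .softmax_bwd(dy, caches[[i]])))
  }
  G
}

# ---- Adam ------------------------------------------------------------------

.adam_state <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim = if (is.null(dim(p)))
         length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p)))
         length(p) else dim(p))))
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
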