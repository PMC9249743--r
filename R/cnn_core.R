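# Minimal convolutional network engine.
#
# Architecture (fixed topology, sizes configurable): a stack of
# valid-padding strided convolutions with ReLU, a flatten, one ReLU dense
# layer, and a single linear output unit.  The scalar output is a margin
# trained with hinge loss on targets {-1, +1}; its raw value is the
# feature handed to the forest.  Everything is plain R: convolutions are
# im2col + BLAS matrix products, so a 32 x 32 batch trains in seconds on
# one CPU.  Data layout: a batch is a (C*H*W) x B matrix, each column one
# image in channel-first pixel order, index c + (i + (j-1)*H - 1)*C.  With
# that layout the F x (P*B) ReLU output of a convolution *is* the next
# layer's (F*P) x B input after a free `dim<-`, so no transposes are
# needed anywhere in the stack.

conv_out_dim <- function(n, k, s) as.integer((n - k) %/% s + 1L)

# Precompute the im2col gather indices for one conv layer, plus the
# scatter indices (grouped by kernel offset) used by the backward pass.
# For a fixed kernel offset the output->input map is injective, so
# col2im is nine vectorised `+=` operations instead of a reduction.
conv_plan <- function(H, W, Cin, F, k = 3L, s = 2L) {
  Ho <- conv_out_dim(H, k, s); Wo <- conv_out_dim(W, k, s)
  if (Ho < 1L || Wo < 1L)
    stop(sprintf("input %dx%d too small for a %dx%d stride-%d convolution",
                 H, W, k, k, s))
  P <- Ho * Wo; K <- k * k * Cin
  oi <- rep(seq_len(Ho), times = Wo)          # p = oi + (oj-1)*Ho
  oj <- rep(seq_len(Wo), each = Ho)
  gather <- matrix(0L, K, P)
  offsets <- vector("list", k * k)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ii <- (oi - 1L) * s + di                  # input row, length P
    jj <- (oj - 1L) * s + dj
    base <- (ii + (jj - 1L) * H - 1L) * Cin   # channel-first linear index
    o <- di + (dj - 1L) * k
    rows <- o + (seq_len(Cin) - 1L) * (k * k)
    for (c in seq_len(Cin))
      gather[rows[c], ] <- base + c
    # scatter target indices ordered (c fastest, then p) to match the
    # as.vector order of dXcol[rows, ] reshaped to (Cin*P) x B
    offsets[[o]] <- list(rows = rows,
                         target = as.vector(outer(seq_len(Cin), base, `+`)))
  }
  list(H = H, W = W, Cin = Cin, F = F, k = k, s = s,
       Ho = Ho, Wo = Wo, P = P, K = K,
       gather = as.vector(gather), offsets = offsets,
       npix_in = H * W * Cin, npix_out = P * F)
}

# Batched gather indices are deterministic functions of (plan, B); cache
# them so each (layer, batch size) pair builds its index vector once.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_batch_idx <- function(plan, B) {
  key <- paste(plan$H, plan$W, plan$Cin, plan$k, plan$s, B, sep = "_")
  idx <- .conv_idx_cache[[key]]
  if (is.null(idx)) {
    idx <- rep.int(plan$gather, B) +
      rep((seq_len(B) - 1L) * plan$npix_in, each = length(plan$gather))
    .conv_idx_cache[[key]] <- idx
  }
  idx
}

# X: npix_in x B  ->  list(Xcol = K x (P*B), Z pre-activation, out (F*P) x B)
conv_forward <- function(plan, X, Wt, b) {
  B <- ncol(X)
  Xcol <- X[conv_batch_idx(plan, B)]
  dim(Xcol) <- c(plan$K, plan$P * B)
  Z <- Wt %*% Xcol + b                        # F x (P*B), bias recycled by col
  A <- Z * (Z > 0)
  dim(A) <- c(plan$npix_out, B)               # channel-first: free reshape
  list(Xcol = Xcol, Z = Z, out = A)
}

# dOut: npix_out x B gradient at this layer's output.
# Returns dW, db and (optionally) dX for the layer below.
conv_backward <- function(plan, fwd, Wt, dOut, need_dx = TRUE) {
  B <- ncol(dOut)
  dim(dOut) <- c(plan$F, plan$P * B)          # channel-first: free reshape
  dZ <- dOut * (fwd$Z > 0)
  dW <- tcrossprod(dZ, fwd$Xcol)              # F x K
  db <- rowSums(dZ)
  dX <- NULL
  if (need_dx) {
    dXcol <- crossprod(Wt, dZ)                # K x (P*B)
    dX <- matrix(0, plan$npix_in, B)
    for (off in plan$offsets) {
      part <- dXcol[off$rows, , drop = FALSE] # Cin x (P*B)
      dim(part) <- c(length(off$rows) * plan$P, B)
      dX[off$target, ] <- dX[off$target, ] + part
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# Glorot-uniform initialisation, biases zero.  Draw order is fixed so a
# given seed always yields the same parameters.
cnn_init_params <- function(plans, dense_units, flat_dim) {
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list()
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    fan_in <- p$K; fan_out <- p$F * p$k * p$k
    params[[paste0("Wc", i)]] <- glorot(p$F, p$K, fan_in, fan_out)
    params[[paste0("bc", i)]] <- numeric(p$F)
  }
  params$Wd <- glorot(dense_units, flat_dim, flat_dim, dense_units)
  params$bd <- numeric(dense_units)
  params$Wo <- glorot(1L, dense_units, dense_units, 1L)
  params$bo <- 0
  params
}

# Full forward pass; returns margins (length B) and, when training,
# the per-layer caches needed by the backward pass.
cnn_forward <- function(net, X, keep = FALSE) {
  caches <- if (keep) vector("list", length(net$plans))
  A <- X
  for (i in seq_along(net$plans)) {
    f <- conv_forward(net$plans[[i]], A,
                      net$params[[paste0("Wc", i)]],
                      net$params[[paste0("bc", i)]])
    if (keep) caches[[i]] <- f else f$Xcol <- f$Z <- NULL
    A <- f$out
  }
  Zd <- net$params$Wd %*% A + net$params$bd
  Hd <- Zd * (Zd > 0)
  score <- as.vector(net$params$Wo %*% Hd) + net$params$bo
  if (keep) list(score = score, caches = caches, flat = A, Zd = Zd, Hd = Hd)
  else score
}

# hinge(s, y) = mean(max(0, 1 - y*s)) + l2 * sum of squared weights
cnn_loss <- function(net, score, y) {
  margin <- pmax(0, 1 - y * score)
  wpen <- sum(vapply(grep("^W", names(net$params), value = TRUE),
                     function(nm) sum(net$params[[nm]]^2), numeric(1)))
  mean(margin) + net$l2 * wpen
}

cnn_gradients <- function(net, fwd, y) {
  B <- length(y)
  active <- (1 - y * fwd$score) > 0
  dscore <- (-y * active) / B                 # d mean-hinge / d score
  g <- list()
  g$Wo <- matrix(dscore, 1L) %*% t(fwd$Hd)
  g$bo <- sum(dscore)
  dHd <- crossprod(net$params$Wo, matrix(dscore, 1L)) * (fwd$Zd > 0)
  g$Wd <- tcrossprod(dHd, fwd$flat)
  g$bd <- rowSums(dHd)
  dX <- crossprod(net$params$Wd, dHd)
  for (i in rev(seq_along(net$plans))) {
    bk <- conv_backward(net$plans[[i]], fwd$caches[[i]],
                        net$params[[paste0("Wc", i)]], dX, need_dx = i > 1L)
    g[[paste0("Wc", i)]] <- bk$dW
    g[[paste0("bc", i)]] <- bk$db
    dX <- bk$dX
  }
  # L2 penalty l2 * sum(w^2) on weight matrices (not biases)
  for (nm in grep("^W", names(net$params), value = TRUE))
    g[[nm]] <- g[[nm]] + 2 * net$l2 * net$params[[nm]]
  g
}

# Optimizers update the parameter buffers IN PLACE via the compiled
# kernels (the dense layer alone has ~4e5 parameters, and pure-R updates
# would allocate several full-size temporaries per mini-batch step).
# Callers must therefore never alias the parameter arrays without an
# explicit deep copy (see the epoch checkpoint in train_cnn).
make_optimizer <- function(name, lr = NULL) {
  name <- tolower(name)
  lr <- lr %||% switch(name, adagrad = 0.01, rmsprop = 0.001, adam = 0.001,
                       stop("unknown optimizer: ", name))
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  buf <- function(key, template) {
    b <- state[[key]]
    if (is.null(b)) {
      b <- numeric(length(template))
      state[[key]] <- b
    }
    b
  }
  step <- switch(name,
    adagrad = function(params, grads) {
      for (nm in names(grads))
        step_adagrad_(params[[nm]], grads[[nm]], buf(nm, grads[[nm]]),
                      lr, 1e-7)
      invisible(NULL)
    },
    rmsprop = function(params, grads) {
      for (nm in names(grads))
        step_rmsprop_(params[[nm]], grads[[nm]], buf(nm, grads[[nm]]),
                      lr, 0.9, 1e-7)
      invisible(NULL)
    },
    adam = function(params, grads) {
      state$t <- state$t + 1L
      corr <- sqrt(1 - 0.999^state$t) / (1 - 0.9^state$t)
      for (nm in names(grads))
        step_adam_(params[[nm]], grads[[nm]],
                   buf(paste0("m.", nm), grads[[nm]]),
                   buf(paste0("v.", nm), grads[[nm]]),
                   lr, 0.9, 0.999, 1e-8, corr)
      invisible(NULL)
    })
  list(name = name, lr = lr, step = step)
}
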