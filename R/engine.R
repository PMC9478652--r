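# A compact batched neural-network engine in base R.
#
# All heavy lifting is BLAS matrix multiplication: convolutions are lowered
# to im2col patch matrices, so a conv layer is one big GEMM per minibatch.
# Tensors are 4-D arrays in (batch, height, width, channels) order; 1-D
# convolutional networks use width 1 and put the feature columns on the
# channel axis. Layers are environments (mutable in place) so parameters,
# gradients and optimizer state live beside each other; a network is a tree
# of such environments (seq / branches / per-channel composites).
#
# Supported layers: conv (same padding, odd kernels), batch normalization,
# leaky ReLU, max pooling (floor semantics), global max pooling, inverted
# dropout, dense. Loss: softmax cross-entropy. Optimizer: Adam.

nn_node <- function(kind, ..., tag = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$tag <- tag
  e$trainable <- TRUE
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "nn_node"
  e
}

# He-uniform initialization from the current RNG stream.
he_init <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_conv <- function(kh, kw, in_c, out_c, tag = NULL) {
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  nn_node("conv", kh = kh, kw = kw, in_c = in_c, out_c = out_c,
          W = he_init(kh * kw * in_c, out_c), b = numeric(out_c), tag = tag)
}

nn_bn <- function(nc, momentum = 0.1, eps = 1e-5) {
  nn_node("bn", nc = nc, gamma = rep(1, nc), beta = numeric(nc),
          rm = numeric(nc), rv = rep(1, nc), momentum = momentum, eps = eps)
}

nn_act <- function(slope = 0.01) nn_node("act", slope = slope)
nn_pool <- function(ph = 2, pw = 2, tag = NULL)
  nn_node("pool", ph = ph, pw = pw, tag = tag)
nn_gpool <- function(tag = NULL) nn_node("gpool", tag = tag)
nn_drop <- function(p) nn_node("drop", p = p)
nn_dense <- function(n_in, n_out, tag = NULL)
  nn_node("dense", n_in = n_in, n_out = n_out,
          W = he_init(n_in, n_out), b = numeric(n_out), tag = tag)
nn_seq <- function(nodes, tag = NULL) nn_node("seq", nodes = nodes, tag = tag)
nn_branches <- function(branches, tag = NULL, meta = NULL)
  nn_node("branches", branches = branches, tag = tag, meta = meta)
nn_channels <- function(mods, mode, tag = NULL, meta = NULL)
  nn_node("channels", mods = mods, mode = mode, tag = tag, meta = meta)
nn_concat_input <- function(mode, tag = NULL) nn_node("cat_in", mode = mode,
                                                      tag = tag)

pad_hw <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  xp[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  xp
}

# ---- forward ----------------------------------------------------------

nn_forward <- function(node, x, train = FALSE) {
  switch(node$kind,
    conv = {
      d <- dim(x)
      ph <- (node$kh - 1) / 2; pw <- (node$kw - 1) / 2
      xp <- pad_hw(x, ph, pw)
      N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      P <- matrix(0, N * H * W, node$kh * node$kw * C)
      idx <- 0L
      for (dj in seq_len(node$kw)) for (di in seq_len(node$kh)) {
        blk <- xp[, di:(di + H - 1), dj:(dj + W - 1), , drop = FALSE]
        P[, idx * C + seq_len(C)] <- matrix(blk, nrow = N * H * W)
        idx <- idx + 1L
      }
      out <- P %*% node$W
      out <- out + rep(node$b, each = nrow(out))
      if (train) { node$P <- P; node$in_dim <- d }
      array(out, c(N, H, W, node$out_c))
    },
    bn = {
      d <- dim(x)
      xm <- matrix(x, ncol = node$nc)
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm * xm) - mu^2
        node$rm <- (1 - node$momentum) * node$rm + node$momentum * mu
        node$rv <- (1 - node$momentum) * node$rv + node$momentum * v
      } else {
        mu <- node$rm; v <- node$rv
      }
      istd <- 1 / sqrt(v + node$eps)
      xhat <- (xm - rep(mu, each = nrow(xm))) * rep(istd, each = nrow(xm))
      out <- xhat * rep(node$gamma, each = nrow(xm)) +
        rep(node$beta, each = nrow(xm))
      if (train) { node$xhat <- xhat; node$istd <- istd; node$in_dim <- d }
      array(out, d)
    },
    act = {
      mask <- (x > 0) + node$slope * (x <= 0)
      if (train) node$mask <- mask
      x * mask
    },
    pool = {
      d <- dim(x)
      Ho <- d[2] %/% node$ph; Wo <- d[3] %/% node$pw
      stopifnot(Ho >= 1, Wo >= 1)
      rows <- function(i) seq(i, by = node$ph, length.out = Ho)
      cols <- function(j) seq(j, by = node$pw, length.out = Wo)
      best <- NULL; sel <- NULL
      idx <- 0L
      for (j in seq_len(node$pw)) for (i in seq_len(node$ph)) {
        idx <- idx + 1L
        sl <- x[, rows(i), cols(j), , drop = FALSE]
        if (is.null(best)) {
          best <- sl; sel <- array(1L, dim(sl))
        } else {
          upd <- sl > best
          best[upd] <- sl[upd]; sel[upd] <- idx
        }
      }
      if (train) { node$sel <- sel; node$in_dim <- d }
      best
    },
    gpool = {
      d <- dim(x)
      xr <- array(x, c(d[1], d[2] * d[3], d[4]))
      best <- matrix(xr[, 1, ], d[1], d[4]); sel <- matrix(1L, d[1], d[4])
      if (d[2] * d[3] > 1) for (k in 2:(d[2] * d[3])) {
        sl <- matrix(xr[, k, ], d[1], d[4])
        upd <- sl > best
        best[upd] <- sl[upd]; sel[upd] <- k
      }
      if (train) { node$sel <- sel; node$in_dim <- d }
      matrix(best, d[1], d[4])
    },
    drop = {
      if (!train || node$p <= 0) return(x)
      mask <- array((stats::runif(length(x)) >= node$p) / (1 - node$p), dim(x))
      node$mask <- mask
      x * mask
    },
    dense = {
      out <- x %*% node$W
      out <- out + rep(node$b, each = nrow(out))
      if (train) node$x_in <- x
      out
    },
    seq = {
      for (nd in node$nodes) x <- nn_forward(nd, x, train)
      x
    },
    branches = {
      outs <- lapply(node$branches, nn_forward, x = x, train = train)
      cs <- vapply(outs, function(o) dim(o)[4], numeric(1))
      d <- dim(outs[[1]])
      out <- array(0, c(d[1], d[2], d[3], sum(cs)))
      off <- 0
      for (b in seq_along(outs)) {
        out[, , , off + seq_len(cs[b])] <- outs[[b]]
        off <- off + cs[b]
      }
      node$cs <- cs
      out
    },
    channels = {
      d <- dim(x)
      if (length(node$mods) != d[2])
        stop("number of input channels does not match the per-channel modules")
      outs <- vector("list", d[2])
      for (ch in seq_len(d[2])) {
        sl <- x[, ch, , , drop = FALSE]
        xin <- if (node$mode == "2d") array(sl, c(d[1], d[3], d[4], 1))
               else array(sl, c(d[1], d[3], 1, d[4]))
        outs[[ch]] <- nn_forward(node$mods[[ch]], xin, train)
      }
      cs <- vapply(outs, function(o) dim(o)[4], numeric(1))
      do <- dim(outs[[1]])
      out <- array(0, c(do[1], do[2], do[3], sum(cs)))
      off <- 0
      for (ch in seq_along(outs)) {
        out[, , , off + seq_len(cs[ch])] <- outs[[ch]]
        off <- off + cs[ch]
      }
      node$cs <- cs; node$in_dim <- d
      out
    },
    cat_in = {
      d <- dim(x)
      node$in_dim <- d
      y <- aperm(x, c(1, 3, 4, 2))  # (N, d1, d2, ch)
      if (node$mode == "2d") y else array(y, c(d[1], d[3], 1, d[4] * d[2]))
    },
    stop("unknown node kind: ", node$kind)
  )
}

# ---- backward ---------------------------------------------------------

nn_backward <- function(node, dout) {
  switch(node$kind,
    conv = {
      d <- node$in_dim
      N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      ph <- (node$kh - 1) / 2; pw <- (node$kw - 1) / 2
      M <- matrix(dout, nrow = N * H * W)
      node$dW <- node$dW + crossprod(node$P, M)
      node$db <- node$db + colSums(M)
      dP <- tcrossprod(M, node$W)
      dxp <- array(0, c(N, H + 2 * ph, W + 2 * pw, C))
      idx <- 0L
      for (dj in seq_len(node$kw)) for (di in seq_len(node$kh)) {
        blk <- array(dP[, idx * C + seq_len(C)], c(N, H, W, C))
        dxp[, di:(di + H - 1), dj:(dj + W - 1), ] <-
          dxp[, di:(di + H - 1), dj:(dj + W - 1), , drop = FALSE] + blk
        idx <- idx + 1L
      }
      node$P <- NULL
      if (ph == 0 && pw == 0) dxp
      else dxp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
    },
    bn = {
      d <- node$in_dim
      m <- prod(d) / node$nc
      dm <- matrix(dout, ncol = node$nc)
      node$dgamma <- node$dgamma + colSums(dm * node$xhat)
      node$dbeta <- node$dbeta + colSums(dm)
      dxhat <- dm * rep(node$gamma, each = m)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * node$xhat)
      dx <- (dxhat - rep(s1 / m, each = m) -
               node$xhat * rep(s2 / m, each = m)) *
        rep(node$istd, each = m)
      node$xhat <- NULL
      array(dx, d)
    },
    act = dout * node$mask,
    pool = {
      d <- node$in_dim
      Ho <- d[2] %/% node$ph; Wo <- d[3] %/% node$pw
      dx <- array(0, d)
      rows <- function(i) seq(i, by = node$ph, length.out = Ho)
      cols <- function(j) seq(j, by = node$pw, length.out = Wo)
      idx <- 0L
      for (j in seq_len(node$pw)) for (i in seq_len(node$ph)) {
        idx <- idx + 1L
        tmp <- array(0, dim(dout))
        msk <- node$sel == idx
        tmp[msk] <- dout[msk]
        dx[, rows(i), cols(j), ] <-
          dx[, rows(i), cols(j), , drop = FALSE] + tmp
      }
      dx
    },
    gpool = {
      d <- node$in_dim
      hw <- d[2] * d[3]
      dxr <- array(0, c(d[1], hw, d[4]))
      for (k in seq_len(hw)) {
        msk <- node$sel == k
        tmp <- matrix(0, d[1], d[4])
        tmp[msk] <- dout[msk]
        dxr[, k, ] <- tmp
      }
      array(dxr, d)
    },
    drop = if (node$p <= 0) dout else dout * node$mask,
    dense = {
      node$dW <- node$dW + crossprod(node$x_in, dout)
      node$db <- node$db + colSums(dout)
      dx <- tcrossprod(dout, node$W)
      node$x_in <- NULL
      dx
    },
    seq = {
      for (nd in rev(node$nodes)) dout <- nn_backward(nd, dout)
      dout
    },
    branches = {
      off <- 0
      dx <- NULL
      for (b in seq_along(node$branches)) {
        dslice <- dout[, , , off + seq_len(node$cs[b]), drop = FALSE]
        off <- off + node$cs[b]
        dxi <- nn_backward(node$branches[[b]], dslice)
        dx <- if (is.null(dx)) dxi else dx + dxi
      }
      dx
    },
    channels = {
      d <- node$in_dim
      dx <- array(0, d)
      off <- 0
      for (ch in seq_along(node$mods)) {
        dslice <- dout[, , , off + seq_len(node$cs[ch]), drop = FALSE]
        off <- off + node$cs[ch]
        dxi <- nn_backward(node$mods[[ch]], dslice)
        dx[, ch, , ] <- if (node$mode == "2d") array(dxi, c(d[1], d[3], d[4]))
                        else array(dxi, c(d[1], d[3], d[4]))
      }
      dx
    },
    cat_in = {
      d <- node$in_dim
      y <- if (node$mode == "2d") dout
           else array(dout, c(d[1], d[3], d[4], d[2]))
      aperm(y, c(1, 4, 2, 3))
    },
    stop("unknown node kind: ", node$kind)
  )
}

# ---- traversal, parameters, optimizer --------------------------------

nn_children <- function(node) {
  switch(node$kind,
         seq = node$nodes,
         branches = node$branches,
         channels = node$mods,
         list())
}

nn_collect <- function(node) {
  out <- list(node)
  for (ch in nn_children(node)) out <- c(out, nn_collect(ch))
  out
}

nn_param_fields <- function(node) {
  switch(node$kind,
         conv = c("W", "b"),
         dense = c("W", "b"),
         bn = c("gamma", "beta"),
         character(0))
}

nn_zero_grads <- function(root) {
  for (e in nn_collect(root)) {
    for (f in nn_param_fields(e)) e[[paste0("d", f)]] <- e[[f]] * 0
  }
  invisible(root)
}

nn_count_params <- function(root) {
  tot <- 0
  for (e in nn_collect(root))
    for (f in nn_param_fields(e)) tot <- tot + length(e[[f]])
  tot
}

# Flatten all trainable parameters to one numeric vector (for checksums
# and no-mutation assertions).
nn_flatten_params <- function(root) {
  out <- list()
  for (e in nn_collect(root))
    for (f in nn_param_fields(e)) out[[length(out) + 1]] <- as.numeric(e[[f]])
  unlist(out)
}

nn_adam_step <- function(root, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 1) {
  for (e in nn_collect(root)) {
    if (!isTRUE(e$trainable)) next
    for (f in nn_param_fields(e)) {
      g <- e[[paste0("d", f)]]
      mf <- paste0("adam_m_", f); vf <- paste0("adam_v_", f)
      if (is.null(e[[mf]])) { e[[mf]] <- g * 0; e[[vf]] <- g * 0 }
      e[[mf]] <- b1 * e[[mf]] + (1 - b1) * g
      e[[vf]] <- b2 * e[[vf]] + (1 - b2) * g * g
      mhat <- e[[mf]] / (1 - b1^t)
      vhat <- e[[vf]] / (1 - b2^t)
      e[[f]] <- e[[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(root)
}

nn_reset_optimizer <- function(root) {
  for (e in nn_collect(root)) {
    st <- grep("^adam_", ls(e), value = TRUE)
    if (length(st)) rm(list = st, envir = e)
  }
  invisible(root)
}

# Deep copy of a node tree (fresh environments, values copied).
nn_clone <- function(node) {
  e <- new.env(parent = emptyenv())
  for (nm in ls(node)) {
    v <- get(nm, envir = node)
    if (nm %in% c("nodes", "branches", "mods")) v <- lapply(v, nn_clone)
    assign(nm, v, envir = e)
  }
  class(e) <- "nn_node"
  e
}

# Drop transient forward caches (keeps serialized/finished models small).
nn_clear_cache <- function(root) {
  for (e in nn_collect(root)) {
    for (f in c("P", "xhat", "istd", "mask", "sel", "x_in"))
      if (!is.null(e[[f]])) e[[f]] <- NULL
  }
  invisible(root)
}

# ---- loss -------------------------------------------------------------

# Numerically stable softmax over rows.
nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# y: 0-based integer class labels. Returns list(loss, grad, prob).
nn_softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  p <- nn_softmax(logits)
  picked <- p[cbind(seq_len(n), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  grad <- p
  grad[cbind(seq_len(n), y + 1L)] <- grad[cbind(seq_len(n), y + 1L)] - 1
  list(loss = loss, grad = grad / n, prob = p)
}
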