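# Minimal CNN engine backing the encoder-decoder architectures.
#
# Feature maps are channel-first R arrays: (C, H, W, N) in 2D and
# (C, D, H, W, N) in 3D. Convolutions are stride-1 'same' via im2col +
# GEMM (src/nn.cpp); max-pooling is 2x (with stored argmax indices for
# SegNet-style max-unpooling); 3D up-convolution is a kernel-2 stride-2
# transposed convolution. Training is mini-batch SGD with momentum on a
# voxel-wise categorical cross-entropy after the soft-max head.

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv2d <- function(in_c, out_c, k = 3L) {
  list(type = "conv2d", k = k, in_c = in_c, out_c = out_c,
       W = he_init(out_c, in_c * k * k, in_c * k * k), b = numeric(out_c),
       vW = matrix(0, out_c, in_c * k * k), vb = numeric(out_c))
}

layer_conv3d <- function(in_c, out_c, k = 3L) {
  list(type = "conv3d", k = k, in_c = in_c, out_c = out_c,
       W = he_init(out_c, in_c * k^3, in_c * k^3), b = numeric(out_c),
       vW = matrix(0, out_c, in_c * k^3), vb = numeric(out_c))
}

layer_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", C = C, eps = eps, momentum = momentum,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C),
       vgamma = numeric(C), vbeta = numeric(C))
}

layer_relu <- function() list(type = "relu")
layer_pool2 <- function() list(type = "pool2")
layer_pool3 <- function() list(type = "pool3")
layer_unpool2 <- function(pair, mode = c("indices", "nearest"))
  list(type = "unpool2", pair = pair, mode = match.arg(mode))
layer_concat3 <- function(from) list(type = "concat3", from = from)

layer_upconv3 <- function(in_c, out_c) {
  list(type = "upconv3", in_c = in_c, out_c = out_c,
       W = he_init(out_c * 8L, in_c, in_c), b = numeric(out_c),
       vW = matrix(0, out_c * 8L, in_c), vb = numeric(out_c))
}

# ---- pooling ---------------------------------------------------------------

pool2_forward <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  if (H %% 2L || W %% 2L) stop("pool2: spatial dims must be even")
  od <- c(C, H %/% 2L, W %/% 2L, N)
  x6 <- array(x, c(C, 2L, H %/% 2L, 2L, W %/% 2L, N))
  i6 <- array(seq_along(x), dim(x6))
  pick <- function(a, b, arr) {
    v <- arr[, a, , b, , , drop = FALSE]; dim(v) <- od; v
  }
  best <- pick(1L, 1L, x6); bidx <- pick(1L, 1L, i6)
  for (cand in list(c(2L, 1L), c(1L, 2L), c(2L, 2L))) {
    v <- pick(cand[1], cand[2], x6); ii <- pick(cand[1], cand[2], i6)
    upd <- v > best
    best[upd] <- v[upd]; bidx[upd] <- ii[upd]
  }
  list(y = best, idx = bidx, in_dim = d)
}

pool3_forward <- function(x) {
  d <- dim(x); C <- d[1]; D <- d[2]; H <- d[3]; W <- d[4]; N <- d[5]
  if (D %% 2L || H %% 2L || W %% 2L) stop("pool3: spatial dims must be even")
  od <- c(C, D %/% 2L, H %/% 2L, W %/% 2L, N)
  x8 <- array(x, c(C, 2L, D %/% 2L, 2L, H %/% 2L, 2L, W %/% 2L, N))
  i8 <- array(seq_along(x), dim(x8))
  pick <- function(a, b, cc, arr) {
    v <- arr[, a, , b, , cc, , , drop = FALSE]; dim(v) <- od; v
  }
  best <- pick(1L, 1L, 1L, x8); bidx <- pick(1L, 1L, 1L, i8)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    if (a == 1L && b == 1L && cc == 1L) next
    v <- pick(a, b, cc, x8); ii <- pick(a, b, cc, i8)
    upd <- v > best
    best[upd] <- v[upd]; bidx[upd] <- ii[upd]
  }
  list(y = best, idx = bidx, in_dim = d)
}

scatter_to <- function(values, idx, n, dims) {
  out <- numeric(n)
  out[idx] <- values
  array(out, dims)
}

# nearest-neighbor 2x upsampling (alternative SegNet decoder mode)
upsample2_nearest <- function(x) {
  d <- dim(x)
  y6 <- array(0, c(d[1], 2L, d[2], 2L, d[3], d[4]))
  for (a in 1:2) for (b in 1:2) y6[, a, , b, , ] <- x
  array(y6, c(d[1], 2L * d[2], 2L * d[3], d[4]))
}

downsum2_nearest <- function(g, in_dim) {
  g6 <- array(g, c(in_dim[1], 2L, in_dim[2], 2L, in_dim[3], in_dim[4]))
  out <- array(0, in_dim)
  for (a in 1:2) for (b in 1:2) {
    v <- g6[, a, , b, , , drop = FALSE]; dim(v) <- in_dim
    out <- out + v
  }
  out
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(model, x, train = TRUE) {
  n <- length(model$layers)
  acts <- vector("list", n + 1L)
  caches <- vector("list", n)
  acts[[1L]] <- x
  for (i in seq_len(n)) {
    ly <- model$layers[[i]]
    a <- acts[[i]]
    if (ly$type == "conv2d") {
      d <- dim(a)
      cols <- im2col2_cpp(as.double(a), d[1], d[2], d[3], d[4], ly$k)
      out <- ly$W %*% cols + ly$b
      acts[[i + 1L]] <- array(out, c(ly$out_c, d[2], d[3], d[4]))
      caches[[i]] <- list(in_dim = d)
    } else if (ly$type == "conv3d") {
      d <- dim(a)
      cols <- im2col3_cpp(as.double(a), d[1], d[2], d[3], d[4], d[5], ly$k)
      out <- ly$W %*% cols + ly$b
      acts[[i + 1L]] <- array(out, c(ly$out_c, d[2], d[3], d[4], d[5]))
      caches[[i]] <- list(in_dim = d)
    } else if (ly$type == "bn") {
      d <- dim(a)
      xm <- matrix(a, nrow = ly$C)
      if (train) {
        mu <- rowMeans(xm)
        va <- rowMeans((xm - mu)^2)
        invstd <- 1 / sqrt(va + ly$eps)
        xhat <- (xm - mu) * invstd
        model$layers[[i]]$rmean <- (1 - ly$momentum) * ly$rmean +
          ly$momentum * mu
        model$layers[[i]]$rvar <- (1 - ly$momentum) * ly$rvar +
          ly$momentum * va
        caches[[i]] <- list(xhat = xhat, invstd = invstd, dim = d)
        acts[[i + 1L]] <- array(ly$gamma * xhat + ly$beta, d)
      } else {
        invstd <- 1 / sqrt(ly$rvar + ly$eps)
        xhat <- (xm - ly$rmean) * invstd
        acts[[i + 1L]] <- array(ly$gamma * xhat + ly$beta, d)
      }
    } else if (ly$type == "relu") {
      acts[[i + 1L]] <- pmax(a, 0)
      caches[[i]] <- list(mask = a > 0)
    } else if (ly$type == "pool2") {
      p <- pool2_forward(a)
      acts[[i + 1L]] <- p$y
      caches[[i]] <- p
    } else if (ly$type == "pool3") {
      p <- pool3_forward(a)
      acts[[i + 1L]] <- p$y
      caches[[i]] <- p
    } else if (ly$type == "unpool2") {
      pc <- caches[[ly$pair]]
      if (ly$mode == "indices") {
        if (is.null(pc)) stop("unpool2: paired pooling cache missing")
        acts[[i + 1L]] <- scatter_to(a, pc$idx, prod(pc$in_dim), pc$in_dim)
        caches[[i]] <- list(idx = pc$idx)
      } else {
        acts[[i + 1L]] <- upsample2_nearest(a)
        caches[[i]] <- list(in_dim = dim(a))
      }
    } else if (ly$type == "upconv3") {
      d <- dim(a)
      xm <- matrix(a, nrow = d[1])
      y <- ly$W %*% xm  # (F*8) x (D H W N)
      od <- c(ly$out_c, 2L * d[2], 2L * d[3], 2L * d[4], d[5])
      out <- array(0, od)
      o <- 0L
      for (cw in 1:2) for (ch in 1:2) for (cd in 1:2) {
        o <- o + 1L
        blk <- array(y[(o - 1L) * ly$out_c + seq_len(ly$out_c), ],
                     c(ly$out_c, d[2], d[3], d[4], d[5]))
        out[, seq(cd, 2L * d[2], 2L), seq(ch, 2L * d[3], 2L),
            seq(cw, 2L * d[4], 2L), ] <- blk
      }
      acts[[i + 1L]] <- out + ly$b
      caches[[i]] <- list(in_dim = d)
    } else if (ly$type == "concat3") {
      skip <- acts[[ly$from + 1L]]
      d1 <- dim(a); d2 <- dim(skip)
      if (!identical(d1[-1], d2[-1]))
        stop("concat3: skip connection resolution mismatch")
      out <- array(0, c(d1[1] + d2[1], d1[-1]))
      out[seq_len(d1[1]), , , , ] <- a
      out[d1[1] + seq_len(d2[1]), , , , ] <- skip
      acts[[i + 1L]] <- out
      caches[[i]] <- list(c1 = d1[1], c2 = d2[1])
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  list(out = acts[[n + 1L]], acts = acts, caches = caches, model = model)
}

# Backward pass; returns per-layer parameter gradients.
nn_backward <- function(model, fwd, dout) {
  n <- length(model$layers)
  grads <- vector("list", n)
  extra <- vector("list", n + 1L)  # skip-connection gradient injections
  g <- dout
  for (i in rev(seq_len(n))) {
    if (!is.null(extra[[i + 1L]])) g <- g + extra[[i + 1L]]
    ly <- model$layers[[i]]
    ca <- fwd$caches[[i]]
    if (ly$type %in% c("conv2d", "conv3d")) {
      d <- ca$in_dim
      a <- fwd$acts[[i]]
      if (ly$type == "conv2d") {
        cols <- im2col2_cpp(as.double(a), d[1], d[2], d[3], d[4], ly$k)
      } else {
        cols <- im2col3_cpp(as.double(a), d[1], d[2], d[3], d[4], d[5], ly$k)
      }
      gm <- matrix(g, nrow = ly$out_c)
      dW <- gm %*% t(cols)
      db <- rowSums(gm)
      dcols <- crossprod(ly$W, gm)
      dx <- if (ly$type == "conv2d") {
        col2im2_cpp(dcols, d[1], d[2], d[3], d[4], ly$k)
      } else {
        col2im3_cpp(dcols, d[1], d[2], d[3], d[4], d[5], ly$k)
      }
      grads[[i]] <- list(W = dW, b = db)
      g <- array(dx, d)
    } else if (ly$type == "bn") {
      d <- ca$dim
      gm <- matrix(g, nrow = ly$C)
      m <- ncol(gm)
      dgamma <- rowSums(gm * ca$xhat)
      dbeta <- rowSums(gm)
      dxhat <- gm * ly$gamma
      dx <- ca$invstd / m *
        (m * dxhat - rowSums(dxhat) - ca$xhat * rowSums(dxhat * ca$xhat))
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      g <- array(dx, d)
    } else if (ly$type == "relu") {
      g <- g * ca$mask
    } else if (ly$type %in% c("pool2", "pool3")) {
      dx <- numeric(prod(ca$in_dim))
      dx[ca$idx] <- g
      g <- array(dx, ca$in_dim)
    } else if (ly$type == "unpool2") {
      if (ly$mode == "indices") {
        g <- array(g[ca$idx], dim(ca$idx))
      } else {
        g <- downsum2_nearest(g, ca$in_dim)
      }
    } else if (ly$type == "upconv3") {
      d <- ca$in_dim
      gb <- matrix(g, nrow = ly$out_c)
      db <- rowSums(gb)
      gm <- matrix(0, ly$out_c * 8L, prod(d[-1]))
      o <- 0L
      for (cw in 1:2) for (ch in 1:2) for (cd in 1:2) {
        o <- o + 1L
        blk <- g[, seq(cd, dim(g)[2], 2L), seq(ch, dim(g)[3], 2L),
                 seq(cw, dim(g)[4], 2L), , drop = FALSE]
        gm[(o - 1L) * ly$out_c + seq_len(ly$out_c), ] <-
          matrix(blk, nrow = ly$out_c)
      }
      xm <- matrix(fwd$acts[[i]], nrow = d[1])
      grads[[i]] <- list(W = gm %*% t(xm), b = db)
      g <- array(crossprod(ly$W, gm), d)
    } else if (ly$type == "concat3") {
      d <- dim(g)
      g1 <- g[seq_len(ca$c1), , , , , drop = FALSE]
      g2 <- g[ca$c1 + seq_len(ca$c2), , , , , drop = FALSE]
      dim(g1) <- c(ca$c1, d[-1])
      dim(g2) <- c(ca$c2, d[-1])
      src <- extra[[ly$from + 1L]]
      extra[[ly$from + 1L]] <- if (is.null(src)) g2 else src + g2
      g <- g1
    }
  }
  grads
}

# soft-max + voxel-wise categorical cross-entropy
# scores: (L, spatial..., N) array; labels: integer array of matching
# spatial x N dims with values 0..L-1
softmax_ce <- function(scores, labels, class_weights = NULL) {
  L <- dim(scores)[1]
  sm <- matrix(scores, nrow = L)
  sm <- sm - rep(apply(sm, 2, max), each = L)
  e <- exp(sm)
  p <- e / rep(colSums(e), each = L)
  lab <- as.integer(labels) + 1L
  m <- ncol(p)
  pick <- p[cbind(lab, seq_len(m))]
  w <- if (is.null(class_weights)) rep(1, m) else class_weights[lab]
  wsum <- sum(w)
  loss <- sum(-w * log(pmax(pick, 1e-12))) / wsum
  dy <- p
  dy[cbind(lab, seq_len(m))] <- dy[cbind(lab, seq_len(m))] - 1
  dy <- dy * rep(w, each = L) / wsum
  list(loss = loss, grad = array(dy, dim(scores)), probs = p)
}

nn_softmax <- function(scores) {
  L <- dim(scores)[1]
  sm <- matrix(scores, nrow = L)
  sm <- sm - rep(apply(sm, 2, max), each = L)
  e <- exp(sm)
  array(e / rep(colSums(e), each = L), dim(scores))
}

sgd_update <- function(model, grads, lr, momentum) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    gr <- grads[[i]]
    if (is.null(gr)) next
    if (ly$type %in% c("conv2d", "conv3d", "upconv3")) {
      ly$vW <- momentum * ly$vW - lr * gr$W
      ly$vb <- momentum * ly$vb - lr * gr$b
      ly$W <- ly$W + ly$vW
      ly$b <- ly$b + ly$vb
    } else if (ly$type == "bn") {
      ly$vgamma <- momentum * ly$vgamma - lr * gr$gamma
      ly$vbeta <- momentum * ly$vbeta - lr * gr$beta
      ly$gamma <- ly$gamma + ly$vgamma
      ly$beta <- ly$beta + ly$vbeta
    }
    model$layers[[i]] <- ly
  }
  model
}
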