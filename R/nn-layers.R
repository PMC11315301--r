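# Minimal explicit-backprop layer library.
#
# Tensor convention: feature maps are R arrays [H, W, C, B] (column-major),
# vector-valued activations are matrices [D, B].  Every module is a plain list
# with a `type` field plus parameters/buffers; `mod_forward()` returns the
# output, a cache for the backward pass, and the (possibly updated) module,
# `mod_backward()` returns the gradient w.r.t. the input and named parameter
# gradients.  Networks are flat lists of modules run by `seq_forward()` /
# `seq_backward()`; the generator adds one skip-excitation connection on top.

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a per-channel vector over an [H,W,C,B] array laid out as a vector
.bc_ch <- function(v, hw, B) rep(rep(v, each = hw), times = B)

# per-channel sums of an [H,W,C,B] array
.ch_sum <- function(x, hw, C, B) {
  rowSums(colSums(array(x, c(hw, C, B))))
}

.he_init <- function(nrow, ncol, fan_in, gain = sqrt(2)) {
  matrix(stats::rnorm(nrow * ncol, sd = gain / sqrt(fan_in)), nrow, ncol)
}

# ---- module constructors ----------------------------------------------------

nn_conv <- function(cin, cout, k = 3, stride = 1, pad = 1, sn = FALSE,
                    gain = sqrt(2)) {
  fan_in <- k * k * cin
  m <- list(type = "conv", W = .he_init(cout, fan_in, fan_in, gain),
            b = numeric(cout), k = k, s = stride, p = pad, sn = sn,
            cin = cin, cout = cout)
  if (sn) m$u <- { u <- stats::rnorm(cout); u / sqrt(sum(u^2)) }
  m
}

nn_dense <- function(din, dout, sn = FALSE, gain = 1) {
  m <- list(type = "dense", W = .he_init(dout, din, din, gain),
            b = numeric(dout), sn = sn)
  if (sn) m$u <- { u <- stats::rnorm(dout); u / sqrt(sum(u^2)) }
  m
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), momentum = momentum, eps = eps)
}

nn_glu <- function() list(type = "glu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_upsample2 <- function() list(type = "upsample2")
nn_noise <- function(c) list(type = "noise", nw = numeric(c))
nn_tanh01 <- function() list(type = "tanh01")
nn_tanh <- function() list(type = "tanh")
nn_sigmoid <- function() list(type = "sigmoid")
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(h, w, c) list(type = "reshape", h = h, w = w, c = c)
nn_sle <- function(c_low, c_high) {
  list(type = "sle", W = .he_init(c_high, c_low, c_low, 1), b = numeric(c_high))
}

# ---- spectral normalization -------------------------------------------------

.sn_apply <- function(mod, training) {
  W <- mod$W
  u <- mod$u
  if (training) {
    v <- crossprod(W, u); v <- v / max(sqrt(sum(v * v)), 1e-12)
    u <- W %*% v;         u <- u / max(sqrt(sum(u * u)), 1e-12)
    mod$u <- as.numeric(u)
  } else {
    v <- crossprod(W, u); v <- v / max(sqrt(sum(v * v)), 1e-12)
  }
  sigma <- max(sum(u * (W %*% v)), 1e-12)
  list(Ws = W / sigma, sigma = sigma, u = as.numeric(u), v = as.numeric(v),
       mod = mod)
}

.sn_backward <- function(gWs, sn) {
  # d/dW of (W / sigma) with sigma = u' W v, u and v treated as constants
  gWs / sn$sigma - (sum(gWs * sn$Ws) / sn$sigma) * (sn$u %o% sn$v)
}

# ---- forward / backward -----------------------------------------------------

mod_forward <- function(mod, x, training = TRUE) {
  switch(mod$type,
    conv = {
      if (isTRUE(mod$sn)) {
        sn <- .sn_apply(mod, training)
        y <- cpp_conv2d_fwd(x, sn$Ws, mod$b, mod$k, mod$s, mod$p)
        list(y = y, cache = list(x = x, sn = sn), mod = sn$mod)
      } else {
        y <- cpp_conv2d_fwd(x, mod$W, mod$b, mod$k, mod$s, mod$p)
        list(y = y, cache = list(x = x), mod = mod)
      }
    },
    dense = {
      if (isTRUE(mod$sn)) {
        sn <- .sn_apply(mod, training)
        y <- sn$Ws %*% x + mod$b
        list(y = y, cache = list(x = x, sn = sn), mod = sn$mod)
      } else {
        list(y = mod$W %*% x + mod$b, cache = list(x = x), mod = mod)
      }
    },
    bn = {
      d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; B <- d[4]; n <- hw * B
      if (training) {
        mu <- .ch_sum(x, hw, C, B) / n
        xc <- x - .bc_ch(mu, hw, B)
        va <- .ch_sum(xc * xc, hw, C, B) / n
        invstd <- 1 / sqrt(va + mod$eps)
        xhat <- xc * .bc_ch(invstd, hw, B)
        mod$rm <- mod$momentum * mod$rm + (1 - mod$momentum) * mu
        mod$rv <- mod$momentum * mod$rv + (1 - mod$momentum) * va
      } else {
        invstd <- 1 / sqrt(mod$rv + mod$eps)
        xhat <- (x - .bc_ch(mod$rm, hw, B)) * .bc_ch(invstd, hw, B)
      }
      y <- xhat * .bc_ch(mod$gamma, hw, B) + .bc_ch(mod$beta, hw, B)
      dim(y) <- d
      list(y = y, cache = list(xhat = xhat, invstd = invstd, training = training,
                               hw = hw, C = C, B = B), mod = mod)
    },
    glu = {
      d <- dim(x); h <- d[3] %/% 2L
      a <- x[, , seq_len(h), , drop = FALSE]
      sb <- sigmoid(x[, , h + seq_len(h), , drop = FALSE])
      list(y = a * sb, cache = list(a = a, sb = sb, d = d), mod = mod)
    },
    lrelu = {
      pos <- x > 0
      y <- x * ifelse(pos, 1, mod$alpha)
      list(y = y, cache = list(pos = pos), mod = mod)
    },
    upsample2 = list(y = cpp_upsample2_fwd(x), cache = NULL, mod = mod),
    noise = {
      if (training) {
        d <- dim(x)
        eps <- array(stats::rnorm(length(x)), d)
        y <- x + eps * .bc_ch(mod$nw, d[1] * d[2], d[4])
        dim(y) <- d
        list(y = y, cache = list(eps = eps, d = d), mod = mod)
      } else {
        list(y = x, cache = list(eps = NULL, d = dim(x)), mod = mod)
      }
    },
    tanh01 = { t <- tanh(x); list(y = (t + 1) / 2, cache = list(t = t), mod = mod) },
    tanh   = { t <- tanh(x); list(y = t, cache = list(t = t), mod = mod) },
    sigmoid = { s <- sigmoid(x); list(y = s, cache = list(s = s), mod = mod) },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(prod(d[1:3]), d[4])
      list(y = y, cache = list(d = d), mod = mod)
    },
    reshape = {
      y <- x; dim(y) <- c(mod$h, mod$w, mod$c, ncol(x))
      list(y = y, cache = list(d = dim(x)), mod = mod)
    },
    stop("unknown module type: ", mod$type)
  )
}

mod_backward <- function(mod, cache, gy, need_gx = TRUE) {
  switch(mod$type,
    conv = {
      Ws <- if (isTRUE(mod$sn)) cache$sn$Ws else mod$W
      r <- cpp_conv2d_bwd(cache$x, Ws, gy, mod$k, mod$s, mod$p, need_gx)
      gW <- if (isTRUE(mod$sn)) .sn_backward(r$gW, cache$sn) else r$gW
      list(gx = if (need_gx) r$gx else NULL, grads = list(W = gW, b = r$gb))
    },
    dense = {
      Ws <- if (isTRUE(mod$sn)) cache$sn$Ws else mod$W
      gW <- gy %*% t(cache$x)
      if (isTRUE(mod$sn)) gW <- .sn_backward(gW, cache$sn)
      gx <- if (need_gx) crossprod(Ws, gy) else NULL
      list(gx = gx, grads = list(W = gW, b = rowSums(gy)))
    },
    bn = {
      hw <- cache$hw; C <- cache$C; B <- cache$B; n <- hw * B
      xhat <- cache$xhat
      ggamma <- .ch_sum(gy * xhat, hw, C, B)
      gbeta <- .ch_sum(gy, hw, C, B)
      gxhat <- gy * .bc_ch(mod$gamma, hw, B)
      if (cache$training) {
        s1 <- .ch_sum(gxhat, hw, C, B)
        s2 <- .ch_sum(gxhat * xhat, hw, C, B)
        gx <- (gxhat - .bc_ch(s1 / n, hw, B) - xhat * .bc_ch(s2 / n, hw, B)) *
          .bc_ch(cache$invstd, hw, B)
      } else {
        gx <- gxhat * .bc_ch(cache$invstd, hw, B)
      }
      dim(gx) <- dim(gy)
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    glu = {
      ga <- gy * cache$sb
      gb <- gy * cache$a * cache$sb * (1 - cache$sb)
      gx <- array(0, cache$d)
      h <- cache$d[3] %/% 2L
      gx[, , seq_len(h), ] <- ga
      gx[, , h + seq_len(h), ] <- gb
      list(gx = gx, grads = NULL)
    },
    lrelu = list(gx = gy * ifelse(cache$pos, 1, mod$alpha), grads = NULL),
    upsample2 = list(gx = cpp_upsample2_bwd(gy), grads = NULL),
    noise = {
      if (is.null(cache$eps)) return(list(gx = gy, grads = NULL))
      d <- cache$d
      gw <- .ch_sum(gy * cache$eps, d[1] * d[2], d[3], d[4])
      list(gx = gy, grads = list(nw = gw))
    },
    tanh01 = list(gx = gy * (1 - cache$t^2) / 2, grads = NULL),
    tanh   = list(gx = gy * (1 - cache$t^2), grads = NULL),
    sigmoid = list(gx = gy * cache$s * (1 - cache$s), grads = NULL),
    flatten = { gx <- gy; dim(gx) <- cache$d; list(gx = gx, grads = NULL) },
    reshape = { gx <- gy; dim(gx) <- cache$d; list(gx = gx, grads = NULL) },
    stop("unknown module type: ", mod$type)
  )
}

seq_forward <- function(mods, x, training = TRUE) {
  caches <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    r <- mod_forward(mods[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    mods[[i]] <- r$mod
  }
  list(y = x, caches = caches, mods = mods)
}

seq_backward <- function(mods, caches, gy, need_gx = TRUE) {
  grads <- vector("list", length(mods))
  for (i in rev(seq_along(mods))) {
    r <- mod_backward(mods[[i]], caches[[i]], gy, need_gx = need_gx || i > 1)
    gy <- r$gx
    grads[i] <- list(r$grads)  # [[<- would drop NULL gradients and misalign
  }
  list(gx = gy, grads = grads)
}

add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  for (i in seq_along(g1)) {
    if (is.null(g1[[i]])) { g1[i] <- list(g2[[i]]); next }
    if (is.null(g2[[i]])) next
    for (nm in names(g1[[i]])) g1[[i]][[nm]] <- g1[[i]][[nm]] + g2[[i]][[nm]]
  }
  g1
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function() list(t = 0L, s = list())

adam_step <- function(mods, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(mods)) {
    g <- grads[[i]]
    if (is.null(g)) next
    key <- as.character(i)
    if (is.null(state$s[[key]])) state$s[[key]] <- list()
    for (nm in names(g)) {
      sl <- state$s[[key]][[nm]]
      if (is.null(sl)) sl <- list(m = g[[nm]] * 0, v = g[[nm]] * 0)
      sl$m <- beta1 * sl$m + (1 - beta1) * g[[nm]]
      sl$v <- beta2 * sl$v + (1 - beta2) * g[[nm]]^2
      mods[[i]][[nm]] <- mods[[i]][[nm]] - lr * (sl$m / c1) / (sqrt(sl$v / c2) + eps)
      state$s[[key]][[nm]] <- sl
    }
  }
  list(mods = mods, state = state)
}
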