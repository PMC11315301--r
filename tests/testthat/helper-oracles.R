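# Brute-force reference implementations used as independent oracles.
# These deliberately share no code with the package internals: everything is
# plain-R looping over pixels.

oracle_dilate <- function(m, se) {
  H <- nrow(m); W <- ncol(m); r <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- FALSE
    for (a in -r:r) for (b in -r:r) {
      if (se[a + r + 1, b + r + 1]) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && m[ii, jj]) v <- TRUE
      }
    }
    out[i, j] <- v
  }
  out
}

oracle_erode <- function(m, se, outside = TRUE) {
  H <- nrow(m); W <- ncol(m); r <- (nrow(se) - 1) / 2
  out <- matrix(TRUE, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- TRUE
    for (a in -r:r) for (b in -r:r) {
      if (se[a + r + 1, b + r + 1]) {
        ii <- i + a; jj <- j + b
        val <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) m[ii, jj] else outside
        if (!val) v <- FALSE
      }
    }
    out[i, j] <- v
  }
  out
}

# disk-brush closing: dilation pads with background, erosion with foreground
oracle_closing <- function(m, radius) {
  if (radius == 0) return(m)
  se <- EBImage::makeBrush(2L * radius + 1L, "disc") > 0
  oracle_erode(oracle_dilate(m, se), se, outside = TRUE)
}

oracle_disk_area <- function(radius) {
  if (radius <= 0) return(0L)
  n <- 0L
  for (i in -ceiling(radius):ceiling(radius))
    for (j in -ceiling(radius):ceiling(radius))
      if (i * i + j * j <= radius^2) n <- n + 1L
  n
}

# 26-connectivity flood fill over a [H,W,S] logical array
oracle_label3d <- function(stack) {
  d <- dim(stack)
  lab <- array(0L, d)
  nxt <- 0L
  for (s0 in 1:d[3]) for (j0 in 1:d[2]) for (i0 in 1:d[1]) {
    if (!stack[i0, j0, s0] || lab[i0, j0, s0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0, s0))
    lab[i0, j0, s0] <- nxt
    while (length(queue) > 0) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) for (ds in -1:1) {
        if (di == 0 && dj == 0 && ds == 0) next
        ii <- v[1] + di; jj <- v[2] + dj; ss <- v[3] + ds
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || ss < 1 || ss > d[3]) next
        if (stack[ii, jj, ss] && lab[ii, jj, ss] == 0L) {
          lab[ii, jj, ss] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj, ss)
        }
      }
    }
  }
  lab
}

# plain-R convolution (stride/pad), matching no internal code path
oracle_conv2d <- function(x, W, b, k, stride, pad) {
  # x: [H,W,C]; W: Cout x (k*k*C) with column order (kh, kw, c); b: Cout
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  Cout <- nrow(W)
  y <- array(0, c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (cc in 1:C) for (kw in 1:k) for (kh in 1:k) {
      hi <- (ho - 1) * stride + kh - pad
      wi <- (wo - 1) * stride + kw - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd) {
        col <- (kh - 1) + k * (kw - 1) + k * k * (cc - 1) + 1
        acc <- acc + W[co, col] * x[hi, wi, cc]
      }
    }
    y[ho, wo, co] <- acc
  }
  y
}

# from-scratch recomputation of the random-conv perceptual distance
oracle_percept <- function(a, b) {
  bk <- pseudohealthy:::percept_backend("random_conv")
  run <- function(img) {
    x <- array(img, c(nrow(img), ncol(img), 1))
    feats <- list()
    for (i in seq_along(bk$mods)) {
      m <- bk$mods[[i]]
      if (m$type == "conv") {
        x <- oracle_conv2d(x, m$W, m$b, m$k, m$s, m$p)
      } else if (m$type == "lrelu") {
        x <- ifelse(x > 0, x, m$alpha * x)
        if (i %in% bk$taps) feats[[length(feats) + 1L]] <- x
      }
    }
    feats
  }
  normalize <- function(f) {
    d <- dim(f)
    out <- f
    for (i in 1:d[1]) for (j in 1:d[2]) {
      ss <- sum(f[i, j, ]^2)
      out[i, j, ] <- f[i, j, ] / sqrt(ss + 1e-8)
    }
    out
  }
  fa <- run(a); fb <- run(b)
  total <- 0
  for (l in seq_along(fa))
    total <- total + mean((normalize(fa[[l]]) - normalize(fb[[l]]))^2)
  total
}

# random binary mask with exactly `area` lit pixels
random_mask_of_area <- function(dim2, area) {
  m <- matrix(FALSE, dim2[1], dim2[2])
  if (area > 0) m[sample.int(prod(dim2), min(area, prod(dim2)))] <- TRUE
  m
}
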