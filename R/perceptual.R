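# Perceptual distance with pluggable feature backends.
#
# The distance follows the LPIPS recipe: run both images through a fixed
# convolutional feature extractor, unit-normalize the features along the
# channel axis at every spatial position, and average the squared differences
# of the normalized features, summed over the tapped layers.  The default
# backend is a fixed-seed stack of random convolution filters: random-feature
# distances of this kind are a self-contained, dependency-free instance of the
# same family of metrics and keep the package fully offline.  Alternative
# extractors can be registered under a new name via
# `register_percept_backend()` without touching any caller.

.percept_registry <- new.env(parent = emptyenv())

#' Register a perceptual-distance feature backend
#'
#' @param name backend identifier.
#' @param builder function() returning a list with elements `mods` (module
#'   list understood by the internal layer engine) and `taps` (indices of
#'   modules whose outputs are compared).
#' @export
register_percept_backend <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  assign(name, builder, envir = .percept_registry)
  invisible(name)
}

percept_backend <- function(name) {
  if (!exists(name, envir = .percept_registry, inherits = FALSE))
    stop("unknown perceptual backend: '", name, "'")
  key <- paste0(".built.", name)
  if (!exists(key, envir = .percept_registry, inherits = FALSE)) {
    b <- get(name, envir = .percept_registry)()
    assign(key, b, envir = .percept_registry)
  }
  get(key, envir = .percept_registry)
}

.build_random_conv_backend <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(104729L)  # fixed filters: the backend is a constant of the package
  mods <- list(
    nn_conv(1, 8, 5, 2, 2), nn_lrelu(),
    nn_conv(8, 16, 3, 2, 1), nn_lrelu(),
    nn_conv(16, 32, 3, 2, 1), nn_lrelu()
  )
  list(mods = mods, taps = c(2L, 4L, 6L))
}

.norm_eps <- 1e-8

# channel-unit normalization of an [H,W,C,B] array; returns value + cache
.chan_normalize <- function(f) {
  d <- dim(f); hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  a <- array(f * f, c(hw, C, B))
  ss <- matrix(0, hw, B)
  for (cc in seq_len(C)) ss <- ss + a[, cc, , drop = TRUE]
  r <- 1 / sqrt(ss + .norm_eps)                      # hw x B
  rb <- array(0, c(hw, C, B))
  for (cc in seq_len(C)) rb[, cc, ] <- r
  dim(rb) <- d
  fn <- f * rb
  list(fn = fn, r = rb, f = f, d = d)
}

.chan_normalize_bwd <- function(cache, gfn) {
  # fn = f * r with r = (sum_c f^2 + eps)^(-1/2)
  d <- cache$d; hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  a <- array(gfn * cache$f, c(hw, C, B))
  dot <- matrix(0, hw, B)
  for (cc in seq_len(C)) dot <- dot + a[, cc, , drop = TRUE]
  db <- array(0, c(hw, C, B))
  for (cc in seq_len(C)) db[, cc, ] <- dot
  dim(db) <- d
  gfn * cache$r - cache$f * cache$r^3 * db
}

# forward pass collecting tapped outputs
.percept_run <- function(backend, x) {
  mods <- backend$mods
  caches <- vector("list", length(mods))
  taps <- list()
  for (i in seq_along(mods)) {
    r <- mod_forward(mods[[i]], x, training = FALSE)
    x <- r$y
    caches[[i]] <- r$cache
    if (i %in% backend$taps) taps[[length(taps) + 1L]] <- x
  }
  list(taps = taps, caches = caches)
}

#' Perceptual distance between two images
#'
#' Symmetric, non-negative, and zero for identical inputs.  `a` and `b` are
#' unit-scale matrices (or [H,W,1,B] arrays) of equal shape.
#'
#' @param a,b images to compare.
#' @param backend name of a registered feature backend.
#' @return scalar distance (averaged over the batch if batched input).
#' @export
perceptual_distance <- function(a, b, backend = "random_conv") {
  perceptual_forward(a, b, backend)$value
}

as_batch_array <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
    return(x)
  }
  if (length(dim(x)) == 4L) return(x)
  stop("expected a matrix or an [H,W,C,B] array")
}

#' @keywords internal
perceptual_forward <- function(a, b, backend = "random_conv") {
  bk <- percept_backend(backend)
  a <- as_batch_array(a); b <- as_batch_array(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  ra <- .percept_run(bk, a)
  rb <- .percept_run(bk, b)
  terms <- vector("list", length(bk$taps))
  value <- 0
  for (l in seq_along(bk$taps)) {
    na <- .chan_normalize(ra$taps[[l]])
    nb <- .chan_normalize(rb$taps[[l]])
    diff <- na$fn - nb$fn
    value <- value + mean(diff * diff)
    terms[[l]] <- list(na = na, nb = nb, diff = diff)
  }
  list(value = value,
       cache = list(bk = bk, ra = ra, rb = rb, terms = terms, d = dim(a)))
}

# gradient of `scale * distance` w.r.t. `a` (and optionally `b`)
#' @keywords internal
perceptual_backward <- function(cache, scale = 1, wrt_b = FALSE) {
  bk <- cache$bk
  if (is.null(bk)) stop("perceptual_backward expects the $cache of perceptual_forward()")
  ga_taps <- vector("list", length(bk$mods))
  gb_taps <- vector("list", length(bk$mods))
  for (l in seq_along(bk$taps)) {
    tm <- cache$terms[[l]]
    g <- (2 * scale / length(tm$diff)) * tm$diff
    ga_taps[[bk$taps[l]]] <- .chan_normalize_bwd(tm$na, g)
    if (wrt_b) gb_taps[[bk$taps[l]]] <- .chan_normalize_bwd(tm$nb, -g)
  }
  ga <- .percept_backprop(bk, cache$ra$caches, ga_taps)
  gb <- if (wrt_b) .percept_backprop(bk, cache$rb$caches, gb_taps) else NULL
  list(ga = ga, gb = gb)
}

.percept_backprop <- function(bk, caches, tap_grads) {
  gy <- NULL
  for (i in rev(seq_along(bk$mods))) {
    if (!is.null(tap_grads[[i]]))
      gy <- if (is.null(gy)) tap_grads[[i]] else gy + tap_grads[[i]]
    r <- mod_backward(bk$mods[[i]], caches[[i]], gy, need_gx = TRUE)
    gy <- r$gx
  }
  gy
}
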