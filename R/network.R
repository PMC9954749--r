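# Network engine: parameter containers, forward and backward passes.
#
# Tensors are dense arrays in (H, W, C, N) layout; the convolution and
# pooling kernels are compiled (src/nn_kernels.cpp), everything else (ReLU,
# channel concat, batch norm, GAP, dense head, softmax) is plain R. The
# topology is fixed by the spec: pairs of blocks, pair fusion + 2x2 average
# pooling, parameter-free average-pool bridges from every pooled pair output
# down to the final spatial size, stage fusion, GAP, dense softmax head.

.relu <- function(x) x * (x > 0)

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Evaluate code under a fixed RNG state without disturbing the caller's.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform fan-in initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
.init_tensor <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a trainable model from an architecture spec
#'
#' Allocates and seeds every trainable tensor: per block the 5x5 and 3x3
#' convolution kernels and biases, the 1x1 bottleneck kernel and bias, and
#' the batch-norm scale/shift; plus the dense softmax head. Weights use a
#' uniform fan-in scheme, biases start at zero, batch-norm at
#' (scale 1, shift 0). Two builds from the same spec and seed are identical.
#'
#' @param spec a \code{\link{fabnet_spec}}.
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{"fabnet_model"}: the spec, a flat named
#'   list of trainable parameter arrays, and batch-norm running statistics.
#' @export
build_model <- function(spec, seed = 1L) {
  validate_fabnet_spec(spec)
  plan <- spec_channel_plan(spec)
  params <- list()
  state <- list()
  .with_seed(seed, {
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      cin <- plan$in_ch[i]; f <- b$filters_parallel; r <- b$reduce_width
      id <- paste0("b", i)
      params[[paste0(id, ".W5")]] <- .init_tensor(c(5, 5, cin, f), 25 * cin)
      params[[paste0(id, ".b5")]] <- numeric(f)
      params[[paste0(id, ".W3")]] <- .init_tensor(c(3, 3, cin, f), 9 * cin)
      params[[paste0(id, ".b3")]] <- numeric(f)
      params[[paste0(id, ".W1")]] <- .init_tensor(c(1, 1, 2 * f, r), 2 * f)
      params[[paste0(id, ".b1")]] <- numeric(r)
      if (b$use_batch_norm) {
        params[[paste0(id, ".gamma")]] <- rep(1, r)
        params[[paste0(id, ".beta")]] <- numeric(r)
        state[[paste0(id, ".rmean")]] <- numeric(r)
        state[[paste0(id, ".rvar")]] <- rep(1, r)
      }
    }
    k <- spec$head_classes
    params[["head.W"]] <- matrix(stats::runif(k * plan$fusion_ch,
                                              -sqrt(6 / plan$fusion_ch),
                                              sqrt(6 / plan$fusion_ch)),
                                 nrow = k)
    params[["head.b"]] <- numeric(k)
  })
  structure(list(spec = spec, params = params, state = state, seed = seed),
            class = "fabnet_model")
}

#' @export
print.fabnet_model <- function(x, ...) {
  cat("Built feature-agglomeration model\n")
  cat("  trainable parameters:",
      format(count_trainable_parameters(x), big.mark = ","), "\n")
  cat("  conv layers:", count_conv_layers(x$spec), "\n")
  cat("  head classes:", x$spec$head_classes, "\n")
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' Sums the lengths of every trainable tensor actually allocated in the
#' model (convolution weights and biases, batch-norm scale and shift, dense
#' weights and biases). Batch-norm running statistics are not trainable and
#' are excluded. Cross-checked in the test suite against the closed-form
#' \code{\link{spec_parameter_count}}.
#'
#' @param model a \code{"fabnet_model"}.
#' @return Total number of trainable scalars.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "fabnet_model"))
  sum(vapply(model$params, length, numeric(1)))
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

.bn_forward <- function(x, gamma, beta, training, rmean, rvar) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- rmean; v <- rvar
  }
  ivar <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  yarr <- aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = yarr, xhat = xhat, ivar = ivar, mu = mu, v = v, dims = d)
}

.bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- sweep(dxhat, 2, s1 / m) - sweep(cache$xhat, 2, s2 / m, "*")
  dxm <- sweep(dxm, 2, cache$ivar, "*")
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.block_forward <- function(x, params, state, id, block, training) {
  a5 <- .relu(.conv2d_forward(x, params[[paste0(id, ".W5")]],
                              params[[paste0(id, ".b5")]]))
  a3 <- .relu(.conv2d_forward(x, params[[paste0(id, ".W3")]],
                              params[[paste0(id, ".b3")]]))
  cc <- .concat_ch(a5, a3)
  r <- .conv2d_forward(cc, params[[paste0(id, ".W1")]],
                       params[[paste0(id, ".b1")]])
  bn_cache <- NULL
  new_state <- NULL
  if (block$use_batch_norm) {
    bn <- .bn_forward(r, params[[paste0(id, ".gamma")]],
                      params[[paste0(id, ".beta")]], training,
                      state[[paste0(id, ".rmean")]],
                      state[[paste0(id, ".rvar")]])
    if (training) {
      new_state <- list(
        rmean = (1 - .bn_momentum) * state[[paste0(id, ".rmean")]] +
          .bn_momentum * bn$mu,
        rvar = (1 - .bn_momentum) * state[[paste0(id, ".rvar")]] +
          .bn_momentum * bn$v)
    }
    pre <- bn$out
    bn_cache <- bn[c("xhat", "ivar", "mu", "v", "dims")]
  } else {
    pre <- r
  }
  out <- .relu(pre)
  list(out = out,
       cache = list(x = x, a5 = a5, a3 = a3, cc = cc, out = out,
                    bn = bn_cache),
       new_state = new_state)
}

.block_backward <- function(dout, cache, params, id, block) {
  dpre <- dout * (cache$out > 0)
  grads <- list()
  if (block$use_batch_norm) {
    bb <- .bn_backward(dpre, cache$bn, params[[paste0(id, ".gamma")]])
    dr <- bb$dx
    grads[[paste0(id, ".gamma")]] <- bb$dgamma
    grads[[paste0(id, ".beta")]] <- bb$dbeta
  } else {
    dr <- dpre
  }
  c1 <- .conv2d_backward(cache$cc, params[[paste0(id, ".W1")]], dr)
  grads[[paste0(id, ".W1")]] <- c1$dw
  grads[[paste0(id, ".b1")]] <- c1$db
  f <- block$filters_parallel
  da5 <- c1$dx[, , seq_len(f), , drop = FALSE] * (cache$a5 > 0)
  da3 <- c1$dx[, , f + seq_len(f), , drop = FALSE] * (cache$a3 > 0)
  c5 <- .conv2d_backward(cache$x, params[[paste0(id, ".W5")]], da5)
  c3 <- .conv2d_backward(cache$x, params[[paste0(id, ".W3")]], da3)
  grads[[paste0(id, ".W5")]] <- c5$dw
  grads[[paste0(id, ".b5")]] <- c5$db
  grads[[paste0(id, ".W3")]] <- c3$dw
  grads[[paste0(id, ".b3")]] <- c3$db
  list(dx = c5$dx + c3$dx, grads = grads)
}

.softmax_cols <- function(L) {
  L <- sweep(L, 2, apply(L, 2, max))
  E <- exp(L)
  sweep(E, 2, colSums(E), "/")
}

# Full forward pass. x: (H, W, C, N). Returns class probabilities (N x K),
# the shape trace of every named tensor, per-layer caches when keep_cache,
# and updated batch-norm running statistics when training.
.forward_full <- function(model, x, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  n_pairs <- length(spec$pairs)
  d <- dim(x)
  if (length(d) != 4) stop("input must be a (H, W, C, N) array")
  if (d[3] != spec$input_shape[3])
    stop("input has ", d[3], " channels; spec expects ", spec$input_shape[3])
  if (any(d[1:2] %% 2^n_pairs != 0))
    stop("input spatial size ", d[1], "x", d[2],
         " is not divisible by 2^", n_pairs, " (one pooling per pair)")
  params <- model$params
  state <- model$state
  shapes <- list()
  caches <- list()
  taps <- vector("list", n_pairs)
  z <- x
  for (p in seq_len(n_pairs)) {
    a <- spec$pairs[[p]][1]; b <- spec$pairs[[p]][2]
    fa <- .block_forward(z, params, state, paste0("b", a),
                         spec$blocks[[a]], training)
    fb <- .block_forward(fa$out, params, state, paste0("b", b),
                         spec$blocks[[b]], training)
    if (training) {
      for (nm in names(fa$new_state))
        state[[paste0("b", a, ".", nm)]] <- fa$new_state[[nm]]
      for (nm in names(fb$new_state))
        state[[paste0("b", b, ".", nm)]] <- fb$new_state[[nm]]
    }
    fused <- .concat_ch(fa$out, fb$out)
    z <- .avgpool_forward(fused, 2L)
    taps[[p]] <- z
    shapes[[paste0("B", a)]] <- dim(fa$out)[1:3]
    shapes[[paste0("B", b)]] <- dim(fb$out)[1:3]
    shapes[[paste0("pair", p, "_concat")]] <- dim(fused)[1:3]
    shapes[[paste0("pair", p, "_pool")]] <- dim(z)[1:3]
    if (keep_cache)
      caches[[p]] <- list(a = fa$cache, b = fb$cache)
  }
  # parameter-free bridges: pool every tap down to the final spatial size
  bridges <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    fac <- 2L^(n_pairs - p)
    bridges[[p]] <- if (fac > 1L) .avgpool_forward(taps[[p]], fac)
                    else taps[[p]]
    shapes[[spec$stage_taps[p]]] <- dim(bridges[[p]])[1:3]
  }
  fusion <- Reduce(.concat_ch, bridges)
  shapes[["stage_fusion"]] <- dim(fusion)[1:3]
  fd <- dim(fusion)
  G <- matrix(colMeans(matrix(fusion, nrow = fd[1] * fd[2])),
              nrow = fd[3], ncol = fd[4])
  shapes[["gap"]] <- c(1L, 1L, fd[3])
  logits <- params[["head.W"]] %*% G + params[["head.b"]]
  probs <- .softmax_cols(logits)
  shapes[["head"]] <- c(1L, 1L, nrow(logits))
  list(probs = t(probs), logits = logits, gap = G,
       shapes = lapply(shapes, as.integer),
       caches = if (keep_cache) caches else NULL,
       fusion_dim = fd, state = state)
}

# Backward pass for softmax cross-entropy. fw must come from .forward_full
# with keep_cache = TRUE and training = TRUE; y is an integer class vector
# (1..K). Returns mean loss and gradients for every trainable parameter.
.backward_full <- function(model, fw, y) {
  spec <- model$spec
  n_pairs <- length(spec$pairs)
  params <- model$params
  N <- length(y)
  K <- spec$head_classes
  P <- t(fw$probs)                      # K x N
  loss <- -mean(log(pmax(P[cbind(y, seq_len(N))], 1e-12)))
  dL <- P
  dL[cbind(y, seq_len(N))] <- dL[cbind(y, seq_len(N))] - 1
  dL <- dL / N
  grads <- list()
  grads[["head.W"]] <- dL %*% t(fw$gap)
  grads[["head.b"]] <- rowSums(dL)
  dG <- t(params[["head.W"]]) %*% dL    # C x N
  fd <- fw$fusion_dim
  hw <- fd[1] * fd[2]
  dfusion <- array(rep(as.vector(dG), each = hw) / hw, dim = fd)
  # split stage-fusion gradient back onto the bridges, undo the bridge pools
  plan <- spec_channel_plan(spec)
  dtap <- vector("list", n_pairs)
  off <- 0L
  for (p in seq_len(n_pairs)) {
    ch <- plan$pair_ch[p]
    dbr <- dfusion[, , off + seq_len(ch), , drop = FALSE]
    off <- off + ch
    fac <- 2L^(n_pairs - p)
    dtap[[p]] <- if (fac > 1L) .avgpool_backward(dbr, fac) else dbr
  }
  for (p in rev(seq_len(n_pairs))) {
    a <- spec$pairs[[p]][1]; b <- spec$pairs[[p]][2]
    dfused <- .avgpool_backward(dtap[[p]], 2L)
    ch_a <- spec$blocks[[a]]$reduce_width
    du <- dfused[, , seq_len(ch_a), , drop = FALSE]
    dv <- dfused[, , ch_a + seq_len(spec$blocks[[b]]$reduce_width), ,
                 drop = FALSE]
    bb <- .block_backward(dv, fw$caches[[p]]$b, params, paste0("b", b),
                          spec$blocks[[b]])
    grads <- c(grads, bb$grads)
    du <- du + bb$dx
    ba <- .block_backward(du, fw$caches[[p]]$a, params, paste0("b", a),
                          spec$blocks[[a]])
    grads <- c(grads, ba$grads)
    if (p > 1L) dtap[[p - 1L]] <- dtap[[p - 1L]] + ba$dx
  }
  list(loss = loss, grads = grads)
}

#' Forward pass: class probabilities for a batch of images
#'
#' Runs the network in inference mode (batch norm uses running statistics)
#' and returns one probability row per sample; rows sum to 1.
#'
#' @param model a built \code{"fabnet_model"}.
#' @param x array (height, width, channels, n) of pixel values in [0, 1].
#' @return Numeric matrix (n x head_classes) of softmax probabilities.
#' @export
model_predict_probs <- function(model, x) {
  stopifnot(inherits(model, "fabnet_model"))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  .forward_full(model, x, training = FALSE)$probs
}

#' Probe tensor shapes of a built model
#'
#' Runs a real forward pass on a zero batch and reports the observed
#' (height, width, channels) of every named tensor, for comparison with the
#' static trace from \code{\link{infer_feature_shapes}}.
#'
#' @param model a \code{"fabnet_model"}.
#' @param input_shape (height, width, channels); defaults to the spec's.
#' @return Named list of integer shape vectors.
#' @export
probe_feature_shapes <- function(model, input_shape = model$spec$input_shape) {
  x <- array(0, dim = c(input_shape, 1L))
  .forward_full(model, x, training = FALSE)$shapes
}
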