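# Internal neural-network engine.
#
# Batches of sequences are stored as a (channels x time*batch) matrix with
# columns grouped sample-major: sample b occupies columns ((b-1)*T+1):(b*T),
# time running fastest. Every layer is expressed through BLAS matrix products
# so that training stays fast in plain R. Backward passes are written by hand
# (no autodiff dependency is available, and the layers are few).

# Shift a batch matrix s steps into the past: output column (b, t) holds input
# column (b, t - s), zero where t <= s. Equivalent to left zero-padding.
shift_time <- function(X, t_len, b_n, s) {
  if (s == 0L) return(X)
  out <- matrix(0, nrow(X), ncol(X))
  if (s >= t_len) return(out)
  t_idx <- rep.int(seq_len(t_len), b_n)
  keep <- which(t_idx > s)
  out[, keep] <- X[, keep - s]
  out
}

# Adjoint of shift_time: scatter gradient columns back to their sources.
unshift_time <- function(M, t_len, b_n, s) {
  if (s == 0L) return(M)
  out <- matrix(0, nrow(M), ncol(M))
  if (s >= t_len) return(out)
  t_idx <- rep.int(seq_len(t_len), b_n)
  keep <- which(t_idx > s)
  out[, keep - s] <- M[, keep]
  out
}

# --- causal dilated 1-D convolution -----------------------------------------
# Weights: list of k matrices (c_out x c_in), one per tap; tap i uses input
# lagged by d*(i-1). Bias: length c_out.

conv1d_fwd <- function(X, W, b, d, t_len, b_n) {
  out <- W[[1L]] %*% X
  k <- length(W)
  if (k > 1L) {
    for (i in 2:k) out <- out + W[[i]] %*% shift_time(X, t_len, b_n, d * (i - 1L))
  }
  out + b
}

conv1d_bwd <- function(dOut, X, W, d, t_len, b_n) {
  k <- length(W)
  dW <- vector("list", k)
  dW[[1L]] <- dOut %*% t(X)
  dX <- crossprod(W[[1L]], dOut)
  if (k > 1L) {
    for (i in 2:k) {
      s <- d * (i - 1L)
      dW[[i]] <- dOut %*% t(shift_time(X, t_len, b_n, s))
      dX <- dX + unshift_time(crossprod(W[[i]], dOut), t_len, b_n, s)
    }
  }
  list(dW = dW, db = rowSums(dOut), dX = dX)
}

init_conv1d <- function(c_in, c_out, k) {
  sd <- sqrt(2 / (c_in * k))
  W <- lapply(seq_len(k), function(i) matrix(rnorm(c_out * c_in, sd = sd), c_out, c_in))
  list(W = W, b = rep(0, c_out))
}

# --- layer normalization (per time step, across channels) -------------------

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colMeans(Xc * Xc)
  istd <- 1 / sqrt(v + eps)
  Xn <- sweep(Xc, 2L, istd, "*")
  list(out = Xn * gamma + beta, Xn = Xn, istd = istd)
}

layernorm_bwd <- function(dOut, cache, gamma) {
  Xn <- cache$Xn
  dgamma <- rowSums(dOut * Xn)
  dbeta <- rowSums(dOut)
  dXn <- dOut * gamma
  n <- nrow(Xn)
  # standard layer-norm backward, per column
  term <- sweep(dXn, 2L, colMeans(dXn)) - Xn * rep(colMeans(dXn * Xn), each = n)
  dX <- sweep(term, 2L, cache$istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- 1-D spatial dropout: drop whole feature maps per sample ----------------

spatial_dropout_mask <- function(c_n, t_len, b_n, rate) {
  keep <- matrix(rbinom(c_n * b_n, 1L, 1 - rate), c_n, b_n) / (1 - rate)
  keep[, rep(seq_len(b_n), each = t_len), drop = FALSE]
}

# --- residual block ---------------------------------------------------------
# conv -> (norm) -> relu -> spatial dropout, twice; skip path is identity when
# channel counts match, otherwise a 1x1 convolution so widths agree.

init_block <- function(c_in, c_out, k, use_norm) {
  p <- list(
    c1 = init_conv1d(c_in, c_out, k),
    c2 = init_conv1d(c_out, c_out, k)
  )
  if (use_norm) {
    p$n1 <- list(gamma = rep(1, c_out), beta = rep(0, c_out))
    p$n2 <- list(gamma = rep(1, c_out), beta = rep(0, c_out))
  }
  if (c_in != c_out) p$proj <- init_conv1d(c_in, c_out, 1L)
  p
}

block_fwd <- function(X, P, d, cfg, t_len, b_n, training, keep_cache = training) {
  k <- cfg$kernel_size
  cache <- if (keep_cache) list(X = X) else NULL
  Z1 <- conv1d_fwd(X, P$c1$W, P$c1$b, d, t_len, b_n)
  if (!is.null(P$n1)) {
    ln1 <- layernorm_fwd(Z1, P$n1$gamma, P$n1$beta)
    Z1 <- ln1$out
    if (keep_cache) cache$ln1 <- ln1
  }
  M1 <- Z1 > 0
  A1 <- Z1 * M1
  if (training && cfg$spatial_dropout > 0) {
    D1 <- spatial_dropout_mask(nrow(A1), t_len, b_n, cfg$spatial_dropout)
    A1 <- A1 * D1
  } else D1 <- NULL
  Z2 <- conv1d_fwd(A1, P$c2$W, P$c2$b, d, t_len, b_n)
  if (!is.null(P$n2)) {
    ln2 <- layernorm_fwd(Z2, P$n2$gamma, P$n2$beta)
    Z2 <- ln2$out
    if (keep_cache) cache$ln2 <- ln2
  }
  M2 <- Z2 > 0
  A2 <- Z2 * M2
  if (training && cfg$spatial_dropout > 0) {
    D2 <- spatial_dropout_mask(nrow(A2), t_len, b_n, cfg$spatial_dropout)
    A2 <- A2 * D2
  } else D2 <- NULL
  S <- if (!is.null(P$proj)) conv1d_fwd(X, P$proj$W, P$proj$b, 1L, t_len, b_n) else X
  if (keep_cache) {
    cache$M1 <- M1; cache$D1 <- D1; cache$A1 <- A1
    cache$M2 <- M2; cache$D2 <- D2
  }
  list(out = A2 + S, cache = cache)
}

block_bwd <- function(dOut, P, cache, d, cfg, t_len, b_n) {
  g <- list()
  dA2 <- if (!is.null(cache$D2)) dOut * cache$D2 else dOut
  dZ2 <- dA2 * cache$M2
  if (!is.null(P$n2)) {
    ln <- layernorm_bwd(dZ2, cache$ln2, P$n2$gamma)
    g$n2 <- list(gamma = ln$dgamma, beta = ln$dbeta)
    dZ2 <- ln$dX
  }
  b2 <- conv1d_bwd(dZ2, cache$A1, P$c2$W, d, t_len, b_n)
  g$c2 <- list(W = b2$dW, b = b2$db)
  dA1 <- if (!is.null(cache$D1)) b2$dX * cache$D1 else b2$dX
  dZ1 <- dA1 * cache$M1
  if (!is.null(P$n1)) {
    ln <- layernorm_bwd(dZ1, cache$ln1, P$n1$gamma)
    g$n1 <- list(gamma = ln$dgamma, beta = ln$dbeta)
    dZ1 <- ln$dX
  }
  b1 <- conv1d_bwd(dZ1, cache$X, P$c1$W, d, t_len, b_n)
  g$c1 <- list(W = b1$dW, b = b1$db)
  dX <- b1$dX + if (!is.null(P$proj)) {
    bp <- conv1d_bwd(dOut, cache$X, P$proj$W, 1L, t_len, b_n)
    g$proj <- list(W = bp$dW, b = bp$db)
    bp$dX
  } else dOut
  # reorder gradient fields to match parameter skeleton order (c1, c2, n?, proj?)
  ord <- intersect(names(P), names(g))
  list(grad = g[ord], dX = dX)
}

# --- encoder / decoder stacks -----------------------------------------------

stack_dilations <- function(cfg) rep(cfg$dilations, cfg$n_stacks)

init_stack <- function(c_in, cfg) {
  dils <- stack_dilations(cfg)
  blocks <- vector("list", length(dils))
  ci <- c_in
  for (i in seq_along(dils)) {
    blocks[[i]] <- init_block(ci, cfg$n_filters, cfg$kernel_size, isTRUE(cfg$use_normalization))
    ci <- cfg$n_filters
  }
  blocks
}

# The compiled kernels cover the default configuration (no normalization
# layer, matching the published setup); the R path above is the reference
# implementation and also serves the layer-normalization variant.
use_fast_path <- function(cfg) !isTRUE(cfg$use_normalization)

stack_fwd <- function(X, blocks, cfg, t_len, b_n, training, keep_cache = training) {
  dils <- stack_dilations(cfg)
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  fast <- use_fast_path(cfg)
  for (i in seq_along(blocks)) {
    r <- if (fast) {
      cpp_block_fwd(X, blocks[[i]], dils[i], cfg$kernel_size,
                    cfg$spatial_dropout, t_len, b_n, training, keep_cache)
    } else {
      block_fwd(X, blocks[[i]], dils[i], cfg, t_len, b_n, training, keep_cache)
    }
    X <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

stack_bwd <- function(dOut, blocks, caches, cfg, t_len, b_n) {
  dils <- stack_dilations(cfg)
  grads <- vector("list", length(blocks))
  fast <- use_fast_path(cfg)
  for (i in rev(seq_along(blocks))) {
    r <- if (fast) {
      cpp_block_bwd(dOut, blocks[[i]], caches[[i]], dils[i], t_len, b_n)
    } else {
      block_bwd(dOut, blocks[[i]], caches[[i]], dils[i], cfg, t_len, b_n)
    }
    grads[[i]] <- r$grad
    dOut <- r$dX
  }
  list(grads = grads, dX = dOut)
}

# --- receptive-field-pruned encoder -----------------------------------------
# Only the final time step of the encoder output feeds the latent state, so
# each block needs outputs at a few columns only. These index sets are
# computed once per (sequence length, config) and drive the gathered-column
# kernels; the result is identical to the dense path at the kept columns.

encoder_prune_maps <- function(t_len, cfg) {
  dils <- stack_dilations(cfg)
  k <- cfg$kernel_size
  taps <- 0:(k - 1L)
  need <- t_len # absolute time indices needed from the top block
  maps <- vector("list", length(dils))
  for (i in rev(seq_along(dils))) {
    d <- dils[i]
    N <- need
    M <- sort(unique(as.vector(outer(N, -d * taps, "+"))))
    M <- M[M >= 1L]
    L <- sort(unique(as.vector(outer(M, -d * taps, "+"))))
    L <- L[L >= 1L]
    maps[[i]] <- list(
      m1 = lapply(taps, function(s) match(M - d * s, L, nomatch = 0L)),
      m2 = lapply(taps, function(s) match(N - d * s, M, nomatch = 0L)),
      skip = match(N, L, nomatch = 0L),
      nL = length(L), nM = length(M), nN = length(N)
    )
    need <- L
  }
  list(blocks = maps, input_cols = need)
}

# Gather the needed raw-input columns of a dense (C x T*B) batch.
gather_input_cols <- function(X, input_cols, t_len, b_n) {
  idx <- as.vector(outer(input_cols, (seq_len(b_n) - 1L) * t_len, "+"))
  X[, idx, drop = FALSE]
}

# Pruned encoder; returns latent (n_filters x B). Requires the fast path.
encoder_fwd_pruned <- function(X, blocks, pm, cfg, t_len, b_n, training,
                               keep_cache = training) {
  Xg <- gather_input_cols(X, pm$input_cols, t_len, b_n)
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  for (i in seq_along(blocks)) {
    r <- cpp_pblock_fwd(Xg, blocks[[i]], pm$blocks[[i]], cfg$spatial_dropout,
                        b_n, training, keep_cache)
    Xg <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(latent = Xg, caches = caches)
}

# Backward through the pruned encoder. Input gradients are never needed
# (inputs are data), so the bottom block skips them.
encoder_bwd_pruned <- function(dLatent, blocks, caches, pm, b_n) {
  grads <- vector("list", length(blocks))
  dOut <- dLatent
  for (i in rev(seq_along(blocks))) {
    r <- cpp_pblock_bwd(dOut, blocks[[i]], caches[[i]], pm$blocks[[i]], b_n,
                        want_dX = i > 1L)
    grads[[i]] <- r$grad
    if (i > 1L) dOut <- r$dX
  }
  grads
}

# Latent state: feature vector at the final time step of each sample.
take_last_step <- function(X, t_len, b_n) {
  X[, t_len * seq_len(b_n), drop = FALSE]
}

scatter_last_step <- function(dLatent, t_len, b_n) {
  out <- matrix(0, nrow(dLatent), t_len * b_n)
  out[, t_len * seq_len(b_n)] <- dLatent
  out
}

# Decoder input: the latent vector repeated f times per sample.
repeat_latent <- function(latent, f) {
  latent[, rep(seq_len(ncol(latent)), each = f), drop = FALSE]
}

sum_latent_grad <- function(dXdec, f, b_n) {
  grp <- rep(seq_len(b_n), each = f)
  t(rowsum(t(dXdec), group = grp, reorder = FALSE))
}

# Convert a (batch x time x channels) array to the engine layout and back.
batch_to_mat <- function(xarr) {
  stopifnot(length(dim(xarr)) == 3L)
  p <- aperm(xarr, c(3L, 2L, 1L))
  dim(p) <- c(dim(xarr)[3L], dim(xarr)[2L] * dim(xarr)[1L])
  p
}

# --- parameter flattening (for Adam and checkpoints) ------------------------
# Hand-rolled: depth-first leaf order, dims preserved; plain lists in, plain
# lists out, fast enough to run once per optimizer step.

flatten_params <- function(p) {
  leaves <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      leaves[[length(leaves) + 1L]] <<- as.numeric(x)
    }
  }
  walk(p)
  unlist(leaves, use.names = FALSE)
}

unflatten_params <- function(vec, skeleton) {
  at <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- vec[(at + 1L):(at + n)]
    at <<- at + n
    dim(out) <- dim(x)
    out
  }
  out <- rec(skeleton)
  abort_if(at != length(vec), "parameter vector length mismatch")
  out
}

# Adam optimizer state over a flat parameter vector.
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad * grad
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}
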