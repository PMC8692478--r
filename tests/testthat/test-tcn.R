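test_that("causal dilated convolution matches its defining sum", {
  # identity kernel
  x <- c(3, 1, 4, 1, 5)
  expect_identical(causal_dilated_conv(x, 1, 1), x)
  # hand evaluation of F(s) = x_s + x_{s-2} with zero padding
  expect_equal(causal_dilated_conv(c(1, 2, 3, 4), c(1, 1), dilation = 2),
               c(1, 2, 4, 6))
  # brute-force oracle on random cases
  withr::local_seed(1)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    k <- sample(1:4, 1)
    d <- sample(1:5, 1)
    xr <- rnorm(n)
    fr <- rnorm(k)
    manual <- vapply(seq_len(n), function(s) {
      sum(vapply(0:(k - 1), function(j) {
        idx <- s - d * j
        fr[j + 1] * if (idx >= 1) xr[idx] else 0
      }, 0))
    }, 0)
    expect_equal(causal_dilated_conv(xr, fr, d), manual, tolerance = 1e-12)
  }
  expect_error(causal_dilated_conv(x, numeric(0), 1), "filter")
  expect_error(causal_dilated_conv(x, 1, 0), "dilation")
})

test_that("convolution output is causal", {
  withr::local_seed(2)
  x <- rnorm(30)
  f <- rnorm(3)
  base <- causal_dilated_conv(x, f, 2)
  for (s0 in c(10, 20, 29)) {
    xp <- x
    xp[s0] <- xp[s0] + 5
    pert <- causal_dilated_conv(xp, f, 2)
    expect_identical(pert[seq_len(s0 - 1)], base[seq_len(s0 - 1)])
    expect_false(isTRUE(all.equal(pert[s0], base[s0])))
  }
})

test_that("residual block reduces to the skip path when the branch is zero", {
  cfg <- tcn_config(n_filters = 8, dilations = c(1, 2), spatial_dropout = 0)
  pb <- init_residual_block(8, cfg, seed = 3)
  pb$c1$W <- lapply(pb$c1$W, function(w) w * 0)
  pb$c2$W <- lapply(pb$c2$W, function(w) w * 0)
  pb$c1$b[] <- 0
  pb$c2$b[] <- 0
  x <- matrix(rnorm(8 * 20), 8, 20)
  expect_equal(residual_block(x, pb, 1, cfg), x)
})

test_that("inference is deterministic; training dropout is stochastic but unbiased", {
  cfg <- tcn_config(n_filters = 8, dilations = c(1, 2), spatial_dropout = 0.3)
  pb <- init_residual_block(3, cfg, seed = 4)
  x <- matrix(rnorm(3 * 15), 3, 15)
  a <- residual_block(x, pb, 2, cfg, training = FALSE)
  b <- residual_block(x, pb, 2, cfg, training = FALSE)
  expect_identical(a, b)
  set.seed(5)
  t1 <- residual_block(x, pb, 2, cfg, training = TRUE)
  t2 <- residual_block(x, pb, 2, cfg, training = TRUE)
  expect_false(identical(t1, t2))
  # inverted spatial dropout masks are unbiased within 5%
  masks <- replicate(600, glucotcn:::spatial_dropout_mask(8, 4, 3, 0.3))
  expect_lt(abs(mean(masks) - 1), 0.05)
})

test_that("the receptive field formula matches perturbation probing", {
  cfg <- tcn_config() # k = 2, dilations 1,2,4: 1 + 2*(1+2+4) = 15
  expect_identical(receptive_field(cfg), 15L)
  expect_identical(receptive_field(tcn_config(kernel_size = 3, dilations = c(1, 2))),
                   13L)

  t_len <- 30L
  measured <- integer(0)
  for (seed in 1:20) {
    cfg8 <- tcn_config(n_filters = 8, spatial_dropout = 0)
    st <- init_tcn_stack(1, cfg8, seed = seed)
    x <- matrix(withr::with_seed(seed, rnorm(t_len)), 1, t_len)
    base <- tcn_encode(x, st, cfg8)
    influences <- vapply(seq_len(t_len), function(pos) {
      xp <- x
      xp[1, pos] <- xp[1, pos] + 1000
      any(tcn_encode(xp, st, cfg8) != base)
    }, TRUE)
    measured <- c(measured, t_len - min(which(influences)) + 1L)
  }
  expect_true(all(measured <= 15L))
  expect_identical(max(measured), 15L)
})

test_that("encoder summarizes causally into the final-step latent", {
  cfg <- tcn_config(n_filters = 8, spatial_dropout = 0)
  st <- init_tcn_stack(2, cfg, seed = 6)
  x <- matrix(rnorm(2 * 20), 2, 20)
  lat <- tcn_encode(x, st, cfg)
  expect_length(lat, 8)
  # zero input with zero biases gives a zero latent
  st0 <- rapply(st, function(v) v * 0, how = "replace")
  expect_equal(tcn_encode(x * 0, st0, cfg), rep(0, 8))
  # appending a step changes the latent
  x2 <- cbind(x, rnorm(2))
  expect_false(isTRUE(all.equal(tcn_encode(x2, st, cfg), lat)))
  # perturbing the final step changes the latent
  xp <- x
  xp[, 20] <- xp[, 20] + 1
  expect_false(isTRUE(all.equal(tcn_encode(xp, st, cfg), lat)))
  expect_error(tcn_encode(matrix(0, 2, 0), st, cfg), "non-empty")
})

test_that("decoder maps a latent to a horizon-length sequence", {
  cfg <- tcn_config(n_filters = 8, spatial_dropout = 0)
  dec <- init_tcn_stack(8, cfg, seed = 7)
  lat <- rnorm(8)
  out <- tcn_decode(lat, 5, dec, cfg)
  expect_identical(dim(out), c(8L, 5L))
  expect_identical(dim(tcn_decode(lat, 1, dec, cfg)), c(8L, 1L))
  # distinct latents decode to distinct outputs
  out2 <- tcn_decode(rnorm(8), 5, dec, cfg)
  expect_false(isTRUE(all.equal(out, out2)))
  # zero latent with zero parameters decodes to zero
  dec0 <- rapply(dec, function(v) v * 0, how = "replace")
  expect_equal(tcn_decode(rep(0, 8), 4, dec0, cfg), matrix(0, 8, 4))
  expect_error(tcn_decode(lat, 0, dec, cfg), "f")
})

test_that("compiled kernels agree with the reference implementation", {
  cfg <- tcn_config(n_filters = 16, dilations = c(1, 2, 4), spatial_dropout = 0)
  blocks <- init_tcn_stack(2, cfg, seed = 8)
  t_len <- 24L; b_n <- 5L
  x <- matrix(rnorm(2 * t_len * b_n), 2, t_len * b_n)
  slow <- glucotcn:::block_fwd(x, blocks[[1]], 1L, cfg, t_len, b_n,
                               training = FALSE, keep_cache = TRUE)
  fast <- glucotcn:::cpp_block_fwd(x, blocks[[1]], 1L, 2L, 0, t_len, b_n,
                                   FALSE, TRUE)
  expect_equal(fast$out, slow$out, tolerance = 1e-12)
  d_out <- matrix(rnorm(16 * t_len * b_n), 16, t_len * b_n)
  gs <- glucotcn:::block_bwd(d_out, blocks[[1]], slow$cache, 1L, cfg, t_len, b_n)
  gf <- glucotcn:::cpp_block_bwd(d_out, blocks[[1]], fast$cache, 1L, t_len, b_n)
  expect_equal(glucotcn:::flatten_params(gf$grad),
               glucotcn:::flatten_params(gs$grad), tolerance = 1e-10)
  expect_equal(gf$dX, gs$dX, tolerance = 1e-10)

  # pruned encoder equals the dense encoder at the latent
  pm <- glucotcn:::encoder_prune_maps(t_len, cfg)
  dense <- glucotcn:::stack_fwd(x, blocks, cfg, t_len, b_n, training = FALSE,
                                keep_cache = FALSE)
  lat_dense <- glucotcn:::take_last_step(dense$out, t_len, b_n)
  lat_pruned <- glucotcn:::encoder_fwd_pruned(x, blocks, pm, cfg, t_len, b_n,
                                              training = FALSE)$latent
  expect_equal(lat_pruned, lat_dense, tolerance = 1e-12)
})

test_that("pruned-encoder gradients match finite differences", {
  cfg <- tcn_config(n_filters = 6, dilations = c(1, 2), spatial_dropout = 0)
  blocks <- init_tcn_stack(2, cfg, seed = 9)
  t_len <- 12L; b_n <- 3L
  x <- matrix(rnorm(2 * t_len * b_n), 2, t_len * b_n)
  pm <- glucotcn:::encoder_prune_maps(t_len, cfg)
  d_lat <- matrix(rnorm(6 * b_n), 6, b_n)
  fw <- glucotcn:::encoder_fwd_pruned(x, blocks, pm, cfg, t_len, b_n,
                                      training = TRUE, keep_cache = TRUE)
  gr <- glucotcn:::encoder_bwd_pruned(d_lat, blocks, fw$caches, pm, b_n)
  eps <- 1e-6
  probe <- list(c(1, "c1", 1), c(2, "c2", 2), c(2, "c1", 1))
  for (pr in probe) {
    bi <- as.integer(pr[1]); cv <- pr[2]; tap <- as.integer(pr[3])
    bp <- blocks; bm <- blocks
    bp[[bi]][[cv]]$W[[tap]][2, 1] <- bp[[bi]][[cv]]$W[[tap]][2, 1] + eps
    bm[[bi]][[cv]]$W[[tap]][2, 1] <- bm[[bi]][[cv]]$W[[tap]][2, 1] - eps
    lp <- glucotcn:::encoder_fwd_pruned(x, bp, pm, cfg, t_len, b_n, FALSE)$latent
    lm <- glucotcn:::encoder_fwd_pruned(x, bm, pm, cfg, t_len, b_n, FALSE)$latent
    fd <- sum(d_lat * (lp - lm)) / (2 * eps)
    expect_equal(gr[[bi]][[cv]]$W[[tap]][2, 1], fd, tolerance = 1e-5)
  }
})
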