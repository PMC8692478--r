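#' Temporal convolutional network configuration
#'
#' Hyperparameters of one TCN stack as used inside every encoder and decoder:
#' causal dilated convolutions arranged in residual blocks, one block per
#' dilation factor, two convolutions per block. Defaults are the published
#' setup: kernel size 2, 64 filters, dilations 1, 2, 4, 1-D spatial dropout
#' 0.2, normalization layers switched off, one stack.
#'
#' @param kernel_size convolution kernel size `k` (samples).
#' @param n_filters number of convolution filters (latent width).
#' @param dilations integer vector of dilation factors, one residual block per
#'   entry.
#' @param spatial_dropout 1-D spatial dropout rate in `[0, 1)`; drops whole
#'   feature maps during training only.
#' @param use_normalization if `TRUE`, layer normalization follows each
#'   convolution.
#' @param n_stacks number of repeats of the dilation schedule.
#' @return an object of class `tcn_config`.
#' @export
tcn_config <- function(kernel_size = 2L, n_filters = 64L, dilations = c(1L, 2L, 4L),
                       spatial_dropout = 0.2, use_normalization = FALSE,
                       n_stacks = 1L) {
  abort_if(kernel_size < 1, "kernel_size must be >= 1")
  abort_if(any(dilations < 1), "dilations must be strictly positive")
  abort_if(spatial_dropout < 0 || spatial_dropout >= 1,
           "spatial_dropout must be in [0, 1)")
  abort_if(n_filters < 1, "n_filters must be >= 1")
  abort_if(n_stacks < 1, "n_stacks must be >= 1")
  structure(list(
    kernel_size = as.integer(kernel_size), n_filters = as.integer(n_filters),
    dilations = as.integer(dilations), spatial_dropout = spatial_dropout,
    use_normalization = isTRUE(use_normalization), n_stacks = as.integer(n_stacks)
  ), class = "tcn_config")
}

#' Receptive field of a TCN stack
#'
#' Number of past input samples that can influence one output sample:
#' `1 + sum((k - 1) * d)` over all convolution layers (two per residual
#' block). The default stack (`k = 2`, dilations 1, 2, 4) spans 15 samples.
#'
#' @param config a [tcn_config()].
#' @return integer receptive field in samples.
#' @export
receptive_field <- function(config) {
  dils <- stack_dilations(config)
  1L + sum(2L * (config$kernel_size - 1L) * dils)
}

#' Causal dilated 1-D convolution
#'
#' Computes `F(s) = sum_{i=0}^{k-1} filter[i+1] * x[s - d*i]` with left zero
#' padding, so the output has the input's length and position `s` depends only
#' on inputs at positions `<= s`.
#'
#' @param x numeric input sequence.
#' @param filter numeric filter of length `k`.
#' @param dilation dilation factor `d` (samples between taps).
#' @return numeric vector, same length as `x`.
#' @export
causal_dilated_conv <- function(x, filter, dilation = 1L) {
  abort_if(length(filter) < 1, "filter must have length >= 1 (k >= 1)")
  abort_if(dilation < 1, "dilation must be >= 1 (d >= 1)")
  abort_if(length(x) < 1, "input sequence must be non-empty")
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(filter)) {
    s <- dilation * (i - 1L)
    if (s >= n) next
    out[(s + 1L):n] <- out[(s + 1L):n] + filter[i] * x[seq_len(n - s)]
  }
  out
}

#' Initialize a residual block
#'
#' Two causal dilated convolutions (ReLU, optional layer normalization,
#' spatial dropout after each) plus a skip path; the skip is a 1x1 convolution
#' when input and output channel counts differ, identity otherwise.
#'
#' @param n_in number of input channels.
#' @param config a [tcn_config()].
#' @param seed integer seed for the weight initialization.
#' @return parameter list consumed by [residual_block()].
#' @export
init_residual_block <- function(n_in, config, seed = 1L) {
  with_seed(seed, init_block(as.integer(n_in), config$n_filters,
                             config$kernel_size, config$use_normalization))
}

#' Apply a residual block to a sequence
#'
#' @param x numeric matrix, channels x time.
#' @param params block parameters from [init_residual_block()].
#' @param dilation dilation factor shared by the block's two convolutions.
#' @param config a [tcn_config()].
#' @param training if `TRUE`, spatial dropout is active (stochastic); at
#'   `FALSE` the block is deterministic.
#' @return numeric matrix, `n_filters` x time.
#' @export
residual_block <- function(x, params, dilation, config, training = FALSE) {
  abort_if(!is.matrix(x) || ncol(x) < 1, "x must be a channels x time matrix")
  block_fwd(x, params, as.integer(dilation), config, ncol(x), 1L,
            training = training, keep_cache = FALSE)$out
}

#' Initialize a TCN encoder or decoder stack
#'
#' @param n_in number of input channels.
#' @inheritParams init_residual_block
#' @return list of residual-block parameter sets, one per dilation.
#' @export
init_tcn_stack <- function(n_in, config, seed = 1L) {
  with_seed(seed, init_stack(as.integer(n_in), config))
}

#' Encode a sequence into a latent state vector
#'
#' Runs the input through the residual stack and summarizes it as the feature
#' vector at the final time step, the encoded state handed to the decoder.
#'
#' @param x numeric matrix, channels x time.
#' @param params stack parameters from [init_tcn_stack()].
#' @param config a [tcn_config()].
#' @return numeric latent vector of length `n_filters`.
#' @export
tcn_encode <- function(x, params, config) {
  abort_if(!is.matrix(x) || ncol(x) < 1, "x must be a non-empty channels x time matrix")
  r <- stack_fwd(x, params, config, ncol(x), 1L, training = FALSE, keep_cache = FALSE)
  drop(take_last_step(r$out, ncol(x), 1L))
}

#' Decode a latent state into a horizon-length feature sequence
#'
#' The latent vector is repeated `f` times to form the decoder input sequence
#' and passed through a TCN stack, yielding one feature vector per horizon
#' step (non-autoregressive multi-step decoding).
#'
#' @param latent numeric latent vector (length `n_filters` of the encoder).
#' @param f prediction horizon in steps, `>= 1`.
#' @param params decoder stack parameters from [init_tcn_stack()].
#' @param config a [tcn_config()].
#' @return numeric matrix, `n_filters` x `f`.
#' @export
tcn_decode <- function(latent, f, params, config) {
  abort_if(f < 1, "horizon f must be >= 1")
  x <- matrix(latent, length(latent), f)
  stack_fwd(x, params, config, as.integer(f), 1L, training = FALSE,
            keep_cache = FALSE)$out
}
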