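# Weight containers for the bespoke blocks.  Every container is a list with
# $meta (immutable shape/config facts) and $params (a flat named list of
# numeric arrays -- the trainable state).  Gradients mirror $params, so
# parameter counting, SGD and serialization are uniform across block types.

# scaled random init: variance-preserving (gain 1) for linear paths; the
# residual-branch kernels use gain < 1 so activation variance stays bounded
# without batch normalization
he_init <- function(dims, fan_in, gain = 1) {
  array(stats::rnorm(prod(dims), 0, gain / sqrt(fan_in)), dims)
}

new_block_weights <- function(meta, params, class) {
  structure(list(meta = meta, params = params), class = c(class, "mfd_weights"))
}

#' Plain pointwise (1x1) convolution weights
#'
#' @param in_channels,out_channels channel fan-in / fan-out.
#' @param bias include a bias vector (default `TRUE`).
#' @return a weight container usable with the block forward functions.
#' @keywords internal
pw_weights <- function(in_channels, out_channels, bias = TRUE) {
  params <- list(W = matrix(he_init(c(out_channels, in_channels), in_channels),
                            out_channels, in_channels))
  if (bias) params$b <- numeric(out_channels)
  new_block_weights(list(cin = in_channels, cout = out_channels, bias = bias),
                    params, "pw_weights")
}

#' Multi-kernel depthwise convolution block weights
#'
#' The block applies one depthwise convolution per kernel size, sums the
#' responses, passes them through GELU, mixes channels with a pointwise
#' convolution and adds the input back (residual).
#'
#' @param channels number of input (= depthwise) channels.
#' @param kernel_sizes integer vector of depthwise kernel sizes (default
#'   `c(3, 4, 6)`; even sizes get asymmetric same-size padding).
#' @param pointwise_out output channels of the mixing convolution (default
#'   `channels`; the residual uses identity only when it equals `channels`).
#' @param bias include bias vectors (default `TRUE`).
#' @param init `"kaiming"` (default) or `"zero"`.
#' @return a `mk_dw_weights` container.
#' @export
multikernel_dw_weights <- function(channels, kernel_sizes = c(3L, 4L, 6L),
                                   pointwise_out = channels, bias = TRUE,
                                   init = c("kaiming", "zero")) {
  init <- match.arg(init)
  kernel_sizes <- as.integer(kernel_sizes)
  params <- list()
  for (k in kernel_sizes) {
    nm <- paste0("dw_k", k)
    params[[nm]] <- if (init == "zero") array(0, c(k, k, channels))
                    else he_init(c(k, k, channels), k * k * length(kernel_sizes),
                                 gain = 0.5)
    if (bias) params[[paste0("dwb_k", k)]] <- numeric(channels)
  }
  params$pw <- if (init == "zero") matrix(0, pointwise_out, channels)
               else matrix(he_init(c(pointwise_out, channels), channels,
                                   gain = 0.5),
                           pointwise_out, channels)
  if (bias) params$pwb <- numeric(pointwise_out)
  new_block_weights(list(channels = channels, kernel_sizes = kernel_sizes,
                         pointwise_out = pointwise_out, bias = bias),
                    params, "mk_dw_weights")
}

#' Multi-kernel blueprint-separable convolution block weights
#'
#' Pointwise mixing comes first and is low-rank factorised: the input is
#' projected into a subspace of size `ceiling(mu * in_channels)` by one 1x1
#' convolution and lifted to `out_channels` by a second one, after which one
#' depthwise convolution per kernel size filters spatially and the responses
#' are summed.  A residual connection uses the identity when shapes allow and
#' a (strided) 1x1 projection otherwise.
#'
#' @param in_channels,out_channels channel fan-in / fan-out.
#' @param kernel_sizes depthwise kernel sizes (default `c(3, 4, 6)`).
#' @param mu subspace fraction in (0, 1); default 0.5.
#' @param stride spatial stride of the depthwise stack (1 or 2).
#' @param bias include bias vectors (default `TRUE`).
#' @param init `"kaiming"` or `"zero"`.
#' @return a `bsconv_weights` container.
#' @export
bsconv_weights <- function(in_channels, out_channels,
                           kernel_sizes = c(3L, 4L, 6L), mu = 0.5,
                           stride = 1L, bias = TRUE,
                           init = c("kaiming", "zero")) {
  init <- match.arg(init)
  stopifnot(mu > 0, mu < 1, stride %in% c(1L, 2L))
  kernel_sizes <- as.integer(kernel_sizes)
  qprime <- max(1L, as.integer(ceiling(mu * in_channels)))
  mk <- function(d, fan, gain = 1) if (init == "zero") array(0, d)
        else he_init(d, fan, gain)
  params <- list(
    pw1 = matrix(mk(c(qprime, in_channels), in_channels), qprime, in_channels),
    pw2 = matrix(mk(c(out_channels, qprime), qprime), out_channels, qprime)
  )
  if (bias) { params$pw1b <- numeric(qprime); params$pw2b <- numeric(out_channels) }
  for (k in kernel_sizes) {
    params[[paste0("dw_k", k)]] <- mk(c(k, k, out_channels),
                                      k * k * length(kernel_sizes), gain = 0.5)
    if (bias) params[[paste0("dwb_k", k)]] <- numeric(out_channels)
  }
  has_proj <- (in_channels != out_channels) || stride != 1L
  if (has_proj) {
    params$proj <- matrix(mk(c(out_channels, in_channels), in_channels),
                          out_channels, in_channels)
    if (bias) params$projb <- numeric(out_channels)
  }
  new_block_weights(list(cin = in_channels, cout = out_channels,
                         kernel_sizes = kernel_sizes, mu = mu,
                         qprime = qprime, stride = as.integer(stride),
                         bias = bias, has_proj = has_proj),
                    params, "bsconv_weights")
}

#' ESCA attention block weights
#'
#' A spatial gate (channel reduction, 2x2 max pool + small dense convolution,
#' bilinear upsampling, residual join, 1x1 restore, sigmoid) followed in
#' series by an optional channel gate (global average pool, 1x1 channel mix,
#' sigmoid).
#'
#' @param channels gated channel count.
#' @param reduction spatial-branch channel reduction ratio (default 8).
#' @param conv_size receptive-field convolution size (default 3).
#' @param channel_attention include the channel gate (default `TRUE`).
#' @param init `"kaiming"` or `"zero"`.
#' @return an `esca_weights` container.
#' @export
esca_weights <- function(channels, reduction = 8L, conv_size = 3L,
                         channel_attention = TRUE, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  cr <- max(1L, channels %/% as.integer(reduction))
  mk <- function(d, fan) if (init == "zero") array(0, d) else he_init(d, fan)
  params <- list(
    sam_reduce = matrix(mk(c(cr, channels), channels), cr, channels),
    sam_reduce_b = numeric(cr),
    sam_conv = mk(c(conv_size, conv_size, cr, cr), conv_size^2 * cr),
    sam_conv_b = numeric(cr),
    sam_out = matrix(mk(c(1L, cr), cr), 1L, cr),
    sam_out_b = numeric(1L)
  )
  if (channel_attention) {
    params$cam_mix <- matrix(mk(c(channels, channels), channels), channels, channels)
    params$cam_mix_b <- numeric(channels)
  }
  new_block_weights(list(channels = channels, reduction = as.integer(reduction),
                         cr = cr, conv_size = as.integer(conv_size),
                         channel_attention = channel_attention),
                    params, "esca_weights")
}

#' Count trainable parameters of a block or a whole model
#'
#' Enumerates the stored arrays: the multi-kernel depthwise part of a block
#' with `C` channels and kernel sizes `k_m` contributes `C * sum(k_m^2)`
#' scalars, a pointwise map `d_i -> d_j` contributes `d_i * d_j`, plus biases
#' where enabled.
#'
#' @param w a weight container, a model built by [build_model()], or any
#'   nested list of weight containers.
#' @return integer number of scalar parameters.
#' @export
count_block_params <- function(w) {
  if (inherits(w, "mfd_weights"))
    return(sum(vapply(w$params, length, integer(1))))
  if (is.list(w))
    return(sum(vapply(w, count_block_params, integer(1))))
  0L
}

# extract / replace the trainable state as one nested named list
get_params <- function(w) {
  if (inherits(w, "mfd_weights")) return(w$params)
  if (is.list(w)) return(lapply(w, get_params))
  NULL
}

set_params <- function(w, p) {
  if (inherits(w, "mfd_weights")) { w$params <- p; return(w) }
  if (is.list(w)) {
    out <- mapply(set_params, w, p, SIMPLIFY = FALSE)
    names(out) <- names(w)
    return(out)
  }
  w
}

params_finite <- function(p) {
  if (is.numeric(p)) return(all(is.finite(p)))
  all(vapply(p, params_finite, logical(1)))
}

#' One plain stochastic-gradient-descent step
#'
#' Applies `w' = w - gamma * gradient` elementwise over an arbitrarily nested
#' parameter structure.  A non-finite gradient refuses the step: the weights
#' are returned unchanged with attribute `refused = TRUE` and a warning.
#'
#' @param w numeric array, weight container, or nested list thereof.
#' @param gradient structure matching `w` (matching `$params` for containers).
#' @param gamma positive learning rate.
#' @return updated weights, same structure as `w`.
#' @export
sgd_update <- function(w, gradient, gamma) {
  stopifnot(is.numeric(gamma), gamma > 0)
  if (!params_finite(gradient)) {
    warning("non-finite gradient: SGD step refused")
    attr(w, "refused") <- TRUE
    return(w)
  }
  step <- function(a, g) {
    if (inherits(a, "mfd_weights")) {
      gg <- if (is.list(g) && !is.null(g$params)) g$params else g
      a$params <- step(a$params, gg)
      return(a)
    }
    if (is.numeric(a)) return(a - gamma * g)
    if (is.list(a)) {
      out <- mapply(step, a, g, SIMPLIFY = FALSE)
      names(out) <- names(a)
      return(out)
    }
    a
  }
  step(w, gradient)
}
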