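#' Mask discriminator
#'
#' A small strided convolutional network scoring an `H x W` mask map in
#' `[0, 1]` as real (a genuine visible mask) versus generated. Three 4x4
#' stride-2 convolutions with leaky-ReLU activations feed a global
#' average pool and a linear sigmoid unit, so the score always lies in
#' `(0, 1)` and is differentiable with respect to the input map. Used
#' adversarially during partial-completion training to sharpen predicted
#' amodal masks.
#'
#' @param seed integer seed for initialisation.
#' @param channels per-layer channel counts.
#' @return an object of class `mask_disc`.
#' @export
build_discriminator <- function(seed = 1L, channels = c(8L, 16L, 32L)) {
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_along(channels)) {
      p[[sprintf("conv%d_W", l)]] <-
        matrix(.tn(16 * cin * channels[l], sd = 0.05), 16 * cin,
               channels[l])
      p[[sprintf("conv%d_b", l)]] <- rep(0, channels[l])
      cin <- channels[l]
    }
    p$out_W <- matrix(.tn(cin * 1, sd = 0.05), cin, 1)
    p$out_b <- 0
    p
  })
  d <- new.env(parent = emptyenv())
  d$params <- params
  d$channels <- channels
  d$meta_cache <- new.env(parent = emptyenv())
  class(d) <- "mask_disc"
  d
}

disc_meta <- function(disc, H, W) {
  key <- sprintf("%dx%d", H, W)
  if (!is.null(disc$meta_cache[[key]])) return(disc$meta_cache[[key]])
  metas <- list()
  h <- H; w <- W
  for (l in seq_along(disc$channels)) {
    metas[[l]] <- conv_meta(h, w, 4, 4, stride = 2, pad = 1)
    h <- metas[[l]]$out_h; w <- metas[[l]]$out_w
  }
  disc$meta_cache[[key]] <- metas
  metas
}

# mask_node: node whose value is a length-H*W vector (row-major); returns a
# scalar node in (0,1)
disc_forward_nodes <- function(disc, mask_node, H, W, tape, pn,
                               input_needs_grad = TRUE) {
  metas <- disc_meta(disc, H, W)
  x <- if (input_needs_grad) {
    ag_node(tape, matrix(mask_node$value, ncol = 1), function(nd) {
      ag_acc(mask_node, as.vector(nd$grad))
    })
  } else {
    ag_leaf(tape, matrix(mask_node$value, ncol = 1))
  }
  ng <- input_needs_grad
  for (l in seq_along(disc$channels)) {
    x <- ag_conv(tape, x, pn[[sprintf("conv%d_W", l)]],
                 pn[[sprintf("conv%d_b", l)]], metas[[l]],
                 x_needs_grad = ng || l > 1)
    x <- ag_lrelu(tape, x)
  }
  pooled <- ag_node(tape, matrix(colMeans(x$value), 1), local({
    xx <- x
    function(nd) {
      n <- nrow(xx$value)
      ag_acc(xx, matrix(rep(nd$grad / n, each = n), n))
    }
  }))
  s <- ag_linear(tape, pooled, pn$out_W, pn$out_b)
  ag_sigmoid(tape, s)
}

#' Score a mask map with the discriminator
#'
#' @param disc a `mask_disc` from [build_discriminator()].
#' @param mask_map `H x W` matrix with values in `[0, 1]`.
#' @return scalar probability in `(0, 1)`.
#' @export
discriminator_score <- function(disc, mask_map) {
  tape <- ag_tape()
  pn <- wrap_params(tape, disc$params)
  v <- as.vector(t(mask_map))  # row-major
  node <- ag_leaf(tape, v)
  out <- disc_forward_nodes(disc, node, nrow(mask_map), ncol(mask_map),
                            tape, pn, input_needs_grad = FALSE)
  as.numeric(out$value)
}
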