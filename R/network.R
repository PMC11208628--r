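#' Network configuration
#'
#' Describes the hierarchical windowed-attention encoder-decoder used for
#' partial completion. The input is split into non-overlapping
#' `patch_size x patch_size` patches, linearly embedded to `embed_dim`
#' channels, and passed through encoder stages of windowed-attention
#' blocks separated by patch-merging layers (2x2 neighbouring patches are
#' concatenated to 4C channels then linearly reduced to 2C). A symmetric
#' decoder uses patch-expanding layers and skip connections (fused with a
#' 1x1 convolution); the final expanding layer upsamples by 4x back to
#' pixel resolution, where a two-channel head emits the amodal
#' probability map (sigmoid) and the boundary-uncertainty map (softplus).
#'
#' The `tiny_test` preset (two stages, C = 24, window 4, 64 x 64 inputs)
#' trains on a single CPU in minutes; `swin_tiny` / `swin_small` /
#' `swin_base` mirror the standard 4-stage 224 x 224 hierarchies.
#'
#' @param preset one of `"tiny_test"`, `"swin_tiny"`, `"swin_small"`,
#'   `"swin_base"`.
#' @param ... overrides for individual fields (`patch_size`, `embed_dim`,
#'   `depths`, `heads`, `window`, `in_channels`, `mlp_ratio`,
#'   `img_size`).
#' @return a list of class `net_config`.
#' @export
net_config <- function(preset = c("tiny_test", "swin_tiny", "swin_small",
                                  "swin_base"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny_test = list(patch_size = 4L, embed_dim = 24L, depths = c(1L, 1L),
                     heads = c(3L, 6L), window = 4L, in_channels = 5L,
                     mlp_ratio = 2, img_size = 64L),
    swin_tiny = list(patch_size = 4L, embed_dim = 96L,
                     depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                     window = 7L, in_channels = 5L, mlp_ratio = 4,
                     img_size = 224L),
    swin_small = list(patch_size = 4L, embed_dim = 96L,
                      depths = c(2L, 2L, 18L, 2L),
                      heads = c(3L, 6L, 12L, 24L), window = 7L,
                      in_channels = 5L, mlp_ratio = 4, img_size = 224L),
    swin_base = list(patch_size = 4L, embed_dim = 128L,
                     depths = c(2L, 2L, 18L, 2L),
                     heads = c(4L, 8L, 16L, 32L), window = 7L,
                     in_channels = 5L, mlp_ratio = 4, img_size = 224L))
  cfg$preset <- preset
  ov <- list(...)
  cfg[names(ov)] <- ov
  S <- length(cfg$depths)
  stopifnot(length(cfg$heads) == S)
  dims <- cfg$embed_dim * 2^(seq_len(S) - 1)
  if (any(dims %% cfg$heads != 0)) {
    stop("attention heads must divide the stage channel dimensions")
  }
  structure(cfg, class = "net_config")
}

.tn <- function(n, sd = 0.02) pmin(2 * sd, pmax(-2 * sd,
                                                stats::rnorm(n, 0, sd)))

.block_params <- function(C, heads, window, mlp_ratio) {
  hidden <- round(C * mlp_ratio)
  list(ln1_g = rep(1, C), ln1_b = rep(0, C),
       qkv_W = matrix(.tn(C * 3 * C), C, 3 * C), qkv_b = rep(0, 3 * C),
       proj_W = matrix(.tn(C * C), C, C), proj_b = rep(0, C),
       bias_table = matrix(0, (2 * window - 1)^2, heads),
       ln2_g = rep(1, C), ln2_b = rep(0, C),
       mlp_W1 = matrix(.tn(C * hidden), C, hidden), mlp_b1 = rep(0, hidden),
       mlp_W2 = matrix(.tn(hidden * C), hidden, C), mlp_b2 = rep(0, C))
}

#' Build a partial-completion segmentation network
#'
#' Allocates and initialises all parameters for the configuration.
#' Weights use a truncated-normal initialisation (sd 0.02, clipped at two
#' standard deviations); layer norms start at identity and the
#' relative-position bias tables at zero. With `informed_init` (the
#' default) the patch embedding, stage-1 skip fusion and output head are
#' additionally wired so that the untrained network already reproduces
#' its modal input channel (`m` high inside the visible mask, low
#' elsewhere) — the no-completion prior. Because the attention and MLP
#' branches are residual, this identity path survives initialisation, and
#' training only has to learn where to extend a mask rather than how to
#' copy it. The parameter count is a pure function of the configuration
#' and two builds with the same seed are identical.
#'
#' @param config a [net_config()].
#' @param seed integer seed for the initialisation.
#' @param informed_init start from the no-completion prior.
#' @return an object of class `amodal_net`.
#' @export
build_network <- function(config, seed = 1L, informed_init = TRUE) {
  stopifnot(inherits(config, "net_config"))
  params <- with_seed(seed, {
    S <- length(config$depths)
    dims <- config$embed_dim * 2^(seq_len(S) - 1)
    p <- list()
    pin <- config$patch_size^2 * config$in_channels
    p$embed_W <- matrix(.tn(pin * dims[1]), pin, dims[1])
    p$embed_b <- rep(0, dims[1])
    for (s in seq_len(S)) {
      for (d in seq_len(config$depths[s])) {
        p[[sprintf("enc_s%d_b%d", s, d)]] <-
          .block_params(dims[s], config$heads[s], config$window,
                        config$mlp_ratio)
      }
      if (s < S) {
        p[[sprintf("merge_s%d", s)]] <- list(
          ln_g = rep(1, 4 * dims[s]), ln_b = rep(0, 4 * dims[s]),
          W = matrix(.tn(4 * dims[s] * 2 * dims[s]), 4 * dims[s],
                     2 * dims[s]))
      }
    }
    for (s in rev(seq_len(S - 1))) {
      p[[sprintf("expand_s%d", s)]] <- list(
        W = matrix(.tn(dims[s + 1] * 4 * dims[s]), dims[s + 1],
                   4 * dims[s]),
        b = rep(0, 4 * dims[s]))
      p[[sprintf("fuse_s%d", s)]] <- list(
        W = matrix(.tn(2 * dims[s] * dims[s]), 2 * dims[s], dims[s]),
        b = rep(0, dims[s]))
      for (d in seq_len(config$depths[s])) {
        p[[sprintf("dec_s%d_b%d", s, d)]] <-
          .block_params(dims[s], config$heads[s], config$window,
                        config$mlp_ratio)
      }
    }
    p$final_W <- matrix(.tn(dims[1] * config$patch_size^2 * dims[1]),
                        dims[1], config$patch_size^2 * dims[1])
    p$final_b <- rep(0, config$patch_size^2 * dims[1])
    p$head_W <- matrix(.tn(dims[1] * 2), dims[1], 2)
    p$head_b <- c(-2, 0)  # start with low amodal probability
    p
  })
  if (informed_init && config$embed_dim >= config$patch_size^2) {
    P2 <- config$patch_size^2
    C <- config$embed_dim
    c0 <- C - P2  # copy channels: the last P^2 token channels
    # patch embedding copies each patch's modal bits into the copy
    # channels (modal is input channel 4 of 5)
    for (k in seq_len(P2)) {
      params$embed_W[(k - 1) * config$in_channels + 4, c0 + k] <- 1
    }
    # stage-1 fusion passes the skip connection through unchanged
    if (length(config$depths) > 1) {
      fuse <- params$fuse_s1$W * 0
      fuse[cbind(C + seq_len(C), seq_len(C))] <- 1
      params$fuse_s1$W <- fuse
    }
    # final expansion reconstructs pixel k from copy channel c0 + k,
    # and the head turns it into a +/- 2 logit around head bias -2
    for (k in seq_len(P2)) {
      params$final_W[c0 + k, (k - 1) * C + 1] <- 1
    }
    params$head_W[1, 1] <- 4
  }
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$params <- params
  net$meta_cache <- new.env(parent = emptyenv())
  class(net) <- "amodal_net"
  net
}

#' Number of trainable parameters
#' @param net an `amodal_net` or discriminator.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else cnt <<- cnt + length(x)
  }
  walk(net$params)
  cnt
}

#' @export
print.amodal_net <- function(x, ...) {
  cat(sprintf("amodal_net (%s): %d stages, C=%d, window=%d, %d parameters\n",
              x$config$preset, length(x$config$depths), x$config$embed_dim,
              x$config$window, n_parameters(x)))
  invisible(x)
}

# ---- geometry metadata (cached per input resolution) -----------------------

.windows_for <- function(Ht, Wt, w) {
  out <- list()
  for (br in seq_len(Ht %/% w)) {
    for (bc in seq_len(Wt %/% w)) {
      rows <- ((br - 1) * w + 1):(br * w)
      cols <- ((bc - 1) * w + 1):(bc * w)
      idx <- as.vector(t(outer((rows - 1) * Wt, cols, "+")))
      out[[length(out) + 1L]] <- idx
    }
  }
  out
}

.bias_idx_for <- function(w) {
  pos <- expand.grid(c = seq_len(w), r = seq_len(w))  # row-major token order
  n <- w * w
  off_r <- outer(pos$r, pos$r, "-") + w - 1
  off_c <- outer(pos$c, pos$c, "-") + w - 1
  matrix(as.integer(off_r * (2 * w - 1) + off_c + 1), n, n)
}

.shift_meta <- function(Ht, Wt, w) {
  s <- w %/% 2
  # row-major token index of the source of each destination token after a
  # cyclic up-left shift by s
  perm <- integer(Ht * Wt)
  for (r in seq_len(Ht)) for (c in seq_len(Wt)) {
    sr <- (r + s - 1) %% Ht + 1; sc <- (c + s - 1) %% Wt + 1
    perm[(r - 1) * Wt + c] <- (sr - 1) * Wt + sc
  }
  lab_r <- ifelse(seq_len(Ht) <= Ht - w, 0L,
                  ifelse(seq_len(Ht) <= Ht - s, 1L, 2L))
  lab_c <- ifelse(seq_len(Wt) <= Wt - w, 0L,
                  ifelse(seq_len(Wt) <= Wt - s, 1L, 2L))
  lab <- outer(lab_r, lab_c, function(a, b) a * 3L + b)
  shifted_lab <- numeric(Ht * Wt)
  for (r in seq_len(Ht)) for (c in seq_len(Wt)) {
    sr <- (r + s - 1) %% Ht + 1; sc <- (c + s - 1) %% Wt + 1
    shifted_lab[(r - 1) * Wt + c] <- lab[sr, sc]
  }
  windows <- .windows_for(Ht, Wt, w)
  masks <- lapply(windows, function(idx) {
    l <- shifted_lab[idx]
    m <- outer(l, l, function(a, b) ifelse(a == b, 0, -1e9))
    m
  })
  list(perm = perm, masks = masks)
}

net_meta <- function(net, H, W) {
  key <- sprintf("%dx%d", H, W)
  if (!is.null(net$meta_cache[[key]])) return(net$meta_cache[[key]])
  cfg <- net$config
  P <- cfg$patch_size; w <- cfg$window
  S <- length(cfg$depths)
  if (H %% P != 0 || W %% P != 0) {
    stop(sprintf("input size %dx%d must be divisible by patch_size %d",
                 H, W, P))
  }
  grids <- list()
  Ht <- H %/% P; Wt <- W %/% P
  for (s in seq_len(S)) {
    if (Ht %% w != 0 || Wt %% w != 0) {
      stop(sprintf(
        "stage %d token grid %dx%d must be divisible by window %d; input size must be divisible by %d",
        s, Ht, Wt, w, P * w * 2^(S - 1)))
    }
    grids[[s]] <- list(
      Ht = Ht, Wt = Wt,
      windows = .windows_for(Ht, Wt, w),
      bias_idx = .bias_idx_for(w),
      shift = if (Ht > w || Wt > w) .shift_meta(Ht, Wt, w) else NULL)
    if (s < S) {
      g1 <- Ht %/% 2; g2 <- Wt %/% 2
      idxm <- matrix(0L, g1 * g2, 4)
      p <- 0L
      for (R in seq_len(g1)) for (C2 in seq_len(g2)) {
        p <- p + 1L
        idxm[p, ] <- c((2 * R - 2) * Wt + 2 * C2 - 1,
                       (2 * R - 2) * Wt + 2 * C2,
                       (2 * R - 1) * Wt + 2 * C2 - 1,
                       (2 * R - 1) * Wt + 2 * C2)
      }
      grids[[s]]$merge_idxm <- idxm
      # expand: from the coarser grid back to this grid
      eidx <- matrix(0L, g1 * g2, 4)
      p <- 0L
      for (R in seq_len(g1)) for (C2 in seq_len(g2)) {
        p <- p + 1L
        eidx[p, ] <- c((2 * R - 2) * Wt + 2 * C2 - 1,
                       (2 * R - 2) * Wt + 2 * C2,
                       (2 * R - 1) * Wt + 2 * C2 - 1,
                       (2 * R - 1) * Wt + 2 * C2)
      }
      grids[[s]]$expand_idxm <- eidx
      Ht <- Ht %/% 2; Wt <- Wt %/% 2
    }
  }
  # patch embedding: token t gathers P*P pixels x in_channels values
  H1 <- H %/% P; W1 <- W %/% P
  Cin <- cfg$in_channels
  embed_idx <- matrix(0L, H1 * W1, P * P * Cin)
  p <- 0L
  for (R in seq_len(H1)) for (C2 in seq_len(W1)) {
    p <- p + 1L
    k <- 0L
    for (a in seq_len(P)) for (b in seq_len(P)) {
      r <- (R - 1) * P + a; c <- (C2 - 1) * P + b
      for (ch in seq_len(Cin)) {
        k <- k + 1L
        embed_idx[p, k] <- r + (c - 1L) * H + (ch - 1L) * H * W
      }
    }
  }
  # final 4x expansion: token -> P*P pixel rows (row-major pixel order)
  final_idxm <- matrix(0L, H1 * W1, P * P)
  p <- 0L
  for (R in seq_len(H1)) for (C2 in seq_len(W1)) {
    p <- p + 1L
    k <- 0L
    for (a in seq_len(P)) for (b in seq_len(P)) {
      k <- k + 1L
      r <- (R - 1) * P + a; c <- (C2 - 1) * P + b
      final_idxm[p, k] <- (r - 1L) * W + c
    }
  }
  meta <- list(grids = grids, embed_idx = embed_idx,
               final_idxm = final_idxm, H = H, W = W)
  net$meta_cache[[key]] <- meta
  meta
}

# ---- forward pass ----------------------------------------------------------

# wrap every parameter array of a nested param list in tape leaves
wrap_params <- function(tape, params) {
  lapply(params, function(p) {
    if (is.list(p)) lapply(p, function(q) ag_leaf(tape, q))
    else ag_leaf(tape, p)
  })
}

# read accumulated gradients back out of wrapped parameter nodes
collect_grads <- function(pnodes) {
  lapply(pnodes, function(p) {
    if (is.list(p) && !is.environment(p)) lapply(p, function(q) q$grad)
    else p$grad
  })
}

.run_block <- function(tape, x, bp, grid, heads, shifted) {
  h <- ag_layernorm(tape, x, bp$ln1_g, bp$ln1_b)
  use_shift <- shifted && !is.null(grid$shift)
  if (use_shift) h <- ag_permute_rows(tape, h, grid$shift$perm)
  qkv <- ag_linear(tape, h, bp$qkv_W, bp$qkv_b)
  att <- ag_window_msa(tape, qkv, grid$windows, heads, bp$bias_table,
                       grid$bias_idx,
                       masks = if (use_shift) grid$shift$masks)
  att <- ag_linear(tape, att, bp$proj_W, bp$proj_b)
  if (use_shift) {
    inv <- integer(length(grid$shift$perm))
    inv[grid$shift$perm] <- seq_along(grid$shift$perm)
    att <- ag_permute_rows(tape, att, inv)
  }
  x <- ag_add(tape, x, att)
  h2 <- ag_layernorm(tape, x, bp$ln2_g, bp$ln2_b)
  h2 <- ag_linear(tape, h2, bp$mlp_W1, bp$mlp_b1)
  h2 <- ag_gelu(tape, h2)
  h2 <- ag_linear(tape, h2, bp$mlp_W2, bp$mlp_b2)
  ag_add(tape, x, h2)
}

# input: H x W x in_channels numeric array (image channels scaled to [0,1])
# returns list(m = node, u = node) with values as length-H*W vectors in
# row-major pixel order
net_forward_nodes <- function(net, input, tape, pn) {
  cfg <- net$config
  H <- dim(input)[1]; W <- dim(input)[2]
  meta <- net_meta(net, H, W)
  S <- length(cfg$depths)
  flat <- as.vector(input)
  xmat <- matrix(flat[meta$embed_idx], nrow(meta$embed_idx))
  x <- ag_linear(tape, ag_leaf(tape, xmat), pn$embed_W, pn$embed_b,
                 x_needs_grad = FALSE)
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    g <- meta$grids[[s]]
    for (d in seq_len(cfg$depths[s])) {
      x <- .run_block(tape, x, pn[[sprintf("enc_s%d_b%d", s, d)]], g,
                      cfg$heads[s], shifted = d %% 2 == 0)
    }
    skips[[s]] <- x
    if (s < S) {
      mp <- pn[[sprintf("merge_s%d", s)]]
      x <- ag_merge_rows(tape, x, g$merge_idxm)
      x <- ag_layernorm(tape, x, mp$ln_g, mp$ln_b)
      x <- ag_linear(tape, x, mp$W)
    }
  }
  for (s in rev(seq_len(S - 1))) {
    g <- meta$grids[[s]]
    ep <- pn[[sprintf("expand_s%d", s)]]
    dims_s <- cfg$embed_dim * 2^(s - 1)
    x <- ag_linear(tape, x, ep$W, ep$b)
    x <- ag_expand_rows(tape, x, g$expand_idxm, dims_s)
    x <- ag_concat_cols(tape, x, skips[[s]])
    fp <- pn[[sprintf("fuse_s%d", s)]]
    x <- ag_linear(tape, x, fp$W, fp$b)
    for (d in seq_len(cfg$depths[s])) {
      x <- .run_block(tape, x, pn[[sprintf("dec_s%d_b%d", s, d)]], g,
                      cfg$heads[s], shifted = d %% 2 == 0)
    }
  }
  x <- ag_linear(tape, x, pn$final_W, pn$final_b)
  x <- ag_expand_rows(tape, x, meta$final_idxm, cfg$embed_dim)
  x <- ag_linear(tape, x, pn$head_W, pn$head_b)
  m <- ag_sigmoid(tape, ag_col(tape, x, 1))
  u <- ag_softplus(tape, ag_col(tape, x, 2))
  list(m = m, u = u)
}

#' Run the network on one input stack
#'
#' @param net an `amodal_net` from [build_network()].
#' @param input `H x W x in_channels` array: RGB image scaled to `[0,1]`
#'   followed by the modal-mask and occlusion-boundary channels (see
#'   [completion_input()]).
#' @return list with `m` (amodal probability, `H x W`, values in
#'   `[0, 1]`) and `u` (boundary uncertainty, `H x W`, values >= 0).
#' @export
net_predict <- function(net, input) {
  tape <- ag_tape()
  pn <- wrap_params(tape, net$params)
  out <- net_forward_nodes(net, input, tape, pn)
  H <- dim(input)[1]; W <- dim(input)[2]
  list(m = matrix(out$m$value, H, W, byrow = TRUE),
       u = matrix(out$u$value, H, W, byrow = TRUE))
}

#' Scaled dot-product attention within one window
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` for the token matrices of a
#' single attention window; each output row is a convex combination of
#' the rows of `V`. This is the primitive applied independently (per
#' window, per head) throughout the network; the shifted-window variant
#' applies the same primitive to a displaced window partition.
#'
#' @param Q,K,V token matrices with the same number of rows.
#' @param d_k key dimensionality used in the softmax scaling (defaults to
#'   `ncol(K)`).
#' @return the attended token matrix.
#' @export
window_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k <= 0) stop("d_k must be positive")
  S <- tcrossprod(Q, K) / sqrt(d_k)
  S <- S - apply(S, 1, max)
  A <- exp(S)
  A <- A / rowSums(A)
  A %*% V
}
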