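# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; a tape records creation order so gradients can be
# propagated by a single reverse sweep. Ops are coarse-grained (a whole
# linear layer, layer norm, windowed multi-head attention, im2col
# convolution) to keep the R-level overhead per training step small.
# Gradient correctness is pinned down by finite-difference tests.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

ag_acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# reverse sweep from a scalar node
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise and linear ops -------------------------------------------

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, function(nd) {
    ag_acc(a, nd$grad); ag_acc(b, nd$grad)
  })
}

ag_scale <- function(tape, a, s) {
  ag_node(tape, a$value * s, function(nd) ag_acc(a, nd$grad * s))
}

ag_linear <- function(tape, x, W, b = NULL, x_needs_grad = TRUE) {
  val <- x$value %*% W$value
  if (!is.null(b)) val <- val + rep(b$value, each = nrow(val))
  ag_node(tape, val, function(nd) {
    g <- nd$grad
    if (x_needs_grad) ag_acc(x, g %*% t(W$value))
    ag_acc(W, crossprod(x$value, g))
    if (!is.null(b)) ag_acc(b, colSums(g))
  })
}

ag_layernorm <- function(tape, x, g, b, eps = 1e-5) {
  X <- x$value
  n <- nrow(X); C <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- xhat * rep(g$value, each = n) + rep(b$value, each = n)
  ag_node(tape, val, function(nd) {
    gr <- nd$grad
    dxhat <- gr * rep(g$value, each = n)
    ag_acc(g, colSums(gr * xhat))
    ag_acc(b, colSums(gr))
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    ag_acc(x, inv * (dxhat - m1 - xhat * m2))
  })
}

ag_gelu <- function(tape, x) {
  X <- x$value
  ag_node(tape, X * stats::pnorm(X), function(nd) {
    ag_acc(x, nd$grad * (stats::pnorm(X) + X * stats::dnorm(X)))
  })
}

ag_lrelu <- function(tape, x, slope = 0.2) {
  X <- x$value
  pos <- X > 0
  fac <- slope + (1 - slope) * pos
  ag_node(tape, X * fac, function(nd) ag_acc(x, nd$grad * fac))
}

ag_sigmoid <- function(tape, x) {
  s <- stats::plogis(x$value)
  ag_node(tape, s, function(nd) ag_acc(x, nd$grad * s * (1 - s)))
}

ag_softplus <- function(tape, x) {
  X <- x$value
  val <- pmax(X, 0) + log1p(exp(-abs(X)))
  ag_node(tape, val, function(nd) {
    ag_acc(x, nd$grad * stats::plogis(X))
  })
}

# ---- structural ops --------------------------------------------------------

# permute rows (idx must be a permutation)
ag_permute_rows <- function(tape, x, idx) {
  inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
  ag_node(tape, x$value[idx, , drop = FALSE], function(nd) {
    ag_acc(x, nd$grad[inv, , drop = FALSE])
  })
}

# out[i, ] = concat over k of x[idxm[i, k], ]; the columns of idxm are
# disjoint index sets jointly covering every row of x exactly once
ag_merge_rows <- function(tape, x, idxm) {
  K <- ncol(idxm); C <- ncol(x$value)
  val <- do.call(cbind, lapply(seq_len(K), function(k)
    x$value[idxm[, k], , drop = FALSE]))
  ag_node(tape, val, function(nd) {
    g <- nd$grad
    dx <- matrix(0, nrow(x$value), C)
    for (k in seq_len(K)) {
      dx[idxm[, k], ] <- g[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    }
    ag_acc(x, dx)
  })
}

# inverse of ag_merge_rows: x has K * c_out columns; block k of row i is
# scattered to output row idxm[i, k]
ag_expand_rows <- function(tape, x, idxm, c_out) {
  K <- ncol(idxm)
  n_out <- max(idxm)
  val <- matrix(0, n_out, c_out)
  for (k in seq_len(K)) {
    val[idxm[, k], ] <-
      x$value[, ((k - 1) * c_out + 1):(k * c_out), drop = FALSE]
  }
  ag_node(tape, val, function(nd) {
    g <- nd$grad
    dx <- do.call(cbind, lapply(seq_len(K), function(k)
      g[idxm[, k], , drop = FALSE]))
    ag_acc(x, dx)
  })
}

ag_concat_cols <- function(tape, a, b) {
  ca <- ncol(a$value)
  ag_node(tape, cbind(a$value, b$value), function(nd) {
    ag_acc(a, nd$grad[, seq_len(ca), drop = FALSE])
    ag_acc(b, nd$grad[, -seq_len(ca), drop = FALSE])
  })
}

ag_col <- function(tape, x, j) {
  ag_node(tape, x$value[, j], function(nd) {
    dx <- matrix(0, nrow(x$value), ncol(x$value))
    dx[, j] <- nd$grad
    ag_acc(x, dx)
  })
}

# ---- windowed multi-head self-attention ------------------------------------

# qkv: N x 3C node (rows are tokens); windows: list of integer index
# vectors (each of length T); bias_table: (2w-1)^2 x heads parameter node;
# bias_idx: T x T integer matrix into bias_table rows; masks: optional list
# (per window) of T x T additive matrices for the shifted variant
ag_window_msa <- function(tape, qkv, windows, heads, bias_table, bias_idx,
                          masks = NULL) {
  X <- qkv$value
  C <- ncol(X) / 3L
  d <- C / heads
  scale <- 1 / sqrt(d)
  nwin <- length(windows)
  out <- matrix(0, nrow(X), C)
  Acache <- vector("list", nwin * heads)
  B <- lapply(seq_len(heads), function(h)
    matrix(bias_table$value[bias_idx, h], nrow(bias_idx)))
  for (w in seq_len(nwin)) {
    idx <- windows[[w]]
    Xw <- X[idx, , drop = FALSE]
    for (h in seq_len(heads)) {
      qc <- ((h - 1) * d + 1):(h * d)
      Q <- Xw[, qc, drop = FALSE]
      K <- Xw[, C + qc, drop = FALSE]
      V <- Xw[, 2 * C + qc, drop = FALSE]
      S <- tcrossprod(Q, K) * scale + B[[h]]
      if (!is.null(masks)) S <- S + masks[[w]]
      S <- S - apply(S, 1, max)
      A <- exp(S)
      A <- A / rowSums(A)
      Acache[[(w - 1) * heads + h]] <- A
      out[idx, qc] <- A %*% V
    }
  }
  ag_node(tape, out, function(nd) {
    g <- nd$grad
    dX <- matrix(0, nrow(X), 3 * C)
    dB <- vector("list", heads)
    for (h in seq_len(heads)) dB[[h]] <- 0
    for (w in seq_len(nwin)) {
      idx <- windows[[w]]
      Xw <- X[idx, , drop = FALSE]
      for (h in seq_len(heads)) {
        qc <- ((h - 1) * d + 1):(h * d)
        Q <- Xw[, qc, drop = FALSE]
        K <- Xw[, C + qc, drop = FALSE]
        V <- Xw[, 2 * C + qc, drop = FALSE]
        A <- Acache[[(w - 1) * heads + h]]
        dO <- g[idx, qc, drop = FALSE]
        dA <- tcrossprod(dO, V)
        dV <- crossprod(A, dO)
        dS <- A * (dA - rowSums(dA * A))
        dB[[h]] <- dB[[h]] + dS
        dX[idx, qc] <- dX[idx, qc] + (dS %*% K) * scale
        dX[idx, C + qc] <- dX[idx, C + qc] + crossprod(dS, Q) * scale
        dX[idx, 2 * C + qc] <- dX[idx, 2 * C + qc] + dV
      }
    }
    ag_acc(qkv, dX)
    dtab <- matrix(0, nrow(bias_table$value), heads)
    for (h in seq_len(heads)) {
      rs <- rowsum(as.vector(dB[[h]]), group = as.vector(bias_idx))
      dtab[as.integer(rownames(rs)), h] <-
        dtab[as.integer(rownames(rs)), h] + rs[, 1]
    }
    ag_acc(bias_table, dtab)
  })
}

# ---- im2col convolution ----------------------------------------------------

# x: (H*W) x Cin node; meta from conv_meta(); W: (KK*Cin) x Cout; b: Cout
ag_conv <- function(tape, x, W, b, meta, x_needs_grad = TRUE) {
  X <- x$value
  Cin <- ncol(X)
  KK <- ncol(meta$idx)
  n_out <- nrow(meta$idx)
  P <- matrix(0, n_out, KK * Cin)
  for (k in seq_len(KK)) {
    sel <- meta$idx[, k]
    pos <- sel > 0
    blk <- matrix(0, n_out, Cin)
    blk[pos, ] <- X[sel[pos], , drop = FALSE]
    P[, ((k - 1) * Cin + 1):(k * Cin)] <- blk
  }
  val <- P %*% W$value + rep(b$value, each = n_out)
  ag_node(tape, val, function(nd) {
    g <- nd$grad
    dP <- g %*% t(W$value)
    ag_acc(W, crossprod(P, g))
    ag_acc(b, colSums(g))
    if (x_needs_grad) {
      dX <- matrix(0, nrow(X), Cin)
      for (k in seq_len(KK)) {
        sel <- meta$idx[, k]
        pos <- sel > 0
        dX[sel[pos], ] <- dX[sel[pos], , drop = FALSE] +
          dP[pos, ((k - 1) * Cin + 1):(k * Cin), drop = FALSE]
      }
      ag_acc(x, dX)
    }
  })
}

# index map for a kh x kw convolution with stride and symmetric zero padding
# over an H x W grid whose rows are flattened row-major (p = (r-1)*W + c)
conv_meta <- function(H, W, kh, kw, stride, pad) {
  ho <- (H + 2 * pad - kh) %/% stride + 1
  wo <- (W + 2 * pad - kw) %/% stride + 1
  idx <- matrix(0L, ho * wo, kh * kw)
  p <- 0L
  for (ro in seq_len(ho)) {
    for (co in seq_len(wo)) {
      p <- p + 1L
      k <- 0L
      for (dr in seq_len(kh)) {
        for (dc in seq_len(kw)) {
          k <- k + 1L
          r <- (ro - 1) * stride + dr - pad
          c <- (co - 1) * stride + dc - pad
          if (r >= 1 && r <= H && c >= 1 && c <= W) {
            idx[p, k] <- (r - 1L) * W + c
          }
        }
      }
    }
  }
  list(idx = idx, out_h = ho, out_w = wo)
}

# ---- scalar reductions -----------------------------------------------------

# sum(L * w) / denom as a scalar node
ag_weighted_mean <- function(tape, L, w, denom) {
  ag_node(tape, sum(L$value * w) / denom, function(nd) {
    ag_acc(L, nd$grad * w / denom)
  })
}

ag_mean_all <- function(tape, x) {
  n <- length(x$value)
  ag_node(tape, sum(x$value) / n, function(nd) {
    ag_acc(x, matrix(nd$grad / n, nrow(x$value), ncol(x$value)))
  })
}

ag_sum_scalars <- function(tape, nodes, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(nodes))
  val <- sum(vapply(seq_along(nodes), function(i)
    nodes[[i]]$value * weights[i], numeric(1)))
  ag_node(tape, val, function(nd) {
    for (i in seq_along(nodes)) ag_acc(nodes[[i]], nd$grad * weights[i])
  })
}

# log(1 - s) and log(s) on a scalar in (0,1), clamped away from the poles
ag_log1m_clamped <- function(tape, s, eps = 1e-6) {
  v <- min(max(s$value, eps), 1 - eps)
  ag_node(tape, log(1 - v), function(nd) {
    g <- if (s$value > eps && s$value < 1 - eps) -nd$grad / (1 - v) else 0
    ag_acc(s, g)
  })
}

ag_log_clamped <- function(tape, s, eps = 1e-6) {
  v <- min(max(s$value, eps), 1 - eps)
  ag_node(tape, log(v), function(nd) {
    g <- if (s$value > eps && s$value < 1 - eps) nd$grad / v else 0
    ag_acc(s, g)
  })
}

# uncertainty-attenuated per-pixel completion loss (see pixel_loss())
ag_pixel_loss <- function(tape, m, u, target, eps = 1e-3,
                          form = "attenuated") {
  M <- m$value; U <- u$value
  if (form == "attenuated") {
    r <- (target - M) / (U + eps)
    val <- 0.5 * (r^2 + U^2)
    ag_node(tape, val, function(nd) {
      g <- nd$grad
      ag_acc(m, g * (-r / (U + eps)))
      ag_acc(u, g * (-r^2 / (U + eps) + U))
    })
  } else {
    r <- target - M * U
    val <- 0.5 * (r^2 + U^2)
    ag_node(tape, val, function(nd) {
      g <- nd$grad
      ag_acc(m, g * (-r * U))
      ag_acc(u, g * (-r * M + U))
    })
  }
}
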