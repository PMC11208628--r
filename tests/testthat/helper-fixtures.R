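# shared fixtures, built in code

random_mask <- function(h, w, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.1, 0.9)
  matrix(rbinom(h * w, 1, p), h, w)
}

disk_mask <- function(size, cy, cx, r) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  matrix(as.integer((yy - cy)^2 + (xx - cx)^2 <= r^2), size, size)
}

flat_image <- function(h, w, value = 120) {
  array(value, c(h, w, 3))
}

# a two-disk scene with a known stacking: disk 2 placed above disk 1
two_disk_scene <- function(size = 48, r = 10, sep = 8) {
  a1 <- disk_mask(size, size / 2, size / 2 - sep / 2, r)
  a2 <- disk_mask(size, size / 2, size / 2 + sep / 2, r)
  m1 <- as_mask(a1 * (1L - a2))
  m2 <- a2
  scene_record(flat_image(size, size),
               list(instance_record(1L, m1, a1),
                    instance_record(2L, m2, a2)),
               order_matrix = matrix(c(0L, 1L, -1L, 0L), 2, 2))
}

# convex polygon (approximate circle) for MVC checks
convex_polygon <- function(n = 16, cy = 10, cx = 10, r = 6) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cy + r * sin(th), cx + r * cos(th))
}

# dense softmax attention, written independently of the package path
dense_attention_oracle <- function(Q, K, V, d_k) {
  S <- Q %*% t(K) / sqrt(d_k)
  E <- exp(S - apply(S, 1, max))
  (E / rowSums(E)) %*% V
}

# independent oracle for the MVC membrane: discrete harmonic membrane
# with the same Dirichlet data, solved as a sparse Laplace system
laplace_membrane <- function(mask, bvals) {
  bnd <- extract_boundary(mask)
  inner <- mask * (1L - bnd)
  idx <- which(inner == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  id <- matrix(0L, nrow(mask), ncol(mask)); id[idx] <- seq_len(n)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  rhs <- numeric(n)
  for (k in seq_len(n)) {
    r <- idx[k, 1]; c <- idx[k, 2]
    ti <- c(ti, k); tj <- c(tj, k); tx <- c(tx, 4)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (inner[rr, cc] == 1L) {
        ti <- c(ti, k); tj <- c(tj, id[rr, cc]); tx <- c(tx, -1)
      } else {
        rhs[k] <- rhs[k] + bvals[rr, cc]
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  out <- matrix(0, nrow(mask), ncol(mask))
  out[idx] <- as.numeric(Matrix::solve(A, rhs))
  out
}

# training is expensive: run the desk-scale smoke experiment once per
# session and cache the result for every test that needs a trained model
smoke_cache <- new.env(parent = emptyenv())

smoke_experiment <- function() {
  if (!is.null(smoke_cache$res)) return(smoke_cache$res)
  sp <- scene_spec(shape = "disk", seed = 1)
  train_scenes <- generate_scenes(sp, 200, seed = 1001)
  test_scenes <- generate_scenes(sp, 20, seed = 2001)
  sp_pairs <- scene_spec(shape = "disk", n_range = c(2L, 2L),
                         distractors = 0, seed = 1)
  test_pairs <- generate_scenes(sp_pairs, 25, seed = 3001)
  net <- build_network(net_config("tiny_test"), seed = 2)
  disc <- build_discriminator(seed = 3)
  cfg <- train_config(lr = 0.4, batch_size = 24L, iterations = 300L,
                      val_period = 50L, n_val = 8L, eps = 0.05,
                      d_lr = 0.002, clip_norm = 1, seed = 7)
  res <- train(net, disc, train_scenes, cfg)
  smoke_cache$res <- list(
    net = res$net, disc = res$disc, trace = res$trace,
    eval_pairs = evaluate_scenes(res$net, test_pairs,
                                 threshold = cfg$binarize_threshold),
    eval_scenes = evaluate_scenes(res$net, test_scenes,
                                  threshold = cfg$binarize_threshold),
    test_pairs = test_pairs, test_scenes = test_scenes, cfg = cfg)
  smoke_cache$res
}
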