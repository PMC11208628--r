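#' Training configuration for the partial-completion game
#'
#' Defaults follow the full-scale recipe (SGD with momentum 0.9, weight
#' decay 1e-4, batch size 32, occluded-region weight gamma = 5,
#' validation every 2000 iterations, learning-rate multiplier 0.1 applied
#' late in training, binarization threshold 0.2); desk-scale experiments
#' pass smaller `iterations` / `batch_size` and the `tiny_test` network.
#'
#' @param gamma occluded-region loss weight (> 0).
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 decay applied to weight matrices.
#' @param batch_size completion samples per iteration.
#' @param iterations total SGD iterations.
#' @param val_period validate (and checkpoint on improvement) every this
#'   many iterations.
#' @param lr_multiplier factor applied to the learning rate at
#'   `lr_drop_at` of the run.
#' @param lr_drop_at fraction of iterations after which the multiplier
#'   applies.
#' @param binarize_threshold threshold for amodal binarization, in (0,1).
#' @param p_occluded share of occluded (vs regularization) cases.
#' @param adv_weight weight of the adversarial term in the total loss.
#' @param d_lr discriminator learning rate.
#' @param eps stabiliser of the attenuated pixel loss.
#' @param loss_form `"attenuated"` or `"literal"` pixel loss.
#' @param clip_norm clip the global gradient norm to this value before
#'   each update (`Inf` disables clipping).
#' @param low_res_frac fraction of the run trained on images downscaled
#'   by `low_res_scale` before switching to full resolution (the
#'   coarse-to-fine schedule; 0 disables it).
#' @param low_res_scale integer downscale factor of the first stage.
#' @param high_res_lr_mult learning-rate multiplier applied in the
#'   full-resolution stage (the fine stage trains with a smaller rate);
#'   momentum is reset at the switch.
#' @param val_fraction share of scenes held out for validation.
#' @param n_val validation samples drawn per validation pass.
#' @param seed integer seed governing sampling and initial conditions.
#' @return list of class `train_config`.
#' @export
train_config <- function(gamma = 5, lr = 0.05, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 32L,
                         iterations = 50000L, val_period = 2000L,
                         lr_multiplier = 0.1, lr_drop_at = 0.8,
                         binarize_threshold = 0.2, p_occluded = 0.5,
                         adv_weight = 1, d_lr = 0.01, eps = 1e-3,
                         loss_form = "attenuated", clip_norm = 5,
                         low_res_frac = 0, low_res_scale = 2L,
                         high_res_lr_mult = 0.3,
                         val_fraction = 0.1, n_val = 8L, seed = 1L) {
  stopifnot(gamma > 0, binarize_threshold > 0, binarize_threshold < 1)
  structure(list(gamma = gamma, lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 val_period = as.integer(val_period),
                 lr_multiplier = lr_multiplier, lr_drop_at = lr_drop_at,
                 binarize_threshold = binarize_threshold,
                 p_occluded = p_occluded, adv_weight = adv_weight,
                 d_lr = d_lr, eps = eps, loss_form = loss_form,
                 clip_norm = clip_norm, low_res_frac = low_res_frac,
                 low_res_scale = as.integer(low_res_scale),
                 high_res_lr_mult = high_res_lr_mult,
                 val_fraction = val_fraction, n_val = as.integer(n_val),
                 seed = as.integer(seed)),
            class = "train_config")
}

# block-mean downscale of an image channel
.down_channel <- function(m, f) {
  h <- nrow(m) %/% f; w <- ncol(m) %/% f
  out <- matrix(0, h, w)
  for (a in seq_len(f)) for (b in seq_len(f)) {
    out <- out + m[seq(a, by = f, length.out = h),
                   seq(b, by = f, length.out = w)]
  }
  out / f^2
}

.down_mask <- function(m, f) {
  matrix(as.integer(.down_channel(m, f) >= 0.5), nrow(m) %/% f)
}

# downscaled view of a completion sample for the coarse training stage
.sample_downscale <- function(smp, f) {
  if (f <= 1) return(smp)
  img <- array(0, c(dim(smp$erased_image)[1] %/% f,
                    dim(smp$erased_image)[2] %/% f, 3))
  for (ch in 1:3) img[, , ch] <- .down_channel(smp$erased_image[, , ch], f)
  target <- .down_mask(smp$target, f)
  eraser <- .down_mask(smp$eraser, f)
  input_modal <- if (smp$case == "occluded") {
    as_mask(target * (1L - eraser))
  } else target
  for (ch in 1:3) img[, , ch][eraser == 1L] <- 0
  list(erased_image = img, input_modal = input_modal,
       boundary = extract_boundary(eraser), eraser = eraser,
       target = target, case = smp$case)
}

# global L2 norm of a nested gradient list (NULLs count as zero)
.grad_norm <- function(grads) {
  s <- 0
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el)
    else if (!is.null(x)) s <<- s + sum(x^2)
  }
  walk(grads)
  sqrt(s)
}

.scale_grads <- function(grads, f) {
  lapply(grads, function(g) {
    if (is.list(g)) .scale_grads(g, f) else if (!is.null(g)) g * f
  })
}

# recursive SGD-with-momentum update; weight decay only on matrices
.sgd_step <- function(params, grads, bufs, lr, momentum, wd) {
  for (nm in names(params)) {
    p <- params[[nm]]; g <- grads[[nm]]
    if (is.list(p)) {
      upd <- .sgd_step(p, g, bufs[[nm]], lr, momentum, wd)
      params[[nm]] <- upd$params; bufs[[nm]] <- upd$bufs
    } else {
      if (is.null(g)) next
      if (is.matrix(p) && wd > 0) g <- g + wd * p
      v <- momentum * bufs[[nm]] - lr * g
      bufs[[nm]] <- v
      params[[nm]] <- p + v
    }
  }
  list(params = params, bufs = bufs)
}

.zeros_like <- function(params) {
  lapply(params, function(p) {
    if (is.list(p)) .zeros_like(p) else p * 0
  })
}

# centre the instance being completed; training and inference share the
# same canonical frame
.center_sample <- function(smp) {
  sh <- .center_shift(smp$input_modal)
  if (sh[1] == 0 && sh[2] == 0) return(smp)
  smp$erased_image <- .shift_image(smp$erased_image, sh[1], sh[2])
  smp$input_modal <- mask_shift(smp$input_modal, sh[1], sh[2])
  smp$boundary <- mask_shift(smp$boundary, sh[1], sh[2])
  smp$eraser <- mask_shift(smp$eraser, sh[1], sh[2])
  smp$target <- mask_shift(smp$target, sh[1], sh[2])
  smp
}

.sample_loss_nodes <- function(net, disc, smp, cfg, tape, pn, dn) {
  smp <- .center_sample(smp)
  input <- completion_input(smp$erased_image, smp$input_modal,
                            smp$boundary)
  out <- net_forward_nodes(net, input, tape, pn)
  H <- nrow(smp$target); W <- ncol(smp$target)
  tgt <- as.vector(t(smp$target))      # row-major, like the output nodes
  er <- as.vector(t(smp$eraser))
  L <- ag_pixel_loss(tape, out$m, out$u, tgt, eps = cfg$eps,
                     form = cfg$loss_form)
  N <- H * W
  l_in <- ag_weighted_mean(tape, L, cfg$gamma * (er == 1), N)
  l_out <- ag_weighted_mean(tape, L, 1 * (er == 0), N)
  adv <- NULL
  if (cfg$adv_weight > 0) {
    d_fake <- disc_forward_nodes(disc, out$m, H, W, tape, dn,
                                 input_needs_grad = TRUE)
    adv <- ag_log1m_clamped(tape, d_fake)
  }
  list(l_in = l_in, l_out = l_out, adv = adv, m_value = out$m$value,
       target = tgt, H = H, W = W)
}

#' Train the partial-completion network
#'
#' Self-supervised training: every iteration draws a batch of
#' completion samples from the training scenes (modal masks only — no
#' amodal labels are read), minimises
#' `L = L_in + L_out + L_adv` by SGD with momentum, and updates the mask
#' discriminator on alternating real (target-mask) / fake (predicted
#' map) examples. Validation loss is computed every `val_period`
#' iterations on samples from held-out scenes; the best-validation
#' parameters are kept as the checkpoint. A non-finite loss aborts
#' training and returns the last good checkpoint.
#'
#' @param net an `amodal_net` (modified in place and returned).
#' @param disc a `mask_disc` (or `NULL` to train without the adversarial
#'   term).
#' @param scenes list of training `scene_record`s.
#' @param cfg a [train_config()].
#' @param verbose print a summary line every 50 iterations.
#' @return list with `net` (best-validation parameters), `disc`, and
#'   `trace` (data frame: iteration, l_in, l_out, l_adv, total,
#'   val_loss).
#' @export
train <- function(net, disc, scenes, cfg = train_config(),
                  verbose = FALSE) {
  set.seed(cfg$seed)
  if (is.null(disc)) cfg$adv_weight <- 0
  n_val_scenes <- max(1, round(length(scenes) * cfg$val_fraction))
  val_scenes <- scenes[seq(length(scenes) - n_val_scenes + 1,
                           length(scenes))]
  train_scenes <- scenes[seq_len(length(scenes) - n_val_scenes)]
  bufs <- .zeros_like(net$params)
  dbufs <- if (!is.null(disc)) .zeros_like(disc$params)
  trace <- data.frame(iteration = integer(0), l_in = numeric(0),
                      l_out = numeric(0), l_adv = numeric(0),
                      total = numeric(0), val_loss = numeric(0))
  best_val <- Inf
  best_params <- net$params
  last_good <- net$params
  val_loss_at <- NA_real_
  switch_at <- ceiling(cfg$low_res_frac * cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    lr <- cfg$lr * if (it > cfg$lr_drop_at * cfg$iterations)
      cfg$lr_multiplier else 1
    if (cfg$low_res_frac > 0 && it > switch_at) {
      lr <- lr * cfg$high_res_lr_mult
      if (it == switch_at + 1L) bufs <- .zeros_like(net$params)
    }
    tape <- ag_tape()
    pn <- wrap_params(tape, net$params)
    dn <- if (!is.null(disc)) wrap_params(tape, disc$params)
    low_res <- cfg$low_res_frac > 0 &&
      it <= cfg$low_res_frac * cfg$iterations
    batch <- lapply(seq_len(cfg$batch_size), function(k) {
      smp <- sample_completion_pair(train_scenes,
                                    p_occluded = cfg$p_occluded)
      if (low_res) .sample_downscale(smp, cfg$low_res_scale) else smp
    })
    parts <- lapply(batch, function(smp)
      .sample_loss_nodes(net, disc, smp, cfg, tape, pn, dn))
    l_in_b <- ag_sum_scalars(tape, lapply(parts, `[[`, "l_in"),
                             rep(1 / cfg$batch_size, cfg$batch_size))
    l_out_b <- ag_sum_scalars(tape, lapply(parts, `[[`, "l_out"),
                              rep(1 / cfg$batch_size, cfg$batch_size))
    objective <- ag_sum_scalars(tape, list(l_in_b, l_out_b))
    l_adv_val <- 0
    if (cfg$adv_weight > 0) {
      adv_b <- ag_sum_scalars(tape, lapply(parts, `[[`, "adv"),
                              rep(1 / cfg$batch_size, cfg$batch_size))
      objective <- ag_sum_scalars(tape, list(objective, adv_b),
                                  c(1, cfg$adv_weight))
      # report the full adversarial loss (fake + real expectations)
      d_real <- vapply(batch, function(smp)
        discriminator_score(disc, smp$target), numeric(1))
      l_adv_val <- adv_b$value + mean(log(pmax(1e-6, d_real)))
    }
    total_val <- l_in_b$value + l_out_b$value +
      cfg$adv_weight * l_adv_val
    if (!is.finite(objective$value)) {
      warning(sprintf("non-finite loss at iteration %d; %s", it,
                      "stopping with the last good checkpoint"))
      net$params <- last_good
      break
    }
    ag_backward(tape, objective)
    grads <- collect_grads(pn)
    gn <- .grad_norm(grads)
    if (is.finite(cfg$clip_norm) && gn > cfg$clip_norm) {
      grads <- .scale_grads(grads, cfg$clip_norm / gn)
    }
    upd <- .sgd_step(net$params, grads, bufs, lr,
                     cfg$momentum, cfg$weight_decay)
    net$params <- upd$params
    bufs <- upd$bufs
    last_good <- net$params
    if (cfg$adv_weight > 0) {
      dt <- ag_tape()
      dn2 <- wrap_params(dt, disc$params)
      terms <- list()
      for (p in parts) {
        fake <- ag_leaf(dt, p$m_value)
        real <- ag_leaf(dt, p$target)
        sf <- disc_forward_nodes(disc, fake, p$H, p$W, dt, dn2,
                                 input_needs_grad = FALSE)
        sr <- disc_forward_nodes(disc, real, p$H, p$W, dt, dn2,
                                 input_needs_grad = FALSE)
        terms[[length(terms) + 1L]] <- ag_log1m_clamped(dt, sf)
        terms[[length(terms) + 1L]] <- ag_log_clamped(dt, sr)
      }
      dloss <- ag_sum_scalars(dt, terms, rep(-1 / length(terms),
                                             length(terms)))
      ag_backward(dt, dloss)
      dupd <- .sgd_step(disc$params, collect_grads(dn2), dbufs,
                        cfg$d_lr, cfg$momentum, cfg$weight_decay)
      disc$params <- dupd$params
      dbufs <- dupd$bufs
    }
    if (it %% cfg$val_period == 0 || it == cfg$iterations) {
      val_loss_at <- .validation_loss(net, disc, val_scenes, cfg, it)
      if (is.finite(val_loss_at) && val_loss_at < best_val) {
        best_val <- val_loss_at
        best_params <- net$params
      }
    } else {
      val_loss_at <- NA_real_
    }
    trace[nrow(trace) + 1L, ] <- list(it, l_in_b$value, l_out_b$value,
                                      l_adv_val, total_val, val_loss_at)
    if (verbose && it %% 50 == 0) {
      message(sprintf("iter %4d  lr %.4g  L_in %.4f  L_out %.4f  L_adv %.4f  total %.4f",
                      it, lr, l_in_b$value, l_out_b$value, l_adv_val,
                      total_val))
    }
  }
  net$params <- best_params
  list(net = net, disc = disc, trace = trace, best_val = best_val)
}

.validation_loss <- function(net, disc, val_scenes, cfg, it) {
  # fixed derived seed so successive validations see comparable samples
  samples <- with_seed(cfg$seed + 7919L, lapply(seq_len(cfg$n_val),
    function(k) sample_completion_pair(val_scenes,
                                       p_occluded = cfg$p_occluded)))
  tot <- 0
  for (smp in samples) {
    smp <- .center_sample(smp)
    input <- completion_input(smp$erased_image, smp$input_modal,
                              smp$boundary)
    pred <- net_predict(net, input)
    L <- pixel_loss(pred$m, pred$u, smp$target, eps = cfg$eps,
                    form = cfg$loss_form)
    tot <- tot + as.numeric(region_weighted_loss(L, smp$eraser,
                                                 cfg$gamma))
  }
  tot / length(samples)
}
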