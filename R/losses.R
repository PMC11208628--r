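#' Uncertainty-attenuated per-pixel completion loss
#'
#' The default (attenuated) form divides the prediction error by the
#' predicted boundary uncertainty, so regions the network flags as
#' uncertain contribute a lower segmentation loss, while the `u^2` term
#' regularises the uncertainty map towards zero:
#' \deqn{L_i = \tfrac12\Big[\Big(\frac{m_i^t - m_i}{u_i +
#'   \varepsilon}\Big)^2 + u_i^2\Big].}
#' A `literal` form, \eqn{L_i = \tfrac12[(m_i^t - m_i u_i)^2 + u_i^2]},
#' is available behind the `form` flag.
#'
#' @param m predicted amodal probability map (values in `[0, 1]`).
#' @param u predicted uncertainty map (values >= 0).
#' @param target binary target mask (the full visible mask of the
#'   instance before synthetic erasure).
#' @param eps stabiliser added to `u` in the attenuated form.
#' @param form `"attenuated"` (default) or `"literal"`.
#' @return per-pixel loss map (same shape as the inputs), everywhere
#'   >= 0.
#' @export
pixel_loss <- function(m, u, target, eps = 1e-3,
                       form = c("attenuated", "literal")) {
  form <- match.arg(form)
  if (any(is.na(m)) || any(is.na(u)) || any(is.na(target))) {
    stop("NaN/NA in pixel_loss inputs")
  }
  stopifnot(all(dim(m) == dim(u)), all(dim(m) == dim(target)),
            all(u >= 0))
  if (form == "attenuated") {
    0.5 * (((target - m) / (u + eps))^2 + u^2)
  } else {
    0.5 * ((target - m * u)^2 + u^2)
  }
}

#' Region-weighted completion loss
#'
#' Splits the per-pixel loss map into the part inside the synthetic
#' occluder (the erased region, weighted by `gamma`) and the part
#' outside it, both normalised by the total pixel count `N`:
#' \deqn{L_{in} = \frac{1}{N}\sum_i \gamma\,[m_i^c = 1]\,L_i,\qquad
#'       L_{out} = \frac{1}{N}\sum_i [m_i^c = 0]\,L_i.}
#' With `gamma = 1` the sum equals the plain mean of the loss map; an
#' empty eraser contributes zero to the inside term.
#'
#' @param L per-pixel loss map.
#' @param eraser binary occluder mask `m^c` (same shape as `L`).
#' @param gamma weight of the occluded-region term (default 5).
#' @return scalar `L_in + L_out`, with the two parts in attributes
#'   `in_mask` and `out_mask`.
#' @export
region_weighted_loss <- function(L, eraser, gamma = 5) {
  stopifnot(all(dim(L) == dim(eraser)))
  N <- length(L)
  l_in <- gamma * sum(L * (eraser == 1)) / N
  l_out <- sum(L * (eraser == 0)) / N
  structure(l_in + l_out, in_mask = l_in, out_mask = l_out)
}

#' Adversarial loss of a batch of completed masks
#'
#' Batch means stand in for the expectations in
#' \deqn{L_{adv} = E_m[\log(1 - D(m))] + E_{m^r}[\log D(m^r)],}
#' where `D` is the mask discriminator, `m` ranges over predicted amodal
#' maps and `m^r` over real mask samples. Scores are clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param pred_masks list of predicted `H x W` maps in `[0, 1]`.
#' @param real_masks list of real binary masks.
#' @param disc a `mask_disc`.
#' @param eps clamping bound.
#' @return scalar loss (<= 0 when the discriminator is calibrated).
#' @export
adversarial_loss <- function(pred_masks, real_masks, disc, eps = 1e-6) {
  stopifnot(length(pred_masks) > 0, length(real_masks) > 0)
  clamp <- function(p) pmin(1 - eps, pmax(eps, p))
  d_fake <- vapply(pred_masks, function(m)
    clamp(discriminator_score(disc, m)), numeric(1))
  d_real <- vapply(real_masks, function(m)
    clamp(discriminator_score(disc, m)), numeric(1))
  mean(log(1 - d_fake)) + mean(log(d_real))
}

#' Total training loss
#'
#' The exact sum of its parts: the region-weighted completion terms and
#' the adversarial term, `L = L_in + L_out + L_adv`.
#'
#' @param parts numeric vector (or list) of finite loss components.
#' @return scalar sum.
#' @export
total_loss <- function(parts) {
  v <- unlist(parts, use.names = FALSE)
  if (any(!is.finite(v))) stop("loss components must be finite")
  sum(v)
}
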