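#' @title Training loop
#'
#' @description
#' Seeded end-to-end training of the detection model with an AdamW-type
#' optimiser (decoupled weight decay, betas 0.9/0.999). Reference defaults
#' follow the published full-scale recipe: learning rate `1e-4`, weight
#' decay `0.05`, 24 epochs; the CPU-scale smoke configuration uses the tiny
#' variant with a learning rate appropriate to its size (see the package
#' vignette). The learning-rate schedule is constant by default with an
#' optional step decay.
#'
#' @name training
NULL

#' Mean training loss of a model over a set of scenes
#'
#' Evaluates the full training objective (no parameter updates) on every
#' scene and returns the mean breakdown. This is the quantity the training
#' smoke tests compare before and after optimisation.
#'
#' @param model a `spike_model`.
#' @param scenes list of annotated images.
#' @param cfg a [loss_config()].
#' @return list with mean `total`, `l_cls`, `l_ctr`, `l_reg`.
#' @export
dataset_loss <- function(model, scenes, cfg = loss_config()) {
  tot <- cls <- ctr <- reg <- 0
  for (sc in scenes) {
    outs <- model_forward(pad_image_32(sc$image), model)
    dims <- lapply(outs, function(o) list(h = o$h, w = o$w, stride = o$stride))
    lb <- compute_losses(outs, assign_targets(dims, sc$boxes), cfg)
    tot <- tot + lb$total; cls <- cls + lb$l_cls
    ctr <- ctr + lb$l_ctr; reg <- reg + lb$l_reg
  }
  n <- length(scenes)
  list(total = tot / n, l_cls = cls / n, l_ctr = ctr / n, l_reg = reg / n)
}

adamw_state <- function(params) {
  list(m = nested_map(function(x) x * 0, unclass(params)),
       v = nested_map(function(x) x * 0, unclass(params)),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, wd,
                       betas = c(0.9, 0.999), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  state$m <- nested_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- nested_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  new_params <- nested_map(function(x, m, v) {
    x - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * x)
  }, unclass(params), state$m, state$v)
  attributes(new_params) <- attributes(params)
  list(params = new_params, state = state)
}

#' Train a detection model on annotated scenes
#'
#' One image per iteration, cycling through the dataset in a seeded random
#' order. Assignments are computed once per image and cached. Returns the
#' trained model and the per-iteration loss trace.
#'
#' @param model a `spike_model`.
#' @param scenes list of annotated images (each with `image`, `boxes`).
#' @param iterations number of optimiser steps.
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay.
#' @param cfg a [loss_config()].
#' @param seed integer seed for the sampling order.
#' @param lr_decay_at optional iteration at which to multiply the rate by
#'   `lr_decay_factor` (default none).
#' @param lr_decay_factor step-decay factor.
#' @param log_file optional CSV path receiving one row per iteration.
#' @param verbose print progress every 25 iterations.
#' @return list with `model`, `trace` (data frame of per-iteration losses),
#'   `final_lr`.
#' @export
train_model <- function(model, scenes, iterations = 200L, lr = 1e-3,
                        weight_decay = 0.05, cfg = loss_config(),
                        seed = 1L, lr_decay_at = NULL, lr_decay_factor = 0.1,
                        log_file = NULL, verbose = FALSE) {
  stopifnot(length(scenes) >= 1L)
  spec <- model$spec
  st_b <- adamw_state(model$backbone)
  st_d <- adamw_state(model$detector)
  assign_cache <- vector("list", length(scenes))
  trace <- data.frame(iteration = integer(), l_cls = numeric(),
                      l_ctr = numeric(), l_reg = numeric(), total = numeric(),
                      lr = numeric(), n_pos = integer())
  order_idx <- with_local_seed(seed, {
    unlist(lapply(seq_len(ceiling(iterations / length(scenes))),
                  function(i) sample(length(scenes))))
  })[seq_len(iterations)]
  if (!is.null(log_file)) {
    utils::write.table(trace, log_file, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double")
  }
  cur_lr <- lr
  for (it in seq_len(iterations)) {
    if (!is.null(lr_decay_at) && it == lr_decay_at) {
      cur_lr <- cur_lr * lr_decay_factor
    }
    si <- order_idx[it]
    sc <- scenes[[si]]
    image <- pad_image_32(sc$image)
    ad_reset()
    bn <- params_to_nodes(model$backbone)
    dn <- params_to_nodes(model$detector)
    outs <- model_forward_ad(image, bn, dn, spec, new.env(parent = emptyenv()))
    if (is.null(assign_cache[[si]])) {
      dims <- lapply(outs, function(o) list(h = o$h, w = o$w, stride = o$stride))
      assign_cache[[si]] <- assign_targets(dims, sc$boxes)
    }
    ls <- compute_losses_ad(outs, assign_cache[[si]], cfg)
    row <- data.frame(iteration = it, l_cls = as.numeric(ls$l_cls$value),
                      l_ctr = as.numeric(ls$l_ctr$value),
                      l_reg = as.numeric(ls$l_reg$value),
                      total = as.numeric(ls$total$value), lr = cur_lr,
                      n_pos = assign_cache[[si]]$n_pos)
    trace <- rbind(trace, row)
    ad_backward(ls$total)
    gb <- nodes_to_grads(bn)
    gd <- nodes_to_grads(dn)
    ad_reset()
    up <- adamw_step(model$backbone, gb, st_b, cur_lr, weight_decay)
    model$backbone <- up$params; st_b <- up$state
    up <- adamw_step(model$detector, gd, st_d, cur_lr, weight_decay)
    model$detector <- up$params; st_d <- up$state
    if (!is.null(log_file)) {
      utils::write.table(row, log_file, sep = ",", row.names = FALSE,
                         col.names = FALSE, append = TRUE, qmethod = "double")
    }
    if (verbose && (it %% 25L == 0L || it == 1L)) {
      message(sprintf("iter %4d  total %.4f (cls %.4f ctr %.4f reg %.4f)",
                      it, row$total, row$l_cls, row$l_ctr, row$l_reg))
    }
  }
  list(model = model, trace = trace, final_lr = cur_lr)
}
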