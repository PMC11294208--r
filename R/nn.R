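# Shared neural-network plumbing: parameter initialisation, one-hidden-layer
# MLPs expressed on the autodiff tape, and an Adam optimiser operating on a
# named list of parameter matrices.

init_mlp <- function(d_in, d_hidden, d_out, prefix, scale = 1) {
  # He-style scaling keeps tanh units away from saturation at init
  p <- list()
  p[[paste0(prefix, "_W1")]] <- matrix(
    stats::rnorm(d_in * d_hidden, sd = scale / sqrt(d_in)), d_in, d_hidden)
  p[[paste0(prefix, "_b1")]] <- matrix(0, 1L, d_hidden)
  p[[paste0(prefix, "_W2")]] <- matrix(
    stats::rnorm(d_hidden * d_out, sd = scale / sqrt(d_hidden)), d_hidden, d_out)
  p[[paste0(prefix, "_b2")]] <- matrix(0, 1L, d_out)
  p
}

# Wrap every parameter matrix as a gradient-tracked leaf for this pass.
leaf_params <- function(tape, params) {
  lapply(params, function(w) ad_leaf(tape, w))
}

mlp_forward <- function(tape, lp, prefix, x) {
  h <- ad_tanh(tape, ad_linear(tape, x,
                               lp[[paste0(prefix, "_W1")]],
                               lp[[paste0(prefix, "_b1")]]))
  ad_linear(tape, h, lp[[paste0(prefix, "_W2")]], lp[[paste0(prefix, "_b2")]])
}

# Plain (off-tape) MLP evaluation for prediction paths that need no gradient.
mlp_eval <- function(params, prefix, x) {
  h <- tanh(sweep(x %*% params[[paste0(prefix, "_W1")]], 2L,
                  params[[paste0(prefix, "_b1")]][1L, ], "+"))
  sweep(h %*% params[[paste0(prefix, "_W2")]], 2L,
        params[[paste0(prefix, "_b2")]][1L, ], "+")
}

adam_state <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

collect_grads <- function(lp) {
  lapply(lp, function(nd) nd$grad)
}

clip_01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
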