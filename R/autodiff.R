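# Minimal tape-based reverse-mode automatic differentiation on dense matrices.
# All model code in this package (state-space networks, LSTM, attribution
# gradients) runs on these primitives; gradients are exact up to floating
# point and are checked against central finite differences in the tests.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

is_ad_node <- function(x) is.environment(x)

# Wrap a plain matrix as a constant leaf (no gradient tracked).
ad_const <- function(tape, x) {
  ad_node(tape, as.matrix(x))
}

# A leaf whose gradient we want (parameters, or inputs for attribution).
ad_leaf <- function(tape, x) {
  ad_node(tape, as.matrix(x))
}

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, out) {
  stopifnot(length(out$value) == 1L)
  out$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$value))
    acc_grad(nd$parents[[2L]], t(nd$parents[[1L]]$value) %*% nd$grad)
  })
}

# Elementwise add; b may be a 1 x k row (bias) broadcast over rows of a.
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, bv[1L, ], "+")
    ad_node(tape, val, list(a, b), function(nd) {
      acc_grad(nd$parents[[1L]], nd$grad)
      acc_grad(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
    })
  } else {
    ad_node(tape, av + bv, list(a, b), function(nd) {
      acc_grad(nd$parents[[1L]], nd$grad)
      acc_grad(nd$parents[[2L]], nd$grad)
    })
  }
}

ad_sub <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, bv[1L, ], "-")
    ad_node(tape, val, list(a, b), function(nd) {
      acc_grad(nd$parents[[1L]], nd$grad)
      acc_grad(nd$parents[[2L]], matrix(-colSums(nd$grad), 1L))
    })
  } else {
    ad_node(tape, av - bv, list(a, b), function(nd) {
      acc_grad(nd$parents[[1L]], nd$grad)
      acc_grad(nd$parents[[2L]], -nd$grad)
    })
  }
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    acc_grad(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

# Multiply / add by a plain numeric constant (scalar or matrix).
ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * k)
  })
}

ad_shift <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad)
  })
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), local({
    vv <- v
    function(nd) acc_grad(nd$parents[[1L]], nd$grad * (1 - vv^2))
  }))
}

ad_sigmoid <- function(tape, a) {
  v <- stats::plogis(a$value)
  ad_node(tape, v, list(a), local({
    vv <- v
    function(nd) acc_grad(nd$parents[[1L]], nd$grad * vv * (1 - vv))
  }))
}

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_node(tape, v, list(a), local({
    vv <- v
    function(nd) acc_grad(nd$parents[[1L]], nd$grad * vv)
  }))
}

# log(1 + exp(x)), numerically stable
ad_softplus <- function(tape, a) {
  x <- a$value
  v <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  sg <- stats::plogis(x)
  ad_node(tape, v, list(a), local({
    ss <- sg
    function(nd) acc_grad(nd$parents[[1L]], nd$grad * ss)
  }))
}

ad_square <- function(tape, a) {
  ad_node(tape, a$value^2, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * 2 * nd$parents[[1L]]$value)
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(nd) {
    g <- nd$grad[1L, 1L]
    p <- nd$parents[[1L]]
    acc_grad(p, matrix(g, nrow(p$value), ncol(p$value)))
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  val <- do.call(cbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tape, val, nodes, local({
    st <- starts; en <- ends
    function(nd) {
      for (j in seq_along(nd$parents)) {
        acc_grad(nd$parents[[j]], nd$grad[, st[j]:en[j], drop = FALSE])
      }
    }
  }))
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), local({
    ii <- idx
    function(nd) {
      p <- nd$parents[[1L]]
      g <- matrix(0, nrow(p$value), ncol(p$value))
      g[, ii] <- nd$grad
      acc_grad(p, g)
    }
  }))
}

# broadcast a 1 x k row to n x k
ad_rep_rows <- function(tape, a, n) {
  ad_node(tape, matrix(a$value[1L, ], n, ncol(a$value), byrow = TRUE),
          list(a), function(nd) {
            acc_grad(nd$parents[[1L]], matrix(colSums(nd$grad), 1L))
          })
}

ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), local({
    ii <- idx
    function(nd) {
      p <- nd$parents[[1L]]
      g <- matrix(0, nrow(p$value), ncol(p$value))
      g[ii, ] <- g[ii, ] + nd$grad
      acc_grad(p, g)
    }
  }))
}

# --- composite helpers used by the models --------------------------------

# Affine layer: X %*% W + b (b a 1 x k row)
ad_linear <- function(tape, x, w, b) {
  ad_add(tape, ad_mm(tape, x, w), b)
}

# Sum over all entries of elementwise Gaussian log-density
# log N(x | mu, exp(logvar)); x is a constant matrix.
ad_gauss_loglik_sum <- function(tape, x_const, mu, logvar) {
  if (nrow(logvar$value) == 1L && nrow(x_const) > 1L) {
    logvar <- ad_rep_rows(tape, logvar, nrow(x_const))
  }
  d <- ad_sub(tape, ad_const(tape, x_const), mu)
  prec <- ad_exp(tape, ad_scale(tape, logvar, -1))
  quad <- ad_mul(tape, ad_square(tape, d), prec)
  per <- ad_add(tape, logvar, quad)          # logvar broadcast if 1 x k
  tot <- ad_sum(tape, per)
  n <- length(x_const)
  ad_shift(tape, ad_scale(tape, tot, -0.5), -0.5 * n * log(2 * pi))
}

# Sum of Bernoulli log-likelihood from logits: sum over entries of
# y*log(sigmoid(l)) + (1-y)*log(1-sigmoid(l)) = -(softplus(l) - y*l)
ad_bernoulli_loglik_sum <- function(tape, y_const, logit) {
  sp <- ad_softplus(tape, logit)
  yl <- ad_mul(tape, ad_const(tape, y_const), logit)
  ad_scale(tape, ad_sum(tape, ad_sub(tape, sp, yl)), -1)
}

# Sum over entries of KL(N(mu_q, exp(lv_q)) || N(mu_p, exp(lv_p)))
ad_kl_diag_sum <- function(tape, mu_q, lv_q, mu_p, lv_p) {
  dmu <- ad_sub(tape, mu_q, mu_p)
  num <- ad_add(tape, ad_exp(tape, lv_q), ad_square(tape, dmu))
  rat <- ad_mul(tape, num, ad_exp(tape, ad_scale(tape, lv_p, -1)))
  per <- ad_add(tape, ad_sub(tape, lv_p, lv_q), rat)
  ad_scale(tape, ad_shift(tape, ad_sum(tape, per), -length(mu_q$value)), 0.5)
}

# closed-form KL used outside the tape
kl_diag_gaussian <- function(mu_q, lv_q, mu_p, lv_p) {
  0.5 * sum(lv_p - lv_q + (exp(lv_q) + (mu_q - mu_p)^2) / exp(lv_p) - 1)
}
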