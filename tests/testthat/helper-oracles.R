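# Closed-form ELBO oracle for 1-D latent toy instances: plain-arithmetic
# evaluation of the two Gaussian log-densities, the Bernoulli term and the
# KL divergences, written independently of the tape machinery.

oracle_mlp <- function(p, prefix, x) {
  h <- tanh(x %*% p[[paste0(prefix, "_W1")]] +
              matrix(p[[paste0(prefix, "_b1")]], nrow(x),
                     ncol(p[[paste0(prefix, "_b1")]]), byrow = TRUE))
  h %*% p[[paste0(prefix, "_W2")]] +
    matrix(p[[paste0(prefix, "_b2")]], nrow(x),
           ncol(p[[paste0(prefix, "_b2")]]), byrow = TRUE)
}

oracle_elbo_t2 <- function(model, cohort, eps, beta) {
  p <- model$params
  sq <- function(v) 5 * tanh(v / 5)
  kl1d <- function(mq, lq, mp, lp) {
    0.5 * (lp - lq + (exp(lq) + (mq - mp)^2) / exp(lp) - 1)
  }
  nx2 <- normalize_mat(model$norm, matrix(cohort$x[1, 2, ], 1, 11), "x")
  nx1 <- normalize_mat(model$norm, matrix(cohort$x[1, 1, ], 1, 11), "x")
  s <- normalize_mat(model$norm, matrix(cohort$s[1, ], 1, 14), "s")
  a1 <- cohort$a[1, 1]
  dt <- cohort$grid$dt[1] / 12
  # step 1
  q1 <- oracle_mlp(p, "q0", cbind(nx1, s))
  p1 <- oracle_mlp(p, "p0", s)
  mu_q1 <- q1[1]; lv_q1 <- sq(q1[2])
  mu_p1 <- p1[1]; lv_p1 <- sq(p1[2])
  kl <- kl1d(mu_q1, lv_q1, mu_p1, lv_p1)
  z1 <- mu_q1 + exp(0.5 * lv_q1) * eps[1, 1, 1]
  lv_x <- sq(p$dx_logvar[1, ])
  mu_x1 <- oracle_mlp(p, "dx", matrix(z1, 1, 1))
  ll <- sum(dnorm(nx1, mu_x1, exp(0.5 * lv_x), log = TRUE))
  pr_y <- plogis(oracle_mlp(p, "dy", matrix(z1, 1, 1))[1])
  ll_y <- dbinom(cohort$y[1, 1], 1, pr_y, log = TRUE)
  # step 2
  pt2 <- oracle_mlp(p, "pt", cbind(z1, a1, dt, s))
  q2 <- oracle_mlp(p, "qt", cbind(z1, nx2, a1, dt, s))
  mu_q2 <- q2[1]; lv_q2 <- sq(q2[2])
  mu_p2 <- pt2[1]; lv_p2 <- sq(pt2[2])
  kl <- kl + kl1d(mu_q2, lv_q2, mu_p2, lv_p2)
  z2 <- mu_q2 + exp(0.5 * lv_q2) * eps[1, 2, 1]
  mu_x2 <- oracle_mlp(p, "dx", matrix(z2, 1, 1))
  ll <- ll + sum(dnorm(nx2, mu_x2, exp(0.5 * lv_x), log = TRUE))
  list(elbo = ll + ll_y - beta * kl, recon_x = ll, recon_y = ll_y, kl = kl)
}

toy_t2_cohort <- function(seed) {
  withr::with_seed(seed, {
    grid <- time_grid(c(0, 4))
    x <- array(runif(2 * 2 * 11, 0, 10), c(2, 2, 11))
    s <- matrix(rnorm(2 * 14), 2, 14)
    colnames(s) <- static_names
    new_cohort(grid, c("A", "B"), x,
               matrix(1, 2, 1), matrix(1, 2, 1), s)
  })
}

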