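test_that("balanced identical groups yield a zero group coefficient", {
  set.seed(30)
  y_half <- sim_ordinal(rep(0, 120), c(-0.5, 1))
  y <- rep(y_half, 2)
  X <- cbind(g = rep(0:1, each = 120))
  f <- fit_clm(y, X)
  expect_lt(abs(f$beta), 1e-6)
})

test_that("with two categories the fit equals logistic regression", {
  set.seed(31)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(-0.4 + 0.9 * x))
  f <- fit_clm(y, cbind(x = x))
  g <- stats::glm(y ~ x, family = binomial)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(coef(g)[2]), tolerance = 1e-5)
  # cutpoint is minus the glm intercept (P(y = 0) = logistic(theta - eta))
  expect_equal(unname(f$theta), -unname(coef(g)[1]), tolerance = 1e-5)
})

test_that("the fit agrees with an independent proportional-odds solver", {
  set.seed(32)
  x <- rnorm(400)
  g2 <- rbinom(400, 1, 0.5)
  y <- sim_ordinal(0.7 * x - 0.5 * g2, c(-0.8, 0.4, 1.6))
  f <- fit_clm(y, cbind(x = x, g = g2))
  o <- MASS::polr(factor(y, ordered = TRUE) ~ x + g2)
  expect_equal(f$logLik, as.numeric(logLik(o)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(coef(o)), tolerance = 1e-4)
  expect_equal(unname(f$theta), unname(o$zeta), tolerance = 1e-4)
})

test_that("simulation recovery: estimates near truth within reported SE", {
  set.seed(33)
  n <- 5000
  x <- rnorm(n)
  theta_true <- c(-0.5, 1.2)
  y <- sim_ordinal(1.1 * x, theta_true)
  f <- fit_clm(y, cbind(x = x))
  se <- sqrt(diag(f$vcov))
  est <- c(f$theta, f$beta)
  expect_true(all(abs(est - c(theta_true, 1.1)) <= 3 * se))
  # fitted category probabilities sum to 1 everywhere
  for (eta in c(-2, 0, 1.5)) {
    cum <- plogis(f$theta - eta)
    probs <- diff(c(0, cum, 1))
    expect_equal(sum(probs), 1, tolerance = 1e-10)
  }
})

test_that("degenerate designs raise errors", {
  expect_error(fit_clm(rep(1, 20)), "categories")
  # complete separation: group 0 always category 1, group 1 always 3
  y <- rep(c(1, 3), each = 30)
  X <- cbind(g = rep(0:1, each = 30))
  expect_error(fit_clm(y, X), "separation|diverged")
  # rank-deficient design
  set.seed(1)
  y2 <- sim_ordinal(rnorm(40), c(0, 1))
  X2 <- cbind(a = 1:40, b = 2 * (1:40))
  expect_error(fit_clm(y2, X2), "rank")
})

test_that("the mixed model collapses to the fixed model as sigma -> 0", {
  set.seed(34)
  n <- 400
  gfac <- factor(rep(1:10, each = 40))
  x <- rnorm(n)
  y <- sim_ordinal(0.8 * x, c(-0.3, 1.1))
  f <- fit_clm(y, cbind(x = x))
  # exact nested limit: marginal likelihood at tiny sigma equals the clm
  r <- nicheshift:::ord_response(y)
  gh <- nicheshift:::gauss_hermite(15)
  ml <- nicheshift:::clmm_marg_ll(f$theta, drop(cbind(x) %*% f$beta),
                                  r$k, r$K, as.integer(gfac), 10, 1e-9, gh)
  expect_equal(ml$ll, f$logLik, tolerance = 1e-8)
  # on data simulated without group effects the fitted sd stays small and
  # the gain over the fixed fit is within the boundary-LRT range
  fm <- fit_clmm(y, cbind(x = x), gfac)
  expect_lt(fm$sigma, 0.05)
  expect_lt(abs(fm$logLik - f$logLik), 0.01)
})

test_that("the mixed fit is exchangeable and quadrature-stable", {
  set.seed(35)
  n <- 300
  gfac <- factor(rep(1:12, each = 25))
  x <- rnorm(n)
  b <- rnorm(12, 0, 0.6)
  y <- sim_ordinal(0.9 * x + b[as.integer(gfac)], c(-0.4, 1.2))
  f15 <- fit_clmm(y, cbind(x = x), gfac, nodes = 15)
  # permuting observation order leaves the likelihood unchanged
  perm <- sample(n)
  fp <- fit_clmm(y[perm], cbind(x = x[perm]), gfac[perm], nodes = 15)
  expect_equal(f15$logLik, fp$logLik, tolerance = 1e-8)
  # 15 -> 25 quadrature nodes moves the likelihood by < 1e-4
  f25 <- fit_clmm(y, cbind(x = x), gfac, nodes = 25)
  expect_lt(abs(f15$logLik - f25$logLik), 1e-4)
  expect_error(fit_clmm(y, NULL, factor(rep(1, n))), "groups")
})

test_that("likelihood-ratio tests behave on nested fits", {
  set.seed(36)
  x <- rnorm(200)
  y <- sim_ordinal(0.6 * x, c(0, 1))
  f1 <- fit_clm(y, cbind(x = x))
  f0 <- fit_clm(y)
  t <- lrt(f0, f1)
  expect_gte(t$statistic, 0)
  expect_equal(t$df, 1)
  expect_lt(t$p, 0.05)
  # identical models: statistic 0, p = 1
  t0 <- lrt(f1, f1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_error(lrt(f1, f0), "nested")
})

test_that("the LRT statistic matches a from-scratch grid-search oracle", {
  # small two-group, three-category dataset
  y <- c(1, 1, 2, 1, 2, 2, 3, 1, 2, 3, 3, 2, 3, 3, 2, 1, 2, 3, 3, 3)
  g <- rep(0:1, each = 10)
  f1 <- fit_clm(y, cbind(g = g))
  f0 <- fit_clm(y)
  stat_pkg <- lrt(f0, f1)$statistic

  # independent likelihood, maximized by iterated grid refinement
  ll <- function(th1, th2, b) {
    if (th2 <= th1) return(-Inf)
    eta <- b * g
    p <- cbind(plogis(th1 - eta), plogis(th2 - eta) - plogis(th1 - eta),
               1 - plogis(th2 - eta))
    sum(log(p[cbind(seq_along(y), y)]))
  }
  grid_max <- function(fix_b = NULL) {
    ctr <- c(0, 1, 0); span <- 4
    best <- -Inf
    for (pass in 1:8) {
      s1 <- ctr[1] + seq(-span, span, length.out = 13)
      s2 <- ctr[2] + seq(-span, span, length.out = 13)
      s3 <- if (is.null(fix_b)) ctr[3] + seq(-span, span, length.out = 13)
      else fix_b
      for (a in s1) for (bb in s2) for (cc in s3) {
        v <- ll(a, bb, cc)
        if (v > best) { best <- v; ctr <- c(a, bb, cc) }
      }
      span <- span / 4
    }
    best
  }
  stat_oracle <- 2 * (grid_max() - grid_max(fix_b = 0))
  expect_equal(stat_pkg, stat_oracle, tolerance = 1e-4)
})
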