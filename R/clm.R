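## Proportional-odds cumulative-link models for ordinal bleaching scores,
## with and without a population random intercept. The mixed model
## integrates the normal random intercept by adaptive Gauss-Hermite
## quadrature. Cutpoints are kept ordered through the reparameterisation
## theta_1 = zeta_1, theta_k = theta_{k-1} + exp(zeta_k).

ord_response <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 observed categories")
  list(k = as.integer(y), K = K, levels = levels(y))
}

make_theta <- function(zeta) {
  if (length(zeta) == 1) return(zeta)
  zeta[1] + c(0, cumsum(exp(zeta[-1])))
}

theta_to_zeta <- function(theta) {
  if (length(theta) == 1) return(theta)
  c(theta[1], log(diff(theta)))
}

# d theta_k / d zeta_m (lower-triangular in the exp terms)
theta_jacobian <- function(zeta) {
  m <- length(zeta)
  J <- matrix(0, m, m)
  J[, 1] <- 1
  if (m > 1) {
    for (col in 2:m) J[col:m, col] <- exp(zeta[col])
  }
  J
}

# Per-observation log-probability and its first/second derivatives with
# respect to the latent mean eta, plus cutpoint-gradient ingredients.
# k: category index (1..K); theta: ordered cutpoints (K-1).
ord_terms <- function(theta, eta, k, K) {
  thx <- c(-Inf, theta, Inf)
  A <- thx[k + 1L] - eta   # upper cutpoint
  B <- thx[k] - eta        # lower cutpoint
  # logistic CDF/pdf inlined (F at -Inf/Inf -> 0/1, f -> 0, no NaN)
  FA <- 1 / (1 + exp(-A)); FB <- 1 / (1 + exp(-B))
  fA <- FA * (1 - FA); fB <- FB * (1 - FB)
  P <- FA - FB
  P[P < 1e-300] <- 1e-300
  dfA <- fA * (1 - 2 * FA)  # f'(A)
  dfB <- fB * (1 - 2 * FB)
  s1 <- (fB - fA) / P                       # d logP / d eta
  s2 <- (dfA - dfB) / P - s1^2              # d2 logP / d eta2
  list(logP = log(P), P = P, fA = fA, fB = fB, s1 = s1, s2 = s2)
}

# Negative log-likelihood and analytic gradient for the fixed-effects CLM,
# in (zeta, beta) parameters.
clm_nll <- function(par, k, X, K) {
  nz <- K - 1
  zeta <- par[seq_len(nz)]
  beta <- par[-seq_len(nz)]
  theta <- make_theta(zeta)
  eta <- if (length(beta)) drop(X %*% beta) else rep(0, length(k))
  t <- ord_terms(theta, eta, k, K)
  nll <- -sum(t$logP)

  # gradient wrt theta: +f(A)/P on upper index, -f(B)/P on lower index
  gth <- numeric(nz)
  up <- k; lo <- k - 1L
  wA <- t$fA / t$P; wB <- t$fB / t$P
  for (j in seq_len(nz)) {
    gth[j] <- sum(wA[up == j]) - sum(wB[lo == j])
  }
  gz <- drop(crossprod(theta_jacobian(zeta), gth))
  gb <- if (length(beta)) drop(crossprod(X, t$s1)) else numeric(0)
  attr(nll, "gradient") <- c(-gz, -gb)
  nll
}

#' Fit a cumulative link model (proportional odds, logit link)
#'
#' Maximum-likelihood proportional-odds regression of an ordinal response on
#' a fixed-effect design, with deterministic initialization (cutpoints from
#' cumulative empirical logits, slopes at zero) and a Newton polish to a
#' gradient-norm tolerance.
#'
#' @param y Ordinal response (factor or numeric; observed levels define the
#'   categories).
#' @param X Design matrix without intercept (or `NULL` for cutpoints only).
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param maxit BFGS iteration cap.
#' @return Object of class `clmm_fit` with `theta`, `beta`, `sigma` (`NA`
#'   here), `logLik`, `df`, `vcov` (for `c(theta, beta)`), `converged`,
#'   `n`, `levels`.
#' @export
fit_clm <- function(y, X = NULL, tol = 1e-8, maxit = 500) {
  r <- ord_response(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(r$k))
    if (ncol(X) > 0 && qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  }
  nz <- r$K - 1
  cum <- cumsum(tabulate(r$k, r$K))[seq_len(nz)] / length(r$k)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  zeta0 <- theta_to_zeta(stats::qlogis(cum))
  par0 <- c(zeta0, rep(0, if (is.null(X)) 0 else ncol(X)))

  fn <- function(p) as.numeric(clm_nll(p, r$k, X, r$K))
  gr <- function(p) attr(clm_nll(p, r$k, X, r$K), "gradient")
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  par <- opt$par
  # Newton polish to drive the gradient norm to tol
  for (it in 1:25) {
    g <- gr(par)
    if (sqrt(sum(g^2)) < tol) break
    H <- stats::optimHess(par, fn, gr)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    cand <- par - step
    if (!all(is.finite(cand)) || fn(cand) > fn(par) + 1e-9) break
    par <- cand
  }
  g <- gr(par)
  converged <- sqrt(sum(g^2)) < max(tol, 1e-6)
  if (max(abs(par)) > 30) {
    stop("cumulative link fit diverged (|parameter| > 30); ",
         "likely complete separation in the design")
  }
  if (!converged) {
    stop("cumulative link model did not converge (gradient norm ",
         format(sqrt(sum(g^2))), "); check for separation or sparse categories")
  }
  zeta <- par[seq_len(nz)]
  theta <- make_theta(zeta)
  beta <- par[-seq_len(nz)]
  names(beta) <- colnames(X)

  # observed-information vcov in natural (theta, beta) coordinates
  nat_fn <- function(p) {
    th <- p[seq_len(nz)]
    if (is.unsorted(th, strictly = TRUE)) return(1e10)
    as.numeric(clm_nll(c(theta_to_zeta(th), p[-seq_len(nz)]), r$k, X, r$K))
  }
  Hn <- stats::optimHess(c(theta, beta), nat_fn)
  vc <- tryCatch(solve(Hn), error = function(e) matrix(NA_real_,
                                                       length(par),
                                                       length(par)))
  structure(list(theta = theta, beta = beta, sigma = NA_real_,
                 logLik = -fn(par), df = length(par), vcov = vc,
                 converged = converged, n = length(r$k), levels = r$levels,
                 grad_norm = sqrt(sum(g^2))),
            class = "clmm_fit")
}

# Marginal log-likelihood of all groups at once by adaptive Gauss-Hermite
# quadrature. g_map maps observations to group index 1..G; b0 warm-starts
# the per-group conditional modes. Returns total logLik, the modes, and
# (when grad = TRUE) the posterior-weighted score with respect to
# (theta, eta-design, log sigma) for use as an analytic gradient.
clmm_marg_ll <- function(theta, eta0, k, K, g_map, G, sigma, gh, b0 = NULL,
                         grad = FALSE, X = NULL) {
  nz <- K - 1
  grp_sum <- function(v) {
    out <- numeric(G)
    s <- rowsum(v, g_map)
    out[as.integer(rownames(s))] <- s
    out
  }
  if (sigma < 1e-8) {
    t <- ord_terms(theta, eta0, k, K)
    res <- list(ll = sum(t$logP), b = numeric(G))
    if (grad) {
      wA <- t$fA / t$P; wB <- t$fB / t$P
      gth <- vapply(seq_len(nz), function(m)
        sum(wA[k == m]) - sum(wB[k - 1L == m]), numeric(1))
      res$gth <- gth
      res$gbeta <- if (!is.null(X)) drop(crossprod(X, t$s1)) else numeric(0)
      res$glsig <- 0
    }
    return(res)
  }
  b <- if (is.null(b0)) numeric(G) else b0
  # joint Newton for all conditional modes of lc(b) - b^2 / (2 sigma^2)
  h_of <- function(bv) {
    t <- ord_terms(theta, eta0 + bv[g_map], k, K)
    grp_sum(t$logP) - bv^2 / (2 * sigma^2)
  }
  h <- h_of(b)
  d2g <- NULL
  for (it in 1:50) {
    t <- ord_terms(theta, eta0 + b[g_map], k, K)
    d1 <- grp_sum(t$s1) - b / sigma^2
    d2g <- grp_sum(t$s2)
    d2 <- d2g - 1 / sigma^2
    step <- d1 / pmin(d2, -1e-10)
    if (max(abs(step)) < 1e-9) break
    bn <- b - step
    hn <- h_of(bn)
    for (hh in 1:20) {     # per-group step halving against divergence
      worse <- hn < h - 1e-12
      if (!any(worse)) break
      bn[worse] <- (b[worse] + bn[worse]) / 2
      hn <- h_of(bn)
    }
    b <- bn; h <- hn
  }
  s <- 1 / sqrt(pmax(1 / sigma^2 - d2g, 1e-12))
  J <- length(gh$nodes)
  n <- length(k)
  terms <- matrix(NA_real_, G, J)
  bjs <- matrix(NA_real_, G, J)
  if (grad) {
    S1 <- matrix(NA_real_, n, J)
    WA <- matrix(NA_real_, n, J)
    WB <- matrix(NA_real_, n, J)
  }
  for (j in seq_len(J)) {
    bj <- b + sqrt(2) * s * gh$nodes[j]
    bjs[, j] <- bj
    t <- ord_terms(theta, eta0 + bj[g_map], k, K)
    terms[, j] <- log(gh$weights[j]) + gh$nodes[j]^2 + grp_sum(t$logP) +
      stats::dnorm(bj, 0, sigma, log = TRUE)
    if (grad) {
      S1[, j] <- t$s1
      WA[, j] <- t$fA / t$P
      WB[, j] <- t$fB / t$P
    }
  }
  m <- apply(terms, 1, max)
  ll_g <- log(sqrt(2) * s) + m + log(rowSums(exp(terms - m)))
  res <- list(ll = sum(ll_g), b = b)
  if (grad) {
    # posterior node weights per group (Fisher-identity score; node
    # positions treated as fixed, exact up to quadrature error)
    A <- exp(terms - m)
    A <- A / rowSums(A)
    A_obs <- A[g_map, , drop = FALSE]
    ws1 <- rowSums(A_obs * S1)
    wwA <- rowSums(A_obs * WA)
    wwB <- rowSums(A_obs * WB)
    res$gth <- vapply(seq_len(nz), function(mm)
      sum(wwA[k == mm]) - sum(wwB[k - 1L == mm]), numeric(1))
    res$gbeta <- if (!is.null(X)) drop(crossprod(X, ws1)) else numeric(0)
    res$glsig <- sum(A * (bjs^2 / sigma^2 - 1))
    res
  } else res
}

#' Fit a cumulative link mixed model (population random intercept)
#'
#' Proportional-odds regression with a normally distributed group-level
#' random intercept, integrated out of the likelihood by adaptive
#' Gauss-Hermite quadrature (nodes centred and scaled at each group's
#' conditional mode). Optimized by quasi-Newton over (ordered-cutpoint
#' transform, slopes, log sigma) from the fixed-effects fit and sigma = 0.3.
#'
#' @param y Ordinal response.
#' @param X Design matrix without intercept (or `NULL`).
#' @param group Grouping factor (population), >= 2 levels.
#' @param nodes Quadrature nodes (default 15).
#' @param maxit Outer BFGS iteration cap.
#' @return Object of class `clmm_fit` with `sigma` the random-intercept SD
#'   and `vcov` for `c(theta, beta, log sigma)`.
#' @export
fit_clmm <- function(y, X = NULL, group, nodes = 15, maxit = 500) {
  r <- ord_response(y)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) {
    stop("random-intercept estimation needs >= 2 groups")
  }
  if (!is.null(X)) X <- as.matrix(X)
  nz <- r$K - 1
  gh <- gauss_hermite(nodes)
  g_map <- as.integer(group)
  G <- nlevels(group)

  cache <- new.env(parent = emptyenv())
  cache$b <- numeric(G)
  cache$par <- NULL
  evaluate <- function(p) {
    if (!is.null(cache$par) && identical(p, cache$par)) return(cache$res)
    zeta <- p[seq_len(nz)]
    np <- if (is.null(X)) 0 else ncol(X)
    beta <- p[nz + seq_len(np)]
    sigma <- exp(p[length(p)])
    theta <- make_theta(zeta)
    eta <- if (np) drop(X %*% beta) else rep(0, length(r$k))
    res <- clmm_marg_ll(theta, eta, r$k, r$K, g_map, G, sigma, gh,
                        b0 = cache$b, grad = TRUE, X = X)
    cache$b <- res$b
    cache$par <- p
    cache$res <- res
    res
  }
  nll <- function(p) -evaluate(p)$ll
  ngr <- function(p) {
    res <- evaluate(p)
    gz <- drop(crossprod(theta_jacobian(p[seq_len(nz)]), res$gth))
    -c(gz, res$gbeta, res$glsig)
  }

  base <- fit_clm(y, X)
  par0 <- c(theta_to_zeta(base$theta), base$beta, log(0.3))
  opt <- stats::optim(par0, nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  # one restart from a larger sigma if the first run looks stuck
  if (opt$convergence != 0) {
    opt2 <- stats::optim(c(theta_to_zeta(base$theta), base$beta, log(1)),
                         nll, ngr, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-12))
    if (opt2$value < opt$value) opt <- opt2
  }
  par <- opt$par
  zeta <- par[seq_len(nz)]
  np <- if (is.null(X)) 0 else ncol(X)
  beta <- par[nz + seq_len(np)]
  names(beta) <- colnames(X)
  sigma <- exp(par[length(par)])
  converged <- opt$convergence == 0
  if (!converged) {
    warning("cumulative link mixed model flagged as non-converged")
  }

  Hn <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  vc <- if (!is.null(Hn)) {
    tryCatch({
      J <- diag(length(par))
      J[seq_len(nz), seq_len(nz)] <- theta_jacobian(zeta)
      # vcov of (theta, beta, log sigma) from the zeta-space Hessian
      Vz <- solve(Hn)
      J %*% Vz %*% t(J)
    }, error = function(e) matrix(NA_real_, length(par), length(par)))
  } else matrix(NA_real_, length(par), length(par))

  structure(list(theta = make_theta(zeta), beta = beta, sigma = sigma,
                 logLik = -opt$value, df = length(par), vcov = vc,
                 converged = converged, n = length(r$k), levels = r$levels,
                 n_groups = nlevels(group), nodes = nodes),
            class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  kind <- if (is.na(x$sigma)) "clm" else "clmm"
  cat(sprintf("<%s fit> n = %d, logLik = %.3f%s\n", kind, x$n, x$logLik,
              if (!x$converged) " (NOT CONVERGED)" else ""))
  cat("cutpoints:", paste(sprintf("%.3f", x$theta), collapse = ", "), "\n")
  if (length(x$beta)) {
    cat("coefficients:\n")
    print(round(x$beta, 4))
  }
  if (!is.na(x$sigma)) cat(sprintf("random-intercept sd: %.4f\n", x$sigma))
  invisible(x)
}

#' @export
logLik.clmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Likelihood-ratio test of nested ordinal fits
#'
#' @param null,full Nested converged [fit_clm()]/[fit_clmm()] objects (the
#'   null has fewer parameters).
#' @return List `statistic` (2 x logLik difference, clamped at 0), `df`
#'   (parameter-count difference) and `p` (chi-squared upper tail; for a
#'   zero-df comparison of identical models, p = 1).
#' @export
lrt <- function(null, full) {
  stopifnot(inherits(null, "clmm_fit"), inherits(full, "clmm_fit"))
  if (!null$converged || !full$converged) stop("both fits must have converged")
  df <- full$df - null$df
  if (df < 0) stop("models are not nested (null has more parameters)")
  stat <- max(0, 2 * (full$logLik - null$logLik))
  p <- if (df == 0) {
    if (stat < 1e-6) 1 else stop("non-nested: zero df but unequal likelihoods")
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}
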