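# Kernel machinery and dual QP solvers for the RBF support vector machines.
#
# Both the one-class SVM (novelty detection on positives) and the binary
# C-SVC are solved in the dual with accelerated projected gradient (FISTA
# with restart). The feasible sets admit exact O(n log n) projections:
#   one-class: { 0 <= a <= C, sum(a) = 1 }      (capped simplex)
#   C-SVC:     { 0 <= a <= C, sum(a * y) = 0 }  (box + hyperplane)
# both via bisection on the dual multiplier of the equality constraint.
# Problem sizes here are a few thousand rows at most, so dense kernel
# matrices are fine.

rbf_kernel <- function(X, Y = X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# sklearn-style "scale" bandwidth: 1 / (n_features * var(all entries))
resolve_gamma <- function(gamma, X) {
  if (is.numeric(gamma)) return(gamma)
  if (!identical(gamma, "scale")) stop("gamma must be numeric or \"scale\"")
  v <- stats::var(as.vector(X)) * (length(X) - 1) / length(X)
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

# largest eigenvalue of a symmetric PSD matrix, power iteration
spectral_bound <- function(K, iters = 60L) {
  v <- rep(1, nrow(K)) / sqrt(nrow(K))
  lam <- 1
  for (i in seq_len(iters)) {
    u <- K %*% v
    lam <- sqrt(sum(u^2))
    if (lam < 1e-12) return(1)
    v <- u / lam
  }
  as.numeric(lam)
}

# project v onto { 0 <= a <= C, sum(a) = s } by bisection on the shift tau
project_capped_simplex <- function(v, C, s) {
  lo <- min(v) - C - 1
  hi <- max(v) + 1
  for (i in 1:64) {
    tau <- (lo + hi) / 2
    if (sum(pmin(pmax(v - tau, 0), C)) > s) lo <- tau else hi <- tau
  }
  pmin(pmax(v - (lo + hi) / 2, 0), C)
}

# project v onto { 0 <= a <= C, sum(a * y) = 0 }, y in {-1, +1}
project_box_hyperplane <- function(v, C, y) {
  g <- function(delta) sum(y * pmin(pmax(v - delta * y, 0), C))
  lo <- -(max(abs(v)) + C + 1)
  hi <- +(max(abs(v)) + C + 1)
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  delta <- (lo + hi) / 2
  pmin(pmax(v - delta * y, 0), C)
}

# FISTA on min_a 0.5 a'Qa + lin'a over a convex set given by project()
fista_qp <- function(Q, lin, project, a0, max_iter = 2000L, tol = 1e-7) {
  L <- spectral_bound(Q) + 1e-6
  a <- project(a0)
  z <- a
  tprev <- 1
  for (it in seq_len(max_iter)) {
    grad <- as.vector(Q %*% z) + lin
    a_new <- project(z - grad / L)
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    z_new <- a_new + ((tprev - 1) / tcur) * (a_new - a)
    # restart on non-monotone step
    if (sum((a_new - a) * (z - a_new)) > 0) z_new <- a_new
    delta <- max(abs(a_new - a))
    a <- a_new
    z <- z_new
    tprev <- tcur
    if (delta < tol) break
  }
  a
}

# ---- one-class SVM ----------------------------------------------------------

solve_ocsvm_dual <- function(K, nu) {
  l <- nrow(K)
  C <- 1 / (nu * l)
  a <- fista_qp(K, numeric(l),
                function(v) project_capped_simplex(v, C, 1),
                rep(1 / l, l))
  f <- as.vector(K %*% a)
  eps <- 1e-6 * C
  free <- a > eps & a < C - eps
  rho <- if (any(free)) {
    mean(f[free])
  } else {
    at_C <- a >= C - eps
    at_0 <- a <= eps
    ub <- if (any(at_0)) min(f[at_0]) else max(f)
    lb <- if (any(at_C)) max(f[at_C]) else min(f)
    (ub + lb) / 2
  }
  list(alpha = a, rho = rho, C = C)
}

# ---- binary C-SVC -----------------------------------------------------------

# y in {-1, +1}
solve_csvc_dual <- function(K, y, C) {
  Q <- K * tcrossprod(y)
  a <- fista_qp(Q, rep(-1, length(y)),
                function(v) project_box_hyperplane(v, C, y),
                rep(0, length(y)))
  f <- as.vector(K %*% (a * y))
  eps <- 1e-6 * C
  free <- a > eps & a < C - eps
  b <- if (any(free)) {
    mean(y[free] - f[free])
  } else {
    # KKT interval midpoint
    up <- y == 1 & a <= eps | y == -1 & a >= C - eps
    lo <- y == -1 & a <= eps | y == 1 & a >= C - eps
    ub <- if (any(up)) min(y[up] - f[up]) else max(y - f)
    lb <- if (any(lo)) max(y[lo] - f[lo]) else min(y - f)
    (ub + lb) / 2
  }
  list(alpha = a, b = b)
}

fit_csvc <- function(X, y01, C = 1, gamma = "scale") {
  y <- ifelse(y01 == 1, 1, -1)
  gamma <- resolve_gamma(gamma, X)
  K <- rbf_kernel(X, gamma = gamma)
  sol <- solve_csvc_dual(K, y, C)
  keep <- sol$alpha > 1e-10
  structure(list(sv = X[keep, , drop = FALSE],
                 coef = (sol$alpha * y)[keep],
                 b = sol$b, gamma = gamma, C = C),
            class = "csvc_model")
}

decision_csvc <- function(model, X) {
  as.vector(rbf_kernel(X, model$sv, model$gamma) %*% model$coef) + model$b
}
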