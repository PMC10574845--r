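# Gaussian-process Bayesian optimization of the cross-validated model
# error over a hyper-parameter search space: Latin-hypercube burn-in, an
# RBF-kernel GP surrogate on the unit cube (log scaling for positive
# dimensions spanning decades), and expected-improvement acquisition
# maximized over random candidates.

#' Define a hyper-parameter search space
#'
#' @param dims Named list; each element is `list(lower, upper, log = FALSE,
#'   integer = FALSE)` (a bare `c(lower, upper)` is also accepted).
#' @return Object of class `search_space`.
#' @export
search_space <- function(dims) {
  dims <- lapply(dims, function(d) {
    if (!is.list(d)) d <- list(lower = d[1], upper = d[2])
    d$log <- isTRUE(d$log)
    d$integer <- isTRUE(d$integer)
    if (!is.finite(d$lower) || !is.finite(d$upper) || d$lower >= d$upper) {
      stop("search dimension with inverted or non-finite bounds")
    }
    if (d$log && d$lower <= 0) stop("log-scaled dimension needs positive bounds")
    d
  })
  structure(dims, class = "search_space")
}

# unit-cube <-> native coordinates
.space_decode <- function(space, u) {
  stats::setNames(lapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- if (d$log) exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
         else d$lower + u[j] * (d$upper - d$lower)
    if (d$integer) as.integer(round(v)) else v
  }), names(space))
}

# squared-exponential kernel matrix on unit-cube rows
.gp_kernel <- function(X1, X2, ls) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  exp(-0.5 * pmax(d2, 0) / ls^2)
}

# GP posterior mean/sd at Xs given observations (X, y), with lengthscale
# and noise picked from a small grid by marginal likelihood.
.gp_posterior <- function(X, y, Xs) {
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  yc <- (y - mu) / sdy
  best <- NULL
  best_ll <- -Inf
  for (ls in c(0.1, 0.2, 0.4, 0.8)) {
    for (nv in c(1e-6, 1e-3, 1e-2)) {
      K <- .gp_kernel(X, X, ls) + diag(nv + 1e-8, nrow(X))
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), yc))
      ll <- -0.5 * sum(yc * alpha) - sum(log(diag(ch)))
      if (ll > best_ll) best <- list(ls = ls, nv = nv, ch = ch, alpha = alpha)
      best_ll <- max(best_ll, ll)
    }
  }
  if (is.null(best)) {
    return(list(mean = rep(mu, nrow(Xs)), sd = rep(sdy, nrow(Xs))))
  }
  Ks <- .gp_kernel(Xs, X, best$ls)
  pm <- as.numeric(Ks %*% best$alpha)
  v <- forwardsolve(t(best$ch), t(Ks))
  pv <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mu + sdy * pm, sd = sdy * sqrt(pv))
}

# expected improvement for minimization
.expected_improvement <- function(mu, sd, best_y) {
  z <- (best_y - mu) / sd
  (best_y - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Minimize an objective over a search space by GP Bayesian optimization
#'
#' @param objective Function taking a named list of hyper-parameter values
#'   and returning a scalar to minimize.
#' @param space A [search_space()].
#' @param n_trials Total evaluations (>= 10).
#' @param n_init Latin-hypercube burn-in evaluations.
#' @param seed Integer seed; the search is deterministic given it.
#' @return List with `best` (named list), `best_value`, and `trace`
#'   (data frame of all trials).
#' @export
gp_minimize <- function(objective, space, n_trials = 50,
                        n_init = max(8, 2 * length(space)), seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (n_trials < 10) stop("n_trials must be >= 10")
  d <- length(space)
  n_init <- min(n_init, n_trials - 2)
  .with_seed(seed, function() {
    U <- lhs::maximinLHS(n_init, d)
    ys <- numeric(0)
    for (i in seq_len(n_init)) {
      ys[i] <- objective(.space_decode(space, U[i, ]))
    }
    while (length(ys) < n_trials) {
      cand <- matrix(stats::runif(500 * d), ncol = d)
      post <- .gp_posterior(U, ys, cand)
      ei <- .expected_improvement(post$mean, post$sd, min(ys))
      u_next <- cand[which.max(ei), , drop = FALSE]
      U <- rbind(U, u_next)
      ys <- c(ys, objective(.space_decode(space, u_next[1, ])))
    }
    best_i <- which.min(ys)
    trace <- cbind(as.data.frame(U), value = ys)
    names(trace)[seq_len(d)] <- names(space)
    list(best = .space_decode(space, U[best_i, ]), best_value = ys[best_i],
         trace = trace)
  })
}
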