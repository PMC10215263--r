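# Box-constrained Bayesian optimization with an expected-improvement
# acquisition over a Gaussian-process surrogate (the package's own GP with
# a squared-exponential kernel).  Numeric dimensions may be log-scaled;
# categorical dimensions are one-hot coded in the surrogate.

bo_param_num <- function(name, lower, upper, log = FALSE, integer = FALSE)
  list(name = name, type = "num", lower = lower, upper = upper,
       log = log, integer = integer)
bo_param_cat <- function(name, levels)
  list(name = name, type = "cat", levels = levels)

# unit-cube coding
bo_decode <- function(u, space) {
  out <- list(); i <- 0
  for (p in space) {
    if (p$type == "num") {
      i <- i + 1
      v <- if (p$log) exp(log(p$lower) + u[i] * (log(p$upper) - log(p$lower)))
      else p$lower + u[i] * (p$upper - p$lower)
      if (p$integer) v <- as.integer(round(v))
      out[[p$name]] <- v
    } else {
      k <- length(p$levels)
      out[[p$name]] <- p$levels[which.max(u[i + seq_len(k)])]
      i <- i + k
    }
  }
  out
}

bo_dim <- function(space)
  sum(vapply(space, function(p) if (p$type == "num") 1L else length(p$levels),
             integer(1)))

bo_midpoint <- function(space) {
  u <- numeric(bo_dim(space)); i <- 0
  for (p in space) {
    if (p$type == "num") { i <- i + 1; u[i] <- 0.5 }
    else {
      k <- length(p$levels)
      u[i + ceiling(k / 2)] <- 1
      i <- i + k
    }
  }
  u
}

bo_random_point <- function(space) {
  u <- numeric(bo_dim(space)); i <- 0
  for (p in space) {
    if (p$type == "num") { i <- i + 1; u[i] <- runif(1) }
    else {
      k <- length(p$levels)
      u[i + sample.int(k, 1)] <- 1
      i <- i + k
    }
  }
  u
}

#' Bayesian optimization of a scalar objective over a box space
#'
#' Minimizes `objective(params)` within `budget` evaluations: the space
#' midpoint first, a seeded random exploration phase, then
#' expected-improvement steps under a Gaussian-process surrogate.  Because
#' the first evaluation is always the midpoint, the incumbent after a
#' larger budget can never be worse than after a smaller one at the same
#' seed.
#'
#' @param objective function taking a named parameter list, returning a
#'   scalar to minimize (non-finite values are treated as failures).
#' @param space list of parameter descriptors (`bo_param_num`,
#'   `bo_param_cat`).
#' @param budget total number of objective evaluations (default 30).
#' @param seed integer seed.
#' @param n_candidates candidate pool size for the acquisition maximizer.
#' @return list with `best_params`, `best_value`, `history` (data frame of
#'   evaluations in order).
#' @keywords internal
bo_optimize <- function(objective, space, budget = 30, seed = 1,
                        n_candidates = 256) {
  withr::with_seed(seed, {
    U <- matrix(NA_real_, 0, bo_dim(space))
    vals <- numeric(0)
    eval_u <- function(u) {
      par <- bo_decode(u, space)
      v <- tryCatch(objective(par), error = function(e) NA_real_)
      if (!is.finite(v)) v <- NA_real_
      U <<- rbind(U, u); vals <<- c(vals, v)
      v
    }
    eval_u(bo_midpoint(space))
    n_init <- min(max(4, length(space) + 1), max(budget - 1, 0))
    for (i in seq_len(min(n_init, budget - 1))) eval_u(bo_random_point(space))
    while (length(vals) < budget) {
      ok <- is.finite(vals)
      if (sum(ok) < 2) { eval_u(bo_random_point(space)); next }
      y <- vals[ok]
      ys <- (y - mean(y)) / max(sd(y), 1e-12)
      sur <- tryCatch(
        gpr_fit(U[ok, , drop = FALSE], ys, kernel = "squared_exponential",
                sigma = 0.05, basis = "constant"),
        error = function(e) NULL)
      if (is.null(sur)) { eval_u(bo_random_point(space)); next }
      cand <- t(vapply(seq_len(n_candidates), function(i) bo_random_point(space),
                       numeric(ncol(U))))
      post <- gpr_posterior(sur, cand)
      best <- min(ys)
      z <- (best - post$mean) / pmax(post$sd, 1e-12)
      ei <- (best - post$mean) * pnorm(z) + post$sd * dnorm(z)
      ei[post$sd < 1e-12] <- 0
      eval_u(cand[which.max(ei), ])
    }
    if (!any(is.finite(vals))) {
      warning("Bayesian optimization: every evaluation failed; falling back to the space midpoint")
      return(list(best_params = bo_decode(bo_midpoint(space), space),
                  best_value = NA_real_,
                  history = data.frame(iteration = seq_along(vals), value = vals)))
    }
    ibest <- which.min(vals)
    list(best_params = bo_decode(U[ibest, ], space),
         best_value = vals[ibest],
         history = data.frame(iteration = seq_along(vals), value = vals))
  })
}
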