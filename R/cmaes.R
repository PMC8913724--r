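# Covariance Matrix Adaptation Evolution Strategy (mu/mu_w, lambda),
# following the standard tutorial formulation (rank-one + rank-mu update,
# cumulative step-size adaptation).  Box constraints are handled by
# projection: sampled points are clipped into the box before evaluation and
# the clipped points drive the distribution update.

#' Minimize a function with CMA-ES
#'
#' Derivative-free stochastic minimizer used to tune feedback gains; also
#' usable on any smooth or multimodal bounded problem.  Deterministic given
#' `seed` (the caller's RNG state is preserved).
#'
#' @param fn objective, `function(x) -> scalar`
#' @param x0 initial mean (numeric vector)
#' @param sigma0 initial global step size
#' @param lower,upper box bounds (vectors, recycled)
#' @param lambda population size; default `4 + floor(3 * log(d))`
#' @param max_iter number of generations, default 100
#' @param seed optional integer seed
#' @param trace if `TRUE`, keep the incumbent (best-so-far) per generation
#' @return list with `par`, `value`, `evals`, and (if traced) `incumbents`
#' @export
cmaes_minimize <- function(fn, x0, sigma0, lower, upper,
                           lambda = NULL, max_iter = 100, seed = NULL,
                           trace = FALSE) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  d <- length(x0)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(d))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  C <- diag(d); pc <- numeric(d); ps <- numeric(d)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors; D <- sqrt(pmax(eig$values, .Machine$double.eps))

  best_x <- xmean; best_f <- Inf; evals <- 0L
  incumbents <- if (trace) numeric(max_iter) else NULL

  for (it in seq_len(max_iter)) {
    arz <- matrix(stats::rnorm(d * lambda), d, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arx <- pmin(pmax(arx, lower), upper)       # projection repair
    ary <- (arx - xmean) / sigma
    f <- apply(arx, 2L, fn)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1L]] < best_f) { best_f <- f[ord[1L]]; best_x <- arx[, ord[1L]] }

    sel <- ord[seq_len(mu)]
    ymean <- drop(ary[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean

    Cinv_y <- B %*% ((t(B) %*% ymean) / D)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinv_y
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    ysel <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (w * t(ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-20))
    if (trace) incumbents[it] <- best_f
  }
  out <- list(par = as.numeric(best_x), value = best_f, evals = evals)
  if (trace) out$incumbents <- incumbents
  out
}
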