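# Covariance Matrix Adaptation Evolution Strategy (minimizer).
#
# Standard (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation and
# rank-one plus rank-mu covariance updates. Written for moderate dimensions
# (a few hundred); the covariance eigendecomposition is refreshed every
# generation. All randomness comes from the supplied stream, so runs are
# bit-reproducible under a fixed seed.
#
# `fn(x, gen, cand)` is the objective to MINIMIZE; the generation and
# candidate indices let noisy objectives derive per-evaluation seeds.

cma_es_min <- function(fn, x0, sigma0, lambda, max_gen, stream,
                       stop_fn = NULL) {
  n <- length(x0)
  stopifnot(lambda >= 2L, sigma0 > 0)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n)
  C <- diag(n)

  best <- list(x = x0, value = Inf, gen = 0L)
  history <- vector("list", max_gen)

  for (gen in seq_len(max_gen)) {
    arz <- matrix(stream_rnorm(stream, n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fit <- vapply(seq_len(lambda), function(k) fn(arx[, k], gen, k), 0)
    ord <- order(fit)
    if (fit[ord[1]] < best$value) {
      best <- list(x = arx[, ord[1]], value = fit[ord[1]], gen = gen)
    }
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- as.vector(ary[, sel, drop = FALSE] %*% w) * sigma + xold
    ymean <- (xmean - xold) / sigma

    zmean <- as.vector(arz[, sel, drop = FALSE] %*% w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.vector(B %*% zmean)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      (1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors

    history[[gen]] <- c(gen = gen, best = fit[ord[1]],
                        mean = mean(fit), sigma = sigma)
    if (!is.null(stop_fn) && isTRUE(stop_fn(gen, fit[ord[1]], best))) {
      history <- history[seq_len(gen)]
      break
    }
  }
  hist_mat <- if (length(history) && !is.null(history[[1]])) {
    do.call(rbind, history[!vapply(history, is.null, NA)])
  } else {
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("gen", "best", "mean", "sigma")))
  }
  list(best = best, history = as.data.frame(hist_mat), xmean = xmean,
       sigma = sigma)
}
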