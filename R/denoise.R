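#' Log-transform CAGE TPM values
#'
#' Applies the amplified log transform \code{10 * ln(TPM) + 4}, defined only
#' for TPM above 0.001; values at or below that cutoff are masked (returned
#' as \code{NA} with \code{kept = FALSE}). The transform spreads the
#' low-expression mass so the two components of the count mixture become
#' visible on a common integer support.
#'
#' @param tpm numeric vector of non-negative TPM values.
#' @return a list with \code{values} (log-TPM, \code{NA} where masked) and
#'   \code{kept} (logical mask, FALSE where TPM <= 0.001).
#' @export
#' @examples
#' logTpm(c(1, exp(1), 0.001))
logTpm <- function(tpm) {
  if (any(is.na(tpm))) stop("TPM must not contain NA")
  if (any(tpm < 0)) stop("TPM must be non-negative")
  kept <- tpm > 0.001
  values <- rep(NA_real_, length(tpm))
  values[kept] <- 10 * log(tpm[kept]) + 4
  list(values = values, kept = kept)
}

#' Discretize log-TPM values onto integer count support
#'
#' The mixture's Poisson and negative-binomial components are probability
#' mass functions on non-negative integers; kept log-TPM values are mapped
#' there by \code{round(max(value, 0))}. The mapping is deterministic and
#' monotone non-decreasing.
#'
#' @param logtpm a list as returned by \code{\link{logTpm}}, or a plain
#'   numeric vector (all values treated as kept).
#' @return integer vector of counts for the kept values.
#' @export
discretizeLogTpm <- function(logtpm) {
  v <- if (is.list(logtpm)) logtpm$values[logtpm$kept] else logtpm
  if (!length(v)) stop("no kept values to discretize")
  as.integer(round(pmax(v, 0)))
}

#' Mixture log-likelihood
#'
#' Log-likelihood of integer counts under the two-component model
#' \code{a * Pois(k; u) + (1 - a) * NB(k; r, p)}, where the negative-binomial
#' pmf is \code{p^r (1-p)^k * gamma(k+r) / (k! gamma(r))} (the factorial form
#' generalized through log-gamma so the size \code{r} may be non-integer).
#'
#' @param params numeric vector or list with elements \code{a}, \code{u},
#'   \code{r}, \code{p}.
#' @param counts non-negative integer vector.
#' @return the summed log-likelihood (finite for in-bounds parameters).
#' @export
mixtureLogLik <- function(params, counts) {
  a <- params[["a"]]; u <- params[["u"]]; r <- params[["r"]]; p <- params[["p"]]
  if (!(a >= 0 && a <= 1)) stop("'a' must lie in [0, 1]")
  if (!(u > 0) || !(r > 0)) stop("'u' and 'r' must be positive")
  if (!(p > 0 && p < 1)) stop("'p' must lie in (0, 1)")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  sum(mixtureLogPmf(counts, a, u, r, p))
}

# log pmf of the mixture, numerically stable via log-sum-exp of the
# component log pmfs.
mixtureLogPmf <- function(k, a, u, r, p) {
  lp <- dpois(k, u, log = TRUE)
  ln <- dnbinom(k, size = r, prob = p, log = TRUE)
  if (a == 0) return(ln)
  if (a == 1) return(lp)
  la <- log(a) + lp
  lb <- log1p(-a) + ln
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m))
}

#' Fit the Poisson + negative-binomial mixture by maximum likelihood
#'
#' Bounded multi-start quasi-Newton maximization of
#' \code{\link{mixtureLogLik}}. Bounds are enforced by reparameterization
#' (\code{a}, \code{p} through logit; \code{u}, \code{r} through log).
#' Starts are method-of-moments initializations perturbed per start: the data
#' are split at the median, the left split initializes the Poisson mean and
#' the mixing weight, the right split initializes the negative-binomial
#' moments. After the fit, the threshold is derived
#' (\code{\link{deriveThreshold}}) and the data split there to populate
#' per-side kurtosis/skewness plus a pooled chi-squared Poisson
#' goodness-of-fit p-value on the noise side.
#'
#' Because the negative binomial contains the Poisson as its r -> Inf
#' limit, the mixing weight is unidentified when the sample is noise-only;
#' a likelihood-ratio guard (0.95 chi-squared bound, 3 df) detects this and
#' pins \code{a} near 1 with no threshold rather than reporting an
#' arbitrary weight.
#'
#' @param counts non-negative integer vector, length >= 100, >= 2 distinct
#'   values.
#' @param n_starts number of optimizer starts (default 10).
#' @param seed integer seed controlling the start perturbations.
#' @param max_iter maximum optimizer iterations per start (default 500).
#' @param tol relative convergence tolerance on the objective (default 1e-8).
#' @return a \code{\linkS4class{MixtureFit}}.
#' @export
fitMixture <- function(counts, n_starts = 10L, seed = 1L,
                       max_iter = 500L, tol = 1e-8) {
  if (length(counts) < 100L) stop("need >= 100 observations")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (length(unique(counts)) < 2L) stop("all counts identical; mixture is unidentifiable")

  # aggregate to (value, frequency): the log-likelihood only depends on the
  # empirical pmf, making each objective evaluation O(#unique values)
  tab <- table(counts)
  ks <- as.numeric(names(tab))
  ws <- as.numeric(tab)

  negll <- function(theta) {
    a <- stats::plogis(theta[1L]); u <- exp(theta[2L])
    r <- exp(theta[3L]); p <- stats::plogis(theta[4L])
    # extreme probes can under/overflow the pmfs; they are penalized, so
    # their NaN warnings are noise
    ll <- suppressWarnings(sum(ws * mixtureLogPmf(ks, a, u, r, p)))
    if (!is.finite(ll)) return(1e300)
    -ll
  }

  starts <- mixtureStarts(counts, n_starts, seed)
  best <- NULL
  trace <- data.frame(start = integer(), converged = logical(),
                      loglik = numeric())
  for (i in seq_len(nrow(starts))) {
    theta0 <- c(stats::qlogis(starts$a[i]), log(starts$u[i]),
                log(starts$r[i]), stats::qlogis(starts$p[i]))
    fit <- tryCatch(
      optim(theta0, negll, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      trace <- rbind(trace, data.frame(start = i, converged = FALSE,
                                       loglik = NA_real_))
      next
    }
    conv <- fit$convergence == 0L
    trace <- rbind(trace, data.frame(start = i, converged = conv,
                                     loglik = -fit$value))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  a <- stats::plogis(best$par[1L]); u <- exp(best$par[2L])
  r <- exp(best$par[3L]); p <- stats::plogis(best$par[4L])
  converged <- any(trace$converged)
  # clamp the open-interval parameters away from the boundary so the fit
  # object is always valid; a fit pinned at a boundary is flagged instead
  eps <- 1e-12
  a <- min(max(a, eps), 1 - eps)
  p <- min(max(p, eps), 1 - eps)

  # noise-collapse guard: a negative binomial can mimic the Poisson exactly
  # (r -> Inf), leaving the mixing weight unidentified on noise-only data.
  # When the two-component fit does not beat a single Poisson by more than
  # the 0.95 chi-squared bound for its 3 extra parameters, the sample is
  # treated as noise-only: a is pinned near 1 and no threshold exists.
  ll_pois <- sum(ws * dpois(ks, mean(counts), log = TRUE))
  if (-best$value - ll_pois < stats::qchisq(0.95, df = 3) / 2) {
    a <- 1 - 1e-6
    u <- mean(counts)
  }

  threshold <- tryCatch(
    deriveThresholdParams(a, u, r, p),
    error = function(e) NA_integer_
  )
  diagnostics <- mixtureDiagnostics(counts, u, threshold)

  new("MixtureFit", a = a, u = u, r = r, p = p, loglik = -best$value,
      threshold = threshold, converged = converged,
      diagnostics = diagnostics, trace = trace)
}

# method-of-moments starts: the unperturbed moment start, two anchors at
# noise-heavy and signal-heavy mixing weights (guarding against the
# label-swapped local optimum), then multiplicatively perturbed copies
mixtureStarts <- function(counts, n_starts, seed) {
  med <- median(counts)
  left <- counts[counts <= med]
  right <- counts[counts > med]
  if (!length(right)) right <- counts[counts >= med]
  a0 <- min(max(length(left) / length(counts), 0.05), 0.95)
  u0 <- max(mean(left), 0.1)
  m <- max(mean(right), u0 + 0.5)
  v <- max(stats::var(right), m + 0.1)   # overdispersed start
  p0 <- min(max(m / v, 0.05), 0.95)
  r0 <- max(m * p0 / (1 - p0), 0.2)
  anchors <- data.frame(
    a = c(a0, 0.9, 0.25),
    u = c(u0, u0, u0),
    r = c(r0, r0, r0),
    p = c(p0, p0, p0)
  )[seq_len(min(3L, n_starts)), , drop = FALSE]
  n_rand <- max(0L, n_starts - nrow(anchors))
  rand <- withSeed(seed, {
    data.frame(
      a = clamp01(a0 * exp(runif(n_rand, -0.3, 0.3)), 0.02, 0.98),
      u = u0 * exp(runif(n_rand, -0.5, 0.5)),
      r = r0 * exp(runif(n_rand, -0.5, 0.5)),
      p = clamp01(p0 * exp(runif(n_rand, -0.3, 0.3)), 0.02, 0.98)
    )
  })
  rbind(anchors, rand)
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

mixtureDiagnostics <- function(counts, u, threshold) {
  if (is.na(threshold)) {
    noise <- counts
    signal <- numeric()
  } else {
    noise <- counts[counts <= threshold]
    signal <- counts[counts > threshold]
  }
  safeStat <- function(f, x) {
    if (length(x) < 4L || stats::sd(x) == 0) return(NA_real_)
    f(x)
  }
  list(
    kurtosis_noise = safeStat(e1071::kurtosis, noise),
    skewness_noise = safeStat(e1071::skewness, noise),
    kurtosis_signal = safeStat(e1071::kurtosis, signal),
    skewness_signal = safeStat(e1071::skewness, signal),
    poisson_gof_pvalue = poissonGofPvalue(noise)
  )
}

# chi-squared GOF of the noise-side counts against Poisson(mean), bins
# pooled from the right until every expected frequency is >= 5;
# df = #bins - 1 - 1 (one estimated parameter)
poissonGofPvalue <- function(x) {
  if (length(x) < 10L) return(NA_real_)
  lam <- mean(x)
  if (lam == 0) return(NA_real_)
  kmax <- max(x)
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  expd <- length(x) * dpois(0:kmax, lam)
  expd[kmax + 1L] <- expd[kmax + 1L] + length(x) * stats::ppois(kmax, lam, lower.tail = FALSE)
  # pool adjacent bins (from the right, then the left) to expected >= 5
  o <- obs; e <- expd
  while (length(e) > 1L && e[length(e)] < 5) {
    n <- length(e)
    e[n - 1L] <- e[n - 1L] + e[n]; o[n - 1L] <- o[n - 1L] + o[n]
    e <- e[-n]; o <- o[-n]
  }
  while (length(e) > 1L && e[1L] < 5) {
    e[2L] <- e[2L] + e[1L]; o[2L] <- o[2L] + o[1L]
    e <- e[-1L]; o <- o[-1L]
  }
  df <- length(e) - 2L
  if (df < 1L) return(NA_real_)
  stat <- sum((o - e)^2 / e)
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Derive the noise/signal count threshold
#'
#' Scans integer counts upward from the noise (Poisson) mode \code{floor(u)}
#' and returns the smallest \code{k} at which the signal component dominates,
#' i.e. \code{(1-a) * NB(k; r, p) > a * Pois(k; u)}. Counts strictly above
#' the threshold are more likely true eRNA signal than noise. The scan stops
#' at the 0.9999 quantile of the mixture distribution; if no crossing is found below
#' that point the signal component has collapsed into the noise and an error
#' is raised.
#'
#' @param fit a converged \code{\linkS4class{MixtureFit}}, or a named vector
#'   or list with \code{a}, \code{u}, \code{r}, \code{p}.
#' @return integer threshold.
#' @export
deriveThreshold <- function(fit) {
  if (is(fit, "MixtureFit")) {
    if (!fit@converged) stop("fit did not converge")
    deriveThresholdParams(fit@a, fit@u, fit@r, fit@p)
  } else {
    deriveThresholdParams(fit[["a"]], fit[["u"]], fit[["r"]], fit[["p"]])
  }
}

deriveThresholdParams <- function(a, u, r, p) {
  # scan cap: the 0.9999 quantile of the mixture distribution itself, so a
  # vanishing component cannot push the scan into its private far tail
  qmax <- max(qpois(0.9999, u), qnbinom(0.9999, size = r, prob = p))
  cdf <- a * stats::ppois(0:qmax, u) +
    (1 - a) * stats::pnbinom(0:qmax, size = r, prob = p)
  q <- which(cdf >= 0.9999)[1L] - 1L
  k0 <- floor(u)                      # noise-component mode
  if (k0 > q)
    stop("no noise/signal crossing below the 0.9999 quantile; ",
         "signal component collapsed")
  ks <- k0:q
  signal_wins <- log1p(-a) + dnbinom(ks, size = r, prob = p, log = TRUE) >
    log(a) + dpois(ks, u, log = TRUE)
  hit <- which(signal_wins)
  if (!length(hit))
    stop("no noise/signal crossing below the 0.9999 quantile; ",
         "signal component collapsed")
  as.integer(ks[hit[1L]])
}

#' Classify regions as noise, true eRNA, or masked
#'
#' Kept regions whose discretized log-TPM count exceeds the fitted threshold
#' are called \code{true_eRNA}; kept regions at or below it are called
#' \code{noise} (a count exactly at the threshold is conservatively assigned
#' to noise); regions masked by the TPM cutoff stay \code{masked}.
#'
#' @param logtpm a list as returned by \code{\link{logTpm}}.
#' @param fit a converged \code{\linkS4class{MixtureFit}} with a derived
#'   threshold.
#' @return character vector (one of \code{"noise"}, \code{"true_eRNA"},
#'   \code{"masked"}) aligned with the input regions.
#' @export
classifyExpression <- function(logtpm, fit) {
  if (!is(fit, "MixtureFit")) stop("'fit' must be a MixtureFit")
  if (!fit@converged) stop("fit did not converge")
  if (is.na(fit@threshold)) stop("fit has no derived threshold")
  calls <- rep("masked", length(logtpm$values))
  kept <- logtpm$kept
  if (any(kept)) {
    k <- as.integer(round(pmax(logtpm$values[kept], 0)))
    calls[kept] <- ifelse(k > fit@threshold, "true_eRNA", "noise")
  }
  calls
}

#' Run the denoising stage on one sample of a CAGE matrix
#'
#' Convenience wrapper: extracts one sample column, applies
#' \code{\link{logTpm}} and \code{\link{discretizeLogTpm}}, fits the mixture
#' and classifies every region.
#'
#' @param se a \code{RangedSummarizedExperiment} from
#'   \code{\link{readCageMatrix}}.
#' @param sample sample (column) name or index.
#' @param ... passed to \code{\link{fitMixture}}.
#' @return list with \code{fit} (MixtureFit) and \code{calls} (character
#'   vector aligned with the matrix rows).
#' @export
denoiseCage <- function(se, sample = 1L, ...) {
  tpm <- SummarizedExperiment::assay(se, "tpm")[, sample]
  lt <- logTpm(tpm)
  fit <- fitMixture(discretizeLogTpm(lt), ...)
  list(fit = fit, calls = classifyExpression(lt, fit))
}
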