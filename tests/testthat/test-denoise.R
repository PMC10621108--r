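test_that("log-TPM transform applies 10*ln(TPM)+4 above the 0.001 cutoff", {
  lt <- logTpm(c(1, exp(1), 0.001, 0.0005, 0))
  expect_equal(lt$values[1], 4)          # ln(1) = 0
  expect_equal(lt$values[2], 14)         # ln(e) = 1
  expect_false(lt$kept[3])               # cutoff is strict: 0.001 is masked
  expect_false(lt$kept[4])
  expect_false(lt$kept[5])
  expect_true(all(is.na(lt$values[!lt$kept])))
  expect_error(logTpm(-1), "non-negative")
})

test_that("discretization rounds, clamps at zero, and preserves order", {
  expect_equal(discretizeLogTpm(c(4.4)), 4L)
  expect_equal(discretizeLogTpm(c(-0.7)), 0L)
  expect_equal(discretizeLogTpm(c(3.2, 7.9)), c(3L, 8L))
  # monotone non-decreasing on sorted input
  v <- sort(runif(100, -5, 30))
  expect_true(all(diff(discretizeLogTpm(v)) >= 0))
  expect_error(discretizeLogTpm(list(values = numeric(), kept = logical())),
               "no kept")
})

test_that("mixture log-likelihood matches closed forms and the summation oracle", {
  # a = 1 limit: pure Poisson
  counts <- c(0L, 1L, 3L, 5L)
  expect_equal(mixtureLogLik(c(a = 1, u = 2, r = 3, p = 0.5), counts),
               sum(dpois(counts, 2, log = TRUE)))
  # closed form at k = 0: log(0.5 e^-2 + 0.5 * 0.5^3)
  expect_equal(mixtureLogLik(c(a = 0.5, u = 2, r = 3, p = 0.5), 0L),
               log(0.5 * exp(-2) + 0.5 * 0.125))
  # random parameter sets against the independent term-by-term oracle
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.1, 0.9); u <- runif(1, 0.5, 5)
    r <- runif(1, 0.5, 8); p <- runif(1, 0.1, 0.9)
    k <- rpois(50, 3)
    expect_equal(mixtureLogLik(c(a = a, u = u, r = r, p = p), k),
                 oracleMixtureLoglik(a, u, r, p, k), tolerance = 1e-10)
  }
  expect_error(mixtureLogLik(c(a = 1.2, u = 2, r = 3, p = 0.5), 1L), "'a'")
})

test_that("the mixture pmf normalizes to 1 over its effective support", {
  for (par in list(c(0.5, 1, 20, 0.5), c(0.3, 2, 4, 0.25), c(0.8, 3, 6, 0.6))) {
    a <- par[1]; u <- par[2]; r <- par[3]; p <- par[4]
    q <- max(qpois(1 - 1e-8, u), qnbinom(1 - 1e-8, size = r, prob = p))
    tot <- sum(a * dpois(0:q, u) + (1 - a) * dnbinom(0:q, size = r, prob = p))
    expect_equal(tot, 1, tolerance = 1e-6)
  }
})

test_that("fitMixture recovers planted parameters and beats its starts", {
  sim <- simulateMixtureCounts(c(a = 0.6, u = 2, r = 4, p = 0.25),
                               n = 8000, seed = 21)
  fit <- suppressWarnings(fitMixture(sim$counts, seed = 21))
  expect_true(fit@converged)
  est <- mixtureParams(fit)
  expect_lt(abs(est[["a"]] - 0.6), 0.1)
  expect_lt(abs(est[["u"]] - 2), 0.2)
  expect_lt(abs(est[["p"]] - 0.25), 0.1)
  # final loglik is at least the loglik of every start that converged
  expect_true(all(fit@loglik >= fit@trace$loglik[fit@trace$converged] - 1e-6))
  # and at least the likelihood at the truth (MLE property)
  expect_gte(fit@loglik,
             mixtureLogLik(c(a = 0.6, u = 2, r = 4, p = 0.25), sim$counts))
  # diagnostics populated
  d <- fit@diagnostics
  expect_true(is.finite(d$kurtosis_noise))
  expect_true(is.finite(d$skewness_signal))
  expect_true(d$poisson_gof_pvalue >= 0 && d$poisson_gof_pvalue <= 1)
})

test_that("fitMixture on pure Poisson data pushes the noise weight up", {
  set.seed(9)
  counts <- rpois(10000, 2)
  fit <- suppressWarnings(fitMixture(counts, seed = 9))
  expect_gte(fit@a, 0.9)
})

test_that("fitMixture rejects degenerate input", {
  expect_error(fitMixture(rep(3L, 200)), "identical")
  expect_error(fitMixture(1:50), ">= 100")
  expect_error(fitMixture(c(-1L, rep(1L, 200))), "non-negative")
})

test_that("derived threshold equals the exhaustive scan oracle", {
  expect_equal(deriveThreshold(c(a = 0.5, u = 1, r = 20, p = 0.5)),
               oracleThreshold(0.5, 1, 20, 0.5))
  # a -> 1: everything noise, no crossing
  expect_error(deriveThreshold(c(a = 1 - 1e-9, u = 2, r = 5, p = 0.5)),
               "no noise/signal crossing")
  # a -> 0 with sub-unit noise mean: threshold 0
  expect_equal(deriveThreshold(c(a = 1e-9, u = 0.5, r = 5, p = 0.3)), 0L)
})

test_that("threshold is non-decreasing in the noise weight for separated components", {
  # NB mean 12 vs Poisson mean 2 (> u + 3*sqrt(u))
  th <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(a)
    deriveThreshold(c(a = a, u = 2, r = 4, p = 0.25)), integer(1))
  expect_true(all(diff(th) >= 0))
})

test_that("expression calls partition regions and respect the boundary rule", {
  fit <- new("MixtureFit", a = 0.5, u = 2, r = 4, p = 0.25,
             loglik = -1, threshold = 5L, converged = TRUE,
             diagnostics = list(), trace = data.frame())
  lt <- list(values = c(4.6, 5.4, 8.0, NA), kept = c(TRUE, TRUE, TRUE, FALSE))
  calls <- classifyExpression(lt, fit)
  expect_equal(calls, c("noise", "noise", "true_eRNA", "masked"))
  # value rounding to exactly the threshold -> noise (conservative tie-break)
  expect_equal(classifyExpression(list(values = 5.0, kept = TRUE), fit), "noise")
  # permutation invariance
  set.seed(1)
  v <- runif(200, 0, 12)
  lt2 <- list(values = v, kept = rep(TRUE, 200))
  perm <- sample(200)
  calls_perm <- classifyExpression(list(values = v[perm], kept = rep(TRUE, 200)), fit)
  expect_equal(calls_perm, classifyExpression(lt2, fit)[perm])
})

test_that("calls agree with planted component labels at default separation", {
  cfg <- simConfig()
  sim <- simulateMixtureCounts(cfg@mixture, n = 10000, seed = 4)
  fit <- suppressWarnings(fitMixture(sim$counts, seed = 4))
  lt <- list(values = as.numeric(sim$counts), kept = rep(TRUE, length(sim$counts)))
  calls <- classifyExpression(lt, fit)
  agreement <- mean((calls == "true_eRNA") == (sim$component == "signal"))
  expect_gte(agreement, 0.9)
})

test_that("parameter recovery improves with sample size", {
  truth <- c(a = 0.6, u = 2, r = 4, p = 0.25)
  rmse <- vapply(c(500, 5000), function(n) {
    errs <- vapply(1:8, function(s) {
      sim <- simulateMixtureCounts(truth, n = n, seed = s)
      fit <- suppressWarnings(fitMixture(sim$counts, n_starts = 6, seed = s))
      est <- mixtureParams(fit)
      sqrt(mean(((est - truth) / pmax(1, truth))^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})
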