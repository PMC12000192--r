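# Independent dense-MVN oracle: per-pair -2 log density computed directly
# from determinant and solve, no shared code with the fitting machinery.
oracleNeg2LL <- function(spec, params, data) {
  sig <- impliedCovariance(spec, params)
  p <- length(variableNames(spec))
  vidx <- match(variableNames(spec), variableNames(data))
  total <- 0
  for (i in seq_len(nPairs(data))) {
    x <- c(phenotypes(data)[i, 1, vidx], phenotypes(data)[i, 2, vidx])
    obs <- which(!is.na(x))
    if (!length(obs)) next
    g <- if (spec@sexLimitation == "none") zygosity(data)[i]
         else paste(zygosity(data)[i], pairSex(data)[i], sep = ".")
    S <- sig[[g]][obs, obs, drop = FALSE]
    total <- total + length(obs) * log(2 * pi) +
      as.numeric(determinant(S, logarithm = TRUE)$modulus) +
      drop(t(x[obs]) %*% solve(S, x[obs]))
  }
  unname(total)
}

test_that("raw-data likelihood matches closed forms and the dense oracle", {
  # one pair, identity covariance, observations at the origin
  ph <- array(0, c(1, 2, 1))
  d1 <- TwinDataset("f1", "MZ", "M", ph, "trait",
                    preprocessing = c("raw", "sex_residualised", "normalised"))
  sp <- univariateACE()
  th <- setNames(c(0, 0, 1), paramIndex(sp)$name)
  expect_equal(neg2LogLik(sp, th, d1), 2 * log(2 * pi), tolerance = 1e-12)

  # complete multivariate data: agreement with the dense per-pair oracle
  spc <- choleskySpec(paste0("t", 1:3))
  set.seed(31)
  thc <- randomParams(spc)
  dc <- simulateTwins(generatingTruth(spc, thc, 80, 70, seed = 13))
  expect_equal(neg2LogLik(spc, thc, dc), oracleNeg2LL(spc, thc, dc),
               tolerance = 1e-8)

  # missing data: same oracle, marginalised sub-vectors
  dm <- simulateTwins(generatingTruth(spc, thc, 80, 70, seed = 14,
                                      missingRate = 0.3))
  expect_equal(neg2LogLik(spc, thc, dm), oracleNeg2LL(spc, thc, dm),
               tolerance = 1e-8)

  # a pair with twin 2 fully missing contributes twin 1's marginal density
  ph2 <- array(NA_real_, c(1, 2, 2))
  ph2[1, 1, 1] <- 0.3   # twin 1, variable a
  ph2[1, 1, 2] <- 0.8   # twin 1, variable b
  d2 <- TwinDataset("f1", "DZ", "F", ph2, c("a", "b"),
                    preprocessing = c("raw", "sex_residualised", "normalised"))
  sp2 <- choleskySpec(c("a", "b"))
  th2 <- randomParams(sp2)
  V <- impliedCovariance(sp2, th2)$DZ[1:2, 1:2]
  x <- c(0.3, 0.8)
  marg <- 2 * log(2 * pi) +
    as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    drop(t(x) %*% solve(V, x))
  expect_equal(neg2LogLik(sp2, th2, d2), unname(marg), tolerance = 1e-10)
})

test_that("likelihood is invariant under twin-1/twin-2 exchange", {
  spc <- choleskySpec(paste0("t", 1:3))
  set.seed(33)
  thc <- randomParams(spc)
  d <- simulateTwins(generatingTruth(spc, thc, 60, 60, seed = 15,
                                     missingRate = 0.2))
  swapped <- d
  swapped@phenotypes <- d@phenotypes[, 2:1, , drop = FALSE]
  expect_equal(neg2LogLik(spc, thc, swapped), neg2LogLik(spc, thc, d),
               tolerance = 1e-9)
})

test_that("univariate ACE recovery is unbiased and triangulates with the
           moment oracle", {
  ests <- t(vapply(1:10, function(r) {
    d <- simulateTwins(univTruth(0.4, 0.1, 5000, 5000, seed = 170 + r))
    f <- fitTwinModel(univariateACE(), d, nRestarts = 1, computeVcov = FALSE)
    stopifnot(f@converged)
    tot <- standardiseFit(f)$totals
    fal <- falconerEstimates(d, "trait")
    c(h2 = tot$h2, c2 = tot$c2, e2 = tot$e2, falh2 = fal$h2)
  }, numeric(4)))
  # recovery: mean estimates sit on the generating values
  expect_near(mean(ests[, "h2"]), 0.4, 0.03)
  expect_near(mean(ests[, "c2"]), 0.1, 0.03)
  expect_near(mean(ests[, "e2"]), 0.5, 0.03)
  # likelihood and moment estimators agree draw by draw
  expect_lt(max(abs(ests[, "h2"] - ests[, "falh2"])), 0.05)

  # refitting from the optimum does not move the objective
  d <- simulateTwins(univTruth(0.4, 0.1, 5000, 5000, seed = 17))
  f <- fitTwinModel(univariateACE(), d, nRestarts = 2, computeVcov = FALSE)
  f2 <- fitTwinModel(univariateACE(), d, nRestarts = 1,
                     start = coef(f), computeVcov = FALSE)
  expect_lt(abs(f2@neg2ll - f@neg2ll), 1e-6)
  expect_equal(f@aic, f@neg2ll + 2 * f@nFree, tolerance = 1e-9)

  # E-only truth: estimated a2 and c2 nearly vanish (mean over draws)
  null_ests <- t(vapply(1:3, function(r) {
    d0 <- simulateTwins(univTruth(0, 0, 5000, 5000, seed = 180 + r))
    f0 <- fitTwinModel(univariateACE(), d0, nRestarts = 1,
                       computeVcov = FALSE)
    tot0 <- standardiseFit(f0)$totals
    c(tot0$h2, tot0$c2)
  }, numeric(2)))
  expect_lt(mean(null_ests[, 1]), 0.05)
  expect_lt(mean(null_ests[, 2]), 0.05)
})

test_that("with e fixed, the AE path matches a fine grid search", {
  d <- simulateTwins(univTruth(0.45, 0, 1500, 1500, seed = 19))
  spAE <- univariateACE(components = c("A", "E"))
  eFix <- sqrt(0.55)
  f <- fitTwinModel(spAE, d, nRestarts = 2,
                    fixedParams = c(E.S1.trait = eFix), computeVcov = FALSE)
  # independent 1-D grid on the closed-form two-group complete-data -2LL
  x <- phenotypes(d)
  SmzC <- crossprod(cbind(x[zygosity(d) == "MZ", 1, 1],
                          x[zygosity(d) == "MZ", 2, 1]))
  SdzC <- crossprod(cbind(x[zygosity(d) == "DZ", 1, 1],
                          x[zygosity(d) == "DZ", 2, 1]))
  nmz <- sum(zygosity(d) == "MZ"); ndz <- sum(zygosity(d) == "DZ")
  gridObj <- function(a) {
    v <- a^2 + eFix^2
    val <- 0
    for (gg in list(list(S = SmzC, n = nmz, b = a^2),
                    list(S = SdzC, n = ndz, b = 0.5 * a^2))) {
      Sg <- matrix(c(v, gg$b, gg$b, v), 2)
      val <- val + gg$n * (2 * log(2 * pi) +
        determinant(Sg, logarithm = TRUE)$modulus) +
        sum(solve(Sg) * gg$S)
    }
    as.numeric(val)
  }
  grid <- seq(0.4, 0.95, by = 1e-4)
  aStar <- grid[which.min(vapply(grid, gridObj, 0))]
  expect_equal(unname(coef(f)["A.S1.trait"]), aStar, tolerance = 1e-3)
})

test_that("chi-square difference tests behave at their fixed points", {
  d <- simulateTwins(univTruth(0.4, 0.1, 800, 800, seed = 23))
  f <- fitTwinModel(univariateACE(), d, nRestarts = 2, computeVcov = FALSE)
  self <- twinLRT(f, f)
  expect_equal(self$delta_neg2ll, 0)
  expect_equal(self$delta_df, 0L)
  expect_equal(self$p_value, 1)
  # nested ordering: the restricted model can never fit better
  fae <- fitTwinModel(univariateACE(components = c("A", "E")), d,
                      nRestarts = 2, computeVcov = FALSE)
  lrt <- twinLRT(fae, f)
  expect_gte(lrt$delta_neg2ll, 0)
  expect_equal(lrt$delta_df, 1L)
  expect_error(twinLRT(f, fae), "more free parameters|not nested")
  # non-nested specs are rejected
  spOther <- univariateACE(variable = "other")
  thO <- setNames(sqrt(c(0.4, 0.1, 0.5)), paramIndex(spOther)$name)
  dO <- simulateTwins(generatingTruth(spOther, thO, 50, 50, seed = 1))
  fO <- fitTwinModel(spOther, dO, nRestarts = 1, computeVcov = FALSE)
  expect_error(twinLRT(f, fO), "not nested")
})

test_that("ACE-vs-AE test keeps its size under a true C = 0 null", {
  rejections <- 0L
  for (r in 1:30) {
    d <- simulateTwins(univTruth(0.4, 0, 2000, 2000, seed = 300 + r))
    f <- fitTwinModel(univariateACE(), d, nRestarts = 1, computeVcov = FALSE)
    fae <- fitTwinModel(univariateACE(components = c("A", "E")), d,
                        nRestarts = 1, computeVcov = FALSE)
    if (twinLRT(fae, f)$p_value < 0.05) rejections <- rejections + 1L
  }
  # boundary-conservative: naive chi-square rejects at most 5% (binomial
  # slack for 30 replicates)
  expect_lte(rejections, 4L)
})

test_that("small true-zero paths are pruned without damaging fit", {
  pruned <- 0L; pvals <- numeric(0)
  for (r in 1:25) {
    d <- simulateTwins(univTruth(0.45, 0, 5000, 5000, seed = 400 + r))
    f <- fitTwinModel(univariateACE(), d, nRestarts = 1)
    pf <- pruneSmallPaths(f, d)
    zc <- pf@spec@zeroConstraints
    if (nrow(zc) && any(zc$component == "C")) {
      pruned <- pruned + 1L
      pvals <- c(pvals, twinLRT(pf, f)$p_value)
    }
  }
  expect_gte(pruned, 22L)          # ~90% of replicates drop the null C path
  expect_true(all(pvals > 0.05))   # pruning never degrades fit significantly

  # a fit with nothing below threshold comes back unchanged
  d <- simulateTwins(univTruth(0.4, 0.25, 3000, 3000, seed = 55))
  f <- fitTwinModel(univariateACE(), d, nRestarts = 2)
  pf <- pruneSmallPaths(f, d)
  expect_equal(pf@neg2ll, f@neg2ll)
  expect_equal(nrow(pf@spec@zeroConstraints), 0L)
})

test_that("sex-difference tests detect scalar effects and respect the null", {
  # equal-structure data: both comparisons stay non-significant
  nonsig <- 0L
  for (r in 1:8) {
    d <- simulateTwins(univTruth(0.4, 0.1, 800, 800, seed = 500 + r,
                                 sexFraction = 0.5))
    res <- testSexDifferences(d, "trait", nRestarts = 1, computeVcov = FALSE)
    if (all(res$tests$p_value > 0.05)) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 6L)

  # scalar 1.3 truth: scalar-vs-none is detected, scalar estimate recovered
  sp <- univariateACE("scalar")
  th <- setNames(c(sqrt(0.4), sqrt(0.1), sqrt(0.5), 1.3),
                 paramIndex(sp)$name)
  sig <- 0L
  for (r in 1:5) {
    d <- simulateTwins(generatingTruth(sp, th, 2500, 2500,
                                       sexFraction = 0.5, seed = 600 + r))
    res <- testSexDifferences(d, "trait", nRestarts = 1, computeVcov = FALSE)
    if (res$tests$p_value[res$tests$comparison == "scalar_vs_none"] < 0.05)
      sig <- sig + 1L
  }
  expect_gte(sig, 4L)

  # identity recovery of the scalar on equal-variance data
  d0 <- simulateTwins(univTruth(0.4, 0.1, 2500, 2500, sexFraction = 0.5,
                                seed = 61))
  f0 <- fitTwinModel(univariateACE("scalar"), d0, nRestarts = 2,
                     computeVcov = FALSE)
  expect_equal(unname(coef(f0)["scalar.trait"]), 1, tolerance = 0.05)
})

test_that("fitted covariance approaches the sample covariance as n grows", {
  frob <- vapply(c(500, 2000, 8000), function(n) {
    d <- simulateTwins(univTruth(0.4, 0.15, n, n, seed = n))
    f <- fitTwinModel(univariateACE(), d, nRestarts = 1, computeVcov = FALSE)
    sig <- impliedCovariance(f@spec, coef(f))
    tot <- 0
    for (z in c("MZ", "DZ")) {
      X <- cbind(phenotypes(d)[zygosity(d) == z, 1, 1],
                 phenotypes(d)[zygosity(d) == z, 2, 1])
      Sn <- crossprod(X) / nrow(X)   # ML (zero-mean) sample covariance
      tot <- tot + sqrt(sum((sig[[z]] - Sn)^2))
    }
    tot
  }, 0)
  expect_true(all(diff(frob) < 0))
})

test_that("all-missing pairs are dropped with a count and groups are sized", {
  d <- simulateTwins(univTruth(0.4, 0.1, 50, 40, seed = 71))
  ph <- phenotypes(d)
  ph[1:3, , ] <- NA
  d@phenotypes <- ph
  f <- fitTwinModel(univariateACE(), d, nRestarts = 1, computeVcov = FALSE)
  expect_equal(f@details$nPairsDroppedAllMissing, 3L)
  expect_equal(sum(f@groups), 87L)
})
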