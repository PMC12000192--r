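test_that("standardised contributions sum correctly and hit fixed points", {
  # equal paths give equal thirds
  sp <- univariateACE()
  th <- setNames(rep(1 / sqrt(3), 3), paramIndex(sp)$name)
  tr <- generatingTruth(sp, th, 10, 10)
  tot <- standardiseFit(tr)$totals
  expect_equal(unname(unlist(tot[, c("h2", "c2", "e2")])), rep(1 / 3, 3),
               tolerance = 1e-12)

  # random valid models: totals sum to 1, factor contributions sum to the
  # component total, all non-negative
  set.seed(91)
  for (sp in list(ipmSpec(c("a12", "b12", "c18", "d18"),
                          age18Mask = c(FALSE, FALSE, TRUE, TRUE)),
                  choleskySpec(paste0("t", 1:3)))) {
    th <- randomParams(sp)
    std <- standardiseFit(generatingTruth(sp, th, 10, 10))
    expect_equal(rowSums(std$totals[, c("h2", "c2", "e2")]),
                 rep(1, nrow(std$totals)), tolerance = 1e-6)
    expect_true(all(std$table$contrib >= 0))
    for (v in variableNames(sp)) for (cmp in c("A", "C", "E")) {
      tabSum <- sum(std$table$contrib[std$table$variable == v &
                                        std$table$component == cmp])
      totName <- c(A = "h2", C = "c2", E = "e2")[[cmp]]
      expect_equal(tabSum, std$totals[[totName]][std$totals$variable == v],
                   tolerance = 1e-9)
    }
    # correlation matrix rebuilt from the decomposition's loadings matches
    # the implied covariance, standardised
    Ls <- std$loadings[[1]]
    V <- Reduce(`+`, lapply(Ls, tcrossprod))
    R1 <- stats::cov2cor(V)
    sig <- impliedCovariance(sp, th)[[1]]
    p <- length(variableNames(sp))
    R2 <- stats::cov2cor(sig[1:p, 1:p])
    expect_equal(unname(R1), unname(R2), tolerance = 1e-9)
  }
})

test_that("scalar sex limitation leaves standardised proportions unchanged", {
  sp <- ipmSpec(c("a12", "b18"), age18Mask = c(FALSE, TRUE),
                scalarVariables = c("a12", "b18"))
  set.seed(92)
  th <- randomParams(sp)
  std <- standardiseFit(generatingTruth(sp, th, 10, 10))
  # rebuild proportions in the female group directly: scalars must cancel
  K <- twinpath:::.modelKernel(sp)
  LsF <- twinpath:::.kernelLoadings(K, th, "F")
  VF <- diag(Reduce(`+`, lapply(LsF, tcrossprod)))
  h2F <- rowSums(LsF[["A"]]^2) / VF
  expect_equal(unname(h2F), std$totals$h2, tolerance = 1e-10)
})

test_that("Cholesky accounting reproduces the printed heritability sums", {
  acc <- choleskyAccounting(c(0.134, 0.064, 0.126, 0.122))
  expect_equal(acc$total, 0.446, tolerance = 1e-12)
  expect_equal(unname(acc$proportionBefore), 0.324 / 0.446, tolerance = 1e-12)
  expect_equal(round(100 * unname(acc$proportionBefore), 2), 72.65)
  expect_equal(round(unname(acc$proportionInPlace[1]), 2), 0.30)
  # everything on the first factor -> fully in place at the first occasion
  acc1 <- choleskyAccounting(c(0.4, 0, 0, 0))
  expect_equal(unname(acc1$proportionInPlace[1]), 1)

  # accounting from an actual Cholesky fit agrees with its decomposition
  spc <- choleskySpec(paste0("t", 1:3))
  set.seed(93)
  thc <- randomParams(spc)
  d <- simulateTwins(generatingTruth(spc, thc, 1500, 1500, seed = 7))
  f <- fitTwinModel(spc, d, nRestarts = 2, computeVcov = FALSE)
  accF <- choleskyAccounting(f, "t3")
  tot <- standardiseFit(f)$totals
  expect_equal(accF$total, tot$h2[tot$variable == "t3"], tolerance = 1e-9)
  expect_equal(length(accF$contributions), 3L)
  expect_equal(unname(accF$proportionInPlace[3]), 1, tolerance = 1e-9)
  expect_named(accF$newVariance, c("A", "C", "E"))
})

test_that("common/specific table matches the reference decomposition", {
  std <- standardiseFit(referenceIPMTruth())
  tab <- commonSpecificTable(std)
  # single-factor genetic structure reports 100% common
  expect_equal(tab["A_C1.pct", "dep12"], 100, tolerance = 1e-9)
  expect_equal(tab["A_S.pct", "dep12"], 0, tolerance = 1e-9)
  # the 0.171 / 0.226 split of iso12 heritability
  expect_near(tab["A_C1.pct", "iso12"], 43.09, 0.05)
  expect_near(tab["A_S.pct", "iso12"], 56.91, 0.05)
  # splits sum to 100 within each defined component
  for (v in colnames(tab)) {
    for (cmp in c("A", "C", "E")) {
      rows <- paste0(cmp, c("_C1", "_C2", "_S"), ".pct")
      vals <- tab[intersect(rows, rownames(tab)), v]
      if (all(is.na(vals))) next
      expect_equal(sum(vals, na.rm = TRUE), 100, tolerance = 1e-6)
    }
  }
})

test_that("correlation shares follow path tracing and sum to 100", {
  expect_near(pathTraceShare(0.171, 0.271, 0.279), 77.16, 0.005)

  # only E is shared -> E share is 100%
  sp <- ipmSpec(c("x12", "y18"), age18Mask = c(FALSE, TRUE))
  th <- setNames(numeric(nFreeParams(sp)), paramIndex(sp)$name)
  th["E.C1.x12"] <- 0.4; th["E.C1.y18"] <- 0.5
  th["E.S1.x12"] <- 0.8; th["E.S2.y18"] <- 0.7
  th["A.S1.x12"] <- 0.3; th["A.S2.y18"] <- 0.3
  std <- standardiseFit(generatingTruth(sp, th, 10, 10))
  cs <- correlationShares(std, "x12", "y18")
  expect_equal(cs$share_E, 100, tolerance = 1e-9)
  expect_equal(cs$share_A, 0)

  # reference model: shares sum to 100 and are symmetric in (i, j); a
  # brute-force enumeration over every common factor path reproduces them
  stdR <- standardiseFit(referenceIPMTruth())
  spR <- stdR$spec
  fi <- factorInfo(spR)
  for (pair in list(c("iso12", "dep12"), c("iso12", "con18"),
                    c("dep12", "psy18"))) {
    cs <- correlationShares(stdR, pair[1], pair[2])
    expect_equal(cs$share_A + cs$share_C + cs$share_E, 100, tolerance = 1e-6)
    cs2 <- correlationShares(stdR, pair[2], pair[1])
    expect_equal(cs$share_A, cs2$share_A, tolerance = 1e-10)
    vi <- match(pair[1], variableNames(spR))
    vj <- match(pair[2], variableNames(spR))
    brute <- c(A = 0, C = 0, E = 0)
    for (r in seq_len(nrow(fi))) {
      if (fi$type[r] != "common") next
      L <- stdR$loadings[[1]][[fi$component[r]]]
      brute[fi$component[r]] <- brute[fi$component[r]] +
        L[vi, fi$col[r]] * L[vj, fi$col[r]]
    }
    expect_equal(cs$share_A, unname(100 * brute["A"] / sum(brute)),
                 tolerance = 1e-10)
    expect_equal(cs$share_E, unname(100 * brute["E"] / sum(brute)),
                 tolerance = 1e-10)
  }

  # genetic share of the concurrent iso12-dep12 association is large
  csAD <- correlationShares(stdR, "iso12", "dep12")
  expect_near(csAD$share_A, 77, 1.5)
})

test_that("Falconer estimates are exact in the ICC arithmetic and recover
           simulated heritability", {
  d <- simulateTwins(univTruth(0.45, 0, 10000, 10000, seed = 95))
  fal <- falconerEstimates(d, "trait")
  expect_equal(fal$h2, 2 * (fal$rMZ - fal$rDZ), tolerance = 1e-12)
  expect_equal(fal$c2, 2 * fal$rDZ - fal$rMZ, tolerance = 1e-12)
  expect_equal(fal$e2, 1 - fal$rMZ, tolerance = 1e-12)
  expect_near(fal$h2, 0.45, 0.05)
  expect_near(fal$c2, 0, 0.05)

  # too few complete pairs in a zygosity group is an error
  tiny <- simulateTwins(univTruth(0.4, 0.1, 2, 30, seed = 96))
  expect_error(falconerEstimates(tiny, "trait"), "fewer than 3")
})
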