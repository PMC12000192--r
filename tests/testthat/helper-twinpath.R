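# Shared fixtures: all data are generated in code.

# Absolute-tolerance comparison (expect_equal's tolerance is relative).
expect_near <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}

# Univariate generating truth on the standardised scale.
univTruth <- function(a2, c2, nMZ, nDZ, seed = 1L, ...) {
  sp <- univariateACE()
  e2 <- 1 - a2 - c2
  th <- stats::setNames(sqrt(c(a2, c2, e2)), paramIndex(sp)$name)
  generatingTruth(sp, th, nMZ, nDZ, seed = seed, ...)
}

# Small two-variable IPM truth with explicit loadings (named assignment).
ipm2Truth <- function(loadings, nMZ = 100L, nDZ = 100L, seed = 1L,
                      vars = c("x12", "y18")) {
  sp <- ipmSpec(vars, age18Mask = c(FALSE, TRUE))
  th <- stats::setNames(numeric(nFreeParams(sp)), paramIndex(sp)$name)
  th[names(loadings)] <- loadings
  generatingTruth(sp, th, nMZ, nDZ, seed = seed)
}

writeTempCSV <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Random valid parameter vector for property checks: keeps E specifics
# comfortably away from zero so implied covariances stay positive definite.
randomParams <- function(spec) {
  idx <- paramIndex(spec)
  th <- stats::rnorm(nrow(idx), 0, 0.3)
  spec_e <- idx$component == "E" & !is.na(idx$component)
  fi <- factorInfo(spec)
  for (k in which(spec_e)) {
    ty <- fi$type[fi$component == "E" & fi$factor == idx$factor[k]]
    if (identical(ty, "specific") ||
        (spec@family == "cholesky" && idx$row[k] == idx$col[k]))
      th[k] <- 0.6 + abs(th[k])
  }
  th[idx$type == "scalar"] <- 1 + abs(th[idx$type == "scalar"]) * 0.3
  stats::setNames(th, idx$name)
}
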