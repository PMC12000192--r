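## Synthetic twin cohorts with known A/C/E generating structure.

#' Construct a GeneratingTruth
#'
#' @param spec a \linkS4class{TwinModelSpec}.
#' @param params named numeric vector of true path coefficients (order of
#'   \code{\link{paramIndex}}).
#' @param nMZ,nDZ pair counts per zygosity.
#' @param sexFraction fraction of male pairs (default 0.49, sex evenly
#'   distributed within zygosity).
#' @param missingRate per-cell MCAR rate (default 0).
#' @param seed integer seed.
#' @return a \linkS4class{GeneratingTruth} (validity checks that every
#'   group's implied covariance is positive definite).
#' @export
generatingTruth <- function(spec, params, nMZ, nDZ, sexFraction = 0.49,
                            missingRate = 0, seed = 1L) {
  if (is.null(names(params))) names(params) <- paramIndex(spec)$name
  new("GeneratingTruth", spec = spec, params = params,
      nMZ = as.integer(nMZ), nDZ = as.integer(nDZ),
      sexFraction = sexFraction, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Simulate a twin cohort from a known generating model
#'
#' Draws each pair's 2p-vector from the zero-mean multivariate normal with
#' its group's implied covariance (MZ cross-twin block A + C, DZ block
#' 0.5 A + C), then applies missing-completely-at-random masking. The
#' result is generated on the standardised scale and is marked normalised,
#' ready for fitting. Deterministic given the truth's seed; the caller's
#' RNG state is restored on exit.
#'
#' @param truth a \linkS4class{GeneratingTruth}.
#' @return a \linkS4class{TwinDataset}; the generating truth is echoed in
#'   the dataset log.
#' @export
simulateTwins <- function(truth) {
  stopifnot(is(truth, "GeneratingTruth"))
  spec <- truth@spec
  p <- length(spec@variableNames)
  sig <- impliedCovariance(spec, truth@params)
  chols <- lapply(sig, chol)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(truth@seed)
  zyg <- sex <- character(0)
  X <- NULL
  for (z in c("MZ", "DZ")) {
    n <- if (z == "MZ") truth@nMZ else truth@nDZ
    if (n == 0) next
    nM <- round(n * truth@sexFraction)
    sx <- c(rep("M", nM), rep("F", n - nM))
    for (s in c("M", "F")) {
      ns <- sum(sx == s)
      if (ns == 0) next
      g <- if (spec@sexLimitation == "none") z else paste(z, s, sep = ".")
      Z <- matrix(stats::rnorm(ns * 2 * p), ns, 2 * p)
      X <- rbind(X, Z %*% chols[[g]])
      zyg <- c(zyg, rep(z, ns))
      sex <- c(sex, rep(s, ns))
    }
  }
  n <- length(zyg)
  if (truth@missingRate > 0) {
    mask <- matrix(stats::runif(n * 2 * p) < truth@missingRate, n, 2 * p)
    X[mask] <- NA_real_
  }
  ph <- array(NA_real_, c(n, 2, p))
  ph[, 1, ] <- X[, seq_len(p)]
  ph[, 2, ] <- X[, p + seq_len(p)]
  TwinDataset(sprintf("fam%05d", seq_len(n)), zyg, sex, ph,
              spec@variableNames,
              preprocessing = c("raw", "sex_residualised", "normalised"),
              log = list(generator = "simulateTwins", seed = truth@seed,
                         nMZ = truth@nMZ, nDZ = truth@nDZ,
                         missingRate = truth@missingRate))
}

#' Reference standardised components for the 8-variable isolation /
#' mental-health independent pathway model
#'
#' The standardised totals (h2, c2, e2, as percentages) and within-component
#' percentage splits (first common factor C1, second common factor C2
#' loading on the age-18 variables, specific factor S) reported for social
#' isolation, depression symptoms, conduct problems and psychotic
#' experiences at ages 12 and 18 in a UK population-representative cohort
#' of same-sex twin pairs. Conduct problems at age 12 showed quantitative
#' sex differences, so that variable appears twice (male and female rows);
#' all other rows apply to both sexes. \code{NA} marks factors absent from
#' the model (no C2 at age 12) and dashes in the source (paths constrained
#' to zero).
#'
#' @return data.frame: variable, sex, h2, c2, e2, A_C1, A_C2, A_S, C_C1,
#'   C_C2, C_S, E_C1, E_C2, E_S (percent).
#' @export
referenceIPMComponents <- function() {
  data.frame(
    variable = c("iso12", "dep12", "con12", "con12", "psy12",
                 "iso18", "dep18", "con18", "psy18"),
    sex = c("both", "both", "M", "F", "both", "both", "both", "both", "both"),
    h2   = c(39.69, 27.07,  1.81, 15.89, 21.08, 42.46, 18.94,  9.74,  9.62),
    c2   = c( 3.66, 11.23, 41.87, 25.36,  9.49,  1.81,  9.64, 35.18, 16.37),
    e2   = c(56.66, 61.70, 56.33, 58.75, 69.44, 55.73, 71.41, 55.08, 74.01),
    A_C1 = c(43.09,   100,   100, 19.88, 45.25, 33.12, 51.26,     0, 92.27),
    A_C2 = c(NA, NA, NA, NA, NA,          9.13, 11.83,   100,     0),
    A_S  = c(56.91,     0,     0, 80.12, 54.76, 57.75, 36.91,     0,  7.73),
    C_C1 = c(  100, 40.37, 60.91,   100,     0,   100,  7.59, 85.10,  2.63),
    C_C2 = c(NA, NA, NA, NA, NA,             0, 92.42, 14.91, 97.37),
    C_S  = c(    0, 59.63, 39.09,     0,   100,     0,     0,     0,     0),
    E_C1 = c( 2.10,  7.56, 55.09, 25.87,  3.84,  0.78,  0.67,  8.66,  3.38),
    E_C2 = c(NA, NA, NA, NA, NA,          7.60, 26.28,  8.42, 22.98),
    E_S  = c(97.90, 92.44, 44.91, 74.14, 96.16, 91.62, 73.05, 82.93, 73.64),
    stringsAsFactors = FALSE)
}

#' Convert standardised components into IPM generating loadings
#'
#' Each loading is \code{sqrt(total * percentage / 100)} (e.g. the C1
#' genetic loading of a variable is the square root of h2 times its A_C1
#' share). Because published rows are rounded, totals need not sum to
#' exactly 1 nor splits to exactly 100; with \code{normalise = TRUE}
#' (default) each variable's totals are rescaled to sum to 1 and each
#' component's splits to 100, so the generating model has exactly
#' unit-variance variables and \code{\link{standardiseFit}} reproduces the
#' (normalised) inputs to machine precision.
#'
#' @param tbl a data.frame in the layout of
#'   \code{\link{referenceIPMComponents}}.
#' @param conductSex which conduct-12 row to use where a variable has
#'   per-sex rows (default \code{"M"}).
#' @param nMZ,nDZ,sexFraction,missingRate,seed cohort dimensions for the
#'   returned truth.
#' @param normalise rescale rounded rows for exact self-consistency.
#' @return a \linkS4class{GeneratingTruth} for the 8-variable IPM.
#' @export
ipmTruthFromComponents <- function(tbl = referenceIPMComponents(),
                                   conductSex = "M",
                                   nMZ = 625, nDZ = 491,
                                   sexFraction = 0.49, missingRate = 0,
                                   seed = 1L, normalise = TRUE) {
  keep <- tbl$sex == "both" | tbl$sex == conductSex
  tbl <- tbl[keep, , drop = FALSE]
  vars <- tbl$variable
  spec <- ipmSpec(vars)
  idx <- paramIndex(spec)
  params <- stats::setNames(numeric(nrow(idx)), idx$name)
  for (k in seq_len(nrow(tbl))) {
    v <- tbl$variable[k]
    tot <- c(A = tbl$h2[k], C = tbl$c2[k], E = tbl$e2[k]) / 100
    if (normalise) tot <- tot / sum(tot)
    for (cmp in c("A", "C", "E")) {
      pct <- c(C1 = tbl[[paste0(cmp, "_C1")]][k],
               C2 = tbl[[paste0(cmp, "_C2")]][k],
               S = tbl[[paste0(cmp, "_S")]][k])
      pct[is.na(pct)] <- 0
      if (normalise && sum(pct) > 0) pct <- 100 * pct / sum(pct)
      sfac <- paste0("S", match(v, vars))
      for (fg in c("C1", "C2", "S")) {
        fac <- if (fg == "S") sfac else fg
        nm <- paste(cmp, fac, v, sep = ".")
        if (nm %in% names(params))
          params[nm] <- sqrt(tot[cmp] * pct[fg] / 100)
      }
    }
  }
  generatingTruth(spec, params, nMZ = nMZ, nDZ = nDZ,
                  sexFraction = sexFraction, missingRate = missingRate,
                  seed = seed)
}

#' Default reference generating truth for the 8-variable IPM
#'
#' Shorthand for \code{ipmTruthFromComponents()} with the reference
#' component table and a cohort mimicking the emulated study: 1,116
#' same-sex pairs, 56\% MZ, 49\% male, no missingness.
#'
#' @param nMZ,nDZ pair counts (defaults 625 MZ / 491 DZ).
#' @param seed integer seed.
#' @param ... passed to \code{\link{ipmTruthFromComponents}}.
#' @return a \linkS4class{GeneratingTruth}.
#' @export
referenceIPMTruth <- function(nMZ = 625, nDZ = 491, seed = 1L, ...) {
  ipmTruthFromComponents(nMZ = nMZ, nDZ = nDZ, seed = seed, ...)
}
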