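#' @import methods
NULL

.ZYG_LEVELS <- c("MZ", "DZ")
.SEX_LEVELS <- c("M", "F")
.COMPONENTS <- c("A", "C", "E")
.PREP_STATES <- c("raw", "sex_residualised", "normalised")

#' TwinDataset: pair-level phenotypes for same-sex MZ/DZ twins
#'
#' One row (slice) per family: a family identifier, zygosity (MZ or DZ), the
#' pair's sex (pairs are same-sex), and an \code{n x 2 x p} array of phenotype
#' values for twin 1 and twin 2 on \code{p} variables. Missing values are
#' allowed and preserved by all preprocessing steps. The
#' \code{preprocessing} slot tracks which of the pipeline stages (raw values,
#' sex residualisation, rank-based normalisation) have been applied; model
#' fitting requires fully normalised data.
#'
#' @slot familyId character vector of pair identifiers.
#' @slot zygosity character vector, \code{"MZ"} or \code{"DZ"}.
#' @slot pairSex character vector, \code{"M"} or \code{"F"}.
#' @slot phenotypes numeric array \code{n x 2 x p} (pairs, twins, variables).
#' @slot variableNames character vector of the \code{p} variable labels.
#' @slot preprocessing character subset of
#'   \code{c("raw", "sex_residualised", "normalised")}.
#' @slot log list of bookkeeping entries (rows dropped at import, etc.).
#' @exportClass TwinDataset
setClass("TwinDataset",
  representation(
    familyId = "character",
    zygosity = "character",
    pairSex = "character",
    phenotypes = "array",
    variableNames = "character",
    preprocessing = "character",
    log = "list"
  )
)

setValidity("TwinDataset", function(object) {
  n <- length(object@familyId)
  d <- dim(object@phenotypes)
  msgs <- character(0)
  if (length(d) != 3L)
    return("phenotypes must be an n x 2 x p array")
  if (d[1] != n || length(object@zygosity) != n || length(object@pairSex) != n)
    msgs <- c(msgs, "familyId, zygosity, pairSex and phenotypes disagree on n")
  if (d[2] != 2L)
    msgs <- c(msgs, "second dimension of phenotypes must be 2 (twins)")
  if (d[3] != length(object@variableNames))
    msgs <- c(msgs, "third dimension of phenotypes must match variableNames")
  if (anyNA(object@zygosity) || !all(object@zygosity %in% .ZYG_LEVELS))
    msgs <- c(msgs, "zygosity must be non-missing MZ/DZ for every pair")
  if (anyNA(object@pairSex) || !all(object@pairSex %in% .SEX_LEVELS))
    msgs <- c(msgs, "pairSex must be non-missing M/F for every pair")
  if (!all(object@preprocessing %in% .PREP_STATES))
    msgs <- c(msgs, "unknown preprocessing state")
  if (anyDuplicated(object@variableNames))
    msgs <- c(msgs, "variableNames must be unique")
  if (length(msgs)) msgs else TRUE
})

#' TwinModelSpec: declarative biometric model description
#'
#' Describes one of the three supported model families — univariate ACE,
#' longitudinal Cholesky, or independent pathway model (IPM) — as free /
#' fixed-zero patterns of factor loadings per variance component, together
#' with sex-limitation rules. Variance components are parameterised through
#' loadings (Gram-matrix form) so every component contribution is positive
#' semi-definite by construction.
#'
#' @slot family one of \code{"univariate_ace"}, \code{"cholesky"},
#'   \code{"ipm"}.
#' @slot variableNames labels of the p phenotypic variables, in model order.
#' @slot components subset of \code{c("A","C","E")}; E is always present.
#' @slot pattern named list (one entry per component) of \code{p x m} logical
#'   matrices; \code{TRUE} marks a free loading. Column names label factors
#'   (\code{C1}, \code{C2}, \code{S1..Sp} for the IPM; \code{F1..Fp} for a
#'   Cholesky). A \code{"type"} attribute on each matrix marks columns as
#'   \code{"common"} or \code{"specific"}.
#' @slot sexLimitation \code{"none"}, \code{"scalar"} or
#'   \code{"quantitative"}.
#' @slot scalarVariables variables given a free female variance scalar.
#' @slot quantVariables variables whose loadings are duplicated per sex.
#' @slot zeroConstraints data.frame (component, variable, factor) of paths
#'   fixed to zero on top of the family's structural pattern.
#' @exportClass TwinModelSpec
setClass("TwinModelSpec",
  representation(
    family = "character",
    variableNames = "character",
    components = "character",
    pattern = "list",
    sexLimitation = "character",
    scalarVariables = "character",
    quantVariables = "character",
    zeroConstraints = "data.frame"
  )
)

setValidity("TwinModelSpec", function(object) {
  msgs <- character(0)
  p <- length(object@variableNames)
  if (!object@family %in% c("univariate_ace", "cholesky", "ipm"))
    msgs <- c(msgs, "unknown model family")
  if (!all(object@components %in% .COMPONENTS))
    msgs <- c(msgs, "components must be within A, C, E")
  if (!"E" %in% object@components)
    msgs <- c(msgs, "E must always be included")
  if (!setequal(names(object@pattern), object@components))
    msgs <- c(msgs, "pattern list must have one entry per component")
  for (cmp in names(object@pattern)) {
    pat <- object@pattern[[cmp]]
    if (!is.matrix(pat) || nrow(pat) != p)
      msgs <- c(msgs, sprintf("pattern for %s must be a p-row matrix", cmp))
  }
  # every variable needs free E variance somewhere (no zero-E variables)
  if ("E" %in% names(object@pattern) && is.matrix(object@pattern[["E"]])) {
    eFree <- rowSums(object@pattern[["E"]]) > 0
    if (!all(eFree))
      msgs <- c(msgs, "every variable must retain at least one free E loading")
  }
  if (!object@sexLimitation %in% c("none", "scalar", "quantitative"))
    msgs <- c(msgs, "unknown sexLimitation")
  if (length(intersect(object@scalarVariables, object@quantVariables)))
    msgs <- c(msgs, "a variable cannot be both scalar and quantitative")
  if (!all(c(object@scalarVariables, object@quantVariables) %in%
           object@variableNames))
    msgs <- c(msgs, "sex-rule variables must be model variables")
  if (nrow(object@zeroConstraints) &&
      !all(c("component", "variable", "factor") %in%
           colnames(object@zeroConstraints)))
    msgs <- c(msgs, "zeroConstraints needs component/variable/factor columns")
  if (length(msgs)) msgs else TRUE
})

#' TwinFit: a fitted biometric twin model
#'
#' Result of full-information maximum-likelihood estimation of a
#' \linkS4class{TwinModelSpec} on a \linkS4class{TwinDataset}.
#'
#' @slot spec the fitted model specification.
#' @slot estimates named numeric vector of free path coefficients (and sex
#'   scalars), signs canonicalised so each factor's first non-zero loading is
#'   non-negative.
#' @slot neg2ll minimised -2 log-likelihood.
#' @slot nFree number of free parameters.
#' @slot aic \code{neg2ll + 2 * nFree}.
#' @slot converged logical; \code{FALSE} if no optimiser start converged.
#' @slot nRestartsUsed number of starts actually run.
#' @slot vcov approximate parameter covariance (inverse observed
#'   information).
#' @slot ci95 per-parameter table with path-scale and standardised
#'   variance-contribution-scale 95\% intervals.
#' @slot groups named integer vector of per-group pair counts used.
#' @slot details list: seed, start values, per-start diagnostics, dropped
#'   all-missing pairs, fixed parameters, pruning history.
#' @exportClass TwinFit
setClass("TwinFit",
  representation(
    spec = "TwinModelSpec",
    estimates = "numeric",
    neg2ll = "numeric",
    nFree = "integer",
    aic = "numeric",
    converged = "logical",
    nRestartsUsed = "integer",
    vcov = "matrix",
    ci95 = "data.frame",
    groups = "integer",
    details = "list"
  )
)

setValidity("TwinFit", function(object) {
  if (abs(object@aic - (object@neg2ll + 2 * object@nFree)) > 1e-9 &&
      is.finite(object@neg2ll))
    return("aic must equal neg2ll + 2 * nFree")
  TRUE
})

#' GeneratingTruth: a known data-generating twin model
#'
#' Couples a \linkS4class{TwinModelSpec} with true parameter values and
#' cohort dimensions, for simulating twin pairs with known A/C/E structure.
#'
#' @slot spec the generating model.
#' @slot params named numeric vector of true path coefficients.
#' @slot nMZ,nDZ numbers of MZ and DZ pairs to simulate.
#' @slot sexFraction fraction of pairs that are male.
#' @slot missingRate per-cell missing-completely-at-random rate.
#' @slot seed integer random seed.
#' @exportClass GeneratingTruth
setClass("GeneratingTruth",
  representation(
    spec = "TwinModelSpec",
    params = "numeric",
    nMZ = "integer",
    nDZ = "integer",
    sexFraction = "numeric",
    missingRate = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratingTruth", function(object) {
  if (object@nMZ < 0 || object@nDZ < 0)
    return("pair counts must be non-negative")
  if (object@sexFraction < 0 || object@sexFraction > 1)
    return("sexFraction must be in [0, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0, 1)")
  sig <- impliedCovariance(object@spec, object@params)
  for (g in names(sig)) {
    ev <- eigen(sig[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12)
      return(sprintf("implied covariance for group %s is not positive definite", g))
  }
  TRUE
})
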