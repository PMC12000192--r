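## Model specification: free/zero loading patterns per variance component and
## construction of the model-implied twin-pair covariance matrices.
##
## All components are parameterised through factor loadings (Gram form
## L %*% t(L)), so each component's covariance contribution is positive
## semi-definite for any real parameter value; no inequality constraints are
## needed during optimisation.

.mkPattern <- function(mat, type) {
  attr(mat, "type") <- type
  mat
}

#' Univariate ACE model specification
#'
#' A single-variable ACE model with free a, c, e paths. Sex limitation
#' options: \code{"scalar"} adds one free female variance scalar (4 free
#' parameters), \code{"quantitative"} duplicates the a, c, e paths per sex
#' (6 free parameters); \code{"none"} gives the classical 3-parameter model.
#'
#' @param sexLimitation one of \code{"none"}, \code{"scalar"},
#'   \code{"quantitative"}.
#' @param variable label for the phenotype (default \code{"trait"}).
#' @param components subset of \code{c("A","C","E")}; E is mandatory. Use
#'   \code{c("A","E")} for an AE model.
#' @return a \linkS4class{TwinModelSpec}.
#' @examples
#' nFreeParams(univariateACE())              # 3
#' nFreeParams(univariateACE("scalar"))      # 4
#' nFreeParams(univariateACE("quantitative")) # 6
#' @export
univariateACE <- function(sexLimitation = c("none", "scalar", "quantitative"),
                          variable = "trait",
                          components = c("A", "C", "E")) {
  sexLimitation <- match.arg(sexLimitation)
  components <- match.arg(components, c("A", "C", "E"), several.ok = TRUE)
  pat <- lapply(components, function(cmp) {
    m <- matrix(TRUE, 1, 1, dimnames = list(variable, "S1"))
    .mkPattern(m, "specific")
  })
  names(pat) <- components
  new("TwinModelSpec",
      family = "univariate_ace", variableNames = variable,
      components = components, pattern = pat,
      sexLimitation = sexLimitation,
      scalarVariables = if (sexLimitation == "scalar") variable else character(0),
      quantVariables = if (sexLimitation == "quantitative") variable else character(0),
      zeroConstraints = .emptyConstraints())
}

#' Longitudinal Cholesky model specification
#'
#' Lower-triangular factor structure per component over repeated measures:
#' factor k loads on variables k..p, separating variance carried over from
#' earlier occasions from variance newly arising at each occasion. Each
#' included component contributes p(p+1)/2 free paths.
#'
#' @param variableNames labels of the repeated measures in temporal order.
#' @param components subset of \code{c("A","C","E")}; E is mandatory.
#' @return a \linkS4class{TwinModelSpec}.
#' @examples
#' nFreeParams(choleskySpec(paste0("iso", c(5, 7, 10, 12)), c("A", "E"))) # 20
#' @export
choleskySpec <- function(variableNames, components = c("A", "C", "E")) {
  p <- length(variableNames)
  stopifnot(p >= 1)
  components <- match.arg(components, c("A", "C", "E"), several.ok = TRUE)
  pat <- lapply(components, function(cmp) {
    m <- lower.tri(matrix(TRUE, p, p), diag = TRUE)
    dimnames(m) <- list(variableNames, paste0("F", seq_len(p)))
    .mkPattern(m, rep("common", p))
  })
  names(pat) <- components
  new("TwinModelSpec",
      family = "cholesky", variableNames = variableNames,
      components = components, pattern = pat,
      sexLimitation = "none",
      scalarVariables = character(0), quantVariables = character(0),
      zeroConstraints = .emptyConstraints())
}

#' Independent pathway model specification
#'
#' Each component acts through a first common factor loading on all p
#' variables (\code{C1}), an optional second common factor restricted to the
#' late-occasion variables (\code{C2}), and p trait-specific factors
#' (\code{S1..Sp}). With all three components and no sex rules this gives
#' 3 * (p + n_late + p) free parameters.
#'
#' @param variableNames labels of the p variables, canonical order.
#' @param age18Mask logical vector marking the variables the second common
#'   factor loads on (default: labels ending in \code{"18"}).
#' @param components subset of \code{c("A","C","E")}; E is mandatory.
#' @param scalarVariables variables given a free female variance scalar.
#' @param quantVariables variables whose loadings are estimated per sex.
#' @param zeroConstraints optional data.frame with columns
#'   \code{component}, \code{variable}, \code{factor}: paths fixed to zero.
#' @param commonFactor2 logical; include the second common factor.
#' @return a \linkS4class{TwinModelSpec}.
#' @examples
#' v <- c("iso12", "dep12", "con12", "psy12", "iso18", "dep18", "con18", "psy18")
#' nFreeParams(ipmSpec(v))  # 3 * (8 + 4 + 8) = 60
#' @export
ipmSpec <- function(variableNames,
                    age18Mask = grepl("18$", variableNames),
                    components = c("A", "C", "E"),
                    scalarVariables = character(0),
                    quantVariables = character(0),
                    zeroConstraints = NULL,
                    commonFactor2 = TRUE) {
  p <- length(variableNames)
  stopifnot(length(age18Mask) == p)
  components <- match.arg(components, c("A", "C", "E"), several.ok = TRUE)
  if (commonFactor2 && !any(age18Mask))
    stop("second common factor requested but no late-occasion variables flagged")
  pat <- lapply(components, function(cmp) {
    cols <- cbind(C1 = rep(TRUE, p))
    types <- "common"
    if (commonFactor2) {
      cols <- cbind(cols, C2 = age18Mask)
      types <- c(types, "common")
    }
    spec_cols <- diag(p) > 0
    colnames(spec_cols) <- paste0("S", seq_len(p))
    cols <- cbind(cols, spec_cols)
    types <- c(types, rep("specific", p))
    rownames(cols) <- variableNames
    .mkPattern(cols, types)
  })
  names(pat) <- components
  spec <- new("TwinModelSpec",
      family = "ipm", variableNames = variableNames,
      components = components, pattern = pat,
      sexLimitation = if (length(quantVariables)) "quantitative"
                      else if (length(scalarVariables)) "scalar" else "none",
      scalarVariables = scalarVariables, quantVariables = quantVariables,
      zeroConstraints = .emptyConstraints())
  if (!is.null(zeroConstraints) && nrow(zeroConstraints))
    spec <- constrainToZero(spec, zeroConstraints)
  spec
}

.emptyConstraints <- function() {
  data.frame(component = character(0), variable = character(0),
             factor = character(0), stringsAsFactors = FALSE)
}

#' Fix paths to zero
#'
#' Removes the listed loadings from the free set (used e.g. to derive a
#' parsimonious model by constraining small non-significant paths to zero).
#' A path that is not structurally free, and any constraint that would leave
#' a variable with zero total E variance, is an error.
#'
#' @param spec a \linkS4class{TwinModelSpec}.
#' @param constraints data.frame with columns component, variable, factor.
#' @return the constrained TwinModelSpec.
#' @export
constrainToZero <- function(spec, constraints) {
  stopifnot(is(spec, "TwinModelSpec"),
            all(c("component", "variable", "factor") %in% colnames(constraints)))
  for (k in seq_len(nrow(constraints))) {
    cmp <- as.character(constraints$component[k])
    v <- as.character(constraints$variable[k])
    f <- as.character(constraints$factor[k])
    if (!cmp %in% spec@components)
      stop("unknown component in constraint: ", cmp)
    pat <- spec@pattern[[cmp]]
    if (!v %in% rownames(pat) || !f %in% colnames(pat))
      stop(sprintf("unknown path %s.%s.%s", cmp, f, v))
    if (!pat[v, f])
      stop(sprintf("path %s.%s.%s is not free; cannot constrain it", cmp, f, v))
    ty <- attr(pat, "type")
    pat[v, f] <- FALSE
    attr(pat, "type") <- ty
    spec@pattern[[cmp]] <- pat
  }
  spec@zeroConstraints <- rbind(spec@zeroConstraints,
    data.frame(component = as.character(constraints$component),
               variable = as.character(constraints$variable),
               factor = as.character(constraints$factor),
               stringsAsFactors = FALSE))
  validObject(spec)
  spec
}

#' Factor bookkeeping for a model specification
#'
#' @param spec a TwinModelSpec.
#' @return data.frame: component, factor label, column index, factor type
#'   (\code{"common"} / \code{"specific"}).
#' @export
factorInfo <- function(spec) {
  do.call(rbind, lapply(spec@components, function(cmp) {
    pat <- spec@pattern[[cmp]]
    data.frame(component = cmp, factor = colnames(pat),
               col = seq_len(ncol(pat)), type = attr(pat, "type"),
               stringsAsFactors = FALSE)
  }))
}

#' Free-parameter index: the bijection between the parameter vector and
#' structured loadings
#'
#' Enumerates every free path implied by the specification, in a fixed
#' deterministic order (components, then factors, then variables; a
#' variable with sex-specific paths contributes a male and a female entry;
#' female variance scalars come last).
#'
#' @param spec a TwinModelSpec.
#' @return data.frame: name, type (loading/scalar), component, factor,
#'   variable, row, col, sex (both/M/F).
#' @export
paramIndex <- function(spec) {
  rows <- list()
  for (cmp in spec@components) {
    pat <- spec@pattern[[cmp]]
    for (j in seq_len(ncol(pat))) {
      for (v in seq_len(nrow(pat))) {
        if (!pat[v, j]) next
        vn <- rownames(pat)[v]
        fn <- colnames(pat)[j]
        sexes <- if (vn %in% spec@quantVariables) c("M", "F") else "both"
        for (sx in sexes) {
          nm <- paste(cmp, fn, vn, sep = ".")
          if (sx != "both") nm <- paste(nm, sx, sep = ".")
          rows[[length(rows) + 1L]] <- data.frame(
            name = nm, type = "loading", component = cmp, factor = fn,
            variable = vn, row = v, col = j, sex = sx,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (vn in spec@scalarVariables) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("scalar.", vn), type = "scalar", component = NA_character_,
      factor = NA_character_, variable = vn,
      row = match(vn, spec@variableNames), col = NA_integer_, sex = "F",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Number of free parameters implied by a specification
#' @param spec a TwinModelSpec.
#' @return integer.
#' @export
nFreeParams <- function(spec) {
  idx <- paramIndex(spec)
  if (is.null(idx)) 0L else nrow(idx)
}

#' Deterministic starting values for optimisation
#'
#' Specific/diagonal E loadings start large (most variance is usually
#' non-shared plus error on the standardised scale), other specifics
#' moderate, common loadings small, scalars at 1.
#'
#' @param spec a TwinModelSpec.
#' @return named numeric vector matching \code{paramIndex(spec)}.
#' @export
defaultStart <- function(spec) {
  idx <- paramIndex(spec)
  val <- numeric(nrow(idx))
  fi <- factorInfo(spec)
  for (k in seq_len(nrow(idx))) {
    if (idx$type[k] == "scalar") { val[k] <- 1; next }
    type <- fi$type[fi$component == idx$component[k] & fi$factor == idx$factor[k]]
    onDiag <- type == "specific" ||
      (spec@family == "cholesky" && idx$row[k] == idx$col[k])
    val[k] <- if (idx$component[k] == "E") (if (onDiag) 0.7 else 0.15)
              else if (idx$component[k] == "A") (if (onDiag) 0.45 else 0.25)
              else (if (onDiag) 0.3 else 0.15)
  }
  names(val) <- idx$name
  val
}

## Structured view of a parameter vector: loadings per component (per sex
## where applicable) and the female scalar vector.
#' Unpack a parameter vector into structured loading matrices
#'
#' @param spec a TwinModelSpec.
#' @param params named numeric vector in \code{paramIndex(spec)} order.
#' @return list with \code{loadings[[component]][[sex]]} numeric matrices and
#'   \code{scalars} (length-p female multipliers, 1 where no scalar).
#' @export
unpackParams <- function(spec, params) {
  idx <- paramIndex(spec)
  stopifnot(length(params) == nrow(idx))
  p <- length(spec@variableNames)
  sexes <- if (spec@sexLimitation == "quantitative") c("M", "F") else "both"
  loadings <- lapply(spec@components, function(cmp) {
    pat <- spec@pattern[[cmp]]
    out <- lapply(sexes, function(sx) {
      L <- matrix(0, nrow(pat), ncol(pat), dimnames = dimnames(pat))
      sel <- idx$type == "loading" & idx$component == cmp &
        (idx$sex == "both" | idx$sex == sx)
      L[cbind(idx$row[sel], idx$col[sel])] <- params[sel]
      L
    })
    names(out) <- sexes
    out
  })
  names(loadings) <- spec@components
  scalars <- rep(1, p)
  names(scalars) <- spec@variableNames
  sel <- idx$type == "scalar"
  scalars[idx$row[sel]] <- params[sel]
  list(loadings = loadings, scalars = scalars)
}

#' Pack structured loadings back into a parameter vector
#'
#' Inverse of \code{\link{unpackParams}}: \code{packParams(spec,
#' unpackParams(spec, v))} returns \code{v} exactly.
#'
#' @param spec a TwinModelSpec.
#' @param structured a list as returned by \code{unpackParams}.
#' @return named numeric vector.
#' @export
packParams <- function(spec, structured) {
  idx <- paramIndex(spec)
  val <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (idx$type[k] == "scalar") {
      val[k] <- structured$scalars[idx$row[k]]
    } else {
      sx <- if (idx$sex[k] == "both") {
        if (spec@sexLimitation == "quantitative") "M" else "both"
      } else idx$sex[k]
      ## shared loadings are stored identically under M and F when unpacked
      L <- structured$loadings[[idx$component[k]]][[sx]]
      val[k] <- L[idx$row[k], idx$col[k]]
    }
  }
  names(val) <- idx$name
  val
}

## Effective per-sex loading matrices and component covariance contributions.
## For female groups under scalar sex limitation each variable's loadings are
## multiplied by its scalar (row scaling), i.e. Comp_F = D Comp D.
.componentMatrices <- function(spec, params, sex = "both") {
  st <- unpackParams(spec, params)
  p <- length(spec@variableNames)
  d <- if (sex == "F") st$scalars else rep(1, p)
  comps <- lapply(spec@components, function(cmp) {
    sx <- if (spec@sexLimitation == "quantitative") {
      if (sex == "both") "M" else sex
    } else "both"
    L <- st$loadings[[cmp]][[sx]] * d
    list(L = L, mat = tcrossprod(L))
  })
  names(comps) <- spec@components
  comps
}

.groupNames <- function(spec) {
  if (spec@sexLimitation == "none") c("MZ", "DZ")
  else c("MZ.M", "DZ.M", "MZ.F", "DZ.F")
}

.groupZyg <- function(g) sub("\\..*$", "", g)
.groupSex <- function(g) if (grepl("\\.", g)) sub("^.*\\.", "", g) else "both"

#' Model-implied twin-pair covariance matrices
#'
#' Assembles, for every zygosity (and sex, under sex limitation) group, the
#' 2p x 2p covariance matrix of a twin pair: identical within-twin blocks
#' V = A + C + E on the diagonal, and cross-twin blocks A + C for MZ pairs
#' and 0.5 A + C for DZ pairs (MZ twins share all, DZ twins on average half,
#' of their segregating genes; E never crosses twins).
#'
#' @param spec a \linkS4class{TwinModelSpec}.
#' @param params named numeric parameter vector.
#' @return named list of symmetric 2p x 2p matrices, one per group.
#' @export
impliedCovariance <- function(spec, params) {
  p <- length(spec@variableNames)
  out <- lapply(.groupNames(spec), function(g) {
    comps <- .componentMatrices(spec, params, .groupSex(g))
    V <- Reduce(`+`, lapply(comps, `[[`, "mat"))
    alpha <- if (.groupZyg(g) == "MZ") 1 else 0.5
    B <- matrix(0, p, p)
    if ("A" %in% names(comps)) B <- B + alpha * comps[["A"]]$mat
    if ("C" %in% names(comps)) B <- B + comps[["C"]]$mat
    sigma <- rbind(cbind(V, B), cbind(t(B), V))
    nms <- c(paste0(spec@variableNames, "_t1"), paste0(spec@variableNames, "_t2"))
    dimnames(sigma) <- list(nms, nms)
    ## enforce exact symmetry against floating-point drift
    (sigma + t(sigma)) / 2
  })
  names(out) <- .groupNames(spec)
  out
}

#' Model-implied within-person cross-trait correlation
#'
#' Path-traced correlation between two variables: the sum over common
#' factors shared by both of the product of their loadings, divided by the
#' product of implied standard deviations. Specific factors never contribute
#' off-diagonal covariance.
#'
#' @param spec a TwinModelSpec.
#' @param params named numeric parameter vector.
#' @param i,j variable labels or indices (distinct).
#' @param sex group to evaluate in (\code{"both"}, \code{"M"}, \code{"F"});
#'   proportions are sex-invariant under scalar limitation.
#' @return the implied correlation (numeric scalar).
#' @export
impliedCorrelation <- function(spec, params, i, j, sex = "both") {
  vi <- if (is.character(i)) match(i, spec@variableNames) else i
  vj <- if (is.character(j)) match(j, spec@variableNames) else j
  stopifnot(!is.na(vi), !is.na(vj), vi != vj)
  if (spec@sexLimitation != "none" && sex == "both") sex <- "M"
  comps <- .componentMatrices(spec, params, sex)
  V <- Reduce(`+`, lapply(comps, `[[`, "mat"))
  V[vi, vj] / sqrt(V[vi, vi] * V[vj, vj])
}

## ---- serialisation -------------------------------------------------------

#' Convert a model specification to a plain list (for YAML/JSON)
#' @param spec a TwinModelSpec.
#' @return a list with documented keys: family, variables, components,
#'   sex_limitation, scalar_variables, quant_variables, zero_constraints,
#'   age18_mask / common_factor2 (IPM only).
#' @export
specToList <- function(spec) {
  out <- list(
    family = spec@family,
    variables = spec@variableNames,
    components = spec@components,
    sex_limitation = spec@sexLimitation,
    scalar_variables = spec@scalarVariables,
    quant_variables = spec@quantVariables,
    zero_constraints = if (nrow(spec@zeroConstraints))
      lapply(seq_len(nrow(spec@zeroConstraints)), function(k)
        as.list(spec@zeroConstraints[k, , drop = FALSE]))
      else list()
  )
  if (spec@family == "ipm") {
    pat <- spec@pattern[[1]]
    out$common_factor2 <- "C2" %in% colnames(pat)
    if (out$common_factor2) {
      ## reconstruct structural mask: C2 column before zero constraints
      mask <- pat[, "C2"]
      zc <- spec@zeroConstraints
      if (nrow(zc)) {
        hit <- zc$factor == "C2"
        mask[zc$variable[hit]] <- TRUE
      }
      out$age18_mask <- unname(mask)
    }
  }
  out
}

#' Rebuild a model specification from its list form
#' @param x a list as produced by \code{\link{specToList}}.
#' @return a TwinModelSpec.
#' @export
specFromList <- function(x) {
  zc <- if (length(x$zero_constraints))
    do.call(rbind, lapply(x$zero_constraints, as.data.frame)) else NULL
  spec <- switch(x$family,
    univariate_ace = univariateACE(x$sex_limitation, x$variables,
                                   unlist(x$components)),
    cholesky = choleskySpec(unlist(x$variables), unlist(x$components)),
    ipm = ipmSpec(unlist(x$variables),
                  age18Mask = if (!is.null(x$age18_mask)) unlist(x$age18_mask)
                              else grepl("18$", unlist(x$variables)),
                  components = unlist(x$components),
                  scalarVariables = as.character(unlist(x$scalar_variables)),
                  quantVariables = as.character(unlist(x$quant_variables)),
                  commonFactor2 = isTRUE(x$common_factor2)),
    stop("unknown family: ", x$family))
  if (!is.null(zc) && nrow(zc) && x$family != "univariate_ace")
    spec <- constrainToZero(spec, zc)
  spec
}

#' Write / read a model specification as YAML
#' @param spec a TwinModelSpec.
#' @param path file path.
#' @return \code{readSpecYAML} returns a TwinModelSpec;
#'   \code{writeSpecYAML} returns \code{path} invisibly.
#' @export
writeSpecYAML <- function(spec, path) {
  yaml::write_yaml(specToList(spec), path)
  invisible(path)
}

#' @rdname writeSpecYAML
#' @export
readSpecYAML <- function(path) specFromList(yaml::read_yaml(path))
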