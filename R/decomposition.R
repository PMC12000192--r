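## Turning fitted models into reported quantities: standardised variance
## contributions, Cholesky heritability accounting, common/specific
## percentage tables, and A/C/E shares of phenotypic correlations by path
## tracing.

#' Standardised variance decomposition of a fitted model
#'
#' Computes, per variable, the standardised totals h2/c2/e2 and, per factor,
#' the standardised variance contribution (squared loading over total
#' implied variance). Under scalar sex limitation the female scalars cancel
#' between numerator and denominator, so proportions are sex-invariant and
#' the reference (male) parameterisation is reported; under quantitative
#' limitation contributions are reported per sex.
#'
#' @param fit a converged \linkS4class{TwinFit}, or a
#'   \linkS4class{GeneratingTruth} (decomposition of the exact generating
#'   parameters).
#' @return object of class \code{"twin_std"}: list with \code{table}
#'   (variable, sex, component, factor, type, contrib), \code{totals}
#'   (variable, sex, h2, c2, e2), the effective \code{loadings} and implied
#'   variable variances used, and the originating \code{spec}.
#' @export
standardiseFit <- function(fit) {
  if (is(fit, "GeneratingTruth")) {
    spec <- fit@spec; params <- fit@params
  } else {
    stopifnot(is(fit, "TwinFit"))
    if (!fit@converged) stop("decomposition requires a converged fit")
    spec <- fit@spec; params <- fit@estimates
  }
  K <- .modelKernel(spec)
  fi <- factorInfo(spec)
  sexes <- if (spec@sexLimitation == "quantitative") c("M", "F") else "both"
  rows <- list(); totals <- list(); loadAll <- list(); varAll <- list()
  for (sx in sexes) {
    Ls <- .kernelLoadings(K, params, if (sx == "both") "both" else sx)
    if (spec@sexLimitation == "scalar" && sx == "both") {
      ## reference parameterisation: scalars not applied (they cancel)
      Ls <- .kernelLoadings(K, params, "M")
    }
    Vd <- diag(Reduce(`+`, lapply(Ls, tcrossprod)))
    if (any(Vd <= 0))
      stop("zero total implied variance for variable(s): ",
           paste(spec@variableNames[Vd <= 0], collapse = ", "))
    loadAll[[sx]] <- Ls; varAll[[sx]] <- Vd
    for (cmp in spec@components) {
      L <- Ls[[cmp]]
      fic <- fi[fi$component == cmp, , drop = FALSE]
      for (j in seq_len(ncol(L))) {
        contribs <- L[, j]^2 / Vd
        keep <- which(contribs > 0 | spec@pattern[[cmp]][, j])
        for (v in keep) {
          rows[[length(rows) + 1L]] <- data.frame(
            variable = spec@variableNames[v], sex = sx, component = cmp,
            factor = fic$factor[j], type = fic$type[j],
            contrib = contribs[v], stringsAsFactors = FALSE)
        }
      }
    }
    comp_tot <- vapply(c("A", "C", "E"), function(cmp) {
      if (!cmp %in% spec@components) return(rep(0, K$p))
      rowSums(Ls[[cmp]]^2) / Vd
    }, numeric(K$p))
    comp_tot <- matrix(comp_tot, nrow = K$p,
                       dimnames = list(NULL, c("A", "C", "E")))
    totals[[length(totals) + 1L]] <- data.frame(
      variable = spec@variableNames, sex = sx,
      h2 = comp_tot[, "A"], c2 = comp_tot[, "C"], e2 = comp_tot[, "E"],
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows),
                 totals = do.call(rbind, totals),
                 loadings = loadAll, variances = varAll,
                 spec = spec),
            class = "twin_std")
}

#' @export
print.twin_std <- function(x, ...) {
  cat(sprintf("Standardised decomposition (%s, %d variable(s))\n",
              x$spec@family, length(x$spec@variableNames)))
  print(x$totals, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cholesky heritability accounting for a target occasion
#'
#' For the k-th variable of a longitudinal Cholesky model: total h2 (the sum
#' of standardised genetic contributions of factors 1..k), the proportion of
#' that h2 already in place before occasion k, the cumulative proportion in
#' place by each earlier occasion, and the per-occasion new-variance series
#' for every component.
#'
#' @param x a \code{"twin_std"} from a Cholesky fit, a
#'   \linkS4class{TwinFit}, or a plain numeric vector of per-factor genetic
#'   contributions at the target (worked-example mode).
#' @param target variable label or index of the target occasion (ignored for
#'   a numeric \code{x}).
#' @param component which component to account (default \code{"A"}).
#' @return list: \code{target}, \code{contributions} (per factor),
#'   \code{total} (their sum, e.g. h2 for A), \code{proportionInPlace}
#'   (cumulative proportion by each occasion), \code{proportionBefore}
#'   (in place before the target), and \code{newVariance} (per-occasion
#'   occasion-specific contributions per component; \code{NULL} in
#'   worked-example mode).
#' @examples
#' a <- choleskyAccounting(c(0.134, 0.064, 0.126, 0.122))
#' a$total              # 0.446
#' a$proportionBefore   # 0.7264...
#' @export
choleskyAccounting <- function(x, target = NULL, component = "A") {
  newVar <- NULL
  if (is.numeric(x)) {
    contribs <- x
    if (is.null(names(contribs))) names(contribs) <- paste0("F", seq_along(contribs))
    targetLab <- if (is.null(target)) "target" else as.character(target)
  } else {
    if (is(x, "TwinFit")) x <- standardiseFit(x)
    stopifnot(inherits(x, "twin_std"))
    if (x$spec@family != "cholesky")
      stop("Cholesky accounting applies to Cholesky fits")
    vars <- x$spec@variableNames
    k <- if (is.character(target)) match(target, vars) else target
    if (is.na(k) || is.null(k)) stop("unknown target variable")
    targetLab <- vars[k]
    tab <- x$table[x$table$sex == x$table$sex[1], , drop = FALSE]
    comp <- tab[tab$component == component & tab$variable == vars[k], , drop = FALSE]
    comp <- comp[order(match(comp$factor, paste0("F", seq_along(vars)))), ]
    contribs <- stats::setNames(comp$contrib, comp$factor)
    newVar <- lapply(stats::setNames(nm = x$spec@components), function(cmp) {
      ## occasion-specific (diagonal) contributions: factor j at variable j
      diagc <- vapply(seq_along(vars), function(j) {
        hit <- tab$component == cmp & tab$factor == paste0("F", j) &
          tab$variable == vars[j]
        if (any(hit)) tab$contrib[hit][1] else 0
      }, 0)
      stats::setNames(diagc, vars)
    })
  }
  tot <- sum(contribs)
  cum <- cumsum(contribs) / tot
  nb <- length(contribs)
  list(target = targetLab, contributions = contribs, total = tot,
       proportionInPlace = cum,
       proportionBefore = if (nb > 1) cum[nb - 1] else 1,
       newVariance = newVar)
}

#' Common/specific percentage table for an independent pathway fit
#'
#' Lays out, per variable, the standardised totals h2/c2/e2 (as percentages)
#' and, within each component, the percentage split of that total across the
#' first common factor (C1), the second common factor (C2) and the specific
#' factor (S). Zero-constrained paths appear as \code{NA}; a component with
#' zero total yields undefined (NA) percentages rather than NaN.
#'
#' @param std a \code{"twin_std"} from an IPM fit (or a TwinFit).
#' @param sex which sex's table under quantitative limitation.
#' @return data.frame, variables as columns; rows h2, A_C1., A_C2.,
#'   A_S., c2, C_C1., ... (percent).
#' @export
commonSpecificTable <- function(std, sex = NULL) {
  if (is(std, "TwinFit")) std <- standardiseFit(std)
  stopifnot(inherits(std, "twin_std"))
  if (std$spec@family != "ipm")
    stop("common/specific tables apply to independent pathway fits")
  sexes <- unique(std$table$sex)
  sx <- if (is.null(sex)) sexes[1] else sex
  tab <- std$table[std$table$sex == sx, , drop = FALSE]
  tot <- std$totals[std$totals$sex == sx, , drop = FALSE]
  vars <- std$spec@variableNames
  hasC2 <- "C2" %in% tab$factor
  fgroups <- c("C1", if (hasC2) "C2", "S")
  rowsOut <- list()
  for (cmp in intersect(c("A", "C", "E"), std$spec@components)) {
    totName <- c(A = "h2", C = "c2", E = "e2")[[cmp]]
    compTot <- stats::setNames(tot[[totName]], tot$variable)[vars]
    rowsOut[[totName]] <- 100 * compTot
    for (fg in fgroups) {
      vals <- vapply(vars, function(v) {
        hit <- tab$component == cmp & tab$variable == v &
          (if (fg == "S") tab$type == "specific" else tab$factor == fg)
        if (!any(hit)) return(NA_real_)
        if (compTot[v] <= 1e-12) return(NA_real_)
        100 * sum(tab$contrib[hit]) / compTot[v]
      }, 0)
      rowsOut[[paste0(cmp, "_", fg, ".pct")]] <- vals
    }
  }
  out <- as.data.frame(do.call(rbind, rowsOut))
  colnames(out) <- vars
  out
}

#' A/C/E shares of a model-implied cross-trait correlation
#'
#' Path tracing on an independent pathway fit: each component's share of the
#' correlation between variables i and j is the sum over that component's
#' common factors shared by both variables of the product of their loadings,
#' divided by the total implied cross-trait covariance, as a percentage.
#' Symmetric in (i, j).
#'
#' @param std a \code{"twin_std"} (or TwinFit) from an IPM fit.
#' @param i,j variable labels or indices, distinct.
#' @param sex sex group under quantitative limitation.
#' @return list of class \code{"twin_corr_shares"}: \code{i}, \code{j},
#'   \code{r_implied}, \code{share_A}, \code{share_C}, \code{share_E}
#'   (percentages summing to 100), \code{defined} (FALSE when the implied
#'   correlation is 0).
#' @export
correlationShares <- function(std, i, j, sex = NULL) {
  if (is(std, "TwinFit")) std <- standardiseFit(std)
  stopifnot(inherits(std, "twin_std"))
  sx <- if (is.null(sex)) names(std$loadings)[1] else sex
  Ls <- std$loadings[[sx]]
  Vd <- std$variances[[sx]]
  spec <- std$spec
  vi <- if (is.character(i)) match(i, spec@variableNames) else i
  vj <- if (is.character(j)) match(j, spec@variableNames) else j
  stopifnot(!is.na(vi), !is.na(vj), vi != vj)
  fi <- factorInfo(spec)
  cross <- c(A = 0, C = 0, E = 0)
  for (cmp in spec@components) {
    L <- Ls[[cmp]]
    commonCols <- fi$col[fi$component == cmp & fi$type == "common"]
    if (length(commonCols))
      cross[cmp] <- sum(L[vi, commonCols] * L[vj, commonCols])
  }
  total <- sum(cross)
  r <- total / sqrt(Vd[vi] * Vd[vj])
  defined <- abs(total) > 1e-12
  shares <- if (defined) 100 * cross / total else rep(NA_real_, 3)
  structure(list(i = spec@variableNames[vi], j = spec@variableNames[vj],
                 r_implied = r, share_A = unname(shares[1]),
                 share_C = unname(shares[2]), share_E = unname(shares[3]),
                 defined = defined),
            class = "twin_corr_shares")
}

#' @export
print.twin_corr_shares <- function(x, ...) {
  cat(sprintf("%s ~ %s: implied r = %.4f\n", x$i, x$j, x$r_implied))
  if (x$defined)
    cat(sprintf("  A = %.2f%%, C = %.2f%%, E = %.2f%%\n",
                x$share_A, x$share_C, x$share_E))
  else cat("  shares undefined (implied correlation is zero)\n")
  invisible(x)
}

#' Worked-example path-traced share of a correlation
#'
#' The single-shared-factor arithmetic: with standardised contributions
#' \code{ci} and \code{cj} of one common factor to two unit-variance traits
#' and phenotypic correlation \code{r}, the factor accounts for
#' \code{sqrt(ci * cj) / r} of the correlation.
#'
#' @param ci,cj standardised variance contributions of the shared factor.
#' @param r the phenotypic correlation to apportion.
#' @return the share as a percentage.
#' @examples
#' pathTraceShare(0.171, 0.271, 0.279)  # 77.16
#' @export
pathTraceShare <- function(ci, cj, r) 100 * sqrt(ci * cj) / r

#' Falconer moment estimates from cross-twin correlations
#'
#' The quick moment-based decomposition used as an independent cross-check
#' of the likelihood machinery: h2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ,
#' e2 = 1 - rMZ, from double-entry intraclass correlations.
#'
#' @param data a normalised \linkS4class{TwinDataset}.
#' @param variable variable label.
#' @return list: rMZ, rDZ, h2, c2, e2.
#' @export
falconerEstimates <- function(data, variable) {
  d <- twinDescriptives(data)
  d <- d[d$variable == variable, , drop = FALSE]
  if (!nrow(d)) stop("unknown variable: ", variable)
  for (z in .ZYG_LEVELS)
    if (d$n_pairs[d$zygosity == z] < 3)
      stop("fewer than 3 complete ", z, " pairs; Falconer estimate undefined")
  rMZ <- d$icc[d$zygosity == "MZ"]
  rDZ <- d$icc[d$zygosity == "DZ"]
  list(rMZ = rMZ, rDZ = rDZ, h2 = 2 * (rMZ - rDZ), c2 = 2 * rDZ - rMZ,
       e2 = 1 - rMZ)
}

#' Write a decomposition report as CSV (and JSON)
#'
#' Emits the common/specific percentage table in the variables-as-columns
#' layout, plus a JSON copy including totals at full precision.
#'
#' @param std a \code{"twin_std"} from an IPM fit.
#' @param path output CSV path (a \code{.json} sibling is written too).
#' @return \code{path}, invisibly.
#' @export
writeDecompositionCSV <- function(std, path) {
  tabout <- commonSpecificTable(std)
  utils::write.csv(round(tabout, 2), path, row.names = TRUE, na = "-")
  jsonlite::write_json(
    list(totals = std$totals, table = std$table),
    paste0(sub("\\.csv$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
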