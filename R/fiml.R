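## Full-information (raw-data) maximum likelihood for twin-pair models.
##
## The objective is the sum over pairs of the multivariate-normal -2
## log-density of each pair's observed sub-vector, with the mean vector
## fixed at zero (data are residualised and standardised upstream). Pairs
## are grouped by zygosity (and sex under sex limitation) and, within
## group, by missingness pattern; per-pattern cross-product matrices are
## precomputed once, so each objective evaluation costs one Cholesky per
## pattern rather than one per pair.

.BIG <- 1e10  # finite sentinel for non-PD implied covariances during search

## Precomputed fill instructions: parameter vector -> loading matrices.
.modelKernel <- function(spec) {
  idx <- paramIndex(spec)
  p <- length(spec@variableNames)
  sexes <- if (spec@sexLimitation == "quantitative") c("M", "F") else "both"
  fill <- list()
  for (cmp in spec@components) {
    pat <- spec@pattern[[cmp]]
    fill[[cmp]] <- list()
    for (sx in sexes) {
      sel <- which(idx$type == "loading" & idx$component == cmp &
                     (idx$sex == "both" | idx$sex == sx))
      fill[[cmp]][[sx]] <- list(rows = idx$row[sel], cols = idx$col[sel],
                                pos = sel, dim = dim(pat))
    }
  }
  scalarPos <- which(idx$type == "scalar")
  list(spec = spec, idx = idx, p = p, sexes = sexes, fill = fill,
       scalarPos = scalarPos, scalarRow = idx$row[scalarPos],
       groups = .groupNames(spec))
}

.kernelLoadings <- function(K, params, sx) {
  sxl <- if (identical(K$sexes, "both")) "both" else if (sx %in% c("both", "M")) "M" else "F"
  d <- rep(1, K$p)
  if (length(K$scalarPos) && sx == "F") d[K$scalarRow] <- params[K$scalarPos]
  out <- lapply(names(K$fill), function(cmp) {
    f <- K$fill[[cmp]][[sxl]]
    L <- matrix(0, f$dim[1], f$dim[2])
    L[cbind(f$rows, f$cols)] <- params[f$pos]
    L * d
  })
  names(out) <- names(K$fill)
  out
}

.kernelSigma <- function(K, params) {
  sexNeeded <- unique(vapply(K$groups, .groupSex, ""))
  mats <- lapply(sexNeeded, function(sx) {
    Ls <- .kernelLoadings(K, params, sx)
    Ms <- lapply(Ls, tcrossprod)
    list(V = Reduce(`+`, Ms), A = Ms[["A"]], C = Ms[["C"]])
  })
  names(mats) <- sexNeeded
  out <- lapply(K$groups, function(g) {
    m <- mats[[.groupSex(g)]]
    alpha <- if (.groupZyg(g) == "MZ") 1 else 0.5
    B <- matrix(0, K$p, K$p)
    if (!is.null(m$A)) B <- B + alpha * m$A
    if (!is.null(m$C)) B <- B + m$C
    rbind(cbind(m$V, B), cbind(B, m$V))
  })
  names(out) <- K$groups
  out
}

## Sufficient statistics of the data for a given spec's grouping: per group,
## per missingness pattern, the observed-column index, pair count and
## cross-product matrix.
.fimlStats <- function(data, spec, checkGroups = TRUE) {
  if (!"normalised" %in% data@preprocessing)
    stop("model fitting expects normalised data (run residualiseSex and ",
         "rankNormalise, or simulate on the standardised scale)")
  vidx <- match(spec@variableNames, data@variableNames)
  if (anyNA(vidx))
    stop("variables missing from data: ",
         paste(spec@variableNames[is.na(vidx)], collapse = ", "))
  p <- length(vidx)
  X <- cbind(matrix(data@phenotypes[, 1, vidx], ncol = p),
             matrix(data@phenotypes[, 2, vidx], ncol = p))
  if (checkGroups) {  # fitting precondition; plain evaluation skips it
    for (k in seq_len(p)) {
      for (z in .ZYG_LEVELS) {
        sel <- data@zygosity == z
        if (!any(is.finite(c(X[sel, k], X[sel, p + k]))))
          stop("variable '", spec@variableNames[k],
               "' has no observed values in the ", z, " group")
      }
    }
  }
  grp <- if (spec@sexLimitation == "none") data@zygosity
         else paste(data@zygosity, data@pairSex, sep = ".")
  allMissing <- rowSums(!is.na(X)) == 0
  nDropped <- sum(allMissing)
  X <- X[!allMissing, , drop = FALSE]
  grp <- grp[!allMissing]
  groups <- list()
  for (g in intersect(.groupNames(spec), unique(grp))) {
    Xg <- X[grp == g, , drop = FALSE]
    obs <- !is.na(Xg)
    key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
    pats <- lapply(split(seq_len(nrow(Xg)), key), function(rows) {
      idx <- which(obs[rows[1], ])
      Xo <- Xg[rows, idx, drop = FALSE]
      list(idx = idx, d = length(idx), n = length(rows), C = crossprod(Xo))
    })
    groups[[g]] <- unname(pats)
  }
  list(groups = groups, nDropped = nDropped,
       sizes = vapply(groups, function(pats)
         sum(vapply(pats, `[[`, 0L, "n")), 0L))
}

.neg2llFromStats <- function(K, params, stats, big = .BIG) {
  sig <- .kernelSigma(K, params)
  total <- 0
  for (g in names(stats$groups)) {
    S <- sig[[g]]
    for (pt in stats$groups[[g]]) {
      Ssub <- S[pt$idx, pt$idx, drop = FALSE]
      R <- tryCatch(chol(Ssub), error = function(e) NULL)
      if (is.null(R)) return(big)
      total <- total + pt$n * (pt$d * log(2 * pi) + 2 * sum(log(diag(R)))) +
        sum(chol2inv(R) * pt$C)
    }
  }
  total
}

## Moment-informed deterministic start: per-variable Falconer decomposition
## of the double-entry cross-twin correlations, spread evenly over each
## component's free loadings in that variable's row. Falls back to
## defaultStart() when moments are unavailable (e.g. too much missingness).
.momentStart <- function(spec, data) {
  vidx <- match(spec@variableNames, data@variableNames)
  p <- length(vidx)
  tots <- matrix(NA_real_, p, 3, dimnames = list(NULL, c("A", "C", "E")))
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (k in seq_len(p)) {
    icc <- sapply(c("MZ", "DZ"), function(z) {
      sel <- data@zygosity == z
      t1 <- data@phenotypes[sel, 1, vidx[k]]
      t2 <- data@phenotypes[sel, 2, vidx[k]]
      comp <- !is.na(t1) & !is.na(t2)
      if (sum(comp) < 10) return(NA_real_)
      stats::cor(c(t1[comp], t2[comp]), c(t2[comp], t1[comp]))
    })
    if (anyNA(icc)) stop("insufficient complete pairs for moment start")
    tot <- clip(c(A = 2 * (icc[1] - icc[2]), C = 2 * icc[2] - icc[1],
                  E = 1 - icc[1]), c(0.02, 0.02, 0.1), 0.95)
    tots[k, ] <- tot / sum(tot)
  }
  idx <- paramIndex(spec)
  val <- numeric(nrow(idx))
  for (cmp in spec@components) {
    pat <- spec@pattern[[cmp]]
    nfree <- pmax(rowSums(pat), 1L)
    sel <- idx$type == "loading" & idx$component == cmp
    val[sel] <- sqrt(tots[idx$row[sel], cmp] / nfree[idx$row[sel]])
  }
  val[idx$type == "scalar"] <- 1
  stats::setNames(val, idx$name)
}

#' Raw-data -2 log-likelihood of a twin model
#'
#' Full-information evaluation: each pair contributes the multivariate-normal
#' -2 log-density of its observed sub-vector under its group's implied
#' covariance, with the mean fixed at zero. A non-positive-definite implied
#' covariance for some observed pattern yields \code{Inf}, not an error.
#'
#' @param spec a \linkS4class{TwinModelSpec}.
#' @param params named numeric parameter vector (see
#'   \code{\link{paramIndex}}).
#' @param data a normalised \linkS4class{TwinDataset}.
#' @return the -2 log-likelihood (numeric scalar).
#' @export
neg2LogLik <- function(spec, params, data) {
  K <- .modelKernel(spec)
  stopifnot(length(params) == nrow(K$idx))
  .neg2llFromStats(K, params, .fimlStats(data, spec, checkGroups = FALSE),
                   big = Inf)
}

## Flip factor columns so the first non-zero loading is non-negative;
## specifics and scalars reported as magnitudes.
.canonicaliseSigns <- function(spec, idx, params) {
  key <- paste(idx$component, idx$col, idx$sex, sep = "\r")
  for (k in unique(key[idx$type == "loading"])) {
    sel <- which(key == k & idx$type == "loading")
    sel <- sel[order(idx$row[sel])]
    lead <- sel[abs(params[sel]) > 1e-8][1]
    if (!is.na(lead) && params[lead] < 0) params[sel] <- -params[sel]
  }
  params[idx$type == "scalar"] <- abs(params[idx$type == "scalar"])
  params
}

.pinv <- function(H, tol = 1e-10) {
  s <- svd((H + t(H)) / 2)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, nrow(H), ncol(H)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Standardised variance contribution of each free parameter (loadings:
## squared effective loading over total implied variance of its variable,
## in the parameter's own sex group; scalars: the scalar itself).
.contribAll <- function(K, params) {
  sexNeeded <- if (identical(K$sexes, "both")) "both" else c("M", "F")
  V <- lapply(sexNeeded, function(sx) {
    Ls <- .kernelLoadings(K, params, sx)
    diag(Reduce(`+`, lapply(Ls, tcrossprod)))
  })
  names(V) <- sexNeeded
  idx <- K$idx
  out <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (idx$type[k] == "scalar") { out[k] <- params[k]; next }
    sx <- if (identical(K$sexes, "both")) "both"
          else if (idx$sex[k] == "F") "F" else "M"
    out[k] <- params[k]^2 / V[[sx]][idx$row[k]]
  }
  names(out) <- idx$name
  out
}

.ciTable <- function(K, params, vcovFull, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(vcovFull), 0))
  contrib <- .contribAll(K, params)
  np <- length(params)
  h <- pmax(1e-5, 1e-4 * abs(params))
  J <- matrix(0, np, np)
  for (l in seq_len(np)) {
    up <- params; up[l] <- up[l] + h[l]
    dn <- params; dn[l] <- dn[l] - h[l]
    J[, l] <- (.contribAll(K, up) - .contribAll(K, dn)) / (2 * h[l])
  }
  cse <- sqrt(pmax(rowSums((J %*% vcovFull) * J), 0))
  data.frame(name = K$idx$name, type = K$idx$type,
             component = K$idx$component, factor = K$idx$factor,
             variable = K$idx$variable, sex = K$idx$sex,
             estimate = unname(params), se = se,
             lower = unname(params - z * se), upper = unname(params + z * se),
             contrib = unname(contrib), contribSE = cse,
             contribLower = unname(contrib - z * cse),
             contribUpper = unname(contrib + z * cse),
             stringsAsFactors = FALSE)
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimises the raw-data -2 log-likelihood with a quasi-Newton optimiser
#' (\code{\link[stats]{nlminb}}, finite-difference gradients) from a
#' deterministic moment-informed start (the per-variable Falconer
#' decomposition spread over each component's free paths) plus seeded
#' perturbed restarts, returning the best
#' converged solution. Loadings are unconstrained reals (component
#' contributions are positive semi-definite by construction); signs are
#' canonicalised afterwards so each factor's first non-zero loading is
#' non-negative. Parameter covariance is the inverse observed information;
#' 95\% intervals are reported on both the path and the standardised
#' variance-contribution scale (delta method).
#'
#' @param spec a \linkS4class{TwinModelSpec}.
#' @param data a normalised \linkS4class{TwinDataset}.
#' @param nRestarts total number of optimiser starts (first is
#'   deterministic).
#' @param seed integer seed for the perturbed restarts.
#' @param relTol,xTol objective and parameter convergence tolerances.
#' @param maxit iteration cap per start.
#' @param fixedParams optional named numeric vector of parameters held fixed
#'   at the given values (excluded from optimisation).
#' @param start optional named start vector overriding
#'   \code{\link{defaultStart}}.
#' @param computeVcov logical; compute the observed-information covariance
#'   and CI table (disable inside tight simulation loops).
#' @return a \linkS4class{TwinFit}.
#' @export
fitTwinModel <- function(spec, data, nRestarts = 5, seed = 1L,
                         relTol = 1e-8, xTol = 1e-6, maxit = 2000,
                         fixedParams = NULL, start = NULL,
                         computeVcov = TRUE) {
  K <- .modelKernel(spec)
  stats_ <- .fimlStats(data, spec)
  np <- nrow(K$idx)
  full0 <- if (is.null(start)) {
    tryCatch(.momentStart(spec, data), error = function(e) defaultStart(spec))
  } else start
  stopifnot(length(full0) == np)
  freeMask <- rep(TRUE, np)
  if (!is.null(fixedParams)) {
    pos <- match(names(fixedParams), K$idx$name)
    if (anyNA(pos)) stop("unknown fixed parameter name(s)")
    freeMask[pos] <- FALSE
    full0[pos] <- fixedParams
  }
  obj <- function(theta) {
    full <- full0
    full[freeMask] <- theta
    .neg2llFromStats(K, full, stats_)
  }
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  runs <- vector("list", nRestarts)
  for (r in seq_len(nRestarts)) {
    th0 <- full0[freeMask]
    if (r > 1) {
      set.seed(seed + r - 1L)
      th0 <- th0 + stats::rnorm(length(th0), 0, 0.15)
    }
    ans <- tryCatch(
      stats::nlminb(th0, obj,
                    control = list(rel.tol = relTol, x.tol = xTol,
                                   iter.max = maxit, eval.max = 4 * maxit)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = th0))
    runs[[r]] <- ans
  }
  conv <- vapply(runs, function(a)
    isTRUE(a$convergence == 0) && is.finite(a$objective) &&
      a$objective < .BIG / 2, TRUE)
  objs <- vapply(runs, function(a) as.numeric(a$objective)[1], 0)
  best <- if (any(conv)) which(conv)[which.min(objs[conv])] else which.min(objs)
  estFree <- runs[[best]]$par
  ## polish: re-run from the optimum until the objective stops moving, so
  ## nested fits are comparable at likelihood-ratio precision; between
  ## rounds, snap parameters to zero wherever that strictly improves the
  ## objective (the likelihood is quartic-flat in a loading near zero, where
  ## finite-difference gradients lose the descent direction)
  bestObj <- objs[best]
  repolish <- function(par, val) {
    ans <- tryCatch(
      stats::nlminb(par, obj,
                    control = list(rel.tol = 1e-12, x.tol = 1e-10,
                                   iter.max = maxit, eval.max = 4 * maxit)),
      error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$objective) || ans$objective > val)
      list(par = par, val = val) else list(par = ans$par, val = ans$objective)
  }
  p1 <- repolish(estFree, bestObj)
  estFree <- p1$par; bestObj <- p1$val
  ## sharpening: BFGS with central-difference gradients (nlminb's internal
  ## forward differences can leave the optimum located only to ~1e-4, not
  ## comparable at likelihood-ratio precision). Between rounds, trial-snap
  ## small coordinates to exactly zero and re-polish before deciding: the
  ## likelihood is quartic-flat in a loading near zero, and on a curved
  ## ridge zeroing one coordinate only pays off after the others adjust.
  cgrad <- function(par) {
    h <- 1e-5 * (1 + abs(par))
    vapply(seq_along(par), function(l) {
      up <- par; up[l] <- up[l] + h[l]
      dn <- par; dn[l] <- dn[l] - h[l]
      (obj(up) - obj(dn)) / (2 * h[l])
    }, 0)
  }
  bfgsPolish <- function(par, val) {
    ans <- tryCatch(
      stats::optim(par, obj, gr = cgrad, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 500)),
      error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$value) || ans$value > val)
      list(par = par, val = val) else list(par = ans$par, val = ans$value)
  }
  for (round in 1:3) {
    pb <- bfgsPolish(estFree, bestObj)
    moved <- bestObj - pb$val
    estFree <- pb$par; bestObj <- pb$val
    snapped <- FALSE
    for (l in order(abs(estFree))) {
      al <- abs(estFree[l])
      if (al == 0 || al > 0.1) next
      cand <- estFree; cand[l] <- 0
      pc <- bfgsPolish(cand, obj(cand))
      if (pc$val < bestObj - 1e-12) {
        estFree <- pc$par; bestObj <- pc$val; snapped <- TRUE
      }
    }
    if (!snapped && moved < 1e-9) break
  }
  objs[best] <- bestObj
  full <- full0
  full[freeMask] <- estFree
  full <- .canonicaliseSigns(spec, K$idx, full)
  names(full) <- K$idx$name
  nFree <- sum(freeMask)
  neg2ll <- objs[best]
  vcovFull <- matrix(0, np, np, dimnames = list(K$idx$name, K$idx$name))
  ci <- data.frame()
  if (computeVcov && any(conv)) {
    H <- tryCatch(stats::optimHess(full[freeMask], obj), error = function(e) NULL)
    if (!is.null(H)) {
      vcovFree <- 2 * .pinv(H)   # obj is -2LL, so information is H/2
      vcovFull[freeMask, freeMask] <- vcovFree
    }
    ci <- .ciTable(K, full, vcovFull)
  }
  new("TwinFit", spec = spec, estimates = full, neg2ll = neg2ll,
      nFree = as.integer(nFree), aic = neg2ll + 2 * nFree,
      converged = any(conv), nRestartsUsed = as.integer(nRestarts),
      vcov = vcovFull, ci95 = ci,
      groups = stats_$sizes,
      details = list(seed = seed, startObjectives = objs,
                     startConverged = conv, bestStart = best,
                     nPairsDroppedAllMissing = stats_$nDropped,
                     fixedParams = fixedParams,
                     options = list(nRestarts = nRestarts, relTol = relTol,
                                    xTol = xTol, maxit = maxit)))
}

.isNested <- function(rspec, fspec) {
  if (!identical(rspec@variableNames, fspec@variableNames)) return(FALSE)
  rn <- paramIndex(rspec)$name
  fn <- paramIndex(fspec)$name
  if (all(rn %in% fn)) return(TRUE)
  ## sex-limitation hierarchy: none < scalar < quantitative on the same
  ## structural pattern (a scalar model is a proportional-loadings
  ## restriction of the quantitative one)
  rank <- function(s) match(s@sexLimitation, c("none", "scalar", "quantitative"))
  samePattern <- identical(lapply(rspec@pattern, function(m) m[, , drop = FALSE]),
                           lapply(fspec@pattern, function(m) m[, , drop = FALSE]))
  samePattern && identical(rspec@components, fspec@components) &&
    rank(rspec) < rank(fspec)
}

#' Chi-square difference test for nested twin models
#'
#' Compares a restricted model to a full model by the likelihood-ratio
#' statistic; the p-value is the upper-tail chi-square probability at
#' \code{delta_df} degrees of freedom (\code{delta_df = 0} gives p = 1).
#' For tests of variance components on the boundary this naive reference
#' distribution is conservative (the 1/2-chi-square mixture issue); the
#' naive value is reported, with a note attached.
#'
#' @param restricted,full \linkS4class{TwinFit} objects; \code{restricted}
#'   must be nested in \code{full}.
#' @return list of class \code{"twin_lrt"}: \code{delta_neg2ll},
#'   \code{delta_df}, \code{p_value}.
#' @export
twinLRT <- function(restricted, full) {
  stopifnot(is(restricted, "TwinFit"), is(full, "TwinFit"))
  if (!.isNested(restricted@spec, full@spec))
    stop("models are not nested (free-parameter sets are not comparable)")
  delta <- restricted@neg2ll - full@neg2ll
  ddf <- full@nFree - restricted@nFree
  if (ddf < 0) stop("restricted model has more free parameters than the full model")
  if (delta < -1e-6)
    stop("restricted model fits better than the full model; ",
         "one of the optimisations did not reach its optimum (refit)")
  delta <- max(delta, 0)
  p <- if (ddf == 0) 1 else stats::pchisq(delta, ddf, lower.tail = FALSE)
  structure(list(delta_neg2ll = delta, delta_df = ddf, p_value = p,
                 note = paste("naive chi-square reference; conservative for",
                              "variance components on the boundary")),
            class = "twin_lrt")
}

#' @export
print.twin_lrt <- function(x, ...) {
  cat(sprintf("chi-square difference test: delta(-2LL) = %.4g, delta(df) = %d, p = %.4g\n",
              x$delta_neg2ll, x$delta_df, x$p_value))
  invisible(x)
}

#' Prune small non-significant paths to a parsimonious model
#'
#' Iteratively constrains to zero the free path with the smallest
#' standardised variance contribution among those below \code{threshold}
#' whose 95\% contribution interval covers zero, refitting after each
#' constraint, until no candidate remains. Paths whose removal would leave
#' a variable with zero total E variance are exempt; sex scalars are never
#' pruned. For sex-specific paths both sexes must qualify before the path
#' is dropped.
#'
#' @param fit a converged \linkS4class{TwinFit}.
#' @param data the \linkS4class{TwinDataset} the fit used.
#' @param threshold standardised-contribution threshold (default 0.05).
#' @return the final pruned \linkS4class{TwinFit}, with the constraint
#'   history recorded in \code{details$pruneHistory}.
#' @export
pruneSmallPaths <- function(fit, data, threshold = 0.05) {
  stopifnot(is(fit, "TwinFit"))
  if (!fit@converged) stop("pruning requires a converged fit")
  opts <- fit@details$options
  history <- list()
  repeat {
    ci <- fit@ci95
    if (!nrow(ci)) break
    cand <- ci[ci$type == "loading", , drop = FALSE]
    ## aggregate sex-specific duplicates of the same structural path
    keys <- unique(cand[, c("component", "factor", "variable")])
    keys$contrib <- NA_real_
    keys$ok <- FALSE
    for (k in seq_len(nrow(keys))) {
      rows <- cand$component == keys$component[k] &
        cand$factor == keys$factor[k] & cand$variable == keys$variable[k]
      keys$contrib[k] <- max(cand$contrib[rows])
      keys$ok[k] <- all(cand$contrib[rows] < threshold &
                          cand$contribLower[rows] <= 0)
    }
    ## keep every variable's E variance alive
    for (k in which(keys$ok & keys$component == "E")) {
      pat <- fit@spec@pattern[["E"]]
      v <- keys$variable[k]
      if (sum(pat[v, ]) <= 1) keys$ok[k] <- FALSE
    }
    keys <- keys[keys$ok, , drop = FALSE]
    if (!nrow(keys)) break
    pick <- keys[which.min(keys$contrib), c("component", "variable", "factor")]
    newSpec <- constrainToZero(fit@spec, pick)
    newFit <- fitTwinModel(newSpec, data, nRestarts = opts$nRestarts,
                           seed = fit@details$seed, relTol = opts$relTol,
                           xTol = opts$xTol, maxit = opts$maxit,
                           fixedParams = fit@details$fixedParams)
    if (!newFit@converged) {
      warning("refit after pruning did not converge; stopping early")
      break
    }
    history[[length(history) + 1L]] <-
      cbind(pick, neg2ll = newFit@neg2ll, row.names = NULL)
    fit <- newFit
  }
  fit@details$pruneHistory <- if (length(history)) do.call(rbind, history)
                              else NULL
  fit
}

#' Test scalar and quantitative sex differences for one trait
#'
#' Fits the no-difference, scalar (free female variance multiplier) and
#' quantitative (sex-specific a, c, e paths) univariate models and returns
#' the two nested chi-square comparisons: quantitative vs scalar and scalar
#' vs none.
#'
#' @param data a normalised \linkS4class{TwinDataset}.
#' @param variable which variable to test (label).
#' @param components subset of \code{c("A","C","E")} for the base model.
#' @param ... passed to \code{\link{fitTwinModel}}.
#' @return list with \code{fits} (none/scalar/quantitative) and
#'   \code{tests} (data.frame of the two comparisons).
#' @export
testSexDifferences <- function(data, variable, components = c("A", "C", "E"),
                               ...) {
  fits <- list(
    none = fitTwinModel(univariateACE("none", variable, components), data, ...),
    scalar = fitTwinModel(univariateACE("scalar", variable, components), data, ...),
    quantitative = fitTwinModel(univariateACE("quantitative", variable,
                                              components), data, ...))
  t1 <- twinLRT(fits$scalar, fits$quantitative)
  t2 <- twinLRT(fits$none, fits$scalar)
  tests <- data.frame(
    comparison = c("quantitative_vs_scalar", "scalar_vs_none"),
    delta_neg2ll = c(t1$delta_neg2ll, t2$delta_neg2ll),
    delta_df = c(t1$delta_df, t2$delta_df),
    p_value = c(t1$p_value, t2$p_value),
    stringsAsFactors = FALSE)
  list(fits = fits, tests = tests)
}

#' Serialise a fit to JSON
#'
#' @param fit a \linkS4class{TwinFit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFitJSON <- function(fit, path) {
  out <- list(
    family = fit@spec@family,
    variables = fit@spec@variableNames,
    spec = specToList(fit@spec),
    estimates = as.list(fit@estimates),
    neg2ll = fit@neg2ll, n_free = fit@nFree, aic = fit@aic,
    converged = fit@converged, n_restarts = fit@nRestartsUsed,
    groups = as.list(fit@groups),
    seed = fit@details$seed,
    ci95 = fit@ci95)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Rebuild a fitted model from its JSON form
#'
#' Restores the specification and point estimates (enough to recompute
#' decompositions and reports; optimiser internals are not round-tripped).
#'
#' @param path path to a JSON file written by \code{\link{writeFitJSON}}.
#' @return a \linkS4class{TwinFit}.
#' @export
readFitJSON <- function(path) {
  x <- jsonlite::read_json(path)
  spec <- specFromList(x$spec)
  est <- unlist(x$estimates)
  ci <- if (length(x$ci95)) do.call(rbind, lapply(x$ci95, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE))) else data.frame()
  new("TwinFit", spec = spec, estimates = est, neg2ll = as.numeric(x$neg2ll),
      nFree = as.integer(x$n_free), aic = as.numeric(x$aic),
      converged = isTRUE(x$converged),
      nRestartsUsed = as.integer(x$n_restarts),
      vcov = matrix(0, length(est), length(est)), ci95 = ci,
      groups = vapply(x$groups, as.integer, 0L),
      details = list(seed = x$seed))
}
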