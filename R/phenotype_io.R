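## Reading, writing and preprocessing of twin-pair phenotype tables.
##
## File dialect: CSV (UTF-8, "." decimal, empty cell = missing) with columns
## family_id, zygosity (MZ|DZ), sex (M|F), then <var>_t1 and <var>_t2 for
## each phenotype.

#' Construct a TwinDataset from vectors and a phenotype array
#'
#' Low-level constructor; most users will use \code{\link{readTwinTable}} or
#' \code{\link{simulateTwins}}.
#'
#' @param familyId character vector of pair identifiers.
#' @param zygosity character, \code{"MZ"}/\code{"DZ"}.
#' @param pairSex character, \code{"M"}/\code{"F"}.
#' @param phenotypes numeric array n x 2 x p.
#' @param variableNames character vector of length p.
#' @param preprocessing states already applied (default \code{"raw"}).
#' @param log list of bookkeeping entries.
#' @return a \linkS4class{TwinDataset}.
#' @export
TwinDataset <- function(familyId, zygosity, pairSex, phenotypes, variableNames,
                        preprocessing = "raw", log = list()) {
  dimnames(phenotypes) <- list(NULL, c("t1", "t2"), variableNames)
  new("TwinDataset", familyId = as.character(familyId),
      zygosity = as.character(zygosity), pairSex = as.character(pairSex),
      phenotypes = phenotypes, variableNames = variableNames,
      preprocessing = preprocessing, log = log)
}

#' Read a twin-pair table from CSV
#'
#' Expects columns \code{family_id}, \code{zygosity}, \code{sex} and
#' \code{<var>_t1}/\code{<var>_t2} pairs for each requested variable. Rows
#' with unparseable zygosity or sex are dropped and counted in the dataset
#' log; missing phenotype cells are kept as \code{NA}.
#'
#' @param path path to a CSV file.
#' @param variableNames variables to load (default: all \code{_t1}/\code{_t2}
#'   pairs found, in file order).
#' @return a \linkS4class{TwinDataset} with \code{preprocessing = "raw"}.
#' @export
readTwinTable <- function(path, variableNames = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("family_id", "zygosity", "sex"))
    if (!col %in% colnames(tab))
      stop("input table is missing mandatory column '", col, "'")
  if (is.null(variableNames)) {
    t1 <- sub("_t1$", "", grep("_t1$", colnames(tab), value = TRUE))
    t2 <- sub("_t2$", "", grep("_t2$", colnames(tab), value = TRUE))
    variableNames <- intersect(t1, t2)
  }
  if (!length(variableNames)) stop("no phenotype variables found in table")
  for (v in variableNames)
    for (suf in c("_t1", "_t2"))
      if (!paste0(v, suf) %in% colnames(tab))
        stop("input table is missing mandatory column '", paste0(v, suf), "'")
  ok <- tab$zygosity %in% .ZYG_LEVELS & tab$sex %in% .SEX_LEVELS
  nDropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  if (!nrow(tab)) stop("no valid rows after dropping unparseable zygosity/sex")
  p <- length(variableNames)
  ph <- array(NA_real_, c(nrow(tab), 2, p))
  for (k in seq_len(p)) {
    ph[, 1, k] <- as.numeric(tab[[paste0(variableNames[k], "_t1")]])
    ph[, 2, k] <- as.numeric(tab[[paste0(variableNames[k], "_t2")]])
  }
  prep <- "raw"
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta)) {
    m <- tryCatch(jsonlite::read_json(meta), error = function(e) NULL)
    if (!is.null(m$preprocessing))
      prep <- intersect(unlist(m$preprocessing), .PREP_STATES)
  }
  TwinDataset(tab$family_id, tab$zygosity, tab$sex, ph, variableNames,
              preprocessing = prep,
              log = list(source = path, rows_dropped = nDropped))
}

#' Write a twin-pair table to CSV (with a JSON sidecar)
#'
#' Writes the same dialect \code{\link{readTwinTable}} reads; numeric cells
#' are serialised at full precision (17 significant digits) so a round trip
#' reproduces finite values bit-exactly. A JSON sidecar
#' (\code{<path>.meta.json}) records the preprocessing states applied and
#' the dataset log.
#'
#' @param data a \linkS4class{TwinDataset}.
#' @param path output CSV path.
#' @param sidecar logical; write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeTwinTable <- function(data, path, sidecar = TRUE) {
  p <- length(data@variableNames)
  out <- data.frame(family_id = data@familyId, zygosity = data@zygosity,
                    sex = data@pairSex, stringsAsFactors = FALSE)
  for (k in seq_len(p)) {
    out[[paste0(data@variableNames[k], "_t1")]] <-
      sprintf("%.17g", data@phenotypes[, 1, k])
    out[[paste0(data@variableNames[k], "_t2")]] <-
      sprintf("%.17g", data@phenotypes[, 2, k])
  }
  for (col in colnames(out)) out[[col]][out[[col]] %in% c("NA", "NaN")] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (sidecar) {
    meta <- list(preprocessing = data@preprocessing, log = data@log,
                 n_pairs = nPairs(data), variables = data@variableNames)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Residualise phenotypes for sex
#'
#' Replaces each variable by the residuals of an ordinary least-squares
#' regression on a sex indicator, pooling both twins of each pair (pairs are
#' same-sex, so the indicator is constant within pair). With a single sex
#' indicator this is removal of per-sex means; missing values stay missing.
#'
#' @param data a raw \linkS4class{TwinDataset}.
#' @return the dataset with residualised phenotypes and
#'   \code{"sex_residualised"} appended to its preprocessing states.
#' @export
residualiseSex <- function(data) {
  stopifnot(is(data, "TwinDataset"))
  if ("sex_residualised" %in% data@preprocessing)
    stop("data are already sex-residualised")
  ph <- data@phenotypes
  sexLong <- rep(data@pairSex, times = 2)   # twin 1 stacked over twin 2
  for (k in seq_along(data@variableNames)) {
    y <- c(ph[, 1, k], ph[, 2, k])
    if (all(is.na(y)))
      stop("variable '", data@variableNames[k], "' has no observed values")
    ## OLS on a sex indicator == removal of per-sex means; stays defined
    ## when a variable is observed in one sex only
    mu <- stats::ave(y, sexLong, FUN = function(u) mean(u, na.rm = TRUE))
    res <- y - mu
    n <- nPairs(data)
    ph[, 1, k] <- res[seq_len(n)]
    ph[, 2, k] <- res[n + seq_len(n)]
  }
  data@phenotypes <- ph
  data@preprocessing <- c(data@preprocessing, "sex_residualised")
  data
}

#' Rank-based inverse-normal transformation
#'
#' Maps each variable through Blom rank scores,
#' \code{qnorm((rank - 3/8) / (n + 1/4))} with ties given average ranks,
#' pooling both twins within variable so twin labelling is irrelevant, then
#' standardises to exact mean 0 and variance 1. The transform is invariant
#' to any strictly monotone re-coding of the input.
#'
#' @param data a sex-residualised \linkS4class{TwinDataset}.
#' @return the dataset with normalised phenotypes and \code{"normalised"}
#'   appended to its preprocessing states.
#' @export
rankNormalise <- function(data) {
  stopifnot(is(data, "TwinDataset"))
  if (!"sex_residualised" %in% data@preprocessing)
    stop("rankNormalise expects sex-residualised data")
  ph <- data@phenotypes
  n <- nPairs(data)
  for (k in seq_along(data@variableNames)) {
    y <- c(ph[, 1, k], ph[, 2, k])
    obs <- !is.na(y)
    m <- sum(obs)
    if (m < 10)
      warning("variable '", data@variableNames[k], "' has fewer than 10 ",
              "non-missing values; rank normalisation is unreliable")
    yo <- y[obs]
    if (max(yo) - min(yo) < .Machine$double.eps * 100)
      stop("variable '", data@variableNames[k], "' is constant; ",
           "cannot rank-normalise")
    r <- rank(yo, ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (m + 1 / 4))
    z <- (z - mean(z)) / stats::sd(z)
    y[obs] <- z
    ph[, 1, k] <- y[seq_len(n)]
    ph[, 2, k] <- y[n + seq_len(n)]
  }
  data@phenotypes <- ph
  data@preprocessing <- c(data@preprocessing, "normalised")
  data
}

#' Per-variable, per-zygosity descriptive statistics
#'
#' For each variable and zygosity group: number of pairs with both twins
#' observed, mean and variance over all observed values, and the cross-twin
#' intraclass correlation computed by the pairwise double-entry method
#' (each complete pair entered as (t1, t2) and (t2, t1), then Pearson
#' correlation), which is invariant to twin labelling.
#'
#' @param data a normalised \linkS4class{TwinDataset}.
#' @return data.frame: variable, zygosity, n_pairs, mean, variance, icc.
#' @export
twinDescriptives <- function(data) {
  stopifnot(is(data, "TwinDataset"))
  out <- list()
  for (k in seq_along(data@variableNames)) {
    for (z in .ZYG_LEVELS) {
      sel <- data@zygosity == z
      t1 <- data@phenotypes[sel, 1, k]
      t2 <- data@phenotypes[sel, 2, k]
      comp <- !is.na(t1) & !is.na(t2)
      allv <- c(t1, t2)
      icc <- if (sum(comp) >= 3) {
        de1 <- c(t1[comp], t2[comp])
        de2 <- c(t2[comp], t1[comp])
        stats::cor(de1, de2)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        variable = data@variableNames[k], zygosity = z,
        n_pairs = sum(comp),
        mean = if (any(!is.na(allv))) mean(allv, na.rm = TRUE) else NA_real_,
        variance = if (sum(!is.na(allv)) > 1) stats::var(allv, na.rm = TRUE)
                   else NA_real_,
        icc = icc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
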