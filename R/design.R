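#' Standardize a continuous covariate
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), so that regression coefficients are comparable effect sizes:
#' the effect of a one-standard-deviation change in the covariate.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param name Covariate name used in error messages.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("'", name, "' must be a numeric vector of length >= 2")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("covariate '", name, "' is constant and cannot be standardized")
  }
  (values - mean(values)) / s
}

#' Validate a site-by-taxon occurrence matrix
#'
#' @param Y Matrix of 0/1 values, sites in rows (rownames are site ids),
#'   taxa in columns (colnames are taxon names).
#' @return The validated matrix (invisibly coerced to integer storage).
#' @export
validate_occurrence <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) stop("occurrence matrix needs at least 2 sites")
  if (ncol(Y) < 1) stop("occurrence matrix needs at least 1 taxon")
  if (anyNA(Y)) stop("occurrence matrix contains missing values")
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(Y)) + 1
    j <- ((bad[1] - 1) %/% nrow(Y)) + 1
    stop("occurrence value not 0/1 at row ", i, " ('",
         if (is.null(rownames(Y))) i else rownames(Y)[i], "'), column ", j,
         " ('", if (is.null(colnames(Y))) j else colnames(Y)[j], "')")
  }
  if (!is.null(rownames(Y)) && anyDuplicated(rownames(Y)))
    stop("duplicated site ids in occurrence matrix")
  if (!is.null(colnames(Y)) && anyDuplicated(colnames(Y)))
    stop("duplicated taxon names in occurrence matrix")
  storage.mode(Y) <- "integer"
  Y
}

#' Build a probit design matrix from a covariate table
#'
#' Produces the design matrix used throughout the package: an intercept
#' column, dummy expansions (first level as reference) of the forced
#' survey-design factors (by default dipping `round` and survey `area`,
#' included in every model to absorb the repeated-measures design),
#' standardized continuous covariates and 0/1 indicator covariates left on
#' their natural scale.
#'
#' @param covariates Data frame with a `site_id` column plus covariates.
#'   Character or factor columns are dummy-expanded; numeric columns
#'   containing only 0/1 are treated as binary indicators; remaining numeric
#'   columns are standardized (see [standardize()]).
#' @param forced Character vector of factor column names treated as forced
#'   survey-design terms (kind `"forced_dummy"`).
#' @param standardize Logical; standardize continuous columns (default TRUE).
#' @return An object of class `jsdm_design`: a list with elements `values`
#'   (numeric matrix, first column the intercept), `kinds` (named character
#'   vector over columns: `intercept`, `continuous`, `binary`,
#'   `forced_dummy`) and `site_ids`.
#' @export
build_design <- function(covariates, forced = c("round", "area"),
                         standardize = TRUE) {
  covariates <- as.data.frame(covariates)
  if (!"site_id" %in% names(covariates))
    stop("covariate table must contain a 'site_id' column")
  site_ids <- as.character(covariates$site_id)
  if (anyDuplicated(site_ids)) stop("duplicated site_id in covariate table")
  covs <- covariates[setdiff(names(covariates), c("site_id", "site"))]
  n <- nrow(covs)
  cols <- list(`(Intercept)` = rep(1, n))
  kinds <- c(`(Intercept)` = "intercept")
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      lev <- levels(x)
      if (length(lev) > 1) {
        for (l in lev[-1]) {
          cn <- paste0(nm, l)
          cols[[cn]] <- as.numeric(x == l)
          kinds[cn] <- if (nm %in% forced) "forced_dummy" else "binary"
        }
      }
    } else if (is.numeric(x)) {
      if (all(x %in% c(0, 1))) {
        cols[[nm]] <- as.numeric(x)
        kinds[nm] <- if (nm %in% forced) "forced_dummy" else "binary"
      } else {
        cols[[nm]] <- if (standardize) standardize(x, nm) else x
        kinds[nm] <- "continuous"
      }
    } else {
      stop("unsupported covariate column type: '", nm, "'")
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- site_ids
  qrv <- qr(values)
  if (qrv$rank < ncol(values)) {
    drop <- colnames(values)[qrv$pivot[-seq_len(qrv$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  structure(list(values = values, kinds = kinds, site_ids = site_ids),
            class = "jsdm_design")
}

# Accept either a jsdm_design or a plain numeric matrix wherever a design
# is needed.
design_values <- function(X) {
  if (inherits(X, "jsdm_design")) return(X$values)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("V", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  X
}

design_kinds <- function(X) {
  if (inherits(X, "jsdm_design")) return(X$kinds)
  V <- design_values(X)
  kinds <- rep("continuous", ncol(V))
  names(kinds) <- colnames(V)
  kinds[apply(V, 2, function(v) all(v %in% c(0, 1)))] <- "binary"
  if (all(V[, 1] == 1)) kinds[1] <- "intercept"
  kinds
}

#' Names of forced survey-design columns in a design
#'
#' @param X A `jsdm_design`.
#' @return Character vector of dummy column names with kind `forced_dummy`.
#' @export
forced_columns <- function(X) {
  kinds <- design_kinds(X)
  names(kinds)[kinds == "forced_dummy"]
}
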