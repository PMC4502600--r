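#' Maximum a posteriori estimate from posterior draws
#'
#' Location of the maximum of a Gaussian kernel density estimate over the
#' draws (Silverman's rule-of-thumb bandwidth, 512-point grid spanning the
#' draw range), the point estimate used for effect sizes.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @return The estimated posterior mode.
#' @export
map_estimate <- function(draws) {
  if (length(draws) < 100) stop("need at least 100 draws for a MAP estimate")
  if (diff(range(draws)) == 0) return(draws[1])
  d <- stats::density(draws, bw = "nrd0", n = 512,
                      from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

#' Central credible interval from posterior draws
#'
#' Equal-tailed quantile interval; quantiles use linear interpolation
#' between order statistics (R's default type-7 rule).
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param level Interval mass (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100) stop("need at least 100 draws for a credible interval")
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Bayesian p-value of a posterior effect
#'
#' The posterior probability that the quantity is zero or of opposite sign
#' to its posterior mean: the fraction of draws that are zero or disagree
#' in sign with the mean (0.5 when the mean is exactly zero). Values below
#' a threshold (conventionally 0.05) play the role of significance at the
#' 5% level.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @return Probability in [0, 1].
#' @export
bayesian_pvalue <- function(draws) {
  if (length(draws) < 100) stop("need at least 100 draws")
  m <- mean(draws)
  if (m == 0) return(0.5)
  mean(draws == 0 | sign(draws) != sign(m))
}

#' Posterior effect-size table
#'
#' MAP estimates and 95% credible intervals for every coefficient included
#' in each taxon's niche model. Continuous covariates were standardized in
#' the design, so their coefficients are effects of a one-standard-deviation
#' change; discrete (0/1) covariates are on their natural scale, and the
#' `kind` column keeps the two types segregated since their effect sizes
#' are not directly comparable.
#'
#' @param fit A [jsdm_fit()].
#' @param X The design the model was fitted to (supplies covariate kinds).
#' @param level Credible level (default 0.95).
#' @param include_intercept Keep intercept rows (default FALSE).
#' @return Data frame with columns `taxon`, `covariate`, `kind`, `map`,
#'   `lower`, `upper`, `bayesian_p`.
#' @export
effect_sizes <- function(fit, X = NULL, level = 0.95,
                         include_intercept = FALSE) {
  kinds <- if (is.null(X)) {
    setNames(rep(NA_character_, length(fit$covariate_names)),
             fit$covariate_names)
  } else design_kinds(X)
  rows <- list()
  for (tx in fit$taxon_names) {
    for (cv in fit$covariate_names[fit$mask[, tx] == 1L]) {
      if (!include_intercept && cv == "(Intercept)") next
      d <- coef_draws(fit, cv, tx)
      ci <- credible_interval(d, level)
      rows[[length(rows) + 1]] <- data.frame(
        taxon = tx, covariate = cv, kind = unname(kinds[cv]),
        map = map_estimate(d), lower = ci[["lower"]], upper = ci[["upper"]],
        bayesian_p = bayesian_pvalue(d), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Residual correlation network
#'
#' Edges are the unordered taxon pairs whose residual correlation has a
#' Bayesian p-value (posterior probability of a zero or opposite-sign
#' correlation) below the threshold; edge weight is the posterior mean
#' correlation.
#'
#' @param fit A [jsdm_fit()] of a community_only or full model.
#' @param threshold Inclusion threshold on the Bayesian p-value
#'   (default 0.05).
#' @return A data frame of class `jsdm_network` with columns `taxon_a`,
#'   `taxon_b`, `correlation`, `bayesian_p`, `sign`; the threshold is kept
#'   as an attribute.
#' @export
correlation_network <- function(fit, threshold = 0.05) {
  if (is.null(fit$R)) stop("no correlations were estimated for this model")
  taxa <- fit$taxon_names
  rows <- list()
  for (a in seq_along(taxa)[-length(taxa)]) {
    for (b in (a + 1):length(taxa)) {
      d <- correlation_draws(fit, taxa[a], taxa[b])
      p <- bayesian_pvalue(d)
      if (p < threshold) {
        m <- mean(d)
        rows[[length(rows) + 1]] <- data.frame(
          taxon_a = taxa[a], taxon_b = taxa[b], correlation = m,
          bayesian_p = p, sign = ifelse(m >= 0, "positive", "negative"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_a = character(), taxon_b = character(),
               correlation = numeric(), bayesian_p = numeric(),
               sign = character(), stringsAsFactors = FALSE)
  structure(out, threshold = threshold,
            class = c("jsdm_network", "data.frame"))
}

#' Co-occurrence dendrogram of the raw distribution data
#'
#' Pairwise dissimilarity between taxa is one minus the empirical Pearson
#' correlation of their presence/absence columns (the phi coefficient for
#' binary data): 0 is perfect positive association, 1 independence, 2
#' perfect negative association. Taxa are clustered agglomeratively
#' (average linkage by default).
#'
#' @param Y Site-by-taxon occurrence matrix; every taxon must vary across
#'   sites.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default "average").
#' @return A list of class `jsdm_dendrogram`: `hclust` (merge tree),
#'   `dissimilarity` (taxa-by-taxa matrix) and `linkage`.
#' @export
cooccurrence_dendrogram <- function(Y, linkage = "average") {
  Y <- validate_occurrence(Y)
  constant <- apply(Y, 2, function(v) length(unique(v)) == 1)
  if (any(constant))
    stop("constant occurrence column(s): ",
         paste(colnames(Y)[constant], collapse = ", "))
  D <- 1 - cor(Y)
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = linkage)
  structure(list(hclust = hc, dissimilarity = D, linkage = linkage),
            class = "jsdm_dendrogram")
}

#' Export a co-occurrence dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the clustering.
#'
#' @param dendrogram A [cooccurrence_dendrogram()].
#' @return A Newick format string.
#' @export
dendrogram_newick <- function(dendrogram) {
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy)
}
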