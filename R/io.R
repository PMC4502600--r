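#' Read occurrence and covariate CSV tables
#'
#' The occurrence file has a `site_id` first column and one 0/1 column per
#' taxon; the covariate file has `site_id` plus named covariates
#' (categorical `round`/`area` columns are kept as factors for later dummy
#' expansion by [build_design()]). Rows are reconciled by `site_id`, so the
#' covariate table may arrive in any order.
#'
#' @param occurrence_path,covariate_path Paths to the two CSV files
#'   (comma-separated, UTF-8, header row, `.` decimal).
#' @return List with `occurrences` (integer matrix, rownames = site ids)
#'   and `covariates` (data frame aligned to the occurrence rows).
#' @export
read_survey_tables <- function(occurrence_path, covariate_path) {
  for (p in c(occurrence_path, covariate_path))
    if (!file.exists(p)) stop("file not found: ", p)
  occ <- read.csv(occurrence_path, stringsAsFactors = FALSE, check.names = FALSE)
  cov <- read.csv(covariate_path, stringsAsFactors = FALSE, check.names = FALSE)
  for (tab in list(occ = occ, cov = cov))
    if (!"site_id" %in% names(tab)) stop("both tables need a 'site_id' column")
  Y <- as.matrix(occ[setdiff(names(occ), "site_id")])
  rownames(Y) <- as.character(occ$site_id)
  Y <- validate_occurrence(Y)
  missing_ids <- setdiff(rownames(Y), as.character(cov$site_id))
  extra_ids <- setdiff(as.character(cov$site_id), rownames(Y))
  if (length(missing_ids) || length(extra_ids))
    stop("unmatched site_ids between tables: ",
         paste(utils::head(c(missing_ids, extra_ids), 10), collapse = ", "))
  cov <- cov[match(rownames(Y), as.character(cov$site_id)), , drop = FALSE]
  rownames(cov) <- NULL
  for (nm in intersect(c("round", "area"), names(cov)))
    cov[[nm]] <- factor(cov[[nm]])
  message("read ", nrow(Y), " site rows, ", ncol(Y), " taxa (",
          paste(utils::head(colnames(Y), 4), collapse = ", "),
          if (ncol(Y) > 4) ", ..." else "", ")")
  list(occurrences = Y, covariates = cov)
}

#' Write a simulated dataset bundle as CSV + JSON
#'
#' Writes `occurrences.csv`, `covariates.csv`, `coords.csv` and
#' `truth.json` in the same dialect [read_survey_tables()] consumes.
#'
#' @param fixture A [make_study_fixture()] bundle (or compatible list).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey_tables <- function(fixture, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  occ <- data.frame(site_id = rownames(fixture$occurrences),
                    fixture$occurrences, check.names = FALSE)
  paths <- c(occurrences = file.path(out_dir, "occurrences.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             coords = file.path(out_dir, "coords.csv"))
  write.csv(occ, paths["occurrences"], row.names = FALSE)
  write.csv(fixture$covariates, paths["covariates"], row.names = FALSE)
  write.csv(fixture$coords, paths["coords"], row.names = FALSE)
  if (!is.null(fixture$truth)) {
    tpath <- file.path(out_dir, "truth.json")
    truth <- fixture$truth
    truth$B <- as.data.frame(truth$B)
    truth$R <- as.data.frame(truth$R)
    jsonlite::write_json(truth, tpath, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
    paths <- c(paths, truth = tpath)
  }
  invisible(paths)
}

flatten_coef_draws <- function(fit, chain) {
  n_keep <- dim(fit$B)[3]
  cols <- list()
  for (j in seq_along(fit$taxon_names)) {
    for (k in which(fit$mask[, j] == 1L)) {
      nm <- paste0(fit$covariate_names[k], ":", fit$taxon_names[j])
      cols[[nm]] <- fit$B[k, j, , chain]
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

flatten_corr_draws <- function(fit, chain) {
  T <- length(fit$taxon_names)
  cols <- list()
  for (a in seq_len(T - 1)) for (b in (a + 1):T) {
    nm <- paste0(fit$taxon_names[a], ":", fit$taxon_names[b])
    cols[[nm]] <- fit$R[a, b, , chain]
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Write fit results and summaries to a results directory
#'
#' Writes a deterministic file layout: per-chain coefficient (and, when
#' estimated, correlation) draw CSVs, any supplied summary tables, and a
#' `manifest.json` recording the package version, model spec, MCMC settings,
#' seed and an md5 hash of every written file. The manifest is written
#' last: its absence signals an incomplete run.
#'
#' @param fit A [jsdm_fit()].
#' @param summaries Optional named list; recognised elements are
#'   `effect_sizes` (data frame), `network` ([correlation_network()]),
#'   `deviance` (data frame), `dic` (data frame) and `dendrogram`
#'   ([cooccurrence_dendrogram()], written as Newick).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(fit, summaries = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ch in seq_len(fit$settings$n_chains)) {
    f <- file.path(out_dir, sprintf("coefficients_chain%d.csv", ch))
    write.csv(flatten_coef_draws(fit, ch), f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(fit$R)) {
      f <- file.path(out_dir, sprintf("correlations_chain%d.csv", ch))
      write.csv(flatten_corr_draws(fit, ch), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  tables <- list(effect_sizes = "effect_sizes.csv", network = "network_edges.csv",
                 deviance = "deviance.csv", dic = "dic.csv")
  for (nm in names(tables)) {
    if (!is.null(summaries[[nm]])) {
      f <- file.path(out_dir, tables[[nm]])
      write.csv(as.data.frame(summaries[[nm]]), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(summaries$dendrogram)) {
    f <- file.path(out_dir, "dendrogram.nwk")
    writeLines(dendrogram_newick(summaries$dendrogram), f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "jsdmprobit",
    version = as.character(utils::packageVersion("jsdmprobit")),
    model_type = fit$spec$model_type,
    forced_terms = fit$spec$forced_terms,
    per_taxon_covariates = fit$spec$per_taxon,
    settings = unclass(fit$settings),
    seed = fit$settings$seed,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
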