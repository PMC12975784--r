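## Report assembly: heritability arithmetic, table-shaped summaries and a
## machine-readable JSON twin.

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`. Full precision is returned;
#' reports display it rounded to 2 decimals.
#'
#' @param sigma2_a additive genetic variance (>= 0).
#' @param sigma2_e residual variance (>= 0; 1 for threshold traits).
#' @examples
#' round(heritability_from_components(0.190, 1.007), 2)  # 0.16
#' @export
heritability_from_components <- function(sigma2_a, sigma2_e) {
  if (any(sigma2_a < 0) || any(sigma2_e < 0))
    stop("variance components must be non-negative")
  if (any(sigma2_a + sigma2_e == 0))
    stop("both variance components are zero: heritability undefined")
  sigma2_a / (sigma2_a + sigma2_e)
}

#' Table-shaped posterior summary row for one fitted trait
#'
#' One row in the layout of a variance-component report: posterior means of
#' the components, the posterior mean of the per-sample heritability (the
#' headline value) together with the ratio-of-means variant, PSD and 95%
#' credibility interval, and convergence flags.
#'
#' @param fit a `gibbs_fit`.
#' @param trait trait code (defaults to the fit's trait).
#' @return One-row data frame.
#' @export
trait_summary_row <- function(fit, trait = fit$trait %||% NA_character_) {
  s <- fit$samples
  ci <- ci_equal_tail(s$h2)
  diag <- diagnostic_report(fit)
  data.frame(trait = trait,
             sigma2_a = mean(s$sigma2_a), sigma2_e = mean(s$sigma2_e),
             h2 = mean(s$h2), h2_psd = sd(s$h2),
             h2_ratio_of_means = heritability_from_components(
               mean(s$sigma2_a), mean(s$sigma2_e)),
             ci_low = ci[1], ci_high = ci[2],
             converged = all(diag$converged),
             stringsAsFactors = FALSE)
}

#' Assemble and write the report bundle
#'
#' Collects per-trait posterior summaries (rows ordered FL, MO, CH, RC, DP,
#' UH, TH, NV, YW), occurrence tables, genetic trends and lineage tables
#' into one deterministic report, optionally written as CSV files plus a
#' machine-readable JSON twin.
#'
#' @param summaries data frame of [trait_summary_row()]s (at least one).
#' @param occurrences optional [occurrence_summary()] data frame.
#' @param trends optional named list of `trend_result`s (names = traits).
#' @param lineages optional [lineage_defect_table()] data frame.
#' @param dir optional output directory; when given, writes `summary.csv`,
#'   `summary.json`, and the optional `occurrence.csv`, `trend.json`,
#'   `lineages.csv`.
#' @return The report as a list (invisibly when written to `dir`).
#' @export
render_reports <- function(summaries, occurrences = NULL, trends = NULL,
                           lineages = NULL, dir = NULL) {
  if (is.null(summaries) || !nrow(summaries)) stop("at least one summary row")
  bad <- setdiff(summaries$trait, TRAIT_CODES)
  if (length(bad))
    stop("unknown trait code(s) in summaries: ", paste(bad, collapse = ", "))
  if (!is.null(occurrences)) {
    bad <- setdiff(occurrences$trait, TRAIT_CODES)
    if (length(bad))
      stop("mixed trait codes across inputs: ", paste(bad, collapse = ", "))
  }
  summaries <- summaries[order(match(summaries$trait, TRAIT_CODES)), ,
                         drop = FALSE]
  rownames(summaries) <- NULL
  disp <- summaries
  num <- c("sigma2_a", "sigma2_e", "h2", "h2_psd", "h2_ratio_of_means",
           "ci_low", "ci_high")
  disp[num] <- lapply(disp[num], round, 3)
  disp$h2 <- round(summaries$h2, 2)
  report <- list(summary = disp)
  if (!is.null(occurrences)) report$occurrence <- occurrences
  if (!is.null(trends)) {
    report$trends <- lapply(trends, function(tr)
      list(slope = tr$slope, intercept = tr$intercept,
           r_squared = tr$r_squared, mode = tr$mode))
  } else message("no trends supplied; trends section omitted")
  if (!is.null(lineages)) report$lineages <- lineages
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(disp, file.path(dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(occurrences))
      utils::write.csv(occurrences, file.path(dir, "occurrence.csv"),
                       row.names = FALSE)
    if (!is.null(trends))
      jsonlite::write_json(report$trends, file.path(dir, "trend.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(lineages))
      utils::write.csv(lineages, file.path(dir, "lineages.csv"),
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Reload a written report
#'
#' @param dir directory written by [render_reports()].
#' @return The report list, as parsed from `summary.json`.
#' @export
load_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
}
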