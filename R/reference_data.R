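#' Published ROI change summaries
#'
#' Group-level eigenvector-centrality change summaries (mean, SEM, 95% CI
#' per group) for the regions reported with significant group-by-time
#' interactions in a longitudinal motor sequence learning study, together
#' with the reported sequence-specificity label of each region. One region
#' (right supplementary motor area, overall learning) was reported as
#' sequence-specific; the remaining effects were driven by the control
#' group. Used as a worked example for validating
#' [classify_specificity()] against expert-assigned labels.
#'
#' @return Data frame with columns stage, region, group, mean, sem, ci_lo,
#'   ci_hi, reported_specific.
#' @export
roi_change_reference <- function() {
  path <- system.file("extdata", "roi_change_reference.tsv",
                      package = "motorecm", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
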