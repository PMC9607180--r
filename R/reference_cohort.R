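#' Sex-stratified regional deviation rates of the reference cohort
#'
#' Percentages of men and women whose depth-sensor face scan deviated by
#' more than 3 mm from the CBCT-derived reference shell, per facial region,
#' in a published 60-subject comparison cohort (19 men, 41 women). These
#' printed rates serve two purposes: as the default defect probabilities of
#' the cohort simulator, and as the input from which the per-region
#' contingency tables can be reconstructed exactly (the per-sex counts are
#' recovered as `round(pct / 100 * n_sex)`).
#'
#' @return data.frame with columns `region`, `pct_men`, `pct_women`.
#' @export
reference_cohort_rates <- function() {
  path <- system.file("extdata", "reference_cohort_rates.csv",
                      package = "facedev", mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reconstruct per-subject flags from the reference cohort's printed rates
#'
#' Inverts the published per-sex percentages back into integer counts
#' (`round(pct / 100 * n_sex)`) and expands them into a per-subject flag
#' table suitable for [contingency_table()] and [report_tables()]. This is
#' exact because the printed percentages are one-decimal roundings of
#' counts over 19 and 41.
#'
#' @param rates data.frame as returned by [reference_cohort_rates()].
#' @param n_men,n_women cohort sizes the percentages refer to.
#' @return data.frame with columns `subject_id`, `sex`, `region`, `flag`.
#' @export
reconstruct_reference_flags <- function(rates = reference_cohort_rates(),
                                        n_men = 19, n_women = 41) {
  men_flagged <- round(rates$pct_men / 100 * n_men)
  women_flagged <- round(rates$pct_women / 100 * n_women)
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    data.frame(
      subject_id = c(sprintf("M%02d", seq_len(n_men)),
                     sprintf("F%02d", seq_len(n_women))),
      sex = c(rep("M", n_men), rep("F", n_women)),
      region = rates$region[i],
      flag = c(seq_len(n_men) <= men_flagged[i],
               seq_len(n_women) <= women_flagged[i]))
  })
  do.call(rbind, rows)
}
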