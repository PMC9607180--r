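# Regional aggregation of the deviation field and the clinical interval
# scale. The relevance rule is strict: a deviation is clinically relevant
# when it is GREATER than 3 mm, so the interval boundaries are half-open
# downward: {0}, (0, 1], (1, 3], (3, Inf).

clinical_intervals <- function() {
  data.frame(
    label = c("0", "0-1", "1-3", "3+"),
    approximation = c(0, 0.5, 2, 4),
    explanation = c(
      "clinically irrelevant",
      "clinically irrelevant",
      "clinically relevant only in extreme detail evaluations for micro-aesthetics",
      "clinically relevant, questioning suitability of this method"),
    stringsAsFactors = FALSE)
}

#' Classify a deviation into the clinical interval scale
#'
#' Maps an absolute deviation (mm) onto the four-interval clinical scale:
#' exactly 0 -> "0" (approximation 0), (0,1] -> "0-1" (0.5), (1,3] ->
#' "1-3" (2), above 3 -> "3+" (4). The 3 mm boundary itself is NOT
#' clinically relevant ("greater than 3 mm" is strict).
#'
#' @param d numeric vector of deviations, mm; must be finite and >= 0.
#' @return data.frame with columns `label`, `approximation`, `explanation`.
#' @export
classify_deviation <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("deviations must be finite and nonnegative")
  iv <- clinical_intervals()
  idx <- ifelse(d == 0, 1L, ifelse(d <= 1, 2L, ifelse(d <= 3, 3L, 4L)))
  out <- iv[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a deviation field over the facial-region atlas
#'
#' One row per atlas region with the count of valid vertices and the
#' median, 95th percentile and maximum of the raw (uncapped) deviation.
#' The clinical class and the relevance flag come from the 95th percentile:
#' `max` is spike-sensitive and `mean` dilutes focal defects, so the 95th
#' percentile is the robust region statistic (configurable via `prob`).
#' Regions with fewer than `min_vertices` valid vertices are marked
#' unassessable (all statistics NA, `flag` NA) — typically regions lost to
#' crop artifacts — and are excluded pairwise from cohort statistics.
#'
#' @param field a [absolute_deviation()] result on the scan mesh.
#' @param atlas per-scan-vertex region labels (NA = unassigned).
#' @param prob quantile used as the region statistic (default 0.95).
#' @param min_vertices minimum valid vertices for assessability (default 20).
#' @return data.frame with columns `region`, `n_valid`, `median_mm`,
#'   `p95_mm`, `max_mm`, `class`, `flag_over_3mm`, `assessable`.
#' @export
summarize_regions <- function(field, atlas, prob = 0.95, min_vertices = 20) {
  if (length(atlas) != length(field$raw))
    stop("atlas and deviation field refer to different vertex counts")
  regions <- atlas_region_names()
  out <- data.frame(region = regions, n_valid = 0L, median_mm = NA_real_,
                    p95_mm = NA_real_, max_mm = NA_real_,
                    class = NA_character_, flag_over_3mm = NA,
                    assessable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    sel <- !is.na(atlas) & atlas == regions[i] & field$valid
    out$n_valid[i] <- sum(sel)
    if (sum(sel) < min_vertices) next
    d <- field$raw[sel]
    p <- quantile(d, prob, names = FALSE, type = 7)
    out$median_mm[i] <- median(d)
    out$p95_mm[i] <- p
    out$max_mm[i] <- max(d)
    out$class[i] <- classify_deviation(p)$label
    out$flag_over_3mm[i] <- p > 3
    out$assessable[i] <- TRUE
  }
  out
}

#' Apply the cohort selection criteria
#'
#' Keeps a subject iff the two scans were taken less than 7 days apart
#' (guarding against BMI/soft-tissue change), the facial expression was
#' neutral, and the reference scan is free of extensive artifacts. The
#' exclusion log lists every violated criterion per excluded subject.
#'
#' @param manifest data.frame with columns `subject_id`, `interval_days`,
#'   `expression_ok`, `artifact_ok` (see [cohort_manifest()]).
#' @return list with `included` (manifest subset) and `exclusions`
#'   (data.frame `subject_id`, `reasons` — semicolon-separated).
#' @export
filter_cohort <- function(manifest) {
  need <- c("subject_id", "interval_days", "expression_ok", "artifact_ok")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  reasons <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- character(0)
    if (!(manifest$interval_days[i] < 7)) r <- c(r, "interval")
    if (!manifest$expression_ok[i]) r <- c(r, "expression")
    if (!manifest$artifact_ok[i]) r <- c(r, "artifact")
    r
  })
  keep <- lengths(reasons) == 0
  list(included = manifest[keep, , drop = FALSE],
       exclusions = data.frame(
         subject_id = manifest$subject_id[!keep],
         reasons = vapply(reasons[!keep], paste, "", collapse = ";"),
         stringsAsFactors = FALSE))
}
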