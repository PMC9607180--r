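# Cohort-level statistics: sex-stratified contingency summaries with a
# self-contained two-sided Fisher's exact test (the expected frequencies
# per region are low, so asymptotic tests are inappropriate), and a
# Friedman rank comparison of the lateral-profile sites. Both tests are
# dual-routed in the test suite against stats::fisher.test /
# stats::friedman.test and direct enumeration oracles.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact min-likelihood two-sided p-value: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table (with a 1e-7 relative slack at ties —
#' the dominant convention in major statistics packages). Computation is in
#' log space via `lchoose`, so large counts are safe.
#'
#' @param a,b,c,d nonnegative integer cell counts, laid out as
#'   rows = groups (e.g. men / women), columns = flagged / not flagged:
#'   `a` men flagged, `b` men not flagged, `c` women flagged, `d` women not.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  n <- a + b + c + d
  if (n == 0) stop("all margins are zero")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  klo <- max(0, c1 - r2)
  khi <- min(r1, c1)
  k <- klo:khi
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  lobs <- logp[k == a]
  min(1, sum(exp(logp[logp <= lobs + log1p(1e-7)])))
}

#' Per-region 2x2 contingency summaries by sex
#'
#' Builds, for every region, the men/women x flagged/not-flagged table from
#' per-subject flags, together with the percentages used for reporting
#' (rounded to one decimal; the raw fractions are retained) and the
#' two-sided Fisher p-value. Subjects whose flag is NA for a region
#' (unassessable, e.g. crop artifacts) are excluded pairwise for that
#' region only.
#'
#' @param flags data.frame with columns `subject_id`, `sex` ("M"/"F"),
#'   `region`, `flag` (logical, NA = unassessable).
#' @return data.frame, one row per region: counts `a`,`b`,`c`,`d`,
#'   rounded percentages `pct_men`, `pct_women`, `pct_total`, raw fractions
#'   `frac_men`, `frac_women`, `frac_total`, and `fisher_p`.
#' @export
contingency_table <- function(flags) {
  need <- c("subject_id", "sex", "region", "flag")
  if (!all(need %in% names(flags)))
    stop("flags must have columns: ", paste(need, collapse = ", "))
  if (!all(flags$sex %in% c("M", "F")))
    stop("unknown sex label(s): ", paste(setdiff(unique(flags$sex), c("M", "F")),
                                         collapse = ", "))
  regions <- unique(flags$region)
  rows <- lapply(regions, function(r) {
    sub <- flags[flags$region == r & !is.na(flags$flag), , drop = FALSE]
    a <- sum(sub$sex == "M" & sub$flag)
    b <- sum(sub$sex == "M" & !sub$flag)
    cc <- sum(sub$sex == "F" & sub$flag)
    d <- sum(sub$sex == "F" & !sub$flag)
    fm <- if (a + b > 0) a / (a + b) else NA_real_
    fw <- if (cc + d > 0) cc / (cc + d) else NA_real_
    ft <- if (a + b + cc + d > 0) (a + cc) / (a + b + cc + d) else NA_real_
    data.frame(region = r, a = a, b = b, c = cc, d = d,
               pct_men = round(100 * fm, 1), pct_women = round(100 * fw, 1),
               pct_total = round(100 * ft, 1),
               frac_men = fm, frac_women = fw, frac_total = ft,
               fisher_p = if (a + b + cc + d > 0)
                 fisher_exact_two_sided(a, b, cc, d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Friedman rank test over k related measurement sites
#'
#' Within-subject average ranks (ties get mean ranks) with the standard
#' tie-corrected chi-square statistic on k-1 degrees of freedom. Subjects
#' with any missing (unassessable) cell are dropped listwise, since the
#' test requires complete blocks; the number dropped is reported.
#'
#' @param mat numeric matrix, subjects x k sites (k >= 3), of per-subject
#'   per-site deviation values. Higher value = higher rank.
#' @return object of class `friedman_result`: `mean_ranks` (named by
#'   column), `statistic`, `df`, `p_value`, `n`, `n_dropped`.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 3) stop("need at least 3 sites (columns)")
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("friedman_test: dropping %d incomplete subject(s)", n_dropped))
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 complete subjects")
  r <- t(apply(mat, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- A - C
  stat <- if (den <= 0) 0 else num / den
  p <- if (den <= 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(mean_ranks = structure(Rj / n, names = colnames(mat)),
                 statistic = stat, df = k - 1, p_value = p,
                 n = n, n_dropped = n_dropped),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi-squared %.4f, df %d, p %.4g (n = %d%s)\n",
              x$statistic, x$df, x$p_value, x$n,
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  mr <- sort(x$mean_ranks)
  for (nm in names(mr)) cat(sprintf("  %-28s %.2f\n", nm, mr[nm]))
  invisible(x)
}

#' The seven lateral-profile sites
#'
#' The midline/profile locations visible from the lateral view that enter
#' the Friedman comparison: frontal region, nasal tip, philtrum, vermilion
#' border, oral fissure, mentolabial sulcus, mental region (atlas names).
#' @export
lateral_sites <- function() {
  c("frontal region", "apex of nose", "philtrum", "vermilion border",
    "oral fissure", "sulcus mentolabialis", "mental region")
}

#' Cohort report tables: contingency summary and Friedman ranks
#'
#' Builds the two cohort-level result tables: the per-region sex-stratified
#' percentage table with two-sided Fisher p-values and significance calls
#' at `alpha` (no multiple-testing correction by default, mirroring
#' unadjusted reporting; set `holm = TRUE` to adjust), and — when
#' per-subject region values are supplied — the Friedman mean-rank table
#' over the seven lateral sites, ordered from lowest to highest rank.
#'
#' @param flags per-subject flag table (see [contingency_table()]).
#' @param values optional data.frame `subject_id`, `region`, `value`
#'   (per-subject per-region deviation statistic, mm) for the Friedman
#'   block.
#' @param alpha significance level (default 0.05).
#' @param holm apply Holm adjustment across regions (default FALSE).
#' @return list with `contingency` (data.frame) and, if `values` given,
#'   `friedman` (data.frame `location`, `mean_rank`, ascending) plus
#'   `friedman_result`.
#' @export
report_tables <- function(flags, values = NULL, alpha = 0.05, holm = FALSE) {
  ct <- contingency_table(flags)
  p <- ct$fisher_p
  if (holm) p <- stats::p.adjust(p, "holm")
  ct$significant <- !is.na(p) & p < alpha
  out <- list(contingency = ct)
  if (!is.null(values)) {
    sites <- intersect(lateral_sites(), unique(values$region))
    if (length(sites) >= 3) {
      subj <- unique(values$subject_id)
      m <- matrix(NA_real_, length(subj), length(sites),
                  dimnames = list(subj, sites))
      idx <- cbind(match(values$subject_id, subj), match(values$region, sites))
      ok <- !is.na(idx[, 2])
      m[idx[ok, , drop = FALSE]] <- values$value[ok]
      fr <- friedman_test(m)
      mr <- sort(fr$mean_ranks)
      out$friedman <- data.frame(location = names(mr), mean_rank = as.numeric(mr),
                                 stringsAsFactors = FALSE)
      out$friedman_result <- fr
    }
  }
  out
}
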