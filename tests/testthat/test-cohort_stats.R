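# contingency tables, Fisher's exact test, Friedman rank test, report tables

test_that("contingency percentages reproduce the reference cohort's printed totals", {
  flags <- reconstruct_reference_flags()
  ct <- contingency_table(flags)
  pick <- function(r, col) ct[[col]][ct$region == r]
  # counts reconstructed from printed per-sex rates over 19 men / 41 women
  expect_equal(pick("orbital region R", "a"), 17)  # 89.5% of 19
  expect_equal(pick("orbital region R", "c"), 24)  # 58.5% of 41
  expect_equal(pick("orbital region R", "pct_total"), 68.3)
  expect_equal(pick("apex of nose", "pct_total"), 6.7)
  expect_equal(pick("frontal region", "pct_men"), 47.4)
  expect_equal(pick("philtrum", "pct_total"), 0)
  # zero flags give 0% everywhere and p = 1
  z <- contingency_table(data.frame(subject_id = c("a", "b"), sex = c("M", "F"),
                                    region = "philtrum", flag = FALSE))
  expect_equal(z$pct_total, 0)
  expect_equal(z$fisher_p, 1)
  expect_error(contingency_table(data.frame(subject_id = "a", sex = "X",
                                            region = "r", flag = TRUE)),
               "unknown sex")
})

test_that("fisher_exact_two_sided: degenerate margins, symmetry, known value", {
  # single attainable table
  expect_equal(fisher_exact_two_sided(0, 19, 0, 41), 1.0)
  # simultaneous row+column swap leaves p unchanged
  expect_equal(fisher_exact_two_sided(9, 10, 7, 34),
               fisher_exact_two_sided(34, 7, 10, 9))
  # independent oracle: stats::fisher.test uses the same min-likelihood rule
  expect_equal(fisher_exact_two_sided(9, 10, 7, 34),
               stats::fisher.test(matrix(c(9, 7, 10, 34), 2))$p.value,
               tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "all margins")
})

test_that("fisher p equals hypergeometric enumeration over random tables", {
  withr::local_seed(19)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    a_c <- sample(0:n, 1)            # column margin (flagged)
    r1 <- sample(0:n, 1)             # row margin (men)
    k <- max(0, a_c - (n - r1)):min(r1, a_c)
    a <- sample(rep(k, 2), 1)
    tab <- c(a, r1 - a, a_c - a, n - r1 - (a_c - a))
    # enumeration oracle via dhyper
    pk <- dhyper(k, r1, n - r1, a_c)
    oracle <- sum(pk[pk <= pk[k == a] * (1 + 1e-7)])
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
                 min(1, oracle), tolerance = 1e-12)
  }
})

test_that("friedman_test: identical columns, rank arithmetic, oracle agreement", {
  # all columns identical: statistic 0, p 1, mean ranks (k+1)/2
  m <- matrix(rep(runif(10), 7), ncol = 7)
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)
  expect_equal(unname(fr$mean_ranks), rep(4, 7))
  # mean ranks always sum to k(k+1)/2 = 28 for k = 7
  withr::local_seed(8)
  m2 <- matrix(runif(70), ncol = 7)
  expect_equal(sum(friedman_test(m2)$mean_ranks), 28)
  # 4x3 toy matrix: statistic from the rank-definition oracle by hand
  toy <- rbind(c(1.2, 2.5, 0.8), c(3.1, 2.2, 1.0), c(0.5, 1.5, 2.5),
               c(2.0, 3.0, 1.0))
  r <- t(apply(toy, 1, rank))
  n <- 4; k <- 3
  oracle <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  fr2 <- friedman_test(toy)
  expect_equal(fr2$statistic, oracle)
  # and against stats::friedman.test (tie-free data)
  expect_equal(fr2$statistic,
               unname(stats::friedman.test(toy)$statistic))
  expect_equal(fr2$p_value, stats::friedman.test(toy)$p.value)
  expect_error(friedman_test(toy[, 1:2]), "at least 3")
})

test_that("friedman_test matches stats::friedman.test with ties and drops incomplete rows", {
  withr::local_seed(12)
  m <- matrix(sample(1:4, 60, replace = TRUE), ncol = 5)  # heavy ties
  fr <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fr$p_value, ref$p.value, tolerance = 1e-12)
  # statistic invariant under strictly monotone per-subject transforms
  m2 <- exp(m) + rep(runif(nrow(m)), ncol(m))  # row-wise shift, monotone
  expect_equal(friedman_test(m2)$statistic, fr$statistic)
  # listwise deletion of incomplete subjects
  m3 <- rbind(m, c(NA, 1, 2, 3, 4))
  expect_message(fr3 <- friedman_test(m3), "dropping 1")
  expect_equal(fr3$statistic, fr$statistic)
})

test_that("report_tables: significance calls, Friedman ordering, reference frontal/orbital", {
  flags <- reconstruct_reference_flags()
  tabs <- report_tables(flags)
  ct <- tabs$contingency
  # the reconstructed counts give p < 0.05 exactly for the frontal and right
  # orbital regions under the min-likelihood two-sided rule
  sig <- ct$region[ct$significant]
  expect_true(all(c("frontal region", "orbital region R") %in% sig))
  expect_false("philtrum" %in% sig)
  # Friedman block ordered ascending by mean rank, over the 7 lateral sites
  values <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:10), each = 7),
    region = rep(lateral_sites(), 10),
    value = runif(70, 0, 3))
  tabs2 <- report_tables(flags, values)
  expect_equal(nrow(tabs2$friedman), 7)
  expect_true(all(diff(tabs2$friedman$mean_rank) >= 0))
  expect_equal(sum(tabs2$friedman$mean_rank), 28)
  # single-region cohort: one-row table
  one <- contingency_table(flags[flags$region == "vermilion", ])
  expect_equal(nrow(one), 1)
})

test_that("null cohorts keep the per-region Fisher type-I rate at or below nominal", {
  # flags simulated at the ground-truth level (no sex effect); 100 replicate
  # cohorts of 19/41 — the full 200-replicate version runs in the acceptance
  # suite
  withr::local_seed(21)
  rates <- data.frame(region = c("orbital region R", "oral fissure"),
                      p_men = c(0.5, 0.3), p_women = c(0.5, 0.3))
  rej <- matrix(FALSE, 100, 2)
  for (b in 1:100) {
    flags <- do.call(rbind, lapply(1:2, function(j) data.frame(
      subject_id = sprintf("s%02d", 1:60),
      sex = c(rep("M", 19), rep("F", 41)),
      region = rates$region[j],
      flag = runif(60) < rates$p_men[j])))
    ct <- contingency_table(flags)
    rej[b, ] <- ct$fisher_p < 0.05
  }
  expect_true(all(colMeans(rej) <= 0.08))
})
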