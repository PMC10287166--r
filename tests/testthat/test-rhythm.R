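diel_hours <- function(n_days = 4, interval = 4, reps = 2, start = 6)
  rep(start + seq(0, n_days * 24 - interval, by = interval), each = reps)

test_that("umbrella statistic hits its extremes for monotone and constant series", {
  tod <- rep(c(0, 4, 8, 12, 16, 20), each = 2)
  # perfect rise to 8 then fall: all cross-group pairs concordant
  v <- rep(c(1, 2, 3, 2.5, 1.5, 0.5), each = 2)
  s <- umbrella_statistic(v, tod, peak_phase = 8)
  expect_equal(as.numeric(s), attr(s, "max"))
  # constant series: every pair ties -> exactly half the maximum
  s0 <- umbrella_statistic(rep(1, 12), tod, peak_phase = 8)
  expect_equal(as.numeric(s0), attr(s0, "max") / 2)
  expect_error(umbrella_statistic(1:4, c(0, 0, 12, 12), 0), "3 distinct")
})

test_that("umbrella statistic equals exhaustive pair enumeration on small cases", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(3:4, 1)
    phases <- sort(sample(seq(0, 20, by = 4), k))
    nper <- sample(1:3, k, replace = TRUE)
    tod <- rep(phases, nper)
    v <- round(runif(length(tod), 0, 4) * 2) / 2   # forces some ties
    peak <- sample(phases, 1)
    expect_equal(as.numeric(umbrella_statistic(v, tod, peak)),
                 oracle_umbrella(v, tod, peak))
  }
})

test_that("a noiseless cosinor attains the minimal p at its true phase", {
  hours <- diel_hours()
  v <- exp(2 * cos(2 * pi * (hours - 10) / 24))
  r <- rain_like_test(tibble::tibble(hours = hours, value = v),
                      n_perm = 999, seed = 5)
  expect_equal(r$p_value, 1 / 1000)
  expect_equal(r$best_phase, 10)
  expect_equal(r$statistic, r$max_statistic)
})

test_that("the permutation p-value ignores observation order", {
  hours <- diel_hours()
  set.seed(6)
  v <- rlnorm(length(hours))
  s1 <- tibble::tibble(hours = hours, value = v)
  perm <- sample(nrow(s1))
  r1 <- rain_like_test(s1, n_perm = 999, seed = 42)
  r2 <- rain_like_test(s1[perm, ], n_perm = 999, seed = 42)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$best_phase, r2$best_phase)
})

test_that("short or degenerate series are rejected", {
  short <- tibble::tibble(hours = seq(0, 20, 4), value = 1:6)
  expect_error(rain_like_test(short, n_perm = 999), "2 full periods")
  expect_error(rain_like_test(tibble::tibble(hours = 1:100, value = 1),
                              n_perm = 100), "n_perm")
})

test_that("bh q-values reproduce the step-up formula and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"))   # independent oracle
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("glance/tidy expose the fitted test and detect_rhythms flags signals", {
  hours <- diel_hours()
  set.seed(9)
  sig <- exp(2 * cos(2 * pi * (hours - 6) / 24) + rnorm(length(hours), 0, 0.3))
  nul <- rlnorm(length(hours))
  series <- dplyr::bind_rows(
    tibble::tibble(contig_id = "sig", hours = hours, value = sig),
    tibble::tibble(contig_id = "null", hours = hours, value = nul))
  res <- detect_rhythms(series, n_perm = 999, seed = 2)
  expect_true(res$significant[res$contig_id == "sig"])
  expect_equal(res$best_phase[res$contig_id == "sig"], 6)
  expect_true(all(res$q_value >= res$p_value))

  r <- rain_like_test(series[series$contig_id == "sig", ],
                      n_perm = 999, seed = 2)
  g <- glance(r)
  expect_identical(names(g), c("statistic", "max_statistic", "best_phase",
                               "p_value", "n_perm"))
  expect_equal(nrow(tidy(r)), length(r$phases))
})

test_that("phase summary counts significant contigs by modal phase", {
  res <- tibble::tibble(contig_id = paste0("c", 1:5),
                        statistic = 1, max_statistic = 2,
                        best_phase = c(6, 6, 10, 14, 6),
                        p_value = c(0.001, 0.002, 0.2, 0.3, 0.004),
                        q_value = c(0.01, 0.01, 0.4, 0.4, 0.01),
                        significant = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  ph <- summarize_phases(res)
  expect_equal(ph$n_significant[ph$phase == 6], 3L)
  expect_equal(sum(ph$n_significant), sum(res$significant))
  expect_equal(attr(ph, "n_tested"), 5L)

  none <- dplyr::mutate(res, q_value = 1, significant = FALSE)
  ph0 <- summarize_phases(none)
  expect_true(all(ph0$n_significant == 0L))
  expect_equal(attr(ph0, "n_tested"), 5L)
})
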