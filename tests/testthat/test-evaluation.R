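test_that("KM without censoring equals one minus the empirical CDF", {
  set.seed(2)
  time <- c(rexp(40, 1e-3), rexp(30, 2e-3))
  groups <- rep(c("a", "b"), c(40, 30))
  km <- km_logrank(time, rep(1, 70), groups)
  for (g in c("a", "b")) {
    cur <- km$curves[km$curves$group == g, ]
    tg <- time[groups == g]
    expect_equal(cur$surv, 1 - ecdf(tg)(cur$time), tolerance = 1e-12)
    expect_true(all(diff(cur$surv) <= 0))
    expect_true(all(diff(cur$n_risk) <= 0))
  }
})

test_that("log-rank is null on duplicated groups and matches the O-E oracle", {
  time <- c(5, 8, 12, 20, 33)
  km <- km_logrank(rep(time, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.999)
  # 6-patient fixture worked through the observed-minus-expected sums
  t6 <- c(1, 2, 3, 4, 5, 6)
  e6 <- c(1, 1, 1, 1, 0, 1)
  g6 <- c("a", "b", "a", "b", "a", "b")
  km6 <- km_logrank(t6, e6, g6)
  expect_equal(km6$chisq, logrank_oracle(t6, e6, g6), tolerance = 1e-10)
  expect_error(km_logrank(t6, e6, rep("a", 6)), "two groups")
})

test_that("survival curves start at 1", {
  km <- km_logrank(c(3, 6, 9, 12), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  for (g in c("a", "b"))
    expect_true(all(km$curves$surv[km$curves$group == g] <= 1))
})

test_that("stage codes encode ordinally with unknowns as NA", {
  expect_identical(encode_stage(c("T0", "T2", "T4", "TX", NA, "N3", "M1")),
                   c(0L, 2L, 4L, NA, NA, 3L, 1L))
})

test_that("the Cox fit matches the analytic three-patient maximiser", {
  # times 1 < 2 < 3 all events, covariate (1, 0, 1): the partial likelihood
  # is exp(b)/(2 exp(b) + 1) * 1/(1 + exp(b)), maximised directly
  pll <- function(b) b - log(2 * exp(b) + 1) - log(1 + exp(b))
  b_star <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  rep_ <- cox_model(time = c(1, 2, 3), event = c(1, 1, 1),
                    covariates = data.frame(x = c(1, 0, 1)))
  expect_equal(log(rep_$hr), b_star, tolerance = 1e-5)
  expect_true(rep_$ci_lower <= rep_$hr & rep_$hr <= rep_$ci_upper)
})

test_that("Cox p-values are uniform under the null", {
  set.seed(18)
  pvals <- replicate(200, {
    n <- 50
    cox_model(rexp(n, 1e-3), rbinom(n, 1, 0.8),
              data.frame(x = rnorm(n)))$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the combined report gates the multivariate model on univariate significance", {
  set.seed(19)
  n <- 400
  risk <- rnorm(n)
  noise <- rnorm(n)  # unrelated covariate, mimicking a null clinical factor
  time <- rexp(n, 1e-3 * exp(0.8 * risk))
  event <- rbinom(n, 1, 0.85)
  rep_ <- cox_report(time, event, data.frame(risk = risk, noise = noise))
  uni <- rep_[rep_$model == "univariate", ]
  multi <- rep_[rep_$model == "multivariate", ]
  expect_identical(sort(uni$covariate), c("noise", "risk"))
  expect_identical(multi$covariate, "risk")
  rep_all <- cox_report(time, event,
                        data.frame(risk = risk, noise = noise),
                        multivariate = "all")
  expect_identical(sort(rep_all$covariate[rep_all$model == "multivariate"]),
                   c("noise", "risk"))
  expect_error(cox_model(time, event, data.frame(k = rep(1, n))),
               "constant")
})

test_that("a perfectly ranking score has AUC 1 at every horizon", {
  time <- seq(100, 1000, by = 100)
  scores <- -time  # higher score = earlier event
  out <- time_dependent_auc(scores, time, rep(1, 10),
                            eval_times = c(250, 550, 850))
  expect_equal(out$auc, rep(1, 3))
})

test_that("IPCW AUC equals brute-force concordance when censoring is absent", {
  set.seed(20)
  n <- 300
  scores <- rnorm(n)
  time <- rexp(n, 1e-3 * exp(0.4 * scores))
  horizons <- quantile(time, c(0.25, 0.5, 0.75))
  out <- time_dependent_auc(scores, time, rep(1, n), eval_times = horizons)
  for (i in seq_along(horizons)) {
    t0 <- horizons[i]
    cs <- scores[time <= t0]
    ct <- scores[time > t0]
    conc <- (sum(outer(cs, ct, ">")) + 0.5 * sum(outer(cs, ct, "=="))) /
      (length(cs) * length(ct))
    expect_equal(out$auc[i], conc, tolerance = 1e-12)
  }
})

test_that("horizons without cases or controls are omitted with a warning", {
  time <- c(100, 200, 300)
  expect_warning(out <- time_dependent_auc(c(3, 2, 1), time, c(1, 1, 1),
                                           eval_times = c(50, 150)),
                 "omitted")
  expect_equal(nrow(out), 1)
  expect_equal(out$eval_time, 150)
})

test_that("years-scale horizons convert to days", {
  time <- c(100, 500, 3000)
  out <- time_dependent_auc(c(3, 2, 1), time, c(1, 1, 0),
                            eval_times = 1, eval_in_years = TRUE)
  expect_equal(out$eval_time, 1)
  expect_equal(out$n_cases, 1)  # only the 100-day event precedes 365.25 d
})

test_that("segment means discretise at the +/-0.2 boundaries", {
  expect_identical(discretize_segment_mean(c(-0.3, 0.25, 0.2, -0.2, 0)),
                   c(-1L, 1L, 0L, 0L, 0L))
  expect_error(discretize_segment_mean(NaN), "finite")
  # partition: every value receives exactly one call
  set.seed(30)
  x <- runif(500, -1.5, 1.5)
  calls <- discretize_segment_mean(x)
  expect_true(all(calls %in% c(-1L, 0L, 1L)))
  expect_identical(calls == -1L, x < -0.2)
  expect_identical(calls == 1L, x > 0.2)
})

test_that("CNV frequency comparison flags planted group differences and skips degenerate genes", {
  groups <- setNames(rep(c("high", "low"), each = 500),
                     sprintf("s%04d", 1:1000))
  seg <- simulate_segment_means(groups,
                                weights = list(high = c(0.05, 0.55, 0.40),
                                               low = c(0.05, 0.85, 0.10)),
                                n_genes = 4, seed = 41)
  out <- cnv_frequency_compare(seg, groups)
  expect_true(all(out$different))
  expect_true(all(out$freq_high > out$freq_low))
  # matched mixtures: differences are at chance level
  seg0 <- simulate_segment_means(groups,
                                 weights = list(high = c(0.1, 0.8, 0.1),
                                                low = c(0.1, 0.8, 0.1)),
                                 n_genes = 4, seed = 42)
  out0 <- suppressWarnings(cnv_frequency_compare(seg0, groups))
  expect_true(all(out0$p > 0.01))
  # an all-neutral gene is skipped
  seg_n <- simulate_segment_means(groups,
                                  weights = list(high = c(0, 1, 0),
                                                 low = c(0, 1, 0)),
                                  n_genes = 1, seed = 43)
  expect_warning(out_n <- cnv_frequency_compare(seg_n, groups),
                 "no variation")
  expect_null(out_n)
})

test_that("group difference reproduces the exact rank-sum p and handles degeneracy", {
  gd <- group_difference(c(1, 2, 3, 4, 5, 6),
                         rep(c("a", "b"), each = 3))
  expect_equal(gd$p_value, 0.1)
  gd_same <- group_difference(rep(c(1, 2, 3), 2),
                              rep(c("a", "b"), each = 3))
  expect_gt(gd_same$p_value, 0.99)
  expect_warning(gd_tied <- group_difference(rep(7, 10),
                                             rep(c("a", "b"), 5)),
                 "tied")
  expect_equal(gd_tied$p_value, 1)
  set.seed(44)
  big <- group_difference(c(rnorm(200), rnorm(200, 1)),
                          rep(c("a", "b"), each = 200))
  expect_lt(big$p_value, 0.001)
})
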