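test_that("risk scores are the coefficient-weighted indicator sums", {
  model <- load_signature_fixture()
  expect_equal(compute_risk_score(rep(0, 37), model), 0)
  one_hot <- function(id) {
    v <- rep(0, 37)
    v[pair_ids(model$pairs) == id] <- 1
    v
  }
  expect_equal(compute_risk_score(one_hot("FGF9|MICB"), model), 0.2288)
  expect_equal(compute_risk_score(one_hot("ROBO3|ESM1"), model), -0.6215)
  # independently computed sum of the 37 published coefficients
  expect_equal(compute_risk_score(rep(1, 37), model), 0.6427,
               tolerance = 1e-12)
  expect_error(compute_risk_score(rep(0, 36), model), "length")
})

test_that("risk scoring is linear in single-indicator flips", {
  model <- load_signature_fixture()
  set.seed(4)
  x <- rbinom(37, 1, 0.5)
  for (k in sample(37, 5)) {
    y <- x
    y[k] <- 1 - x[k]
    expect_equal(compute_risk_score(y, model) - compute_risk_score(x, model),
                 (1 - 2 * x[k]) * model$coefficients[k])
  }
})

test_that("an infinite penalty empties the model and zero penalty matches direct maximisation", {
  set.seed(6)
  n <- 60
  ind <- rbinom(n, 1, 0.5)
  time <- rexp(n, 1e-3 * exp(0.9 * ind))  # continuous: no ties
  cl <- make_clinical(time, event = rep(1, n))
  values <- matrix(as.integer(ind), nrow = 1,
                   dimnames = list("A|B", cl$sample_id))
  irgp <- make_irgp(values)
  empty <- fit_l1_cox(irgp, cl, lambda = 1e6)
  expect_length(empty$model, 0)
  fit0 <- fit_l1_cox(irgp, cl, lambda = 0)
  # oracle: direct maximisation of the (tie-free) Cox partial log-likelihood
  pll <- function(beta) {
    ord <- order(time)
    x <- ind[ord]
    sum(vapply(seq_len(n), function(i)
      beta * x[i] - log(sum(exp(beta * x[i:n]))), numeric(1)))
  }
  beta_hat <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit0$model$coefficients, beta_hat, tolerance = 1e-4)
})

test_that("cross-validated fits are seeded and report their diagnostics", {
  res <- simulate_and_fit(seed = 51,
                          simulation_params(n_genes = 30, n_tumor = 150,
                                            n_normal = 40,
                                            n_signal_pairs = 5, seed = 51))
  d <- res$fit$diagnostics
  expect_true(d$lambda_chosen %in% d$lambda)
  expect_equal(length(d$cvm), length(d$lambda))
  expect_gt(length(res$fit$model), 0)
  refit <- fit_l1_cox(subset_pairs(res$irgp, res$screen$candidates),
                      res$clinical, pipeline_config(random_seed = 51))
  expect_identical(refit$model, res$fit$model)
})

test_that("the optimal cutoff maximises the log-rank split", {
  # two distinct scores: the only candidate is their midpoint
  expect_equal(find_optimal_cutoff(c(rep(1, 5), rep(2, 5)),
                                   time = c(1:5, 11:15),
                                   event = rep(1, 10), min_group_frac = 0.2),
               1.5)
  # events cluster early among high scores: cutoff lands in (50, 51]
  scores <- 1:100
  time <- c(rep(1000, 50), rep(100, 50))
  event <- c(rep(0, 50), rep(1, 50))
  cut <- find_optimal_cutoff(scores, time, event)
  expect_gt(cut, 50)
  expect_lte(cut, 51)
  expect_error(find_optimal_cutoff(rep(1, 10), 1:10, rep(1, 10)),
               "distinct")
  expect_error(find_optimal_cutoff(1:10, 1:10, rep(0, 10)), "events")
  expect_error(find_optimal_cutoff(c(rep(1, 9), 2), 1:10, rep(1, 10),
                                   min_group_frac = 0.3),
               "group-size")
})

test_that("cutoff search equals the exhaustive midpoint-scan oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(30:200, 1)
    scores <- rnorm(n)
    time <- rexp(n, 1e-3 * exp(0.5 * scores))
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    u <- sort(unique(scores))
    mids <- (u[-1] + u[-length(u)]) / 2
    feas <- vapply(mids, function(ct)
      min(sum(scores > ct), sum(scores <= ct)) >= 0.1 * n, logical(1))
    stats <- vapply(mids[feas], function(ct)
      logrank_oracle(time, event, scores > ct), numeric(1))
    expect_equal(find_optimal_cutoff(scores, time, event),
                 mids[feas][which.max(stats)])
  }
})

test_that("classification is strict at the cutoff and monotone in it", {
  ra <- classify_patients(c(a = -0.14, b = -0.12, c = -0.13), -0.13)
  expect_identical(ra$group, c("low", "high", "low"))
  set.seed(9)
  scores <- rnorm(50)
  g1 <- classify_patients(scores, 0)$group
  g2 <- classify_patients(scores, 0.5)$group
  expect_false(any(g1 == "low" & g2 == "high"))
})

test_that("the published signature scores expression profiles as printed", {
  model <- load_signature_fixture()
  # all reference orderings satisfied -> every indicator 0 -> score 0,
  # which lies above the -0.13 cutoff, hence high risk
  vals <- signature_consistent_expr(model)
  ra <- apply_published_signature(expression_matrix(vals))
  expect_equal(ra$risk_score, 0)
  expect_identical(ra$group, "high")
  # only ROBO3 > ESM1 violated -> score -0.6215, low at cutoff -0.13
  vals2 <- signature_consistent_expr(model, reversed = "ROBO3|ESM1")
  ra2 <- apply_published_signature(expression_matrix(vals2))
  expect_equal(ra2$risk_score, -0.6215)
  expect_identical(ra2$group, "low")
})

test_that("published-signature assignments are invariant under monotone transforms", {
  model <- load_signature_fixture()
  genes <- unique(c(model$pairs$gene_a, model$pairs$gene_b))
  x <- rand_expr(seed = 77, genes = genes, n_samples = 8)
  base <- apply_published_signature(x)
  for (tr in list("affine", "log1p", function(v) 2 * v + 1)) {
    y <- apply_platform_transform(x, tr)
    expect_identical(apply_published_signature(y), base)
  }
})

test_that("missing signature genes are reported by name", {
  x <- rand_expr(seed = 1, genes = c("FGF9", "MICB"), n_samples = 2)
  expect_error(apply_published_signature(x), "ROBO3")
})
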