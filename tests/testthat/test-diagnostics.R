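test_that("Cochran's Q matches the published heterogeneity p-values", {
  fx <- mr_fixture("chinese")
  q_cn <- cochran_q(harmonize(fx$exposure, fx$outcome))
  expect_equal(q_cn$df, 4)
  expect_equal(q_cn$pval, 0.290, tolerance = 0.005)
  jp <- mr_fixture("japanese")
  q_jp <- cochran_q(harmonize(jp$exposure, jp$outcome))
  expect_equal(q_jp$pval, 0.641, tolerance = 0.005)
})

test_that("Q decomposes as the weighted residual sum of the IVW regression", {
  for (seed in 1:5) {
    sim <- simulate_mr(sim_config(k = 10, theta = 0.1,
                                  pleiotropy = "balanced"), seed = seed)
    set <- harmonize(sim$exposure, sim$outcome)
    q <- cochran_q(set)
    # independent path: residuals of the zero-intercept weighted regression
    fit <- lm(beta_y ~ beta_x - 1, data = set, weights = 1 / set$se_y^2)
    q_ref <- sum(stats::resid(fit)^2 / set$se_y^2)
    expect_equal(q$q_stat, q_ref, tolerance = 1e-10)
    expect_equal(q$pval, pchisq(q_ref, nrow(set) - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("identical ratios give zero heterogeneity", {
  set <- make_set(beta_x = c(0.02, 0.05, 0.1), beta_y = 2 * c(0.02, 0.05, 0.1))
  q <- cochran_q(set)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  expect_error(cochran_q(make_set(beta_x = 0.1, beta_y = 0.1)), ">= 2")
  # the second-order variant exists and differs once se_x matters
  fx <- mr_fixture("chinese")
  h <- harmonize(fx$exposure, fx$outcome)
  expect_false(isTRUE(all.equal(cochran_q(h)$q_stat,
                                cochran_q(h, "second_order")$q_stat)))
})

test_that("leave-one-out rows equal independent IVW fits on the reduced sets", {
  fx <- mr_fixture("chinese")
  set <- harmonize(fx$exposure, fx$outcome)
  loo <- leave_one_out(set)
  expect_equal(nrow(loo), 6)
  expect_equal(loo$omitted, c(set$snp_id, "(all)"))
  for (j in seq_len(nrow(set))) {
    ref <- mr_ivw(set[-j, , drop = FALSE])
    expect_equal(loo$beta[j], ref$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], ref$se, tolerance = 1e-12)
  }
  # no single omission is influential for this set
  expect_false(any(loo$influential))
})

test_that("two-SNP leave-one-out degrades to Wald ratios", {
  set <- make_set(beta_x = c(0.05, 0.1), beta_y = c(0.02, -0.03))
  loo <- leave_one_out(set)
  wr <- wald_ratios(set)
  expect_equal(loo$beta[1], wr$ratio[2])   # omitting SNP 1 leaves SNP 2
  expect_equal(loo$beta[2], wr$ratio[1])
  expect_equal(loo$se[1], wr$se_ratio[2])
})

test_that("an extreme outlier SNP is flagged as influential", {
  # seven consistent negative-ratio instruments plus one high-precision
  # outlier whose ratio sits far on the other side of the null: only the
  # outlier's omission drags the pooled estimate across zero
  set <- make_set(
    beta_x = rep(0.1, 8),
    beta_y = c(-0.048, -0.052, -0.050, -0.049, -0.051, -0.047, -0.053, 0.2),
    se_y = c(rep(0.02, 7), 0.005))
  loo <- leave_one_out(set)
  expect_true(loo$influential[8])
  expect_false(any(loo$influential[1:7]))
})

test_that("MR-PRESSO reproduces the published global p-values", {
  fx <- mr_fixture("chinese")
  pr <- mr_presso(harmonize(fx$exposure, fx$outcome), n_sim = 10000,
                  seed = 101)
  expect_lt(abs(pr$global_pval - 0.455), 0.03)
  expect_equal(length(pr$outliers), 0)
  expect_null(pr$distortion)
  jp <- mr_fixture("japanese")
  pr_jp <- mr_presso(harmonize(jp$exposure, jp$outcome), n_sim = 10000,
                     seed = 101)
  expect_lt(abs(pr_jp$global_pval - 0.802), 0.03)
})

test_that("MR-PRESSO is seed-reproducible with binomial Monte-Carlo spread", {
  fx <- mr_fixture("chinese")
  set <- harmonize(fx$exposure, fx$outcome)
  a <- mr_presso(set, n_sim = 2000, seed = 7)
  b <- mr_presso(set, n_sim = 2000, seed = 7)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$per_snp$pval, b$per_snp$pval)

  reps <- vapply(1:10, function(s)
    mr_presso(set, n_sim = 10000, seed = s)$global_pval, numeric(1))
  mc_se <- sqrt(mean(reps) * (1 - mean(reps)) / 10000)
  expect_lt(sd(reps), 5 * mc_se)     # no extra-binomial variation
  expect_gt(sd(reps), mc_se / 10)    # genuinely re-simulated
})

test_that("MR-PRESSO global p is roughly uniform under the null model", {
  pvals <- vapply(1:200, function(s) {
    sim <- simulate_mr(sim_config(k = 10, theta = 0.2), seed = 5000 + s)
    set <- harmonize(sim$exposure, sim$outcome)
    mr_presso(set, n_sim = 199, seed = s)$global_pval
  }, numeric(1))
  rejection <- mean(pvals < 0.05)
  expect_gte(rejection, 0.01)
  expect_lte(rejection, 0.12)
})

test_that("an injected pleiotropic outlier is detected and distortion reported", {
  sim <- simulate_mr_outliers(sim_config(k = 10, theta = 0.2),
                              n_outliers = 1, outlier_shift = 8 * 0.09,
                              seed = 31)
  set <- harmonize(sim$exposure, sim$outcome)
  pr <- mr_presso(set, n_sim = 2000, seed = 1)
  expect_equal(pr$outliers, sim$truth$snp_id[sim$truth$is_outlier])
  expect_lt(pr$global_pval, 0.05)
  expect_false(is.null(pr$distortion))
  expect_true(pr$distortion$pval > 0 && pr$distortion$pval <= 1)
  # the distortion block is internally consistent with the two IVW fits
  expect_equal(pr$distortion$distortion,
               pr$distortion$beta_full - pr$distortion$beta_outlier_removed,
               tolerance = 1e-12)
  clean <- set[!set$snp_id %in% pr$outliers, , drop = FALSE]
  expect_equal(pr$distortion$beta_outlier_removed, mr_ivw(clean)$beta,
               tolerance = 1e-12)
  expect_error(mr_presso(make_set(beta_x = c(0.1, 0.2, 0.3),
                                  beta_y = c(0, 0, 0))),
               "too few SNPs")
})

test_that("funnel coordinates pair each ratio with its precision", {
  fx <- mr_fixture("chinese")
  set <- harmonize(fx$exposure, fx$outcome)
  fd <- funnel_data(set)
  expect_equal(nrow(fd), 5)
  wr <- wald_ratios(set)
  expect_equal(fd$precision, 1 / wr$se_ratio)
  expect_equal(attr(fd, "reference"), mr_ivw(set)$beta)
  expect_equal(attr(fd, "reference"), log(0.510), tolerance = 0.02)

  one <- funnel_data(make_set(beta_x = 0.1, beta_y = 0.05))
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "reference"), 0.5)

  # ratios mirrored about theta with equal precisions: zero mean deviation
  sym <- make_set(beta_x = rep(0.1, 4),
                  beta_y = 0.1 * c(0.3 - 0.2, 0.3 + 0.2, 0.3 - 0.1, 0.3 + 0.1))
  fs <- funnel_data(sym)
  expect_equal(mean(fs$ratio - attr(fs, "reference")), 0, tolerance = 1e-12)
})

test_that("forest data and the sensitivity bundle assemble all components", {
  fx <- mr_fixture("japanese")
  set <- harmonize(fx$exposure, fx$outcome)
  res <- mr_all(set, seed = 1)
  fo <- forest_data(set, res)
  expect_equal(sum(fo$kind == "snp"), 4)
  expect_equal(sum(fo$kind == "summary"), 3)
  expect_true(all(fo$ci_low < fo$ci_high))

  rep <- sensitivity_report(set, results = res, n_sim = 500, seed = 3)
  expect_s3_class(rep$heterogeneity, "mr_heterogeneity")
  expect_s3_class(rep$presso, "mr_presso")
  expect_equal(nrow(rep$leave_one_out), 5)
  # plots build without error
  expect_s3_class(autoplot(rep$funnel), "ggplot")
  expect_s3_class(autoplot(rep$forest), "ggplot")
  expect_s3_class(autoplot(rep$leave_one_out), "ggplot")
  expect_s3_class(plot_mr_scatter(set, res), "ggplot")
})
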