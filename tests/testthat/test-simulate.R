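test_that("true effects and variances follow the configured laws", {
  cfg0 <- sim_config("sim1", n_gene = 100, s_between = 0)
  set.seed(51)
  expect_true(all(draw_truth(cfg0)$beta == 0))

  # scaled-t LFCs: empirical median |beta| vs the t3 quantile
  cfg1 <- sim_config("sim1", n_gene = 1e5)
  set.seed(52)
  tr <- draw_truth(cfg1)
  expect_lt(abs(median(abs(tr$beta)) - 0.5 * qt(0.75, df = 3)) /
              (0.5 * qt(0.75, df = 3)), 0.02)
  # d_within = 2 has no finite variance mean; check the median instead:
  # median(sigma2) = d s^2 / qchisq(0.5, d)
  med_ref <- 2 * 0.75^2 / qchisq(0.5, df = 2)
  expect_lt(abs(median(tr$sigma2) - med_ref) / med_ref, 0.03)
  expect_true(all(tr$sigma2 > 0))

  # Laplace LFCs and the finite inverse-chi-square mean of sim2
  cfg2 <- sim_config("sim2", n_gene = 1e5)
  set.seed(53)
  tr2 <- draw_truth(cfg2)
  expect_lt(abs(mean(tr2$sigma2) - 5 * 0.25 / 3) / (5 * 0.25 / 3), 0.03)
  expect_lt(abs(mean(abs(tr2$beta)) - 0.8) / 0.8, 0.03)  # Laplace mean |b| = s
})

test_that("datasets realise the group-shift observation model", {
  # vanishing noise: observed difference equals the true effect
  cfg <- sim_config("sim2", n_gene = 50, n_rep = 3, s_within = 1e-7)
  set.seed(54)
  tr <- draw_truth(cfg)
  d <- draw_dataset(tr, cfg)
  f <- fit_group_difference(d$x, d$group)
  expect_equal(unname(f$effect), tr$beta, tolerance = 1e-4)

  # pooled variance is unbiased for sigma2
  cfg <- sim_config("sim2", n_gene = 1e5, n_rep = 8)
  set.seed(55)
  tr <- draw_truth(cfg)
  d <- draw_dataset(tr, cfg)
  f <- fit_group_difference(d$x, d$group)
  expect_lt(abs(mean(f$sigma2 / tr$sigma2) - 1), 0.02)

  # swapping the groups negates every estimated effect
  f2 <- fit_group_difference(d$x[, c(9:16, 1:8)], d$group)
  expect_equal(unname(f2$effect), -unname(f$effect))
})

test_that("top-k scoring is set overlap against the true magnitudes", {
  set.seed(56)
  beta <- rnorm(500)
  true_order <- order(-abs(beta))
  expect_equal(topk_correct(true_order, beta, 50)$correct, 1)
  expect_equal(topk_correct(rev(true_order), beta, 50)$correct, 0)
  # random orders recover k/n on average (hypergeometric mean)
  hits <- replicate(200, topk_correct(sample(500), beta, 50)$correct)
  expect_lt(abs(mean(hits) - 0.1), 0.01)
  expect_error(topk_correct(true_order, beta, 501), "k")
})

test_that("false discovery and coverage counting follow their definitions", {
  # wrong sign is a false coverage statement even with a modest magnitude
  r <- bound_error_rates(bound = c(1, -1), beta = c(5, 5), thresholds = 0.5)
  expect_equal(r$n_false_cov, 1)
  expect_equal(r$n_false_disc, 0)
  expect_equal(r$fcp, 0.5)
  # bound magnitude above the truth is a false coverage statement
  r <- bound_error_rates(bound = 3, beta = 2.5, thresholds = c(0, 2.8))
  expect_equal(r$n_false_cov, c(1, 1))
  expect_equal(r$n_false_disc, c(0, 1))   # |beta| <= 2.8 at that threshold
  # huge effects, tight bounds: no false discoveries at threshold zero
  set.seed(57)
  beta <- rnorm(100, 0, 1) + 20 * sign(rnorm(100))
  bound <- beta - sign(beta) * 0.5
  r <- bound_error_rates(bound, beta, thresholds = 0)
  expect_equal(r$n_false_disc, 0)
  expect_equal(r$fcp, 0)
  # no discoveries contribute a rate of zero
  r <- bound_error_rates(rep(NA_real_, 5), rnorm(5), thresholds = 1)
  expect_equal(r$fdp, 0)
  expect_equal(r$n_discoveries, 0)
  expect_error(bound_error_rates(1, 1, thresholds = -1), "non-negative")
})

test_that("the benchmark is reproducible and schema-stable", {
  cfg <- sim_config("sim1", n_gene = 200, n_rep = 4, n_runs = 2, seed = 58)
  b1 <- run_benchmark(cfg, methods = c("pvalue", "confect"), ks = c(20, 100))
  b2 <- run_benchmark(cfg, methods = c("pvalue", "confect"), ks = c(20, 100))
  expect_identical(b1$topk, b2$topk)
  expect_identical(b1$rates, b2$rates)
  expect_named(b1$topk, c("method", "k", "correct", "se_correct",
                          "fallback_share"))
  expect_named(b1$rates, c("method", "threshold", "fdr", "se_fdr", "fcr",
                           "se_fcr", "n_true", "n_discoveries"))
  expect_true(all(b1$topk$correct >= 0 & b1$topk$correct <= 1))
  expect_true(all(b1$rates$fdr >= 0 & b1$rates$fdr <= 1))
})

test_that("Monte Carlo standard errors shrink with the number of runs", {
  cfg10 <- sim_config("sim1", n_gene = 300, n_rep = 4, n_runs = 10,
                      seed = 59)
  cfg40 <- sim_config("sim1", n_gene = 300, n_rep = 4, n_runs = 40,
                      seed = 59)
  b10 <- run_benchmark(cfg10, methods = "pvalue", ks = 20)
  b40 <- run_benchmark(cfg40, methods = "pvalue", ks = 20)
  ratio <- b10$topk$se_correct / b40$topk$se_correct
  # quadrupling the runs should roughly halve the SE; the sd estimate from
  # 10 runs is itself noisy, hence the wide band
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.3)
})

test_that("unadjusted CI bounds fail FCR control under heteroscedasticity", {
  cfg <- sim_config("sim1", n_gene = 1000, n_rep = 3, n_runs = 5, seed = 60)
  b <- run_benchmark(cfg, methods = "ci_inner", ks = 20)
  expect_gt(max(b$rates$fcr), 0.05)
  expect_gt(max(b$rates$fdr), 0.05)
})
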