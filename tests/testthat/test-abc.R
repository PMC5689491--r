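# a fabricated linear reference table lets the rejection/regression
# machinery be tested without coalescent noise
linear_table <- function(n = 600L, seed = 1L, noise = 0.05) {
  set.seed(seed)
  theta <- runif(n, 0.01, 10)
  stats <- cbind(s1 = theta + rnorm(n, 0, noise),
                 s2 = 2 * theta + rnorm(n, 0, noise),
                 s3 = rnorm(n))
  structure(list(params = matrix(theta, ncol = 1,
                                 dimnames = list(NULL, "theta")),
                 stats = stats, model = "lin", flagged = rep(FALSE, n),
                 seed = seed, priors = prior_spec(), n_sims = n),
            class = "reference_table")
}
lin_spec <- list(id = "lin", param_names = "theta", param_type = "theta")

test_that("prior draws respect bounds, uniformity and the tau ordering", {
  spec <- im_model_spec(c("C", "P", "Q"))
  pri <- prior_spec()
  set.seed(3)
  par <- draw_params(spec, pri, 10000L)
  expect_true(all(par[, 1:3] >= 0.01 & par[, 1:3] <= 10))
  expect_true(all(par[, "tau1"] <= par[, "tau2"]))
  expect_true(all(par[, 6:9] >= 0 & par[, 6:9] <= 50))
  # marginal uniformity of an unconstrained parameter
  ks <- suppressWarnings(ks.test((par[, "theta_C"] - 0.01) / 9.99, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("reference tables are reproducible and non-degenerate", {
  spec <- im_model_spec(c("C", "P", "Q"))
  ss <- study_sample_sizes()
  t1 <- build_reference_table(spec, prior_spec(), 10L, ss, rng_seed = 5)
  t2 <- build_reference_table(spec, prior_spec(), 10L, ss, rng_seed = 5)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$stats, t2$stats)
  expect_equal(nrow(t1$stats), 10L)
  expect_false(any(t1$flagged))
  expect_true(all(apply(t1$stats, 2L, sd) >= 0))
})

test_that("rejection retains the closest rows at the requested rate", {
  tab <- linear_table()
  obs <- tab$stats[17L, ]
  rej <- abc_rejection(obs, tab, tolerance = 1)
  expect_equal(length(rej$index), nrow(tab$stats))  # tolerance 1 keeps all

  rej2 <- abc_rejection(obs, tab, tolerance = 0.05)
  expect_equal(length(rej2$index), ceiling(0.05 * nrow(tab$stats)))
  expect_equal(rej2$index[1L], 17L)                 # own row ranks first
  expect_error(abc_rejection(obs, tab, 0), "tolerance")

  # a constant statistic column is excluded with a warning
  tab2 <- tab; tab2$stats[, "s3"] <- 1
  expect_warning(abc_rejection(obs, tab2, 0.05), "zero-variance")
})

test_that("regression adjustment recovers a noiseless linear relation", {
  tab <- linear_table(noise = 0.02)
  truth <- 4.2
  obs <- c(s1 = truth, s2 = 2 * truth, s3 = 0)
  rej <- abc_rejection(obs, tab, tolerance = 0.2)
  post <- regression_adjust(rej, lin_spec, prior_spec(), method = "loclinear")
  expect_equal(unname(post$summary$mean), truth, tolerance = 0.02)
  # adjusted draws stay inside the prior support
  expect_true(all(post$adjusted >= 0.01 & post$adjusted <= 10))
  expect_true(all(post$weights >= 0))
  # observed at the retained-set centroid: adjustment shifts little
  ctr <- colMeans(tab$stats)
  rejc <- abc_rejection(ctr, tab, tolerance = 0.2)
  postc <- regression_adjust(rejc, lin_spec, prior_spec(), method = "loclinear")
  expect_equal(unname(postc$summary$mean), mean(rejc$params),
               tolerance = 0.05)
  expect_error(regression_adjust(abc_rejection(obs, tab, 0.01), lin_spec,
                                 prior_spec()), ">= 20 retained")
})

test_that("neural-network adjustment variant runs and respects the support", {
  tab <- linear_table(noise = 0.02)
  obs <- c(s1 = 3, s2 = 6, s3 = 0)
  rej <- abc_rejection(obs, tab, tolerance = 0.2)
  set.seed(11)
  post <- regression_adjust(rej, lin_spec, prior_spec(), method = "neuralnet")
  expect_equal(unname(post$summary$mean), 3, tolerance = 0.15)
  expect_true(all(post$adjusted >= 0.01 & post$adjusted <= 10))
})

test_that("weighted quantile and HPD behave on known distributions", {
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 2, 1), 0.5), 2)
  x <- c(1, 2, 3, 4, 100)
  w <- c(1, 1, 1, 1, 0.0001)
  hpd <- weighted_hpd(x, w, level = 0.95)
  expect_lte(hpd[1L], 1); expect_lte(hpd[2L], 100)
  # symmetric sample: HPD approximates the central interval
  set.seed(4)
  z <- rnorm(5000)
  hpd2 <- weighted_hpd(z, rep(1, 5000), 0.95)
  expect_equal(hpd2[1L], -1.96, tolerance = 0.1)
  expect_equal(hpd2[2L], 1.96, tolerance = 0.1)
})

test_that("two identical models split the posterior evenly", {
  spec <- im_model_spec(c("C", "P", "Q"))
  ss <- study_sample_sizes()
  tA <- build_reference_table(spec, prior_spec(), 400L, ss, rng_seed = 21)
  tB <- build_reference_table(spec, prior_spec(), 400L, ss, rng_seed = 22)
  tA$model <- "A"; tB$model <- "B"
  set.seed(30)
  obs <- sim_summary_vector(simulate_dataset(default_truth_model(), ss))
  mp <- model_posterior(obs, list(tA, tB), tolerance = 0.25)
  expect_equal(sum(mp$prob), 1)
  expect_equal(unname(mp$prob[["A"]]), 0.5, tolerance = 0.2)
  expect_equal(unname(mp$bayes_factors["A", "B"]),
               mp$prob[["A"]] / mp$prob[["B"]], ignore_attr = TRUE)
})

test_that("PCA goodness-of-fit separates well-fitting from absurd observations", {
  spec <- im_model_spec(c("C", "P", "Q"))
  ss <- study_sample_sizes()
  tab <- build_reference_table(spec, prior_spec(), 500L, ss, rng_seed = 31)
  set.seed(32)
  obs <- sim_summary_vector(simulate_dataset(default_truth_model(), ss))
  rej <- abc_rejection(obs, tab, tolerance = 0.1)
  good <- gof_pca(tab$stats, rej$stats, obs)
  expect_true(good$pass)
  # pi inflated far beyond the prior range must fail
  bad_obs <- as.numeric(obs)
  bad_obs[grep("^pi", names(obs))] <- bad_obs[grep("^pi", names(obs))] * 50
  bad <- gof_pca(tab$stats, rej$stats, bad_obs)
  expect_false(bad$pass)
  # PCA is centred: the prior cloud projects around the origin
  expect_lt(max(abs(colMeans(good$prior_scores))), 1e-8)
})

test_that("time-unit conversion follows the worked example and its algebra", {
  rt <- data.frame(name = "L1", length = 1000L, rate = 0.01)  # 1e-8 /site/yr
  res <- convert_time_units(0.1, c(L1 = 2), rt, generation_time = 1)
  expect_equal(res$per_locus$four_Ne, 2e5)
  expect_equal(res$generations, 2e4)
  expect_equal(res$years, 2e4)

  expect_equal(convert_time_units(0, c(L1 = 2), rt)$years, 0)

  # doubling generation time halves generations, leaves years unchanged
  res2 <- convert_time_units(0.1, c(L1 = 2), rt, generation_time = 2)
  expect_equal(res2$generations, res$generations / 2)
  expect_equal(res2$years, res$years)

  expect_error(convert_time_units(0.1, c(L1 = 2),
                                  data.frame(name = "L1", length = 0L,
                                             rate = 0.01)), "positive")
})
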