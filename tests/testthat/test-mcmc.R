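std_normal_lp <- function(th) -0.5 * sum(th^2)

test_that("sampler reproduces standard-normal target moments", {
  init <- matrix(c(-5, 0, 5), 3, 1)
  ch <- run_mcmc(std_normal_lp, init, proposal_sd = 2.4, n_steps = 50000,
                 seed = 2)
  pooled <- do.call(rbind, ch$samples)
  expect_lt(abs(mean(pooled)), 0.05)
  expect_lt(abs(sd(pooled) - 1), 0.05)
  expect_true(all(gelman_rubin(ch) < 1.05))
  expect_true(all(ch$accept_fraction > 0 & ch$accept_fraction < 1))
})

test_that("runs are bit-reproducible given the seed", {
  init <- matrix(c(-2, 2), 2, 1)
  a <- run_mcmc(std_normal_lp, init, 1, 500, seed = 42)
  b <- run_mcmc(std_normal_lp, init, 1, 500, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$log_post, b$log_post)
  c <- run_mcmc(std_normal_lp, init, 1, 500, seed = 43)
  expect_false(identical(a$samples, c$samples))
})

test_that("flat targets accept nearly every proposal and defeat tuning", {
  flat <- function(th) 0
  ch <- run_mcmc(flat, matrix(0, 2, 1), 1, 2000, seed = 5)
  expect_true(all(ch$accept_fraction > 0.99))
  tn <- tune_proposals(flat, 0, proposal_sd = 3, seed = 6)
  expect_true(tn$flat)
  expect_identical(tn$proposal_sd, 3)   # initial sd returned unchanged
})

test_that("proposal tuning reaches the target acceptance band", {
  # narrow target, huge initial sd: tuned sd must shrink
  tn <- tune_proposals(std_normal_lp, 0, proposal_sd = 50, seed = 8)
  expect_lt(tn$proposal_sd, 50)
  expect_false(tn$flat)
  # confirmation run at 10000 steps lands in 0.2 +/- 0.05
  conf <- run_mcmc(std_normal_lp, matrix(0, 1, 1), tn$proposal_sd,
                   10000, seed = 9)
  expect_gte(conf$accept_fraction, 0.15)
  expect_lte(conf$accept_fraction, 0.25)
})

test_that("tuning failure carries the last acceptance fraction", {
  # a target whose acceptance cannot reach 0.2 within the round cap:
  # near-zero acceptance everywhere thanks to a spike target and a floor
  # on rounds via max_rounds = 2
  spike <- function(th) if (abs(th) < 1e-12) 0 else -1e10
  err <- tryCatch(
    tune_proposals(spike, 0, proposal_sd = 1, max_rounds = 2, seed = 3),
    tuning_failure = function(e) e)
  expect_s3_class(err, "tuning_failure")
  expect_true(is.numeric(err$last_acceptance))
})

test_that("Gelman-Rubin diagnostic matches the textbook oracle exactly", {
  withr::with_seed(11, {
    chains <- lapply(1:4, function(i) matrix(rnorm(600), 200, 3))
  })
  expect_equal(unname(gelman_rubin(chains, burn_in = 0)),
               psrf_oracle(chains), tolerance = 1e-10)

  # well-mixed chains: psrf -> 1
  withr::with_seed(12, {
    good <- lapply(1:3, function(i) matrix(rnorm(10000), 10000, 1))
  })
  expect_lt(gelman_rubin(good, burn_in = 0), 1.05)

  # disjoint chains: psrf far above the 1.2 convergence cut
  withr::with_seed(13, {
    bad <- list(matrix(rnorm(1000, 0), 1000, 1),
                matrix(rnorm(1000, 10), 1000, 1))
  })
  expect_gt(gelman_rubin(bad, burn_in = 0), 1.2)

  # degenerate chain
  expect_error(
    gelman_rubin(list(matrix(1, 100, 1), matrix(rnorm(100), 100, 1)),
                 burn_in = 0),
    "degenerate")
  expect_error(gelman_rubin(list(matrix(rnorm(100), 100, 1)), burn_in = 0),
               "2 chains")
})

test_that("posterior summaries match hand counts on pooled samples", {
  # craft a run whose post-burn pooled samples are {-1, 1, 2, 3}
  fake <- structure(list(
    samples = list(matrix(c(9, 9, -1, 1), 4, 1),
                   matrix(c(9, 9, 2, 3), 4, 1)),
    log_post = list(c(-5, -5, -1, -2), c(-5, -5, -0.5, -3)),
    accept_fraction = c(0.5, 0.5), proposal_sd = 1,
    n_steps = 4L, n_chains = 2L, param_names = "theta"),
    class = "mcmc_chains")
  s <- summarize_posterior(fake, burn_in = 0.5, threshold = 0,
                           allow_unconverged = TRUE)
  expect_equal(unname(s$tail_prob), 0.25)
  expect_equal(unname(s$median), 1.5)
  expect_equal(unname(s$ml_value), 2)   # highest stored log posterior
  expect_false(s$significant)

  # all samples above threshold -> tail probability 0
  fake$samples <- lapply(fake$samples, function(m) abs(m))
  s2 <- summarize_posterior(fake, burn_in = 0.5, allow_unconverged = TRUE)
  expect_equal(unname(s2$tail_prob), 0)
  expect_true(s2$significant)
})

test_that("symmetric targets give tail probability near one half", {
  ch <- run_mcmc(std_normal_lp, matrix(c(-1, 1), 2, 1), 2.4, 20000, seed = 21)
  s <- summarize_posterior(ch, burn_in = 0.5, threshold = 0)
  expect_lt(abs(s$tail_prob - 0.5), 0.03)
  expect_true(s$ci_95[1] <= s$median && s$median <= s$ci_95[2])
})

test_that("long-run state frequencies on a 3-state target match the target", {
  # states are the unit intervals [0,1), [1,2), [2,3) with masses p;
  # the piecewise-constant density makes the state frequencies enumerable
  p <- c(0.2, 0.3, 0.5)
  lp <- function(th) {
    if (th < 0 || th >= 3) return(-Inf)
    log(p[floor(th) + 1])
  }
  n <- 60000
  ch <- run_mcmc(lp, matrix(1.5, 1, 1), proposal_sd = 1.0, n_steps = n,
                 seed = 31)
  states <- floor(ch$samples[[1]][, 1]) + 1
  freq <- tabulate(states, 3) / n
  # Monte-Carlo standard error from batch means
  batches <- matrix(states, nrow = 600)
  for (k in 1:3) {
    bm <- colMeans(batches == k)
    se <- sd(bm) / sqrt(length(bm))
    expect_lt(abs(freq[k] - p[k]), 3 * se + 1e-12)
  }
})

test_that("posterior intervals recover known rescue parameters", {
  d <- gen_viability(viability_design(
    truth = dose_response_params(10, 1), noise_sd = 3, seed = 5))
  fit <- fit_viability_mcmc(d, n_steps = 10000, seed = 5)
  expect_true(all(fit$psrf < 1.2))
  ci <- fit$summary$ci_95
  expect_true(ci[1, "ec50"] <= 10 && 10 <= ci[2, "ec50"])
  expect_true(ci[1, "alpha"] <= 1 && 1 <= ci[2, "alpha"])
  # identical config + data reproduce the fit exactly
  fit2 <- fit_viability_mcmc(d, n_steps = 10000, seed = 5)
  expect_identical(fit$chains$samples, fit2$chains$samples)
})
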