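test_that("sim_config validates criteria and rates", {
  cfg <- sim_config(mu = 1.5, sigma = 1.5)
  expect_identical(cfg$n_levels, 3L)
  expect_equal(cfg$criteria, c(-1, -0.5, 0, 0.5, 1))
  expect_error(sim_config(criteria = c(1, 0, -1)), "increasing")
  expect_error(sim_config(criteria = c(-1, 0.5, 1)), "middle criterion")
  expect_error(sim_config(sigma = 0), "invalid")
  expect_error(sim_config(rt_tau = -1), "invalid")
})

test_that("simulated yes rates match the Gaussian model", {
  null <- simulate_observer(sim_config(mu = 0, sigma = 1, n_trials = 1e5),
                            seed = 51)
  expect_lt(abs(mean(null$response[null$stimulus == 1]) - 0.5), 0.005)
  expect_lt(abs(mean(null$response[null$stimulus == 0]) - 0.5), 0.005)

  tr <- simulate_observer(sim_config(mu = 1.5, sigma = 1.5,
                                     criteria = c(-1, 0, 1), n_trials = 1e5),
                          seed = 52)
  expect_lt(abs(mean(tr$response[tr$stimulus == 1]) - (1 - pnorm(-1))), 0.005)
  expect_lt(abs(mean(tr$response[tr$stimulus == 0]) - 0.5), 0.005)
})

test_that("noise-free RT is a strictly monotone map of evidence distance", {
  tr <- simulate_observer(sim_config(mu = 1, sigma = 1.3, n_trials = 2000,
                                     rt_tau = 0), seed = 53)
  d <- abs(tr$evidence - 0)
  for (r in 0:1) {
    sel <- tr$response == r
    expect_identical(order(tr$rt[sel]), order(-d[sel]))
  }
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(mu = 1, n_trials = 200)
  expect_identical(simulate_observer(cfg, seed = 54),
                   simulate_observer(cfg, seed = 54))
  expect_false(identical(simulate_observer(cfg, seed = 54),
                         simulate_observer(cfg, seed = 55)))
  co <- simulate_cohort(cfg, 5, sd_mu = 0.3, sd_c0 = 0.2, seed = 56)
  expect_identical(co, simulate_cohort(cfg, 5, sd_mu = 0.3, sd_c0 = 0.2,
                                       seed = 56))
})

test_that("confidence levels fold the criterion intervals around c0", {
  cfg <- sim_config(mu = 1.5, sigma = 1.5, criteria = c(-1, 0, 1),
                    n_trials = 5000)
  tr <- simulate_observer(cfg, seed = 57)
  x <- tr$evidence
  # yes responses: level 2 above the top criterion, level 1 between
  expect_true(all(tr$confidence[x > 1] == 2 & tr$response[x > 1] == 1))
  mid_yes <- x > 0 & x <= 1
  expect_true(all(tr$confidence[mid_yes] == 1 & tr$response[mid_yes] == 1))
  # no responses mirror below c0
  expect_true(all(tr$confidence[x <= -1] == 2 & tr$response[x <= -1] == 0))
  mid_no <- x <= 0 & x > -1
  expect_true(all(tr$confidence[mid_no] == 1 & tr$response[mid_no] == 0))
})

test_that("with tau = 0 and symmetric criteria, RT bins reproduce confidence categories", {
  cfg <- sim_config(mu = 1.5, sigma = 1.5, criteria = c(-1, 0, 1),
                    n_trials = 4000, rt_tau = 0)
  tr <- simulate_observer(cfg, seed = 58)
  out <- bin_rt(tr, 2)
  tab_rt <- build_table(out, 2, evidence = "rt")
  tab_conf <- build_table(out, 2, evidence = "confidence")
  # quantile cutpoints sit at the empirical |x| median rather than at 1, so
  # compare the rating dimension itself, not the marginal counts: within
  # each response the strength ranking must agree perfectly
  for (r in 0:1) {
    sel <- out$response == r
    expect_gt(cor(out$rt_strength[sel], out$confidence[sel],
                  method = "spearman"), 0.7)
  }
  # and with criteria at the pooled |x - c0| tertile positions the
  # categories agree exactly
  d <- abs(tr$evidence)
  q <- quantile(d, 0.5, type = 7, names = FALSE)
  cfg2 <- sim_config(mu = 1.5, sigma = 1.5, criteria = c(-q, 0, q),
                     n_trials = 4000, rt_tau = 0)
  tr2 <- simulate_observer(cfg2, seed = 58)
  out2 <- bin_rt(tr2, 2)
  agree <- mean(out2$rt_strength == out2$confidence)
  expect_gt(agree, 0.99)
})

test_that("empirical ROC of a large simulation matches the model ROC pointwise", {
  crit <- c(-1, 0, 1)
  cfg <- sim_config(mu = 1.5, sigma = 1.5, criteria = crit, n_trials = 1e6)
  tr <- simulate_observer(cfg, seed = 59)
  emp <- empirical_roc(build_table(tr, 2, evidence = "confidence"))$points
  ks <- rev(crit)
  expect_equal(emp$fa, 1 - pnorm(ks), tolerance = 0.005)
  expect_equal(emp$hit, 1 - pnorm((ks - 1.5) / 1.5), tolerance = 0.005)
})

test_that("cohort criterion spread is recovered by the fitted criterion c", {
  # under sigma = 1 the bias index c moves one-for-one with the decision
  # criterion, so the across-subject SD of fitted c recovers sd_c0
  cohort <- simulate_cohort(
    sim_config(mu = 1.5, sigma = 1, criteria = c(-0.5, 0, 0.5),
               n_trials = 1000),
    n_subjects = 100, sd_c0 = 0.5, seed = 60)
  tabs <- prepare_tables(cohort, 2, evidence = "confidence")
  res <- fit_subjects(tabs, "confidence", seed = 61)
  expect_lt(abs(sd(res$c) - 0.5), 0.1)
})

test_that("RT noise attenuates RT-based sigma recovery but not confidence-based", {
  sigma_hat <- function(tau) {
    cohort <- simulate_cohort(
      sim_config(mu = 1.5, sigma = 1.5, criteria = c(-1, 0, 1),
                 n_trials = 1000, rt_tau = tau),
      n_subjects = 30, seed = 62)
    rt <- fit_subjects(prepare_tables(cohort, 2, "rt"), "rt", seed = 63)
    cf <- fit_subjects(prepare_tables(cohort, 2, "confidence"),
                       "confidence", seed = 63)
    c(rt = mean(rt$sigma[rt$converged]), conf = mean(cf$sigma[cf$converged]))
  }
  s0 <- sigma_hat(0)
  s2 <- sigma_hat(0.2)
  s5 <- sigma_hat(0.5)
  # RT-based estimates fall toward 1 as tau grows
  expect_true(s0["rt"] > s2["rt"] && s2["rt"] > s5["rt"])
  # confidence-based estimates stay put
  expect_lt(abs(s5["conf"] - s0["conf"]), 0.15)
})
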