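trials_df <- function(subject = "a", stimulus, response, rt = NULL,
                      confidence = NULL) {
  n <- length(stimulus)
  df <- data.frame(subject = subject, stimulus = stimulus,
                   response = response, stringsAsFactors = FALSE)
  df$rt <- if (is.null(rt)) rep(0.5, n) else rt
  if (!is.null(confidence)) df$confidence <- confidence
  df
}

test_that("confidence tertiles follow per-subject type-7 cutpoints, ties downward", {
  tr <- trials_df(stimulus = rep(0:1, 3), response = rep(0:1, 3),
                  confidence = c(10, 20, 30, 40, 50, 60))
  out <- discretize_confidence(tr, 3)
  expect_identical(out$confidence, c(1L, 1L, 2L, 2L, 3L, 3L))

  # degenerate confidence errors, naming the subject
  same <- trials_df(subject = "subj7", stimulus = rep(0:1, 3),
                    response = rep(0:1, 3), confidence = rep(5, 6))
  expect_error(discretize_confidence(same, 3), "subj7")
})

test_that("confidence quantile levels are balanced for continuous scales", {
  set.seed(11)
  tr <- trials_df(stimulus = rbinom(300, 1, 0.5), response = rbinom(300, 1, 0.5),
                  confidence = runif(300, 0, 100))
  out <- discretize_confidence(tr, 3)
  counts <- table(out$confidence)
  expect_true(all(abs(counts - 100) <= 1))
})

test_that("RT bins assign faster responses higher strength", {
  tr <- trials_df(stimulus = rep(0:1, 3), response = rep(0:1, 3),
                  rt = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  out <- bin_rt(tr, 3)
  expect_identical(out$rt_strength, c(3L, 3L, 2L, 2L, 1L, 1L))

  # degenerate RTs: error by default, middle-strength collapse on request
  same <- trials_df(stimulus = rep(0:1, 3), response = rep(0:1, 3),
                    rt = rep(0.5, 6))
  expect_error(bin_rt(same, 3), "distinct RTs")
  out2 <- bin_rt(same, 3, degenerate = "collapse")
  expect_true(all(out2$rt_strength == 2L))
})

test_that("RT quantile bins have equal occupancy", {
  set.seed(12)
  tr <- trials_df(stimulus = rbinom(400, 1, 0.5), response = rbinom(400, 1, 0.5),
                  rt = rexp(400, 1))
  out <- bin_rt(tr, 4)
  expect_true(all(abs(table(out$rt_strength) - 100) <= 1))
})

test_that("within-response binning uses separate clocks per response", {
  set.seed(13)
  # yes responses systematically slower: pooled and within disagree
  n <- 200
  resp <- rep(0:1, each = n / 2)
  tr <- trials_df(stimulus = rbinom(n, 1, 0.5), response = resp,
                  rt = ifelse(resp == 1, rexp(n, 1) + 1, rexp(n, 1)))
  within <- bin_rt(tr, 2, scheme = "within_response")
  # each response class is split evenly under its own median
  for (r in 0:1) {
    expect_true(all(abs(table(within$rt_strength[resp == r]) - n / 4) <= 1))
  }
})

test_that("pooled RT binning with noise-free RTs equals binning |x - c0| directly", {
  cfg <- sim_config(mu = 1.5, sigma = 1.5, criteria = c(-1, 0, 1),
                    n_trials = 301, rt_tau = 0)
  tr <- simulate_observer(cfg, seed = 21)
  out <- bin_rt(tr, 3)
  d <- abs(tr$evidence - cfg$decision_criterion)
  cuts <- quantile(d, probs = 1:2 / 3, type = 7, names = FALSE)
  oracle <- 1L + rowSums(outer(d, cuts, ">"))
  expect_identical(out$rt_strength, as.integer(oracle))
})

test_that("build_table places yes/no and strength in the documented column order", {
  tr <- data.frame(
    subject = "a",
    stimulus = c(1, 1, 0, 0), response = c(1, 0, 1, 0),
    confidence = c(3L, 1L, 1L, 3L)
  )
  tab <- build_table(tr, 3, evidence = "confidence")
  expect_equal(unname(tab$freq["present", ]), c(1, 0, 0, 1, 0, 0))
  expect_equal(unname(tab$freq["absent", ]), c(0, 0, 1, 0, 0, 1))
  expect_equal(sum(tab$freq), nrow(tr))

  one_class <- tr[tr$stimulus == 1, ]
  expect_error(build_table(one_class, 3, evidence = "confidence"),
               "stimulus classes")
})

test_that("simulated tables total trials-per-subject and match model rates", {
  cfg <- sim_config(mu = 1.5, sigma = 1.5, criteria = c(-1, 0, 1),
                    n_trials = 10000)
  tr <- simulate_observer(cfg, seed = 31)
  tab <- build_table(tr, 2, evidence = "confidence")
  expect_equal(sum(tab$freq), cfg$n_trials)
  emp <- empirical_roc(tab)
  mod_fa <- 1 - pnorm(c(1, 0, -1))
  mod_hit <- 1 - pnorm((c(1, 0, -1) - 1.5) / 1.5)
  expect_equal(emp$points$fa, mod_fa, tolerance = 0.02)
  expect_equal(emp$points$hit, mod_hit, tolerance = 0.02)
})

test_that("padding adds 1/N per cell and preserves cumulative-rate ordering", {
  freq <- rbind(c(10, 20, 15, 5), c(25, 15, 8, 2))  # N = 100
  tab <- rating_table(freq)
  padded <- pad_table(tab)
  expect_equal(padded$freq, tab$freq + 0.01,
               ignore_attr = TRUE)
  expect_true(padded$padded)
  expect_error(pad_table(padded), "already padded")

  zero <- pad_table(rating_table(rbind(c(0, 5, 5, 0), c(5, 0, 0, 5))))
  expect_true(all(zero$freq > 0))
  expect_equal(min(zero$freq), 1 / 20)

  set.seed(14)
  for (i in 1:25) {
    tab <- random_table(sample(2:3, 1))
    before <- empirical_roc(tab)$points
    after <- empirical_roc(pad_table(tab))$points
    expect_true(all(diff(after$fa) >= 0) && all(diff(after$hit) >= 0))
    expect_equal(after$fa, before$fa, tolerance = 0.05)
  }
})

test_that("below-chance screen flags non-positive midpoint d' (boundary excluded)", {
  make_tab <- function(hit, fa, N = 100) {
    pad_table(rating_table(rbind(
      c(fa * N / 2, fa * N / 2, (1 - fa) * N / 2, (1 - fa) * N / 2),
      c(hit * N / 2, hit * N / 2, (1 - hit) * N / 2, (1 - hit) * N / 2)
    )))
  }
  tabs <- list(good = make_tab(0.7, 0.3), bad = make_tab(0.3, 0.7),
               boundary = make_tab(0.5, 0.5))
  rep <- exclude_below_chance(tabs)
  expect_identical(rep$below_chance, c(FALSE, TRUE, TRUE))
  expect_identical(attr(rep, "n_input_subjects"), 3L)
  expect_identical(attr(rep, "n_below_chance_excluded"), 2L)
  expect_identical(attr(rep, "n_final"), 1L)
})
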