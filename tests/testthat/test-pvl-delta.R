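test_that("prospect utility matches its defining cases", {
  expect_equal(pvl_utility(0, A = 0.5, w = 2), 0)
  expect_equal(pvl_utility(0, A = 0, w = 2), 0)  # 0^0 convention
  expect_equal(pvl_utility(100, A = 1, w = 1), 100)
  expect_equal(pvl_utility(-100, A = 1, w = 1), -100)
  expect_equal(pvl_utility(-100, A = 0.5, w = 2), -20)
  expect_error(pvl_utility(1, A = 1.2, w = 1), "A")
})

test_that("delta rule updates only the chosen deck", {
  expect_equal(update_expectancies(rep(0, 4), 1, 1.0, 0.3), c(0.3, 0, 0, 0))
  ev <- c(0.2, -0.1, 0.4, 0)
  expect_equal(update_expectancies(ev, 3, 0.9, 0), ev)        # a = 0: frozen
  ev2 <- update_expectancies(ev, 2, -0.2, 1)                  # a = 1: replace
  expect_equal(ev2[2], -0.2)
  expect_equal(ev2[-2], ev[-2])
})

test_that("sensitivity and softmax behave as specified", {
  expect_equal(pvl_sensitivity(0), 0)
  expect_equal(pvl_sensitivity(1), 2)
  expect_equal(pvl_sensitivity(5), 242)
  expect_equal(choice_probabilities(c(9, -3, 0.5, 2), 0), rep(0.25, 4))
  expect_equal(choice_probabilities(rep(1.3, 4), 3), rep(0.25, 4))
  # direct arithmetic oracle for Ev = (1,0,0,0), c = 1 (theta = 2)
  expect_equal(choice_probabilities(c(1, 0, 0, 0), 1)[1],
               exp(2) / (exp(2) + 3), tolerance = 1e-12)
  # numerically stable at the extreme of the parameter range
  p <- choice_probabilities(c(60, -60, 0, 0), 5)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("softmax properties hold over random draws", {
  set.seed(11)
  for (r in 1:200) {
    ev <- stats::rnorm(4, 0, 5)
    cc <- stats::runif(1, 0, 5)
    p <- choice_probabilities(ev, cc)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # monotonicity: more consistency never hurts the argmax deck
    p_hi <- choice_probabilities(ev, min(cc + stats::runif(1, 0, 1), 5))
    expect_gte(p_hi[which.max(ev)], p[which.max(ev)] - 1e-12)
  }
})

test_that("log-likelihood equals the independent oracle", {
  set.seed(21)
  p1 <- random_participant(1)
  expect_equal(pvl_log_likelihood(p1, random_params()), log(0.25))
  pT <- random_participant(37)
  expect_equal(pvl_log_likelihood(pT, pvl_params(0.5, 1, 0.3, 0)),
               37 * log(0.25))
  for (r in 1:100) {
    p <- random_participant(20)
    th <- random_params()
    got <- pvl_log_likelihood(p, th)
    want <- oracle_pvl(p$deck, (p$reward + p$loss) / 100,
                       th[["A"]], th[["w"]], th[["a"]], th[["c"]])$loglik
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant to the loss sign convention", {
  deck <- c(1, 2, 3, 4, 1, 2)
  reward <- c(100, 100, 50, 50, 100, 100)
  loss <- c(0, -1250, -50, 0, -150, 0)
  a <- participant_data("a", deck, reward, loss)
  b <- suppressWarnings(participant_data("b", deck, reward, abs(loss)))
  th <- pvl_params(0.4, 2, 0.4, 1)
  expect_equal(pvl_log_likelihood(a, th), pvl_log_likelihood(b, th))
})

test_that("simulated agents respect the choice rule and payoff scheme", {
  set.seed(31)
  # c = 0: uniform random choice
  ag <- simulate_pvl_agent(pvl_params(0.5, 1, 0.5, 0), n_trials = 10000)
  freq <- tabulate(ag$deck, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
  # a = 0: no updating, choices stay uniform whatever c
  ag0 <- simulate_pvl_agent(pvl_params(1, 5, 0, 5), n_trials = 5000)
  freq0 <- tabulate(ag0$deck, 4) / 5000
  expect_true(all(abs(freq0 - 0.25) < 0.03))
  # forced onto deck D for 10 trials: net outcome +250
  agD <- simulate_pvl_agent(pvl_params(0.5, 1, 0.3, 1), n_trials = 10,
                            forced_choices = rep(4, 10))
  expect_equal(sum(net_outcomes(agD)), 250)
  # reproducible given the seed
  set.seed(99); s1 <- simulate_pvl_agent(random_params(), n_trials = 50)
  set.seed(99); s2 <- simulate_pvl_agent(random_params(), n_trials = 50)
  expect_identical(s1$deck, s2$deck)
  expect_identical(s1$loss, s2$loss)
})

test_that("parameter constructor enforces the closed ranges", {
  expect_error(pvl_params(-0.1, 1, 0.5, 1), "A")
  expect_error(pvl_params(0.5, 5.1, 0.5, 1), "w")
  expect_error(pvl_params(0.5, 1, 0.5, 6), "c")
  expect_silent(pvl_params(0, 0, 0, 0))
  expect_silent(pvl_params(1, 5, 1, 5))
})
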