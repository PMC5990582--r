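test_that("traditional scheme reproduces the canonical per-deck structure", {
  sch <- traditional_scheme()
  s <- scheme_summary(sch)
  expect_equal(s$reward_per_trial, c(100, 100, 50, 50))
  expect_equal(s$n_losses_per_block, c(5, 1, 5, 1))
  expect_equal(s$loss_per_block, c(-1250, -1250, -250, -250))
  expect_equal(s$net_per_block, c(-250, -250, 250, 250))
  expect_equal(sch$endowment, 2000)
  expect_equal(sch$n_trials_default, 100)
})

test_that("draw_payoff follows the block schedule deterministically", {
  sch <- traditional_scheme()
  a <- draw_payoff(sch, "A", 1:30)
  expect_true(all(a$reward == 100))
  # every aligned 10-draw window reproduces the block totals
  for (b in 1:3)
    expect_equal(sum(a$loss[((b - 1) * 10 + 1):(b * 10)]), -1250)
  b <- draw_payoff(sch, "B", 1:10)
  expect_equal(sum(b$loss != 0), 1)
  expect_equal(sum(b$loss), -1250)
  d <- draw_payoff(sch, 4, 1:10)
  expect_equal(sum(d$reward + d$loss), 250)
  # deterministic given the draw counter when shuffling is off
  expect_identical(draw_payoff(sch, "C", 5), draw_payoff(sch, "C", 5))
  expect_error(draw_payoff(sch, "E", 1), "deck")
})

test_that("within-block shuffling permutes positions but not totals", {
  sch <- traditional_scheme(shuffle_within_block = TRUE)
  set.seed(1); l1 <- draw_payoff(sch, "A", 1:10)$loss
  set.seed(2); l2 <- draw_payoff(sch, "A", 1:10)$loss
  expect_equal(sort(l1), sort(l2))
  expect_equal(sum(l1), -1250)
  set.seed(1); l1b <- draw_payoff(sch, "A", 1:10)$loss
  expect_identical(l1, l1b)  # seed-reproducible
})

test_that("block_proportions counts exactly and normalizes", {
  p <- participant_data("s", rep(1, 100), rep(100, 100), rep(0, 100))
  bp <- block_proportions(p)
  expect_equal(unname(bp$proportions[, "A"]), rep(1, 10))
  expect_equal(unname(bp$good), rep(0, 10))

  q <- participant_data("q", c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4),
                        rep(50, 10), rep(0, 10))
  bq <- block_proportions(q)
  expect_equal(unname(bq$proportions[1, ]), c(0.3, 0.2, 0.4, 0.1))
  expect_equal(unname(bq$good[1]), 0.5)

  set.seed(42)
  r <- random_participant(73)
  br <- block_proportions(r)
  expect_true(br$partial_final)
  expect_equal(unname(rowSums(br$proportions)), rep(1, 8))
})

test_that("CSV roundtrip is the identity and errors are descriptive", {
  set.seed(7)
  ds <- group_dataset(list(random_participant(12, "s1"),
                           random_participant(9, "s2")), name = "toy")
  path <- withr::local_tempfile(fileext = ".csv")
  write_igt_csv(ds, path)
  back <- read_igt_csv(path, name = "toy")
  for (i in 1:2) {
    expect_identical(back$participants[[i]]$deck, ds$participants[[i]]$deck)
    expect_equal(back$participants[[i]]$reward, ds$participants[[i]]$reward)
    expect_equal(back$participants[[i]]$loss, ds$participants[[i]]$loss)
  }

  df <- utils::read.csv(path)
  df$loss <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_igt_csv(path2), "loss")

  df2 <- utils::read.csv(path)
  df2$deck[17] <- 5
  utils::write.csv(df2, path2, row.names = FALSE)
  expect_error(read_igt_csv(path2), "row 17")

  df3 <- utils::read.csv(path)
  df3 <- df3[-3, ]  # break trial contiguity for subject s1
  utils::write.csv(df3, path2, row.names = FALSE)
  expect_error(read_igt_csv(path2), "contiguous")
})

test_that("participant and dataset constructors validate their input", {
  expect_error(participant_data("s", integer(0), numeric(0), numeric(0)),
               "empty")
  expect_error(participant_data("s", c(1, 9), c(1, 1), c(0, 0)), "deck")
  expect_error(group_dataset(list()), "participant")
  expect_warning(participant_data("s", 1, 100, 50), "magnitude")
})

test_that("scheme JSON config round-trips", {
  sch <- traditional_scheme()
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme_json(sch, path)
  back <- read_scheme_json(path)
  expect_equal(scheme_summary(back), scheme_summary(sch))
  expect_equal(back$decks$A$losses, sch$decks$A$losses)
  expect_equal(back$endowment, 2000)
})
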