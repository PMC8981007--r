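# Argmin-CATE recommendation policy, matched-vs-unmatched outcomes,
# recommendation distribution and the personalization effect.

test_that("the most negative effect wins, with fixed tie-break order", {
  tau <- c(coaching = -1.7, monitoring = -1.4, physical_activity = -1.0,
           nutrition = -0.9, content = -0.8)
  expect_equal(recommend_action(tau), "coaching")
  expect_equal(recommend_action(tau * 0), "none")
  tie <- c(coaching = -1.0, monitoring = -1.0, physical_activity = 0,
           nutrition = 0, content = 0)
  expect_equal(recommend_action(tie), "coaching")
  # only non-negative effects -> none, even if small
  expect_equal(recommend_action(c(coaching = 0.01, monitoring = 0,
                                  physical_activity = 0.5, nutrition = 2,
                                  content = 0.2)), "none")
  expect_error(recommend_action(tau[-1]), class = "rdmprec_schema_error")
})

test_that("table-wise recommendations align with the scalar rule", {
  tau_df <- data.frame(member_id = c("a", "b", "c"),
                       coaching = c(-1.7, 0.2, -0.5),
                       monitoring = c(-1.4, 0.1, -0.5),
                       physical_activity = c(0, 0.3, -0.2),
                       nutrition = c(0, 0.1, -0.1),
                       content = c(0, 0.4, -0.9))
  cohorts <- data.frame(member_id = c("a", "b", "c"),
                        coaching = c(TRUE, FALSE, FALSE),
                        monitoring = c(FALSE, FALSE, TRUE),
                        physical_activity = FALSE, nutrition = FALSE,
                        content = c(FALSE, FALSE, TRUE),
                        other = c(FALSE, TRUE, FALSE))
  recs <- recommend_actions(tau_df, cohorts)
  expect_equal(recs$recommended, c("coaching", "none", "content"))
  expect_equal(recs$matched, c(TRUE, FALSE, TRUE))
})

test_that("matched analysis matches hand computation on a toy table", {
  # six members, all in the coaching treatment cohort; three recommended
  # coaching (matched), three recommended monitoring (unmatched)
  tau_df <- data.frame(
    member_id = paste0("m", 1:6),
    coaching = c(-2, -2, -2, -0.1, -0.1, -0.1),
    monitoring = c(-1, -1, -1, -2, -2, -2),
    physical_activity = 0, nutrition = 0, content = 0)
  cohorts <- data.frame(member_id = paste0("m", 1:6),
                        coaching = TRUE, monitoring = FALSE,
                        physical_activity = FALSE, nutrition = FALSE,
                        content = FALSE, other = FALSE)
  outcomes <- data.frame(member_id = paste0("m", 1:6),
                         outcome_y = c(-2.0, -1.6, -1.2, -0.4, -0.2, 0.0))
  recs <- recommend_actions(tau_df, cohorts)
  ma <- matched_outcome_analysis(recs, cohorts, outcomes)
  coaching_row <- ma[ma$category == "coaching", ]
  expect_equal(coaching_row$n_matched, 3)
  expect_equal(coaching_row$mean_y_matched, mean(c(-2.0, -1.6, -1.2)))
  expect_equal(coaching_row$mean_y_unmatched, mean(c(-0.4, -0.2, 0.0)))
  expect_equal(coaching_row$difference, -1.6 - (-0.2))
  # monitoring cohort is empty -> undefined means, not an error
  mon_row <- ma[ma$category == "monitoring", ]
  expect_equal(mon_row$n_matched + mon_row$n_unmatched, 0)
  expect_true(is.na(mon_row$mean_y_matched))
  # pooled row covers members in >= 1 cohort
  pooled <- ma[ma$category == "pooled", ]
  expect_equal(pooled$n_matched + pooled$n_unmatched, 6)
  expect_equal(pooled$mean_y_matched, mean(c(-2.0, -1.6, -1.2)))
})

test_that("all-matched partitions leave the unmatched mean undefined", {
  tau_df <- data.frame(member_id = "m1", coaching = -1, monitoring = 0,
                       physical_activity = 0, nutrition = 0, content = 0)
  cohorts <- data.frame(member_id = "m1", coaching = TRUE, monitoring = FALSE,
                        physical_activity = FALSE, nutrition = FALSE,
                        content = FALSE, other = FALSE)
  outcomes <- data.frame(member_id = "m1", outcome_y = -1)
  ma <- matched_outcome_analysis(recommend_actions(tau_df, cohorts),
                                 cohorts, outcomes)
  row <- ma[ma$category == "coaching", ]
  expect_true(is.na(row$mean_y_unmatched))
  expect_true(is.na(row$difference))
})

test_that("the recommendation distribution counts non-none members", {
  tau_df <- data.frame(
    member_id = paste0("m", 1:5),
    coaching = c(-1, -1, 0, 0, 0),
    monitoring = 0, physical_activity = 0,
    nutrition = c(0, 0, 0, -0.5, 0),
    content = c(0, 0, -0.3, 0, 0.2))
  recs <- recommend_actions(tau_df)
  d <- recommendation_distribution(recs)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(unname(d[c("coaching", "content", "nutrition")]),
               c(0.5, 0.25, 0.25))
  # all "none" -> empty distribution
  none_df <- tau_df
  none_df[ACTION_CATEGORIES] <- 0
  expect_length(recommendation_distribution(recommend_actions(none_df)), 0)
})

test_that("the if-optimal mean dominates the as-received mean", {
  tau_df <- data.frame(member_id = c("m1", "m2"),
                       coaching = c(-0.5, -0.2),
                       monitoring = c(-0.5, -0.9),
                       physical_activity = 0, nutrition = 0, content = 0)
  cohorts <- data.frame(member_id = c("m1", "m2"), coaching = TRUE,
                        monitoring = FALSE, physical_activity = FALSE,
                        nutrition = FALSE, content = FALSE, other = FALSE)
  pe <- personalization_effect(tau_df, cohorts)
  row <- pe[pe$category == "coaching", ]
  expect_equal(row$mean_tau_as_received, -0.35)
  expect_equal(row$mean_tau_if_optimal, -0.7)

  # property: argmin dominance for every category on arbitrary tables
  set.seed(99)
  big <- data.frame(member_id = sprintf("r%03d", 1:60))
  for (cat in ACTION_CATEGORIES) big[[cat]] <- stats::rnorm(60)
  fl <- data.frame(member_id = big$member_id)
  for (cat in ACTION_CATEGORIES) fl[[cat]] <- stats::runif(60) < 0.5
  fl$other <- !Reduce(`|`, fl[ACTION_CATEGORIES])
  pe2 <- personalization_effect(big, fl)
  ok <- !is.na(pe2$mean_tau_as_received)
  expect_true(all(pe2$mean_tau_if_optimal[ok] <=
                    pe2$mean_tau_as_received[ok] + 1e-12))
  # constant effects: as-received equals if-optimal
  const <- big
  const[ACTION_CATEGORIES] <- -1
  pe3 <- personalization_effect(const, fl)
  expect_equal(pe3$mean_tau_as_received, pe3$mean_tau_if_optimal)
})
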