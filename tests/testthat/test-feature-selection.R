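# Ensemble stability selection: K rule, voting arithmetic, retention
# scenarios, the skip rule, determinism, and planted-signal power.

test_that("candidate breadth K follows the floor-and-cap rule", {
  expect_identical(determine_k(60, 50), 60L)       # capped at p
  expect_identical(determine_k(5000, 50), 250L)    # ceil(.05p) wins
  expect_identical(determine_k(1, 1), 1L)
  expect_identical(determine_k(5092, 150), 450L)   # 3*U_max wins
  expect_identical(determine_k(100, 1), 5L)
  expect_error(determine_k(0, 10), class = "eb_config_error")
  expect_error(determine_k(100, 151), class = "eb_config_error")
})

test_that("stability scores are appearance fractions over 15 slots", {
  feats <- sprintf("F%02d", 1:10)
  # fabricate 15 ranking vectors with known top-3 membership: distinct base
  # importances avoid accidental ties; F01 always top, F02 in 9 lists
  rankings <- lapply(1:15, function(i) {
    v <- stats::setNames((10:1) / 1000, feats)
    v["F01"] <- 3
    v["F02"] <- if (i <= 9) 2 else 0.0001
    v
  })
  class(rankings) <- "eb_rankings"
  tab <- stability_scores(rankings, K = 3)
  expect_equal(tab$stability[tab$feature == "F01"], 1.0)
  expect_equal(tab$stability[tab$feature == "F02"], 0.6)
  expect_identical(tab$appearances[tab$feature == "F02"], 9L)
  # F03 takes the third slot whenever F02 drops out
  expect_identical(tab$appearances[tab$feature == "F03"], 15L)
  # every score is a multiple of 1/15 in [0, 1]
  expect_true(all(tab$stability >= 0 & tab$stability <= 1))
  expect_true(all(abs(tab$stability * 15 - round(tab$stability * 15)) < 1e-12))
  # total appearances = 15 * K
  expect_identical(sum(tab$appearances), 15L * 3L)
  expect_error(stability_scores(rankings, K = 11), class = "eb_config_error")
})

test_that("retention scenarios follow the three-branch rule", {
  mk_table <- function(stab) {
    structure(data.frame(feature = sprintf("F%02d", seq_along(stab)),
                         appearances = as.integer(round(stab * 15)),
                         stability = stab,
                         mean_rank = seq_along(stab),
                         stringsAsFactors = FALSE),
              class = c("eb_stability", "data.frame"))
  }
  # abundant: 80 features above threshold, want 66
  tab <- mk_table(c(rep(0.8, 80), rep(0.2, 20)))
  res <- select_features(tab, N_final = 66, M_min = 40)
  expect_identical(res$scenario, "abundant")
  expect_length(res$selected, 66L)

  # clipped: 4 above threshold, want 20, need at least 12
  tab <- mk_table(c(rep(0.9, 4), rep(0.4, 26)))
  res <- select_features(tab, N_final = 20, M_min = 12)
  expect_identical(res$scenario, "clipped")
  expect_length(res$selected, 12L)
  expect_true(all(sprintf("F%02d", 1:4) %in% res$selected))

  # clipped but already above M_min: keep exactly the high-stability set
  tab <- mk_table(c(rep(0.9, 15), rep(0.3, 15)))
  res <- select_features(tab, N_final = 20, M_min = 12)
  expect_identical(res$scenario, "clipped")
  expect_length(res$selected, 15L)

  # fallback: nothing above threshold
  tab <- mk_table(rep(0.3, 30))
  res <- select_features(tab, N_final = 20, M_min = 10)
  expect_identical(res$scenario, "fallback")
  expect_length(res$selected, 10L)

  # boundary: exactly 0.5 does not pass the strict threshold
  tab <- mk_table(c(rep(0.5, 10), rep(8 / 15, 3), rep(0.2, 17)))
  res <- select_features(tab, N_final = 20, M_min = 3)
  expect_identical(res$scenario, "clipped")
  expect_length(res$selected, 3L)
  # 7/15 and 8/15 sit on either side of the threshold
  expect_true(8 / 15 > 0.5 && 7 / 15 < 0.5)

  expect_error(select_features(mk_table(rep(0.4, 5)), 20, M_min = 6),
               class = "eb_config_error")
})

test_that("selection is skipped below 100 features with stability 1", {
  fx <- make_cohort(n = 60, p = 71, seed = 4)
  res <- maybe_skip_selection(fx$cohort, selection_config(), M_min = 20)
  expect_identical(res$scenario, "skipped")
  expect_length(res$selected, 71L)
  expect_equal(res$mean_stability, 1.0)
  expect_true(all(res$table$stability == 1))
})

test_that("ensemble rankings have the right shape, seeds and error paths", {
  fx <- make_cohort(n = 100, p = 110, seed = 6, scheme = "binary_case_control")
  cfg <- selection_config()
  r1 <- train_fold_rankings(fx$cohort, cfg)
  expect_length(r1, 15L)
  expect_true(all(vapply(r1, length, 1L) == 110L))
  expect_setequal(unique(vapply(r1, attr, "", "classifier")),
                  c("gbt", "logistic", "random_forest"))
  # determinism: identical seeds give identical importance vectors
  r2 <- train_fold_rankings(fx$cohort, cfg)
  expect_equal(r1, r2)

  single <- fx$cohort
  single$meta$Outcome <- "Tumor"
  single$outcome_order <- "Tumor"
  expect_error(train_fold_rankings(single, cfg), class = "eb_config_error")

  tiny <- fx$cohort
  tiny$meta$Outcome <- c(rep("A", 97), rep("B", 3))
  tiny$outcome_order <- c("A", "B")
  err <- expect_error(train_fold_rankings(tiny, cfg),
                      class = "eb_config_error")
  expect_match(conditionMessage(err), "folds")
})

test_that("planted informative features are recovered at high effect size", {
  # event boundaries are aligned with the outcome classes (S = 2, three
  # ordered classes) so every planted biomarker carries between-class signal
  spec <- generator_spec(n_subjects = 150, n_features = 600,
                         n_informative = 30, n_stages = 2, effect_size = 5,
                         noise_sd = 1, outcome_scheme = "ordered_three_class",
                         seed = 9)
  g <- generate_cohort(spec)
  X <- as.matrix(g$data[, -1]); rownames(X) <- g$data$SubjectID
  cohort <- new_cohort(X, g$meta, outcome_order = g$outcome_order)
  res <- maybe_skip_selection(cohort, selection_config(U_max = 40),
                              M_min = 20)
  # every planted feature crosses the stability threshold ...
  inf_S <- res$table$stability[res$table$feature %in% g$truth$informative]
  expect_true(all(inf_S > 0.5))
  # ... and selection recovers at least 90% of them
  recall <- mean(g$truth$informative %in% res$selected)
  expect_gte(recall, 0.9)
  # the feature space shrinks by >= 90% here (>= 97% at full scale)
  expect_lte(length(res$selected) / 600, 0.1)
})

test_that("null effect gives planted features no stability advantage", {
  spec <- generator_spec(n_subjects = 120, n_features = 200,
                         n_informative = 20, n_stages = 4, effect_size = 0,
                         noise_sd = 1, outcome_scheme = "binary_case_control",
                         seed = 10)
  g <- generate_cohort(spec)
  X <- as.matrix(g$data[, -1]); rownames(X) <- g$data$SubjectID
  cohort <- new_cohort(X, g$meta, outcome_order = g$outcome_order,
                       baseline = g$baseline)
  rk <- train_fold_rankings(cohort, selection_config())
  tab <- stability_scores(rk, determine_k(200, 150))
  inf <- tab$stability[tab$feature %in% g$truth$informative]
  noi <- tab$stability[!tab$feature %in% g$truth$informative]
  # indistinguishable stability: no material mean shift in favour of the
  # (now signal-free) planted set
  expect_lt(abs(mean(inf) - mean(noi)), 0.15)
})
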