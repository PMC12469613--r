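# Event-based model: distributions, likelihood arithmetic, EM recovery,
# MCMC positional confidence, and subject assignment.

test_that("event distributions recover class moments with a baseline", {
  set.seed(21)
  n <- 200
  X <- cbind(B1 = c(rnorm(n), rnorm(n, 3)),
             B2 = c(rnorm(n, 1, 2), rnorm(n, 6, 2)))
  rownames(X) <- sprintf("S%03d", seq_len(2 * n))
  meta <- data.frame(SubjectID = rownames(X),
                     Outcome = rep(c("Control", "Case"), each = n),
                     stringsAsFactors = FALSE)
  co <- new_cohort(X, meta, outcome_order = c("Control", "Case"),
                   baseline = "Control")
  d <- fit_event_distributions(co)
  expect_lt(abs(d$mu_pre[d$feature == "B1"] - 0), 0.2)
  expect_lt(abs(d$mu_post[d$feature == "B1"] - 3), 0.2)
  expect_lt(abs(d$mu_post[d$feature == "B2"] - 6), 0.4)
  expect_true(all(d$sd_pre > 0 & d$sd_post > 0))
})

test_that("degenerate and no-baseline inputs take the documented paths", {
  set.seed(22)
  X <- cbind(Flat = rep(2, 60),
             Mix = c(rnorm(30), rnorm(30, 5)))
  rownames(X) <- sprintf("S%02d", 1:60)
  meta <- data.frame(SubjectID = rownames(X),
                     Outcome = rep(c("g1", "g2", "g3"), 20),
                     stringsAsFactors = FALSE)
  co <- new_cohort(X, meta)  # no baseline -> mixture path
  d <- fit_event_distributions(co)
  expect_true(all(is.finite(d$sd_pre)) && all(d$sd_pre > 0))
  expect_lt(d$mu_pre[d$feature == "Mix"], 1)
  expect_gt(d$mu_post[d$feature == "Mix"], 4)

  # tiny baseline class falls back to the mixture fit with a warning
  meta2 <- data.frame(SubjectID = rownames(X),
                      Outcome = c(rep("Control", 2), rep("Case", 58)),
                      stringsAsFactors = FALSE)
  co2 <- new_cohort(X, meta2, outcome_order = c("Control", "Case"),
                    baseline = "Control")
  expect_warning(fit_event_distributions(co2), class = "eb_model_warning")
})

test_that("stage log-likelihood matches a hand-computed normal sum", {
  dists <- data.frame(feature = c("A", "B"),
                      mu_pre = c(0, 0), sd_pre = c(1, 1),
                      mu_post = c(3, 3), sd_post = c(1, 2))
  x <- c(A = 2.5, B = -0.5)
  z <- c(A = 1L, B = 2L)
  # s = 0: both pre; s = 1: A post, B pre; s = 2: both post
  expect_equal(subject_stage_loglik(x, z, 0, dists),
               dnorm(2.5, 0, 1, log = TRUE) + dnorm(-0.5, 0, 1, log = TRUE))
  expect_equal(subject_stage_loglik(x, z, 1, dists),
               dnorm(2.5, 3, 1, log = TRUE) + dnorm(-0.5, 0, 1, log = TRUE))
  expect_equal(subject_stage_loglik(x, z, 2, dists),
               dnorm(2.5, 3, 1, log = TRUE) + dnorm(-0.5, 3, 2, log = TRUE))
})

test_that("the E-step normalises responsibilities and honours the prior", {
  fx <- make_cohort(n = 50, p = 12, S = 3, seed = 30)
  dists <- fit_event_distributions(fx$cohort)
  z <- stats::setNames(rep(1:3, each = 4), colnames(fx$cohort$X))
  es <- e_step(fx$cohort, list(z, z), dists, pi = c(1, 0))
  sums <- apply(es$r, 1L, sum)
  expect_equal(sums, rep(1, 50), tolerance = 1e-9)
  # zero-prior subtype receives zero responsibility
  expect_true(all(es$r[, 2, ] == 0))
  expect_true(is.finite(es$loglik))

  # a subject sitting at the baseline means goes MAP stage 0
  co <- fx$cohort
  co$X[1, ] <- dists$mu_pre
  es2 <- e_step(co, list(z), dists, pi = 1)
  expect_identical(which.max(es2$r[1, 1, ]), 1L)  # slot 1 = stage 0
})

test_that("EM recovers a planted single-subtype partition at low noise", {
  fx <- make_cohort(n = 150, p = 24, K = 1, S = 4, effect = 5, noise = 0.5,
                    seed = 31)
  cfg <- ebm_config(n_subtypes = 1, n_stages = 4, min_cluster = 6,
                    em_iters = 25, mcmc_burnin = 50, mcmc_final = 200,
                    seed = 7)
  m <- run_em(fx$cohort, cfg)
  # loglik trace non-decreasing (within tolerance)
  expect_true(all(diff(m$loglik_trace) > -1e-6))
  agree <- mean(m$partitions[[1]][fx$truth$informative] ==
                  fx$truth$partitions[[1]])
  expect_gte(agree, 0.9)
  # determinism
  m2 <- run_em(fx$cohort, cfg)
  expect_identical(m$partitions, m2$partitions)
  expect_equal(m$loglik_trace, m2$loglik_trace)
})

test_that("uninformative data keep the incumbent ordering at the M-step", {
  set.seed(33)
  X <- matrix(5, 40, 12, dimnames = list(sprintf("S%02d", 1:40),
                                         sprintf("F%02d", 1:12)))
  meta <- data.frame(SubjectID = rownames(X),
                     Outcome = rep(c("a", "b"), 20),
                     stringsAsFactors = FALSE)
  co <- new_cohort(X, meta)
  dists <- data.frame(feature = colnames(X), mu_pre = 0, sd_pre = 1,
                      mu_post = 1, sd_post = 1)
  z <- stats::setNames(rep(1:3, each = 4), colnames(X))
  es <- e_step(co, list(z), dists, pi = 1)
  ms <- m_step(co, es$r, dists, list(z))
  expect_identical(ms$partitions[[1]], z)
  expect_equal(sum(ms$pi), 1)
})

test_that("EM + MCMC attain the enumerated optimum on separable data", {
  # brute-force oracle: M = 6 biomarkers, S = 3 stages, K = 1; enumerate
  # every ordered partition with clusters of at least 2
  fx <- make_cohort(n = 120, p = 6, K = 1, S = 3, effect = 5, noise = 0.5,
                    seed = 35)
  co <- fx$cohort
  dists <- fit_event_distributions(co)
  parts <- list()
  for (ord in all_orderings(6L)) {
    parts <- c(parts, enumerate_partitions(ord, S = 3L, min_size = 2L))
  }
  parts <- unique(parts)
  lls <- vapply(parts, function(z) {
    names(z) <- colnames(co$X)
    partition_loglik(co$X, dists, z)
  }, numeric(1))
  best_ll <- max(lls)

  cfg <- ebm_config(n_subtypes = 1, n_stages = 3, min_cluster = 2,
                    em_iters = 25, mcmc_burnin = 200, mcmc_final = 500,
                    seed = 3)
  m <- run_em(co, cfg, dists = dists)
  em_ll <- partition_loglik(co$X, dists, m$partitions[[1]])
  expect_equal(em_ll, best_ll, tolerance = 1e-8)
})

test_that("positional confidence rows are frequencies with modal agreement", {
  fx <- make_cohort(n = 200, p = 24, K = 1, S = 4, effect = 6, noise = 0.5,
                    seed = 36)
  cfg <- ebm_config(n_subtypes = 1, n_stages = 4, min_cluster = 6,
                    em_iters = 20, mcmc_burnin = 500, mcmc_final = 2000,
                    seed = 5)
  m <- run_em(fx$cohort, cfg)
  # at this separation the EM optimum is sharp enough that burn-in may
  # accept nothing; the sampler warns about it by design
  conf <- suppressWarnings(run_mcmc(m))
  P <- conf$P[[1]]
  expect_equal(unname(rowSums(P)), rep(1, 24), tolerance = 1e-9)
  modal <- apply(P, 1, which.max)
  expect_gte(mean(modal == m$partitions[[1]][rownames(P)]), 0.9)
})

test_that("pure-noise data leave the ordering posterior near uniform", {
  set.seed(37)
  X <- matrix(rnorm(80 * 12), 80, 12,
              dimnames = list(sprintf("S%02d", 1:80), sprintf("F%02d", 1:12)))
  meta <- data.frame(SubjectID = rownames(X),
                     Outcome = rep(c("a", "b"), 40),
                     stringsAsFactors = FALSE)
  co <- new_cohort(X, meta)
  dists <- data.frame(feature = colnames(X), mu_pre = -0.2, sd_pre = 1,
                      mu_post = 0.2, sd_post = 1)
  cfg <- ebm_config(n_subtypes = 1, n_stages = 3, min_cluster = 2,
                    em_iters = 5, mcmc_burnin = 1000, mcmc_final = 10000,
                    seed = 8)
  m <- run_em(co, cfg, dists = dists)
  conf <- run_mcmc(m)
  P <- conf$P[[1]]
  # every biomarker visits several stages; no deterministic staircase
  expect_lt(max(P), 0.95)
  expect_gt(mean(apply(P, 1, function(r) sum(r > 0.05))), 2)
})

test_that("two planted subtypes with disjoint orderings are recovered", {
  spec <- generator_spec(n_subjects = 200, n_features = 71,
                         n_informative = 71, n_subtypes = 2, n_stages = 4,
                         effect_size = 5, noise_sd = 1,
                         outcome_scheme = "ordered_three_class",
                         outcome_props = c(0.1, 0.8, 0.1), seed = 11)
  g <- generate_cohort(spec)
  X <- as.matrix(g$data[, -1]); rownames(X) <- g$data$SubjectID
  co <- new_cohort(X, g$meta, outcome_order = g$outcome_order)
  cfg <- ebm_config(n_subtypes = 2, n_stages = 4, min_cluster = 10,
                    em_iters = 30, mcmc_burnin = 50, mcmc_final = 100,
                    seed = 42, n_starts = 8)
  m <- run_em(co, cfg)
  a <- assign_subjects(m)
  expect_gte(subtype_accuracy2(a$Subtype, g$truth$subtype), 0.9)
  agree <- vapply(1:2, function(k) {
    max(vapply(1:2, function(kt) {
      mean(m$partitions[[k]][g$truth$informative] == g$truth$partitions[[kt]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(agree >= 0.8))
})

test_that("MAP assignment breaks ties toward lower stage then subtype", {
  r <- array(0, c(2, 2, 4))
  r[1, 2, 3] <- 0.6; r[1, 1, 1] <- 0.4      # clear MAP: subtype 2, stage 2
  r[2, 1, 2] <- 0.5; r[2, 1, 3] <- 0.5      # tie between stages 1 and 2
  model <- structure(list(
    posterior = r,
    cohort = list(meta = data.frame(SubjectID = c("S1", "S2"),
                                    Outcome = c("a", "b")))),
    class = "eb_model")
  a <- assign_subjects(model)
  expect_identical(a$Subtype, c(2L, 1L))
  expect_identical(a$Stage, c(2L, 1L))
  expect_equal(a$PosteriorProb, c(0.6, 0.5))
  expect_identical(nrow(a), 2L)
})

test_that("config guards reject infeasible stage/cluster combinations", {
  fx <- make_cohort(n = 30, p = 12, S = 3, seed = 39)
  cfg <- ebm_config(n_subtypes = 1, n_stages = 3, min_cluster = 5)
  expect_error(run_em(fx$cohort, cfg), class = "eb_config_error")
})
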