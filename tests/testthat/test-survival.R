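# Kaplan-Meier, log-rank, Cox hazard ratio and cutpoint dichotomization
# against closed forms and grid-search / hand-worked oracles.

test_that("KM product-limit estimates match telescoping products", {
  # 22 subjects, 7 events at distinct times before month 36, no censoring
  tab <- survival_table(paste0("s", 1:22),
                        time = c(2, 5, 9, 14, 20, 26, 33, rep(40, 15)),
                        event = c(rep(1, 7), rep(0, 15)))
  km <- km_estimate(tab)
  expect_equal(km_surv_at(km, 36), 15 / 22, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 1), 1)

  # no events: S(t) = 1 everywhere
  none <- survival_table(paste0("s", 1:5), time = 1:5, event = rep(0, 5))
  expect_equal(km_surv_at(km_estimate(none), c(1, 10)), c(1, 1))

  # single subject with an event at t = 5
  one <- survival_table("s1", 5, 1)
  expect_equal(km_surv_at(km_estimate(one), 5), 0)

  # without censoring, S(t) = 1 - ECDF exactly
  set.seed(9)
  times <- round(rexp(30, 0.1) + 0.5, 3)
  full <- survival_table(paste0("s", 1:30), times, rep(1, 30))
  kmf <- km_estimate(full)
  qs <- seq(0.5, max(times) + 1, length.out = 40)
  expect_equal(km_surv_at(kmf, qs), 1 - ecdf(times)(qs), tolerance = 1e-12)

  # record order never matters
  perm <- full[sample(30), ]
  expect_equal(km_surv_at(km_estimate(perm), qs), km_surv_at(kmf, qs))
})

test_that("log-rank matches the hand-worked two-event risk tables", {
  # A: events at 1, 2; B: censored at 3, 3
  tab <- survival_table(paste0("s", 1:4), c(1, 2, 3, 3), c(1, 1, 0, 0),
                        group = c("A", "A", "B", "B"))
  res <- logrank_test(tab)
  # t=1: O-E = 1 - 2/4, V = .25; t=2: O-E = 1 - 1/3, V = 2/9
  # chi = (7/6)^2 / (17/36) = 49/17
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # identical groups: statistic 0, p = 1
  dup <- survival_table(paste0("s", 1:8), rep(c(1, 3, 5, 7), 2),
                        rep(c(1, 0, 1, 0), 2),
                        group = rep(c("A", "B"), each = 4))
  same <- logrank_test(dup)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(survival_table("s1", 1, 1, group = "A")), "2 nonempty")
})

test_that("log-rank p-values are calibrated under label permutation", {
  set.seed(55)
  times <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.8)
  ps <- vapply(1:500, function(i) {
    g <- sample(rep(c("A", "B"), 20))
    logrank_test(survival_table(paste0("s", 1:40), times, ev, group = g))$p_value
  }, numeric(1))
  hits <- sum(ps < 0.05)
  band <- qbinom(c(0.005, 0.995), 500, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("Cox HR matches a partial-likelihood grid search", {
  tab <- survival_table(paste0("s", 1:6), c(1, 2, 3, 4, 5, 6),
                        c(1, 1, 1, 1, 0, 0),
                        group = c("A", "A", "B", "B", "A", "B"))
  fit <- cox_hr(tab)
  grid <- seq(-4, 4, by = 1e-4)
  x <- as.numeric(tab$group == "B")
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = tab$time, event = tab$event, x = x)
  expect_equal(fit$log_hr, grid[which.max(ll)], tolerance = 1e-3)

  # exchangeable groups -> HR = 1
  dup <- survival_table(paste0("s", 1:8), rep(c(1, 3, 5, 7), 2),
                        rep(1, 8), group = rep(c("A", "B"), each = 4))
  expect_equal(cox_hr(dup)$hr, 1, tolerance = 1e-8)

  # zero events in one group -> divergence flag, no finite estimate
  mono <- survival_table(paste0("s", 1:8), c(1:4, 11:14),
                         c(1, 1, 1, 1, 0, 0, 0, 0),
                         group = rep(c("A", "B"), each = 4))
  expect_true(cox_hr(mono)$diverged)
  expect_error(cox_hr(survival_table(paste0("s", 1:4), 1:4, rep(0, 4),
                                     group = rep(c("A", "B"), 2))),
               "no events")
})

test_that("Cox recovers a true two-group hazard ratio with small bias", {
  lhr <- vapply(1:200, function(i) {
    tab <- generate_survival(n = c(A = 100, B = 100),
                             hazard_by_group = c(A = 0.05, B = 0.1),
                             censor_time = 60, rng_seed = 5000 + i)
    cox_hr(tab)$log_hr
  }, numeric(1))
  expect_lt(abs(mean(lhr) - log(2)), 0.05)
})

test_that("dichotomization honors the median and best-cutpoint rules", {
  scores <- 1:10
  tab <- survival_table(paste0("s", 1:10), c(1, 2, 3, 4, 5, 20, 22, 24, 26, 28),
                        c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  med <- dichotomize(scores, tab, cutpoint_params("median"))
  expect_equal(med$labels, rep(c("low", "high"), each = 5))  # strict > median

  best <- dichotomize(scores, tab, cutpoint_params("best", min_prop = 0.1))
  # candidates leave >= 1 subject on each side: cut 10 (zero high) excluded
  expect_lt(best$cutpoint, 10)
  # chosen cutpoint maximizes the standardized log-rank over candidates
  # (independent survdiff sweep)
  oracle_stat <- vapply(1:9, function(cc) {
    g <- ifelse(scores > cc, "high", "low")
    sqrt(survival::survdiff(survival::Surv(tab$time, tab$event) ~ g)$chisq)
  }, numeric(1))
  expect_equal(best$cutpoint, which.max(oracle_stat))
  expect_equal(best$statistic, max(oracle_stat), tolerance = 1e-12)
  expect_error(dichotomize(rep(1, 10), tab), "all scores equal")
  expect_error(dichotomize(1:3, tab[1:3, ]), ">= 4 subjects")
})

test_that("best cutpoint recovers a planted hazard boundary", {
  # hazard ratio 3 between the score halves; the maximally selected
  # estimator has O(1)-rank error, so recovery is asserted within a
  # +-10%-of-cohort window around the planted boundary
  n_side <- 50
  hitrate <- mean(vapply(1:100, function(i) {
    tab <- generate_survival(n = c(low = n_side, high = n_side),
                             hazard_by_group = c(low = 0.15, high = 0.05),
                             censor_time = 40, rng_seed = 800 + i)
    scores <- seq_len(2 * n_side)      # low group = first half of scores
    cut <- dichotomize(scores, tab, cutpoint_params("best", 0.1))$cutpoint
    abs(cut - n_side) <= 0.1 * 2 * n_side
  }, logical(1)))
  expect_gte(hitrate, 0.90)
})

test_that("EFS takes the first component event; OS takes death", {
  clin <- data.frame(subject_id = paste0("p", 1:4),
                     progression = c(10, NA, NA, NA),
                     recurrence = c(12, 8, NA, NA),
                     metastasis = c(NA, NA, NA, NA),
                     death = c(15, NA, 20, NA),
                     last_followup = c(20, 30, 25, 36))
  efs <- derive_endpoint(clin, "EFS")
  expect_equal(efs$time, c(10, 8, 20, 36))
  expect_equal(efs$event, c(1, 1, 1, 0))
  os <- derive_endpoint(clin, "OS")
  expect_equal(os$time, c(15, 30, 20, 36))
  expect_equal(os$event, c(1, 0, 1, 0))
})
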