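test_that("KM equals the empirical survival function without censoring", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1)
  km <- km_estimate(d)
  curve <- tidy(km)
  expect_equal(curve$estimate, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$medians$median, 2)

  # all censored: S stays 1, median not reached
  dc <- data.frame(time = 1:5, event = 0)
  expect_warning(kmc <- km_estimate(dc), "no events")
  expect_true(all(tidy(kmc)$estimate == 1))
  expect_true(is.na(kmc$medians$median))
})

test_that("KM matches a direct product-limit hand computation with censoring", {
  # hand oracle: iterate event times, multiply (1 - d_i / n_i)
  km_oracle <- function(time, event) {
    ord <- order(time)
    time <- time[ord]
    event <- event[ord]
    s <- 1
    out <- numeric(0)
    times <- numeric(0)
    for (tt in unique(time[event == 1])) {
      n_risk <- sum(time >= tt)
      d <- sum(time == tt & event == 1)
      s <- s * (1 - d / n_risk)
      out <- c(out, s)
      times <- c(times, tt)
    }
    list(time = times, surv = out)
  }
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (!any(event == 1)) event[1] <- 1
    d <- data.frame(time = time, event = event)
    km <- km_estimate(d)
    o <- km_oracle(time, event)
    got <- tidy(km)
    got_ev <- got[got$n.event > 0, ]
    expect_equal(got_ev$time, o$time)
    expect_equal(got_ev$estimate, o$surv)
  }
})

test_that("log-rank: identical groups give statistic 0, p = 1", {
  d <- data.frame(time = rep(c(1, 2, 3), 2), event = 1,
                  group = rep(c("a", "b"), each = 3))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("log-rank detects HR = 2 with high power at n = 500 per arm", {
  reject <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(
      time = c(rexp(500, 0.2), rexp(500, 0.4)),
      event = 1,
      group = rep(c("lo", "hi"), each = 500)
    )
    logrank_test(d)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("Cox score test equals the log-rank statistic for a binary covariate", {
  set.seed(12)
  d <- data.frame(
    time = rexp(60) + (1:60) * 1e-6, # continuous, no ties
    event = rbinom(60, 1, 0.8),
    group = rep(c(0, 1), 30)
  )
  lr <- logrank_test(d)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  expect_equal(unname(summary(cx)$sctest["test"]), lr$statistic,
               tolerance = 1e-8)
})

test_that("multivariate Cox applies the strict p < 0.05 univariate entry rule", {
  set.seed(13)
  n <- 300
  strong <- rbinom(n, 1, 0.5)
  weak <- rnorm(n)
  time <- rexp(n, 0.2 * exp(-0.8 * strong))
  d <- data.frame(time = time, event = 1, strong = strong, weak = weak)
  res <- cox_fit(d, c("strong", "weak"), mode = "multivariate")
  uni <- res[res$analysis == "univariate", ]
  entered <- unique(res$covariate[res$analysis == "multivariate"])
  should_enter <- unique(uni$covariate[uni$p < 0.05])
  expect_setequal(entered, should_enter)
  expect_true("strong" %in% entered)
  # a covariate at p >= 0.05 never enters
  expect_true(all(res$p[res$analysis == "univariate" &
                        !res$covariate %in% entered] >= 0.05))
})

test_that("Cox recovers a planted group log-hazard and flags separation", {
  set.seed(14)
  n <- 1000
  grp <- rep(c(0, 1), n / 2)
  d <- data.frame(time = rexp(n, 0.3 * exp(-0.4 * grp)), event = 1, group = grp)
  res <- cox_fit(d, "group")
  expect_lt(abs(res$estimate + 0.4), 0.15)
  expect_true(res$ci_lower <= res$hr & res$hr <= res$ci_upper)
})

test_that("rank and count statistics match their closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_true(spearman_cor(rep(1, 5), x)$undefined)

  expect_equal(wilcoxon_rank_sum(x, x)$p, 1, tolerance = 0.05)

  ft <- fisher_or(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ft$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(is.infinite(ft$or_sample))

  ft2 <- fisher_or(matrix(c(8, 2, 3, 9), 2))
  base_ft <- fisher.test(matrix(c(8, 2, 3, 9), 2))
  expect_equal(ft2$p, base_ft$p.value)
  expect_equal(ft2$or_conditional_mle, unname(base_ft$estimate))
})

test_that("response comparisons cover exactly the two stated contrasts", {
  set.seed(15)
  pred <- tibble::tibble(sample_id = 1:60, score = rnorm(60),
                         group = "high")
  resp <- rep(c("responder", "stable", "progressive"), each = 20)
  rc <- response_comparison(pred, resp)
  expect_equal(rc$comparison,
               c("responder vs progressive", "stable vs progressive"))
  expect_false(any(rc$skipped))
  # shifted responders: both p small with a +3 SD shift
  pred2 <- pred
  pred2$score[resp != "progressive"] <- pred2$score[resp != "progressive"] + 3
  rc2 <- response_comparison(pred2, resp)
  expect_true(all(rc2$p < 0.001))
  # an empty category is skipped with a note
  # with no progressive subjects both comparisons are skipped with a note
  rc3 <- response_comparison(pred[1:40, ], resp[1:40])
  expect_true(all(rc3$skipped))
  expect_true(all(is.na(rc3$p)))
})

test_that("group label permutations give uniform p under the null", {
  set.seed(16)
  n <- 40
  d <- data.frame(time = rexp(n, 0.3), event = rbinom(n, 1, 0.8))
  ps <- vapply(1:300, function(i) {
    d$group <- sample(rep(c("a", "b"), n / 2))
    logrank_test(d)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
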