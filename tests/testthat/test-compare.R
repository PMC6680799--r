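test_that("pairwise differences form the festival-minus-pre cross product", {
  expect_setequal(pairwise_diffs(c(1, 2), 4), c(3, 2))
  expect_length(pairwise_diffs(rnorm(19), rnorm(19)), 361)
  expect_true(all(pairwise_diffs(rep(3, 5), rep(3, 4)) == 0))
})

test_that("parameter transforms follow their definitions", {
  expect_equal(apply_transform(0, "log_di"), log(1 + 1e-6))
  expect_equal(apply_transform(c(-30, 10), "shift_min"), c(0, 40))
  z <- apply_transform(rnorm(50, 5, 2), "zscore")
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(apply_transform(-1, "log_di", eps = 0), "eps")
})

test_that("build_diffs counts usable day pairs and excludes empty phases", {
  daily <- tibble::tibble(
    individual_id = rep(c("a", "b"), each = 6),
    phase = rep(rep(c("pre", "festival"), each = 3), 2),
    val = c(1, 2, 3, 4, 5, 6, 1, NA, NA, 2, 2, 2)
  )
  d <- build_diffs(daily, "val", transform = "identity")
  expect_equal(sum(d$individual_id == "a"), 9)
  expect_equal(sum(d$individual_id == "b"), 3)
  daily$val[daily$individual_id == "b" & daily$phase == "festival"] <- NA
  expect_warning(d2 <- build_diffs(daily, "val", transform = "identity"),
                 "excluded")
  expect_false("b" %in% d2$individual_id)
})

test_that("REML fit matches the balanced one-way random-effects closed form", {
  set.seed(60)
  n_id <- 6; m <- 30
  ids <- rep(sprintf("i%02d", 1:n_id), each = m)
  y <- rep(rnorm(n_id, -1, 2), each = m) + rnorm(n_id * m, 0, 3)
  f <- fit_random_intercept(tibble::tibble(individual_id = ids, diff = y))
  gm <- tapply(y, ids, mean)
  MSB <- m * var(gm)
  MSW <- sum((y - ave(y, ids))^2) / (n_id * m - n_id)
  expect_equal(f$mu, mean(gm), tolerance = 1e-6)
  expect_equal(f$sigma_e, sqrt(MSW), tolerance = 1e-6)
  expect_equal(f$sigma_b, sqrt((MSB - MSW) / m), tolerance = 1e-6)
  shrink <- ((MSB - MSW) / m) / ((MSB - MSW) / m + MSW / m)
  blup <- mean(gm) + shrink * (gm - mean(gm))
  expect_equal(f$estimates$pred_change,
               as.numeric(blup[f$estimates$individual_id]), tolerance = 1e-6)
})

test_that("predictions shrink toward the grand mean and approach truth as noise vanishes", {
  set.seed(61)
  ids <- rep(c("a", "b", "c", "d"), each = 20)
  truth <- c(a = -3, b = -1, c = 1, d = 3)
  y <- truth[ids] + rnorm(80, 0, 1e-4)
  # near-zero residual variance sits at the edge of lmer's numerics
  f <- suppressWarnings(
    fit_random_intercept(tibble::tibble(individual_id = ids, diff = y)))
  expect_equal(unname(f$estimates$pred_change),
               unname(truth[f$estimates$individual_id]), tolerance = 1e-3)
  expect_true(all(f$estimates$ci_hi - f$estimates$ci_lo < 0.01))
  # with real noise, each BLUP lies between the grand mean and the raw mean
  y2 <- truth[ids] + rnorm(80, 0, 3)
  f2 <- fit_random_intercept(tibble::tibble(individual_id = ids, diff = y2))
  raw <- tapply(y2, ids, mean)
  for (i in seq_len(4)) {
    id <- f2$estimates$individual_id[i]
    lo <- min(f2$mu, raw[id]); hi <- max(f2$mu, raw[id])
    expect_gte(f2$estimates$pred_change[i], lo - 1e-8)
    expect_lte(f2$estimates$pred_change[i], hi + 1e-8)
  }
})

test_that("interval coverage is nominal when differences are independent draws", {
  # model-generated data: mu = -2, sigma_b = 1, sigma_e = 3
  set.seed(62)
  n_id <- 8; m <- 100
  mus <- numeric(40); cover <- 0; tot <- 0
  for (s in 1:40) {
    b <- rnorm(n_id, 0, 1)
    ids <- rep(sprintf("i%d", 1:n_id), each = m)
    y <- -2 + rep(b, each = m) + rnorm(n_id * m, 0, 3)
    f <- fit_random_intercept(tibble::tibble(individual_id = ids, diff = y))
    mus[s] <- f$mu
    truth <- -2 + b
    names(truth) <- sprintf("i%d", 1:n_id)
    est <- f$estimates
    cover <- cover + sum(est$ci_lo <= truth[est$individual_id] &
                           truth[est$individual_id] <= est$ci_hi)
    tot <- tot + n_id
  }
  expect_equal(mean(mus), -2, tolerance = 0.25)
  expect_gte(cover / tot, 0.90)
  expect_lte(cover / tot, 0.99)
})

test_that("degenerate between-individual variance falls back to a pooled intercept", {
  set.seed(63)
  ids <- rep(c("a", "b", "c"), each = 30)
  y <- rnorm(90, 2, 0.5)  # no between-individual structure
  f <- fit_random_intercept(tibble::tibble(individual_id = ids, diff = y))
  if (f$pooled) {
    expect_true(all(f$estimates$pred_change == f$mu))
  }
  expect_error(fit_random_intercept(tibble::tibble(individual_id = "a",
                                                   diff = c(1, 2))),
               "2 individuals")
})

test_that("change summaries count signs of significant changes correctly", {
  set.seed(64)
  ids <- rep(sprintf("i%d", 1:6), each = 50)
  strong_neg <- tibble::tibble(individual_id = ids,
                               diff = rnorm(300, -5, 0.5))
  f_neg <- fit_random_intercept(strong_neg)
  s <- summarize_changes(list(par = f_neg))
  expect_equal(s$n_decrease, 6)
  expect_equal(s$n_increase, 0)
  # mixed truth: half decrease, half increase
  truth <- rep(c(-4, 4), each = 3)[as.integer(factor(ids))]
  mixed <- tibble::tibble(individual_id = ids,
                          diff = truth + rnorm(300, 0, 1))
  f_mix <- fit_random_intercept(mixed)
  est <- f_mix$estimates
  expect_true(all(sign(est$pred_change) ==
                    rep(c(-1, 1), each = 3)[as.integer(factor(est$individual_id))]))
  s2 <- summarize_changes(list(par = f_mix))
  expect_equal(s2$n_decrease, 3)
  expect_equal(s2$n_increase, 3)
})

test_that("duplicating one individual's rows barely moves its prediction", {
  set.seed(65)
  ids <- rep(c("a", "b", "c", "d", "e"), each = 40)
  y <- rep(rnorm(5, 0, 2), each = 40) + rnorm(200, 0, 2)
  d <- tibble::tibble(individual_id = ids, diff = y)
  f1 <- fit_random_intercept(d)
  d2 <- rbind(d, d[d$individual_id == "a", ])
  f2 <- fit_random_intercept(d2)
  p1 <- f1$estimates$pred_change[f1$estimates$individual_id == "a"]
  p2 <- f2$estimates$pred_change[f2$estimates$individual_id == "a"]
  expect_equal(p2, p1, tolerance = 0.05)
})

test_that("an injected reduction yields negative predicted changes end to end", {
  daily <- tibble::tibble(
    individual_id = rep(sprintf("i%d", 1:4), each = 10),
    phase = rep(rep(c("pre", "festival"), each = 5), 4),
    val = NA_real_
  )
  set.seed(66)
  daily$val <- ifelse(daily$phase == "pre", rnorm(40, 10, 1),
                      rnorm(40, 7, 1))
  f <- fit_random_intercept(build_diffs(daily, "val", transform = "identity"))
  expect_true(all(f$estimates$pred_change < 0))
})
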