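mk_checks <- function(nests, start = "2016-08-10", id = "N01", sex = "m") {
  tibble::tibble(
    individual_id = id, sex = sex,
    date = as.Date(start) + seq_along(nests) - 1,
    nest_id = nests
  )
}

small_cal <- phase_calendar(study_config(n_individuals = 1, pre_days = 19,
                                         festival_days = 19, post_days = 5))

test_that("spells are run-length coded with events and boundary censoring", {
  sp <- build_spells(mk_checks(c("A", "A", "A", "B")), small_cal)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$duration, c(3L, 1L))
  expect_equal(sp$event, c(1L, 0L))
  expect_equal(sp$nest_id, c("A", "B"))
  # a spell spanning the phase boundary (28 -> 29 Aug) is censored there
  sp2 <- build_spells(mk_checks(rep("A", 25)), small_cal)
  expect_equal(nrow(sp2), 2)
  expect_equal(sp2$event, c(0L, 0L))
  expect_equal(sp2$duration, c(19L, 6L))
  expect_equal(sp2$phase, c("non_festival", "festival"))
  # carry mode assigns the whole spell to the phase of its start
  sp3 <- build_spells(mk_checks(rep("A", 25)), small_cal, boundary = "carry")
  expect_equal(nrow(sp3), 1)
  expect_equal(sp3$duration, 25L)
  expect_equal(sp3$phase, "non_festival")
  # gaps censor and flag
  ck <- mk_checks(c("A", "A", "A", "A"))
  ck <- ck[-2, ]
  sp4 <- build_spells(ck, small_cal)
  expect_equal(sp4$event, c(0L, 0L))
  expect_true(sp4$gap_flag[1])
  # conflicting duplicates error with the date
  dup <- rbind(mk_checks(c("A", "A")), mk_checks("B", start = "2016-08-11"))
  expect_error(build_spells(dup, small_cal), "2016-08-11")
})

test_that("total spell durations equal monitored nest-days", {
  st <- small_study()
  sp <- build_spells(st$nests, st$calendar)
  days_per_ind <- table(st$nests$individual_id)
  dur_per_ind <- tapply(sp$duration, sp$individual_id, sum)
  expect_equal(as.numeric(dur_per_ind[names(days_per_ind)]),
               as.numeric(days_per_ind))
})

test_that("Kaplan-Meier curve matches the hand product-limit estimate", {
  sp <- tibble::tibble(duration = c(1, 2, 3), event = 1)
  km <- km_curve(sp)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # first factor: S(1) = 1 - e1/n
  sp2 <- tibble::tibble(duration = c(1, 1, 2, 5, 5), event = c(1, 1, 1, 0, 0))
  km2 <- km_curve(sp2)
  expect_equal(km2$surv[km2$time == 1], 1 - 2 / 5)
  # hand product-limit with censoring: S(2) = (1 - 2/5) * (1 - 1/3)
  expect_equal(km2$surv[km2$time == 2], (3 / 5) * (2 / 3))
  # all censored: survival stays at 1
  km3 <- km_curve(tibble::tibble(duration = c(2, 4), event = 0))
  expect_true(all(km3$surv == 1))
  # step function properties
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
  # without censoring the curve is the empirical survival function
  set.seed(50)
  d <- sample(1:8, 30, replace = TRUE)
  km4 <- km_curve(tibble::tibble(duration = d, event = 1))
  emp <- vapply(km4$time, function(t) mean(d > t), numeric(1))
  expect_equal(km4$surv, emp)
})

test_that("log-rank is symmetric and matches a permutation-moment oracle", {
  a <- tibble::tibble(duration = c(1, 2, 4, 5), event = 1)
  b <- tibble::tibble(duration = c(2, 3, 5, 7), event = 1)
  lr <- logrank_test(a, b)
  # oracle: exhaustive enumeration of group labelings; the observed score
  # standardized by the exact permutation moments
  dur <- c(a$duration, b$duration)
  score <- function(gA) {
    U <- 0
    for (t in sort(unique(dur))) {
      at <- dur >= t
      d <- sum(dur == t)
      dA <- sum(dur == t & gA)
      U <- U + dA - d * sum(at & gA) / sum(at)
    }
    U
  }
  combs <- utils::combn(8, 4)
  Us <- apply(combs, 2, function(ix) score(seq_len(8) %in% ix))
  z_perm <- (score(seq_len(8) <= 4) - mean(Us)) / stats::sd(Us)
  p_perm <- 2 * stats::pnorm(-abs(z_perm))
  expect_lt(abs(lr$p - p_perm), 0.021)
  expect_equal(sign(lr$z), sign(z_perm))
  # identical groups: no difference
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$z, 0)
  expect_equal(lr0$p, 1)
  # swapping groups flips Z and keeps p
  sw <- logrank_test(b, a)
  expect_equal(sw$z, -lr$z)
  expect_equal(sw$p, lr$p)
  expect_error(logrank_test(tibble::tibble(duration = 1, event = 0),
                            tibble::tibble(duration = 2, event = 0)),
               "no events")
})

test_that("an elevated male festival hazard shortens male festival spells", {
  cfg <- study_config(n_individuals = 8, pre_days = 19, festival_days = 19,
                      post_days = 5, male_nest_hazard_mult = 2.5)
  st <- simulate_study(cfg, seed = 51)
  sp <- build_spells(st$nests, st$calendar)
  males <- sp[sp$sex == "m", ]
  cmp <- nest_phase_comparison(sp)
  expect_lt(mean(males$duration[males$phase == "festival"]),
            mean(males$duration[males$phase == "non_festival"]))
  # re-use probability drops for males during the festival
  m <- cmp[cmp$sex == "m", ]
  expect_lt(m$reuse_prob_fest, m$reuse_prob_nonfest)
  expect_true(all(c("n_spells", "n_nest_days") %in% names(cmp)))
})
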