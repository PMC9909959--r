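make_profiles <- function(mat, bone = "distal_femur", side = "right") {
  lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    structure(list(volumes_mm3 = v, total_btoi_mm3 = sum(v),
                   pct = 100 * v / sum(v), bone = bone, side = side),
              class = "btv_profile")
  })
}

# simulated %BTV cohorts: lognormal volumes around a base composition. An
# injected shift moves volume from bin 1 into the shifted bin, holding the
# total fixed so the other bins' percentages are untouched (percentages are
# compositional).
sim_profiles <- function(n, shift_bin = NULL, shift = 0, side = "right",
                         bone = "distal_femur") {
  base <- c(300, 280, 240, 170, 90, 50, 25, 12, 6, 3, 2, 1)
  mat <- t(vapply(seq_len(n), function(i) {
    v <- base * rlnorm(12, 0, 0.25)
    if (!is.null(shift_bin)) {
      extra <- v[shift_bin] * (exp(shift) - 1)
      v[shift_bin] <- v[shift_bin] + extra
      v[1] <- max(v[1] - extra, 1)
    }
    v
  }, numeric(12)))
  make_profiles(mat, bone, side)
}

test_that("the KS gate accepts normal samples and rejects uniform ones", {
  withr::local_seed(101)
  accept <- vapply(1:40, function(i) ks_normal(rnorm(1000))$is_normal, TRUE)
  expect_gte(mean(accept), 0.95)
  reject <- vapply(1:40, function(i) ks_normal(runif(1000))$is_normal, TRUE)
  expect_lt(mean(reject), 0.1)
  expect_gte(ks_normal(rnorm(50))$statistic, 0)
})

test_that("the KS gate requires variation and minimum sample size", {
  expect_error(ks_normal(rep(1, 10)), "constant")
  expect_error(ks_normal(c(1, 2)), "at least 3")
})

test_that("identical samples give t = 0 and p = 1", {
  a <- c(3.1, 4.5, 2.2, 5.0, 3.3, 4.1)
  cmp <- compare_groups(a, a)
  expect_identical(cmp$test_used, "student_t")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
})

test_that("the pooled-variance t matches a hand-computed evaluation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test_used, "student_t")
  # closed form: sp2 = 2.5, t = -1/sqrt(2.5 * (1/5 + 1/5)) = -1, df = 8
  expect_equal(cmp$statistic, -1)
  expect_equal(cmp$p_value, 2 * pt(-1, 8))
  expect_identical(cmp$direction, -1)
})

test_that("non-normal data routes to the Mann-Whitney branch", {
  withr::local_seed(102)
  a <- rexp(60)^3  # heavily skewed: fails the gate
  b <- rexp(60)^3
  expect_false(ks_normal(a)$is_normal)
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test_used, "mann_whitney")
  # a constant sample cannot be gated as normal
  cmp2 <- compare_groups(rep(2, 10), c(1, 2, 3, 2, 1, 3))
  expect_identical(cmp2$test_used, "mann_whitney")
})

test_that("degenerate equal constant samples return p = 1 and are flagged", {
  cmp <- compare_groups(rep(5, 4), rep(5, 4))
  expect_identical(cmp$test_used, "degenerate")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)
})

test_that("identical cohorts produce no significant %BTV rows", {
  withr::local_seed(103)
  profs <- sim_profiles(15)
  rep <- btv_report(profs, profs)
  expect_identical(nrow(rep$group_comparison), 12L)
  expect_false(any(rep$group_comparison$significant))
  expect_identical(rep$group_comparison$density_hu[12], "1201-maximum")
  expect_identical(rep$group_comparison$density_hu[1], "100-200")
})

test_that("an injected single-bin shift is flagged in that bin", {
  withr::local_seed(104)
  hits <- 0; false_pos <- integer(10)
  n_seeds <- 20
  for (s in 1:n_seeds) {
    a <- sim_profiles(15, shift_bin = 6, shift = 1.2)
    b <- sim_profiles(15)
    rep <- btv_report(a, b)
    sig <- rep$group_comparison$significant
    if (sig[6] && rep$group_comparison$direction[6] > 0) hits <- hits + 1
    false_pos <- false_pos + sig[-c(1, 6)]  # bin 1 absorbs the compensation
  }
  expect_gte(hits / n_seeds, 0.9)
  expect_true(all(false_pos / n_seeds <= 0.3))
})

test_that("rejection is monotone in effect size", {
  withr::local_seed(105)
  rate <- vapply(c(0, 0.6, 1.5), function(shift) {
    mean(vapply(1:15, function(s) {
      a <- sim_profiles(12, shift_bin = 5, shift = shift)
      b <- sim_profiles(12)
      btv_report(a, b)$group_comparison$significant[5]
    }, TRUE))
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.3)
  expect_gt(rate[3], 0.8)
})

test_that("left-right contrasts appear when both sides are present", {
  withr::local_seed(106)
  a <- c(sim_profiles(8, side = "right"), sim_profiles(8, side = "left"))
  b <- c(sim_profiles(8, side = "right"), sim_profiles(8, side = "left"))
  rep <- btv_report(a, b)
  expect_identical(nrow(rep$group_comparison), 24L)  # 12 rows per side
  expect_false(is.null(rep$left_right))
  expect_setequal(unique(rep$left_right$group), c("judo", "control"))
  # paired option
  rep_p <- btv_report(a, b, paired = TRUE)
  expect_true(all(rep_p$left_right$test == "paired_t"))
})

test_that("mixed bones are rejected", {
  a <- sim_profiles(5, bone = "distal_femur")
  b <- sim_profiles(5, bone = "tibial_plateau")
  expect_error(btv_report(a, b), "mixed bones")
})

test_that("multiple-testing correction is off by default but available", {
  withr::local_seed(107)
  a <- sim_profiles(15, shift_bin = 6, shift = 1.5)
  b <- sim_profiles(15)
  rep_none <- btv_report(a, b)
  expect_identical(rep_none$group_comparison$p_value,
                   rep_none$group_comparison$p_adjusted)
  rep_bonf <- btv_report(a, b, p_adjust = "bonferroni")
  expect_true(all(rep_bonf$group_comparison$p_adjusted >=
                  rep_bonf$group_comparison$p_value))
})
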