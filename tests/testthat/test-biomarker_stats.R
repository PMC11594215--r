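test_that("paired trajectory test matches the hand-computed t on a 3-point example", {
  g <- c(10, 12, 14)
  u <- c(9, 10, 11)
  d <- g - u                        # 1, 2, 3
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  res <- paired_walk_test(g, u)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("degenerate and balanced pairings behave as expected", {
  u <- c(40, 42, 44, 46)
  expect_error(paired_walk_test(u + 5, u), "degenerate")
  expect_error(paired_walk_test(u, u), "degenerate")
  expect_error(paired_walk_test(u, u[1:3]), "equal-length")
  # symmetric differences with zero mean: t = 0, p = 1
  res <- paired_walk_test(u + c(-1, 1, -2, 2), u)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$code, "")
})

test_that("significance codes respect thresholds with boundaries on the weaker side", {
  expect_equal(significance_code(0.005), "**")
  expect_equal(significance_code(0.01), "*")
  expect_equal(significance_code(0.05), "*")
  expect_equal(significance_code(0.1), "")
  expect_equal(significance_code(0.5), "")
  expect_equal(significance_code(c(0.001, 0.02, 0.9)), c("**", "*", ""))
  expect_error(significance_code(-0.1), "\\[0, 1\\]")
  expect_error(significance_code(1.5), "\\[0, 1\\]")
})

test_that("cortisol percent change is (post - pre) / pre * 100", {
  expect_equal(cortisol_pct_change(10, 5), -50)
  expect_equal(cortisol_pct_change(4, 4), 0)
  expect_equal(cortisol_pct_change(8, 10), 25)
  expect_equal(cortisol_pct_change(c(10, 4), c(5, 4)), c(-50, 0))
  expect_error(cortisol_pct_change(0, 5), "> 0")
})

test_that("group aggregates reproduce the published cortisol summaries", {
  tc <- table1_contrasts()
  g2 <- group_aggregate(tc[tc$group == 2L, ])
  g3 <- group_aggregate(tc[tc$group == 3L, ])
  expect_equal(round_half_away(g2$mu_delta_cortisol), -10)
  expect_equal(g3$mu_delta_cortisol, -15.3, tolerance = 1e-12)
  expect_equal(round_half_away(g2$pct_delta_cortisol), 27)
  expect_equal(round_half_away(g3$pct_delta_cortisol), 40)
})

test_that("restricting to significant responders reproduces the published group-1 HRV row", {
  tc <- table1_contrasts()
  g1 <- group_aggregate(tc[tc$group == 1L, ], hrv_subset = "significant")
  expect_equal(g1$n_hrv, 7L)  # the two subjects with no significant change drop out
  expect_equal(g1$mu_delta_rmssd, 37.5, tolerance = 0.005)
  expect_equal(g1$mu_delta_sdnn, 27.5, tolerance = 0.005)
  # per-subject percent-change convention reproduces the printed 104% / 47%
  expect_equal(g1$mean_subject_pct_rmssd, 104, tolerance = 0.02)
  expect_equal(g1$mean_subject_pct_sdnn, 47, tolerance = 0.03)
  # groups with no (or all) significant responders fall back to every member
  g3 <- group_aggregate(tc[tc$group == 3L, ], hrv_subset = "significant")
  expect_equal(g3$n_hrv, 2L)
})

test_that("a single-subject group reports its subject's delta with no spread", {
  one <- data.frame(subject_id = "x", group = 1L,
                    mean_rmssd_green = 50, mean_rmssd_urban = 40,
                    mean_sdnn_green = 70, mean_sdnn_urban = 60,
                    delta_rmssd = 10, delta_sdnn = 10,
                    sig_rmssd = "**", sig_sdnn = "**",
                    cortisol_pct_green = -50, cortisol_pct_urban = -40)
  ga <- group_aggregate(one)
  expect_equal(ga$mu_delta_rmssd, 10)
  expect_true(is.na(ga$sigma_delta_rmssd))
  expect_equal(ga$mu_delta_cortisol, -10)
  expect_true(is.na(ga$sigma_delta_cortisol))
})

test_that("overall cortisol means round to the published per-arm values", {
  tc <- table1_contrasts()
  oc <- overall_cortisol_means(tc)
  expect_equal(round_half_away(oc$green), -53)
  expect_equal(round_half_away(oc$urban), -37)
  one <- data.frame(cortisol_pct_green = -50, cortisol_pct_urban = -50)
  expect_equal(overall_cortisol_means(one)$green, -50)
})

test_that("order effect stratifies second-day walks by condition", {
  toy <- data.frame(
    cortisol_pct_green = c(-70, -66, -40, -35),
    cortisol_pct_urban = c(-20, -25, 5, 12),
    green_order = c("second", "second", "first", "first"))
  oe <- order_effect(toy)
  expect_equal(oe$mean_pct_change_green_when_second, -68)
  expect_equal(oe$mean_pct_change_urban_when_second, 8.5)
  expect_equal(oe$n_green_second, 2L)

  same <- toy
  same$green_order <- "second"
  oe2 <- order_effect(same)
  expect_true(is.na(oe2$mean_pct_change_urban_when_second))
  expect_equal(oe2$n_urban_second, 0L)
  expect_error(order_effect(toy[, 1:2]), "green_order")
})

test_that("residualised partial correlation matches the closed-form formula", {
  set.seed(30)
  z <- rnorm(40)
  x <- 0.7 * z + rnorm(40)
  y <- -0.4 * z + 0.5 * x + rnorm(40)
  pr <- partial_correlation(y, x, z)
  expect_equal(pr$r, partial_r_closed_form(cor(y, x), cor(y, z), cor(x, z)),
               tolerance = 1e-12)
  # two covariates vs the recursive formula applied twice
  z2 <- rnorm(40)
  y2 <- y + 0.3 * z2
  r_ab_c <- function(a, b, cv) partial_r_closed_form(cor(a, b),
                                                     cor(a, cv), cor(b, cv))
  rz2 <- resid(lm(cbind(y2, x, z) ~ z2))
  expect_equal(partial_correlation(y2, x, cbind(z, z2))$r,
               partial_r_closed_form(cor(rz2[, 1], rz2[, 2]),
                                     cor(rz2[, 1], rz2[, 3]),
                                     cor(rz2[, 2], rz2[, 3])),
               tolerance = 1e-10)
})

test_that("partial correlation is invariant under affine rescaling", {
  set.seed(31)
  z <- cbind(rnorm(30), rnorm(30))
  x <- rnorm(30) + z[, 1]
  y <- rnorm(30) - z[, 2]
  r0 <- partial_correlation(y, x, z)$r
  expect_equal(partial_correlation(3 * y - 7, x, z)$r, r0)
  expect_equal(partial_correlation(y, -2 * x + 1, z)$r, -r0)
  expect_equal(partial_correlation(y, x, cbind(10 * z[, 1] + 5, z[, 2]))$r, r0)
})

test_that("partial correlation approaches the simple correlation for irrelevant covariates", {
  set.seed(32)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  z <- rnorm(n)  # unrelated to both
  expect_equal(partial_correlation(y, x, z)$r, cor(y, x), tolerance = 0.01)
})

test_that("degenerate partial-correlation inputs raise errors", {
  z <- rnorm(20)
  x <- rnorm(20)
  expect_error(partial_correlation(z, x, z), "zero residual variance")
  expect_error(partial_correlation(x, z, cbind(z, 2 * z)), "collinear")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "n >= k \\+ 3")
})
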