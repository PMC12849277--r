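# Product-of-coefficients mediation, Monte Carlo CIs, contrasts

test_that("double-FDR screening keeps pairs significant in both steps", {
  step1 <- data.frame(cluster = "cluster_1",
                      protein = c("p1", "p2", "p3"),
                      beta = c(0.5, 0.01, 0.02), se = 0.05,
                      p = c(1e-8, 0.8, 0.6))
  step2 <- data.frame(protein = c("p1", "p2", "p3"),
                      beta = c(-0.3, 0.01, 0.0), se = 0.05,
                      p = c(1e-6, 0.9, 0.95))
  scr <- screen_mediators(step1, step2)
  expect_equal(nrow(scr$candidates), 1)
  expect_equal(scr$candidates$protein, "p1")
  expect_equal(scr$candidates$cluster, "cluster_1")

  all_in <- screen_mediators(step1, step2, alpha = 1.0000001)
  expect_equal(nrow(all_in$candidates), 3)
})

test_that("proteins absent from step 2 are excluded and reported", {
  step1 <- data.frame(cluster = "cluster_1", protein = c("p1", "p9"),
                      beta = 0.5, se = 0.05, p = 1e-8)
  step2 <- data.frame(protein = "p1", beta = -0.3, se = 0.05, p = 1e-6)
  expect_message(scr <- screen_mediators(step1, step2), "absent from step 2")
  expect_equal(scr$excluded, "p9")
  expect_equal(scr$candidates$protein, "p1")
})

test_that("step-1 FDR families are per cluster by default", {
  # the same p-value vector repeated across two clusters must yield the
  # same q-values as a single cluster would
  p <- c(0.001, 0.04, 0.2, 0.6)
  step1 <- data.frame(cluster = rep(c("cluster_1", "cluster_2"), each = 4),
                      protein = rep(paste0("p", 1:4), 2),
                      beta = 1, se = 0.1, p = rep(p, 2))
  step2 <- data.frame(protein = paste0("p", 1:4), beta = 1, se = 0.1,
                      p = rep(1e-6, 4))
  scr <- screen_mediators(step1, step2)
  expect_equal(scr$step1$q[1:4], bh_fdr(p))
  expect_equal(scr$step1$q[5:8], bh_fdr(p))
})

test_that("product of coefficients and its delta-method SE", {
  pc <- product_of_coefficients(0.5, 0.1, 0.4, 0.1)
  expect_equal(pc$mediated, 0.2)
  expect_equal(pc$se, sqrt(0.5^2 * 0.01 + 0.4^2 * 0.01))
  expect_equal(pc$se, sqrt(0.0041))

  z <- product_of_coefficients(0, 0.1, 0.7, 0.2)
  expect_equal(z$mediated, 0)
  expect_equal(z$se, 0.7 * 0.1)

  a <- product_of_coefficients(0.3, 0.05, -0.8, 0.2)
  b <- product_of_coefficients(-0.8, 0.2, 0.3, 0.05)
  expect_equal(a$mediated, b$mediated)
  expect_equal(a$se, b$se)
})

test_that("Monte Carlo CIs are symmetric for null products and deterministic", {
  ci <- monte_carlo_ci(0, 1, 0, 1, draws = 2e5, seed = 4)
  expect_lt(abs(ci$lower + ci$upper), 0.05)
  ci2 <- monte_carlo_ci(0, 1, 0, 1, draws = 2e5, seed = 4)
  expect_identical(ci, ci2)
  expect_error(monte_carlo_ci(0, 1, 0, 1, draws = 100, seed = 1), "10,000")
})

test_that("Monte Carlo CIs approach the delta-method limit for strong effects", {
  ci <- monte_carlo_ci(5, 0.01, 5, 0.01, draws = 5e5, seed = 5)
  delta_se <- sqrt(25 * 1e-4 + 25 * 1e-4)
  expect_equal(ci$lower, 25 - qnorm(0.975) * delta_se, tolerance = 1e-3)
  expect_equal(ci$upper, 25 + qnorm(0.975) * delta_se, tolerance = 1e-3)
})

test_that("proportions mediated reproduce the published supplementary arithmetic", {
  # risk-increasing cluster: mediated 0.015 of a 1.27 total
  expect_equal(round(100 * proportion_mediated(0.015, 1.27), 2), 1.18)
  # highly protective cluster: mediated 0.029 against a -1.92 total
  p2 <- proportion_mediated(0.029, -1.92)
  expect_equal(round(100 * p2, 2), -1.51)
  expect_equal(round(100 * abs(p2), 2), 1.51)
  expect_equal(proportion_mediated(0.4, 0.4), 1)
  expect_error(proportion_mediated(0.1, 0), "undefined")
})

test_that("between-cluster contrasts follow the delta-method plug-in formulas", {
  ct <- cluster_difference(0.3, 0.05, -0.1, 0.05, -0.148, 0.04,
                           draws = 1e4, seed = 6)
  expect_equal(ct$beta_diff, 0.4)
  expect_equal(ct$se_diff, sqrt(0.005))
  expect_equal(ct$se_contrast,
               sqrt(0.4^2 * 0.04^2 + 0.148^2 * 0.005))
  expect_equal(ct$z, (0.4 * -0.148) / ct$se_contrast)
  expect_equal(ct$p, 2 * pnorm(-abs(ct$z)))

  nul <- cluster_difference(0.3, 0.05, 0.3, 0.05, -0.148, 0.04,
                            draws = 1e4, seed = 6)
  expect_equal(nul$beta_diff, 0)
  expect_equal(nul$z, 0)
  expect_equal(nul$p, 1)

  sw <- cluster_difference(-0.1, 0.05, 0.3, 0.05, -0.148, 0.04,
                           draws = 1e4, seed = 6)
  expect_equal(sw$beta_diff, -ct$beta_diff)
  expect_equal(sw$z, -ct$z)
  expect_equal(sw$p, ct$p)
})

test_that("the contrast equals the difference of mediated effects exactly", {
  set.seed(301)
  for (i in 1:25) {
    bA <- rnorm(1); bB <- rnorm(1); bP <- rnorm(1)
    medA <- product_of_coefficients(bA, 0.1, bP, 0.1)$mediated
    medB <- product_of_coefficients(bB, 0.1, bP, 0.1)$mediated
    expect_equal(medA - medB, (bA - bB) * bP, tolerance = 1e-14)
  }
})

test_that("z-tests compare independent estimates", {
  zt <- z_test(1, 0.1, 0, 0.1)
  expect_equal(zt$z, 1 / sqrt(0.02))
  expect_equal(z_test(0.4, 0.2, 0.4, 0.3)$p, 1)
  expect_equal(z_test(0, 0.1, 1, 0.1)$z, -zt$z)
})

test_that("delta-method SE matches the Monte Carlo SD for strong effects", {
  set.seed(302)
  for (i in 1:5) {
    b1 <- runif(1, 1, 3); s1 <- b1 / runif(1, 6, 20)
    b2 <- runif(1, 1, 3); s2 <- b2 / runif(1, 6, 20)
    delta <- product_of_coefficients(b1, s1, b2, s2)$se
    draws <- rnorm(2e5, b1, s1) * rnorm(2e5, b2, s2)
    expect_equal(delta, sd(draws), tolerance = 0.05)
  }
})

test_that("mediation tables carry proportions and significance tiers", {
  cand <- data.frame(cluster = c("cluster_1", "cluster_2"),
                     protein = "p1",
                     beta1 = c(0.5, 0.1), se1 = c(0.05, 0.2),
                     beta2 = -0.4, se2 = 0.05,
                     q1 = 0.01, q2 = 0.001, stringsAsFactors = FALSE)
  totals <- data.frame(cluster = c("cluster_1", "cluster_2"),
                       beta = c(1.0, -0.5))
  med <- mediation_results(cand, totals, draws = 1e4, seed = 7)
  expect_equal(med$mediated, c(-0.2, -0.04))
  expect_equal(med$proportion, c(-0.2, 0.08))
  expect_equal(med$tier[1], "**")
  expect_true(all(med$ci_lower <= med$mediated & med$mediated <= med$ci_upper))
})

test_that("pairwise contrasts cover every cluster pair per protein", {
  cand <- data.frame(cluster = paste0("cluster_", 1:3), protein = "p1",
                     beta1 = c(0.5, -0.2, 0.1), se1 = 0.05,
                     beta2 = -0.3, se2 = 0.04,
                     q1 = 0.01, q2 = 0.001, stringsAsFactors = FALSE)
  ct <- cluster_contrasts(cand, draws = 1e4, seed = 8)
  expect_equal(nrow(ct), 3)
  expect_setequal(paste(ct$cluster_a, ct$cluster_b),
                  c("cluster_1 cluster_2", "cluster_1 cluster_3",
                    "cluster_2 cluster_3"))
  i12 <- ct$cluster_a == "cluster_1" & ct$cluster_b == "cluster_2"
  expect_equal(ct$beta_diff[i12], 0.7)
  expect_equal(ct$contrast[i12], 0.7 * -0.3)
})
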