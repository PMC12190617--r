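test_that("Wald ratio arithmetic, null case, and OR/CI display", {
  r <- wald_ratio(list(beta_x = 0.5, se_x = 0.01, beta_y = 0.1,
                       se_y = 0.02))
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.04)
  null <- wald_ratio(list(beta_x = 0.5, se_x = 0.01, beta_y = 0,
                          se_y = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$p, 1)
  expect_error(wald_ratio(list(beta_x = 0, se_x = 1, beta_y = 1,
                               se_y = 1)), "beta_x")
  # display convention: beta 0.2070 with CI (1.13-1.33) back-solved se
  r2 <- wald_ratio(list(beta_x = 1, se_x = 0.01, beta_y = 0.2070,
                        se_y = 0.0416))
  expect_equal(round(r2$or_, 2), 1.23)
  expect_equal(round(r2$ci_low, 2), 1.13)
  expect_equal(round(r2$ci_high, 2), 1.33)
})

test_that("IVW: single-instrument reduction, equal ratios, WLS oracle", {
  one <- toy_instruments(0.5, 0.1, 0.02)
  expect_equal(ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(ivw(one)$se, wald_ratio(one)$se)

  eq <- toy_instruments(c(0.5, 0.4, 0.3), 0.2 * c(0.5, 0.4, 0.3),
                        c(0.02, 0.03, 0.04))
  r <- ivw(eq)
  expect_equal(r$beta, 0.2)
  expect_equal(r$q, 0)
  expect_equal(r$q_p, 1)

  set.seed(10)
  bx <- rnorm(6, 0.3, 0.1); by <- 0.2 * bx + rnorm(6, 0, 0.02)
  sy <- runif(6, 0.01, 0.05)
  ins <- toy_instruments(bx, by, sy)
  oracle <- wls_origin_oracle(bx, by, sy)
  fit <- ivw(ins, model = "fixed")
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-12)
  expect_equal(fit$se, oracle$se, tolerance = 1e-12)
  expect_error(ivw(ins[0, ]), "empty")
})

test_that("MR-Egger: exact fit through origin, intercept shift identity", {
  bx <- c(0.2, 0.4, 0.6)
  ins <- toy_instruments(bx, 0.2 * bx, c(0.02, 0.02, 0.02))
  r <- mr_egger(ins)
  expect_equal(r$beta, 0.2, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0, tolerance = 1e-10)

  set.seed(11)
  bx <- runif(8, 0.1, 0.5); by <- 0.3 * bx + rnorm(8, 0, 0.02)
  sy <- runif(8, 0.01, 0.05)
  base <- mr_egger(toy_instruments(bx, by, sy))
  shifted <- mr_egger(toy_instruments(bx, by + 0.05, sy))
  expect_equal(shifted$beta, base$beta, tolerance = 1e-10)
  expect_equal(shifted$egger_intercept, base$egger_intercept + 0.05,
               tolerance = 1e-10)
  expect_error(mr_egger(toy_instruments(c(1, 2), c(1, 2), c(1, 1))),
               "3 instruments")
})

test_that("weighted median: brute-force oracle, robustness, invariances", {
  eqw <- toy_instruments(c(1, 1, 1), c(0.1, 0.2, 0.9), c(0.05, 0.05, 0.05))
  expect_equal(weighted_median(eqw, n_boot = 50, seed = 1)$beta, 0.2)

  # duplicate every instrument: point estimate unchanged
  dup <- rbind(eqw, eqw)
  expect_equal(weighted_median(dup, n_boot = 50, seed = 1)$beta, 0.2)

  # 7 valid instruments at theta 0.2, 3 with large pleiotropic offsets:
  # the median stays near truth while IVW is pulled away
  bx <- rep(0.3, 10)
  by <- 0.2 * bx
  by[1:3] <- by[1:3] + 0.3
  ins <- toy_instruments(bx, by, rep(0.02, 10))
  wm <- weighted_median(ins, n_boot = 200, seed = 3)
  expect_lt(abs(wm$beta - 0.2), 0.05)
  expect_gt(abs(ivw(ins)$beta - 0.2), 0.05)
  # brute-force oracle: smallest x with >= half the weight on each side
  ratio <- ins$beta_y / ins$beta_x
  w <- (ins$beta_x / ins$se_y)^2; w <- w / sum(w)
  ord <- order(ratio)
  s <- cumsum(w[ord]) - w[ord] / 2
  brute <- approx(s, ratio[ord], xout = 0.5)$y
  expect_equal(wm$beta, brute)
})

test_that("Cochran's Q: two-instrument closed form, reorder invariance", {
  ins <- toy_instruments(c(0.5, 0.4), c(0.12, 0.06), c(0.02, 0.03))
  q <- cochran_q(ins)
  # closed form: Q = (theta1 - theta2)^2 / (1/w1 + 1/w2)
  th <- ins$beta_y / ins$beta_x
  w <- (ins$beta_x / ins$se_y)^2
  expect_equal(q$q, (th[1] - th[2])^2 / (1 / w[1] + 1 / w[2]),
               tolerance = 1e-12)
  expect_equal(q$df, 1)
  expect_equal(cochran_q(ins[2:1, ])$q, q$q)
  expect_error(cochran_q(ins[1, ]), "2 instruments")
})

test_that("SMR statistic and p-value match the chi-square oracle", {
  # z_x 10, z_y 3: T = 900/109
  r <- smr_test(list(beta = 1, se = 0.1), list(beta = 0.3, se = 0.1))
  expect_equal(r$t_smr, 900 / 109, tolerance = 1e-12)
  expect_equal(r$p, 4.059783e-3, tolerance = 1e-6)
  # z_y = 0 -> T = 0, p = 1
  r0 <- smr_test(list(beta = 1, se = 0.1), list(beta = 0, se = 0.1))
  expect_equal(r0$t_smr, 0)
  expect_equal(r0$p, 1)
  # T <= min(zx^2, zy^2)
  set.seed(13)
  for (i in 1:25) {
    zx <- rnorm(1, 0, 5); zy <- rnorm(1, 0, 5)
    if (zx == 0) next
    rr <- smr_test(list(beta = zx, se = 1), list(beta = zy, se = 1))
    expect_lte(rr$t_smr, min(zx^2, zy^2) + 1e-12)
  }
})

test_that("Bonferroni thresholds and formatting", {
  expect_equal(bonferroni_threshold(0.05, 1954), 0.05 / 1954)
  expect_equal(signif(bonferroni_threshold(0.05, 1954), 3), 2.56e-5)
  expect_equal(signif(bonferroni_threshold(5e-8, 2923), 2), 1.7e-11)
  expect_equal(bonferroni_threshold(0.01, 1), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("estimators are invariant under joint sign flip of every instrument", {
  set.seed(14)
  bx <- runif(5, 0.2, 0.5); by <- 0.25 * bx + rnorm(5, 0, 0.02)
  sy <- runif(5, 0.01, 0.04)
  ins <- toy_instruments(bx, by, sy)
  flp <- toy_instruments(-bx, -by, sy)
  expect_equal(ivw(flp)$beta, ivw(ins)$beta, tolerance = 1e-12)
  expect_equal(cochran_q(flp)$q, cochran_q(ins)$q, tolerance = 1e-12)
  expect_equal(wald_ratio(flp[1, ])$beta, wald_ratio(ins[1, ])$beta)
})

test_that("weighted median approaches IVW when all instruments are valid", {
  set.seed(15)
  k <- 50
  bx <- runif(k, 0.2, 0.5)
  by <- 0.2 * bx + rnorm(k, 0, 0.015)
  ins <- toy_instruments(bx, by, rep(0.015, k))
  wm <- weighted_median(ins, n_boot = 300, seed = 4)
  expect_lt(abs(wm$beta - ivw(ins)$beta), 2 * wm$se)
})

test_that("Egger intercept p-values are uniform under a zero-intercept model", {
  set.seed(16)
  n_sim <- 200
  ps <- vapply(seq_len(n_sim), function(i) {
    bx <- runif(8, 0.2, 0.6)
    sy <- rep(0.03, 8)
    by <- 0.2 * bx + rnorm(8, 0, sy)
    mr_egger(toy_instruments(bx, by, sy))$egger_intercept_p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
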