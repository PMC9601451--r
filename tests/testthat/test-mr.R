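test_that("single-instrument IVW reduces to the ratio estimate", {
  inst <- make_instruments(0.5, 0.1, 0.02, 0.05)
  res <- mr_ivw(inst)
  expect_equal(res$estimate, 0.2)
  expect_equal(res$se, 0.1)
  expect_equal(res$ci95, c(0.2 - 1.96 * 0.1, 0.2 + 1.96 * 0.1))
})

test_that("IVW equals an independent weighted-regression oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 10
    inst <- make_instruments(rnorm(n, 0.2, 0.05), rnorm(n, 0.06, 0.02),
                             runif(n, 0.005, 0.02), runif(n, 0.01, 0.05))
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
              weights = 1 / inst$se_outcome^2)
    expect_equal(mr_ivw(inst)$estimate, unname(coef(fit)),
                 tolerance = 1e-12)
    # fixed-effect SE from the analytic weighted-average formula
    w <- inst$beta_exposure^2 / inst$se_outcome^2
    expect_equal(mr_ivw(inst, model = "fixed")$se, sqrt(1 / sum(w)),
                 tolerance = 1e-12)
  }
})

test_that("identical ratios give Q = 0 and equal fixed/random SEs", {
  inst <- make_instruments(c(0.2, 0.4, 0.5), 0.3 * c(0.2, 0.4, 0.5),
                           0.01, c(0.02, 0.03, 0.04))
  r_fixed <- mr_ivw(inst, model = "fixed")
  r_random <- mr_ivw(inst, model = "random")
  expect_equal(r_random$estimate, 0.3)
  expect_equal(r_random$Q, 0)
  expect_equal(r_random$se, r_fixed$se)
})

test_that("zero exposure effect is an error naming the SNP", {
  inst <- make_instruments(c(0.2, 0), c(0.05, 0.01), 0.01, 0.02,
                           rsid = c("rsA", "rsB"))
  expect_error(mr_ivw(inst), "rsB")
})

test_that("Egger recovers an exact linear data-generating process", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  inst <- make_instruments(bx, 0.02 + 0.3 * bx, 0.01,
                           c(0.01, 0.02, 0.015, 0.01, 0.03))
  res <- mr_egger(inst)
  expect_equal(res$estimate, 0.3, tolerance = 1e-12)
  expect_equal(res$egger_intercept, 0.02, tolerance = 1e-12)
  expect_equal(res$Q, 0, tolerance = 1e-20)
})

test_that("Egger matches a weighted-least-squares oracle after orientation", {
  set.seed(6)
  n <- 10
  bx <- rnorm(n, 0, 0.3)  # mixed signs force the orientation step
  inst <- make_instruments(bx, 0.01 + 0.25 * bx + rnorm(n, 0, 0.02),
                           0.01, runif(n, 0.01, 0.04))
  res <- mr_egger(inst)
  flip <- sign(inst$beta_exposure)
  fit <- lm(I(flip * beta_outcome) ~ I(abs(beta_exposure)), data = inst,
            weights = 1 / se_outcome^2)
  expect_equal(res$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_error(mr_egger(inst[1:2, ]), "at least 3")
})

test_that("Egger with the intercept constrained to zero reproduces IVW", {
  set.seed(7)
  inst <- make_instruments(rnorm(8, 0.2, 0.05), rnorm(8, 0.05, 0.03),
                           0.01, runif(8, 0.01, 0.04))
  e0 <- mr_egger(inst, intercept = FALSE)
  iv <- mr_ivw(inst)
  expect_equal(e0$estimate, iv$estimate, tolerance = 1e-12)
  expect_equal(e0$se, iv$se, tolerance = 1e-12)
})

test_that("weighted median: degenerate and small hand cases", {
  inst <- make_instruments(c(0.2, 0.3, 0.4), 0.25 * c(0.2, 0.3, 0.4),
                           0.01, 0.02)
  res <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(res$estimate, 0.25, tolerance = 1e-12)

  # equal ratio SEs -> equal weights; median of (0.1, 0.2, 0.9) is 0.2
  inst2 <- make_instruments(c(1, 1, 1), c(0.1, 0.2, 0.9), 0.01, 0.05)
  res2 <- mr_weighted_median(inst2, n_boot = 50, seed = 1)
  expect_equal(res2$estimate, 0.2, tolerance = 1e-12)
  expect_error(mr_weighted_median(inst2[1:2, ]), "at least 3")
})

test_that("weighted-median bootstrap SE is stable across seeds", {
  set.seed(9)
  inst <- make_instruments(rnorm(20, 0.2, 0.04), rnorm(20, 0.06, 0.02),
                           0.01, 0.02)
  se1 <- mr_weighted_median(inst, n_boot = 5000, seed = 1)$se
  se2 <- mr_weighted_median(inst, n_boot = 5000, seed = 2)$se
  expect_lt(abs(se1 - se2) / se1, 0.05)
})

test_that("all estimators converge to the true ratio as SEs vanish", {
  theta <- 0.37
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  inst <- make_instruments(bx, theta * bx, 1e-6, 1e-6)
  expect_lt(abs(mr_ivw(inst)$estimate - theta), 1e-4)
  expect_lt(abs(mr_egger(inst)$estimate - theta), 1e-4)
  expect_lt(abs(mr_weighted_median(inst, n_boot = 20,
                                   seed = 1)$estimate - theta), 1e-4)
  expect_lt(abs(mr_presso(inst, n_sim = 50,
                          seed = 1)$estimate_all$estimate - theta), 1e-4)
})

test_that("estimates and SEs scale linearly with the outcome scale", {
  set.seed(10)
  inst <- make_instruments(rnorm(12, 0.2, 0.05), rnorm(12, 0.06, 0.02),
                           0.01, runif(12, 0.01, 0.04))
  scaled <- inst
  scaled$beta_outcome <- 3 * inst$beta_outcome
  scaled$se_outcome <- 3 * inst$se_outcome
  for (f in list(mr_ivw, mr_egger)) {
    a <- f(inst); b <- f(scaled)
    expect_equal(b$estimate, 3 * a$estimate, tolerance = 1e-10)
    expect_equal(b$se, 3 * a$se, tolerance = 1e-10)
  }
  a <- mr_weighted_median(inst, n_boot = 200, seed = 3)
  b <- mr_weighted_median(scaled, n_boot = 200, seed = 3)
  expect_equal(b$estimate, 3 * a$estimate, tolerance = 1e-10)
})

test_that("mr_all assembles the per-method summary table", {
  set.seed(11)
  inst <- make_instruments(rnorm(10, 0.2, 0.03), rnorm(10, 0.02, 0.02),
                           0.01, 0.02)
  res <- mr_all(inst, n_boot = 50, n_sim = 100, seed = 1)
  expect_setequal(res$table$method,
                  c("ivw_random", "weighted_median", "mr_egger",
                    "presso_raw", "presso_outlier_corrected"))
  expect_true(all(is.finite(res$table$estimate)))
})
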