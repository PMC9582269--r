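test_that("Wald ratios and Delta-method standard errors evaluate correctly", {
  p0 <- make_pairs(0.1, 0.01, 0, 0.02)
  r0 <- wald_ratios(p0)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se_ratio, 0.02 / 0.1)

  p1 <- make_pairs(0.1, 0.01, 0.05, 0.02)
  r1 <- wald_ratios(p1)
  expect_equal(r1$ratio, 0.5)
  expect_equal(r1$se_ratio, 0.2)
  # second-order: sqrt(se_out^2/bx^2 + by^2 se_x^2/bx^4), evaluated by hand
  r2 <- wald_ratios(p1, "second_order")
  expect_equal(r2$se_ratio, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_equal(r2$se_ratio, 0.2061553, tolerance = 1e-6)

  expect_error(wald_ratios(make_pairs(0, 0.01, 0.05, 0.02)), "degenerate")
})

test_that("IVW reproduces the hand-computed weighted mean, SE and Q", {
  r <- make_ratios(c(0.5, 0.3, 0.4), c(0.2, 0.1, 0.1))
  est <- ivw_mre(r)
  expect_equal(est$beta, 0.36667, tolerance = 1e-4)
  # Q = 1 < df so the multiplicative scale is floored at the fixed SE
  expect_equal(est$se, 1 / sqrt(25 + 100 + 100), tolerance = 1e-4)
  expect_equal(attr(est, "q"), 1.00, tolerance = 1e-10)
  expect_equal(est$ci_low, est$beta - 1.96 * est$se)
  expect_equal(est$ci_high, est$beta + 1.96 * est$se)
  expect_equal(est$or, exp(est$beta))
})

test_that("identical ratios give that ratio back with zero dispersion", {
  set.seed(1)
  r <- make_ratios(rep(0.25, 5), runif(5, 0.05, 0.2))
  est <- ivw_mre(r)
  expect_equal(est$beta, 0.25)
  expect_equal(attr(est, "q"), 0)
  expect_equal(est$se, 1 / sqrt(sum(1 / r$se_ratio^2)))
})

test_that("IVW is order-invariant and reduces to the mean for equal SEs", {
  set.seed(2)
  r <- make_ratios(rnorm(8, 0.1, 0.3), runif(8, 0.05, 0.4))
  perm <- sample(8)
  expect_equal(ivw_mre(r[perm, ])$beta, ivw_mre(r)$beta)
  req <- make_ratios(c(0.1, 0.5, 0.3, -0.2), rep(0.2, 4))
  expect_equal(ivw_mre(req)$beta, mean(req$ratio))
})

test_that("a single instrument falls back to the Wald ratio with a warning", {
  r <- make_ratios(0.4, 0.1)
  expect_warning(est <- ivw_mre(r), "single Wald")
  expect_equal(est$beta, 0.4)
  expect_equal(est$method, "wald")
})

test_that("medians hit their closed-form points", {
  r <- make_ratios(c(0.2, 0.4, 0.6), rep(0.1, 3))
  expect_equal(simple_median(r, boot_reps = 50, seed = 1)$beta, 0.4)
  sym <- make_ratios(c(-0.3, -0.1, 0.1, 0.3), rep(0.1, 4))
  expect_equal(simple_median(sym, boot_reps = 50, seed = 1)$beta, 0)
  # weighted median: normalized weights (0.25, 0.25, 0.50), interpolated
  # cumulative weight crosses 0.5 between the second and third ratio
  rw <- make_ratios(c(0.2, 0.4, 0.6), 1 / sqrt(c(0.25, 0.25, 0.5)))
  expect_equal(weighted_median(rw, boot_reps = 50, seed = 1)$beta,
               0.4667, tolerance = 1e-4)
  expect_error(simple_median(make_ratios(c(1, 2), c(1, 1)), 50, seed = 1),
               "at least 3")
})

test_that("weighted median equals simple median under equal weights", {
  for (k in c(3, 4, 7, 10)) {
    set.seed(k)
    r <- make_ratios(rnorm(k), rep(0.3, k))
    expect_equal(weighted_median(r, boot_reps = 10, seed = 2)$beta,
                 simple_median(r, boot_reps = 10, seed = 2)$beta)
  }
})

test_that("bootstrap SE stabilizes as replicates grow", {
  r <- make_ratios(c(0.1, 0.3, 0.25, 0.4, 0.15), rep(0.1, 5))
  se1 <- simple_median(r, boot_reps = 1e4, seed = 7)$se
  se2 <- simple_median(r, boot_reps = 1e5, seed = 8)$se
  expect_lt(abs(se1 - se2) / se2, 0.05)
})

test_that("Egger recovers exact linear structure and affine shifts", {
  set.seed(3)
  bx <- runif(6, 0.05, 0.3)
  pairs <- make_pairs(bx, 0.01, 0.5 * bx, runif(6, 0.01, 0.05))
  eg <- egger(pairs)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)

  shifted <- pairs
  shifted$beta_out <- shifted$beta_out + 0.02
  eg2 <- egger(shifted)
  expect_equal(eg2$intercept$beta, 0.02, tolerance = 1e-12)
  expect_equal(eg2$slope$beta, eg$slope$beta, tolerance = 1e-12)
})

test_that("Egger matches a generic weighted-least-squares oracle", {
  for (seed in 1:20) {
    pairs <- random_pairs(k = sample(4:15, 1), seed = seed)
    eg <- egger(pairs)
    w <- 1 / pairs$se_out^2
    fit <- lm(beta_out ~ beta_exp, data = pairs, weights = w)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    # unit-weight covariance agrees; the package floors the residual
    # scale at 1 while lm always applies it
    sm <- summary(fit)
    k <- nrow(pairs)
    sigma <- sm$sigma
    expect_equal(eg$slope$se,
                 unname(sm$coefficients[2, 2]) / sigma * max(1, sigma),
                 tolerance = 1e-8)
  }
})

test_that("Egger with the intercept constrained to zero equals fixed-effect
          IVW", {
  for (seed in 1:5) {
    pairs <- random_pairs(10, seed)
    w <- 1 / pairs$se_out^2
    through_origin <- sum(w * pairs$beta_exp * pairs$beta_out) /
      sum(w * pairs$beta_exp^2)
    ratios <- wald_ratios(pairs)
    expect_equal(through_origin, summr:::ivw_fixed_beta(ratios),
                 tolerance = 1e-12)
  }
})

test_that("all estimators are sign-equivariant in the outcome", {
  pairs <- random_pairs(9, seed = 31)
  neg <- pairs
  neg$beta_out <- -neg$beta_out
  r <- wald_ratios(pairs); rn <- wald_ratios(neg)
  expect_equal(ivw_mre(rn)$beta, -ivw_mre(r)$beta)
  expect_equal(simple_median(rn, 50, seed = 4)$beta,
               -simple_median(r, 50, seed = 4)$beta)
  expect_equal(weighted_median(rn, 50, seed = 4)$beta,
               -weighted_median(r, 50, seed = 4)$beta)
  en <- egger(neg); ep <- egger(pairs)
  expect_equal(en$slope$beta, -ep$slope$beta)
  expect_equal(en$intercept$beta, -ep$intercept$beta)
})

test_that("mr_all_methods returns one labelled row per estimator", {
  d <- generate_gwas(synth_config(seed = 21))
  h <- harmonize(d$exposure, d$outcome, d$exposure$rsid)
  est <- mr_all_methods(h, boot_reps = 100, seed = 10)
  expect_equal(est$method, c("ivw_mre", "simple_median", "weighted_median",
                             "egger_slope", "egger_intercept"))
  expect_true(all(est$or > 0))
  expect_equal(est$k, rep(12L, 5))
})
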