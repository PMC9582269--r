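make_panel <- function(k, seed, b1 = 0.1, b2 = 0.3, noise = 0) {
  set.seed(seed)
  bx1 <- runif(k, 0.02, 0.2)
  bx2 <- runif(k, 0.02, 0.2)
  se_out <- runif(k, 0.01, 0.05)
  tibble::tibble(rsid = sprintf("rs%03d", 1:k),
                 beta_exp1 = bx1, se_exp1 = 0.01,
                 beta_exp2 = bx2, se_exp2 = 0.01,
                 beta_out = b1 * bx1 + b2 * bx2 + noise * rnorm(k, 0, se_out),
                 se_out = se_out)
}

test_that("an exact two-exposure linear structure is recovered to machine
          precision", {
  panel <- make_panel(15, seed = 1)
  est <- mvmr_ivw(panel)
  expect_equal(est$beta[1], 0.1, tolerance = 1e-10)
  expect_equal(est$beta[2], 0.3, tolerance = 1e-10)
  expect_equal(est$method, c("mvmr_direct_exp1", "mvmr_direct_exp2"))
})

test_that("estimates are invariant to row permutation", {
  panel <- make_panel(12, seed = 2, noise = 1)
  est <- mvmr_ivw(panel)
  set.seed(3)
  est_p <- mvmr_ivw(panel[sample(12), ])
  expect_equal(est_p$beta, est$beta)
  expect_equal(est_p$se, est$se)
})

test_that("a degenerate exposure column raises a collinearity error naming
          it", {
  panel <- make_panel(10, seed = 4)
  panel$beta_exp2 <- 0
  expect_error(mvmr_ivw(panel), "beta_exp2")
})

test_that("a single-exposure panel reduces to fixed-effect IVW through the
          origin", {
  panel <- make_panel(10, seed = 5, noise = 1)[, c("rsid", "beta_exp1",
                                                   "se_exp1", "beta_out",
                                                   "se_out")]
  est <- mvmr_ivw(panel)
  w <- 1 / panel$se_out^2
  oracle <- sum(w * panel$beta_exp1 * panel$beta_out) /
    sum(w * panel$beta_exp1^2)
  expect_equal(est$beta, oracle, tolerance = 1e-12)
})

test_that("MVMR agrees with a weighted-least-squares oracle on random
          panels", {
  for (seed in 1:15) {
    panel <- make_panel(sample(5:20, 1), seed = seed, noise = 1)
    est <- mvmr_ivw(panel)
    fit <- lm(beta_out ~ 0 + beta_exp1 + beta_exp2, data = panel,
              weights = 1 / panel$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("both direct effects are recovered within 2 SE on a generated
          two-exposure panel", {
  g <- generate_mvmr(synth_config(k = 50, gamma_scale = 0.05, seed = 11),
                     synth_config(k = 50, gamma_scale = 0.05, seed = 11),
                     theta1 = 0.10, theta2 = 0.30, rho_gamma = 0.3)
  panel <- build_mvmr_panel(g$exposure1, g$exposure2, g$outcome,
                            g$instruments1, g$instruments2)
  est <- mvmr_ivw(panel)
  expect_lt(abs(est$beta[1] - 0.10), 2 * est$se[1])
  expect_lt(abs(est$beta[2] - 0.30), 2 * est$se[2])
  expect_true(all(attr(est, "conditional_f") > 0))
})

test_that("adjusting for a null second exposure leaves the primary effect
          essentially unchanged", {
  g <- generate_mvmr(synth_config(k = 40, seed = 21),
                     synth_config(k = 40, seed = 21),
                     theta1 = 0.15, theta2 = 0, rho_gamma = 0.2)
  panel <- build_mvmr_panel(g$exposure1, g$exposure2, g$outcome,
                            g$instruments1, g$instruments2)
  mv <- mvmr_ivw(panel)
  h <- harmonize(g$exposure1, g$outcome, g$instruments1)
  uni <- ivw_mre(wald_ratios(h))
  expect_lt(abs(mv$beta[1] - uni$beta), 2 * mv$se[1])
})

test_that("near-collinear exposures trigger a conditioning warning", {
  g <- generate_mvmr(synth_config(k = 30, gamma_scale = 0.06, seed = 31),
                     synth_config(k = 30, gamma_scale = 0.06, seed = 31),
                     theta1 = 0.1, theta2 = 0.1, rho_gamma = 0.99)
  panel <- build_mvmr_panel(g$exposure1, g$exposure2, g$outcome,
                            g$instruments1, g$instruments2)
  expect_warning(mvmr_ivw(panel), "near-collinear")
})

test_that("the MVMR panel is the union of the instrument sets with shared
          SNPs counted once", {
  g <- generate_mvmr(synth_config(k = 10, seed = 41),
                     synth_config(k = 8, seed = 41),
                     theta1 = 0.1, theta2 = 0.2, rho_gamma = 0)
  panel <- build_mvmr_panel(g$exposure1, g$exposure2, g$outcome,
                            g$instruments1, g$instruments2)
  expect_equal(sort(panel$rsid),
               sort(union(g$instruments1, g$instruments2)))
  # a shared SNP appears once
  panel2 <- build_mvmr_panel(g$exposure1, g$exposure2, g$outcome,
                             g$instruments1,
                             c(g$instruments2, g$instruments1[1]))
  expect_equal(anyDuplicated(panel2$rsid), 0)
  expect_equal(nrow(panel2), nrow(panel))
})

test_that("joint re-clumping drops the weaker of two linked SNPs across
          sets", {
  e1 <- as_stats(snp_row("rsA", "A", "G", 0.3, 0.1, pos = 1e6,
                         pval = 1e-9))
  e2 <- as_stats(rbind(snp_row("rsB", "C", "T", 0.3, 0.1, pos = 1.2e6,
                               pval = 1e-7),
                       snp_row("rsC", "A", "C", 0.4, 0.1, pos = 9e7,
                               pval = 1e-8),
                       snp_row("rsD", "G", "T", 0.2, 0.1, pos = 5e7,
                               pval = 1e-8, chrom = "2"),
                       snp_row("rsA", "A", "G", 0.3, 0.05, pos = 1e6,
                               pval = 1e-4)), "e2")
  # outcome and cross-exposure lookups for every SNP
  all_rows <- rbind(snp_row("rsA", "A", "G", 0.3, 0.02, pos = 1e6),
                    snp_row("rsB", "C", "T", 0.3, 0.01, pos = 1.2e6),
                    snp_row("rsC", "A", "C", 0.4, 0.015, pos = 9e7),
                    snp_row("rsD", "G", "T", 0.2, 0.015, pos = 5e7,
                            chrom = "2"))
  out <- as_stats(all_rows, "out")
  e1_full <- as_stats(rbind(snp_row("rsA", "A", "G", 0.3, 0.1, pos = 1e6,
                                    pval = 1e-9),
                            snp_row("rsB", "C", "T", 0.3, 0.04,
                                    pos = 1.2e6, pval = 1e-3),
                            snp_row("rsC", "A", "C", 0.4, 0.03, pos = 9e7,
                                    pval = 1e-3),
                            snp_row("rsD", "G", "T", 0.2, 0.03, pos = 5e7,
                                    pval = 1e-3, chrom = "2")))
  ld <- ld_matrix(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.5))
  panel <- suppressWarnings(
    build_mvmr_panel(e1_full, e2, out, "rsA", c("rsB", "rsC", "rsD"),
                     ld = ld, cfg = clump_config()))
  # rsB is within the window and linked to the stronger rsA: dropped
  expect_setequal(panel$rsid, c("rsA", "rsC", "rsD"))
})
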