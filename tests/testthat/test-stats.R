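sim_cohort <- function(means, n = 6, sd = 1, region = "r") {
  data.frame(
    animal_id = paste0("a", seq_len(n * length(means))),
    group = rep(names(means), each = n),
    sex = "M", region = region,
    density = unlist(lapply(means, function(m) rnorm(n, m, sd))))
}

test_that("depletion percentage arithmetic and sign convention", {
  coh <- data.frame(group = rep(c("ctrl", "t1", "t2"), each = 2),
                    region = "r",
                    density = c(100, 100, 35, 35, 120, 120))
  d <- depletion_percent(coh, "ctrl")
  expect_equal(d$percent_depletion[d$group == "t1"], 65)
  expect_equal(d$percent_depletion[d$group == "t2"], -20)
  coh$density[coh$group == "t1"] <- 100
  d2 <- depletion_percent(coh, "ctrl")
  expect_equal(d2$percent_depletion[d2$group == "t1"], 0)
  coh$density[coh$group == "ctrl"] <- 0
  expect_error(depletion_percent(coh, "ctrl"), "zero")
})

test_that("delta-method SE shrinks with sample size", {
  set.seed(5)
  des <- function(n) sim_cohort(c(ctrl = 100, trt = 50), n = n, sd = 10)
  se_small <- depletion_percent(des(4), "ctrl")$se
  se_big <- depletion_percent(des(64), "ctrl")$se
  expect_lt(se_big, se_small)
})

test_that("ANOVA F matches the reference implementation on random cohorts", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    means <- stats::setNames(runif(k, 50, 150), c("ctrl", paste0("t", seq_len(k - 1))))
    coh <- sim_cohort(means, n = sample(3:8, 1), sd = runif(1, 1, 20))
    r <- anova_dunnett(coh, "ctrl")
    ref <- summary(stats::aov(density ~ group, data = coh))[[1]]
    expect_equal(r$F, ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(r$p_overall, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  }
})

test_that("single-treatment Dunnett reduces to the pooled t-test", {
  set.seed(11)
  for (i in 1:20) {
    coh <- sim_cohort(c(ctrl = 100, trt = runif(1, 60, 140)),
                      n = sample(3:10, 1), sd = 8)
    r <- anova_dunnett(coh, "ctrl")
    tt <- stats::t.test(density ~ group, data = coh, var.equal = TRUE)
    expect_equal(r$comparisons$p_adjusted, tt$p.value, tolerance = 1e-8)
  }
})

test_that("Dunnett adjustment dominates the unadjusted p and grows with k", {
  # the multiplicity penalty for a fixed statistic, fixed df, growing family
  for (t0 in c(1.2, 2.5)) {
    p_by_k <- vapply(1:5, function(k) {
      gliaquant:::dunnett_p_adjust(rep(t0, k), df2 = 20,
                                   ns = rep(6, k), n0 = 6)[1]
    }, numeric(1))
    expect_true(all(diff(p_by_k) > 0))
    expect_gte(p_by_k[1], 2 * pt(t0, 20, lower.tail = FALSE) - 1e-12)
  }
  # and within a fitted cohort the adjusted p never undercuts the raw p
  set.seed(31)
  coh <- sim_cohort(c(ctrl = 100, t1 = 95, t2 = 104, t3 = 90), n = 5, sd = 8)
  r <- anova_dunnett(coh, "ctrl")
  expect_true(all(r$comparisons$p_adjusted >=
                    r$comparisons$p_unadjusted - 1e-12))
})

test_that("Dunnett quadrature matches mvtnorm's integrator", {
  skip_if_not_installed("mvtnorm")
  set.seed(37)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    q <- runif(1, 0.5, 4)
    df2 <- sample(c(6, 10, 25, 60, 200), 1)
    ns <- sample(3:9, k, replace = TRUE)
    n0 <- sample(3:9, 1)
    lambda <- sqrt(ns / (ns + n0))
    corr <- outer(lambda, lambda); diag(corr) <- 1
    mine <- gliaquant:::dunnett_prob(q, df2, lambda)
    ref <- mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                         df = df2, corr = corr,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                        maxpts = 5e5))[1]
    expect_equal(mine, ref, tolerance = 1e-5)
  }
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(13)
  coh <- sim_cohort(c(ctrl = 100, t1 = 90, t2 = 105, t3 = 80), n = 6, sd = 9)
  r <- anova_dunnett(coh, "ctrl")
  coh$group <- stats::relevel(factor(coh$group), ref = "ctrl")
  fit <- stats::aov(density ~ group, data = coh)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(unname(r$comparisons$p_adjusted),
               unname(as.numeric(ref$test$pvalues)), tolerance = 2e-3)
})

test_that("degenerate equal groups give F near zero and p near one", {
  coh <- data.frame(group = rep(c("ctrl", "t1", "t2"), each = 4), region = "r",
                    density = rep(c(10, 11, 9, 10), 3))
  r <- anova_dunnett(coh, "ctrl")
  expect_lt(r$F, 1e-10)
  expect_true(all(r$comparisons$p_adjusted > 0.999))
})

test_that("insufficient replication is rejected", {
  coh <- data.frame(group = c("ctrl", "ctrl", "t1"), region = "r",
                    density = c(1, 2, 3))
  expect_error(anova_dunnett(coh, "ctrl"), "replication")
})

test_that("binned KS equals the exhaustive bin-scan oracle exactly", {
  expect_equal(ks_binned(hist_from_counts(c(rep(2, 25), rep(0, 26))),
                         hist_from_counts(c(rep(2, 25), rep(0, 26))))$D, 0)
  disjoint_a <- c(rep(3, 10), rep(0, 41))
  disjoint_b <- c(rep(0, 41), rep(3, 10))
  expect_equal(ks_binned(hist_from_counts(disjoint_a),
                         hist_from_counts(disjoint_b))$D, 1)
  set.seed(17)
  for (i in 1:50) {
    a <- rpois(51, 2); b <- rpois(51, 2)
    if (sum(a) == 0 || sum(b) == 0) next
    got <- ks_binned(hist_from_counts(a), hist_from_counts(b))
    expect_identical(got$D, ks_oracle_D(a, b))
  }
  expect_error(ks_binned(hist_from_counts(rpois(51, 2)),
                         list(bin_edges = seq(0, 250, 5), counts = rpois(51, 2))),
               "bin edges")
})

test_that("KS p-value is calibrated against stats::ks.test asymptotics", {
  # unbinned data placed in singleton bins reproduces the classical test
  set.seed(19)
  x <- sample(0:250, 40, replace = TRUE)
  y <- sample(5:255, 55, replace = TRUE)
  bin <- function(v) tabulate(pmin(51, floor(v / 5) + 1), 51)
  got <- ks_binned(hist_from_counts(bin(x)), hist_from_counts(bin(y)))
  ref <- suppressWarnings(stats::ks.test(floor(x / 5), floor(y / 5)))
  expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
})

test_that("concentration-response R2 behaves like OLS", {
  x <- 1:10; y <- 2 + 3 * x
  expect_equal(suppressWarnings(concentration_response_r2(x, y))$r_squared, 1)
  set.seed(23)
  xn <- runif(200); yn <- sample(xn)   # permuted: no relation
  expect_lt(concentration_response_r2(xn, yn)$r_squared, 0.05)
  # affine rescaling of x leaves R2 unchanged
  yv <- 2 + 3 * x + rnorm(10)
  r1 <- concentration_response_r2(x, yv)$r_squared
  r2 <- concentration_response_r2(10 * x - 4, yv)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(concentration_response_r2(x, rep(1, 10)), "zero variance")
  expect_error(concentration_response_r2(1:2, 1:2), "3")
})

test_that("programmed 65% depletion is recovered with significant Dunnett", {
  des <- experiment_design(
    groups = data.frame(group = c("control", "treated"), n_animals = 6,
                        control = c(TRUE, FALSE)),
    regions = data.frame(region = c("hit", "null"),
                         baseline_density = c(3000, 2000), cv = 0.10),
    depletion = data.frame(group = "treated", region = "hit",
                           fraction = 0.65))
  hits <- 0; nulls <- 0
  for (s in 1:40) {
    coh <- generate_cohort(des, seed = 1000 + s)
    d <- depletion_percent(coh, "control")
    est <- d$percent_depletion[d$region == "hit"]
    p_hit <- anova_dunnett(coh, "control", "hit")$comparisons$p_adjusted
    p_null <- anova_dunnett(coh, "control", "null")$comparisons$p_adjusted
    if (abs(est - 65) <= 8 && p_hit < 0.001) hits <- hits + 1
    if (p_null > 0.05) nulls <- nulls + 1
  }
  expect_gte(hits, 38)   # >= 95%
  expect_gte(nulls, 36)  # >= 90%
})
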