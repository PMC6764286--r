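# Group-comparison statistics: depletion percentages relative to control
# and one-way ANOVA with Dunnett's many-to-one post hoc test.

check_cohort <- function(cohort) {
  need <- c("group", "region", "density")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
    bad_arg("cohort", "needs columns group, region, density")
  invisible(cohort)
}

#' Percent depletion relative to a control group
#'
#' For each treatment group and region, depletion is
#' `100 * (1 - mean_group / mean_control)`; negative values indicate
#' densities above control (repopulation direction). The standard error is
#' obtained by the delta method from the two group means' standard errors.
#'
#' @param cohort data frame with columns `group`, `region`, `density`
#'   (one row per animal x region), e.g. from [generate_cohort()].
#' @param control name of the control group.
#' @param region optional region name to restrict to (default: all).
#' @return data frame: `group`, `region`, `n`, `mean_density`,
#'   `percent_depletion`, `se`.
#' @export
depletion_percent <- function(cohort, control, region = NULL) {
  check_cohort(cohort)
  if (!control %in% cohort$group)
    bad_arg("control", sprintf("group '%s' not present in cohort", control))
  regions <- if (is.null(region)) unique(cohort$region) else region
  out <- list()
  for (reg in regions) {
    sub <- cohort[cohort$region == reg, ]
    ctrl <- sub$density[sub$group == control]
    if (length(ctrl) < 1L)
      bad_arg("control", sprintf("no control animals in region '%s'", reg))
    mc <- mean(ctrl)
    if (mc == 0)
      stop(sprintf("control mean density is zero in region '%s': ",
                   reg), "depletion percentage undefined", call. = FALSE)
    vc <- if (length(ctrl) > 1) var(ctrl) / length(ctrl) else 0
    for (g in setdiff(unique(sub$group), control)) {
      x <- sub$density[sub$group == g]
      mt <- mean(x)
      vt <- if (length(x) > 1) var(x) / length(x) else 0
      # delta method on d = 1 - mt/mc
      se <- 100 * sqrt(vt / mc^2 + mt^2 * vc / mc^4)
      out[[length(out) + 1L]] <- data.frame(
        group = g, region = reg, n = length(x), mean_density = mt,
        percent_depletion = 100 * (1 - mt / mc), se = se)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached.
quad_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(quad_cache[[key]])) return(quad_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  quad_cache[[key]] <- res
  res
}
# Gauss-Hermite (weight exp(-x^2)); cached.
gauss_hermite <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(quad_cache[[key]])) return(quad_cache[[key]])
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = rev(e$values), w = rev(sqrt(pi) * e$vectors[1, ]^2))
  quad_cache[[key]] <- res
  res
}

# P(max_j |T_j| <= q) for the Dunnett many-to-one statistics: the
# correlation matrix lambda_i * lambda_j (off-diagonal) is a one-factor
# model, T_j = (lambda_j Z0 + sqrt(1 - lambda_j^2) X_j) / W with Z0, X_j
# iid standard normal and W^2 ~ chi^2_df / df, so the probability reduces
# to a two-dimensional integral over (z0, w), evaluated by fixed 64 x 64
# tensor Gauss quadrature (agreement with mvtnorm's integrator is at the
# 1e-6 level or better; see the test suite).
dunnett_prob <- function(q, df2, lambda) {
  sig <- sqrt(1 - lambda^2)
  gh <- gauss_hermite(64L)
  z <- sqrt(2) * gh$x                 # integral against the normal density
  wz <- gh$w / sqrt(pi)
  lo <- max(0, 1 - 12 / sqrt(2 * df2))
  hi <- 1 + 12 / sqrt(2 * df2)
  gl <- gauss_legendre(64L)
  w <- (gl$x + 1) / 2 * (hi - lo) + lo
  log_c <- (df2 / 2) * log(df2 / 2) - lgamma(df2 / 2) + log(2)
  fw <- exp(log_c + (df2 - 1) * log(w) - df2 * w^2 / 2)
  ww <- gl$w * (hi - lo) / 2 * fw
  acc <- matrix(1, length(w), length(z))
  qw <- q * w
  for (j in seq_along(lambda)) {
    lz <- lambda[j] * z
    acc <- acc * (pnorm((outer(qw, lz, function(a, b) a - b)) / sig[j]) -
                    pnorm((outer(-qw, lz, function(a, b) a - b)) / sig[j]))
  }
  min(1, max(0, as.numeric(t(ww) %*% acc %*% wz)))
}

# Dunnett single-step adjustment: two-sided adjusted p for each statistic
# in `tval` under the multivariate t with correlation lambda_i * lambda_j,
# lambda_i = sqrt(n_i / (n_i + n0)), and `df2` pooled-variance degrees of
# freedom. The adjusted p is never below the unadjusted two-sided t p.
dunnett_p_adjust <- function(tval, df2, ns, n0) {
  k <- length(tval)
  lambda <- sqrt(ns / (ns + n0))
  p_unadj <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
  p_adj <- if (k == 1L) p_unadj else {
    vapply(abs(tval), function(q) 1 - dunnett_prob(q, df2, lambda),
           numeric(1))
  }
  pmin(1, pmax(p_adj, p_unadj))
}

#' One-way ANOVA with Dunnett's many-to-one post hoc test
#'
#' Fits the one-way layout for a region, reports the overall F test, and
#' compares each treatment group against the control with Dunnett's test:
#' two-sided adjusted p-values from the multivariate t distribution with the
#' standard correlation structure implied by group sizes
#' (`corr[i, j] = lambda_i * lambda_j`, `lambda_i = sqrt(n_i / (n_i + n_0))`)
#' and pooled-variance degrees of freedom `N - k` (k = number of groups).
#'
#' @param cohort data frame with `group`, `region`, `density`.
#' @param control name of the control group.
#' @param region region to analyse (required if the cohort has several).
#' @return a `dunnett_result`: list with `F`, `df1`, `df2`, `p_overall`,
#'   `region`, `control`, and `comparisons` — a data frame of per-treatment
#'   `estimate` (mean difference from control), `se`, `t`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
anova_dunnett <- function(cohort, control, region = NULL) {
  check_cohort(cohort)
  regs <- unique(cohort$region)
  if (is.null(region)) {
    if (length(regs) > 1L)
      bad_arg("region", "cohort has several regions; pick one")
    region <- regs
  }
  sub <- cohort[cohort$region == region, ]
  if (!control %in% sub$group)
    bad_arg("control", sprintf("group '%s' not present in region '%s'",
                               control, region))
  groups <- unique(sub$group)
  k <- length(groups)
  if (k < 2L) bad_arg("cohort", "need at least two groups")
  ns <- table(factor(sub$group, levels = groups))
  if (any(ns < 2L))
    stop("insufficient replication: every group needs >= 2 observations",
         call. = FALSE)

  means <- tapply(sub$density, factor(sub$group, levels = groups), mean)
  N <- nrow(sub)
  grand <- mean(sub$density)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((sub$density - means[as.character(sub$group)])^2)
  df1 <- k - 1L
  df2 <- N - k
  mse <- ss_within / df2
  f_stat <- (ss_between / df1) / mse
  p_overall <- pf(f_stat, df1, df2, lower.tail = FALSE)

  trt <- setdiff(groups, control)
  n0 <- ns[[control]]
  est <- means[trt] - means[control]
  se <- sqrt(mse * (1 / ns[trt] + 1 / n0))
  tval <- est / se
  p_unadj <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
  p_adj <- dunnett_p_adjust(tval, df2, as.numeric(ns[trt]), n0)

  structure(list(
    F = f_stat, df1 = df1, df2 = df2, p_overall = p_overall,
    region = region, control = control,
    comparisons = data.frame(group = trt, n = as.integer(ns[trt]),
                             estimate = as.numeric(est),
                             se = as.numeric(se), t = as.numeric(tval),
                             p_unadjusted = as.numeric(p_unadj),
                             p_adjusted = as.numeric(p_adj),
                             row.names = NULL)),
    class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA, region '%s': F(%d, %d) = %.3f, p = %.3g\n",
              x$region, x$df1, x$df2, x$F, x$p_overall))
  cat(sprintf("Dunnett many-to-one vs '%s':\n", x$control))
  print(x$comparisons, digits = 4)
  invisible(x)
}
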