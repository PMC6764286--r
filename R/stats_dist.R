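# Distribution comparison of binned intensity histograms and simple
# concentration-response regression.

#' Kolmogorov-Smirnov test on binned histograms
#'
#' Compares two [intensity_histogram()]s (or any histograms on identical bin
#' edges): D is the maximum gap between the empirical CDFs evaluated at the
#' bin boundaries, and the p-value uses the asymptotic two-sample KS
#' distribution with effective sample size `nA * nB / (nA + nB)`.
#'
#' @param hist_a,hist_b objects with `bin_edges` and `counts` (identical
#'   edges required).
#' @return list with `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_binned <- function(hist_a, hist_b) {
  if (!isTRUE(all.equal(hist_a$bin_edges, hist_b$bin_edges)))
    stop("histograms have different bin edges", call. = FALSE)
  na <- sum(hist_a$counts); nb <- sum(hist_b$counts)
  if (na == 0 || nb == 0)
    stop("both histograms need at least one observation", call. = FALSE)
  ca <- cumsum(hist_a$counts) / na
  cb <- cumsum(hist_b$counts) / nb
  D <- max(abs(ca - cb))
  ne <- na * nb / (na + nb)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  # asymptotic KS survival function, 2 * sum_k (-1)^(k-1) exp(-2 k^2 l^2)
  p <- if (lambda < 1e-8) 1 else {
    kk <- 1:100
    min(1, max(0, 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))))
  }
  list(D = D, p_value = p, n_a = na, n_b = nb)
}

#' R-squared of a simple linear concentration-response fit
#'
#' Ordinary least-squares fit of response on concentration;
#' `R^2 = 1 - SS_res / SS_tot`. Used to summarize how strongly depletion
#' tracks measured tissue drug concentration.
#'
#' @param x tissue concentrations (or any predictor), length >= 3.
#' @param y responses (density or percent depletion).
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
concentration_response_r2 <- function(x, y) {
  if (length(x) != length(y)) bad_arg("y", "lengths of x and y differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) bad_arg("x", "need at least 3 finite points")
  if (var(y) == 0)
    stop("response has zero variance: R^2 undefined", call. = FALSE)
  fit <- lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}
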