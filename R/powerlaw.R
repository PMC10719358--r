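#' Power-law fit of a frequency spectrum
#'
#' Continuous maximum-likelihood fit of a Pareto tail in the style of
#' Clauset, Shalizi & Newman: for each candidate lower cutoff `xmin` the
#' exponent is `alpha = 1 + m / sum(log(x/xmin))` over the `m` tail
#' observations, `xmin` is chosen to minimise the Kolmogorov-Smirnov
#' distance between the tail and the fitted CDF, and a semi-parametric
#' bootstrap gives a goodness-of-fit p value (the fraction of synthetic
#' data sets fitting worse than the observed one; large p = the power law
#' is not rejected).  A discrete (zeta) variant is available for counts.
#'
#' @param values Positive numerics (e.g. carrier counts); at least 50.
#' @param n_bootstrap Bootstrap replicates for the goodness-of-fit p
#'   (0 skips the bootstrap, `gof_p = NA`).
#' @param seed Integer seed (the whole fit is deterministic given it).
#' @param discrete Use the discrete MLE (approximate zeta form) instead of
#'   the continuous one.
#' @param max_xmin_candidates Cap on distinct `xmin` candidates scanned
#'   (candidates are thinned to quantiles beyond this).
#' @return Object of class `powerlaw_fit` with `alpha`, `xmin`, `ks_stat`,
#'   `gof_p`, `n_tail`; see also `glance()`.
#' @export
powerlaw_fit <- function(values, n_bootstrap = 100L, seed = 1L,
                         discrete = FALSE, max_xmin_candidates = 60L) {
  x <- as.numeric(values)
  if (any(!is.finite(x)) || any(x <= 0)) abort("values must be positive")
  if (base::length(x) < 50) abort("need at least 50 values")
  if (base::length(unique(x)) == 1) abort("degenerate input: all values identical")
  set.seed(seed)
  fit <- pl_fit_core(x, discrete, max_xmin_candidates)
  gof_p <- NA_real_
  if (n_bootstrap > 0) {
    n <- base::length(x)
    body <- x[x < fit$xmin]
    p_tail <- fit$n_tail / n
    worse <- 0L
    for (b in seq_len(n_bootstrap)) {
      from_tail <- runif(n) < p_tail
      xb <- numeric(n)
      xb[from_tail] <- rpareto(sum(from_tail), fit$xmin, fit$alpha,
                               discrete)
      if (base::length(body) > 0) {
        xb[!from_tail] <- sample(body, sum(!from_tail), replace = TRUE)
      } else {
        xb[!from_tail] <- rpareto(sum(!from_tail), fit$xmin, fit$alpha,
                                  discrete)
      }
      fb <- pl_fit_core(xb, discrete, max_xmin_candidates)
      if (fb$ks_stat >= fit$ks_stat) worse <- worse + 1L
    }
    gof_p <- worse / n_bootstrap
  }
  structure(list(alpha = fit$alpha, xmin = fit$xmin,
                 ks_stat = fit$ks_stat, gof_p = gof_p,
                 n_tail = fit$n_tail, discrete = discrete,
                 n = base::length(x)),
            class = "powerlaw_fit")
}

# core Clauset scan: returns alpha, xmin, ks, n_tail
pl_fit_core <- function(x, discrete, max_cand) {
  xs <- sort(x)
  cand <- unique(xs)
  cand <- cand[cand < xs[base::length(xs)]]  # need >= 2 tail points
  if (base::length(cand) > max_cand) {
    qs <- quantile(cand, probs = seq(0, 0.95, length.out = max_cand),
                   type = 1, names = FALSE)
    cand <- unique(qs)
  }
  best <- NULL
  for (xm in cand) {
    tail_x <- xs[xs >= xm]
    m <- base::length(tail_x)
    if (m < 10) next
    alpha <- if (discrete) {
      1 + m / sum(log(tail_x / (xm - 0.5)))
    } else {
      1 + m / sum(log(tail_x / xm))
    }
    if (!is.finite(alpha) || alpha <= 1) next
    cdf_fit <- 1 - (tail_x / xm)^(1 - alpha)
    ecdf_lo <- (seq_len(m) - 1) / m
    ecdf_hi <- seq_len(m) / m
    ks <- max(pmax(abs(cdf_fit - ecdf_lo), abs(cdf_fit - ecdf_hi)))
    if (is.null(best) || ks < best$ks_stat) {
      best <- list(alpha = alpha, xmin = xm, ks_stat = ks, n_tail = m)
    }
  }
  if (is.null(best)) abort("no viable xmin candidate (tail too short)")
  best
}

rpareto <- function(n, xmin, alpha, discrete = FALSE) {
  out <- xmin * (1 - runif(n))^(-1 / (alpha - 1))
  if (discrete) out <- round(out)
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.3f, xmin = %g, KS = %.4f, n_tail = %d%s\n",
              x$alpha, x$xmin, x$ks_stat, x$n_tail,
              if (is.na(x$gof_p)) "" else sprintf(", gof p = %.2f", x$gof_p)))
  invisible(x)
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, ks_stat = x$ks_stat,
         gof_p = x$gof_p, n_tail = x$n_tail, n = x$n,
         discrete = x$discrete)
}
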