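#' Parallel-culture mutant counts from a fluctuation assay
#'
#' Bundles the observed mutant counts of one strain/locus combination with
#' the final number of cells per culture (`Nt`). The distribution of counts
#' across parallel cultures grown from small inocula follows the
#' Luria-Delbruck distribution, whose location encodes the per-cell mutation
#' rate; [estimate_rate()] turns a `culture_set` into a [rate_estimate].
#'
#' @param mutant_counts Non-negative integer vector, one entry per culture
#'   (number of selected colonies, e.g. Can-r or His+ revertants).
#' @param n_final_cells Positive number: viable cells per culture at plating
#'   (`Nt`). The per-cell rate is `m / Nt`.
#' @param strain,locus Optional labels carried through to reports.
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#'   Defaults to 1 (no dilution correction).
#' @return An object of class `culture_set`.
#' @examples
#' cs <- culture_set(c(0, 1, 0, 3, 2, 0, 1, 12, 0), n_final_cells = 1e8,
#'                   strain = "wt", locus = "CAN1")
#' estimate_rate(cs)
#' @export
culture_set <- function(mutant_counts, n_final_cells, strain = "", locus = "",
                        plating_fraction = 1) {
  if (!is_count_vector(mutant_counts))
    stop_mutlab("'mutant_counts' must be non-negative integers (>= 1 culture)")
  if (!is.numeric(n_final_cells) || length(n_final_cells) != 1L ||
      !is.finite(n_final_cells) || n_final_cells <= 0)
    stop_mutlab("'n_final_cells' (Nt) must be a single positive number")
  if (any(mutant_counts > n_final_cells))
    stop_mutlab("mutant counts cannot exceed the final cell number Nt")
  if (!is.numeric(plating_fraction) || length(plating_fraction) != 1L ||
      plating_fraction <= 0 || plating_fraction > 1)
    stop_mutlab("'plating_fraction' must lie in (0, 1]")
  structure(
    list(strain = as.character(strain), locus = as.character(locus),
         mutant_counts = as.numeric(mutant_counts),
         n_final_cells = as.numeric(n_final_cells),
         plating_fraction = as.numeric(plating_fraction)),
    class = "culture_set")
}

#' @export
print.culture_set <- function(x, ...) {
  lab <- paste(c(x$strain, x$locus)[nzchar(c(x$strain, x$locus))],
               collapse = " / ")
  cat("Fluctuation-assay culture set", if (nzchar(lab)) paste0(" (", lab, ")"),
      "\n", sep = "")
  cat("  cultures: ", length(x$mutant_counts),
      ",  median count: ", stats::median(x$mutant_counts),
      ",  Nt: ", format(x$n_final_cells, scientific = TRUE), "\n", sep = "")
  invisible(x)
}

#' Lea-Coulson method-of-the-median estimator of m
#'
#' Solves the Lea-Coulson median equation `r/m - log(m) = 1.24` for the
#' expected number of mutation events per culture `m`, given the sample
#' median mutant count `r`. The left-hand side is strictly decreasing in
#' `m`, so the root is unique; it is located numerically to a relative
#' tolerance of 1e-10. A median of 0 returns 0 — callers should fall back
#' to the P0 method in that case (see [estimate_rate()]).
#'
#' @param median_count Non-negative number: the median number of mutant
#'   colonies per culture (may be half-integer for even culture numbers).
#' @return The estimate `m >= 0` (mutation events per culture).
#' @examples
#' lea_coulson_m(1.24)  # exactly 1
#' lea_coulson_m(5)     # about 2.375
#' @seealso [mle_m()] for the Ma-Sandri-Sarkar maximum-likelihood estimator.
#' @export
lea_coulson_m <- function(median_count) {
  if (!is.numeric(median_count) || length(median_count) != 1L ||
      !is.finite(median_count) || median_count < 0)
    stop_mutlab("'median_count' must be a single non-negative number")
  if (median_count == 0) return(0)
  f <- function(m) median_count / m - log(m) - 1.24
  # bracket: f(+0) = +Inf; grow the upper end until f < 0
  hi <- max(2, median_count)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, lower = .Machine$double.xmin^0.25, upper = hi,
                 tol = 1e-10 * max(1, median_count))$root
}

#' Luria-Delbruck probability mass function (MSS recursion)
#'
#' Computes `P(R = r)` for `r = 0, ..., r_max` under the Luria-Delbruck
#' mutant-count distribution with `m` expected mutation events per culture,
#' using the exact Ma-Sandri-Sarkar recursion
#' `p_0 = exp(-m)`, `p_r = (m / r) * sum_{i<r} p_i / (r - i + 1)`.
#'
#' @param m Positive number: expected mutation events per culture.
#' @param r_max Largest count to evaluate (integer >= 0).
#' @return Numeric vector of length `r_max + 1` with `p_0, ..., p_rmax`.
#'   Entries lie in `[0, 1]`; partial sums increase towards 1.
#' @examples
#' p <- ld_pmf(1, 10)
#' p[1]  # exp(-1), the Poisson zero class
#' @export
ld_pmf <- function(m, r_max) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop_mutlab("'m' must be a single positive number")
  if (!is.numeric(r_max) || length(r_max) != 1L || r_max < 0)
    stop_mutlab("'r_max' must be a non-negative integer")
  r_max <- as.integer(r_max)
  p <- numeric(r_max + 1L)
  p[1L] <- exp(-m)
  if (r_max >= 1L) {
    w <- 1 / (2:(r_max + 1L))   # w[k] = 1/(k + 1)
    for (r in seq_len(r_max))
      p[r + 1L] <- (m / r) * sum(p[seq_len(r)] * w[r:1L])
  }
  p
}

#' Maximum-likelihood estimate of m from mutant counts
#'
#' Maximises the Luria-Delbruck log-likelihood of the observed counts over
#' `m` using [ld_pmf()] and one-dimensional bounded search. Counts larger
#' than `r_cap` are treated as right-censored at `r_cap` via the MSS tail
#' probability, which keeps the quadratic-cost recursion tractable for
#' jackpot cultures without discarding them.
#'
#' @param counts Non-negative integer vector of mutant counts.
#' @param r_cap Censoring threshold for very large (jackpot) counts.
#' @return The MLE `m >= 0`. All-zero counts return 0 with a warning.
#' @examples
#' mle_m(c(0, 1, 0, 3, 2, 0, 1, 12, 0))
#' @export
mle_m <- function(counts, r_cap = 1000L) {
  if (!is_count_vector(counts))
    stop_mutlab("'counts' must be non-negative integers")
  if (all(counts == 0)) {
    warning("all cultures have zero mutants; returning m = 0", call. = FALSE)
    return(0)
  }
  cens <- counts > r_cap
  r_obs <- pmin(counts, r_cap)
  r_max <- max(r_obs)
  tab <- tabulate(r_obs[!cens] + 1L, nbins = r_max + 1L)
  n_cens <- sum(cens)
  negll <- function(m) {
    p <- ld_pmf(m, r_max)
    p <- pmax(p, 1e-300)
    ll <- sum(tab * log(p))
    if (n_cens > 0) ll <- ll + n_cens * log(max(1 - sum(p), 1e-300))
    -ll
  }
  # bracket around the median-based estimate when available
  m0 <- max(lea_coulson_m(stats::median(counts)), 0.05)
  stats::optimize(negll, interval = c(1e-4, max(20, 10 * m0)))$minimum
}

#' Estimate a spontaneous mutation rate from a fluctuation assay
#'
#' Fits the per-cell, per-generation mutation rate to the mutant counts of
#' parallel cultures. Three estimators are available:
#' \describe{
#'   \item{`median`}{the Lea-Coulson method of the median (the default):
#'     the sample median count is mapped through [lea_coulson_m()]. The 95%
#'     confidence interval is the distribution-free binomial order-statistic
#'     interval on the median count, with each bound mapped through the same
#'     estimator — a monotone transform, so the interval brackets the point
#'     estimate by construction.}
#'   \item{`mle`}{the Ma-Sandri-Sarkar maximum-likelihood estimate via
#'     [mle_m()], with a profile-likelihood 95% interval.}
#'   \item{`p0`}{`m = -log(P0)` where `P0` is the fraction of cultures with
#'     zero mutants, with an exact binomial interval on `P0` mapped through
#'     `-log`. Used automatically when the median is 0.}
#' }
#' The rate is `m / (Nt * plating_fraction)`, i.e. mutations per cell per
#' generation under exponential growth from a small inoculum.
#'
#' @param cultures A [culture_set()].
#' @param method One of `"median"`, `"mle"`, `"p0"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `rate_estimate` with components `m`, `rate`,
#'   `ci_low`, `ci_high`, `n_cultures`, `method`, plus the labels of the
#'   input culture set.
#' @examples
#' cs <- culture_set(c(2, 0, 5, 1, 3, 0, 8, 2, 1), 1e8, "wt", "CAN1")
#' est <- estimate_rate(cs)
#' est
#' confint(est)
#' @export
estimate_rate <- function(cultures, method = c("median", "mle", "p0"),
                          conf_level = 0.95) {
  if (!inherits(cultures, "culture_set"))
    stop_mutlab("'cultures' must be a culture_set")
  method <- match.arg(method)
  counts <- cultures$mutant_counts
  n <- length(counts)
  nt_eff <- cultures$n_final_cells * cultures$plating_fraction
  if (all(counts == cultures$n_final_cells))
    stop_mutlab("every culture is a full jackpot (count = Nt); ",
                "the rate is unidentifiable")

  med <- stats::median(counts)
  if (method == "median" && med == 0) {
    message("median mutant count is 0; falling back to the P0 method")
    method <- "p0"
  }

  if (method == "median") {
    m <- lea_coulson_m(med)
    srt <- sort(counts)
    # largest j with P(Binom(n, 1/2) < j) <= alpha/2 -> order-stat bounds
    alpha <- 1 - conf_level
    j <- stats::qbinom(alpha / 2, n, 0.5)
    if (stats::pbinom(j - 1, n, 0.5) > alpha / 2) j <- j - 1L
    j <- max(j, 0L)
    lo_count <- if (j >= 1L) srt[j] else srt[1L]
    hi_count <- if (j >= 1L) srt[n - j + 1L] else srt[n]
    m_lo <- lea_coulson_m(lo_count)
    m_hi <- lea_coulson_m(hi_count)
  } else if (method == "p0") {
    nz <- sum(counts == 0)
    if (nz == 0)
      stop_mutlab("no zero-mutant cultures; the P0 method is inapplicable")
    m <- -log(nz / n)
    bt <- stats::binom.test(nz, n, conf.level = conf_level)$conf.int
    m_lo <- -log(bt[2L])  # larger P0 -> smaller m
    m_hi <- -log(bt[1L])
    m_lo <- max(m_lo, 0)
  } else { # mle
    m <- mle_m(counts)
    ci <- profile_ci_m(counts, m, conf_level)
    m_lo <- ci[1L]; m_hi <- ci[2L]
  }

  structure(
    list(m = m, rate = m / nt_eff,
         ci_low = m_lo / nt_eff, ci_high = m_hi / nt_eff,
         n_cultures = n, method = method,
         strain = cultures$strain, locus = cultures$locus,
         n_final_cells = cultures$n_final_cells,
         conf_level = conf_level),
    class = "rate_estimate")
}

# Profile-likelihood CI for the MLE method: log-likelihood drop of
# qchisq(level, 1)/2 on either side of the maximum.
profile_ci_m <- function(counts, m_hat, conf_level) {
  r_cap <- 1000L
  cens <- counts > r_cap
  r_obs <- pmin(counts, r_cap)
  r_max <- max(r_obs)
  tab <- tabulate(r_obs[!cens] + 1L, nbins = r_max + 1L)
  n_cens <- sum(cens)
  ll <- function(m) {
    p <- pmax(ld_pmf(m, r_max), 1e-300)
    out <- sum(tab * log(p))
    if (n_cens > 0) out <- out + n_cens * log(max(1 - sum(p), 1e-300))
    out
  }
  ll_hat <- ll(m_hat)
  drop <- stats::qchisq(conf_level, 1) / 2
  f <- function(m) ll(m) - (ll_hat - drop)
  lo <- tryCatch({
    if (f(1e-4) > 0) 0 else stats::uniroot(f, c(1e-4, m_hat))$root
  }, error = function(e) 0)
  hi <- tryCatch({
    up <- 2 * m_hat + 1
    while (f(up) > 0 && up < 1e4) up <- up * 2
    stats::uniroot(f, c(m_hat, up))$root
  }, error = function(e) Inf)
  c(lo, hi)
}

#' @export
print.rate_estimate <- function(x, digits = 3, ...) {
  lab <- paste(c(x$strain, x$locus)[nzchar(c(x$strain, x$locus))],
               collapse = " / ")
  cat("Mutation-rate estimate", if (nzchar(lab)) paste0(" (", lab, ")"),
      "\n", sep = "")
  cat(sprintf("  method: %s   cultures: %d\n", x$method, x$n_cultures))
  cat(sprintf("  m (events/culture): %s\n", signif(x$m, digits)))
  cat(sprintf("  rate: %s per cell per generation  (%.0f%% CI %s - %s)\n",
              signif(x$rate, digits), 100 * x$conf_level,
              signif(x$ci_low, digits), signif(x$ci_high, digits)))
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) {
  c(m = object$m, rate = object$rate)
}

#' @export
confint.rate_estimate <- function(object, parm = "rate", level = NULL, ...) {
  out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                dimnames = list("rate", c("lower", "upper")))
  out
}

#' Relative mutation rate under the printed rounding convention
#'
#' Ratio of a strain's rate to a reference (typically wild-type) rate,
#' rounded the way mutation-rate tables print it: one decimal place for
#' ratios below 100 and three significant figures at or above 100.
#'
#' @param est,reference [rate_estimate] objects or plain positive numbers
#'   (absolute rates).
#' @param round Apply the table rounding convention (default `TRUE`); set
#'   `FALSE` for the raw ratio.
#' @return A single number.
#' @examples
#' relative_rate(74.3, 10.1)  # 7.4
#' relative_rate(2720, 12.9)  # 211
#' @export
relative_rate <- function(est, reference, round = TRUE) {
  r1 <- if (inherits(est, "rate_estimate")) est$rate else est
  r0 <- if (inherits(reference, "rate_estimate")) reference$rate else reference
  if (!is.numeric(r1) || !is.numeric(r0) || length(r1) != 1L ||
      length(r0) != 1L)
    stop_mutlab("rates must be single numbers or rate_estimate objects")
  if (r0 <= 0) stop_mutlab("reference rate must be positive")
  ratio <- r1 / r0
  if (round) round_relative(ratio) else ratio
}

#' Do two confidence intervals overlap?
#'
#' The significance call used in mutation-rate tables: two rates are
#' declared "different" when their 95% confidence limits do not overlap.
#' A shared endpoint counts as overlap (the conservative convention).
#'
#' @param a,b [rate_estimate] objects, or numeric length-2 vectors
#'   `c(lower, upper)`.
#' @return `TRUE` if the intervals intersect (rates not distinguishable),
#'   `FALSE` if they are disjoint (rates "different").
#' @examples
#' ci_overlap(c(3.9, 14.6), c(72.2, 95.2))  # FALSE -> "different"
#' @export
ci_overlap <- function(a, b) {
  ia <- if (inherits(a, "rate_estimate")) c(a$ci_low, a$ci_high) else a
  ib <- if (inherits(b, "rate_estimate")) c(b$ci_low, b$ci_high) else b
  if (length(ia) != 2L || length(ib) != 2L || any(!is.finite(c(ia, ib))))
    stop_mutlab("each interval must be two finite numbers")
  if (ia[1] > ia[2] || ib[1] > ib[2])
    stop_mutlab("interval bounds must be ordered (lower <= upper)")
  ia[1] <= ib[2] && ib[1] <= ia[2]
}
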