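#' Mutation spectrum
#'
#' A labelled vector of mutant counts by mutation class (base-substitution
#' types, frameshifts, complex changes, ...), i.e. one column of a
#' spectrum table. Columns may have unequal totals (a sequenced isolate can
#' carry more than one mutation), so no normalisation is applied.
#'
#' @param counts Non-negative integer vector.
#' @param categories Character vector of class names, same length as
#'   `counts`; defaults to `names(counts)`.
#' @param label Text label for the strain or enzyme.
#' @return An object of class `mutation_spectrum`.
#' @examples
#' holo <- mutation_spectrum(c(214, 53, 9, 11),
#'   categories = c("substitutions", "-1 frameshifts", "+1 frameshifts",
#'                  "other"),
#'   label = "holoenzyme pol2-4")
#' holo
#' @export
mutation_spectrum <- function(counts, categories = names(counts), label = "") {
  if (is.null(categories))
    stop_mutlab("'categories' must be supplied (or 'counts' must be named)")
  categories <- as.character(categories)
  if (length(categories) != length(counts))
    stop_mutlab("'categories' and 'counts' differ in length")
  if (anyDuplicated(categories))
    stop_mutlab("category names must be unique")
  if (length(counts) < 1L || !is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop_mutlab("'counts' must be non-negative integers (>= 1 category)")
  structure(
    list(label = as.character(label), categories = categories,
         counts = as.numeric(counts)),
    class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Mutation spectrum", if (nzchar(x$label)) paste0(" (", x$label, ")"),
      " - ", sum(x$counts), " mutations\n", sep = "")
  print(stats::setNames(as.integer(x$counts), x$categories))
  invisible(x)
}

# Align two spectra on a shared category list and drop classes whose pooled
# count is zero (the chi-squared statistic is undefined there).
align_spectra <- function(s1, s2) {
  if (!inherits(s1, "mutation_spectrum") || !inherits(s2, "mutation_spectrum"))
    stop_mutlab("both arguments must be mutation_spectrum objects")
  if (!identical(s1$categories, s2$categories))
    stop_mutlab("spectra have different category lists; align them first")
  keep <- (s1$counts + s2$counts) > 0
  if (sum(keep) < 2L)
    stop_mutlab("fewer than 2 categories with non-zero pooled count")
  list(o1 = s1$counts[keep], o2 = s2$counts[keep],
       categories = s1$categories[keep])
}

#' Pearson chi-squared statistic for two spectra
#'
#' The standard Pearson statistic on the 2xN contingency table formed by
#' two mutation spectra over the same classes, with expected counts from
#' the row and column margins. Categories whose pooled count is zero are
#' dropped before computing the statistic.
#'
#' @param s1,s2 [mutation_spectrum] objects over identical category lists.
#' @return The chi-squared statistic (a non-negative number).
#' @examples
#' a <- mutation_spectrum(c(sub = 214, minus1 = 53, plus1 = 9, other = 11))
#' b <- mutation_spectrum(c(sub = 229, minus1 = 35, plus1 = 7, other = 29))
#' pearson_chi2(a, b)  # about 12.26
#' @export
pearson_chi2 <- function(s1, s2) {
  al <- align_spectra(s1, s2)
  chi2_stat(al$o1, al$o2)
}

chi2_stat <- function(o1, o2) {
  n1 <- sum(o1); n2 <- sum(o2)
  if (n1 == 0 || n2 == 0) stop_mutlab("each spectrum needs a positive total")
  pooled <- o1 + o2
  e1 <- n1 * pooled / (n1 + n2)
  e2 <- n2 * pooled / (n1 + n2)
  sum((o1 - e1)^2 / e1 + (o2 - e2)^2 / e2)
}

#' Monte Carlo test of mutation-spectrum homogeneity
#'
#' Tests whether two spectra are draws from one underlying multinomial by
#' comparing the observed Pearson chi-squared statistic with its null
#' distribution conditional on both margins of the 2xN table: the pooled
#' mutations are randomly re-partitioned into groups of the observed sizes
#' (a multivariate hypergeometric draw per resample, the label-permutation
#' construction used by the COLLAPSE program). Small p-values (p <= 0.05 by
#' the usual criterion) indicate that the spectra differ.
#'
#' The p-value uses the add-one estimator `p = (1 + k) / (1 + B)` where `k`
#' resampled statistics are at least the observed one, so it is never
#' exactly zero.
#'
#' @param s1,s2 [mutation_spectrum] objects over identical category lists.
#' @param B Number of Monte Carlo resamples (default 100000).
#' @param seed Integer seed; required, for reproducibility.
#' @return An object of classes `spectrum_homogeneity` and `htest` with
#'   components `statistic` (observed chi-squared), `p.value`,
#'   `n_resamples`, `seed`, and `categories_used`.
#' @examples
#' a <- mutation_spectrum(c(sub = 214, minus1 = 53, plus1 = 9, other = 11),
#'                        label = "holoenzyme")
#' b <- mutation_spectrum(c(sub = 229, minus1 = 35, plus1 = 7, other = 29),
#'                        label = "Pol2/Dpb2")
#' mc_homogeneity(a, b, B = 1000, seed = 1)
#' @export
mc_homogeneity <- function(s1, s2, B = 100000L, seed) {
  if (missing(seed) || is.null(seed))
    stop_mutlab("a 'seed' is required for reproducibility")
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop_mutlab("'B' must be a positive integer")
  B <- as.integer(B)
  al <- align_spectra(s1, s2)
  o1 <- al$o1; o2 <- al$o2
  n1 <- sum(o1); n2 <- sum(o2); n <- n1 + n2
  pooled <- o1 + o2
  obs <- chi2_stat(o1, o2)

  # Null resamples: sequential multivariate hypergeometric allocation of the
  # pooled counts to group 1, vectorised across all B resamples.
  k <- length(pooled)
  e1 <- n1 * pooled / n
  e2 <- n2 * pooled / n
  w <- 1 / e1 + 1 / e2
  stat_null <- with_seed(seed, {
    left <- rep.int(n1, B)            # group-1 slots still to fill
    rest <- n - cumsum(pooled)        # pooled count beyond category i
    chi2 <- numeric(B)
    for (i in seq_len(k)) {
      xi <- if (i < k) stats::rhyper(B, pooled[i], rest[i], left) else left
      chi2 <- chi2 + (xi - e1[i])^2 * w[i]
      left <- left - xi
    }
    chi2
  })
  kge <- sum(stat_null >= obs - 1e-9)
  p <- (1 + kge) / (1 + B)

  structure(
    list(statistic = c("X-squared" = obs), p.value = p,
         n_resamples = B, seed = seed, categories_used = al$categories,
         method = paste("Monte Carlo Pearson chi-squared test of",
                        "spectrum homogeneity"),
         data.name = paste(sq_label(s1), "vs", sq_label(s2)),
         parameter = c(B = B)),
    class = c("spectrum_homogeneity", "htest"))
}

sq_label <- function(s) if (nzchar(s$label)) s$label else "spectrum"

#' Drop categories from a spectrum
#'
#' Removes the named classes (e.g. the heterogeneous "Other mutations"
#' class) and leaves the remaining counts untouched.
#'
#' @param s A [mutation_spectrum].
#' @param drop Character vector of category names to remove.
#' @return A [mutation_spectrum] without the dropped classes.
#' @examples
#' s <- mutation_spectrum(c(sub = 229, minus1 = 35, plus1 = 7, other = 29))
#' drop_categories(s, "other")
#' @export
drop_categories <- function(s, drop) {
  if (!inherits(s, "mutation_spectrum"))
    stop_mutlab("'s' must be a mutation_spectrum")
  drop <- as.character(drop)
  unknown <- setdiff(drop, s$categories)
  if (length(unknown))
    stop_mutlab("unknown categories: ", paste(unknown, collapse = ", "))
  keep <- !(s$categories %in% drop)
  mutation_spectrum(s$counts[keep], s$categories[keep], s$label)
}

#' Per-category percentages of a spectrum
#'
#' `100 * count / total` per class, rounded to `decimals` places with
#' halves away from zero (the convention of printed spectrum tables, where
#' 3 of 48 appears as 6.3%). The unrounded values sum to exactly 100.
#'
#' @param s A [mutation_spectrum] with a positive total.
#' @param decimals Decimal places for rounding (default 1).
#' @return Named numeric vector of percentages.
#' @examples
#' wt <- mutation_spectrum(c(`GC->CG` = 12, `GC->AT` = 7, rest = 29))
#' percentages(wt)
#' @export
percentages <- function(s, decimals = 1L) {
  if (!inherits(s, "mutation_spectrum"))
    stop_mutlab("'s' must be a mutation_spectrum")
  total <- sum(s$counts)
  if (total <= 0) stop_mutlab("spectrum total must be positive")
  stats::setNames(round_half_up(100 * s$counts / total, decimals),
                  s$categories)
}

#' Linear correlation of two spectra
#'
#' Pearson correlation of the per-class proportion vectors of two spectra
#' over the same categories — a crude similarity summary to accompany the
#' homogeneity test.
#'
#' @param s1,s2 [mutation_spectrum] objects over identical category lists,
#'   with at least 3 categories (the two-category case is degenerate).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spectrum_correlation <- function(s1, s2) {
  if (!inherits(s1, "mutation_spectrum") || !inherits(s2, "mutation_spectrum"))
    stop_mutlab("both arguments must be mutation_spectrum objects")
  if (!identical(s1$categories, s2$categories))
    stop_mutlab("spectra have different category lists")
  if (length(s1$categories) < 3L)
    stop_mutlab("at least 3 categories are required")
  p1 <- s1$counts / sum(s1$counts)
  p2 <- s2$counts / sum(s2$counts)
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0)
    stop_mutlab("correlation undefined: a proportion vector has no variance")
  stats::cor(p1, p2)
}
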