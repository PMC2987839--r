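#' lacZ forward-mutation fidelity assay summary
#'
#' Summary of an M13mp2 lacZ gap-filling fidelity assay for one polymerase:
#' the number of independent mutants sequenced (`N`), the observed lacZ
#' mutant frequency (`MF`), and, per mutation class, the number of
#' mutations of that type among the sequenced mutants (`Ni`) and the
#' number of template sites at which such a mutation is phenotypically
#' detectable (`D`). Because one sequenced mutant can carry several
#' mutations, the class counts need not sum to `N`.
#'
#' @param enzyme Text label for the polymerase or complex.
#' @param n_mutants_sequenced Integer `N > 0`.
#' @param mutant_frequency `MF` in `[0, 1]`.
#' @param classes A data frame with columns `class`, `Ni`, `D`
#'   (each `Ni >= 0`, each `D >= 1`).
#' @param background_frequency Optional background mutant frequency of
#'   uncopied DNA, for [background_adjusted_frequency()].
#' @param expression_prob Probability that a mutant lacZ allele is
#'   expressed in E. coli; 0.6 by assay convention, configurable.
#' @return An object of class `lacz_assay`.
#' @examples
#' a <- lacz_assay("pol2-4/Dpb2", n_mutants_sequenced = 277,
#'   mutant_frequency = 0.029,
#'   classes = data.frame(class = c("substitutions", "-1 frameshifts"),
#'                        Ni = c(229, 35), D = c(150, 90)))
#' error_rate(a, "substitutions")
#' @export
lacz_assay <- function(enzyme, n_mutants_sequenced, mutant_frequency, classes,
                       background_frequency = NULL, expression_prob = 0.6) {
  if (!is.numeric(n_mutants_sequenced) || length(n_mutants_sequenced) != 1L ||
      n_mutants_sequenced < 1)
    stop_mutlab("'n_mutants_sequenced' (N) must be a positive integer")
  if (!is.numeric(mutant_frequency) || length(mutant_frequency) != 1L ||
      mutant_frequency < 0 || mutant_frequency > 1)
    stop_mutlab("'mutant_frequency' (MF) must lie in [0, 1]")
  if (!is.data.frame(classes) ||
      !all(c("class", "Ni", "D") %in% names(classes)))
    stop_mutlab("'classes' must be a data frame with columns class, Ni, D")
  if (anyDuplicated(classes$class))
    stop_mutlab("class names must be unique")
  if (any(classes$Ni < 0) || any(abs(classes$Ni - round(classes$Ni)) > 1e-8))
    stop_mutlab("every Ni must be a non-negative integer")
  if (any(classes$D < 1))
    stop_mutlab("every D (detectable sites) must be >= 1")
  if (!is.null(background_frequency) &&
      (!is.numeric(background_frequency) || background_frequency < 0))
    stop_mutlab("'background_frequency' must be non-negative")
  if (!is.numeric(expression_prob) || length(expression_prob) != 1L ||
      expression_prob <= 0 || expression_prob > 1)
    stop_mutlab("'expression_prob' must lie in (0, 1]")
  structure(
    list(enzyme = as.character(enzyme),
         n_mutants_sequenced = as.integer(n_mutants_sequenced),
         mutant_frequency = as.numeric(mutant_frequency),
         background_frequency = background_frequency,
         classes = data.frame(class = as.character(classes$class),
                              Ni = as.numeric(classes$Ni),
                              D = as.numeric(classes$D),
                              stringsAsFactors = FALSE),
         expression_prob = as.numeric(expression_prob)),
    class = "lacz_assay")
}

#' @export
print.lacz_assay <- function(x, ...) {
  cat("lacZ forward-mutation assay (", x$enzyme, ")\n", sep = "")
  cat(sprintf("  N sequenced: %d   mutant frequency: %g\n",
              x$n_mutants_sequenced, x$mutant_frequency))
  df <- x$classes
  df$error_rate <- vapply(df$class, function(cl) error_rate(x, cl), 0)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mutant frequency from plaque counts
#'
#' Fraction of mutant (light blue plus colourless) plaques among all
#' plaques scored in the lacZ assay.
#'
#' @param n_mutant_plaques,n_total_plaques Non-negative integers with
#'   `0 <= n_mutant <= n_total` and `n_total > 0`.
#' @return The mutant frequency as a plain fraction.
#' @examples
#' mutant_frequency(26, 10000)  # 0.0026
#' @export
mutant_frequency <- function(n_mutant_plaques, n_total_plaques) {
  if (!is.numeric(n_mutant_plaques) || !is.numeric(n_total_plaques) ||
      length(n_mutant_plaques) != 1L || length(n_total_plaques) != 1L)
    stop_mutlab("plaque counts must be single numbers")
  if (n_total_plaques <= 0)
    stop_mutlab("'n_total_plaques' must be positive")
  if (n_mutant_plaques < 0 || n_mutant_plaques > n_total_plaques)
    stop_mutlab("'n_mutant_plaques' must lie in [0, n_total_plaques]")
  n_mutant_plaques / n_total_plaques
}

#' Per-class error rate of a polymerase
#'
#' The per-detectable-site, per-synthesis error rate for one mutation
#' class: `ER = ((Ni / N) * MF) / (D * expression_prob)`, where `Ni` is the
#' number of mutations of that type among the `N` sequenced mutants, `MF`
#' the lacZ mutant frequency, `D` the number of sites where the class is
#' phenotypically detectable, and `expression_prob` (0.6 by default) the
#' probability of expressing a mutant lacZ allele.
#'
#' @param assay A [lacz_assay].
#' @param class_name Name of one class in `assay$classes`.
#' @return The error rate (errors per detectable nucleotide synthesised).
#' @examples
#' a <- lacz_assay("holoenzyme", 285, 0.026,
#'                 data.frame(class = "substitutions", Ni = 214, D = 150))
#' error_rate(a, "substitutions")
#' @export
error_rate <- function(assay, class_name) {
  if (!inherits(assay, "lacz_assay"))
    stop_mutlab("'assay' must be a lacz_assay")
  i <- match(class_name, assay$classes$class)
  if (is.na(i))
    stop_mutlab("unknown class: ", class_name)
  ni <- assay$classes$Ni[i]
  d <- assay$classes$D[i]
  ((ni / assay$n_mutants_sequenced) * assay$mutant_frequency) /
    (d * assay$expression_prob)
}

#' All per-class error rates of an assay
#'
#' @param assay A [lacz_assay].
#' @return Named numeric vector of error rates, one per class.
#' @export
error_rates <- function(assay) {
  if (!inherits(assay, "lacz_assay"))
    stop_mutlab("'assay' must be a lacz_assay")
  stats::setNames(
    vapply(assay$classes$class, function(cl) error_rate(assay, cl), 0),
    assay$classes$class)
}

#' Background-adjusted mutant frequency
#'
#' Subtracts the background lacZ mutant frequency of uncopied DNA from an
#' observed mutant frequency, truncating at zero. When the observed
#' frequency does not exceed the background the result carries the
#' attribute `near_background = TRUE`, flagging that the polymerase's own
#' error contribution is not resolvable above background.
#'
#' @param MF Observed mutant frequency (>= 0).
#' @param MF_background Background mutant frequency (>= 0).
#' @return `max(MF - MF_background, 0)` with attribute `near_background`.
#' @examples
#' background_adjusted_frequency(0.029, 0.001)
#' background_adjusted_frequency(0.0018, 0.0018)  # flagged
#' @export
background_adjusted_frequency <- function(MF, MF_background) {
  if (!is.numeric(MF) || !is.numeric(MF_background) ||
      length(MF) != 1L || length(MF_background) != 1L ||
      MF < 0 || MF_background < 0)
    stop_mutlab("frequencies must be single non-negative numbers")
  out <- max(MF - MF_background, 0)
  attr(out, "near_background") <- MF <= MF_background
  out
}
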