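#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Generates per-culture mutant counts with the statistical structure of a
#' fluctuation assay: the number of mutation events per culture is
#' Poisson with mean `m = mu * (nt - n0)`, and each event founds a clone
#' whose size follows the classic `floor(1/u)` law (`u ~ Uniform(0,1)`),
#' the deterministic-growth approximation whose heavy tail produces
#' jackpot cultures. Clone sizes and per-culture totals are capped at
#' `nt`. Bit-reproducible given `seed`.
#'
#' @param mu Per-cell, per-generation mutation rate (must satisfy
#'   `mu <= 0.1`; larger values are biologically absurd for this design).
#' @param nt Final cells per culture (`Nt`).
#' @param n_cultures Number of parallel cultures.
#' @param n0 Initial inoculum size (default 1).
#' @param seed Integer seed.
#' @param strain,locus Labels passed to [culture_set()].
#' @param plating_fraction Passed to [culture_set()].
#' @return A [culture_set()].
#' @examples
#' cs <- simulate_cultures(mu = 1e-7, nt = 1e8, n_cultures = 45, seed = 1)
#' estimate_rate(cs)
#' @export
simulate_cultures <- function(mu, nt, n_cultures, n0 = 1, seed,
                              strain = "sim", locus = "sim",
                              plating_fraction = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop_mutlab("'mu' must be a single non-negative number")
  if (mu > 0.1)
    stop_mutlab("'mu' = ", mu, " is absurdly large for a fluctuation assay")
  if (!is.numeric(nt) || nt <= 0 || !is.numeric(n0) || n0 < 1 || nt <= n0)
    stop_mutlab("need nt > n0 >= 1")
  if (!is.numeric(n_cultures) || n_cultures < 1)
    stop_mutlab("'n_cultures' must be >= 1")
  n_cultures <- as.integer(n_cultures)
  m <- mu * (nt - n0)
  counts <- with_seed(seed, {
    k <- stats::rpois(n_cultures, m)
    total <- sum(k)
    out <- numeric(n_cultures)
    if (total > 0) {
      clone <- pmin(floor(1 / stats::runif(total)), nt)
      idx <- rep.int(seq_len(n_cultures), k)
      agg <- rowsum(clone, idx)
      out[as.integer(rownames(agg))] <- agg[, 1L]
    }
    pmin(out, nt)
  })
  culture_set(counts, n_final_cells = nt, strain = strain, locus = locus,
              plating_fraction = plating_fraction)
}

#' Simulate a mutation spectrum
#'
#' One multinomial draw of `n` mutations across the given class
#' probabilities.
#'
#' @param probs Probability vector (non-negative, summing to 1).
#' @param n Total number of mutations (>= 0).
#' @param seed Integer seed.
#' @param categories Class names; defaults to `names(probs)` or
#'   `cat1, cat2, ...`.
#' @param label Label for the resulting spectrum.
#' @return A [mutation_spectrum()] whose counts sum to `n`.
#' @examples
#' simulate_spectrum(c(A = 0.5, B = 0.3, C = 0.2), n = 48, seed = 7)
#' @export
simulate_spectrum <- function(probs, n, seed, categories = names(probs),
                              label = "simulated") {
  if (!is.numeric(probs) || length(probs) < 1L || any(!is.finite(probs)) ||
      any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop_mutlab("'probs' must be non-negative and sum to 1")
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop_mutlab("'n' must be a non-negative integer")
  if (is.null(categories))
    categories <- paste0("cat", seq_along(probs))
  counts <- with_seed(seed, as.numeric(stats::rmultinom(1L, as.integer(n),
                                                        probs)))
  mutation_spectrum(counts, categories = categories, label = label)
}

#' Simulate a gel lane from a true termination profile
#'
#' Produces the band intensities an ideal single-hit experiment would
#' yield for a known per-position termination-probability vector: the
#' molecules are apportioned deterministically, so the count stopping at
#' position `N` is `n_molecules * T(N) * prod(1 - T(earlier))`, with
#' "earlier" following the direction of synthesis (ascending positions)
#' or excision (descending). Molecules that survive every position
#' accumulate in the runoff band. Measurement noise is multiplicative
#' Gaussian on each band (`intensity = count * (1 + N(0, noise_cv))`,
#' floored at 0), emulating phosphoimager quantification error. With
#' `noise_cv = 0`, [termination_profile()] recovers the truth exactly.
#'
#' @param termination_truth Named numeric vector, position -> probability
#'   in `[0, 1]`.
#' @param n_molecules Number of molecules in the lane (scales intensity).
#' @param noise_cv Coefficient of variation of the band noise (>= 0).
#' @param direction `"synthesis"` or `"excision"`.
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @param runoff_position Position for the completion band; defaults to
#'   one past the final position in the walk direction.
#' @param lane_id Label for the lane.
#' @return A [lane_profile()] with `runoff_position` set.
#' @examples
#' tr <- stats::setNames(rep(0.2, 10), 51:60)
#' ln <- simulate_lane(tr, n_molecules = 1e4, noise_cv = 0,
#'                     direction = "synthesis", seed = 1)
#' termination_profile(ln)
#' @export
simulate_lane <- function(termination_truth, n_molecules, noise_cv = 0,
                          direction = c("synthesis", "excision"), seed,
                          runoff_position = NULL, lane_id = "sim") {
  direction <- match.arg(direction)
  tt <- termination_truth
  if (is.null(names(tt)))
    stop_mutlab("'termination_truth' must be named by position")
  pos <- as.integer(names(tt))
  if (any(is.na(pos)) || any(pos < 1))
    stop_mutlab("positions must be positive integers")
  if (!is.numeric(tt) || any(tt < 0) || any(tt > 1))
    stop_mutlab("termination probabilities must lie in [0, 1]")
  if (!is.numeric(n_molecules) || n_molecules <= 0)
    stop_mutlab("'n_molecules' must be positive")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop_mutlab("'noise_cv' must be non-negative")

  ord <- if (direction == "synthesis") order(pos) else order(pos,
                                                             decreasing = TRUE)
  pos_w <- pos[ord]
  t_w <- as.numeric(tt)[ord]
  surv <- cumprod(1 - t_w)
  reach <- c(1, surv[-length(surv)])        # fraction reaching each position
  counts <- n_molecules * reach * t_w
  runoff_count <- n_molecules * surv[length(surv)]
  if (is.null(runoff_position))
    runoff_position <- if (direction == "synthesis") max(pos) + 1L
                       else max(min(pos) - 1L, 1L)
  runoff_position <- as.integer(runoff_position)
  if (runoff_position %in% pos_w)
    stop_mutlab("'runoff_position' collides with a profile position")

  all_pos <- c(pos_w, runoff_position)
  all_counts <- c(counts, runoff_count)
  ints <- if (noise_cv > 0) {
    with_seed(seed, pmax(all_counts *
                           (1 + stats::rnorm(length(all_counts), 0, noise_cv)),
                         0))
  } else all_counts
  lane_profile(ints, direction = direction, positions = all_pos,
               runoff_position = runoff_position, lane_id = lane_id)
}

#' Simulate a lacZ fidelity-assay summary
#'
#' Draws the per-class mutation counts `Ni` of a lacZ forward-mutation
#' assay from the multinomial implied by known per-class error rates: the
#' probability that a sequenced mutant carries a class-`i` mutation is
#' `ER_i * D_i * expression_prob / MF`. Probabilities must sum to at most
#' 1; any remainder is drawn into an `"unclassified"` class that is not
#' reported in the assay classes (class counts need not sum to `N`).
#' Running [error_rate()] on the result recovers the input rates within
#' multinomial sampling error.
#'
#' @param classes Data frame with columns `class`, `error_rate`, `D`.
#' @param N Number of mutants sequenced.
#' @param MF Mutant frequency of the simulated reaction.
#' @param seed Integer seed.
#' @param enzyme Label for the assay.
#' @param expression_prob Probability of expressing a mutant allele
#'   (default 0.6).
#' @return A [lacz_assay()].
#' @examples
#' cls <- data.frame(class = c("sub", "fs"), error_rate = c(5e-5, 1e-5),
#'                   D = c(150, 90))
#' a <- simulate_lacz(cls, N = 1000, MF = 0.02, seed = 3)
#' error_rates(a)
#' @export
simulate_lacz <- function(classes, N, MF, seed, enzyme = "sim",
                          expression_prob = 0.6) {
  if (!is.data.frame(classes) ||
      !all(c("class", "error_rate", "D") %in% names(classes)))
    stop_mutlab("'classes' needs columns class, error_rate, D")
  if (!is.numeric(N) || N < 1) stop_mutlab("'N' must be >= 1")
  if (!is.numeric(MF) || MF <= 0 || MF > 1)
    stop_mutlab("'MF' must lie in (0, 1]")
  w <- classes$error_rate * classes$D * expression_prob / MF
  if (any(w < 0)) stop_mutlab("error rates and D must be non-negative")
  if (sum(w) > 1 + 1e-9)
    stop_mutlab("class weights ER*D*", expression_prob, "/MF sum to ",
                signif(sum(w), 4), " > 1; inconsistent inputs")
  resid <- max(1 - sum(w), 0)
  ni <- with_seed(seed,
                  as.numeric(stats::rmultinom(1L, as.integer(N),
                                              c(w, resid))))
  lacz_assay(enzyme = enzyme, n_mutants_sequenced = N, mutant_frequency = MF,
             classes = data.frame(class = classes$class,
                                  Ni = ni[seq_len(nrow(classes))],
                                  D = classes$D),
             expression_prob = expression_prob)
}
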