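#' Gel-lane band-intensity profile
#'
#' Phosphoimager band intensities from one lane of a denaturing gel, keyed
#' by product length in nucleotides (1-based). For a primer-extension
#' (synthesis) lane, products grow towards the runoff (full-length) band;
#' for a 3'->5' exonuclease (excision) lane, products shrink towards the
#' fully degraded end. Unquantified positions are simply absent, not zero.
#'
#' @param intensities Named (or `positions`-keyed) non-negative numeric
#'   vector of band intensities.
#' @param direction `"synthesis"` or `"excision"`.
#' @param positions Integer product lengths; defaults to
#'   `as.integer(names(intensities))`.
#' @param runoff_position Optional position of the full-length (synthesis)
#'   or terminal-degradation band: completion rather than termination.
#' @param lane_id Optional label.
#' @return An object of class `lane_profile` (positions sorted ascending).
#' @examples
#' lane_profile(c(`10` = 50, `20` = 50), direction = "synthesis")
#' @export
lane_profile <- function(intensities, direction = c("synthesis", "excision"),
                         positions = NULL, runoff_position = NULL,
                         lane_id = "") {
  direction <- match.arg(direction)
  if (is.null(positions)) {
    if (is.null(names(intensities)))
      stop_mutlab("supply 'positions' or a named 'intensities' vector")
    positions <- suppressWarnings(as.integer(names(intensities)))
  }
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1))
    stop_mutlab("positions must be positive integers (product length in nt)")
  if (anyDuplicated(positions)) stop_mutlab("positions must be distinct")
  if (length(positions) != length(intensities))
    stop_mutlab("'positions' and 'intensities' differ in length")
  if (length(positions) < 2L)
    stop_mutlab("a lane needs at least 2 distinct positions")
  if (!is.numeric(intensities) || any(!is.finite(intensities)) ||
      any(intensities < 0))
    stop_mutlab("intensities must be finite and non-negative")
  if (sum(intensities) <= 0)
    stop_mutlab("total lane intensity must be positive")
  if (!is.null(runoff_position)) {
    runoff_position <- as.integer(runoff_position)
    if (!(runoff_position %in% positions))
      stop_mutlab("'runoff_position' must be one of the lane positions")
  }
  ord <- order(positions)
  structure(
    list(lane_id = as.character(lane_id), direction = direction,
         positions = positions[ord],
         intensities = as.numeric(intensities)[ord],
         runoff_position = runoff_position),
    class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("Gel lane", if (nzchar(x$lane_id)) paste0(" '", x$lane_id, "'"),
      " (", x$direction, "): ", length(x$positions), " bands, positions ",
      min(x$positions), "-", max(x$positions), sep = "")
  if (!is.null(x$runoff_position))
    cat(", runoff at ", x$runoff_position, sep = "")
  cat("\n")
  invisible(x)
}

#' Per-position termination probabilities from a gel lane
#'
#' Converts band intensities measured under single-hit conditions into the
#' probability that the enzyme dissociates at each template position. For
#' a synthesis lane, `T(N) = I_N / sum(I_n, n >= N)`: of the molecules
#' that reached length `N`, the fraction that stopped there. For an
#' excision lane the sum runs over `n <= N`, mirroring the direction of
#' processive degradation. When `runoff_position` is set, that band counts
#' in the denominators (those molecules did reach every position) but is
#' excluded from the reported profile, since running off the template is
#' completion, not termination.
#'
#' Positions with a zero denominator are omitted with a message.
#'
#' @param lane A [lane_profile].
#' @return An object of class `termination_profile` with components
#'   `direction`, `positions`, and `probabilities` (each in `[0, 1]`).
#' @examples
#' ln <- lane_profile(c(`10` = 50, `20` = 50), "synthesis")
#' termination_profile(ln)  # T(10) = 0.5, T(20) = 1
#' @export
termination_profile <- function(lane) {
  if (!inherits(lane, "lane_profile"))
    stop_mutlab("'lane' must be a lane_profile")
  pos <- lane$positions
  ints <- lane$intensities
  denom <- if (lane$direction == "synthesis") {
    rev(cumsum(rev(ints)))   # sum over n >= N
  } else {
    cumsum(ints)             # sum over n <= N
  }
  keep <- denom > 0
  if (any(!keep))
    message("omitting ", sum(!keep), " position(s) with zero denominator")
  tp <- ints[keep] / denom[keep]
  pos <- pos[keep]
  if (!is.null(lane$runoff_position)) {
    rep_keep <- pos != lane$runoff_position
    tp <- tp[rep_keep]
    pos <- pos[rep_keep]
  }
  structure(
    list(lane_id = lane$lane_id, direction = lane$direction,
         positions = pos, probabilities = tp),
    class = "termination_profile")
}

#' @export
print.termination_profile <- function(x, digits = 3, ...) {
  cat("Termination-probability profile (", x$direction, "), ",
      length(x$positions), " positions\n", sep = "")
  print(stats::setNames(signif(x$probabilities, digits), x$positions))
  invisible(x)
}

#' @export
plot.termination_profile <- function(x, ...) {
  graphics::plot(x$positions, x$probabilities, type = "h", lwd = 3,
                 xlab = "Product length (nt)",
                 ylab = "Termination probability", ylim = c(0, 1), ...)
  invisible(x)
}

#' Position-by-position termination-probability ratio of two enzymes
#'
#' Ratios `a(N) / b(N)` at every template position quantified for both
#' profiles (and with `b(N) > 0`) — e.g. a two-subunit complex versus the
#' four-subunit holoenzyme on the same template.
#'
#' @param a,b [termination_profile] objects with the same direction.
#' @return Named numeric vector of per-position ratios.
#' @seealso [mean_fold_change()] for the one-number summary.
#' @export
fold_change <- function(a, b) {
  if (!inherits(a, "termination_profile") ||
      !inherits(b, "termination_profile"))
    stop_mutlab("both arguments must be termination_profile objects")
  if (a$direction != b$direction)
    stop_mutlab("profiles have different directions")
  shared <- intersect(a$positions, b$positions)
  ib <- match(shared, b$positions)
  ok <- b$probabilities[ib] > 0
  shared <- shared[ok]
  if (length(shared) == 0L)
    stop_mutlab("no shared positions with positive reference probability")
  ia <- match(shared, a$positions)
  ib <- match(shared, b$positions)
  stats::setNames(a$probabilities[ia] / b$probabilities[ib], shared)
}

#' Average fold change of termination probability
#'
#' One-number summary of a per-position ratio map. The geometric mean is
#' the default (ratios are multiplicative); the arithmetic mean is
#' attached as an attribute for transparency.
#'
#' @param ratios Positive numeric vector, e.g. from [fold_change()].
#' @return The geometric mean, with attribute `arithmetic`.
#' @examples
#' mean_fold_change(c(2, 8))  # 4, arithmetic 5
#' @export
mean_fold_change <- function(ratios) {
  if (!is.numeric(ratios) || length(ratios) < 1L || any(!is.finite(ratios)) ||
      any(ratios <= 0))
    stop_mutlab("'ratios' must be a non-empty vector of positive numbers")
  out <- geometric_mean(ratios)
  attr(out, "arithmetic") <- mean(ratios)
  out
}
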