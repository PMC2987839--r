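# TSV dialects shared by the functions and the command-line script.
# All files are tab-separated UTF-8 with a header row and plain decimal
# numerics; confidence limits are always two columns, never a dash-joined
# token.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop_mutlab("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_mutlab(path, ": missing column(s) ",
                paste(missing_cols, collapse = ", "))
  df
}

# data row i lives on file line i + 1 (header is line 1)
row_err <- function(path, i, col, msg) {
  stop_mutlab(path, " line ", i + 1L, ", column '", col, "': ", msg)
}

#' Read fluctuation-assay cultures from TSV
#'
#' Reads a `cultures.tsv` with columns `strain`, `locus`, `culture_id`,
#' `mutant_count`, `n_final_cells` (optionally `plating_fraction`) and
#' returns one [culture_set()] per strain/locus combination.
#'
#' @param path Path to the TSV file.
#' @return Named list of [culture_set()] objects (`"strain/locus"` keys).
#' @export
read_cultures <- function(path) {
  df <- read_tsv_checked(path, c("strain", "locus", "culture_id",
                                 "mutant_count", "n_final_cells"))
  for (i in seq_len(nrow(df))) {
    v <- df$mutant_count[i]
    if (!is.numeric(v) || is.na(v) || v < 0 || abs(v - round(v)) > 1e-8)
      row_err(path, i, "mutant_count", "must be a non-negative integer")
    if (!is.numeric(df$n_final_cells[i]) || is.na(df$n_final_cells[i]) ||
        df$n_final_cells[i] <= 0)
      row_err(path, i, "n_final_cells", "must be a positive number")
  }
  key <- paste(df$strain, df$locus, sep = "/")
  out <- lapply(split(df, key), function(g) {
    pf <- if ("plating_fraction" %in% names(g)) g$plating_fraction[1L] else 1
    culture_set(g$mutant_count, n_final_cells = g$n_final_cells[1L],
                strain = g$strain[1L], locus = g$locus[1L],
                plating_fraction = pf)
  })
  out[unique(key)]
}

#' Write fluctuation-assay cultures to TSV
#'
#' Inverse of [read_cultures()]: `read_cultures(write_cultures(x, f))`
#' reproduces `x`.
#'
#' @param sets A [culture_set()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cultures <- function(sets, path) {
  if (inherits(sets, "culture_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(cs) {
    data.frame(strain = cs$strain, locus = cs$locus,
               culture_id = seq_along(cs$mutant_counts),
               mutant_count = cs$mutant_counts,
               n_final_cells = cs$n_final_cells,
               plating_fraction = cs$plating_fraction)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mutation spectra from a wide TSV
#'
#' Reads a spectrum table shaped like a printed spectrum table: a
#' `category` column followed by one count column per strain.
#'
#' @param path Path to the TSV file.
#' @return Named list of [mutation_spectrum()] objects, one per strain
#'   column.
#' @export
read_spectra <- function(path) {
  df <- read_tsv_checked(path, "category")
  strains <- setdiff(names(df), "category")
  if (length(strains) == 0L)
    stop_mutlab(path, ": no strain columns after 'category'")
  for (s in strains) for (i in seq_len(nrow(df))) {
    v <- df[[s]][i]
    if (!is.numeric(v) || is.na(v) || v < 0 || abs(v - round(v)) > 1e-8)
      row_err(path, i, s, "must be a non-negative integer count")
  }
  stats::setNames(lapply(strains, function(s)
    mutation_spectrum(df[[s]], categories = df$category, label = s)),
    strains)
}

#' Write mutation spectra to a wide TSV
#'
#' @param spectra List of [mutation_spectrum()] objects over identical
#'   category lists; list names (or spectrum labels) become columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "mutation_spectrum")) spectra <- list(spectra)
  cats <- spectra[[1L]]$categories
  for (s in spectra)
    if (!identical(s$categories, cats))
      stop_mutlab("all spectra must share one category list")
  nm <- names(spectra)
  if (is.null(nm)) nm <- vapply(spectra, function(s) s$label, "")
  df <- data.frame(category = cats, check.names = FALSE)
  for (i in seq_along(spectra)) df[[nm[i]]] <- spectra[[i]]$counts
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gel-lane profiles from TSV
#'
#' Reads a long-format lane table with columns `lane_id`, `direction`,
#' `position`, `intensity`, `is_runoff` (0/1) and returns one
#' [lane_profile()] per lane.
#'
#' @param path Path to the TSV file.
#' @return Named list of [lane_profile()] objects.
#' @export
read_lanes <- function(path) {
  df <- read_tsv_checked(path, c("lane_id", "direction", "position",
                                 "intensity", "is_runoff"))
  for (i in seq_len(nrow(df))) {
    if (!is.numeric(df$intensity[i]) || is.na(df$intensity[i]) ||
        df$intensity[i] < 0)
      row_err(path, i, "intensity", "must be non-negative")
    if (!df$direction[i] %in% c("synthesis", "excision"))
      row_err(path, i, "direction", "must be 'synthesis' or 'excision'")
  }
  key <- as.character(df$lane_id)
  out <- lapply(split(df, key), function(g) {
    ro <- g$position[g$is_runoff %in% c(1, TRUE)]
    lane_profile(g$intensity, direction = g$direction[1L],
                 positions = g$position,
                 runoff_position = if (length(ro)) ro[1L] else NULL,
                 lane_id = g$lane_id[1L])
  })
  out[unique(key)]
}

#' Write gel-lane profiles to TSV
#'
#' @param lanes A [lane_profile()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lanes <- function(lanes, path) {
  if (inherits(lanes, "lane_profile")) lanes <- list(lanes)
  rows <- do.call(rbind, lapply(lanes, function(ln) {
    data.frame(lane_id = ln$lane_id, direction = ln$direction,
               position = ln$positions, intensity = ln$intensities,
               is_runoff = as.integer(!is.null(ln$runoff_position) &
                                        ln$positions == ln$runoff_position))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read lacZ assay summaries from TSV
#'
#' Reads an assay table with columns `enzyme`, `N`, `MF`, `class`, `Ni`,
#' `D` (optionally `background`, `expression_prob`); rows with the same
#' `enzyme` form one assay.
#'
#' @param path Path to the TSV file.
#' @return Named list of [lacz_assay()] objects.
#' @export
read_lacz <- function(path) {
  df <- read_tsv_checked(path, c("enzyme", "N", "MF", "class", "Ni", "D"))
  for (i in seq_len(nrow(df))) {
    if (!is.numeric(df$Ni[i]) || is.na(df$Ni[i]) || df$Ni[i] < 0)
      row_err(path, i, "Ni", "must be a non-negative integer")
    if (!is.numeric(df$D[i]) || is.na(df$D[i]) || df$D[i] < 1)
      row_err(path, i, "D", "must be >= 1")
  }
  key <- as.character(df$enzyme)
  out <- lapply(split(df, key), function(g) {
    lacz_assay(enzyme = g$enzyme[1L], n_mutants_sequenced = g$N[1L],
               mutant_frequency = g$MF[1L],
               classes = data.frame(class = g$class, Ni = g$Ni, D = g$D),
               background_frequency =
                 if ("background" %in% names(g)) g$background[1L] else NULL,
               expression_prob =
                 if ("expression_prob" %in% names(g)) g$expression_prob[1L]
                 else 0.6)
  })
  out[unique(key)]
}

#' Mutation-rate report table
#'
#' Assembles the familiar rates-table layout from a list of
#' [rate_estimate] objects: absolute rate, 95% confidence limits,
#' relative rate versus a reference estimate, and the CI-overlap
#' significance call ("different" when the limits do not overlap).
#'
#' @param estimates List of [rate_estimate] objects.
#' @param reference A [rate_estimate] to compare against (e.g. the
#'   wild-type strain), or `NULL` to omit the comparison columns.
#' @return A data frame with one row per estimate.
#' @export
rate_table <- function(estimates, reference = NULL) {
  if (inherits(estimates, "rate_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(strain = e$strain, locus = e$locus, method = e$method,
               n_cultures = e$n_cultures, rate = e$rate,
               ci_low = e$ci_low, ci_high = e$ci_high)
  }))
  if (!is.null(reference)) {
    df$relative_rate <- vapply(estimates, relative_rate, 0,
                               reference = reference)
    df$significant_vs_reference <- vapply(estimates, function(e)
      !ci_overlap(e, reference), NA)
  }
  df
}

#' Write a mutation-rate report to TSV
#'
#' @param estimates List of [rate_estimate] objects (see [rate_table()]).
#' @param path Output path.
#' @param reference Optional reference [rate_estimate].
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(estimates, path, reference = NULL) {
  utils::write.table(rate_table(estimates, reference), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a termination-probability report to TSV
#'
#' @param profiles A [termination_profile] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_termination <- function(profiles, path) {
  if (inherits(profiles, "termination_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(tp) {
    data.frame(lane_id = tp$lane_id, direction = tp$direction,
               position = tp$positions,
               termination_probability = tp$probabilities)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
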