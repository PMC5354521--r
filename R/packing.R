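# Complex counts from subunit copy numbers, membrane occupancy fractions,
# and required per-complex ATP turnover rates.

#' Estimate assembled complexes per cell from subunit copy numbers
#'
#' Each subunit of a multiprotein complex gives an independent estimate of
#' the number of assembled complexes: its per-cell copy number divided by
#' its stoichiometry in the complex, assuming all copies are assembled. All
#' per-subunit estimates are reported together with their arithmetic mean
#' and range; the minimum is the conservative assembled-limit (assembly can
#' use no more complexes than the scarcest subunit allows).
#'
#' The reference census for *E. coli* ATP synthase gives 3018 complexes
#' (`reference_constants$ecoli_synthase_complexes`).
#'
#' @param copies_per_cell Numeric vector of per-cell protein copy numbers,
#'   `>= 0`.
#' @param stoichiometry Integer vector of copies of each subunit per
#'   complex, `>= 1` (recycled if scalar).
#' @param subunits Optional subunit names.
#' @return A list with `estimates` (named per-subunit vector), `mean`,
#'   `min`, `max`.
#' @examples
#' complexes_per_cell(c(a = 300, b = 150), c(3, 1))
#' @export
complexes_per_cell <- function(copies_per_cell, stoichiometry = 1,
                               subunits = names(copies_per_cell)) {
  check_non_negative(copies_per_cell, "copies_per_cell")
  if (any(stoichiometry < 1)) stop_invalid("`stoichiometry` must be >= 1")
  if (all(copies_per_cell == 0)) {
    stop_invalid("all subunit copy numbers are zero; cannot estimate complexes")
  }
  stoichiometry <- rep_len(stoichiometry, length(copies_per_cell))
  est <- copies_per_cell / stoichiometry
  if (!is.null(subunits)) names(est) <- subunits
  list(estimates = est, mean = mean(est), min = min(est), max = max(est))
}

#' Membrane area fraction occupied by a set of complexes
#'
#' `n` complexes of footprint `f` nm^2 in a membrane of `A` um^2 occupy the
#' fraction `n f / (A * 1e6)`. For the *E. coli* reference census (3018
#' synthases of 64 nm^2 in 15.8 um^2) this is ~1.2 percent; measured
#' bacterial ATP synthase occupancies average ~1.1 percent, and the
#' electron transport chain, with a ~5-fold larger physical footprint,
#' takes that to ~5.5 percent of bacterial membranes. A fraction above 1 is
#' geometrically impossible and triggers a warning rather than an error, as
#' it usually signals an inconsistent area or census.
#'
#' @param n_complexes Number of complexes, `>= 0`.
#' @param footprint_nm2 Membrane footprint per complex in nm^2, positive
#'   (see `reference_constants` for ATP synthase and ETC defaults).
#' @param membrane_area_um2 Membrane area in um^2, positive.
#' @return Dimensionless occupancy fraction.
#' @examples
#' occupancy_fraction(3018, 64, 15.8)
#' @export
occupancy_fraction <- function(n_complexes, footprint_nm2, membrane_area_um2) {
  check_non_negative(n_complexes, "n_complexes")
  check_positive(footprint_nm2, "footprint_nm2")
  check_positive(membrane_area_um2, "membrane_area_um2")
  frac <- n_complexes * footprint_nm2 / (membrane_area_um2 * 1e6)
  if (any(frac > 1)) {
    warning("computed occupancy exceeds 1: complexes cannot fit in the ",
            "stated membrane area", call. = FALSE)
  }
  frac
}

#' Required ATP production rate per complex
#'
#' Divides the ATP a cell must produce per cell cycle among its ATP
#' synthase complexes: `budget * share / (t * 3600 * n)` in ATP per second
#' per complex. The `atp_share` discount reflects that only a minority of
#' biosynthetic energy flows through ATP hydrolysis (the rest is spent as
#' NADH/NADPH oxidations); the default 0.15 discounts the budget by 85
#' percent (see [atp_hydrolysis_share()]). Comparing the result with
#' measured maximum turnover capacities
#' (`reference_constants$turnover_capacity`; e.g. ~195/s for bacterial
#' synthases in liposomes) checks whether a census and budget are mutually
#' consistent.
#'
#' @param total_budget_atp Energy budget per cell cycle in ATP, positive.
#' @param atp_share Fraction of the budget flowing through ATP hydrolysis,
#'   in (0, 1].
#' @param division_time_h Cell cycle duration in hours, positive.
#' @param n_complexes Number of ATP synthase complexes, positive.
#' @return ATP per second per complex.
#' @examples
#' required_turnover(27e9, 0.15, 1, 3018)
#' @export
required_turnover <- function(total_budget_atp, atp_share = 0.15,
                              division_time_h, n_complexes) {
  check_positive(total_budget_atp, "total_budget_atp")
  if (any(atp_share <= 0 | atp_share > 1)) {
    stop_invalid("`atp_share` must lie in (0, 1]")
  }
  check_positive(division_time_h, "division_time_h")
  check_positive(n_complexes, "n_complexes")
  total_budget_atp * atp_share / (division_time_h * 3600 * n_complexes)
}

#' Read a complex census table
#'
#' Tab-delimited columns `complex`, `subunit`, `copies_per_cell`,
#' `stoichiometry`; returns per-complex estimates via
#' [complexes_per_cell()].
#'
#' @param path Path to a TSV file.
#' @return A named list (by complex) of [complexes_per_cell()] results.
#' @export
read_complex_census <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("complex", "subunit", "copies_per_cell", "stoichiometry")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop_invalid("complex census lacks column(s): ",
                 paste(missing, collapse = ", "))
  }
  lapply(split(tab, tab$complex), function(d) {
    complexes_per_cell(stats::setNames(d$copies_per_cell, d$subunit),
                       d$stoichiometry)
  })
}
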