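# Cell and organelle geometry, inner:outer mitochondrial membrane
# conversion, and apportionment of the growth budget across membrane
# compartments.

#' Define a cell geometry
#'
#' Supported shapes: `"sphere"` (radius), `"spherocylinder"` (a cylinder
#' capped by hemispheres: radius and cylinder length, the usual idealisation
#' of rod-shaped bacteria), and `"ellipsoid"` (three semi-axes).
#'
#' @param shape `"sphere"`, `"spherocylinder"` or `"ellipsoid"`.
#' @param radius Radius in um (sphere, spherocylinder).
#' @param length Cylindrical section length in um (spherocylinder); 0
#'   degenerates to a sphere.
#' @param semi_axes Numeric length-3 vector of semi-axes in um (ellipsoid).
#' @return An object of class `cell_geometry`.
#' @examples
#' surface_area(cell_geometry("spherocylinder", radius = 0.5, length = 2))
#' @export
cell_geometry <- function(shape = c("sphere", "spherocylinder", "ellipsoid"),
                          radius = NULL, length = NULL, semi_axes = NULL) {
  shape <- match.arg(shape)
  g <- switch(shape,
    sphere = {
      check_positive(radius, "radius")
      list(radius = radius)
    },
    spherocylinder = {
      check_positive(radius, "radius")
      check_non_negative(length, "length")
      list(radius = radius, length = length)
    },
    ellipsoid = {
      if (length(semi_axes) != 3) stop_invalid("`semi_axes` must have length 3")
      check_positive(semi_axes, "semi_axes")
      list(semi_axes = semi_axes)
    }
  )
  structure(c(list(shape = shape), g), class = "cell_geometry")
}

# triaxial ellipsoid surface area by nested quadrature over the spherical
# parameterisation; exact closed forms need incomplete elliptic integrals
.ellipsoid_area <- function(a, b, c) {
  integrand_theta <- function(theta) {
    vapply(theta, function(th) {
      st <- sin(th); ct <- cos(th)
      f <- function(phi) {
        st * sqrt((b * c * st * cos(phi))^2 +
                  (a * c * st * sin(phi))^2 +
                  (a * b * ct)^2)
      }
      stats::integrate(f, 0, 2 * pi, rel.tol = 1e-12)$value
    }, numeric(1))
  }
  stats::integrate(integrand_theta, 0, pi, rel.tol = 1e-12)$value
}

#' Surface area of a cell geometry
#'
#' Closed forms for the sphere (`4 pi r^2`) and spherocylinder
#' (`2 pi r L + 4 pi r^2`); high-precision numerical quadrature for the
#' triaxial ellipsoid.
#'
#' @param geometry A [cell_geometry()].
#' @return Surface area in um^2.
#' @export
surface_area <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  switch(geometry$shape,
    sphere = 4 * pi * geometry$radius^2,
    spherocylinder = 2 * pi * geometry$radius * geometry$length +
      4 * pi * geometry$radius^2,
    ellipsoid = .ellipsoid_area(geometry$semi_axes[1], geometry$semi_axes[2],
                                geometry$semi_axes[3])
  )
}

#' Volume of a cell geometry
#'
#' @param geometry A [cell_geometry()].
#' @return Volume in um^3.
#' @export
cell_volume <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  switch(geometry$shape,
    sphere = 4 / 3 * pi * geometry$radius^3,
    spherocylinder = pi * geometry$radius^2 * geometry$length +
      4 / 3 * pi * geometry$radius^3,
    ellipsoid = 4 / 3 * pi * prod(geometry$semi_axes)
  )
}

#' Total mitochondrial membrane area from an outer-membrane measurement
#'
#' Inner mitochondrial membranes (cristae included) are several-fold larger
#' than the outer membrane. When only the outer area has been measured, the
#' total (inner + outer) area is extrapolated as
#' `outer_area * (1 + inner_to_outer_ratio)`. The default ratio 4.6 is the
#' published cross-species average; the four individually reported ratios
#' (mammal 5.0, *Ochromonas* 2.4, *Rhus* 2.5, *Tetrahymena* 5.2) average
#' 3.775, so sensitivity to the ratio is worth checking
#' (`reference_constants$inner_outer_ratios_measured`). When the inner area
#' is measured directly, pass the summed inner + outer area downstream and
#' skip this extrapolation.
#'
#' @param outer_area Outer membrane area in um^2, `>= 0`. Vectorised.
#' @param inner_to_outer_ratio Dimensionless ratio, `>= 1`.
#' @return Total membrane area in um^2.
#' @examples
#' total_mito_area(10)  # 56
#' @export
total_mito_area <- function(outer_area,
                            inner_to_outer_ratio = reference_constants$inner_outer_ratio) {
  check_non_negative(outer_area, "outer_area")
  if (any(inner_to_outer_ratio < 1)) {
    stop_invalid("`inner_to_outer_ratio` must be >= 1")
  }
  outer_area * (1 + inner_to_outer_ratio)
}

#' Apportion a cell's growth budget across membrane compartments
#'
#' Converts per-compartment membrane areas to ATP costs via
#' [membrane_lipid_cost()], divides their sum by the growth budget
#' [growth_cost()] of the cell, and normalises the per-compartment costs
#' into fractional shares. The compartment named `"plasma"` is treated as
#' the cell surface; everything else is internal membrane, so the report
#' includes the internal share (`1 -` plasma share) and the internal
#' fraction of the whole growth budget (total fraction times internal
#' share). Across measured eukaryotes roughly 10-30 percent of the growth
#' budget goes to membranes, with the internal share rising with cell size.
#'
#' When species-specific lipid costs are unknown the eukaryotic mean direct
#' cost (143 ATP per lipid) is used for every compartment and the result is
#' labelled a generic-cost approximation; published per-species fractions
#' (see [membrane_budget_reference]) were built from species-specific costs
#' and are not exactly recoverable this way.
#'
#' @param areas Named numeric vector of membrane areas in um^2 per
#'   compartment (e.g. `c(plasma = ..., mitochondria = ...)`), all `>= 0`.
#' @param volume Cell volume in um^3.
#' @param mean_lipid_cost Per-lipid cost in ATP: a single value applied to
#'   all compartments (default the eukaryotic mean direct cost, 143) or a
#'   named vector matching `areas`.
#' @param ... Passed to [membrane_lipid_cost()].
#' @return An object of class `membrane_budget`: list with `table` (data
#'   frame of compartment, area, cost_atp, share), `total_fraction`,
#'   `internal_share`, `internal_fraction_of_total`, `generic_costs`
#'   (logical).
#' @examples
#' membrane_budget_table(c(plasma = 8.3, mitochondria = 3.0), volume = 1)
#' @export
membrane_budget_table <- function(areas, volume,
                                  mean_lipid_cost = reference_constants$mean_direct_cost_eukaryote,
                                  ...) {
  check_non_negative(areas, "areas")
  check_positive(volume, "volume")
  if (is.null(names(areas)) || any(!nzchar(names(areas)))) {
    stop_invalid("`areas` must be a named vector of compartments")
  }
  generic <- length(mean_lipid_cost) == 1
  costs_per_lipid <- if (generic) {
    rep(mean_lipid_cost, length(areas))
  } else {
    if (is.null(names(mean_lipid_cost)) ||
        !all(names(areas) %in% names(mean_lipid_cost))) {
      stop_invalid("per-compartment `mean_lipid_cost` must be named to match `areas`")
    }
    mean_lipid_cost[names(areas)]
  }
  total_area <- sum(areas)
  if (total_area == 0) {
    warning("total membrane area is zero; returning a zero budget",
            call. = FALSE)
    cost_atp <- rep(0, length(areas))
    share <- rep(0, length(areas))
    total_fraction <- 0
    internal_share <- 0
  } else {
    cost_atp <- mapply(membrane_lipid_cost, areas, costs_per_lipid,
                       MoreArgs = list(...))
    share <- cost_atp / sum(cost_atp)
    total_fraction <- sum(cost_atp) / growth_cost(volume)
    plasma_share <- if ("plasma" %in% names(areas)) share[["plasma"]] else 0
    internal_share <- 1 - plasma_share
  }
  structure(
    list(table = data.frame(compartment = names(areas),
                            area_um2 = unname(areas),
                            mean_lipid_cost = unname(costs_per_lipid),
                            cost_atp = unname(cost_atp),
                            share = unname(share),
                            stringsAsFactors = FALSE),
         volume = volume,
         total_fraction = total_fraction,
         internal_share = internal_share,
         internal_fraction_of_total = total_fraction * internal_share,
         generic_costs = generic),
    class = "membrane_budget"
  )
}

#' @export
print.membrane_budget <- function(x, ...) {
  cat(sprintf("Membrane budget for a %g um^3 cell%s\n", x$volume,
              if (x$generic_costs) " (generic-cost approximation)" else ""))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("  membranes take %.1f%% of the growth budget;\n",
              100 * x$total_fraction))
  cat(sprintf("  internal membranes: %.0f%% of membrane cost, %.1f%% of the budget\n",
              100 * x$internal_share, 100 * x$internal_fraction_of_total))
  invisible(x)
}

#' Internal-membrane summary from published budget shares
#'
#' Given a published total membrane fraction of the growth budget and the
#' plasma-membrane share of membrane costs, returns the internal-membrane
#' share and the internal fraction of the whole budget. E.g. a mammalian
#' cell spending 30 percent of its budget on membranes with a plasma share
#' of 0.044 puts 96 percent of membrane costs (~29 percent of its whole
#' budget) into internal membranes; the tiny alga *Ostreococcus* (plasma
#' share 0.556) still puts 44 percent of membrane costs inside.
#'
#' @param membrane_fraction Fraction of the growth budget spent on
#'   membranes, in `[0, 1]`.
#' @param plasma_share Plasma-membrane share of membrane costs, in `[0, 1]`.
#' @return A list with `internal_share` and `internal_fraction_of_total`.
#' @examples
#' membrane_share_summary(0.302, 0.044)
#' @export
membrane_share_summary <- function(membrane_fraction, plasma_share) {
  if (any(membrane_fraction < 0 | membrane_fraction > 1) ||
      any(plasma_share < 0 | plasma_share > 1)) {
    stop_invalid("fractions must lie in [0, 1]")
  }
  internal <- 1 - plasma_share
  list(internal_share = internal,
       internal_fraction_of_total = membrane_fraction * internal)
}

#' Read a membrane inventory table
#'
#' Tab-delimited columns `species`, `compartment`, `area_um2` and optional
#' `mean_lipid_cost`. Returns one named area vector per species, suitable
#' for [membrane_budget_table()].
#'
#' @param path Path to a TSV file.
#' @return A named list (by species) of named area vectors, each carrying a
#'   `mean_lipid_cost` attribute when the column is present.
#' @export
read_membrane_inventory <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("species", "compartment", "area_um2")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop_invalid("membrane inventory lacks column(s): ",
                 paste(missing, collapse = ", "))
  }
  split_tab <- split(tab, tab$species)
  lapply(split_tab, function(d) {
    areas <- stats::setNames(d$area_um2, d$compartment)
    if ("mean_lipid_cost" %in% names(d) && !anyNA(d$mean_lipid_cost)) {
      attr(areas, "mean_lipid_cost") <- stats::setNames(d$mean_lipid_cost,
                                                        d$compartment)
    }
    areas
  })
}
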