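# ATP-denominated biosynthetic costs of lipid molecules and membrane
# compositions, plus the arithmetic splitting biosynthetic energy between
# direct ATP hydrolysis and redox-cofactor (NADH/NADPH) oxidation.

# linear cost coefficients: cost = base + chain_slope*(NL - 16) + 6*NU
.lipid_coef <- list(
  total = list(bacteria = c(base = 320, chain = 38, unsat = 6),
               eukaryote = c(base = 340, chain = 40, unsat = 6)),
  reduced = list(bacteria = c(base = 110, chain = 7, unsat = 6),
                 eukaryote = c(base = 120, chain = 9, unsat = 6))
)

.lipid_cost <- function(chain_length, unsaturations, domain, kind) {
  if (!is.numeric(chain_length) || length(chain_length) == 0 ||
      anyNA(chain_length) || any(chain_length <= 0)) {
    stop_invalid("`chain_length` must be a positive number of carbons")
  }
  check_non_negative(unsaturations, "unsaturations")
  domain <- match.arg(domain, c("bacteria", "eukaryote"))
  if (any(chain_length < 10)) {
    warning("chain lengths below 10 carbons are outside the lipid chemistry ",
            "the cost model was calibrated on; extrapolating", call. = FALSE)
  }
  k <- .lipid_coef[[kind]][[domain]]
  cost <- k[["base"]] + k[["chain"]] * (chain_length - 16) +
    k[["unsat"]] * unsaturations
  if (any(cost <= 0)) {
    stop_invalid("computed lipid cost is non-positive; chain length is ",
                 "outside the model's domain of validity")
  }
  unname(cost)
}

#' Total (evolutionary) biosynthetic cost of a glycerophospholipid
#'
#' The cost of one lipid molecule in ATP hydrolysis equivalents, counting
#' both the direct ATP consumed along the biosynthetic pathway and the
#' ATP-generating potential lost by diverting metabolic precursors (acetyl-CoA
#' and reducing equivalents) away from catabolism. The cost is linear in the
#' mean fatty-acid chain length `NL` and the mean number of unsaturated
#' carbons per chain `NU`:
#' \deqn{c_L = 320 + 38 (N_L - 16) + 6 N_U \quad \textrm{(bacteria)}}
#' \deqn{c_L = 340 + 40 (N_L - 16) + 6 N_U \quad \textrm{(eukaryotes)}}
#' Eukaryotic synthesis is dearer per carbon largely because acetyl-CoA must
#' be regenerated in the cytosol via mitochondrial export of oxaloacetate.
#' For membrane lipids generally (14 <= NL <= 22, 0 <= NU <= 6) costs fall
#' roughly between 200 and 600 ATP.
#'
#' @param chain_length Mean fatty-acid chain length in carbons (`NL`).
#'   Vectorised. Values below 10 trigger an extrapolation warning.
#' @param unsaturations Mean number of unsaturated carbons per chain (`NU`),
#'   `>= 0`. Vectorised.
#' @param domain `"bacteria"` or `"eukaryote"`.
#' @return Cost in ATP molecules per lipid molecule (full floating precision;
#'   round only when reporting).
#' @seealso [lipid_cost_reduced()] for the direct-cost variant,
#'   [species_cost()] for species with overrides (e.g. cardiolipin).
#' @examples
#' lipid_cost_total(16, 0, "bacteria")   # 320
#' lipid_cost_total(18, 1, "eukaryote")  # 340 + 80 + 6
#' @export
lipid_cost_total <- function(chain_length, unsaturations = 0,
                             domain = c("bacteria", "eukaryote")) {
  .lipid_cost(chain_length, unsaturations, domain, "total")
}

#' Reduced (direct) biosynthetic cost of a glycerophospholipid
#'
#' As [lipid_cost_total()], but counting only ATP directly hydrolysed in the
#' pathway and ignoring the opportunity cost of diverted precursors:
#' \deqn{c_L' = 110 + 7 (N_L - 16) + 6 N_U \quad \textrm{(bacteria)}}
#' \deqn{c_L' = 120 + 9 (N_L - 16) + 6 N_U \quad \textrm{(eukaryotes)}}
#' This is the relevant quantity when asking what fraction of a cell's ATP
#' turnover a membrane consumes, rather than its full evolutionary price.
#'
#' @inheritParams lipid_cost_total
#' @return Cost in ATP molecules per lipid molecule.
#' @examples
#' lipid_cost_reduced(16, 0, "eukaryote")  # 120
#' @export
lipid_cost_reduced <- function(chain_length, unsaturations = 0,
                               domain = c("bacteria", "eukaryote")) {
  .lipid_cost(chain_length, unsaturations, domain, "reduced")
}

#' Define a lipid species
#'
#' Bundles the parameters needed to cost a lipid: chain length, unsaturation,
#' the domain whose pathway coefficients apply, and optional per-molecule
#' cost overrides for lipids whose structure the two-chain glycerophospholipid
#' formulas cannot represent (see [cardiolipin()]).
#'
#' @param name Character label.
#' @param domain `"bacteria"` or `"eukaryote"`.
#' @param chain_length Mean fatty-acid chain length (carbons), `>= 1`.
#' @param unsaturations Mean unsaturated carbons per chain, `>= 0`.
#' @param total_cost_override,reduced_cost_override Optional explicit ATP
#'   costs taking precedence over the formulas; both must be positive and the
#'   reduced cost must not exceed the total cost.
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(name, domain = c("bacteria", "eukaryote"),
                          chain_length = 16, unsaturations = 0,
                          total_cost_override = NA_real_,
                          reduced_cost_override = NA_real_) {
  domain <- match.arg(domain)
  if (!is.numeric(chain_length) || length(chain_length) != 1 ||
      is.na(chain_length) || chain_length < 1) {
    stop_invalid("`chain_length` must be a single value >= 1")
  }
  if (!is.numeric(unsaturations) || length(unsaturations) != 1 ||
      is.na(unsaturations) || unsaturations < 0) {
    stop_invalid("`unsaturations` must be a single value >= 0")
  }
  for (ov in c(total_cost_override, reduced_cost_override)) {
    if (!is.na(ov) && ov <= 0) stop_invalid("cost overrides must be positive")
  }
  if (!is.na(total_cost_override) && !is.na(reduced_cost_override) &&
      reduced_cost_override > total_cost_override) {
    stop_invalid("reduced cost override cannot exceed the total cost override")
  }
  structure(
    list(name = as.character(name), domain = domain,
         chain_length = chain_length, unsaturations = unsaturations,
         total_cost_override = total_cost_override,
         reduced_cost_override = reduced_cost_override),
    class = "lipid_species"
  )
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("Lipid species:", x$name, sprintf("(%s)\n", x$domain))
  cat(sprintf("  NL = %g carbons, NU = %g unsaturated\n",
              x$chain_length, x$unsaturations))
  cat(sprintf("  total cost %.5g ATP, reduced cost %.5g ATP%s\n",
              species_cost(x, reduced = FALSE),
              species_cost(x, reduced = TRUE),
              if (!is.na(x$total_cost_override)) " (override)" else ""))
  invisible(x)
}

#' Cardiolipin as a predefined lipid species
#'
#' Cardiolipin carries four acyl chains on a double glycerophosphate
#' backbone, so the two-chain cost formulas do not apply; its published
#' per-molecule costs are shipped as overrides: ~640 ATP total and ~240 ATP
#' reduced. It is concentrated in mitochondrial (and bacterial) membranes
#' and rarely exceeds 20 percent of membrane lipids.
#'
#' @return A `lipid_species` with cost overrides 640 (total) and 240
#'   (reduced).
#' @export
cardiolipin <- function() {
  lipid_species("cardiolipin", domain = "eukaryote",
                chain_length = 18, unsaturations = 2,
                total_cost_override = 640, reduced_cost_override = 240)
}

#' Cost of one lipid species
#'
#' Returns the species' cost override when one is present, otherwise
#' evaluates the domain-appropriate cost formula.
#'
#' @param lipid A [lipid_species()].
#' @param reduced If `TRUE`, the direct (reduced) cost; otherwise the total
#'   (evolutionary) cost.
#' @return Cost in ATP molecules.
#' @examples
#' species_cost(cardiolipin())                  # 640
#' species_cost(cardiolipin(), reduced = TRUE)  # 240
#' @export
species_cost <- function(lipid, reduced = FALSE) {
  stopifnot(inherits(lipid, "lipid_species"))
  ov <- if (reduced) lipid$reduced_cost_override else lipid$total_cost_override
  if (!is.na(ov)) return(ov)
  f <- if (reduced) lipid_cost_reduced else lipid_cost_total
  f(lipid$chain_length, lipid$unsaturations, lipid$domain)
}

#' Define a membrane composition
#'
#' A membrane as a mixture of lipid species with mole fractions. Fractions
#' must be non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param species A list of [lipid_species()] objects.
#' @param fractions Numeric mole fractions, one per species.
#' @return An object of class `membrane_composition`.
#' @export
membrane_composition <- function(species, fractions) {
  if (length(species) == 0) stop_invalid("composition must contain at least one species")
  if (!all(vapply(species, inherits, logical(1), "lipid_species"))) {
    stop_invalid("`species` must be a list of lipid_species objects")
  }
  check_non_negative(fractions, "fractions")
  if (length(fractions) != length(species)) {
    stop_invalid("`fractions` must match `species` in length")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("mole fractions must sum to 1 (tolerance 1e-9); got ",
                 format(sum(fractions), digits = 12))
  }
  structure(list(species = species, fractions = as.numeric(fractions)),
            class = "membrane_composition")
}

#' Average lipid cost of a membrane composition
#'
#' Mole-fraction-weighted mean per-molecule cost, the quantity that feeds
#' [membrane_lipid_cost()] as the mean lipid cost of a bilayer. For the
#' average mitochondrial membrane use the published constant
#' `reference_constants$mito_mean_lipid_cost` (440 ATP) rather than
#' recomputing from a composition.
#'
#' @param composition A [membrane_composition()].
#' @param reduced Use reduced (direct) costs instead of total costs.
#' @return Mean cost in ATP per lipid molecule.
#' @export
mean_membrane_cost <- function(composition, reduced = FALSE) {
  if (!inherits(composition, "membrane_composition")) {
    stop_invalid("`composition` must be a membrane_composition")
  }
  costs <- vapply(composition$species, species_cost, numeric(1),
                  reduced = reduced)
  sum(costs * composition$fractions)
}

#' Read a lipid composition table
#'
#' Reads a tab-delimited table with columns `name`, `domain`, `chain_length`,
#' `unsaturations`, `fraction`, and optional `total_cost_override`,
#' `reduced_cost_override` (blank = no override) into a
#' [membrane_composition()].
#'
#' @param path Path to a TSV file.
#' @return A `membrane_composition`.
#' @export
read_lipid_composition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "domain", "chain_length", "unsaturations", "fraction")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop_invalid("lipid composition table lacks column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (!"total_cost_override" %in% names(tab)) tab$total_cost_override <- NA_real_
  if (!"reduced_cost_override" %in% names(tab)) tab$reduced_cost_override <- NA_real_
  sp <- lapply(seq_len(nrow(tab)), function(i) {
    lipid_species(tab$name[i], tab$domain[i], tab$chain_length[i],
                  tab$unsaturations[i],
                  as.numeric(tab$total_cost_override[i]),
                  as.numeric(tab$reduced_cost_override[i]))
  })
  membrane_composition(sp, tab$fraction)
}

#' Fraction of biosynthetic energy contributed by direct ATP hydrolysis
#'
#' Biosynthesis spends energy both as ATP hydrolyses and as oxidations of
#' the redox cofactors NADH/NADPH. With `r` cofactor oxidations per ATP
#' hydrolysis and each oxidation worth `k` ATP equivalents, the share of the
#' energy bill paid directly in ATP is
#' \deqn{\frac{1}{1 + r k}.}
#' Amino-acid biosynthesis runs at about r = 1.5 (giving ~18 percent), lipid
#' biosynthesis nearer r = 2.0 (~14 percent); overall only about 15 percent
#' of biosynthetic energy flows through ATP hydrolysis, which is why
#' ATP-synthase turnover requirements are discounted by 85 percent in
#' [required_turnover()].
#'
#' @param redox_per_atp Cofactor oxidations per ATP hydrolysis (`r >= 0`).
#' @param atp_equiv_per_redox ATP equivalents per oxidation (`k > 0`,
#'   default 3).
#' @return A fraction in (0, 1].
#' @examples
#' atp_hydrolysis_share(1.5)  # ~0.18
#' atp_hydrolysis_share(2.0)  # ~0.14
#' @export
atp_hydrolysis_share <- function(redox_per_atp,
                                 atp_equiv_per_redox = reference_constants$atp_equiv_per_redox) {
  check_non_negative(redox_per_atp, "redox_per_atp")
  check_positive(atp_equiv_per_redox, "atp_equiv_per_redox")
  1 / (1 + redox_per_atp * atp_equiv_per_redox)
}

#' Monomer biosynthesis cost constants
#'
#' Per-molecule evolutionary costs of the monomeric building blocks used for
#' perspective alongside lipid costs: ~30 ATP per amino acid and ~50 ATP per
#' nucleotide, with redox cofactor oxidations convertible at ~3 ATP each.
#'
#' @param amino_acid_cost,nucleotide_cost,atp_equiv_per_redox Positive
#'   overrides of the defaults.
#' @return A named list of the three constants.
#' @export
monomer_cost_table <- function(amino_acid_cost = reference_constants$amino_acid_cost,
                               nucleotide_cost = reference_constants$nucleotide_cost,
                               atp_equiv_per_redox = reference_constants$atp_equiv_per_redox) {
  check_positive(amino_acid_cost, "amino_acid_cost")
  check_positive(nucleotide_cost, "nucleotide_cost")
  check_positive(atp_equiv_per_redox, "atp_equiv_per_redox")
  list(amino_acid_cost = amino_acid_cost,
       nucleotide_cost = nucleotide_cost,
       atp_equiv_per_redox = atp_equiv_per_redox)
}
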