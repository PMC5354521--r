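# Tabular I/O, flat-file configuration, and the end-to-end pipeline that
# ties simulation, fitting, budgets and packing into one reproducible
# report bundle.

.species_columns <- c("species", "group", "cell_volume_um3", "division_time_h",
                      "plasma_area_um2", "mito_outer_um2", "mito_inner_um2",
                      "ribosomes_per_cell", "atp_synthase_per_cell")

#' Read a cross-species trait table
#'
#' Tab-delimited, UTF-8, '.' decimal. Mandatory columns: `species`,
#' `cell_volume_um3`; the remaining trait columns are optional and missing
#' values are allowed (they are flagged in the `missing_cells` attribute).
#' Unparseable numeric cells and negative trait values are rejected with
#' row-numbered messages; duplicate species labels are an error.
#'
#' @param path Path to a TSV file with a header.
#' @return A data frame of traits with attribute `missing_cells` (a data
#'   frame of row/column positions that were empty).
#' @seealso [write_species_table()], [generate_species_table()]
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop_invalid("cannot parse ", path, ": ",
                                     conditionMessage(e))
  )
  if (nrow(tab) == 0 && ncol(tab) <= 1) {
    stop_invalid("species table is empty or has no usable header")
  }
  mandatory <- c("species", "cell_volume_um3")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols)) {
    stop_invalid("species table lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$species)) {
    stop_invalid("species labels must be unique; duplicated: ",
                 paste(unique(tab$species[duplicated(tab$species)]),
                       collapse = ", "))
  }
  numeric_cols <- setdiff(intersect(.species_columns, names(tab)),
                          c("species", "group"))
  missing_cells <- list()
  for (col in numeric_cols) {
    raw <- tab[[col]]
    empty <- is.na(raw) | !nzchar(trimws(raw))
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(parsed))
    if (length(bad)) {
      stop_invalid("column `", col, "` has unparseable numeric value(s) in ",
                   "row(s): ", paste(bad, collapse = ", "))
    }
    neg <- which(!is.na(parsed) & parsed < 0)
    if (length(neg)) {
      stop_invalid("column `", col, "` has negative value(s) in row(s): ",
                   paste(neg, collapse = ", "))
    }
    if (any(empty)) {
      missing_cells[[col]] <- data.frame(row = which(empty), column = col,
                                         stringsAsFactors = FALSE)
    }
    tab[[col]] <- parsed
  }
  if (anyNA(tab$cell_volume_um3) || any(tab$cell_volume_um3 <= 0)) {
    stop_invalid("`cell_volume_um3` must be present and positive for every row")
  }
  attr(tab, "missing_cells") <- if (length(missing_cells)) {
    do.call(rbind, unname(missing_cells))
  } else {
    data.frame(row = integer(), column = character(), stringsAsFactors = FALSE)
  }
  tab
}

#' Write a cross-species trait table
#'
#' Tab-delimited, UTF-8, '.' decimal, no quoting or row names; inverse of
#' [read_species_table()].
#'
#' @param table A species-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values that parse as numbers become numeric.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop_invalid("malformed config line: ", ln)
    key <- trimws(parts[1])
    value <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(value))
    cfg[[key]] <- if (!is.na(num)) num else value
  }
  cfg
}

# round to the 2-3 significant figures used in prose ("~15%")
as_printed <- function(x, digits = 2) signif(x, digits)

#' Run the full energetics pipeline
#'
#' Executes the standard analysis sequence on a cross-species trait table
#' and writes a reproducible report bundle:
#'
#' 1. **Input** — a species table read from `config$input`, or simulated
#'    via [generate_species_table()] when no input path is given
#'    (`config$seed` is then mandatory).
#' 2. **Fits** — log-log power-law fits of ribosome count, ATP synthase
#'    count, division time and (where present) total mitochondrial membrane
#'    area against cell volume or surface area.
#' 3. **Budgets** — per-species maintenance, growth and total ATP costs
#'    from volumes and division times.
#' 4. **Membranes** — the relative cost of mitochondrial membrane lipids
#'    at `V = 1` um^3 and per species.
#' 5. **Packing** — ATP synthase occupancy of the plasma membrane and
#'    required turnover per complex, where synthase counts are present.
#'
#' Outputs under `out_dir`: `species.tsv`, `fits.tsv`, `budgets.tsv`,
#' `report.json` (every number at full precision plus `printed` values at
#' 2 significant figures) and `run_log.txt` recording the constants, seed
#' and package version so every reported number can be re-derived. Reruns
#' with the same config produce byte-identical numeric reports.
#'
#' @param config A named list or path to a key-value file (see
#'   [read_config()]). Recognised keys: `input` (TSV path; optional),
#'   `seed`, `n_species`, `group`, `volume_min`, `volume_max`, `sd_log10`
#'   (simulation), `atp_share`, `synthase_footprint_nm2` (packing).
#' @param out_dir Directory for the report bundle (created if needed).
#' @return Invisibly, a list with `species`, `fits`, `budgets`, `report`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  if (!is.list(config)) stop_invalid("`config` must be a list or a file path")
  if (missing(out_dir) || is.null(out_dir)) {
    stop_invalid("`out_dir` is required")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage: input ---------------------------------------------------------
  species <- tryCatch({
    if (!is.null(config$input)) {
      read_species_table(config$input)
    } else {
      if (is.null(config$seed)) {
        stop_invalid("config must provide `input` or a simulation `seed`")
      }
      group <- if (is.null(config$group)) "eukaryote" else config$group
      vol_range <- if (!is.null(config$volume_min) && !is.null(config$volume_max)) {
        c(config$volume_min, config$volume_max)
      } else NULL
      generate_species_table(
        n_species = if (is.null(config$n_species)) 50 else config$n_species,
        group = group, seed = config$seed, volume_range = vol_range,
        sd_log10 = if (is.null(config$sd_log10)) 0.2 else config$sd_log10)
    }
  }, error = function(e) {
    stop_invalid("pipeline stage `input` failed: ", conditionMessage(e))
  })

  # stage: fits ----------------------------------------------------------
  fit_one <- function(xcol, ycol, trait) {
    ok <- stats::complete.cases(species[c(xcol, ycol)])
    if (sum(ok) < 3) return(NULL)
    fit_report(fit_power_law(species[[xcol]][ok], species[[ycol]][ok]), trait)
  }
  fits <- tryCatch({
    mito_total <- if (all(c("mito_outer_um2", "mito_inner_um2") %in% names(species))) {
      species$mito_outer_um2 + species$mito_inner_um2
    } else NA_real_
    species$mito_total_um2 <- mito_total
    do.call(rbind, Filter(Negate(is.null), list(
      fit_one("cell_volume_um3", "ribosomes_per_cell", "ribosomes~volume"),
      fit_one("plasma_area_um2", "atp_synthase_per_cell", "atp_synthase~surface"),
      fit_one("cell_volume_um3", "division_time_h", "division_time~volume"),
      fit_one("cell_volume_um3", "mito_total_um2", "mito_area~volume")
    )))
  }, error = function(e) {
    stop_invalid("pipeline stage `fits` failed: ", conditionMessage(e))
  })

  # stage: budgets -------------------------------------------------------
  budgets <- tryCatch({
    data.frame(
      species = species$species,
      cell_volume_um3 = species$cell_volume_um3,
      maintenance_atp_per_h = maintenance_rate(species$cell_volume_um3),
      growth_atp = growth_cost(species$cell_volume_um3),
      total_atp = ifelse(
        is.na(species$division_time_h), NA_real_,
        growth_cost(species$cell_volume_um3) +
          ifelse(is.na(species$division_time_h), 0, species$division_time_h) *
          maintenance_rate(species$cell_volume_um3)),
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop_invalid("pipeline stage `budgets` failed: ", conditionMessage(e))
  })

  # stage: membranes + packing -------------------------------------------
  report <- tryCatch({
    rel_v1 <- mito_membrane_relative_cost(1)
    rep <- list(
      n_species = nrow(species),
      mito_relative_cost_v1 = rel_v1,
      mito_relative_cost_v1_printed = as_printed(rel_v1),
      mean_growth_atp = mean(budgets$growth_atp)
    )
    if (!all(is.na(species$atp_synthase_per_cell)) &&
        !all(is.na(species$plasma_area_um2))) {
      fp <- if (!is.null(config$synthase_footprint_nm2)) {
        config$synthase_footprint_nm2
      } else if (identical(unique(species$group), "bacteria")) {
        reference_constants$footprint_synthase_bacteria_nm2
      } else {
        reference_constants$footprint_synthase_eukaryote_nm2
      }
      ok <- stats::complete.cases(species[c("atp_synthase_per_cell",
                                            "plasma_area_um2")])
      occ <- occupancy_fraction(species$atp_synthase_per_cell[ok], fp,
                                species$plasma_area_um2[ok])
      rep$mean_synthase_occupancy <- mean(occ)
      ok_t <- ok & !is.na(species$division_time_h)
      if (any(ok_t)) {
        share <- if (is.null(config$atp_share)) 0.15 else config$atp_share
        turn <- required_turnover(
          total_cost(species$cell_volume_um3[ok_t],
                     species$division_time_h[ok_t]),
          share, species$division_time_h[ok_t],
          species$atp_synthase_per_cell[ok_t])
        rep$median_required_turnover_per_s <- stats::median(turn)
      }
    }
    rep
  }, error = function(e) {
    stop_invalid("pipeline stage `membranes/packing` failed: ",
                 conditionMessage(e))
  })

  # stage: reports --------------------------------------------------------
  species_out <- species
  write_species_table(species_out, file.path(out_dir, "species.tsv"))
  if (!is.null(fits)) {
    utils::write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$fits <- fits
  }
  utils::write.table(budgets, file.path(out_dir, "budgets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("cellergy version: ",
           as.character(utils::packageVersion("cellergy"))),
    paste0("seed: ", if (is.null(config$seed)) "none (external input)"
           else config$seed),
    paste0("input: ", if (is.null(config$input)) "simulated" else config$input),
    "constants:",
    paste0("  ", names(reference_constants)[1:13], " = ",
           vapply(reference_constants[1:13],
                  function(v) paste(format(v), collapse = ","), character(1)))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(species = species_out, fits = fits, budgets = budgets,
                 report = report))
}
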