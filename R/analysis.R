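#' Categorize extant species as native, alien or invasive
#'
#' Evaluated on the census of a single year (normally the final one):
#' `NATIVE` species are members of the original island community that are
#' still extant; `ALIEN` species were introduced but failed to spread beyond
#' the point of entry (all their populations sit in the entry cell);
#' `INVASIVE` species were introduced and hold at least one population outside
#' the point of entry (landscape spread). Extinct species receive no category.
#'
#' @param census census records of one year: columns `species_id`, `origin`,
#'   `row`, `col` (one row per extant population).
#' @param entry_cell length-2 integer `(row, col)` of the point of entry.
#' @return Data frame with `species_id`, `origin`, `category`.
#' @export
categorize_species <- function(census, entry_cell) {
  if (nrow(census) == 0L)
    return(data.frame(species_id = character(0), origin = character(0),
                      category = character(0)))
  at_entry <- census$row == entry_cell[1] & census$col == entry_cell[2]
  spread <- tapply(!at_entry, census$species_id, any)
  ids <- names(spread)
  origin <- census$origin[match(ids, census$species_id)]
  category <- ifelse(origin == "native", "NATIVE",
                     ifelse(spread, "INVASIVE", "ALIEN"))
  out <- data.frame(species_id = ids, origin = origin, category = category)
  rownames(out) <- NULL
  out
}

final_census_by_run <- function(experiment) {
  cen <- experiment$census
  fin <- cen[cen$year == experiment$final_year, , drop = FALSE]
  split(fin, fin$run_id)
}

#' Cumulative invasive species per scenario
#'
#' Counts, for every scenario of an experiment, the number of species
#' categorized invasive at the final census, summed over replicates. A species
#' that becomes invasive in two replicates of one scenario counts twice (each
#' run is an independent invasion event).
#'
#' @param experiment an `invasim_experiment` from [full_experiment()].
#' @return Data frame with one row per scenario: the three factor levels,
#'   `runs` and `invasive_species`.
#' @export
invasion_counts <- function(experiment) {
  man <- experiment$manifest
  runs <- final_census_by_run(experiment)
  inv_per_run <- setNames(integer(nrow(man)), man$run_id)
  for (rid in names(runs)) {
    cats <- categorize_species(runs[[rid]], experiment$entry_cell)
    inv_per_run[rid] <- sum(cats$category == "INVASIVE")
  }
  man$invasive <- inv_per_run[as.character(man$run_id)]
  key <- list(base_temperature = man$base_temperature,
              propagule_pressure = man$propagule_pressure,
              disturbance = man$disturbance)
  agg <- aggregate(cbind(runs = rep(1L, nrow(man)), invasive = man$invasive),
                   by = key, FUN = sum)
  names(agg)[names(agg) == "invasive"] <- "invasive_species"
  agg[order(agg$base_temperature, agg$propagule_pressure, agg$disturbance), ,
      drop = FALSE]
}

#' Adaptation of a population from its census trait medians
#'
#' Evaluates the combined Gaussian adaptation at the population's median
#' optima and tolerances against the temperature and precipitation of its own
#' patch. Useful when only the census log is available.
#'
#' @param census census records (columns `row`, `col`, `med_temp_opt`,
#'   `med_temp_tol`, `med_precip_opt`, `med_precip_tol`).
#' @param island the `invasim_island` the census was recorded on.
#' @return Numeric vector in `(0, 1]`, one value per census row.
#' @export
population_adaptation <- function(census, island) {
  idx <- census$row * island$side + census$col + 1L
  gauss(census$med_temp_opt, census$med_temp_tol,
        island$patches$temperature[idx]) *
    gauss(census$med_precip_opt, census$med_precip_tol,
          island$patches$precipitation[idx])
}

#' Export the pooled population trait table
#'
#' Pools all populations of the final census year across runs, attaches the
#' per-run species category, and log(x+1)-transforms the trait medians used in
#' the community trait analysis: dispersal scale, dispersal shape (the
#' long-distance dispersal parameter), precipitation tolerance, temperature
#' tolerance, adult mass, seed mass and the combined adaptation. Niche optima
#' are excluded (they mostly reflect geography and the temperature scenario).
#' This table is the input for downstream standard statistics (mixed models,
#' simultaneous tests, PCA), which are deliberately left to general-purpose
#' tools.
#'
#' @param experiment an `invasim_experiment`.
#' @param path optional TSV output path.
#' @return Data frame with one row per population: `run_id`, scenario labels,
#'   `species_id`, `category`, patch, `abundance` and the transformed traits.
#' @export
export_trait_table <- function(experiment, path = NULL) {
  runs <- final_census_by_run(experiment)
  man <- experiment$manifest
  out <- lapply(runs, function(fin) {
    cats <- categorize_species(fin, experiment$entry_cell)
    fin$category <- cats$category[match(fin$species_id, cats$species_id)]
    fin
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  tab <- data.frame(
    run_id = out$run_id,
    base_temperature = out$base_temperature,
    propagule_pressure = out$propagule_pressure,
    disturbance = out$disturbance,
    replicate = out$replicate,
    species_id = out$species_id,
    category = out$category,
    row = out$row,
    col = out$col,
    abundance = out$abundance,
    dispersal_scale = log1p(out$med_dispersal_scale),
    dispersal_shape = log1p(out$med_dispersal_shape),
    precip_tol = log1p(out$med_precip_tol),
    temp_tol = log1p(out$med_temp_tol),
    adult_mass = log1p(out$med_adult_mass),
    seed_mass = log1p(out$med_seed_mass),
    adaptation = log1p(out$med_adaptation)
  )
  if (!is.null(path)) write_run_tsv(tab, path)
  tab
}

#' Category counts through time
#'
#' Applies the native/alien/invasive categorization to every census year of
#' every run, not just the final one, giving the time course of community
#' composition. (The headline analysis evaluates categories at the final
#' census only; this view is an extra.)
#'
#' @param experiment an `invasim_experiment`.
#' @return Data frame with one row per run and census year: counts of
#'   `native`, `alien` and `invasive` species.
#' @export
category_timeseries <- function(experiment) {
  cen <- experiment$census
  groups <- split(cen, list(cen$run_id, cen$year), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(d) {
    cats <- categorize_species(d, experiment$entry_cell)
    data.frame(run_id = d$run_id[1], year = d$year[1],
               native = sum(cats$category == "NATIVE"),
               alien = sum(cats$category == "ALIEN"),
               invasive = sum(cats$category == "INVASIVE"))
  }))
  out <- out[order(out$run_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load an experiment written to disk by [full_experiment()]
#'
#' Reads `manifest.tsv` and the per-run `census.tsv` files back into an
#' experiment object so that the analysis layer can run on stored outputs
#' (e.g. through the command-line interface).
#'
#' @param dir directory passed as `out_dir` to [full_experiment()].
#' @return An `invasim_experiment`.
#' @export
load_experiment <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.tsv"), comment.char = "#")
  census <- do.call(rbind, lapply(man$run_id, function(rid) {
    cen <- read.delim(file.path(dir, sprintf("run_%03d", rid), "census.tsv"),
                      comment.char = "#")
    cen$run_id <- rep(rid, nrow(cen))
    cen
  }))
  structure(
    list(manifest = man,
         census = census,
         final_year = man$horizon[1],
         entry_cell = c(man$entry_row[1], man$entry_col[1])),
    class = "invasim_experiment"
  )
}

#' Write the analysis layer of an experiment to TSV files
#'
#' Convenience wrapper producing `categories.tsv` (per-run species
#' categories), `invasion_counts.tsv` (cumulative invasives per scenario) and
#' `trait_table.tsv` (see [export_trait_table()]).
#'
#' @param experiment an `invasim_experiment`.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the list of written paths.
#' @export
analyze_experiment <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- final_census_by_run(experiment)
  cats <- do.call(rbind, lapply(names(runs), function(rid) {
    cbind(run_id = as.integer(rid),
          categorize_species(runs[[rid]], experiment$entry_cell))
  }))
  paths <- c(
    categories = file.path(out_dir, "categories.tsv"),
    invasion_counts = file.path(out_dir, "invasion_counts.tsv"),
    trait_table = file.path(out_dir, "trait_table.tsv")
  )
  write_run_tsv(cats, paths["categories"])
  write_run_tsv(invasion_counts(experiment), paths["invasion_counts"])
  export_trait_table(experiment, paths["trait_table"])
  invisible(paths)
}
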