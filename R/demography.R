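#' Max-normalized Gaussian niche function
#'
#' `gauss(b, c, x)` is the Gaussian bell with mean `b` and standard deviation
#' `c`, evaluated at `x` and normalized to peak at 1 (it is a suitability
#' weight in `(0, 1]`, not a probability density).
#'
#' @param b niche optimum.
#' @param c niche tolerance (standard deviation), strictly positive.
#' @param x local environmental value.
#' @return `exp(-(x - b)^2 / (2 c^2))`, vectorized over all arguments.
#' @examples
#' gauss(0, 1, 0)   # 1 at the optimum
#' gauss(0, 1, 1)   # exp(-1/2) one tolerance away
#' @export
gauss <- function(b, c, x) {
  if (any(c <= 0)) stop("tolerance `c` must be strictly positive",
                        call. = FALSE)
  exp(-((x - b)^2) / (2 * c^2))
}

#' Environmental adaptation of a phenotype in a patch
#'
#' The overall adaptation of a plant is the product of its temperature
#' adaptation and its precipitation adaptation, each a max-normalized Gaussian
#' of the local environment around the plant's optimum with its tolerance as
#' the standard deviation.
#'
#' @param traits named numeric vector of traits (see [TRAIT_NAMES]), or an
#'   `invasim_individual`'s `phenotype`.
#' @param patch one-row patch data frame (from [patch_at()] or
#'   `island$patches`) with `temperature` and `precipitation`.
#' @return List with components `temp` (A_T), `precip` (A_P) and `combined`
#'   (A_T * A_P), each in `(0, 1]`.
#' @export
adaptation <- function(traits, patch) {
  a_t <- gauss(traits[["temp_opt"]], traits[["temp_tol"]],
               patch$temperature)
  a_p <- gauss(traits[["precip_opt"]], traits[["precip_tol"]],
               patch$precipitation)
  list(temp = a_t, precip = a_p, combined = a_t * a_p)
}

# vectorized adaptation for a phenotype matrix against per-individual
# environment vectors
adaptation_components <- function(phen, tenv, penv) {
  list(at = gauss(phen[, "temp_opt"], phen[, "temp_tol"], tenv),
       ap = gauss(phen[, "precip_opt"], phen[, "precip_tol"], penv))
}

#' Metabolic-rate constants
#'
#' Vital rates follow the Metabolic Theory of Ecology,
#' `rate = coeff * M^exponent * exp(-E / (k (T + 273.15)))`, with a 3/4-power
#' for whole-organism production (growth, fecundity) and a -1/4-power for
#' mass-specific mortality. The three process coefficients are calibrated at a
#' reference point: at `ref_temperature` a plant of `ref_mass` with perfect
#' temperature adaptation has annual mortality probability `ref_mortality`,
#' grows from a 1 g seed to `ref_mass` in about `ref_growth_years` years, and
#' allocates the fraction `fecundity_fraction` of its `M^(3/4)`-scaled yearly
#' production to seed biomass.
#'
#' @param activation_energy metabolic activation energy E in eV.
#' @param boltzmann Boltzmann constant in eV/K.
#' @param ref_temperature calibration temperature in degrees Celsius.
#' @param ref_mass calibration mass in grams.
#' @param ref_mortality annual mortality of the reference plant at full
#'   temperature adaptation.
#' @param ref_growth_years years for the reference plant to grow from a 1 g
#'   seed to `ref_mass`.
#' @param fecundity_fraction fraction of yearly production allocated to
#'   seeds, at the reference temperature.
#' @return An `invasim_mte` list with `E`, `k` and the coefficients `m0`
#'   (mortality), `g0` (growth) and `f0` (fecundity).
#' @export
mte_constants <- function(activation_energy = 0.65,
                          boltzmann = 8.617e-5,
                          ref_temperature = 20,
                          ref_mass = 1000,
                          ref_mortality = 0.05,
                          ref_growth_years = 10,
                          fecundity_fraction = 0.05) {
  stopifnot(activation_energy >= 0, boltzmann > 0, ref_mass > 1,
            ref_mortality > 0, ref_mortality < 1, ref_growth_years > 0,
            fecundity_fraction > 0)
  arrh_ref <- exp(-activation_energy /
                    (boltzmann * (ref_temperature + 273.15)))
  # growth is applied in discrete yearly steps M <- M + g0 M^(3/4) arrh;
  # solve for the increment coefficient that takes a 1 g seed to ref_mass in
  # ref_growth_years steps at the reference temperature
  steps <- max(1L, round(ref_growth_years))
  grown <- function(cc) {
    m <- 1
    for (i in seq_len(steps)) m <- m + cc * m^0.75
    m
  }
  cc <- uniroot(function(cc) grown(cc) - ref_mass, c(1e-9, 1e3),
                tol = 1e-12)$root
  g0 <- cc / arrh_ref
  structure(
    list(E = activation_energy,
         k = boltzmann,
         m0 = ref_mortality * ref_mass^0.25 / arrh_ref,
         g0 = g0,
         f0 = fecundity_fraction / arrh_ref,
         ref_temperature = ref_temperature,
         ref_mass = ref_mass),
    class = "invasim_mte"
  )
}

#' Metabolic rate kernel
#'
#' @param mass body mass in grams (> 0).
#' @param temperature local temperature in degrees Celsius.
#' @param exponent allometric exponent, `3/4` for whole-organism production
#'   or `-1/4` for mass-specific rates.
#' @param coeff normalization coefficient (e.g. `constants$m0`).
#' @param constants an `invasim_mte` object.
#' @return `coeff * mass^exponent * exp(-E / (k (temperature + 273.15)))`,
#'   vectorized.
#' @export
mte_rate <- function(mass, temperature, exponent, coeff, constants) {
  stopifnot(all(mass > 0))
  coeff * mass^exponent *
    exp(-constants$E / (constants$k * (temperature + 273.15)))
}

arrhenius <- function(temperature, constants) {
  exp(-constants$E / (constants$k * (temperature + 273.15)))
}

# shared establishment filter for dispersing seeds and transported arrivals
establishes <- function(aind, threshold, mode = c("threshold", "bernoulli")) {
  mode <- match.arg(mode)
  if (mode == "threshold") aind >= threshold else runif(length(aind)) < aind
}

# death probability of every plant: metabolic baseline hazard over A_T
survival_probability <- function(pop, island, constants) {
  tenv <- island$patches$temperature[pop$patch]
  pmin(1, mte_rate(pop$mass, tenv, -0.25, constants$m0, constants) /
         pmax(pop$at, 1e-6))
}

#' Yearly survival: density-independent, adaptation-linked mortality
#'
#' Every plant dies independently with probability
#' `min(1, m0 * M^(-1/4) * exp(-E/kT) / max(A_T, 1e-6))`: the metabolic
#' baseline hazard divided by the plant's temperature adaptation, so poorly
#' adapted plants die sooner and heavier plants live longer.
#'
#' @param pop internal population object.
#' @param island an `invasim_island`.
#' @param constants an `invasim_mte`.
#' @return List with `pop` (survivors), `removed` (the dead), and
#'   `n_removed`.
#' @keywords internal
#' @export
survival_step <- function(pop, island, constants) {
  n <- pop_size(pop)
  if (n == 0L)
    return(list(pop = pop, removed = pop, n_removed = 0L))
  dead <- runif(n) < survival_probability(pop, island, constants)
  list(pop = pop_subset(pop, !dead),
       removed = pop_subset(pop, dead),
       n_removed = sum(dead))
}

# in-place mass update for the individuals listed in `idx`
grow_masses <- function(pop, island, constants, idx) {
  adult <- pop$phen[idx, "adult_mass"]
  mass <- pop$mass[idx]
  juv <- mass < adult
  if (any(juv)) {
    j <- idx[juv]
    tenv <- island$patches$temperature[pop$patch[j]]
    inc <- mte_rate(mass[juv], tenv, 0.75, constants$g0, constants)
    pop$mass[j] <- pmin(adult[juv], mass[juv] + inc)
  }
  pop
}

#' Yearly growth: juveniles gain mass until reproductive size
#'
#' Each plant below its adult mass gains `g0 * M^(3/4) * exp(-E/kT)` grams,
#' capped at adult mass. Adults do not grow further.
#'
#' @inheritParams survival_step
#' @return The population with updated masses.
#' @keywords internal
#' @export
growth_step <- function(pop, island, constants) {
  if (pop_size(pop) == 0L) return(pop)
  grow_masses(pop, island, constants, seq_len(pop_size(pop)))
}

# global indices removed by competition, restricted to the individuals in
# `idx` (default: everyone)
competition_removals <- function(pop, island, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(pop_size(pop))
  if (length(idx) == 0L) return(integer(0))
  biomass <- pop_biomass_by_patch(pop, nrow(island$patches), idx)
  over <- which(biomass > island$patches$capacity)
  if (length(over) == 0L) return(integer(0))
  members_by_patch <- split(idx, pop$patch[idx])
  drop_global <- integer(0)
  for (p in over) {
    members <- members_by_patch[[as.character(p)]]
    rem <- compete_patch(pop$mass[members], pop$ap[members],
                         island$patches$capacity[p])
    drop_global <- c(drop_global, members[rem])
  }
  drop_global
}

#' Yearly competition: density-dependent mortality above carrying capacity
#'
#' In every patch whose total biomass exceeds the carrying capacity, pairs of
#' plants are drawn uniformly at random and the one with the lower
#' precipitation adaptation is removed (ties broken at random), until biomass
#' fits the capacity or a single plant remains.
#'
#' @inheritParams survival_step
#' @return List with `pop`, `removed` and `n_removed`.
#' @keywords internal
#' @export
competition_step <- function(pop, island) {
  n <- pop_size(pop)
  if (n == 0L) return(list(pop = pop, removed = pop, n_removed = 0L))
  drop_global <- competition_removals(pop, island)
  keep <- rep(TRUE, n)
  keep[drop_global] <- FALSE
  list(pop = pop_subset(pop, keep),
       removed = pop_subset(pop, !keep),
       n_removed = length(drop_global))
}

# meiosis for a batch of crosses: one gamete per parent, picking a homolog
# uniformly per chromosome. Returns an n x n_genes allele matrix.
meiosis_gametes <- function(h1, h2, idx, arch) {
  ns <- length(idx)
  chroms <- unique(arch$chromosome)
  expand <- match(arch$chromosome, chroms)
  pick <- matrix(as.numeric(runif(ns * length(chroms)) < 0.5),
                 ns)[, expand, drop = FALSE]
  a <- h1[idx, , drop = FALSE]
  b <- h2[idx, , drop = FALSE]
  pick * a + (1 - pick) * b
}

# reproduction restricted to the adults listed in `adults` (global indices)
reproduction_core <- function(pop, island, constants, architecture, adults) {
  if (length(adults) < 2L) return(pop_empty(architecture))
  key <- pop$patch[adults] +
    nrow(island$patches) * as.double(pop$species[adults])
  groups <- split(adults, key)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(pop_empty(architecture))

  mothers <- vector("list", length(groups))
  fathers <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    m <- length(g)
    # uniform partner among the other m - 1 adults of the group
    shift <- 1L + floor(runif(m) * (m - 1L))
    shift[shift > m - 1L] <- m - 1L   # guard against runif() == 1
    mothers[[i]] <- g
    fathers[[i]] <- g[((seq_len(m) - 1L + shift) %% m) + 1L]
  }
  mothers <- unlist(mothers)
  fathers <- unlist(fathers)
  tenv <- island$patches$temperature[pop$patch[mothers]]
  alloc <- mte_rate(pop$mass[mothers], tenv, 0.75, constants$f0, constants)
  counts <- as.integer(round(alloc / pop$phen[mothers, "seed_mass"]))
  keep <- counts > 0L
  mothers <- mothers[keep]; fathers <- fathers[keep]; counts <- counts[keep]
  if (length(mothers) == 0L) return(pop_empty(architecture))

  midx <- rep.int(mothers, counts)
  fidx <- rep.int(fathers, counts)
  ns <- length(midx)
  h1 <- meiosis_gametes(pop$h1, pop$h2, midx, architecture)
  h2 <- meiosis_gametes(pop$h1, pop$h2, fidx, architecture)
  phen <- express_phenotype_matrix(h1, h2, architecture)
  list(species = pop$species[midx],
       patch = pop$patch[midx],
       mass = phen[, "seed_mass"],
       introduced = rep(FALSE, ns),
       h1 = h1,
       h2 = h2,
       phen = phen,
       at = rep(NA_real_, ns),
       ap = rep(NA_real_, ns))
}

#' Yearly reproduction: local sexual reproduction with meiosis
#'
#' Every adult (mass at reproductive size) with at least one conspecific adult
#' in the same patch acts once as a mother; its pollen partner is drawn
#' uniformly among the other conspecific adults of the patch (self-pollination
#' is not permitted, pollen does not cross patches). The mother produces
#' `round(f0 * M^(3/4) * exp(-E/kT) / seed_mass)` seeds (allocation scaled by
#' its production, divided by its seed mass), each with a genome recombined
#' from one maternal and one paternal gamete. Seeds are returned, not yet
#' placed; [dispersal_step()] decides where they land.
#'
#' @inheritParams survival_step
#' @param architecture the shared gene-trait layout.
#' @return A population object of seeds, each located in its natal patch with
#'   mass equal to its own expressed seed mass.
#' @keywords internal
#' @export
reproduction_step <- function(pop, island, constants,
                              architecture = trait_architecture()) {
  n <- pop_size(pop)
  if (n == 0L) return(pop_empty(architecture))
  adults <- which(pop$mass >= pop$phen[, "adult_mass"])
  reproduction_core(pop, island, constants, architecture, adults)
}

#' Yearly disturbance: density- and species-independent mortality
#'
#' Removes each plant independently with probability `d`. In full runs the
#' process only acts after the burn-in period.
#'
#' @inheritParams survival_step
#' @param d disturbance intensity, fraction of plants removed per year.
#' @return List with `pop`, `removed` and `n_removed`.
#' @keywords internal
#' @export
disturbance_step <- function(pop, d) {
  stopifnot(d >= 0, d <= 1)
  n <- pop_size(pop)
  if (n == 0L || d == 0)
    return(list(pop = pop, removed = pop_subset(pop, logical(n)),
                n_removed = 0L))
  hit <- runif(n) < d
  list(pop = pop_subset(pop, !hit),
       removed = pop_subset(pop, hit),
       n_removed = sum(hit))
}

#' Yearly transport: introduction of alien propagules at the point of entry
#'
#' Places exactly `pressure` individuals in the entry patch. The species of
#' each arrival is drawn independently and uniformly from the alien pool (a
#' year's batch can contain several plants of one species). Arrivals are
#' spawned at seed mass and pass the same establishment filter as dispersing
#' seeds; those below the adaptation threshold die on arrival.
#'
#' @param island an `invasim_island`.
#' @param pool full species pool table; rows with `origin == "alien"` are the
#'   alien reservoir.
#' @param pressure propagule pressure: individuals introduced per year.
#' @param year current simulation year; must exceed `burn_in`.
#' @param burn_in length of the burn-in period in years.
#' @param cv individual trait variation.
#' @param architecture shared gene-trait layout.
#' @param threshold,mode establishment filter, see [dispersal_step()].
#' @return List with `pop` (established arrivals), `attempted` (= `pressure`),
#'   `species_drawn` (pool row index of every arrival) and `n_established`.
#' @keywords internal
#' @export
transport_step <- function(island, pool, pressure, year, burn_in,
                           cv = 0.05, architecture = trait_architecture(),
                           threshold = 0.05, mode = "threshold") {
  stopifnot(pressure >= 0)
  if (year <= burn_in)
    stop("transport must not run during the burn-in period", call. = FALSE)
  alien_rows <- which(pool$origin == "alien")
  if (length(alien_rows) == 0L)
    stop("alien species pool is empty", call. = FALSE)
  if (pressure == 0L) {
    return(list(pop = pop_empty(architecture), attempted = 0L,
                species_drawn = integer(0), n_established = 0L))
  }
  drawn <- alien_rows[sample.int(length(alien_rows), pressure,
                                 replace = TRUE)]
  arrivals <- spawn_cohort(pool, drawn, cv, architecture, stage = "seed",
                           patch = island$entry_patch, introduced = TRUE)
  env <- island$patches[island$entry_patch, ]
  ad <- adaptation_components(arrivals$phen, env$temperature,
                              env$precipitation)
  arrivals$at <- ad$at
  arrivals$ap <- ad$ap
  ok <- establishes(ad$at * ad$ap, threshold, mode)
  list(pop = pop_subset(arrivals, ok),
       attempted = as.integer(pressure),
       species_drawn = drawn,
       n_established = sum(ok))
}

#' Sample seed displacement distances from the log-logistic kernel
#'
#' Distances follow the log-logistic (logistic dispersal) kernel with scale
#' `a` (the median displacement) and shape `s`; smaller shapes give heavier
#' tails (more long-distance dispersal). Sampling is by inverse CDF:
#' `a * (u / (1 - u))^(1/s)` with `u ~ Uniform(0, 1)`.
#'
#' @param n number of samples.
#' @param scale kernel scale `a` in grid units (> 0); recycled over `n`.
#' @param shape kernel shape `s` (> 1); recycled over `n`.
#' @return Numeric vector of `n` non-negative distances.
#' @examples
#' set.seed(1)
#' median(sample_dispersal_distance(1e4, scale = 1, shape = 2))  # ~ 1
#' @export
sample_dispersal_distance <- function(n, scale, shape) {
  stopifnot(all(scale > 0), all(shape > 1))
  u <- runif(n)
  scale * (u / (1 - u))^(1 / shape)
}

# closed-form CDF of the log-logistic dispersal kernel (used by tests and
# documented for reference): F(x) = 1 / (1 + (x / a)^(-s))
#' Log-logistic dispersal kernel CDF
#'
#' @param q quantiles (distances, >= 0).
#' @param scale,shape kernel parameters, see [sample_dispersal_distance()].
#' @return `P(distance <= q)`.
#' @export
dispersal_cdf <- function(q, scale, shape) {
  ifelse(q <= 0, 0, 1 / (1 + (q / scale)^(-shape)))
}

#' Yearly dispersal: move seeds and apply the establishment filter
#'
#' Every seed travels from its natal patch center a kernel-sampled distance in
#' a uniformly random direction. Seeds landing beyond the island border die.
#' Seeds landing in a patch establish if their combined adaptation to the
#' local temperature and precipitation reaches the establishment threshold
#' (or, in `"bernoulli"` mode, with probability equal to their adaptation);
#' otherwise the patch is unsuitable and they die.
#'
#' @param seeds population object of seeds (from [reproduction_step()] or
#'   [transport_step()]); each seed's `patch` is its natal patch.
#' @param island an `invasim_island`.
#' @param threshold establishment threshold on combined adaptation.
#' @param mode `"threshold"` (hard cutoff) or `"bernoulli"` (establishment
#'   lottery with success probability equal to the adaptation).
#' @return List with `pop` (established seedlings, placed in their landing
#'   patches), `n_dispersed`, `n_off_island`, `n_established`.
#' @keywords internal
#' @export
dispersal_step <- function(seeds, island, threshold = 0.05,
                           mode = "threshold") {
  ns <- pop_size(seeds)
  if (ns == 0L)
    return(list(pop = seeds, n_dispersed = 0L, n_off_island = 0L,
                n_established = 0L))
  res <- disperse_cpp(seeds$species, seeds$patch, seeds$mass,
                      seeds$introduced, seeds$h1, seeds$h2, seeds$phen,
                      as.numeric(island$patches$row),
                      as.numeric(island$patches$col),
                      island$patches$temperature,
                      island$patches$precipitation,
                      island$side, threshold,
                      identical(mode, "bernoulli"))
  list(pop = as_pop(res$pop),
       n_dispersed = res$n_dispersed,
       n_off_island = res$n_off_island,
       n_established = res$n_established)
}
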