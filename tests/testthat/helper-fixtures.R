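# fixtures are built in code: small populations, species rows and degenerate
# trait ranges used across the unit tests

trait_defaults <- c(temp_opt = 20, temp_tol = 5, precip_opt = 5,
                    precip_tol = 5, seed_mass = 10, adult_mass = 1000,
                    dispersal_scale = 1, dispersal_shape = 2)

# a one-row species table
make_species <- function(..., species_id = "S001", origin = "native") {
  vals <- trait_defaults
  ov <- c(...)
  vals[names(ov)] <- ov
  cbind(data.frame(species_id = species_id, origin = origin),
        as.data.frame(as.list(vals)))
}

# degenerate (point-mass) generation ranges at the given trait values
point_ranges <- function(...) {
  vals <- trait_defaults
  ov <- c(...)
  vals[names(ov)] <- ov
  lapply(as.list(vals), function(v) c(v, v))
}

# build an internal population of n identical (or vectorized) individuals,
# homozygous at the given phenotype
make_pop <- function(n = 1L, species = 1L, patch = 1L, mass = NULL,
                     at = 1, ap = 1, introduced = FALSE, island = NULL, ...) {
  vals <- trait_defaults
  ov <- list(...)
  phen <- matrix(rep(vals, each = n), n,
                 dimnames = list(NULL, names(vals)))
  for (nm in names(ov)) phen[, nm] <- ov[[nm]]
  if (is.null(mass)) mass <- phen[, "adult_mass"]
  pop <- list(species = rep_len(as.integer(species), n),
              patch = rep_len(as.integer(patch), n),
              mass = rep_len(mass, n),
              introduced = rep_len(introduced, n),
              h1 = phen, h2 = phen, phen = phen,
              at = rep_len(at, n), ap = rep_len(ap, n))
  if (!is.null(island)) {
    ad <- invasim:::adaptation_components(
      pop$phen, island$patches$temperature[pop$patch],
      island$patches$precipitation[pop$patch])
    pop$at <- ad$at
    pop$ap <- ad$ap
  }
  pop
}

pop_total_mass <- function(pop) sum(pop$mass)

# literal transcription of the adaptation formula used as an independent
# oracle: product of two Gaussians in x, max-normalized via the density ratio
adaptation_oracle <- function(topt, ttol, popt, ptol, tenv, penv) {
  (dnorm(tenv, mean = topt, sd = ttol) / dnorm(topt, mean = topt, sd = ttol)) *
    (dnorm(penv, mean = popt, sd = ptol) / dnorm(popt, mean = popt, sd = ptol))
}
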