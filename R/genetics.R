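#' The eight heritable traits of a plant
#'
#' Every individual expresses eight quantitative traits: Gaussian niche
#' optimum and tolerance for temperature and for precipitation, seed and
#' reproductive (adult) mass in grams, and the scale (median displacement, in
#' grid units) and shape of a log-logistic seed dispersal kernel.
#'
#' @export
TRAIT_NAMES <- c("temp_opt", "temp_tol", "precip_opt", "precip_tol",
                 "seed_mass", "adult_mass", "dispersal_scale",
                 "dispersal_shape")

# legal phenotype/allele domain per trait; expression and individual variation
# clamp into these. adult mass is bounded by the grassland/shrubland range
# (150 g to 1.2 t); tolerances and kernel parameters must stay positive and
# the kernel shape must exceed 1 so that the dispersal distribution has a
# finite mean.
TRAIT_LOWER <- c(temp_opt = -Inf, temp_tol = 1e-2, precip_opt = -Inf,
                 precip_tol = 1e-2, seed_mass = 1e-3, adult_mass = 150,
                 dispersal_scale = 1e-3, dispersal_shape = 1 + 1e-6)
TRAIT_UPPER <- c(temp_opt = Inf, temp_tol = Inf, precip_opt = Inf,
                 precip_tol = Inf, seed_mass = Inf, adult_mass = 1.2e6,
                 dispersal_scale = Inf, dispersal_shape = Inf)

# traits generated log-uniformly (they span orders of magnitude)
LOG_UNIFORM_TRAITS <- c("seed_mass", "adult_mass")

clamp_trait_matrix <- function(m) {
  for (j in seq_along(TRAIT_NAMES)) {
    if (is.finite(TRAIT_LOWER[j])) m[, j] <- pmax(m[, j], TRAIT_LOWER[j])
    if (is.finite(TRAIT_UPPER[j])) m[, j] <- pmin(m[, j], TRAIT_UPPER[j])
  }
  # a seed must weigh strictly less than the reproductive mass
  m[, "seed_mass"] <- pmin(m[, "seed_mass"], 0.5 * m[, "adult_mass"])
  m
}

#' Gene-to-trait architecture of the genome
#'
#' Genomes are diploid. The architecture maps each gene to the trait it codes
#' for and to the chromosome it sits on; both haplotypes share it. The default
#' places one gene per trait, each on its own chromosome, so meiosis
#' recombines freely between traits and not at all within a trait. The
#' architecture is isolated behind this constructor so alternative layouts
#' (several genes per trait, linkage) can be swapped in.
#'
#' @param genes_per_trait integer >= 1; number of genes coding for each trait.
#'   Each gene goes on its own chromosome.
#' @return An object of class `invasim_architecture`: list with `trait`
#'   (integer index into [TRAIT_NAMES] per gene), `chromosome` (integer per
#'   gene) and `n_genes`.
#' @export
trait_architecture <- function(genes_per_trait = 1L) {
  genes_per_trait <- as.integer(genes_per_trait)
  stopifnot(genes_per_trait >= 1L)
  trait <- rep(seq_along(TRAIT_NAMES), each = genes_per_trait)
  structure(
    list(trait = trait,
         chromosome = seq_along(trait),
         n_genes = length(trait)),
    class = "invasim_architecture"
  )
}

validate_trait_ranges <- function(trait_ranges) {
  if (!all(TRAIT_NAMES %in% names(trait_ranges)))
    stop("trait_ranges must name all of: ",
         paste(TRAIT_NAMES, collapse = ", "), call. = FALSE)
  for (tr in TRAIT_NAMES) {
    r <- trait_ranges[[tr]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for trait ", tr, call. = FALSE)
    if (r[1] < TRAIT_LOWER[tr] || r[2] > TRAIT_UPPER[tr])
      stop("range for trait ", tr, " leaves its legal domain", call. = FALSE)
    if (tr %in% LOG_UNIFORM_TRAITS && r[1] <= 0)
      stop("log-uniform trait ", tr, " needs a positive range", call. = FALSE)
  }
  invisible(trait_ranges)
}

#' Default species-generation ranges for an island
#'
#' Mean traits of random species are drawn uniformly within these ranges
#' (log-uniformly for the two mass traits). Niche optima cover the island's
#' realized environmental range widened by twice (temperature) or once
#' (precipitation) the maximal tolerance, so that many random species are
#' poorly adapted anywhere and community assembly acts as a filter.
#'
#' @param island an `invasim_island`.
#' @return Named list of `(lo, hi)` ranges, one per trait in [TRAIT_NAMES].
#' @export
default_trait_ranges <- function(island) {
  tr <- range(island$patches$temperature)
  pr <- island$precip_range
  temp_tol <- c(0.5, 5)
  precip_tol <- c(0.5, 5)
  list(
    temp_opt = c(tr[1] - 2 * temp_tol[2], tr[2] + 2 * temp_tol[2]),
    temp_tol = temp_tol,
    precip_opt = c(pr[1] - precip_tol[2], pr[2] + precip_tol[2]),
    precip_tol = precip_tol,
    seed_mass = c(1, 100),
    adult_mass = c(150, 1.2e6),
    dispersal_scale = c(0.1, 2),
    dispersal_shape = c(1.1, 4)
  )
}

#' Generate one random species
#'
#' Draws the species' mean trait values independently: uniform within the
#' given range for niche and dispersal traits, log-uniform for seed and adult
#' mass. Uses R's global random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param trait_ranges named list of `(lo, hi)` per trait, e.g. from
#'   [default_trait_ranges()]. Degenerate ranges (`lo == hi`) give a point
#'   mass.
#' @param origin `"native"` or `"alien"` species pool membership.
#' @param species_id identifier token; autogenerated if `NULL`.
#' @return One-row data frame: `species_id`, `origin` and the eight mean
#'   traits.
#' @export
random_species <- function(trait_ranges, origin = c("native", "alien"),
                           species_id = NULL) {
  origin <- match.arg(origin)
  pool <- random_species_pool(1L, trait_ranges, origin)
  if (!is.null(species_id)) pool$species_id <- species_id
  pool
}

#' Generate a pool of random species
#'
#' @param n number of species.
#' @param trait_ranges see [random_species()].
#' @param origin pool label for all generated species.
#' @param prefix prefix for autogenerated species ids.
#' @return Data frame with `species_id`, `origin` and one column per trait.
#' @export
random_species_pool <- function(n, trait_ranges,
                                origin = c("native", "alien"),
                                prefix = NULL) {
  origin <- match.arg(origin)
  validate_trait_ranges(trait_ranges)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(prefix)) prefix <- if (origin == "native") "N" else "A"
  m <- matrix(NA_real_, n, length(TRAIT_NAMES),
              dimnames = list(NULL, TRAIT_NAMES))
  for (tr in TRAIT_NAMES) {
    r <- trait_ranges[[tr]]
    m[, tr] <- if (tr %in% LOG_UNIFORM_TRAITS) {
      exp(runif(n, log(r[1]), log(r[2])))
    } else {
      runif(n, r[1], r[2])
    }
  }
  m <- clamp_trait_matrix(m)
  out <- data.frame(
    species_id = sprintf("%s%03d", prefix, seq_len(n)),
    origin = origin
  )
  cbind(out, as.data.frame(m))
}

#' Express the phenotype of a diploid genome
#'
#' Each trait value is the arithmetic mean of all allele values coding for
#' that trait, across both haplotypes and all genes, clamped to the trait's
#' legal domain. Expression is a pure function of the genome: with mutation
#' switched off, re-expressing an unchanged genome always returns the same
#' trait set.
#'
#' @param genome an `invasim_genome` (see [mate()]), or a list with numeric
#'   haplotype vectors `h1` and `h2` plus an `architecture` attribute.
#' @return Named numeric vector of the eight traits.
#' @export
express_phenotype <- function(genome) {
  arch <- attr(genome, "architecture")
  if (is.null(arch)) arch <- trait_architecture()
  h1 <- genome$h1
  h2 <- genome$h2
  stopifnot(length(h1) == arch$n_genes, length(h2) == arch$n_genes)
  covered <- sort(unique(arch$trait))
  if (!identical(covered, seq_along(TRAIT_NAMES)))
    stop("genome architecture leaves a trait without a coding gene",
         call. = FALSE)
  alleles <- c(h1, h2)
  traits <- c(arch$trait, arch$trait)
  phen <- as.numeric(tapply(alleles, traits, mean))
  m <- matrix(phen, nrow = 1, dimnames = list(NULL, TRAIT_NAMES))
  drop(clamp_trait_matrix(m))
}

# vectorized expression for n individuals: h1, h2 are n x n_genes matrices.
express_phenotype_matrix <- function(h1, h2, arch) {
  if (arch$n_genes == length(TRAIT_NAMES) &&
      identical(arch$trait, seq_along(TRAIT_NAMES))) {
    # one gene per trait: mean of the two alleles, no regrouping needed
    phen <- (h1 + h2) / 2
    dimnames(phen) <- list(NULL, TRAIT_NAMES)
    return(clamp_trait_matrix(phen))
  }
  n <- nrow(h1)
  phen <- matrix(NA_real_, n, length(TRAIT_NAMES),
                 dimnames = list(NULL, TRAIT_NAMES))
  for (j in seq_along(TRAIT_NAMES)) {
    g <- which(arch$trait == j)
    phen[, j] <- (rowSums(h1[, g, drop = FALSE]) +
                    rowSums(h2[, g, drop = FALSE])) / (2 * length(g))
  }
  clamp_trait_matrix(phen)
}

new_genome <- function(h1, h2, arch) {
  structure(list(h1 = h1, h2 = h2), class = "invasim_genome",
            architecture = arch)
}

#' Spawn one individual of a species
#'
#' Introduces standing variation: for each trait, a value is drawn from a
#' normal distribution centered on the species' mean with standard deviation
#' `cv` times the absolute mean, clamped to the trait's legal domain, and
#' written to every gene coding for that trait on both haplotypes (new
#' individuals are born homozygous; heterozygosity arises from matings between
#' individuals carrying different alleles). Mass starts at the expressed seed
#' mass for `stage = "seed"` or at adult mass for founders.
#'
#' @param species one-row data frame as returned by [random_species()].
#' @param cv relative standard deviation of individual trait variation
#'   (>= 0).
#' @param stage `"seed"` or `"adult"`: initial mass of the individual.
#' @param architecture gene-trait layout, see [trait_architecture()].
#' @param id identifier for the new individual.
#' @param location length-2 integer `(row, col)` patch of residence.
#' @return An `invasim_individual`: list with `id`, `species_id`, `genome`,
#'   `phenotype`, `mass`, `location`, `introduced`.
#' @export
spawn_individual <- function(species, cv = 0.05,
                             stage = c("seed", "adult"),
                             architecture = trait_architecture(),
                             id = 1L, location = c(0L, 0L)) {
  stage <- match.arg(stage)
  stopifnot(cv >= 0, nrow(species) == 1L)
  means <- as.numeric(species[1, TRAIT_NAMES])
  vals <- rnorm(length(means), mean = means, sd = cv * abs(means))
  m <- matrix(vals, 1, dimnames = list(NULL, TRAIT_NAMES))
  vals <- drop(clamp_trait_matrix(m))
  h <- vals[TRAIT_NAMES[architecture$trait]]
  names(h) <- NULL
  genome <- new_genome(h, h, architecture)
  phen <- express_phenotype(genome)
  structure(
    list(id = id,
         species_id = species$species_id,
         genome = genome,
         phenotype = phen,
         mass = unname(if (stage == "seed") phen["seed_mass"]
                       else phen["adult_mass"]),
         location = as.integer(location),
         introduced = identical(species$origin, "alien")),
    class = "invasim_individual"
  )
}

# one gamete: per chromosome pick one homolog uniformly, take its alleles
gamete <- function(genome, arch) {
  chroms <- unique(arch$chromosome)
  pick <- runif(length(chroms)) < 0.5
  use_h1 <- pick[match(arch$chromosome, chroms)]
  ifelse(use_h1, genome$h1, genome$h2)
}

#' Mate two conspecific adults and return the offspring genome
#'
#' Sexual reproduction with meiotic recombination: each parent contributes one
#' gamete, built by picking one of its two homologs uniformly at random for
#' every chromosome (free recombination between chromosomes, none within).
#' Self-pollination is not permitted, pollen does not travel between patches,
#' and parents must belong to the same species.
#'
#' @param mother,father `invasim_individual`s sharing species and location,
#'   with different ids.
#' @return An `invasim_genome` for the offspring.
#' @export
mate <- function(mother, father) {
  if (!identical(mother$species_id, father$species_id))
    stop("parents must belong to the same species", call. = FALSE)
  if (identical(mother$id, father$id))
    stop("self-pollination is not permitted", call. = FALSE)
  if (!identical(as.integer(mother$location), as.integer(father$location)))
    stop("pollen dispersal is restricted to the local grid cell",
         call. = FALSE)
  arch <- attr(mother$genome, "architecture")
  new_genome(gamete(mother$genome, arch), gamete(father$genome, arch), arch)
}
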