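# Internal column-oriented population container.
#
# The simulator holds all plants of the island in one plain list of parallel
# vectors/matrices so that the yearly processes can be vectorized:
#   species     integer index into the world's species pool table
#   patch       integer patch index (row * side + col + 1), NA for seeds
#               that have not yet landed
#   mass        current mass in grams
#   introduced  TRUE for individuals placed by the transport process
#   h1, h2      n x n_genes haplotype allele matrices
#   phen        n x 8 expressed trait matrix (fixed for life: mutation off)
#   at, ap      temperature and precipitation adaptation in the patch of
#               residence (fixed once established, because neither phenotype
#               nor patch environment changes)
#
# These helpers avoid classed objects and keep allocations to a minimum: the
# year loop rebuilds the population once per year.

# restore column names on a population list coming back from compiled code
as_pop <- function(lst) {
  dimnames(lst$phen) <- list(NULL, TRAIT_NAMES)
  lst
}

pop_empty <- function(arch) {
  list(species = integer(0),
       patch = integer(0),
       mass = numeric(0),
       introduced = logical(0),
       h1 = matrix(numeric(0), 0, arch$n_genes),
       h2 = matrix(numeric(0), 0, arch$n_genes),
       phen = matrix(numeric(0), 0, length(TRAIT_NAMES),
                     dimnames = list(NULL, TRAIT_NAMES)),
       at = numeric(0),
       ap = numeric(0))
}

pop_size <- function(pop) length(pop$species)

pop_subset <- function(pop, keep) {
  list(species = pop$species[keep],
       patch = pop$patch[keep],
       mass = pop$mass[keep],
       introduced = pop$introduced[keep],
       h1 = pop$h1[keep, , drop = FALSE],
       h2 = pop$h2[keep, , drop = FALSE],
       phen = pop$phen[keep, , drop = FALSE],
       at = pop$at[keep],
       ap = pop$ap[keep])
}

pop_bind <- function(...) {
  pops <- list(...)
  pops <- pops[vapply(pops, pop_size, 1L) > 0L]
  if (length(pops) == 0L) return((list(...))[[1L]])
  if (length(pops) == 1L) return(pops[[1L]])
  list(species = unlist(lapply(pops, `[[`, "species")),
       patch = unlist(lapply(pops, `[[`, "patch")),
       mass = unlist(lapply(pops, `[[`, "mass")),
       introduced = unlist(lapply(pops, `[[`, "introduced")),
       h1 = do.call(rbind, lapply(pops, `[[`, "h1")),
       h2 = do.call(rbind, lapply(pops, `[[`, "h2")),
       phen = do.call(rbind, lapply(pops, `[[`, "phen")),
       at = unlist(lapply(pops, `[[`, "at")),
       ap = unlist(lapply(pops, `[[`, "ap")))
}

# total biomass per patch, as a full-length vector over all patches;
# optionally restricted to a subset of individuals
pop_biomass_by_patch <- function(pop, n_patches, idx = NULL) {
  out <- numeric(n_patches)
  mass <- pop$mass
  patch <- pop$patch
  if (!is.null(idx)) {
    mass <- mass[idx]
    patch <- patch[idx]
  }
  if (length(mass) == 0L) return(out)
  bm <- rowsum(mass, patch)
  out[as.integer(rownames(bm))] <- bm[, 1]
  out
}

# vectorized individual creation: one per entry of species_idx. Per trait one
# normal deviate around the species mean (sd = cv * |mean|), clamped, written
# homozygously to every gene coding for the trait.
spawn_cohort <- function(pool, species_idx, cv, arch,
                         stage = c("seed", "adult"), patch = NA_integer_,
                         introduced = FALSE) {
  stage <- match.arg(stage)
  n <- length(species_idx)
  if (n == 0L) return(pop_empty(arch))
  means <- as.matrix(pool[species_idx, TRAIT_NAMES, drop = FALSE])
  vals <- means + matrix(rnorm(n * ncol(means)), n) * (cv * abs(means))
  vals <- clamp_trait_matrix(vals)
  h <- vals[, arch$trait, drop = FALSE]
  dimnames(h) <- NULL
  phen <- express_phenotype_matrix(h, h, arch)
  list(species = as.integer(species_idx),
       patch = rep_len(as.integer(patch), n),
       mass = if (stage == "seed") phen[, "seed_mass"]
              else phen[, "adult_mass"],
       introduced = rep_len(introduced, n),
       h1 = h,
       h2 = h,
       phen = phen,
       at = rep(NA_real_, n),
       ap = rep(NA_real_, n))
}
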