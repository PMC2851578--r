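## Forward-in-time population simulation.
##
## A population is a set of phased haplotypes: an integer matrix with
## entries in {0, 1}, one row per haplotype, one column per locus.  Rows
## 2i - 1 and 2i are the two haplotypes of individual i.  The genome is a
## fixed grid of equally spaced loci on equally sized chromosomes of
## 1 Morgan each.

#' Simulation configuration
#'
#' Parameters of the forward simulation: genome layout, base-population
#' polymorphism, population size, mutation rate and number of drift
#' generations.  Defaults describe a 4-Morgan genome of 40,000 loci with
#' 4,000 biallelic base loci at frequency 0.5, a population of 100
#' individuals in which each parent contributes exactly two gametes per
#' generation (effective size 2N - 1 = 199), per-locus mutation rate 1e-5
#' and 5,000 generations of drift to reach mutation-drift equilibrium.
#'
#' @param n_chromosomes number of chromosomes (1 Morgan each).
#' @param loci_per_chromosome equally spaced loci per chromosome.
#' @param n_biallelic_base number of base-population biallelic loci,
#'   placed deterministically at every \code{(total loci / n_biallelic_base)}-th
#'   locus along the genome.
#' @param base_allele_freq allele-1 frequency of biallelic base loci.
#' @param population_size number of diploid individuals, N.
#' @param mutation_rate per-locus, per-transmitted-gamete flip rate u.
#' @param n_drift_generations generations of drift before the training
#'   generation.
#' @param training_family_size full-sib family size in the training
#'   generation (10 gives 500 training individuals, 20 gives 1,000).
#' @param allow_selfing logical; gametes are paired by uniform random
#'   union (selfing possible), the scheme under which equal parental
#'   contributions give Ne = 2N - 1.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_chromosomes = 4L,
                       loci_per_chromosome = 10000L,
                       n_biallelic_base = 4000L,
                       base_allele_freq = 0.5,
                       population_size = 100L,
                       mutation_rate = 1e-5,
                       n_drift_generations = 5000L,
                       training_family_size = 10L,
                       allow_selfing = TRUE) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    n_biallelic_base = as.integer(n_biallelic_base),
    base_allele_freq = base_allele_freq,
    population_size = as.integer(population_size),
    mutation_rate = mutation_rate,
    n_drift_generations = as.integer(n_drift_generations),
    training_family_size = as.integer(training_family_size),
    allow_selfing = isTRUE(allow_selfing)
  )
  stopifnot(
    cfg$n_chromosomes >= 1L, cfg$loci_per_chromosome >= 1L,
    cfg$n_biallelic_base >= 0L,
    cfg$n_biallelic_base <= cfg$n_chromosomes * cfg$loci_per_chromosome,
    cfg$base_allele_freq > 0, cfg$base_allele_freq < 1,
    cfg$population_size >= 2L,
    cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
    cfg$n_drift_generations >= 0L,
    cfg$training_family_size >= 1L
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Forward simulation configuration\n")
  cat(sprintf("  genome: %d chromosomes x %d loci (1 Morgan each)\n",
              x$n_chromosomes, x$loci_per_chromosome))
  cat(sprintf("  base biallelic loci: %d at frequency %.2f\n",
              x$n_biallelic_base, x$base_allele_freq))
  cat(sprintf("  N = %d, u = %g, %d drift generations, Ne = %d\n",
              x$population_size, x$mutation_rate, x$n_drift_generations,
              effective_size(x)))
  invisible(x)
}

#' Effective population size under equal parental contributions
#'
#' With every parent contributing exactly two gametes the variance of
#' contributions is zero and the effective size is 2N - 1.
#'
#' @param config a \code{sim_config}.
#' @return integer effective size Ne.
#' @export
effective_size <- function(config) 2L * config$population_size - 1L

#' Genetic map of the simulated genome
#'
#' @param config a \code{sim_config}.
#' @return data.frame with columns \code{locus_id} (1-based, genome order),
#'   \code{chromosome} and \code{position} (Morgan within chromosome,
#'   equally spaced in [0, 1)).
#' @export
locus_map <- function(config = sim_config()) {
  lpc <- config$loci_per_chromosome
  nc <- config$n_chromosomes
  data.frame(
    locus_id = seq_len(nc * lpc),
    chromosome = rep(seq_len(nc), each = lpc),
    position = rep((seq_len(lpc) - 1) / lpc, times = nc)
  )
}

#' Indices of the base-population biallelic loci
#'
#' Deterministic placement: loci 1, 1 + s, 1 + 2s, ... with spacing
#' s = total loci / n_biallelic_base ("equally distributed over the
#' genome").
#'
#' @param config a \code{sim_config}.
#' @return integer vector of locus ids.
#' @export
base_biallelic_loci <- function(config = sim_config()) {
  L <- config$n_chromosomes * config$loci_per_chromosome
  if (config$n_biallelic_base == 0L) return(integer(0))
  spacing <- L / config$n_biallelic_base
  as.integer(floor((seq_len(config$n_biallelic_base) - 1) * spacing)) + 1L
}

new_haplotype_set <- function(alleles, generation = 0L) {
  stopifnot(is.matrix(alleles), nrow(alleles) %% 2 == 0)
  structure(list(alleles = alleles, generation = as.integer(generation)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d individuals x %d loci (generation %d)\n",
              n_individuals(x), ncol(x$alleles), x$generation))
  invisible(x)
}

#' Number of individuals in a haplotype set
#' @param pop a \code{haplotype_set}.
#' @return integer.
#' @export
n_individuals <- function(pop) nrow(pop$alleles) %/% 2L

#' Genotype dosage matrix
#'
#' Collapses phased haplotypes into allele-1 dosages.
#'
#' @param pop a \code{haplotype_set}.
#' @param loci optional locus ids (columns) to keep.
#' @return integer matrix, individuals x loci, entries 0/1/2.
#' @export
genotype_matrix <- function(pop, loci = NULL) {
  a <- pop$alleles
  if (!is.null(loci)) a <- a[, loci, drop = FALSE]
  odd <- seq(1L, nrow(a), by = 2L)
  g <- a[odd, , drop = FALSE] + a[odd + 1L, , drop = FALSE]
  storage.mode(g) <- "integer"
  if (!is.null(loci)) colnames(g) <- as.character(loci)
  g
}

#' Allele-1 frequencies
#' @param pop a \code{haplotype_set}.
#' @param loci optional locus ids.
#' @return numeric vector of per-locus allele-1 frequencies.
#' @export
allele_frequencies <- function(pop, loci = NULL) {
  a <- pop$alleles
  if (!is.null(loci)) a <- a[, loci, drop = FALSE]
  colMeans(a)
}

#' Initialize the base population
#'
#' Base haplotypes are in linkage equilibrium: at each designated
#' biallelic locus every haplotype carries allele 1 independently with the
#' base frequency; all other loci are monomorphic 0.
#'
#' @param config a \code{sim_config}.
#' @param seed optional integer seed (uses the current RNG state if NULL).
#' @return a \code{haplotype_set} at generation 0.
#' @export
init_base_population <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- 2L * config$population_size
  L <- config$n_chromosomes * config$loci_per_chromosome
  alleles <- matrix(0L, nrow = H, ncol = L)
  bi <- base_biallelic_loci(config)
  if (length(bi))
    alleles[, bi] <- matrix(
      as.integer(runif(H * length(bi)) < config$base_allele_freq),
      nrow = H)
  new_haplotype_set(alleles, generation = 0L)
}

#' Sample one gamete from a parent
#'
#' Recombination: per chromosome the crossover count is Poisson(1)
#' (chromosomes are 1 Morgan), crossover positions are uniform with no
#' interference, and the starting strand is chosen with probability 1/2.
#' The gamete is the resulting mosaic of the two parental haplotypes; the
#' strand switches at the first locus whose position exceeds a crossover.
#'
#' @param parent_alleles 2 x L matrix, the parent's two haplotypes.
#' @param map genetic map as returned by [locus_map()].
#' @param crossovers optional list (one element per chromosome) of fixed
#'   crossover positions in Morgan, for deterministic testing.
#' @param start_strand optional integer vector (1 or 2 per chromosome)
#'   fixing the starting strand.
#' @return integer vector of length L.
#' @export
sample_gamete <- function(parent_alleles, map, crossovers = NULL,
                          start_strand = NULL) {
  stopifnot(nrow(parent_alleles) == 2L, ncol(parent_alleles) == nrow(map))
  blocks <- chrom_blocks(map)
  gamete_mosaic(parent_alleles[1L, ], parent_alleles[2L, ], blocks,
                crossovers = crossovers, start_strand = start_strand)
}

# Precompute per-chromosome locus indices and positions from a map.
chrom_blocks <- function(map) {
  chroms <- unique(map$chromosome)
  lapply(chroms, function(ch) {
    idx <- which(map$chromosome == ch)
    list(idx = idx, pos = map$position[idx])
  })
}

# Mosaic of two haplotype vectors; shared by sample_gamete and
# make_families (which precomputes the blocks once per generation).
gamete_mosaic <- function(hapA, hapB, blocks, crossovers = NULL,
                          start_strand = NULL) {
  gamete <- hapA
  for (ci in seq_along(blocks)) {
    idx <- blocks[[ci]]$idx
    pos <- blocks[[ci]]$pos
    cx <- if (is.null(crossovers)) runif(rpois(1L, 1)) else crossovers[[ci]]
    s0 <- if (is.null(start_strand)) 1L + (runif(1L) < 0.5) else start_strand[ci]
    if (length(cx)) {
      cx <- sort(cx)
      # segment index of each locus: number of crossovers at position < pos
      seg <- findInterval(pos, cx, left.open = TRUE)
      take2 <- (s0 - 1L + seg) %% 2L == 1L
    } else {
      if (s0 == 1L) next
      take2 <- TRUE
    }
    sel <- idx[take2]
    gamete[sel] <- hapB[sel]
  }
  gamete
}

#' Apply mutations to a gamete
#'
#' Each locus is flipped (0 to 1, 1 to 0) independently with probability
#' \code{u}, implemented by drawing a Poisson(u L) flip count with uniform
#' positions; a position drawn twice is flipped twice, restoring the
#' allele.
#'
#' @param gamete integer 0/1 vector.
#' @param u per-locus mutation rate.
#' @return mutated gamete.
#' @export
apply_mutations <- function(gamete, u) {
  stopifnot(u >= 0)
  if (u == 0) return(gamete)
  L <- length(gamete)
  n_mut <- rpois(1L, u * L)
  if (n_mut == 0L) return(gamete)
  pos <- floor(runif(n_mut) * L) + 1L
  flips <- tabulate(pos, nbins = L) %% 2L
  as.integer((gamete + flips) %% 2L)
}

#' One generation of drift
#'
#' Every parent contributes exactly two gametes (zero contribution
#' variance, hence Ne = 2N - 1); gametes are mutated at rate \code{u} and
#' paired by uniform random union into N offspring.
#'
#' @param pop a \code{haplotype_set} with the configured number of
#'   individuals (100 in the standard setting).
#' @param config a \code{sim_config}; \code{pop} must match
#'   \code{config$population_size}.
#' @param u per-locus mutation rate (defaults to the configured rate).
#' @return offspring \code{haplotype_set}.
#' @export
next_generation_drift <- function(pop, config = sim_config(),
                                  u = config$mutation_rate) {
  if (n_individuals(pop) != config$population_size)
    stop("population size does not match configuration")
  res <- drift_phase_cpp(pop$alleles, 1L, u, config$n_chromosomes,
                         config$loci_per_chromosome, config$allow_selfing)
  new_haplotype_set(res$alleles, generation = pop$generation + 1L)
}

#' Run the drift phase to mutation-drift equilibrium
#'
#' Simulates \code{config$n_drift_generations} generations of
#' recombination, mutation and random union of gametes starting from the
#' linkage-equilibrium base population, and records the mean observed
#' heterozygosity of every generation.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return list with \code{pop} (the final \code{haplotype_set}),
#'   \code{heterozygosity} (per-generation trajectory) and \code{base}
#'   (the generation-0 \code{haplotype_set}).
#' @export
run_drift_phase <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  base <- init_base_population(config)
  res <- drift_phase_cpp(base$alleles, config$n_drift_generations,
                         config$mutation_rate, config$n_chromosomes,
                         config$loci_per_chromosome, config$allow_selfing)
  list(pop = new_haplotype_set(res$alleles,
                               generation = config$n_drift_generations),
       heterozygosity = as.numeric(res$heterozygosity),
       base = base)
}

# Random monogamous pairing of parents followed by full-sib family
# production; mutation rate 0 (families are produced after equilibrium).
make_families <- function(pop, map, couples, n_offspring_per_couple) {
  a <- pop$alleles
  blocks <- chrom_blocks(map)
  n_fam <- nrow(couples)
  n_off <- n_fam * n_offspring_per_couple
  off <- matrix(0L, nrow = 2L * n_off, ncol = ncol(a))
  sire_v <- integer(n_off); dam_v <- integer(n_off); fam_v <- integer(n_off)
  k <- 0L
  for (f in seq_len(n_fam)) {
    sire <- couples[f, 1L]; dam <- couples[f, 2L]
    sA <- a[2L * sire - 1L, ]; sB <- a[2L * sire, ]
    dA <- a[2L * dam - 1L, ]; dB <- a[2L * dam, ]
    for (j in seq_len(n_offspring_per_couple)) {
      k <- k + 1L
      off[2L * k - 1L, ] <- gamete_mosaic(sA, sB, blocks)
      off[2L * k, ] <- gamete_mosaic(dA, dB, blocks)
      sire_v[k] <- sire; dam_v[k] <- dam; fam_v[k] <- f
    }
  }
  ped <- data.frame(id = seq_len(n_off), sire = sire_v, dam = dam_v,
                    family = fam_v)
  list(pop = new_haplotype_set(off, generation = pop$generation + 1L),
       pedigree = ped)
}

#' Create the training generation
#'
#' The parents of the final drift generation are randomly paired into
#' monogamous couples; each couple produces \code{family_size} full-sib
#' offspring (family size 10 gives 50 families of 10 = 500 individuals).
#' Mutation rate is 0 in this and the following generation, so no new
#' low-frequency alleles appear after equilibrium.
#'
#' @param pop final drift-phase \code{haplotype_set}.
#' @param config a \code{sim_config}.
#' @param family_size offspring per couple (10 or 20).
#' @return list with \code{pop} and \code{pedigree} (columns id, sire,
#'   dam, family).
#' @export
make_training_generation <- function(pop, config = sim_config(),
                                     family_size = config$training_family_size) {
  n <- n_individuals(pop)
  if (n %% 2L != 0L) stop("parent count must be even")
  map <- locus_map(config)
  perm <- sample.int(n)
  couples <- cbind(perm[seq(1L, n, by = 2L)], perm[seq(2L, n, by = 2L)])
  make_families(pop, map, couples, family_size)
}

#' Create the evaluation generation
#'
#' Training individuals are paired into monogamous couples of 2 offspring
#' each, yielding 250 full-sib families of 2 (500 individuals) from 500
#' training parents.  When the training generation is larger than 500
#' (family size 20), 500 of its individuals are sampled as parents so the
#' evaluation population stays at 500.
#'
#' @param training list with \code{pop} and \code{pedigree}, from
#'   [make_training_generation()].
#' @param config a \code{sim_config}.
#' @param n_parents number of training individuals used as parents.
#' @return list with \code{pop} and \code{pedigree}.
#' @export
make_evaluation_generation <- function(training, config = sim_config(),
                                       n_parents = 500L) {
  pop <- training$pop
  n <- n_individuals(pop)
  n_parents <- min(n_parents, n)
  if (n_parents %% 2L != 0L) stop("parent count must be even")
  map <- locus_map(config)
  parents <- if (n > n_parents) sort(sample.int(n, n_parents)) else seq_len(n)
  perm <- sample(parents)
  couples <- cbind(perm[seq(1L, n_parents, by = 2L)],
                   perm[seq(2L, n_parents, by = 2L)])
  make_families(pop, map, couples, 2L)
}

#' Simulate one complete replicate population
#'
#' Runs the drift phase, then builds the training and evaluation
#' generations.  Deterministic given the seed.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @return list with \code{base}, \code{pop5000}, \code{training},
#'   \code{evaluation}, \code{heterozygosity} (drift trajectory),
#'   \code{map} and \code{config}.
#' @export
simulate_replicate <- function(config = sim_config(), seed = 1L) {
  drift <- run_drift_phase(config, seed = seed)
  set.seed(derive_seed(seed, 5001L))
  training <- make_training_generation(drift$pop, config)
  set.seed(derive_seed(seed, 5002L))
  evaluation <- make_evaluation_generation(training, config)
  list(base = drift$base, pop5000 = drift$pop, training = training,
       evaluation = evaluation, heterozygosity = drift$heterozygosity,
       map = locus_map(config), config = config)
}
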