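# Shared fixtures.  Everything is generated in code; the full-scale
# simulations used by the acceptance tests are cached per test run so
# several criteria can share replicates without re-simulating.

# Small genome for unit tests: 2 chromosomes x 50 loci.
toy_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, loci_per_chromosome = 50L,
         n_biallelic_base = 20L, population_size = 20L,
         mutation_rate = 1e-3, n_drift_generations = 20L,
         training_family_size = 4L),
    list(...))
  do.call(sim_config, args)
}

# Mid-sized world able to feed the whole pipeline quickly: enough
# eligible loci for QTL selection after a short drift phase.
pipeline_config <- function(...) {
  sim_config(n_chromosomes = 2L, loci_per_chromosome = 500L,
             n_biallelic_base = 200L, population_size = 40L,
             mutation_rate = 1e-4, n_drift_generations = 150L,
             training_family_size = 10L, ...)
}

toy_map <- function(n_chromosomes = 1L, loci_per_chromosome = 10L) {
  locus_map(sim_config(n_chromosomes = n_chromosomes,
                       loci_per_chromosome = loci_per_chromosome,
                       n_biallelic_base = 0L,
                       population_size = 2L))
}

# Hardy-Weinberg dosage matrix at given allele frequencies.
hw_genotypes <- function(n, p) {
  vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
}

# ---- cache of full-scale replicates for the acceptance tests ----------

.accept_cache <- new.env(parent = emptyenv())

# Full-scale replicate plus everything the acceptance criteria reuse,
# reduced to a compact summary so ten replicates fit in memory.  BM
# chains are shortened to 4,000 iterations / 400 burn-in, the reduced
# scale the acceptance protocol allows.
accept_bundle <- function(i, need_lars = i <= 5L) {
  key <- paste0("rep", i)
  if (!is.null(.accept_cache[[key]])) return(.accept_cache[[key]])
  simc <- sim_config()
  bmc <- bm_config(n_iter = 4000L, burn_in = 400L)
  rep <- simulate_replicate(simc, seed = i)
  set.seed(derive_seed(i, 11L))
  freq <- allele_frequencies(rep$training$pop)
  qs <- select_qtl_sets(freq)
  diag <- replicate_diagnostics(rep, qs)
  diag$het_plateau <- mean(rep$heterozygosity[4000:5000])
  cfg <- run_config(scenarios = c(1L, 3L), methods = c("BM", "PLSR"),
                    bm = bmc, seed = i)
  res <- run_replicate(cfg, i, replicate = rep)
  if (need_lars) {
    cfg2 <- run_config(scenarios = 1L, methods = "LARS", seed = i)
    res <- rbind(res, run_replicate(cfg2, i, replicate = rep))
  }
  out <- list(diag = diag, results = res)
  .accept_cache[[key]] <- out
  out
}
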