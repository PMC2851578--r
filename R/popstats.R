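## Population diagnostics: heterozygosity (observed and the mutation-drift
## expectation), linkage disequilibrium between adjacent markers, Sved's
## expected r2, and the coefficient of determination of QTL by their
## best markers.

#' Expected heterozygosity at mutation-drift equilibrium
#'
#' Closed form H = 4 Ne u / (1 + 4 Ne u) for an infinite-alleles-like
#' balance between mutation gain and drift loss of heterozygosity.
#'
#' @param u per-locus mutation rate.
#' @param Ne effective population size.
#' @return expected per-locus heterozygosity (fraction).
#' @export
expected_heterozygosity <- function(u, Ne) {
  stopifnot(u >= 0, Ne > 0)
  4 * Ne * u / (1 + 4 * Ne * u)
}

#' Observed heterozygosity of a population
#'
#' Average over individuals of the number of loci at which the two
#' haplotypes of an individual differ.
#'
#' @param pop a \code{haplotype_set}.
#' @return list with \code{fraction} (per-locus) and \code{count}
#'   (average number of heterozygous loci per individual).
#' @export
observed_heterozygosity <- function(pop) {
  frac <- observed_het_cpp(pop$alleles)
  list(fraction = frac, count = frac * ncol(pop$alleles))
}

#' Sved's expected LD
#'
#' Expected squared correlation between neutral loci at recombination
#' distance c Morgan in a population of effective size Ne:
#' E[r2] = 1 / (1 + 4 Ne c).
#'
#' @param Ne effective population size.
#' @param c recombination distance in Morgan.
#' @return expected r2.
#' @export
sved_expected_ld <- function(Ne, c) {
  stopifnot(Ne > 0, all(c >= 0))
  1 / (1 + 4 * Ne * c)
}

# Squared correlations between consecutive columns of a 0/1 haplotype (or
# dosage) matrix; NA for pairs involving a constant column.
adjacent_r2 <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  k <- ncol(m)
  if (k < 2L) return(numeric(0))
  cross <- colMeans(m[, -k, drop = FALSE] * m[, -1L, drop = FALSE])
  covs <- cross - mu[-k] * mu[-1L]
  denom <- v[-k] * v[-1L]
  r2 <- ifelse(denom > 0, covs^2 / denom, NA_real_)
  r2
}

#' Linkage disequilibrium between adjacent markers
#'
#' For every pair of markers adjacent within a chromosome, the squared
#' Pearson correlation of allele indicators across haplotypes (gametic
#' LD; phase is known in simulation).  Pairs spanning chromosome
#' boundaries are excluded and pairs with a monomorphic member skipped.
#'
#' @param pop a \code{haplotype_set} (or, with \code{use = "genotype"},
#'   correlations are computed on 0/1/2 dosages instead).
#' @param marker_indices locus ids of the markers, in genome order.
#' @param map genetic map from [locus_map()].
#' @param use "haplotype" (default) or "genotype".
#' @param subset label stored in the summary (e.g. "all", "MAF>0.10").
#' @return object of class \code{ld_summary}: list with \code{mean_r2},
#'   \code{n_pairs}, \code{r2} (per-pair values) and \code{subset}.
#' @export
adjacent_ld <- function(pop, marker_indices, map,
                        use = c("haplotype", "genotype"), subset = "all") {
  use <- match.arg(use)
  marker_indices <- sort(marker_indices)
  m <- if (use == "haplotype") pop$alleles[, marker_indices, drop = FALSE]
       else genotype_matrix(pop, marker_indices)
  chrom <- map$chromosome[marker_indices]
  r2 <- adjacent_r2(m)
  same_chrom <- chrom[-length(chrom)] == chrom[-1L]
  r2 <- r2[same_chrom]
  r2 <- r2[!is.na(r2)]
  structure(list(mean_r2 = if (length(r2)) mean(r2) else NA_real_,
                 n_pairs = length(r2), r2 = r2, subset = subset),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("ld_summary [%s]: mean r2 = %.4f over %d adjacent pairs\n",
              x$subset, x$mean_r2, x$n_pairs))
  invisible(x)
}

#' LD among surviving founder markers
#'
#' Restricts to the base-generation biallelic loci that are still
#' polymorphic in the final generation and computes adjacent-marker LD on
#' that subset.  Because no newly mutated locus can fall between two
#' surviving founder markers in this subset, the result is comparable to
#' Sved's expectation.
#'
#' @param final_pop \code{haplotype_set} of the final generation.
#' @param config a \code{sim_config} (identifies the founder biallelic
#'   loci).
#' @param map genetic map.
#' @return an \code{ld_summary} with an extra element
#'   \code{n_surviving}; empty summary if fewer than 2 loci survive.
#' @export
founder_surviving_ld <- function(final_pop, config = sim_config(),
                                 map = locus_map(config)) {
  base_loci <- base_biallelic_loci(config)
  freq <- allele_frequencies(final_pop, base_loci)
  surviving <- base_loci[freq > 0 & freq < 1]
  if (length(surviving) < 2L) {
    out <- structure(list(mean_r2 = NA_real_, n_pairs = 0L, r2 = numeric(0),
                          subset = "founder-surviving"), class = "ld_summary")
    out$n_surviving <- length(surviving)
    return(out)
  }
  out <- adjacent_ld(final_pop, surviving, map, subset = "founder-surviving")
  out$n_surviving <- length(surviving)
  out
}

# Greedy pruning: markers ordered by descending LD with the QTL; a marker
# is kept unless its absolute correlation with an already kept marker
# exceeds the threshold (first kept wins; order ties broken by locus index
# through the initial sort).
prune_correlated <- function(K, order_idx, threshold) {
  kept <- integer(0)
  for (j in order_idx) {
    if (!length(kept) || all(abs(K[j, kept]) <= threshold))
      kept <- c(kept, j)
  }
  kept
}

#' Coefficient of determination of QTL by their best markers
#'
#' For each QTL, markers are ranked by squared (haplotype) correlation
#' with the QTL; the \code{top_k} best are taken and greedily pruned so
#' that no retained pair has absolute correlation above
#' \code{prune_threshold} (the marker in higher LD with the QTL wins).
#' With c the vector of marker-QTL correlations and K the retained
#' markers' correlation matrix, R2 = c' K^-1 c, the proportion of QTL
#' variance explained by the markers -- an upper bound on achievable
#' prediction accuracy squared.
#'
#' @param pop training-generation \code{haplotype_set}.
#' @param qtl_indices locus ids of the QTL.
#' @param marker_indices locus ids of the markers.
#' @param top_k number of highest-LD markers per QTL.
#' @param prune_threshold absolute-correlation cut-off.
#' @return object of class \code{qtl_r2_report}: list with
#'   \code{per_qtl}, \code{mean_r2}, \code{top_k},
#'   \code{prune_threshold}.
#' @export
qtl_r2 <- function(pop, qtl_indices, marker_indices, top_k = 50L,
                   prune_threshold = 0.95) {
  H <- pop$alleles
  Mm <- H[, marker_indices, drop = FALSE]
  Qm <- H[, qtl_indices, drop = FALSE]
  keep_m <- apply(Mm, 2L, function(x) var(x) > 0)
  Mm <- Mm[, keep_m, drop = FALSE]
  if (!ncol(Mm)) stop("no polymorphic markers")
  cq <- suppressWarnings(cor(Mm, Qm))   # markers x QTL
  per_qtl <- rep(NA_real_, length(qtl_indices))
  for (q in seq_along(qtl_indices)) {
    cvec <- cq[, q]
    if (all(is.na(cvec))) next
    ord <- order(cvec^2, decreasing = TRUE)
    top <- ord[seq_len(min(top_k, length(ord)))]
    K <- cor(Mm[, top, drop = FALSE])
    kept_local <- prune_correlated(K, order(cvec[top]^2, decreasing = TRUE),
                                   prune_threshold)
    repeat {
      Ksub <- K[kept_local, kept_local, drop = FALSE]
      csub <- cvec[top][kept_local]
      sol <- tryCatch(solve(Ksub, csub), error = function(e) NULL)
      if (!is.null(sol)) {
        per_qtl[q] <- sum(csub * sol)
        break
      }
      if (length(kept_local) <= 1L) { per_qtl[q] <- csub[1L]^2; break }
      kept_local <- kept_local[-length(kept_local)]  # drop weakest, retry
    }
  }
  structure(list(per_qtl = per_qtl,
                 mean_r2 = mean(per_qtl, na.rm = TRUE),
                 top_k = top_k, prune_threshold = prune_threshold),
            class = "qtl_r2_report")
}

#' @export
print.qtl_r2_report <- function(x, ...) {
  cat(sprintf("qtl_r2_report: mean R2 = %.3f over %d QTL (top %d markers, prune %.2f)\n",
              x$mean_r2, length(x$per_qtl), x$top_k, x$prune_threshold))
  invisible(x)
}

#' Replicate diagnostics table
#'
#' One-row summary of a simulated replicate mirroring the standard
#' population-diagnostics layout: observed and expected heterozygosity,
#' marker counts, adjacent-marker r2 by subset, Sved expectations and the
#' mean QTL R2 for a given QTL set.
#'
#' @param replicate output of [simulate_replicate()].
#' @param qtl_sets output of [select_qtl_sets()] (optional; computed on
#'   the training generation when NULL with a fresh RNG draw).
#' @return data.frame with one row.
#' @export
replicate_diagnostics <- function(replicate, qtl_sets = NULL) {
  cfg <- replicate$config
  map <- replicate$map
  Ne <- effective_size(cfg)
  freq <- allele_frequencies(replicate$training$pop)
  if (is.null(qtl_sets)) qtl_sets <- select_qtl_sets(freq)
  markers <- build_marker_set(freq, qtl_sets$high)
  markers_maf <- build_marker_set(freq, qtl_sets$high, maf_filter = 0.10)
  het <- observed_heterozygosity(replicate$pop5000)
  ld_all <- adjacent_ld(replicate$training$pop, markers$marker_indices, map)
  ld_maf <- adjacent_ld(replicate$training$pop, markers_maf$marker_indices,
                        map, subset = "MAF>0.10")
  ld_founder <- founder_surviving_ld(replicate$pop5000, cfg, map)
  r2rep <- qtl_r2(replicate$training$pop, qtl_sets$high,
                  markers$marker_indices)
  data.frame(
    H_observed = het$fraction,
    H_expected = expected_heterozygosity(cfg$mutation_rate, Ne),
    n_markers = length(markers$marker_indices),
    n_markers_maf = length(markers_maf$marker_indices),
    r2_all = ld_all$mean_r2,
    r2_maf = ld_maf$mean_r2,
    r2_founder = ld_founder$mean_r2,
    n_founder_surviving = ld_founder$n_surviving,
    sved_all = sved_expected_ld(Ne, cfg$n_chromosomes /
                                  max(length(markers$marker_indices), 1L)),
    sved_founder = sved_expected_ld(Ne, cfg$n_chromosomes /
                                      max(ld_founder$n_surviving, 1L)),
    n_qtl_high = length(qtl_sets$high),
    qtl_R2 = r2rep$mean_r2
  )
}
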