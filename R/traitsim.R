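## QTL architecture and trait simulation.
##
## QTL are assigned in the training generation, after the population has
## been simulated, so that the realized number of QTL is controlled and
## identical loci serve as QTL in the equal- and unequal-variance
## scenarios.  Six standard scenarios combine three QTL fractions (5%,
## 25%, 50% of loci with MAF > 0.10) with two variance modes (all QTL
## variance 1, or every tenth QTL variance 81).

#' Minor allele frequency
#' @param freq allele-1 frequencies.
#' @return pmin(freq, 1 - freq).
#' @export
minor_allele_frequency <- function(freq) pmin(freq, 1 - freq)

#' Select nested QTL sets
#'
#' Eligible loci are those with training-generation MAF strictly greater
#' than \code{maf_threshold}.  The high set is a uniform random 50% of the
#' eligible loci; the intermediate set is 25% of the eligible count drawn
#' from the high set; the low set is 5% drawn from the intermediate set.
#' Nesting guarantees that scenarios differing only in QTL fraction share
#' their smaller QTL sets.
#'
#' @param training_freq allele-1 frequencies in the training generation
#'   (vector over all loci).
#' @param fractions QTL fractions of the eligible count, smallest first.
#' @param maf_threshold MAF cut-off for eligibility.
#' @return list with \code{low}, \code{intermediate}, \code{high} (sorted
#'   locus ids) and \code{eligible} (eligible locus ids); for
#'   non-standard \code{fractions} the names are \code{set1}, ... plus
#'   \code{eligible}.
#' @export
select_qtl_sets <- function(training_freq, fractions = c(0.05, 0.25, 0.50),
                            maf_threshold = 0.10) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions))
  eligible <- which(minor_allele_frequency(training_freq) > maf_threshold)
  if (length(eligible) < 20L)
    stop("fewer than 20 loci with MAF above threshold; replicate rejected")
  counts <- round(fractions * length(eligible))
  counts <- pmax(counts, 1L)
  k <- length(fractions)
  sets <- vector("list", k)
  # draw the largest set, then subsample downwards to nest
  sets[[k]] <- sort(sample(eligible, counts[k]))
  if (k > 1L)
    for (j in seq(k - 1L, 1L))
      sets[[j]] <- sort(sample(sets[[j + 1L]], counts[j]))
  names(sets) <- if (k == 3L) c("low", "intermediate", "high")
                 else paste0("set", seq_len(k))
  c(sets, list(eligible = eligible))
}

#' Assign per-QTL variances
#'
#' In \code{"equal"} mode every QTL gets variance 1.  In \code{"unequal"}
#' mode every tenth QTL in ascending genome order (ranks 10, 20, ...) gets
#' variance 81 and the rest variance 1, so 10% of the QTL carry 90% of the
#' specified additive variance.
#'
#' @param qtl_indices sorted locus ids of the QTL.
#' @param variance_mode "equal" or "unequal".
#' @return numeric vector of per-QTL variances.
#' @export
assign_variances <- function(qtl_indices, variance_mode = c("equal", "unequal")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(!is.unsorted(qtl_indices))
  n <- length(qtl_indices)
  Vq <- rep(1, n)
  if (variance_mode == "unequal" && n >= 10L) {
    big <- seq(10L, n, by = 10L)
    Vq[big] <- 81
  }
  Vq
}

#' Additive allele-substitution effects from specified QTL variances
#'
#' With 0/1/2 dosage coding and Hardy-Weinberg frequencies, a locus with
#' allele frequency p and substitution effect a contributes additive
#' variance 2 p (1 - p) a^2; the effect magnitude is therefore
#' \code{sqrt(Vq / (2 p (1 - p)))}.  The sign of each effect is random
#' (+1 or -1 with probability 1/2).
#'
#' @param Vq per-QTL specified variances.
#' @param p per-QTL allele-1 frequencies in the training generation.
#' @param signs optional fixed sign vector (+1/-1) overriding the random
#'   draw.
#' @return numeric vector of signed effects.
#' @export
compute_effects <- function(Vq, p, signs = NULL) {
  stopifnot(length(Vq) == length(p))
  if (any(p <= 0 | p >= 1))
    stop("monomorphic QTL are not allowed (p must be in (0,1))")
  if (is.null(signs)) signs <- sample(c(-1, 1), length(Vq), replace = TRUE)
  stopifnot(length(signs) == length(Vq), all(signs %in% c(-1, 1)))
  signs * sqrt(Vq / (2 * p * (1 - p)))
}

#' True breeding values
#'
#' The TBV of an individual is the sum of its QTL dosages weighted by the
#' allele-substitution effects.
#'
#' @param qtl_dosages individuals x QTL dosage matrix (0/1/2).
#' @param effects per-QTL effects.
#' @return numeric vector of TBV.
#' @export
compute_tbv <- function(qtl_dosages, effects) {
  if (ncol(qtl_dosages) != length(effects))
    stop("dosage columns and effect length differ")
  drop(qtl_dosages %*% effects)
}

#' Build a QTL scenario on a simulated replicate
#'
#' @param qtl_indices sorted locus ids of the QTL of this scenario.
#' @param training_freq allele-1 frequencies over all loci in the
#'   training generation.
#' @param variance_mode "equal" or "unequal".
#' @param scenario_id integer label.
#' @param signs optional fixed effect signs.
#' @return object of class \code{qtl_scenario}: list with
#'   \code{qtl_indices}, \code{Vq}, \code{effects}, \code{variance_mode},
#'   \code{scenario_id}.
#' @export
build_qtl_scenario <- function(qtl_indices, training_freq,
                               variance_mode = c("equal", "unequal"),
                               scenario_id = NA_integer_, signs = NULL) {
  variance_mode <- match.arg(variance_mode)
  qtl_indices <- sort(qtl_indices)
  Vq <- assign_variances(qtl_indices, variance_mode)
  p <- training_freq[qtl_indices]
  effects <- compute_effects(Vq, p, signs = signs)
  structure(list(qtl_indices = qtl_indices, Vq = Vq, effects = effects,
                 variance_mode = variance_mode,
                 scenario_id = as.integer(scenario_id)),
            class = "qtl_scenario")
}

#' @export
print.qtl_scenario <- function(x, ...) {
  cat(sprintf("qtl_scenario %s: %d QTL, %s variance (sum Vq = %g)\n",
              x$scenario_id, length(x$qtl_indices), x$variance_mode,
              sum(x$Vq)))
  invisible(x)
}

#' Simulate phenotypes for the training generation
#'
#' The additive genetic variance is the sample variance of the TBV in the
#' training generation; the environmental variance is set from the target
#' heritability, sigma2_e = sigma2_a (1 - h2) / h2, and independent
#' normal deviates are added to the TBV.
#'
#' @param tbv training-generation TBV.
#' @param h2 heritability in (0, 1].
#' @return object of class \code{trait}: list with \code{tbv},
#'   \code{phenotypes}, \code{sigma2_a}, \code{sigma2_e}, \code{h2}.
#' @export
simulate_phenotypes <- function(tbv, h2 = 0.5) {
  stopifnot(h2 > 0, h2 <= 1)
  sigma2_a <- var(tbv)
  if (sigma2_a <= 0) stop("zero additive variance; replicate rejected")
  sigma2_e <- sigma2_a * (1 - h2) / h2
  phen <- tbv + rnorm(length(tbv), 0, sqrt(sigma2_e))
  structure(list(tbv = tbv, phenotypes = phen, sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e, h2 = h2),
            class = "trait")
}

#' @export
print.trait <- function(x, ...) {
  cat(sprintf("trait: n = %d, sigma2_a = %.3g, sigma2_e = %.3g, h2 = %.2f\n",
              length(x$tbv), x$sigma2_a, x$sigma2_e, x$h2))
  invisible(x)
}

#' Build the marker set of a replicate
#'
#' Markers are the polymorphic loci of the training generation that were
#' not selected as QTL in any scenario (i.e. excluding the high-fraction
#' QTL set, of which all smaller sets are subsets), so the marker set is
#' identical across scenarios.  An optional MAF filter additionally drops
#' markers with training-generation MAF below the threshold.
#'
#' @param training_freq allele-1 frequencies over all loci in the
#'   training generation.
#' @param high_qtl_set locus ids of the largest QTL set.
#' @param maf_filter optional MAF threshold (e.g. 0.10); markers with MAF
#'   strictly below it are dropped.
#' @return object of class \code{marker_set}: list with
#'   \code{marker_indices}, \code{maf}.
#' @export
build_marker_set <- function(training_freq, high_qtl_set, maf_filter = NULL) {
  polymorphic <- which(training_freq > 0 & training_freq < 1)
  markers <- setdiff(polymorphic, high_qtl_set)
  maf <- minor_allele_frequency(training_freq[markers])
  if (!is.null(maf_filter)) {
    keep <- maf >= maf_filter
    markers <- markers[keep]
    maf <- maf[keep]
  }
  if (!length(markers)) stop("empty marker set; replicate rejected")
  structure(list(marker_indices = markers, maf = maf), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers (median MAF %.3f)\n",
              length(x$marker_indices), stats::median(x$maf)))
  invisible(x)
}
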