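## Replicate orchestration and evaluation.
##
## A replicate = one simulated population, one shared marker set and QTL
## selection, and one fit per scenario x method x alternative.  Accuracy
## (correlation of MEBV with TBV) and MSEP are computed on the evaluation
## generation; the additive variance entering the unbiasedness check is
## always the TBV variance of the training generation.

#' Accuracy of MEBV
#'
#' Pearson correlation between marker-estimated and true breeding values
#' in the evaluation population.
#'
#' @param mebv,tbv numeric vectors of equal length (at least 3).
#' @return correlation, or NA if either vector is constant.
#' @export
accuracy <- function(mebv, tbv) {
  stopifnot(length(mebv) == length(tbv), length(mebv) >= 3L)
  if (sd(mebv) == 0 || sd(tbv) == 0) return(NA_real_)
  cor(mebv, tbv)
}

#' Mean squared error of prediction
#'
#' @param mebv,tbv numeric vectors of equal length.
#' @return mean((mebv - tbv)^2).
#' @export
msep <- function(mebv, tbv) {
  stopifnot(length(mebv) == length(tbv))
  mean((mebv - tbv)^2)
}

#' Unbiasedness check of MEBV variance
#'
#' If MEBV were unbiased predictors of TBV, var(MEBV) would equal
#' accuracy^2 times the additive variance.  Shrinking estimators give a
#' ratio below 1, inflating estimators above 1.
#'
#' @param mebv,tbv numeric vectors on the evaluation population.
#' @param sigma2_a additive genetic variance (training generation).
#' @return list with \code{var_mebv}, \code{expected} (r2 sigma2_a) and
#'   \code{ratio}.
#' @export
unbiasedness_check <- function(mebv, tbv, sigma2_a) {
  r <- accuracy(mebv, tbv)
  v <- var(mebv)
  expected <- r^2 * sigma2_a
  list(var_mebv = v, expected = expected, ratio = v / expected)
}

#' Standard scenario table
#'
#' The six standard QTL architectures: scenarios 1-3 use the unequal
#' variance mode (every tenth QTL has variance 81) with low (5%),
#' intermediate (25%) and high (50%) QTL fractions; scenarios 4-6 repeat
#' the fractions with equal variance.
#'
#' @return data.frame with columns scenario_id, qtl_fraction (as the set
#'   name), variance_mode.
#' @export
scenario_table <- function() {
  data.frame(
    scenario_id = 1:6,
    qtl_set = rep(c("low", "intermediate", "high"), 2L),
    variance_mode = rep(c("unequal", "equal"), each = 3L)
  )
}

#' Run configuration for a simulation experiment
#'
#' @param n_replicates number of replicates.
#' @param scenarios subset of 1..6.
#' @param methods estimation methods to run.
#' @param alternative one of "standard", "h2_0.25", "maf_filter",
#'   "ntr_1000" (alternatives are run one at a time against the
#'   standard situation).
#' @param h2 heritability of the standard situation.
#' @param sim a [sim_config()].
#' @param bm a [bm_config()].
#' @param seed root seed.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(n_replicates = 1L, scenarios = 1:6,
                       methods = c("BM", "LARS", "PLSR"),
                       alternative = "standard", h2 = 0.5,
                       sim = sim_config(), bm = bm_config(), seed = 1L) {
  stopifnot(n_replicates >= 1L, all(scenarios %in% 1:6),
            alternative %in% c("standard", "h2_0.25", "maf_filter",
                               "ntr_1000"))
  structure(list(n_replicates = as.integer(n_replicates),
                 scenarios = as.integer(scenarios),
                 methods = methods, alternative = alternative, h2 = h2,
                 sim = sim, bm = bm, seed = as.integer(seed)),
            class = "run_config")
}

# Build the shared per-replicate trait inputs: QTL sets, marker set,
# scenario effect signs.  Signs are drawn once per (replicate, qtl set)
# so equal- and unequal-variance scenarios share QTL and signs.
prepare_replicate_traits <- function(replicate, seed, maf_filter = NULL) {
  freq <- allele_frequencies(replicate$training$pop)
  set.seed(derive_seed(seed, 11L))
  qtl_sets <- select_qtl_sets(freq)
  markers <- build_marker_set(freq, qtl_sets$high, maf_filter = maf_filter)
  set.seed(derive_seed(seed, 12L))
  signs <- lapply(qtl_sets[c("low", "intermediate", "high")], function(idx)
    sample(c(-1, 1), length(idx), replace = TRUE))
  list(freq = freq, qtl_sets = qtl_sets, markers = markers, signs = signs)
}

# Fit one method on one scenario of a prepared replicate and evaluate.
evaluate_method <- function(method, X_train, y, X_eval, tbv_eval, sigma2_a,
                            bm_cfg, seed) {
  est <- switch(method,
                BM = fit_bm(X_train, y, config = bm_cfg, seed = seed),
                LARS = fit_lars(X_train, y, seed = seed),
                PLSR = fit_plsr(X_train, y, seed = seed),
                stop("unknown method ", method))
  mebv <- predict_mebv(X_eval, est)
  ub <- unbiasedness_check(mebv, tbv_eval, sigma2_a)
  list(estimate = est, mebv = mebv,
       accuracy = accuracy(mebv, tbv_eval),
       msep = msep(mebv, tbv_eval),
       var_mebv = ub$var_mebv, ub_ratio = ub$ratio)
}

#' Run one replicate of the simulation experiment
#'
#' Simulates one population, builds the shared QTL and marker sets, and
#' for every requested scenario and method fits marker effects on the
#' training generation and evaluates MEBV on the evaluation generation.
#' Deterministic given \code{replicate_seed}: estimator sub-seeds are
#' derived per (scenario, method) so scenario comparisons share the
#' simulated data exactly.
#'
#' @param config a [run_config()].
#' @param replicate_seed seed of this replicate.
#' @param replicate optional pre-simulated replicate (from
#'   [simulate_replicate()]) to reuse across alternatives.
#' @return data.frame of class \code{replicate_result} with one row per
#'   scenario x method.
#' @export
run_replicate <- function(config, replicate_seed, replicate = NULL) {
  alt <- config$alternative
  simc <- config$sim
  if (alt == "ntr_1000") simc$training_family_size <- 20L
  if (is.null(replicate) || alt == "ntr_1000")
    replicate <- simulate_replicate(simc, seed = replicate_seed)
  h2 <- if (alt == "h2_0.25") 0.25 else config$h2
  maf_filter <- if (alt == "maf_filter") 0.10 else NULL

  prep <- prepare_replicate_traits(replicate, replicate_seed,
                                   maf_filter = maf_filter)
  X_train <- genotype_matrix(replicate$training$pop,
                             prep$markers$marker_indices)
  X_eval <- genotype_matrix(replicate$evaluation$pop,
                            prep$markers$marker_indices)
  scen <- scenario_table()
  rows <- list()
  for (sid in config$scenarios) {
    set_name <- scen$qtl_set[sid]
    mode <- scen$variance_mode[sid]
    qtl_idx <- prep$qtl_sets[[set_name]]
    scenario <- build_qtl_scenario(qtl_idx, prep$freq, mode,
                                   scenario_id = sid,
                                   signs = prep$signs[[set_name]])
    tbv_train <- compute_tbv(
      genotype_matrix(replicate$training$pop, qtl_idx), scenario$effects)
    tbv_eval <- compute_tbv(
      genotype_matrix(replicate$evaluation$pop, qtl_idx), scenario$effects)
    set.seed(derive_seed(replicate_seed, 100L + sid))
    trait <- simulate_phenotypes(tbv_train, h2 = h2)
    for (method in config$methods) {
      res <- evaluate_method(
        method, X_train, trait$phenotypes, X_eval, tbv_eval,
        trait$sigma2_a, config$bm,
        seed = derive_seed(replicate_seed, 1000L + sid,
                           match(method, c("BM", "LARS", "PLSR"))))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_seed = replicate_seed, scenario_id = sid,
        alternative = alt, method = method,
        accuracy = res$accuracy, msep = res$msep,
        var_mebv = res$var_mebv, ub_ratio = res$ub_ratio,
        sigma2_a = trait$sigma2_a, n_qtl = length(qtl_idx),
        n_markers = length(prep$markers$marker_indices))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("replicate_result", class(out))
  out
}

#' Run a multi-replicate experiment
#'
#' @param config a [run_config()].
#' @param progress print per-replicate progress.
#' @return row-bound replicate results.
#' @export
run_experiment <- function(config, progress = FALSE) {
  out <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    rs <- derive_seed(config$seed, i)
    if (progress) message("replicate ", i, " (seed ", rs, ")")
    out[[i]] <- run_replicate(config, rs)
  }
  res <- do.call(rbind, out)
  class(res) <- c("replicate_result", class(res))
  res
}

#' Summarize replicate results
#'
#' Per (scenario, alternative, method) cell: mean and standard error
#' (sample sd over replicates divided by sqrt(replicates)) of a metric.
#'
#' @param results a \code{replicate_result} data.frame.
#' @param metric column to summarize.
#' @return data.frame with mean, se and n per cell.
#' @export
summarize_results <- function(results, metric = "accuracy") {
  stopifnot(metric %in% names(results))
  key <- interaction(results$scenario_id, results$alternative,
                     results$method, drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    x <- d[[metric]]
    data.frame(scenario_id = d$scenario_id[1L],
               alternative = d$alternative[1L], method = d$method[1L],
               metric = metric, mean = mean(x, na.rm = TRUE),
               se = sd(x) / sqrt(length(x)), n = length(x))
  }))
  rownames(out) <- NULL
  out[order(out$scenario_id, out$method), ]
}

#' Within-replicate deltas against the standard situation
#'
#' Differences (alternative minus standard) computed per replicate and
#' scenario x method cell before averaging, the layout used to report
#' the effect of alternative simulation situations.
#'
#' @param standard results run with \code{alternative = "standard"}.
#' @param alternative results run with another alternative on the same
#'   replicate seeds.
#' @param metric column to difference.
#' @return summary data.frame of the per-cell mean delta and its se.
#' @export
delta_vs_standard <- function(standard, alternative, metric = "accuracy") {
  key_cols <- c("replicate_seed", "scenario_id", "method")
  m <- merge(standard[, c(key_cols, metric)],
             alternative[, c(key_cols, metric)],
             by = key_cols, suffixes = c("_std", "_alt"))
  m$delta <- m[[paste0(metric, "_alt")]] - m[[paste0(metric, "_std")]]
  m$alternative <- alternative$alternative[1L]
  d <- m[, c(key_cols, "alternative", "delta")]
  names(d)[names(d) == "delta"] <- metric
  summarize_results(d, metric)
}
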