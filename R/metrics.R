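#' Benjamini-Hochberg step-up procedure
#'
#' Standard BH step-up at level `q`. `NA` p-values (undefined statistics)
#' are excluded from `m`.
#'
#' Two thresholds are reported: `p_threshold`, the largest rejected p-value
#' itself, and `p_equiv = q * k / m` at the rejection count `k` — the
#' "equivalent p-value threshold" of the FDR level, which is the cutoff
#' applied to CIFBAT quantile intervals. Both are 0 when nothing is
#' rejected.
#'
#' @param p Numeric vector of p-values (may contain `NA`).
#' @param q FDR level in (0, 1).
#' @return List with `reject` (logical vector aligned with `p`),
#'   `n_rejected`, `p_threshold`, and `p_equiv`.
#' @export
bh_fdr <- function(p, q) {
  stopifnot(q > 0, q < 1)
  ok <- !is.na(p)
  m <- sum(ok)
  reject <- rep(FALSE, length(p))
  thr <- 0; equiv <- 0
  if (m > 0) {
    ps <- sort(p[ok])
    below <- which(ps <= q * seq_len(m) / m)
    if (length(below)) {
      k <- max(below)
      thr <- ps[k]
      equiv <- q * k / m
      reject[ok] <- p[ok] <= thr
    }
  }
  list(reject = reject, n_rejected = sum(reject), p_threshold = thr,
       p_equiv = equiv)
}

#' Classification metrics against a known causative set
#'
#' Recall (sensitivity), precision, specificity, negative predictive value
#' and F-measure (harmonic mean of recall and precision) of a set of called
#' markers against the known causative markers. Undefined ratios (empty
#' call set or empty causative set) are reported as 0 with a flag.
#'
#' @param called Logical vector of per-marker calls.
#' @param causative Integer indices of the truly causative markers.
#' @return Named list of metrics plus TP/FP/TN/FN counts and
#'   `precision_defined`.
#' @export
classification_metrics <- function(called, causative) {
  truth <- seq_along(called) %in% causative
  tp <- sum(called & truth); fp <- sum(called & !truth)
  fn <- sum(!called & truth); tn <- sum(!called & !truth)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f <- if (recall + precision > 0) 2 * recall * precision / (recall + precision)
       else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       recall = recall, precision = precision, specificity = specificity,
       npv = npv, f_measure = f, precision_defined = precision_defined)
}

#' Evaluate one simulated replicate: FBAT vs CIFBAT calls and metrics
#'
#' FBAT calls are the BH rejections of the per-marker FBAT p-values at FDR
#' `q`. CIFBAT acts as a validation filter on those calls: a CIFBAT call is
#' an FBAT call whose quantile interval is also significant
#' ([interval_significant()] rule) at the equivalent BH p-value threshold
#' `q * k / m`. Markers whose interval is significant without an FBAT
#' rejection are counted separately (`n_cifbat_only`) but are not calls.
#' Metrics are computed against the known causative set. Null-model
#' summaries (FBAT false-positive fraction at p < 0.1, fraction of
#' intervals whose entire p-value spread is below 0.1, CIFBAT-after-BH call
#' count) are always included.
#'
#' @param res Per-marker results from the internal scan (columns `p_value`,
#'   `z_lo`, `z_hi`, `p_at_lo`, `p_at_hi`, `p_max`, `same_sign`).
#' @param causative Integer indices of causative markers (may be empty).
#' @param q FDR level.
#' @return List with `fbat` and `cifbat` metric lists, `p_threshold`, and
#'   null summaries `fbat_fp10`, `cifbat_below10`, `n_cifbat_bh`.
#' @export
evaluate_run <- function(res, causative, q) {
  bh <- bh_fdr(res$p_value, q)
  fbat_calls <- bh$reject
  qi_sig <- if (bh$p_equiv > 0) res$same_sign & res$p_max < bh$p_equiv
            else rep(FALSE, nrow(res))
  cif_calls <- fbat_calls & qi_sig
  list(
    fbat = classification_metrics(fbat_calls, causative),
    cifbat = classification_metrics(cif_calls, causative),
    p_threshold = bh$p_threshold, p_equiv = bh$p_equiv,
    fbat_fp10 = mean(res$p_value < 0.1, na.rm = TRUE),
    cifbat_below10 = mean(res$same_sign & res$p_max < 0.1),
    n_cifbat_bh = sum(cif_calls),
    n_cifbat_only = sum(qi_sig & !fbat_calls)
  )
}

# One complete simulate -> inject -> test -> evaluate replicate.
.sim_one_run <- function(cfg, rate, target, phenotype, cif_seed) {
  ped <- simulate_families(cfg)
  ped <- if (phenotype == "disease") assign_disease(ped, cfg)
         else assign_random_phenotype(ped)
  sel <- select_case_control(
    ped, on_short = if (phenotype == "random") "downsample" else "error")
  sel_trios <- c(sel$cases, sel$controls)
  members <- unique(unlist(ped$trios[sel_trios,
                                     c("father", "mother", "offspring")]))
  if (rate > 0)
    ped <- inject_missingness(ped, members, rate = rate, target = target,
                              case_trios = sel$cases)
  tr <- ped$trios[sel_trios, , drop = FALSE]
  F <- ped$geno[tr$father, , drop = FALSE]
  M <- ped$geno[tr$mother, , drop = FALSE]
  O <- ped$geno[tr$offspring, , drop = FALSE]
  tt <- coded_trait(ped$ind$affected[tr$offspring], cfg$mu)
  res <- .cifbat_matrix(F, M, O, tt, cfg$model,
                        n_iterations = cfg$cifbat_trials,
                        alpha = cfg$alpha, seed = cif_seed)
  ev <- evaluate_run(res, ped$causative, cfg$fdr)
  ev$prevalence <- attr(ped, "prevalence")
  ev$n_cases <- length(sel$cases)
  ev$res <- res
  ev
}

#' Run a simulation scenario
#'
#' Repeats simulate -> assign phenotype -> select cases/controls -> inject
#' missingness -> FBAT + CIFBAT -> evaluate, and returns per-run metrics.
#' Per-run seeds are derived deterministically from `seed`, so any run count
#' is reproducible.
#'
#' @param cfg A [sim_config()].
#' @param rate Missingness rate (fraction of genotype entries per marker).
#' @param target Missingness concentration target, see
#'   [inject_missingness()].
#' @param n_runs Number of replicates.
#' @param seed Integer seed.
#' @param phenotype `"disease"` (log-additive penetrance model) or
#'   `"random"` (null, uniformly random affection).
#' @return A data.frame with one row per run: prevalence, case count, BH
#'   threshold, null summaries (`fbat_fp10`, `cifbat_below10`,
#'   `n_cifbat_bh`), and recall / precision / specificity / NPV / F-measure
#'   for FBAT and CIFBAT.
#' @export
run_scenario <- function(cfg, rate = 0, target = "random", n_runs = 1,
                         seed = 1, phenotype = c("disease", "random")) {
  phenotype <- match.arg(phenotype)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer((seed + 104729 * r) %% 2147483647)
    set.seed(run_seed)
    ev <- .sim_one_run(cfg, rate, target, phenotype, cif_seed = run_seed + 1L)
    rows[[r]] <- data.frame(
      run = r, rate = rate, target = target, phenotype = phenotype,
      prevalence = ev$prevalence, n_cases = ev$n_cases,
      p_threshold = ev$p_threshold,
      fbat_fp10 = ev$fbat_fp10, cifbat_below10 = ev$cifbat_below10,
      n_cifbat_bh = ev$n_cifbat_bh, n_cifbat_only = ev$n_cifbat_only,
      recall_fbat = ev$fbat$recall, precision_fbat = ev$fbat$precision,
      specificity_fbat = ev$fbat$specificity, npv_fbat = ev$fbat$npv,
      f_fbat = ev$fbat$f_measure,
      tp_fbat = ev$fbat$tp, fp_fbat = ev$fbat$fp,
      recall_cifbat = ev$cifbat$recall,
      precision_cifbat = ev$cifbat$precision,
      specificity_cifbat = ev$cifbat$specificity, npv_cifbat = ev$cifbat$npv,
      f_cifbat = ev$cifbat$f_measure,
      tp_cifbat = ev$cifbat$tp, fp_cifbat = ev$cifbat$fp)
  }
  do.call(rbind, rows)
}
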