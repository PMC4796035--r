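# Simulator: frequency laws, pedigree generation, disease model,
# missingness injection, BH-FDR and metrics.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_families = 300, n_markers = 40),
                            list(...))
  do.call(sim_config, args)
}

test_that("marker frequencies follow the clipped Gamma law", {
  cfg <- sim_config(n_families = 10, n_markers = 5000)
  set.seed(1)
  fr <- draw_marker_freqs(cfg)
  base <- attr(fr, "base")
  expect_true(all(base >= 0.001 & base <= 0.5))
  # unclipped mean is shape*scale/divisor = 4/35; clipping pulls it down
  expect_equal(mean(base), 2 * 2 / 35, tolerance = 0.08)
  expect_equal(dim(fr), c(2, 5000))
  # no differentiation => both populations share the base frequency
  cfg0 <- sim_config(n_families = 10, n_markers = 100, fst = 0)
  fr0 <- draw_marker_freqs(cfg0)
  expect_equal(fr0[1, ], fr0[2, ])
  expect_equal(fr0[1, ], attr(fr0, "base"))
})

test_that("families follow Hardy-Weinberg and Mendelian transmission", {
  cfg <- sim_config(n_families = 2000, n_markers = 12, fst = 0)
  set.seed(2)
  ped <- simulate_families(cfg)
  # population fractions
  expect_equal(mean(ped$fam$pop == 1), 1 / 3, tolerance = 0.1)
  # parental dosage law at a marker
  p <- attr(ped$freqs, "base")[1]
  fathers <- ped$geno[ped$ind$role == "father", 1]
  expect_equal(mean(fathers), 2 * p, tolerance = 0.15)
  expect_equal(mean(fathers == 1), 2 * p * (1 - p), tolerance = 0.15)
  # every generated trio is Mendelian-consistent at every marker
  tr <- ped$trios[sample.int(nrow(ped$trios), 200), ]
  for (j in c(1, 5, 12))
    expect_true(all(is_mendelian_consistent(
      ped$geno[tr$father, j], ped$geno[tr$mother, j],
      ped$geno[tr$offspring, j])))
  # offspring per family within the configured range
  noff <- table(ped$trios$fid)
  expect_true(all(noff %in% 1:2))
})

test_that("the closed-form environmental solve hits its two targets", {
  s <- solve_env_params(0.125, 3, 0.001)
  q <- s$p_env; a <- 0.001 * exp(s$env_log_effect)
  expect_equal(q * a + (1 - q) * 0.001, 0.125, tolerance = 1e-8)
  expect_equal((q * a^2 + (1 - q) * 0.001^2) / 0.125^2, 3, tolerance = 1e-6)
})

test_that("disease assignment follows the log-additive penetrance model", {
  cfg <- small_cfg(p_env = 0, f0_sd = 0, f2_sd = 0)
  set.seed(3)
  ped <- simulate_families(cfg)
  ped <- assign_disease(ped, cfg, causative = 1:3)
  off <- which(ped$ind$role == "offspring")
  G <- ped$geno[off, 1:3, drop = FALSE]
  none <- rowSums(G) == 0
  # with no exposure and zero causative copies, pi = f0 = 0.001
  expect_lt(mean(ped$ind$affected[off][none]), 0.01)
  # prevalence attribute matches the affected fraction
  expect_equal(attr(ped, "prevalence"), mean(ped$ind$affected[off]))
  # siblings correlate through shared exposure when p_env is interior
  cfg2 <- small_cfg(n_families = 4000, p_env = 0.3)
  set.seed(4)
  ped2 <- assign_disease(simulate_families(cfg2), cfg2, causative = integer(0))
  off2 <- which(ped2$ind$role == "offspring")
  two <- names(which(table(ped2$ind$fid[off2]) == 2))
  sib <- do.call(rbind, lapply(two, function(f)
    ped2$ind$affected[off2][ped2$ind$fid[off2] == f]))
  k <- mean(sib)
  lam <- mean(sib[, 1] & sib[, 2]) / k^2
  expect_gt(lam, 1.5)   # sibling recurrence well above independence
})

test_that("prevalence calibration reaches the 12.5% target", {
  cfg <- sim_config(n_families = 1000)
  set.seed(5)
  cal <- calibrate_prevalence(cfg, tol = 0.005, n_families = 1500,
                              n_reps = 2)
  expect_lt(abs(cal$achieved - 0.125), 0.0051)
  expect_true(cal$p_env >= 0 && cal$p_env <= 1)
  expect_error(calibrate_prevalence(cfg, target = 0.9, n_families = 400,
                                    n_reps = 1), "attainable")
})

test_that("case/control selection is balanced and disjoint", {
  cfg <- small_cfg()
  set.seed(6)
  ped <- assign_disease(simulate_families(cfg), cfg)
  sel <- select_case_control(ped)
  expect_equal(length(sel$cases), length(sel$controls))
  expect_length(intersect(sel$cases, sel$controls), 0)
  expect_true(all(ped$ind$affected[ped$trios$offspring[sel$cases]]))
  expect_false(any(ped$ind$affected[ped$trios$offspring[sel$controls]]))
})

test_that("missingness injection hits the configured rate and 80/20 split", {
  cfg <- small_cfg(n_families = 800, n_markers = 30)
  set.seed(7)
  ped <- assign_disease(simulate_families(cfg), cfg)
  n_ind <- nrow(ped$ind)
  # rate 0 leaves data untouched
  p0 <- inject_missingness(ped, rate = 0)
  expect_identical(p0$geno, ped$geno)
  # MCAR achieves the marginal rate
  p1 <- inject_missingness(ped, rate = 0.10, target = "random")
  expect_equal(mean(is.na(p1$geno)), 0.10, tolerance = 0.02)
  # MAR on males: ~80% of missing entries are male
  p2 <- inject_missingness(ped, rate = 0.05, target = "males")
  miss_by_sex <- colSums(apply(is.na(p2$geno), 2, tapply,
                               ped$ind$sex, sum))
  male_frac <- sum(is.na(p2$geno[ped$ind$sex == 1L, ])) /
    sum(is.na(p2$geno))
  expect_equal(male_frac, 0.8, tolerance = 0.05)
  # MNAR on heterozygotes: het entries enriched among missing
  p3 <- inject_missingness(ped, rate = 0.05, target = "heterozygotes")
  het_frac <- mean(ped$geno[is.na(p3$geno)] == 1L)
  expect_gt(het_frac, 2 * mean(ped$geno == 1L))
})

test_that("bh_fdr implements the step-up procedure and both thresholds", {
  r <- bh_fdr(c(0.001, 0.02, 0.2), 0.10)
  expect_equal(r$n_rejected, 2L)
  expect_equal(r$p_threshold, 0.02)
  expect_equal(r$p_equiv, 0.10 * 2 / 3)
  expect_equal(bh_fdr(rep(1, 5), 0.1)$n_rejected, 0L)
  expect_equal(bh_fdr(rep(1, 5), 0.1)$p_threshold, 0)
  expect_equal(bh_fdr(0.05, 0.1)$n_rejected, 1L)
  # rejection set agrees with stats::p.adjust
  set.seed(8)
  p <- c(runif(80), runif(20)^4)
  r2 <- bh_fdr(p, 0.1)
  expect_identical(r2$reject, stats::p.adjust(p, "BH") <= 0.1)
  # NA p-values excluded from m
  r3 <- bh_fdr(c(0.001, NA, 0.02, 0.2), 0.10)
  expect_equal(r3$n_rejected, 2L)
})

test_that("classification metrics are exact functions of the counts", {
  m <- classification_metrics(c(TRUE, TRUE, FALSE, FALSE, TRUE), c(1, 2, 3))
  expect_equal(m$tp, 2); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 1)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f_measure, 2 / 3)
  # Table-style check: recall 0.263, precision 1 => F ~ 0.417
  r <- 0.263; pr <- 1
  expect_equal(2 * r * pr / (r + pr), 0.417, tolerance = 0.01)
  z <- classification_metrics(rep(FALSE, 5), c(1, 2))
  expect_equal(z$precision, 0)
  expect_false(z$precision_defined)
})

test_that("run_scenario is reproducible from its seed", {
  cfg <- small_cfg(cifbat_trials = 30)
  a <- run_scenario(cfg, rate = 0.05, target = "random", n_runs = 2,
                    seed = 123, phenotype = "random")
  b <- run_scenario(cfg, rate = 0.05, target = "random", n_runs = 2,
                    seed = 123, phenotype = "random")
  expect_identical(a, b)
  expect_equal(nrow(a), 2L)
})
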