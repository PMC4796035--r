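#' Simulation configuration
#'
#' Parameters of the family genotype/phenotype simulator. Defaults are the
#' study conditions used throughout: 4000 families split 1/3 : 2/3 over two
#' subpopulations, 300 independent bi-allelic autosomal markers of which 3
#' are causative, 1 or 2 offspring per family, marker allele frequencies
#' drawn from Gamma(shape 2, scale 2)/35 clipped to \[0.001, 0.5\] with
#' Balding-Nichols differentiation (Fst 0.01) between the subpopulations,
#' penetrances f0 ~ N(0.001, sd 0.001) (zero causative copies) and
#' f2 ~ N(0.1, sd 0.01) (two copies) drawn per family, heterozygote
#' penetrance ratio lambda_g = 2, family-shared environmental effect scaled
#' so that the sibling recurrence ratio is lambda_s = 3 at the target mean
#' population prevalence of 12.5%.
#'
#' The environmental exposure is Bernoulli per family: with probability
#' `p_env` the family's baseline log-penetrance is raised by
#' `env_log_effect`. When these are `NULL` they are solved in closed form
#' from `(prevalence, lambda_s, f0_mean)` by [solve_env_params()];
#' [calibrate_prevalence()] refines `p_env` by simulation, accounting for
#' the genetic term and clipping.
#'
#' @param n_families Number of nuclear families.
#' @param n_markers,n_causative Number of markers and of causative markers.
#' @param pop_fractions Subpopulation assignment probabilities (sum to 1).
#' @param fst Balding-Nichols differentiation between subpopulations
#'   (0 = none).
#' @param freq_shape,freq_scale,freq_divisor Base allele-frequency law:
#'   `Gamma(shape, scale) / divisor`.
#' @param freq_clip Clipping bounds for the base allele frequency.
#' @param f0_mean,f0_sd,f2_mean,f2_sd Penetrance laws (per-family normal
#'   draws, truncated to `[min_penetrance, 0.999]`).
#' @param lambda_g Heterozygote penetrance ratio (single causative copy).
#' @param lambda_s Target sibling recurrence ratio of the shared
#'   environmental exposure.
#' @param prevalence Target mean population prevalence.
#' @param p_env,env_log_effect Environmental exposure probability and
#'   log-effect; solved from the targets when `NULL`.
#' @param offspring_range Offspring per family, uniform over this range.
#' @param cifbat_trials CIFBAT iterations per marker in evaluation runs.
#' @param fdr Benjamini-Hochberg FDR level for calling markers.
#' @param mu,model,alpha Test settings passed to [fbat()]/[cifbat()].
#' @param max_pi Upper clip for the disease probability.
#' @param min_penetrance Lower truncation for penetrance draws.
#' @return An object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(n_families = 4000, n_markers = 300, n_causative = 3,
                       pop_fractions = c(1 / 3, 2 / 3), fst = 0.01,
                       freq_shape = 2, freq_scale = 2, freq_divisor = 35,
                       freq_clip = c(0.001, 0.5),
                       f0_mean = 0.001, f0_sd = 0.001,
                       f2_mean = 0.1, f2_sd = 0.01,
                       lambda_g = 2, lambda_s = 3, prevalence = 0.125,
                       p_env = NULL, env_log_effect = NULL,
                       offspring_range = c(1, 2),
                       cifbat_trials = 100, fdr = 0.10,
                       mu = 0.5, model = "additive", alpha = 0.05,
                       max_pi = 0.999, min_penetrance = 1e-5) {
  stopifnot(abs(sum(pop_fractions) - 1) < 1e-8, n_causative <= n_markers,
            freq_clip[1] > 0, freq_clip[2] <= 1)
  if (is.null(p_env) || is.null(env_log_effect)) {
    env <- solve_env_params(prevalence, lambda_s, f0_mean)
    if (is.null(p_env)) p_env <- env$p_env
    if (is.null(env_log_effect)) env_log_effect <- env$env_log_effect
  }
  structure(list(
    n_families = n_families, n_markers = n_markers, n_causative = n_causative,
    pop_fractions = pop_fractions, fst = fst,
    freq_shape = freq_shape, freq_scale = freq_scale,
    freq_divisor = freq_divisor, freq_clip = freq_clip,
    f0_mean = f0_mean, f0_sd = f0_sd, f2_mean = f2_mean, f2_sd = f2_sd,
    lambda_g = lambda_g, lambda_s = lambda_s, prevalence = prevalence,
    p_env = p_env, env_log_effect = env_log_effect,
    offspring_range = offspring_range,
    cifbat_trials = cifbat_trials, fdr = fdr,
    mu = mu, model = .norm_model(model), alpha = alpha,
    max_pi = max_pi, min_penetrance = min_penetrance
  ), class = "sim_config")
}

#' Solve environmental-exposure parameters from prevalence and sibling
#' recurrence targets
#'
#' Two-point exposure model ignoring the (small) genetic term: a family is
#' exposed with probability `q`, exposed offspring have baseline risk `a`,
#' unexposed have `f0`. `q` and `a` are determined by the mean prevalence
#' `K = q a + (1 - q) f0` and the sibling recurrence ratio
#' `lambda_s = (q a^2 + (1 - q) f0^2) / K^2`.
#'
#' @param prevalence Target mean prevalence `K`.
#' @param lambda_s Target sibling recurrence ratio (> 1).
#' @param f0 Baseline penetrance of unexposed non-carriers.
#' @return List with `p_env` (= `q`) and `env_log_effect` (= `log(a / f0)`).
#' @export
solve_env_params <- function(prevalence, lambda_s, f0) {
  stopifnot(prevalence > 0, prevalence < 1, lambda_s > 1, f0 > 0,
            f0 < prevalence)
  K <- prevalence
  g <- function(q) (K - (1 - q) * f0)^2 / q + (1 - q) * f0^2 - lambda_s * K^2
  q <- stats::uniroot(g, c(1e-6, 1), tol = 1e-12)$root
  a <- (K - (1 - q) * f0) / q
  if (a >= 1) stop("infeasible targets: exposed risk would exceed 1",
                   call. = FALSE)
  list(p_env = q, env_log_effect = log(a / f0))
}

#' Draw per-population marker allele frequencies
#'
#' Base frequencies follow `Gamma(shape, scale) / divisor`, clipped to
#' `freq_clip`; the two subpopulations are differentiated from the base by
#' the Balding-Nichols model with the configured Fst.
#'
#' @param cfg A [sim_config()].
#' @return A 2 x n_markers matrix of alternate-allele frequencies (rows =
#'   subpopulations) with the base frequencies as attribute `"base"`.
#' @export
draw_marker_freqs <- function(cfg) {
  base <- stats::rgamma(cfg$n_markers, shape = cfg$freq_shape,
                        scale = cfg$freq_scale) / cfg$freq_divisor
  base <- pmin(pmax(base, cfg$freq_clip[1]), cfg$freq_clip[2])
  if (cfg$fst > 0) {
    sh1 <- base * (1 - cfg$fst) / cfg$fst
    sh2 <- (1 - base) * (1 - cfg$fst) / cfg$fst
    fr <- rbind(stats::rbeta(cfg$n_markers, sh1, sh2),
                stats::rbeta(cfg$n_markers, sh1, sh2))
    fr <- pmin(pmax(fr, 1e-4), 1 - 1e-4)
  } else {
    fr <- rbind(base, base)
  }
  dimnames(fr) <- NULL
  attr(fr, "base") <- base
  fr
}

#' Simulate nuclear families
#'
#' Each family is assigned to a subpopulation; parental genotypes are drawn
#' under Hardy-Weinberg equilibrium from the family's subpopulation allele
#' frequencies; each family has 1 or 2 offspring whose genotypes follow
#' Mendelian transmission and whose sex is uniform. All markers are
#' autosomal and independent.
#'
#' @param cfg A [sim_config()].
#' @param freqs Optional frequency matrix from [draw_marker_freqs()] (drawn
#'   if missing).
#' @return An object of class `"pedigree_set"`: a list with `fam`
#'   (family table: `fid`, `pop`), `ind` (individual table: `iid`, `fid`,
#'   `role`, `sex`, `affected`), `geno` (individuals x markers dosage
#'   matrix), `trios` (rows of `ind` for father/mother/offspring of each
#'   trio), `markers`, `freqs`, `causative`.
#' @export
simulate_families <- function(cfg, freqs = NULL) {
  if (is.null(freqs)) freqs <- draw_marker_freqs(cfg)
  nf <- cfg$n_families; m <- cfg$n_markers
  pop <- sample.int(2L, nf, replace = TRUE, prob = cfg$pop_fractions)
  n_off <- sample(seq(cfg$offspring_range[1], cfg$offspring_range[2]),
                  nf, replace = TRUE)

  # parents: rows 1..nf fathers, nf+1..2nf mothers
  P <- freqs[pop, , drop = FALSE]                       # nf x m
  Gf <- matrix(stats::rbinom(nf * m, 2L, P), nf, m)
  Gm <- matrix(stats::rbinom(nf * m, 2L, P), nf, m)

  off_fam <- rep.int(seq_len(nf), n_off)
  no <- length(off_fam)
  Tf <- matrix(stats::rbinom(no * m, 1L, Gf[off_fam, , drop = FALSE] / 2),
               no, m)
  Tm <- matrix(stats::rbinom(no * m, 1L, Gm[off_fam, , drop = FALSE] / 2),
               no, m)
  Go <- Tf + Tm

  n_ind <- 2L * nf + no
  geno <- rbind(Gf, Gm, Go)
  ind <- data.frame(
    iid = seq_len(n_ind),
    fid = c(seq_len(nf), seq_len(nf), off_fam),
    role = rep(c("father", "mother", "offspring"), c(nf, nf, no)),
    sex = c(rep(1L, nf), rep(2L, nf),
            sample.int(2L, no, replace = TRUE)),
    affected = NA)
  trios <- data.frame(
    fid = off_fam,
    father = off_fam,
    mother = nf + off_fam,
    offspring = 2L * nf + seq_len(no))
  markers <- data.frame(
    marker = sprintf("M%04d", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 1000L, ref = "A", alt = "B",
    stringsAsFactors = FALSE)
  structure(list(fam = data.frame(fid = seq_len(nf), pop = pop),
                 ind = ind, geno = geno, trios = trios,
                 markers = markers, freqs = freqs, causative = integer(0)),
            class = "pedigree_set")
}

#' Assign disease status under the log-additive penetrance model
#'
#' The log disease probability of offspring `j` in family `i` is
#' `log(pi_ij) = log(f0_i) + e_i + sum_m beta_m(G_ijm)` over the causative
#' markers, with `beta(1 copy) = log(lambda_g)` and
#' `beta(2 copies) = log(f2_i / f0_i)`. `f0_i` and `f2_i` are per-family
#' penetrance draws; `e_i` is the family-shared environmental log-effect
#' (`env_log_effect` with probability `p_env`, else 0), which induces the
#' sibling disease correlation. `pi_ij` is clipped to `(0, max_pi]` and
#' affection is Bernoulli.
#'
#' @param ped A [simulate_families()] pedigree set.
#' @param cfg A [sim_config()].
#' @param causative Optional causative marker indices (sampled if `NULL`).
#' @return `ped` with `affected` filled in for offspring, `causative` set,
#'   and attributes `prevalence` and `n_clipped` on the `causative` field's
#'   sibling attribute `disease` (a list with the per-offspring
#'   probabilities).
#' @export
assign_disease <- function(ped, cfg, causative = NULL) {
  nf <- nrow(ped$fam)
  if (is.null(causative))
    causative <- sort(sample.int(cfg$n_markers, cfg$n_causative))
  off <- which(ped$ind$role == "offspring")
  fam_of <- ped$ind$fid[off]

  trunc_norm <- function(n, mean, sd)
    pmin(pmax(stats::rnorm(n, mean, sd), cfg$min_penetrance), 0.999)
  f0 <- trunc_norm(nf, cfg$f0_mean, cfg$f0_sd)
  f2 <- trunc_norm(nf, cfg$f2_mean, cfg$f2_sd)
  e <- ifelse(stats::runif(nf) < cfg$p_env, cfg$env_log_effect, 0)

  logpi <- log(f0[fam_of]) + e[fam_of]
  if (length(causative)) {
    G <- ped$geno[off, causative, drop = FALSE]
    b1 <- log(cfg$lambda_g)
    b2 <- log(f2 / f0)[fam_of]
    logpi <- logpi + rowSums((G == 1L) * b1 + (G == 2L) * b2)
  }
  pi <- exp(logpi)
  n_clipped <- sum(pi > cfg$max_pi)
  pi <- pmin(pi, cfg$max_pi)
  ped$ind$affected[off] <- stats::runif(length(off)) < pi
  ped$causative <- causative
  attr(ped, "prevalence") <- mean(ped$ind$affected[off])
  attr(ped, "n_clipped") <- n_clipped
  ped
}

#' Assign a uniformly random phenotype (null model)
#'
#' Each offspring is affected independently with probability 1/2,
#' irrespective of genotype.
#'
#' @inheritParams assign_disease
#' @return `ped` with random `affected` flags and an empty causative set.
#' @export
assign_random_phenotype <- function(ped) {
  off <- which(ped$ind$role == "offspring")
  ped$ind$affected[off] <- stats::runif(length(off)) < 0.5
  ped$causative <- integer(0)
  attr(ped, "prevalence") <- mean(ped$ind$affected[off])
  ped
}

#' Calibrate the environmental exposure probability to a target prevalence
#'
#' Bisection on `p_env`: repeatedly simulates small cohorts under the full
#' disease model (genetic term and clipping included) until the mean
#' prevalence is within `tol` of the target. Prevalence is monotone
#' non-decreasing in `p_env`.
#'
#' @param cfg A [sim_config()].
#' @param target Target mean prevalence (default `cfg$prevalence`).
#' @param tol Absolute tolerance (default 0.005, i.e. half a percentage
#'   point).
#' @param n_families Cohort size per probe simulation.
#' @param n_reps Probe simulations averaged per bisection step.
#' @param max_iter Maximum bisection steps.
#' @return List with `p_env`, `achieved` prevalence, and `iterations`;
#'   errors if the target is outside the attainable range.
#' @export
calibrate_prevalence <- function(cfg, target = cfg$prevalence, tol = 0.005,
                                 n_families = 2000, n_reps = 2,
                                 max_iter = 20) {
  stopifnot(target > 0, target < 1)
  probe_cfg <- cfg
  probe_cfg$n_families <- n_families
  prev_at <- function(p) {
    probe_cfg$p_env <- p
    mean(vapply(seq_len(n_reps), function(i) {
      ped <- assign_disease(simulate_families(probe_cfg), probe_cfg)
      attr(ped, "prevalence")
    }, numeric(1)))
  }
  lo <- 0; hi <- 1
  p_lo <- prev_at(lo); p_hi <- prev_at(hi)
  if (target < p_lo - tol || target > p_hi + tol)
    stop(sprintf("target prevalence %.4f outside attainable range [%.4f, %.4f]",
                 target, p_lo, p_hi), call. = FALSE)
  p <- cfg$p_env; achieved <- prev_at(p); it <- 1L
  while (abs(achieved - target) > tol && it < max_iter) {
    if (achieved > target) hi <- p else lo <- p
    p <- (lo + hi) / 2
    achieved <- prev_at(p)
    it <- it + 1L
  }
  list(p_env = p, achieved = achieved, iterations = it)
}

#' Select case and control trios
#'
#' All trios with an affected offspring are cases; an equal number of
#' control trios is drawn uniformly without replacement from the trios with
#' unaffected offspring.
#'
#' @param ped A pedigree set with phenotypes assigned.
#' @param on_short What to do when fewer control than case trios exist:
#'   `"error"` (default) or `"downsample"` the cases to the control count
#'   (useful under a random 50/50 null phenotype).
#' @return List with integer trio indices `cases` and `controls` (into
#'   `ped$trios`).
#' @export
select_case_control <- function(ped, on_short = c("error", "downsample")) {
  on_short <- match.arg(on_short)
  aff <- ped$ind$affected[ped$trios$offspring]
  cases <- which(aff %in% TRUE)
  pool <- which(aff %in% FALSE)
  if (length(pool) < length(cases)) {
    if (on_short == "error")
      stop(sprintf("only %d control trios available for %d case trios",
                   length(pool), length(cases)), call. = FALSE)
    cases <- sort(cases[sample.int(length(cases), length(pool))])
  }
  controls <- if (length(cases))
    sort(pool[sample.int(length(pool), length(cases))]) else integer(0)
  list(cases = cases, controls = controls)
}

#' Inject missing genotypes (MCAR / MAR / MNAR)
#'
#' Sets a fraction `rate` of the per-marker genotype entries of the selected
#' individuals to missing. Under MCAR entries are chosen uniformly; under
#' MAR/MNAR a fraction `split` (default 80%) of the missing entries falls in
#' the target group and the rest outside, spilling over (with a count) when
#' a group is too small. Targets: `"random"`, `"small_pop"`, `"large_pop"`,
#' `"males"`, `"females"`, `"cases"`, `"controls"` (an individual is a case
#' when it belongs to at least one selected case trio), `"heterozygotes"`,
#' `"homozygotes"` (genotype at the marker itself; MNAR).
#'
#' @param ped A pedigree set.
#' @param individuals Integer indices of the individuals subject to
#'   missingness (e.g. the members of the selected trios); defaults to all.
#' @param rate Fraction of entries per marker set to missing.
#' @param target Missingness concentration target, see above.
#' @param split Fraction of missing entries concentrated in the target
#'   group (default 0.8).
#' @param case_trios Trio indices defining the case group (required for
#'   `"cases"`/`"controls"` targets).
#' @return `ped` with `NA` entries in `geno`; attribute `n_spilled` counts
#'   entries that could not be placed in the intended group.
#' @export
inject_missingness <- function(ped, individuals = seq_len(nrow(ped$ind)),
                               rate, target = "random", split = 0.8,
                               case_trios = NULL) {
  stopifnot(rate >= 0, rate <= 1, split > 0.5, split <= 1)
  target <- match.arg(tolower(target),
                      c("random", "small_pop", "large_pop", "males",
                        "females", "cases", "controls", "heterozygotes",
                        "homozygotes"))
  if (rate == 0) { attr(ped, "n_spilled") <- 0L; return(ped) }
  n <- length(individuals)
  m <- ncol(ped$geno)
  n_miss <- round(rate * n)
  if (n_miss == 0) { attr(ped, "n_spilled") <- 0L; return(ped) }

  pop_of <- ped$fam$pop[match(ped$ind$fid[individuals], ped$fam$fid)]
  # pop 1 has fraction 1/3 (small), pop 2 has 2/3 (large)
  grp <- switch(target,
    random = NULL,
    small_pop = pop_of == 1L,
    large_pop = pop_of == 2L,
    males = ped$ind$sex[individuals] == 1L,
    females = ped$ind$sex[individuals] == 2L,
    cases = , controls = {
      if (is.null(case_trios))
        stop("`case_trios` required for case/control-targeted missingness",
             call. = FALSE)
      case_members <- unique(unlist(ped$trios[case_trios,
                                              c("father", "mother", "offspring")]))
      inc <- individuals %in% case_members
      if (target == "cases") inc else !inc
    },
    heterozygotes = , homozygotes = "per_marker")

  n_spill <- 0L
  for (j in seq_len(m)) {
    if (is.null(grp)) {
      pick <- sample.int(n, n_miss)
    } else {
      gj <- if (identical(grp, "per_marker")) {
        g <- ped$geno[individuals, j]
        if (target == "heterozygotes") !is.na(g) & g == 1L
        else !is.na(g) & g == 2L
      } else grp
      in_t <- which(gj); out_t <- which(!gj)
      want_t <- round(split * n_miss)
      take_t <- min(want_t, length(in_t))
      take_o <- min(n_miss - take_t, length(out_t))
      short <- n_miss - take_t - take_o
      if (short > 0) {            # spill back into whichever side has room
        extra <- min(short, length(in_t) - take_t)
        take_t <- take_t + extra
        short <- short - extra
      }
      n_spill <- n_spill + (want_t - min(want_t, length(in_t)))
      pick <- c(if (take_t) in_t[sample.int(length(in_t), take_t)],
                if (take_o) out_t[sample.int(length(out_t), take_o)])
    }
    ped$geno[individuals[pick], j] <- NA_integer_
  }
  attr(ped, "n_spilled") <- n_spill
  ped
}
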