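#' Coded offspring trait
#'
#' The coded trait is the observed binary trait minus an offset
#' `mu` in \[0, 1\]: `T = 1 - mu` for affected offspring and `-mu` for
#' unaffected. With `mu = 0` only affected trios contribute to the test;
#' `mu = 0.5` gives affected and unaffected trios equal but opposite
#' weights.
#'
#' @param affected Logical vector (TRUE = affected offspring).
#' @param mu Offset in \[0, 1\]; default 0.5.
#' @return Numeric vector of coded traits.
#' @export
coded_trait <- function(affected, mu = 0.5) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1)
    stop("`mu` must be a single value in [0, 1]", call. = FALSE)
  as.numeric(affected) - mu
}

# Map trio genotypes to complete-config indices per context; returns integer
# vector (NA = incomplete or inconsistent) plus which complete rows are
# inconsistent. `sex` only matters for chrom = "X".
.config_index <- function(father, mother, offspring, chrom, sex) {
  ch <- .norm_chrom(chrom)
  n <- length(offspring)
  idx <- rep(NA_integer_, n)
  if (ch == "A") {
    idx <- .tabs("A")$code_map[.pattern_code(father, mother, offspring)]
  } else {
    sex <- .norm_sex(rep_len(sex, n))
    for (s in unique(sex)) {
      w <- sex == s
      tb <- .tabs(if (s == 1L) "XM" else "XF")
      idx[w] <- tb$code_map[.pattern_code(father[w], mother[w], offspring[w])]
    }
  }
  idx
}

#' FBAT statistic over complete trios
#'
#' Family-based association test for a bi-allelic marker. Each complete,
#' Mendelian-consistent trio contributes `T * (X - E[X])` to the score
#' `U` and `T^2 * Var(X)` to its variance, where `T` is the coded trait
#' ([coded_trait()]) and the genotype moments condition on the parents
#' ([trio_score()]). The statistic `z = U / sqrt(Var(U))` is standard normal
#' under the null of no linkage and no association; a positive `z` means the
#' alternate allele is over-transmitted to affected offspring. Incomplete
#' trios are ignored; inconsistent complete trios are excluded and counted.
#'
#' @param trios A data.frame with columns `father`, `mother`, `offspring`
#'   (allele dosages, `NA` = missing), `affected` (logical), and `sex`
#'   (1 = male, 2 = female; required when `chrom = "X"`).
#' @param model Genetic model: `"additive"`, `"dominant"` or `"recessive"`.
#' @param mu Trait offset, see [coded_trait()].
#' @param chrom `"autosomal"` or `"X"`.
#' @return An object of class `"fbat_result"`: a list with `u`, `var_u`,
#'   `z` (`NA` when no informative trio), `p_value` (two-sided normal),
#'   `n_complete`, `n_informative`, `n_excluded_mendel`, `n_incomplete`.
#' @examples
#' tr <- data.frame(father = 0, mother = 1, offspring = 1, affected = TRUE)
#' fbat(tr, mu = 0)  # u = 0.5, var_u = 0.25, z = 1
#' @export
fbat <- function(trios, model = "additive", mu = 0.5, chrom = "autosomal") {
  model <- .norm_model(model)
  sex <- if ("sex" %in% names(trios)) trios$sex else NULL
  idx <- .config_index(trios$father, trios$mother, trios$offspring, chrom, sex)
  complete <- !is.na(trios$father) & !is.na(trios$mother) &
    !is.na(trios$offspring)
  used <- !is.na(idx)
  ch <- .norm_chrom(chrom)
  tt <- coded_trait(trios$affected, mu)

  xme <- varx <- rep(NA_real_, nrow(trios))
  if (ch == "A") {
    md <- .tabs("A")$models[[model]]
    xme[used] <- md$xme[idx[used]]
    varx[used] <- md$varx[idx[used]]
  } else {
    sx <- .norm_sex(rep_len(sex, nrow(trios)))
    for (s in unique(sx)) {
      w <- used & sx == s
      md <- .tabs(if (s == 1L) "XM" else "XF")$models[[model]]
      xme[w] <- md$xme[idx[w]]
      varx[w] <- md$varx[idx[w]]
    }
  }

  u <- sum(tt[used] * xme[used])
  var_u <- sum(tt[used]^2 * varx[used])
  z <- if (var_u > 0) u / sqrt(var_u) else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(
    u = u, var_u = var_u, z = z, p_value = p,
    n_complete = sum(complete),
    n_informative = sum(varx[used] > 0),
    n_excluded_mendel = sum(complete & !used),
    n_incomplete = sum(!complete)
  ), class = "fbat_result")
}

#' @export
print.fbat_result <- function(x, ...) {
  cat("FBAT result\n")
  cat(sprintf("  U = %.6g, Var(U) = %.6g\n", x$u, x$var_u))
  if (is.na(x$z)) {
    cat("  z = undefined (no informative trio)\n")
  } else {
    cat(sprintf("  z = %.4f, two-sided p = %s\n", x$z, format_pvalue(x$p_value)))
  }
  cat(sprintf("  trios: %d complete (%d informative), %d incomplete, %d Mendelian errors excluded\n",
              x$n_complete, x$n_informative, x$n_incomplete, x$n_excluded_mendel))
  invisible(x)
}

#' Format a p-value, flooring at machine epsilon
#'
#' Two-sided normal p-values smaller than machine epsilon are reported as
#' `"<2.22e-16"`.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  eps <- .Machine$double.eps
  ifelse(is.na(p), "NA",
         ifelse(p < eps, sprintf("<%.3g", eps), sprintf("%.3g", p)))
}

# Vectorized FBAT across markers for autosomal dosage matrices
# (n_trios x n_markers). Used by the simulator evaluation harness and the
# scan interface; identical arithmetic to fbat().
.fbat_matrix <- function(F, M, O, tt, model) {
  md <- .tabs("A")$models[[model]]
  cc <- .pattern_code(F, M, O)           # complete codes only meaningful
  cc[is.na(F) | is.na(M) | is.na(O)] <- NA_integer_
  idx <- .tabs("A")$code_map[cc]
  dim(idx) <- dim(F)
  xme <- md$xme[idx]; dim(xme) <- dim(F)
  varx <- md$varx[idx]; dim(varx) <- dim(F)
  u <- colSums(tt * xme, na.rm = TRUE)
  var_u <- colSums(tt^2 * varx, na.rm = TRUE)
  z <- ifelse(var_u > 0, u / sqrt(var_u), NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  n_complete <- colSums(!is.na(cc))
  list(u = u, var_u = var_u, z = z, p_value = p,
       n_complete = n_complete,
       n_informative = colSums(varx > 0, na.rm = TRUE),
       n_excluded_mendel = n_complete - colSums(!is.na(idx)),
       used = !is.na(idx))
}
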