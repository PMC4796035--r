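#' Transmission counts for the TDT
#'
#' Tallies transmissions from heterozygous parents to affected offspring in
#' complete, Mendelian-consistent trios: `b` counts transmissions of the
#' alternate allele and `c` of the reference allele. A transmission is
#' counted only when it is informative under the genetic model, i.e. when
#' the two candidate transmitted alleles (holding the other parent's
#' realized transmission fixed) would yield different coded offspring
#' genotypes; under the additive model this reduces to the classical count
#' over all heterozygous-parent transmissions (the ambiguous
#' het x het -> het trio contributes one `b` and one `c`). On the X
#' chromosome fathers are hemizygous and never counted, and sons receive no
#' paternal X.
#'
#' @inheritParams fbat
#' @return A named integer vector `c(b = , c = )` with attributes
#'   `n_excluded_mendel` (inconsistent complete trios skipped) and `n_used`
#'   (affected complete trios tallied).
#' @export
tdt_counts <- function(trios, model = "additive", chrom = "autosomal") {
  model <- .norm_model(model)
  ch <- .norm_chrom(chrom)
  trios <- trios[trios$affected %in% TRUE, , drop = FALSE]
  complete <- !is.na(trios$father) & !is.na(trios$mother) &
    !is.na(trios$offspring)
  trios <- trios[complete, , drop = FALSE]
  sex <- if ("sex" %in% names(trios)) trios$sex else NULL
  idx <- .config_index(trios$father, trios$mother, trios$offspring, ch, sex)
  used <- !is.na(idx)
  b <- 0L; cc <- 0L
  if (any(used)) {
    if (ch == "A") {
      md <- .tabs("A")$models[[model]]
      b <- sum(md$db[idx[used]]); cc <- sum(md$dc[idx[used]])
    } else {
      sx <- .norm_sex(rep_len(sex, nrow(trios)))
      for (s in unique(sx)) {
        w <- used & sx == s
        md <- .tabs(if (s == 1L) "XM" else "XF")$models[[model]]
        b <- b + sum(md$db[idx[w]]); cc <- cc + sum(md$dc[idx[w]])
      }
    }
  }
  structure(c(b = b, c = cc),
            n_excluded_mendel = sum(!used), n_used = sum(used))
}

#' TDT (McNemar) statistic from transmission counts
#'
#' `chi2 = (b - c)^2 / (b + c)`, referred to the chi-squared distribution
#' with 1 degree of freedom. Undefined (NA) when `b + c = 0`.
#'
#' @param b,c Transmission counts; `b` may also be the vector returned by
#'   [tdt_counts()], in which case `c` is taken from it.
#' @return A list with `b`, `c`, `chi2` and `p_value`.
#' @export
tdt_statistic <- function(b, c = NULL) {
  if (is.null(c) && length(b) >= 2) { c <- b[["c"]]; b <- b[["b"]] }
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    chi2 <- (b - c)^2 / (b + c)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(b = as.integer(b), c = as.integer(c), chi2 = chi2, p_value = p)
}

#' Transmission disequilibrium test
#'
#' Classical case-parent trio TDT over complete trios, extended to dominant
#' and recessive models and the X chromosome. See [tdt_counts()] for the
#' counting rules.
#'
#' @inheritParams tdt_counts
#' @return An object of class `"tdt_result"`: [tdt_statistic()] output plus
#'   trio bookkeeping counts.
#' @export
tdt <- function(trios, model = "additive", chrom = "autosomal") {
  cts <- tdt_counts(trios, model = model, chrom = chrom)
  out <- tdt_statistic(cts)
  out$n_used <- attr(cts, "n_used")
  out$n_excluded_mendel <- attr(cts, "n_excluded_mendel")
  class(out) <- "tdt_result"
  out
}

#' @export
print.tdt_result <- function(x, ...) {
  cat(sprintf("TDT: b = %d, c = %d", x$b, x$c))
  if (is.na(x$chi2)) cat("; statistic undefined (b + c = 0)\n")
  else cat(sprintf("; chi2(1) = %.4f, p = %s\n", x$chi2,
                   format_pvalue(x$p_value)))
  invisible(x)
}

#' Transmission-count options of an incomplete trio
#'
#' For an affected incomplete trio, returns the distinct `(b, c)` count
#' increments realized by its Mendelian-consistent completions. robustTDT
#' explores these options to bound the TDT statistic.
#'
#' @param father,mother,offspring Scalar allele dosages, `NA` = missing.
#' @inheritParams tdt_counts
#' @param sex Offspring sex (required when `chrom = "X"`).
#' @return Integer matrix with columns `db`, `dc`, one row per distinct
#'   option.
#' @examples
#' trio_count_options(NA, 0, 1)  # {(1,0), (0,0)}
#' @export
trio_count_options <- function(father, mother, offspring, model = "additive",
                               chrom = "autosomal", sex = NULL) {
  model <- .norm_model(model)
  ctx <- .ctx_of(chrom, sex)
  if (!anyNA(c(father, mother, offspring)))
    stop("trio is complete; no completion options", call. = FALSE)
  tb <- .tabs(ctx)
  rows <- tb$comp[[.pattern_code(father, mother, offspring)]]
  if (!length(rows))
    stop("observed members are Mendelian-inconsistent", call. = FALSE)
  md <- tb$models[[model]]
  opts <- unique(cbind(db = md$db[rows], dc = md$dc[rows]))
  rownames(opts) <- NULL
  opts
}

#' robustTDT: exact bounds of the TDT statistic over genotype completions
#'
#' Lower and upper bounds of the TDT chi-squared statistic over all joint
#' Mendelian-consistent completions of the incomplete affected trios, with
#' base counts from the complete affected trios. The reachable set of
#' `(b, c)` totals is built by dynamic programming (each incomplete trio
#' contributes one option from [trio_count_options()]), and the exact
#' minimum and maximum of `(b - c)^2 / (b + c)` over that set are returned;
#' totals with `b + c = 0` carry no transmission information and enter the
#' bounds as 0. With no incomplete trios both bounds equal the TDT
#' statistic.
#'
#' @inheritParams tdt_counts
#' @return An object of class `"robust_tdt_result"`: a list with
#'   `chi2_lower`, `chi2_upper`, `p_lower`, `p_upper` (p-values at the upper
#'   and lower statistic bounds respectively), `counts_base`,
#'   `reachable_count`, `n_incomplete`, `n_excluded_mendel`.
#' @export
robust_tdt <- function(trios, model = "additive", chrom = "autosomal") {
  model <- .norm_model(model)
  ch <- .norm_chrom(chrom)
  trios <- trios[trios$affected %in% TRUE, , drop = FALSE]
  complete <- !is.na(trios$father) & !is.na(trios$mother) &
    !is.na(trios$offspring)
  cts <- tdt_counts(trios[complete, , drop = FALSE], model = model,
                    chrom = ch)
  inc <- trios[!complete, , drop = FALSE]
  n_excl <- attr(cts, "n_excluded_mendel")

  reach <- matrix(c(cts[["b"]], cts[["c"]]), nrow = 1)
  n_inc <- 0L
  if (nrow(inc)) {
    for (i in seq_len(nrow(inc))) {
      opts <- tryCatch(
        trio_count_options(inc$father[i], inc$mother[i], inc$offspring[i],
                           model = model, chrom = ch,
                           sex = if (ch == "X") inc$sex[i] else NULL),
        error = function(e) NULL)
      if (is.null(opts)) { n_excl <- n_excl + 1L; next }
      n_inc <- n_inc + 1L
      new_b <- rep(reach[, 1], times = nrow(opts)) +
        rep(opts[, 1], each = nrow(reach))
      new_c <- rep(reach[, 2], times = nrow(opts)) +
        rep(opts[, 2], each = nrow(reach))
      key <- new_b * 1e6 + new_c
      keep <- !duplicated(key)
      reach <- cbind(new_b[keep], new_c[keep])
    }
  }
  tot <- reach[, 1] + reach[, 2]
  chi2 <- ifelse(tot > 0, (reach[, 1] - reach[, 2])^2 / tot, 0)
  lo <- min(chi2); hi <- max(chi2)
  structure(list(
    chi2_lower = lo, chi2_upper = hi,
    p_lower = stats::pchisq(hi, df = 1, lower.tail = FALSE),
    p_upper = stats::pchisq(lo, df = 1, lower.tail = FALSE),
    counts_base = c(b = cts[["b"]], c = cts[["c"]]),
    reachable_count = nrow(reach),
    n_incomplete = n_inc, n_excluded_mendel = n_excl
  ), class = "robust_tdt_result")
}

#' @export
print.robust_tdt_result <- function(x, ...) {
  cat(sprintf("robustTDT bounds: chi2 in [%.4f, %.4f]\n",
              x$chi2_lower, x$chi2_upper))
  cat(sprintf("  p in [%s, %s]; base counts b = %d, c = %d\n",
              format_pvalue(x$p_lower), format_pvalue(x$p_upper),
              x$counts_base[["b"]], x$counts_base[["c"]]))
  cat(sprintf("  %d incomplete trios, %d reachable (b, c) totals, %d excluded\n",
              x$n_incomplete, x$reachable_count, x$n_excluded_mendel))
  invisible(x)
}
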