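#' Mendelian offspring genotype distribution
#'
#' Distribution of the offspring allele dosage given parental dosages, under
#' Mendelian transmission: on autosomes each parent transmits one of its two
#' alleles with probability 1/2; on the X chromosome a son receives his
#' single X from the mother while a daughter additionally receives the
#' father's X allele with certainty.
#'
#' @param father,mother Parental allele dosages (autosomal/mother: 0, 1 or 2;
#'   X-chromosome father: 0 or 1). Must be non-missing.
#' @param chrom `"autosomal"` or `"X"`.
#' @param sex Offspring sex, required when `chrom = "X"`: 1/`"male"` or
#'   2/`"female"`.
#' @return Named numeric vector of probabilities over the possible offspring
#'   dosages; sums to 1.
#' @examples
#' offspring_distribution(0, 1)             # {0: 1/2, 1: 1/2}
#' offspring_distribution(1, 1, "X", "female")
#' @export
offspring_distribution <- function(father, mother, chrom = "autosomal",
                                   sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  .check_dosage(father, .father_space(ctx), "father")
  .check_dosage(mother, .mother_space(ctx), "mother")
  .off_dist(father, mother, ctx)
}

#' Code a genotype under a genetic model
#'
#' Converts an allele dosage into the coded value X used by the association
#' statistics: additive counts non-reference alleles; dominant codes 1 for
#' any non-reference allele; recessive codes 1 only for the alternate
#' homozygote (or the hemizygous alternate on the male X, which expresses a
#' recessive allele).
#'
#' @param g Allele dosage vector (non-missing).
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @inheritParams offspring_distribution
#' @return Numeric vector of coded values.
#' @export
code_genotype <- function(g, model = "additive", chrom = "autosomal",
                          sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  model <- .norm_model(model)
  .check_dosage(g, .offspring_space(ctx), "genotype")
  .code_geno(g, model, ctx)
}

#' Score a complete trio
#'
#' Computes the centered coded offspring genotype `X - E[X]` and its
#' conditional variance `Var(X)`, where the expectation is over the
#' Mendelian offspring distribution given the parents. These are the
#' per-trio building blocks of the FBAT statistic. Both are exactly 0 for
#' non-informative matings (e.g. both parents homozygous).
#'
#' @param father,mother,offspring Allele dosage vectors (recycled to common
#'   length). All must be non-missing and Mendelian-consistent.
#' @inheritParams code_genotype
#' @return A data.frame with columns `x_minus_e` and `var_x`.
#' @examples
#' trio_score(0, 1, 1)  # (0.5, 0.25)
#' @export
trio_score <- function(father, mother, offspring, model = "additive",
                       chrom = "autosomal", sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  model <- .norm_model(model)
  n <- max(length(father), length(mother), length(offspring))
  father <- rep_len(father, n); mother <- rep_len(mother, n)
  offspring <- rep_len(offspring, n)
  .check_dosage(father, .father_space(ctx), "father")
  .check_dosage(mother, .mother_space(ctx), "mother")
  .check_dosage(offspring, .offspring_space(ctx), "offspring")
  tb <- .tabs(ctx)
  idx <- tb$code_map[.pattern_code(father, mother, offspring)]
  if (anyNA(idx))
    stop(sprintf("Mendelian-inconsistent trio(s) at position(s): %s",
                 paste(which(is.na(idx)), collapse = ", ")), call. = FALSE)
  md <- tb$models[[model]]
  data.frame(x_minus_e = md$xme[idx], var_x = md$varx[idx])
}

#' Is a mating informative under a genetic model?
#'
#' A mating (parental genotype pair) is informative when the coded offspring
#' genotype has positive variance over the Mendelian offspring distribution.
#' Under the dominant model heterozygote x alternate-homozygote matings are
#' non-informative; under the recessive model heterozygote x
#' reference-homozygote matings are non-informative.
#'
#' @param father,mother Parental allele dosage vectors (non-missing).
#' @inheritParams code_genotype
#' @return Logical vector.
#' @export
is_informative <- function(father, mother, model = "additive",
                           chrom = "autosomal", sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  model <- .norm_model(model)
  n <- max(length(father), length(mother))
  father <- rep_len(father, n); mother <- rep_len(mother, n)
  .check_dosage(father, .father_space(ctx), "father")
  .check_dosage(mother, .mother_space(ctx), "mother")
  vapply(seq_len(n), function(i) {
    d <- .off_dist(father[i], mother[i], ctx)
    x <- .code_geno(as.numeric(names(d)), model, ctx)
    sum(d * x^2) - sum(d * x)^2 > 0
  }, logical(1))
}

#' Mendelian consistency of a (possibly incomplete) trio
#'
#' TRUE when some assignment of transmitted alleles reconciles the observed
#' (non-missing) members; missing members impose no constraint, so a fully
#' missing trio is vacuously consistent.
#'
#' @inheritParams trio_score
#' @param father,mother,offspring Allele dosages, `NA` = missing.
#' @return Logical vector.
#' @export
is_mendelian_consistent <- function(father, mother, offspring,
                                    chrom = "autosomal", sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  n <- max(length(father), length(mother), length(offspring))
  father <- rep_len(father, n); mother <- rep_len(mother, n)
  offspring <- rep_len(offspring, n)
  .check_dosage(father, .father_space(ctx), "father", allow_na = TRUE)
  .check_dosage(mother, .mother_space(ctx), "mother", allow_na = TRUE)
  .check_dosage(offspring, .offspring_space(ctx), "offspring", allow_na = TRUE)
  tb <- .tabs(ctx)
  pc <- .pattern_code(father, mother, offspring)
  vapply(pc, function(p) length(tb$comp[[p]]) > 0, logical(1))
}

#' Enumerate Mendelian-consistent completions of an incomplete trio
#'
#' Returns every distinct assignment of genotypes to the missing members of
#' a trio such that the completed trio is Mendelian-consistent. Completions
#' with non-informative matings are included (they score (0, 0)). CIFBAT and
#' robustTDT treat all completions as equally likely.
#'
#' @param father,mother,offspring Scalar allele dosages, `NA` = missing; at
#'   least one must be missing.
#' @inheritParams offspring_distribution
#' @return A data.frame with columns `father`, `mother`, `offspring`, one
#'   row per completion.
#' @examples
#' enumerate_completions(NA, 1, 2)          # father in {1, 2}
#' nrow(enumerate_completions(NA, NA, NA))  # 15 on autosomes
#' @export
enumerate_completions <- function(father, mother, offspring,
                                  chrom = "autosomal", sex = NULL) {
  ctx <- .ctx_of(chrom, sex)
  stopifnot(length(father) == 1, length(mother) == 1, length(offspring) == 1)
  .check_dosage(father, .father_space(ctx), "father", allow_na = TRUE)
  .check_dosage(mother, .mother_space(ctx), "mother", allow_na = TRUE)
  .check_dosage(offspring, .offspring_space(ctx), "offspring", allow_na = TRUE)
  if (!anyNA(c(father, mother, offspring)))
    stop("trio is already complete; nothing to enumerate", call. = FALSE)
  tb <- .tabs(ctx)
  rows <- tb$comp[[.pattern_code(father, mother, offspring)]]
  if (!length(rows))
    stop("observed members are Mendelian-inconsistent; no valid completion",
         call. = FALSE)
  out <- tb$configs[rows, , drop = FALSE]
  names(out) <- c("father", "mother", "offspring")
  rownames(out) <- NULL
  out
}
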