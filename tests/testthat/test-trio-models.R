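# Genotype coding, Mendelian transmission, trio scoring and completion
# enumeration, checked against brute-force transmission oracles.

ctx_args <- list(A  = list(chrom = "autosomal", sex = NULL),
                 XM = list(chrom = "X", sex = 1L),
                 XF = list(chrom = "X", sex = 2L))

test_that("offspring distributions follow Mendelian transmission and sum to 1", {
  expect_equal(offspring_distribution(0, 1), c(`0` = 0.5, `1` = 0.5, `2` = 0))
  expect_equal(offspring_distribution(0, 0), c(`0` = 1, `1` = 0, `2` = 0))
  expect_equal(offspring_distribution(1, 1, "X", "female"),
               c(`0` = 0, `1` = 0.5, `2` = 0.5))
  expect_equal(offspring_distribution(0, 2, "X", "male"), c(`0` = 0, `1` = 1))
  for (ctx in names(ctx_args)) {
    a <- ctx_args[[ctx]]
    for (f in if (ctx == "A") 0:2 else 0:1) for (m in 0:2) {
      d <- offspring_distribution(f, m, a$chrom, a$sex)
      expect_equal(sum(d), 1)
      # matches the empirical distribution of enumerated transmissions
      out <- oracle_offspring_outcomes(f, m, ctx)
      for (o in as.numeric(names(d)))
        expect_equal(d[[as.character(o)]], mean(out == o))
    }
  }
  expect_error(offspring_distribution(2, 1, "X", "male"), "father")
  expect_error(offspring_distribution(NA, 1), "father")
})

test_that("genotype coding implements the three genetic models", {
  expect_equal(code_genotype(0:2, "additive"), c(0, 1, 2))
  expect_equal(code_genotype(0:2, "dominant"), c(0, 1, 1))
  expect_equal(code_genotype(0:2, "recessive"), c(0, 0, 1))
  # hemizygous alternate expresses a recessive allele
  expect_equal(code_genotype(0:1, "recessive", "X", "male"), c(0, 1))
  expect_equal(code_genotype(0:1, "dominant", "X", "male"), c(0, 1))
  expect_error(code_genotype(NA, "additive"), "genotype")
})

test_that("trio_score matches the worked example and flags inconsistency", {
  s <- trio_score(0, 1, 1)
  expect_equal(s$x_minus_e, 0.5)
  expect_equal(s$var_x, 0.25)
  expect_equal(trio_score(1, 1, 0), data.frame(x_minus_e = -1, var_x = 0.5))
  expect_error(trio_score(0, 0, 1), "inconsistent")
})

test_that("trio_score equals the transmission-enumeration oracle everywhere", {
  for (ctx in names(ctx_args)) {
    a <- ctx_args[[ctx]]
    for (model in c("additive", "dominant", "recessive")) {
      for (f in .space_f(ctx)) for (m in 0:2) for (o in .space_o(ctx)) {
        expected <- oracle_trio_score(f, m, o, model, ctx)
        if (is.null(expected)) {
          expect_error(trio_score(f, m, o, model, a$chrom, a$sex),
                       "inconsistent")
        } else {
          got <- trio_score(f, m, o, model, a$chrom, a$sex)
          expect_equal(c(got$x_minus_e, got$var_x), expected,
                       info = sprintf("%s/%s f=%d m=%d o=%d", ctx, model, f, m, o))
        }
      }
    }
  }
})

test_that("model-specific non-informative matings score (0, 0)", {
  # dominant: het x alt-hom; recessive: het x ref-hom; any double homozygote
  for (o in 1:2)
    expect_equal(unlist(trio_score(1, 2, o, "dominant")),
                 c(x_minus_e = 0, var_x = 0))
  for (o in 0:1)
    expect_equal(unlist(trio_score(1, 0, o, "recessive")),
                 c(x_minus_e = 0, var_x = 0))
  for (model in c("additive", "dominant", "recessive")) {
    expect_equal(unlist(trio_score(0, 0, 0, model)),
                 c(x_minus_e = 0, var_x = 0))
    expect_equal(unlist(trio_score(2, 2, 2, model)),
                 c(x_minus_e = 0, var_x = 0))
  }
  expect_false(is_informative(1, 2, "dominant"))
  expect_false(is_informative(1, 0, "recessive"))
  expect_true(is_informative(1, 1, "recessive"))
  expect_true(is_informative(1, 0, "additive"))
  expect_false(is_informative(0, 0, "additive"))
})

test_that("informativeness equals positive score variance", {
  for (ctx in names(ctx_args)) {
    a <- ctx_args[[ctx]]
    for (model in c("additive", "dominant", "recessive"))
      for (f in .space_f(ctx)) for (m in 0:2) {
        out <- oracle_offspring_outcomes(f, m, ctx)
        x <- oracle_code(out, model, ctx)
        expect_identical(is_informative(f, m, model, a$chrom, a$sex),
                         stats::var(x) > 0)
      }
  }
})

test_that("Mendelian consistency handles missing members", {
  expect_false(is_mendelian_consistent(0, 0, 1))
  expect_true(is_mendelian_consistent(0, 1, 1))
  expect_false(is_mendelian_consistent(NA, 0, 2))
  expect_true(is_mendelian_consistent(NA, NA, NA))   # vacuous
  expect_true(is_mendelian_consistent(NA, 1, 2))
  # X: son's genotype constrains only the mother
  expect_true(is_mendelian_consistent(0, 1, 1, "X", sex = 1))
  expect_false(is_mendelian_consistent(1, 0, 1, "X", sex = 1))
  expect_false(is_mendelian_consistent(0, 1, 2, "X", sex = 2))
})

test_that("completion enumeration equals brute force for all missingness patterns", {
  for (ctx in names(ctx_args)) {
    a <- ctx_args[[ctx]]
    vals_f <- c(.space_f(ctx), NA); vals_o <- c(.space_o(ctx), NA)
    for (f in vals_f) for (m in c(0:2, NA)) for (o in vals_o) {
      if (!anyNA(c(f, m, o))) next
      expected <- oracle_completions(f, m, o, ctx)
      if (nrow(expected) == 0) {
        expect_error(enumerate_completions(f, m, o, a$chrom, a$sex),
                     "inconsistent")
      } else {
        got <- enumerate_completions(f, m, o, a$chrom, a$sex)
        expect_equal(nrow(got), nrow(expected))
        expect_setequal(paste(got$father, got$mother, got$offspring),
                        paste(expected$f, expected$m, expected$o))
      }
    }
  }
  expect_equal(nrow(enumerate_completions(NA, NA, NA)), 15)
  expect_equal(sort(enumerate_completions(NA, 1, 2)$father), c(1, 2))
  expect_error(enumerate_completions(0, 1, 1), "complete")
})

test_that("allele relabelling negates x_minus_e and preserves var_x (additive)", {
  for (f in 0:2) for (m in 0:2) for (o in 0:2) {
    if (is.null(oracle_trio_score(f, m, o, "additive", "A"))) next
    s <- trio_score(f, m, o)
    sflip <- trio_score(2 - f, 2 - m, 2 - o)
    expect_equal(sflip$x_minus_e, -s$x_minus_e)
    expect_equal(sflip$var_x, s$var_x)
  }
})
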