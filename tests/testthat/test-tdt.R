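# TDT transmission counts, McNemar statistic and robustTDT bounds.

test_that("tdt_counts matches the classical additive construction", {
  expect_equal(unname(tdt_counts(make_trios(0, 1, 1))[1:2]), c(1L, 0L))
  expect_equal(unname(tdt_counts(make_trios(0, 0, 0))[1:2]), c(0L, 0L))
  # het x het -> het: one b and one c under additive
  expect_equal(unname(tdt_counts(make_trios(1, 1, 1))[1:2]), c(1L, 1L))
  # oracle over every consistent complete trio
  for (f in 0:2) for (m in 0:2) for (o in 0:2) {
    expected <- oracle_tdt_additive(f, m, o)
    if (is.null(expected)) next
    got <- tdt_counts(make_trios(f, m, o))
    expect_equal(unname(got[1:2]), expected,
                 info = sprintf("f=%d m=%d o=%d", f, m, o))
  }
})

test_that("dominant/recessive transmissions follow model informativeness", {
  # het x alt-hom is non-informative under dominance
  for (o in 1:2)
    expect_equal(sum(tdt_counts(make_trios(1, 2, o), model = "dominant")),
                 0L)
  # het x ref-hom is non-informative under recessivity
  for (o in 0:1)
    expect_equal(sum(tdt_counts(make_trios(1, 0, o), model = "recessive")),
                 0L)
  # but het x ref-hom is informative under dominance
  expect_equal(unname(tdt_counts(make_trios(1, 0, 1), model = "dominant")[1:2]),
               c(1L, 0L))
  # and het x alt-hom under recessivity
  expect_equal(unname(tdt_counts(make_trios(1, 2, 2), model = "recessive")[1:2]),
               c(1L, 0L))
})

test_that("only affected complete consistent trios are tallied", {
  tr <- make_trios(c(0, 0, NA, 0), c(1, 1, 1, 0), c(1, 1, 1, 1),
                   affected = c(TRUE, FALSE, TRUE, TRUE))
  got <- tdt_counts(tr)
  expect_equal(unname(got[1:2]), c(1L, 0L))
  expect_equal(attr(got, "n_excluded_mendel"), 1L)  # the (0,0,1) trio
})

test_that("X-linked counting: sons maternal-only, fathers never counted", {
  # affected son, het mother transmitting alt
  expect_equal(unname(tdt_counts(make_trios(1, 1, 1, sex = 1L),
                                 chrom = "X")[1:2]), c(1L, 0L))
  # affected daughter: father hemizygous alt is never a counted transmission
  expect_equal(unname(tdt_counts(make_trios(1, 0, 1, sex = 2L),
                                 chrom = "X")[1:2]), c(0L, 0L))
  # daughter with het mother
  expect_equal(unname(tdt_counts(make_trios(0, 1, 1, sex = 2L),
                                 chrom = "X")[1:2]), c(1L, 0L))
})

test_that("tdt_statistic is the McNemar form", {
  s <- tdt_statistic(10, 5)
  expect_equal(s$chi2, 25 / 15)
  expect_equal(s$p_value, pchisq(25 / 15, 1, lower.tail = FALSE))
  expect_equal(tdt_statistic(7, 7)$chi2, 0)
  expect_equal(tdt_statistic(7, 7)$p_value, 1)
  expect_true(is.na(tdt_statistic(0, 0)$chi2))
})

test_that("trio_count_options enumerates distinct completion increments", {
  opts <- trio_count_options(NA, 0, 1)
  expect_setequal(paste(opts[, 1], opts[, 2]), c("1 0", "0 0"))
  expect_error(trio_count_options(0, 1, 1), "complete")
  full <- trio_count_options(NA, NA, NA)
  brute <- unique(t(sapply(seq_len(15), function(i) {
    cp <- enumerate_completions(NA, NA, NA)[i, ]
    unname(tdt_counts(make_trios(cp$father, cp$mother, cp$offspring)))[1:2]
  })))
  expect_setequal(paste(full[, 1], full[, 2]), paste(brute[, 1], brute[, 2]))
})

test_that("robust_tdt collapses to TDT without incomplete trios", {
  tr <- make_trios(c(1, 1, 0), c(0, 1, 1), c(1, 2, 1))
  r <- robust_tdt(tr)
  t0 <- tdt(tr)
  expect_equal(r$chi2_lower, t0$chi2)
  expect_equal(r$chi2_upper, t0$chi2)
  expect_equal(r$reachable_count, 1L)
})

test_that("robust_tdt reproduces the two-case hand example", {
  # base counts (10, 5) plus one trio with options {(1,0), (0,0)}
  base <- make_trios(rep(1, 15), rep(0, 15), c(rep(1, 10), rep(0, 5)))
  tr <- rbind(base, make_trios(NA_integer_, 0, 1))
  r <- robust_tdt(tr)
  expect_equal(r$chi2_lower, 25 / 15)
  expect_equal(r$chi2_upper, 36 / 16)
  expect_equal(r$p_upper, pchisq(25 / 15, 1, lower.tail = FALSE))
  expect_equal(r$p_lower, pchisq(36 / 16, 1, lower.tail = FALSE))
})

test_that("DP bounds equal exhaustive joint enumeration on random instances", {
  set.seed(41)
  for (model in c("additive", "dominant", "recessive")) {
    for (rep in 1:6) {
      nC <- sample(3:8, 1); nI <- sample(1:5, 1)
      q <- runif(1, 0.2, 0.6)
      f <- rbinom(nC, 2, q); m <- rbinom(nC, 2, q)
      o <- rbinom(nC, 1, f / 2) + rbinom(nC, 1, m / 2)
      complete <- make_trios(f, m, o)
      fi <- rbinom(nI, 2, q); mi <- rbinom(nI, 2, q)
      oi <- rbinom(nI, 1, fi / 2) + rbinom(nI, 1, mi / 2)
      incomplete <- make_trios(fi, mi, oi)
      for (i in seq_len(nI)) {
        drop <- sample(c("father", "mother", "offspring"),
                       sample(1:2, 1))
        incomplete[i, drop] <- NA
      }
      expected <- oracle_robust_tdt_bounds(complete, incomplete, model,
                                           "autosomal")
      r <- robust_tdt(rbind(complete, incomplete), model = model)
      expect_equal(c(r$chi2_lower, r$chi2_upper), expected,
                   info = paste(model, rep))
    }
  }
})

test_that("adding an incomplete trio never narrows the bounds", {
  set.seed(43)
  tr <- make_trios(c(1, 1, 1, 0), c(0, 1, 2, 1), c(1, 2, 2, 1))
  r0 <- robust_tdt(tr)
  extra <- make_trios(NA_integer_, 1, 1)
  r1 <- robust_tdt(rbind(tr, extra))
  expect_lte(r1$chi2_lower, r0$chi2_lower)
  expect_gte(r1$chi2_upper, r0$chi2_upper)
})

test_that("TDT p-values are uniform under null transmission", {
  set.seed(47)
  p <- replicate(300, {
    n <- 80
    f <- rbinom(n, 2, 0.4); m <- rbinom(n, 2, 0.4)
    o <- rbinom(n, 1, f / 2) + rbinom(n, 1, m / 2)
    tdt(make_trios(f, m, o))$p_value
  })
  expect_equal(mean(p < 0.2, na.rm = TRUE), 0.2, tolerance = 0.3)
})
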