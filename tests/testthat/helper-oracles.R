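# Independent brute-force oracles used throughout the test suite.
# They enumerate equally likely allele transmissions directly and never go
# through the package's lookup tables.

# parental allele pair from a dosage
.alleles <- function(d) c(as.integer(d >= 1), as.integer(d == 2))

# enumerate the equally likely transmission outcomes (offspring dosages):
# 4 on autosomes, 2 on the X
oracle_offspring_outcomes <- function(f, m, ctx) {
  ma <- .alleles(m)
  if (ctx == "A") {
    fa <- .alleles(f)
    as.vector(outer(fa, ma, `+`))
  } else if (ctx == "XM") {
    ma
  } else {
    f + ma
  }
}

oracle_code <- function(g, model, ctx) {
  switch(model,
    additive = g,
    dominant = as.numeric(g >= 1),
    recessive = if (ctx == "XM") as.numeric(g == 1) else as.numeric(g == 2))
}

# (x - E[x], Var(x)) for a complete trio, or NULL if inconsistent
oracle_trio_score <- function(f, m, o, model, ctx) {
  out <- oracle_offspring_outcomes(f, m, ctx)
  if (!o %in% out) return(NULL)
  x <- oracle_code(out, model, ctx)
  ex <- mean(x); ex2 <- mean(x^2)
  c(oracle_code(o, model, ctx) - ex, ex2 - ex^2)
}

.space_f <- function(ctx) if (ctx == "A") 0:2 else 0:1
.space_o <- function(ctx) if (ctx == "XM") 0:1 else 0:2

# brute-force completion enumeration over the full genotype space
oracle_completions <- function(f, m, o, ctx) {
  grid <- expand.grid(f = .space_f(ctx), m = 0:2, o = .space_o(ctx))
  ok <- !logical(nrow(grid))
  if (!is.na(f)) ok <- ok & grid$f == f
  if (!is.na(m)) ok <- ok & grid$m == m
  if (!is.na(o)) ok <- ok & grid$o == o
  cons <- mapply(function(ff, mm, oo) oo %in% oracle_offspring_outcomes(ff, mm, ctx),
                 grid$f, grid$m, grid$o)
  grid[ok & cons, , drop = FALSE]
}

# classical additive autosomal TDT counting, written independently:
# every heterozygous parent with unambiguous transmission contributes; the
# doubly-ambiguous het x het -> het trio contributes one b and one c
oracle_tdt_additive <- function(f, m, o) {
  b <- 0L; cc <- 0L
  if (f == 1L && m == 1L && o == 1L) return(c(1L, 1L))
  pairs <- expand.grid(tf = unique(.alleles(f)), tm = unique(.alleles(m)))
  pairs <- pairs[pairs$tf + pairs$tm == o, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  tf <- pairs$tf[1]; tm <- pairs$tm[1]
  if (f == 1L) { if (tf == 1L) b <- b + 1L else cc <- cc + 1L }
  if (m == 1L) { if (tm == 1L) b <- b + 1L else cc <- cc + 1L }
  c(b, cc)
}

# exhaustive joint-completion bounds of the TDT chi2 statistic; increments
# per completed trio come from tdt_counts() on a single-trio frame, but the
# joint exploration (the part robust_tdt's DP replaces) is exhaustive here
oracle_robust_tdt_bounds <- function(complete, incomplete, model, chrom) {
  base <- tdt_counts(complete, model = model, chrom = chrom)
  opt_list <- lapply(seq_len(nrow(incomplete)), function(i) {
    tr <- incomplete[i, , drop = FALSE]
    comps <- enumerate_completions(tr$father, tr$mother, tr$offspring,
                                   chrom = chrom,
                                   sex = if ("sex" %in% names(tr)) tr$sex else NULL)
    t(vapply(seq_len(nrow(comps)), function(k) {
      one <- data.frame(father = comps$father[k], mother = comps$mother[k],
                        offspring = comps$offspring[k], affected = TRUE,
                        sex = if ("sex" %in% names(tr)) tr$sex else 1L)
      unname(tdt_counts(one, model = model, chrom = chrom))
    }, numeric(2)))
  })
  combos <- expand.grid(lapply(opt_list, function(o) seq_len(nrow(o))))
  chi2 <- apply(combos, 1, function(ix) {
    bc <- c(base[["b"]], base[["c"]])
    for (i in seq_along(ix)) bc <- bc + opt_list[[i]][ix[i], ]
    if (sum(bc) == 0) 0 else (bc[1] - bc[2])^2 / sum(bc)
  })
  c(min(chi2), max(chi2))
}

# small deterministic trio frame builder
make_trios <- function(f, m, o, affected = TRUE, sex = NULL) {
  df <- data.frame(father = f, mother = m, offspring = o,
                   affected = affected)
  if (!is.null(sex)) df$sex <- sex
  df
}
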