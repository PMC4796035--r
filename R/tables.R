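# Internal lookup tables for trio genetics.
#
# A trio context is one of:
#   "A"  - autosomal marker (father, mother, offspring dosages in 0:2)
#   "XM" - X marker, male offspring (father in 0:1, offspring in 0:1)
#   "XF" - X marker, female offspring (father in 0:1, offspring in 0:2)
#
# Observed genotype patterns (possibly missing) are encoded base-4 with
# missing mapped to 3: code = f*16 + m*4 + o, in 0..63.  All per-pattern
# quantities (Mendelian consistency, completion sets, per-model completion
# scores and TDT count options) are precomputed once per context so that
# marker-level scans reduce to table lookups.

.famtrio_cache <- new.env(parent = emptyenv())

.CTX <- c("A", "XM", "XF")
.MODELS <- c("additive", "dominant", "recessive")

.father_space <- function(ctx) if (ctx == "A") 0:2 else 0:1
.mother_space <- function(ctx) 0:2
.offspring_space <- function(ctx) if (ctx == "XM") 0:1 else 0:2

# P(offspring dosage) given parental dosages, from Mendelian transmission.
.off_dist <- function(f, m, ctx) {
  pm <- m / 2
  if (ctx == "A") {
    pf <- f / 2
    c(`0` = (1 - pf) * (1 - pm),
      `1` = pf * (1 - pm) + (1 - pf) * pm,
      `2` = pf * pm)
  } else if (ctx == "XM") {
    # sons inherit their single X from the mother
    c(`0` = 1 - pm, `1` = pm)
  } else {
    # daughters always receive the father's single X allele
    d <- c(`0` = 0, `1` = 0, `2` = 0)
    d[[as.character(f)]] <- 1 - pm
    d[[as.character(f + 1)]] <- pm
    d
  }
}

# Offspring genotype coding under the genetic model.
.code_geno <- function(g, model, ctx) {
  switch(model,
    additive  = g,
    dominant  = as.numeric(g >= 1),
    recessive = if (ctx == "XM") as.numeric(g == 1) else as.numeric(g == 2))
}

.pattern_code <- function(f, m, o) {
  fi <- ifelse(is.na(f), 3L, as.integer(f))
  mi <- ifelse(is.na(m), 3L, as.integer(m))
  oi <- ifelse(is.na(o), 3L, as.integer(o))
  fi * 16L + mi * 4L + oi + 1L
}

# TDT transmission-count increments (b, c) for one complete consistent trio.
# A heterozygous parent's transmission is counted when swapping the
# transmitted allele (holding the other parent's realized transmission fixed)
# would change the coded offspring genotype under the model.
.tdt_increments <- function(f, m, o, ctx, model) {
  b <- 0L; c_ <- 0L
  count_one <- function(t, o_alt, off_ctx_code) {
    if (off_ctx_code(o) != off_ctx_code(o_alt)) {
      if (t == 1L) b <<- b + 1L else c_ <<- c_ + 1L
    }
  }
  code <- function(g) .code_geno(g, model, ctx)
  if (ctx == "A") {
    # realized transmissions; het x het with het offspring is ambiguous but
    # both attributions give identical totals, so pick (father=1, mother=0)
    pairs <- list()
    tf_opts <- if (f == 1L) 0:1 else f / 2L
    tm_opts <- if (m == 1L) 0:1 else m / 2L
    for (tf in tf_opts) for (tm in tm_opts)
      if (tf + tm == o) pairs[[length(pairs) + 1L]] <- c(tf, tm)
    if (!length(pairs)) return(NULL)
    p <- pairs[[1L]]
    if (length(pairs) > 1L) p <- c(1L, 0L)
    tf <- p[1]; tm <- p[2]
    if (f == 1L) count_one(tf, (1L - tf) + tm, code)
    if (m == 1L) count_one(tm, tf + (1L - tm), code)
  } else if (ctx == "XM") {
    # father transmits no X to sons; only a heterozygous mother counts
    if (m == 1L) count_one(o, 1L - o, code)
  } else {
    # father is hemizygous, never heterozygous; mother's transmission is
    # determined as o - f
    if (m == 1L) {
      tm <- o - f
      if (tm %in% 0:1) count_one(tm, f + (1L - tm), code)
    }
  }
  c(b, c_)
}

.build_ctx_tables <- function(ctx) {
  fs <- .father_space(ctx); ms <- .mother_space(ctx); os <- .offspring_space(ctx)
  grid <- expand.grid(f = fs, m = ms, o = os, KEEP.OUT.ATTRS = FALSE)
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- .off_dist(grid$f[i], grid$m[i], ctx)
    keep[i] <- d[[as.character(grid$o[i])]] > 0
  }
  configs <- grid[keep, , drop = FALSE]
  rownames(configs) <- NULL
  nconf <- nrow(configs)

  # complete-pattern code -> config row (NA if incomplete or inconsistent)
  code_map <- rep(NA_integer_, 64L)
  code_map[.pattern_code(configs$f, configs$m, configs$o)] <- seq_len(nconf)

  # completion sets for every observed pattern (rows into `configs`)
  comp <- vector("list", 64L)
  vals_f <- c(fs, NA); vals_m <- c(ms, NA); vals_o <- c(os, NA)
  for (f in vals_f) for (m in vals_m) for (o in vals_o) {
    pc <- .pattern_code(f, m, o)
    ok <- rep(TRUE, nconf)
    if (!is.na(f)) ok <- ok & configs$f == f
    if (!is.na(m)) ok <- ok & configs$m == m
    if (!is.na(o)) ok <- ok & configs$o == o
    comp[[pc]] <- which(ok)
  }
  # patterns never set above (e.g. father=2 on X) stay NULL -> invalid input

  models <- list()
  for (model in .MODELS) {
    xme <- numeric(nconf); varx <- numeric(nconf)
    db <- integer(nconf); dc <- integer(nconf)
    for (i in seq_len(nconf)) {
      d <- .off_dist(configs$f[i], configs$m[i], ctx)
      g <- as.numeric(names(d))
      x <- .code_geno(g, model, ctx)
      ex <- sum(d * x); ex2 <- sum(d * x^2)
      xme[i] <- .code_geno(configs$o[i], model, ctx) - ex
      varx[i] <- max(ex2 - ex^2, 0)
      inc <- .tdt_increments(configs$f[i], configs$m[i], configs$o[i], ctx, model)
      db[i] <- inc[1]; dc[i] <- inc[2]
    }
    # per-pattern completion scores for fast randomized completion draws
    comp_xme <- vector("list", 64L); comp_varx <- vector("list", 64L)
    for (pc in seq_len(64L)) {
      if (is.null(comp[[pc]])) next
      comp_xme[[pc]] <- xme[comp[[pc]]]
      comp_varx[[pc]] <- varx[comp[[pc]]]
    }
    models[[model]] <- list(xme = xme, varx = varx, db = db, dc = dc,
                            comp_xme = comp_xme, comp_varx = comp_varx)
  }
  list(configs = configs, code_map = code_map, comp = comp, models = models)
}

.tabs <- function(ctx) {
  if (is.null(.famtrio_cache[[ctx]]))
    .famtrio_cache[[ctx]] <- .build_ctx_tables(ctx)
  .famtrio_cache[[ctx]]
}

# --- argument normalization helpers ------------------------------------------

.norm_model <- function(model) {
  match.arg(tolower(model), .MODELS)
}

.norm_chrom <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  if (chrom %in% c("AUTOSOMAL", "AUTO", "A")) return("A")
  if (chrom == "X") return("X")
  stop("`chrom` must be \"autosomal\" or \"X\"", call. = FALSE)
}

.norm_sex <- function(sex) {
  if (is.character(sex)) {
    s <- match.arg(tolower(sex), c("male", "female"))
    return(if (s == "male") 1L else 2L)
  }
  sex <- as.integer(sex)
  if (any(!sex %in% 1:2)) stop("`sex` must be 1 (male) or 2 (female)", call. = FALSE)
  sex
}

.ctx_of <- function(chrom, sex = NULL) {
  ch <- .norm_chrom(chrom)
  if (ch == "A") return("A")
  if (is.null(sex)) stop("offspring `sex` is required for X-chromosome markers",
                         call. = FALSE)
  if (.norm_sex(sex) == 1L) "XM" else "XF"
}

.check_dosage <- function(g, space, what, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(g) & !g %in% space else is.na(g) | !g %in% space
  if (any(bad))
    stop(sprintf("invalid %s dosage: %s (allowed: %s%s)", what,
                 paste(unique(g[bad]), collapse = ", "),
                 paste(space, collapse = ","),
                 if (allow_na) " or NA" else ""), call. = FALSE)
  invisible(TRUE)
}
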