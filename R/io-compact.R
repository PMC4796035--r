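# Compact per-marker genotype format.
#
# A plain-text transposed dosage matrix that stores one character per
# genotype, so a file is at most half the size of the equivalent PED (which
# spends at least four characters, "A A " per genotype):
#
#   ##famtrio-compact 1
#   #FID IID PID MID SEX PHENO          <- one header line per individual
#   marker chrom pos ref alt GENOSTRING <- one body line per marker
#
# The genotype string has one character per individual, in header order:
# '0'/'1'/'2' alternate-allele dosage or '.' for missing.

#' Write genotype data in the compact per-marker format
#'
#' @param td A `trio_data` list (see [read_ped()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_compact <- function(td, path) {
  s <- td$samples
  header <- c("##famtrio-compact 1",
              paste0("#", s$fid, " ", s$iid, " ", s$pid, " ", s$mid, " ",
                     s$sex, " ", s$phenotype))
  g <- td$geno
  gs <- matrix(".", nrow(g), ncol(g))
  gs[!is.na(g)] <- as.character(g[!is.na(g)])
  body <- paste(td$markers$marker, td$markers$chrom, td$markers$pos,
                ifelse(is.na(td$markers$ref), "A", td$markers$ref),
                ifelse(is.na(td$markers$alt), "B", td$markers$alt),
                apply(gs, 2, paste0, collapse = ""))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype data from the compact per-marker format
#'
#' @param path Path to a file written by [write_compact()].
#' @return A `trio_data` list; trios are decomposed exactly as in
#'   [read_ped()].
#' @export
read_compact <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##famtrio-compact"))
    stop("not a famtrio compact file (missing magic line)", call. = FALSE)
  lines <- lines[-1]
  hdr <- startsWith(lines, "#")
  smp <- do.call(rbind, strsplit(sub("^#", "", lines[hdr]), " ", fixed = TRUE))
  if (is.null(smp) || ncol(smp) != 6L)
    stop("malformed sample header lines", call. = FALSE)
  samples <- data.frame(fid = smp[, 1], iid = smp[, 2], pid = smp[, 3],
                        mid = smp[, 4], sex = as.integer(smp[, 5]),
                        phenotype = as.numeric(smp[, 6]),
                        stringsAsFactors = FALSE)
  n <- nrow(samples)

  body <- strsplit(lines[!hdr], " ", fixed = TRUE)
  m <- length(body)
  markers <- data.frame(marker = character(m), chrom = character(m),
                        pos = integer(m), ref = character(m),
                        alt = character(m), stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    fl <- body[[j]]
    if (length(fl) != 6L)
      stop(sprintf("malformed body line %d (expected 6 fields)", j),
           call. = FALSE)
    ch <- strsplit(fl[6], "", fixed = TRUE)[[1]]
    if (length(ch) != n)
      stop(sprintf("marker %s: genotype string length %d != %d samples",
                   fl[1], length(ch), n), call. = FALSE)
    bad <- !ch %in% c("0", "1", "2", ".")
    if (any(bad))
      stop(sprintf("marker %s: invalid genotype character '%s'",
                   fl[1], ch[which(bad)[1]]), call. = FALSE)
    markers[j, ] <- list(fl[1], fl[2], as.integer(fl[3]), fl[4], fl[5])
    geno[ch != ".", j] <- as.integer(ch[ch != "."])
  }

  key <- paste(samples$fid, samples$iid)
  fa <- match(paste(samples$fid, samples$pid), key)
  mo <- match(paste(samples$fid, samples$mid), key)
  is_off <- !is.na(fa) & !is.na(mo)
  pheno_known <- samples$phenotype %in% c(1, 2)
  keep <- is_off & pheno_known
  trios <- data.frame(fid = samples$fid[keep],
                      father = fa[keep], mother = mo[keep],
                      offspring = which(keep),
                      sex = samples$sex[keep],
                      affected = samples$phenotype[keep] == 2)
  out <- list(markers = markers, samples = samples, geno = geno,
              trios = trios)
  attr(out, "n_excluded_phenotype") <- sum(is_off & !pheno_known)
  class(out) <- "trio_data"
  out
}
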