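# PED/MAP reading and writing.
#
# The in-memory container produced by the readers and consumed by the
# writers is a "trio_data" list:
#   markers  data.frame(marker, chrom, pos, ref, alt)
#   samples  data.frame(fid, iid, pid, mid, sex, phenotype)  [PED columns]
#   geno     samples x markers integer dosage matrix (NA = missing)
#   trios    data.frame(fid, father, mother, offspring, sex, affected)
#            with father/mother/offspring as row indices into `samples`

#' Read pedigree genotype data from PED/MAP files
#'
#' Reads whitespace-delimited PED (six pedigree columns plus two allele
#' columns per marker, `0` = missing allele) and MAP (four columns
#' `chrom, marker, cM, pos`, or six with declared `ref` and `alt` alleles).
#' Allele pairs are converted to alternate-allele dosages; when the MAP file
#' does not declare alleles, the first allele observed at a marker becomes
#' the reference (the orientation is recorded in the marker table). Nuclear
#' families are decomposed into father-mother-offspring trios: every
#' individual whose two parent ids are present in the same family yields
#' one trio. Offspring with unknown phenotype (0 or -9) are excluded from
#' the trio list and counted in attribute `n_excluded_phenotype`.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A `trio_data` list (see Details).
#' @export
read_ped <- function(ped_path, map_path) {
  map <- data.table::fread(map_path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (!ncol(map) %in% c(4L, 6L))
    stop("MAP file must have 4 columns (chrom, marker, cM, pos) or 6 (+ ref, alt)",
         call. = FALSE)
  markers <- data.frame(marker = map[[2]], chrom = map[[1]],
                        pos = as.integer(map[[4]]),
                        ref = if (ncol(map) == 6L) map[[5]] else NA_character_,
                        alt = if (ncol(map) == 6L) map[[6]] else NA_character_,
                        stringsAsFactors = FALSE)
  m <- nrow(markers)

  ped <- data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * m)
    stop(sprintf("PED has %d columns; expected %d (6 + 2 x %d markers)",
                 ncol(ped), 6L + 2L * m, m), call. = FALSE)
  samples <- data.frame(fid = ped[[1]], iid = ped[[2]], pid = ped[[3]],
                        mid = ped[[4]], sex = as.integer(ped[[5]]),
                        phenotype = suppressWarnings(as.numeric(ped[[6]])),
                        stringsAsFactors = FALSE)
  key <- paste(samples$fid, samples$iid)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicated individual id at PED line %d: %s", d, key[d]),
         call. = FALSE)
  }
  n <- nrow(samples)

  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    half <- xor(a1 == "0", a2 == "0")
    if (any(half))
      stop(sprintf("half-missing allele pair for marker %s at PED line %d",
                   markers$marker[j], which(half)[1]), call. = FALSE)
    obs <- a1 != "0"
    alleles <- unique(c(a1[obs], a2[obs]))
    if (length(alleles) > 2L)
      stop(sprintf("marker %s has >2 alleles (%s); split multi-allelic sites upstream",
                   markers$marker[j], paste(alleles, collapse = ",")),
           call. = FALSE)
    if (is.na(markers$ref[j])) {
      markers$ref[j] <- if (length(alleles) >= 1L) alleles[1] else "A"
      markers$alt[j] <- if (length(alleles) == 2L) alleles[2] else "B"
    } else {
      bad <- setdiff(alleles, c(markers$ref[j], markers$alt[j]))
      if (length(bad))
        stop(sprintf("marker %s: allele(s) %s not among declared ref/alt",
                     markers$marker[j], paste(bad, collapse = ",")),
             call. = FALSE)
    }
    alt <- markers$alt[j]
    geno[obs, j] <- (a1[obs] == alt) + (a2[obs] == alt)
  }

  # nuclear family decomposition
  idx_of <- function(fid, id) match(paste(fid, id), key)
  fa <- idx_of(samples$fid, samples$pid)
  mo <- idx_of(samples$fid, samples$mid)
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

#' Write pedigree genotype data to PED/MAP files
#'
#' Inverse of [read_ped()]: writes a six-column MAP (with declared ref/alt
#' alleles) and a whitespace-delimited PED with allele pairs; missing
#' genotypes become `0 0`.
#'
#' @param td A `trio_data` list.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped <- function(td, ped_path, map_path) {
  mk <- td$markers
  ref <- ifelse(is.na(mk$ref), "A", mk$ref)
  alt <- ifelse(is.na(mk$alt), "B", mk$alt)
  utils::write.table(
    data.frame(mk$chrom, mk$marker, 0, mk$pos, ref, alt),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  n <- nrow(td$samples); m <- nrow(mk)
  g <- td$geno
  cols <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1L, alt[j], ref[j]))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2L, alt[j], ref[j]))
    cols[[2L * j - 1L]] <- a1
    cols[[2L * j]] <- a2
  }
  ped <- cbind(td$samples[, c("fid", "iid", "pid", "mid", "sex", "phenotype")],
               as.data.frame(cols, optional = TRUE))
  data.table::fwrite(ped, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(c(ped_path, map_path))
}

#' Extract the per-marker trio table from a `trio_data` object
#'
#' Convenience accessor: builds the data.frame of trios (father, mother,
#' offspring dosages plus `sex` and `affected`) for one marker, in the form
#' expected by [fbat()], [cifbat()], [tdt()] and [robust_tdt()].
#'
#' @param td A `trio_data` list.
#' @param marker Marker name or index.
#' @return A data.frame with one row per trio.
#' @export
marker_trios <- function(td, marker) {
  j <- if (is.character(marker)) match(marker, td$markers$marker)
       else as.integer(marker)
  if (is.na(j) || j < 1 || j > nrow(td$markers))
    stop("unknown marker: ", marker, call. = FALSE)
  data.frame(fid = td$trios$fid,
             father = td$geno[td$trios$father, j],
             mother = td$geno[td$trios$mother, j],
             offspring = td$geno[td$trios$offspring, j],
             sex = td$trios$sex,
             affected = td$trios$affected)
}

#' Convert a simulated pedigree set to `trio_data`
#'
#' Restricts a [simulate_families()] pedigree set (optionally to the members
#' of selected trios) and reshapes it into the `trio_data` container used
#' by the file writers.
#'
#' @param ped A `pedigree_set`.
#' @param trio_idx Optional trio indices to keep (default all).
#' @return A `trio_data` list.
#' @export
as_trio_data <- function(ped, trio_idx = seq_len(nrow(ped$trios))) {
  tr <- ped$trios[trio_idx, , drop = FALSE]
  rows <- sort(unique(c(tr$father, tr$mother, tr$offspring)))
  remap <- match(seq_len(nrow(ped$ind)), rows)
  ind <- ped$ind[rows, , drop = FALSE]
  role <- ind$role
  samples <- data.frame(
    fid = as.character(ind$fid),
    iid = paste0(ind$fid, "_", c(father = "f", mother = "m",
                                 offspring = "o")[role],
                 ifelse(role == "offspring", ind$iid, "")),
    pid = "0", mid = "0",
    sex = ind$sex,
    phenotype = ifelse(is.na(ind$affected), 0, ifelse(ind$affected, 2, 1)),
    stringsAsFactors = FALSE)
  # wire offspring to parent ids
  off <- which(role == "offspring")
  fa_row <- remap[tr$father]; mo_row <- remap[tr$mother]
  off_row <- remap[tr$offspring]
  samples$pid[off_row] <- samples$iid[fa_row]
  samples$mid[off_row] <- samples$iid[mo_row]
  structure(list(markers = ped$markers, samples = samples,
                 geno = ped$geno[rows, , drop = FALSE],
                 trios = data.frame(fid = as.character(tr$fid),
                                    father = fa_row, mother = mo_row,
                                    offspring = off_row,
                                    sex = ind$sex[off_row],
                                    affected = ind$affected[off_row])),
            class = "trio_data")
}

#' Write per-marker association results to a TSV file
#'
#' @param res A data.frame of per-marker results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(res, path) {
  utils::write.table(res, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
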