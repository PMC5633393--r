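pheno_required_cols <- function() {
  c("strain", "animal_id", "age_wk", trab_parameters())
}

#' Read and validate a phenotype table
#'
#' CSV schema: `strain, animal_id, age_wk, BVTV, TbN, ConnD, TbSp, SMI,
#' TbTh` — one row per animal.  Validation errors name the offending row:
#' missing columns, non-numeric cells, duplicate animal ids, and BV/TV
#' values outside \[0, 1\].
#'
#' @param path CSV file path.
#' @return A tibble in the standard schema.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  tab <- readr::read_csv(path, col_types = readr::cols(
    strain = readr::col_character(),
    animal_id = readr::col_character(),
    .default = readr::col_character()))
  if (nrow(tab) == 0) abort(sprintf("phenotype file is empty: %s", path))
  missing <- setdiff(pheno_required_cols(), names(tab))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in c("age_wk", trab_parameters())) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(num) & !is.na(tab[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s', row %d: '%s'",
                    col, bad[1], tab[[col]][bad[1]]))
    }
    tab[[col]] <- num
  }
  dup <- which(duplicated(tab$animal_id))
  if (length(dup) > 0) {
    abort(sprintf("duplicate animal_id '%s' at row %d.",
                  tab$animal_id[dup[1]], dup[1]))
  }
  bad <- which(tab$BVTV < 0 | tab$BVTV > 1)
  if (length(bad) > 0) {
    abort(sprintf("BVTV = %g at row %d is outside [0, 1].",
                  tab$BVTV[bad[1]], bad[1]))
  }
  tab[, pheno_required_cols()]
}

#' @rdname read_phenotype_table
#' @param table Phenotype tibble to write.
#' @export
write_phenotype_table <- function(table, path) {
  readr::write_csv(table[, pheno_required_cols()], path)
  invisible(path)
}

#' Read and write genotype marker tables
#'
#' TSV schema: columns `marker`, `position_mb`, then one column per strain
#' with alleles `B` (host) or `M` (donor).  On read, donor-allele runs are
#' converted to half-open Mb intervals with the midpoint breakpoint
#' convention (see [genotype_map()]); write-then-read round-trips exactly
#' because the marker alleles themselves are stored.
#'
#' @param path TSV file path.
#' @param chromosome_length_mb Chromosome length; defaults to the last
#'   marker position.
#' @return A [genotype_map()].
#' @export
read_genotype_map <- function(path, chromosome_length_mb = NULL) {
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(),
    position_mb = readr::col_double(),
    .default = readr::col_character()))
  if (!all(c("marker", "position_mb") %in% names(tab))) {
    abort("genotype file needs `marker` and `position_mb` columns.")
  }
  if (is.unsorted(tab$position_mb, strictly = TRUE)) {
    abort("marker positions must be sorted and strictly increasing.")
  }
  strains <- setdiff(names(tab), c("marker", "position_mb"))
  if (length(strains) == 0) abort("genotype file has no strain columns.")
  al <- t(as.matrix(tab[, strains]))
  colnames(al) <- tab$marker
  bad <- which(!(al %in% c("B", "M")))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(al))
    abort(sprintf("allele '%s' (strain %s, marker %s) is not B or M.",
                  al[ij[1], ij[2]], strains[ij[1]], tab$marker[ij[2]]))
  }
  genotype_map(tab[, c("marker", "position_mb")], al,
               chromosome_length_mb = chromosome_length_mb)
}

#' @rdname read_genotype_map
#' @param gmap A [genotype_map()] to write.
#' @export
write_genotype_map <- function(gmap, path) {
  stopifnot(inherits(gmap, "genotype_map"))
  out <- dplyr::bind_cols(gmap$markers,
                          as_tibble(t(gmap$alleles)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write binary volumes as multi-page TIFF
#'
#' Volumes are stored as 8-bit binary multi-page TIFF stacks (one page per
#' third-axis slice) with a JSON sidecar `<path>.json` carrying the voxel
#' size and, for phantoms, the analytic ground truth.
#'
#' @param path TIFF file path.
#' @param voxel_um Voxel size override; defaults to the sidecar value.
#' @return A [voxel_volume()].
#' @export
read_volume_tiff <- function(path, voxel_um = NULL) {
  if (!file.exists(path)) abort(sprintf("volume file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(FALSE, c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                        length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] > 0.5
  gt <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxel_um <- voxel_um %||% meta$voxel_um
    gt <- meta$ground_truth
  }
  if (is.null(voxel_um)) {
    abort("no voxel size: supply `voxel_um` or a JSON sidecar.")
  }
  voxel_volume(arr, voxel_um = voxel_um, ground_truth = gt)
}

#' @rdname read_volume_tiff
#' @param volume A [voxel_volume()] to write.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  arr <- vv_array(volume)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    m <- matrix(0, dim(arr)[1], dim(arr)[2])
    m[arr[, , k]] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  meta <- list(shape = dim(arr), voxel_um = voxel_um(volume))
  gt <- attr(volume, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
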