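#' Genotype map of a (sub)consomic panel on one chromosome
#'
#' Marker-table representation of which chromosomal segments each strain
#' carries from the donor genome.  The primitive data are the marker
#' alleles (`"B"` host, `"M"` donor); donor-segment intervals are always
#' *derived* from them with the midpoint breakpoint convention (a
#' recombination breakpoint is placed halfway between the two flanking
#' discordant markers, or at the chromosome end when the run reaches the
#' first or last marker).
#'
#' @param markers A data frame with columns `marker` (character) and
#'   `position_mb` (sorted, strictly increasing).
#' @param alleles A character matrix (strains x markers) with entries in
#'   `{"B","M"}`; rownames are strain labels.
#' @param chromosome_length_mb Total chromosome length, Mb (defaults to the
#'   last marker position).
#' @return An object of class `genotype_map`.
#' @seealso [strain_intervals()], [read_genotype_map()]
#' @export
genotype_map <- function(markers, alleles, chromosome_length_mb = NULL) {
  markers <- as_tibble(markers)
  if (!all(c("marker", "position_mb") %in% names(markers))) {
    abort("`markers` needs columns `marker` and `position_mb`.")
  }
  pos <- markers$position_mb
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("marker positions must be sorted and strictly increasing.")
  }
  if (!is.matrix(alleles) || is.null(rownames(alleles))) {
    abort("`alleles` must be a character matrix with strain rownames.")
  }
  if (ncol(alleles) != nrow(markers)) {
    abort("`alleles` must have one column per marker.")
  }
  if (!all(alleles %in% c("B", "M"))) {
    abort("alleles must be 'B' (host) or 'M' (donor).")
  }
  chromosome_length_mb <- chromosome_length_mb %||% max(pos)
  if (chromosome_length_mb < max(pos)) {
    abort("`chromosome_length_mb` must reach the last marker.")
  }
  structure(list(markers = markers, alleles = alleles,
                 chromosome_length_mb = chromosome_length_mb),
            class = "genotype_map")
}

#' @export
print.genotype_map <- function(x, ...) {
  cat(sprintf("<genotype_map> %d strains, %d markers, chromosome %.4g Mb\n",
              nrow(x$alleles), nrow(x$markers), x$chromosome_length_mb))
  print(strain_intervals(x), n = 8)
  invisible(x)
}

#' Strains of a genotype map
#' @param gmap A [genotype_map()].
#' @return Character vector of strain labels.
#' @export
map_strains <- function(gmap) rownames(gmap$alleles)

# breakpoint grid: chromosome ends plus midpoints of adjacent markers
breakpoint_grid <- function(gmap) {
  pos <- gmap$markers$position_mb
  c(0, (pos[-length(pos)] + pos[-1]) / 2, gmap$chromosome_length_mb)
}

#' Donor-segment intervals of every strain
#'
#' Derives half-open donor intervals `[start_mb, end_mb)` from the marker
#' alleles with the midpoint breakpoint convention.
#'
#' @param gmap A [genotype_map()].
#' @return A tibble with columns `strain`, `start_mb`, `end_mb` (zero rows
#'   for all-host strains).
#' @export
strain_intervals <- function(gmap) {
  pos <- gmap$markers$position_mb
  L <- gmap$chromosome_length_mb
  one <- function(al) {
    m <- al == "M"
    if (!any(m)) return(tibble(start_mb = double(), end_mb = double()))
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    tibble(
      start_mb = as.numeric(ifelse(starts[keep] == 1L, 0,
                                   (pos[starts[keep] - 1L] +
                                      pos[starts[keep]]) / 2)),
      end_mb = as.numeric(ifelse(ends[keep] == length(pos), L,
                                 (pos[ends[keep]] +
                                    pos[ends[keep] + 1L]) / 2)))
  }
  purrr::map_dfr(setNames(seq_len(nrow(gmap$alleles)), map_strains(gmap)),
                 function(i) one(gmap$alleles[i, ]), .id = "strain")
}

# alleles implied by a set of half-open intervals, on the map's marker grid
intervals_to_alleles <- function(intervals, positions) {
  al <- rep("B", length(positions))
  if (nrow(intervals) > 0) {
    for (i in seq_len(nrow(intervals))) {
      al[positions >= intervals$start_mb[i] &
           positions < intervals$end_mb[i]] <- "M"
    }
  }
  al
}

#' Build a genotype map from donor intervals
#'
#' Convenience constructor: places markers (if not supplied) and converts
#' per-strain interval lists to marker alleles.  Interval endpoints must be
#' representable on the midpoint breakpoint grid of the marker positions
#' (otherwise deriving intervals back from alleles would silently move the
#' breakpoints); an explicit error is raised when they are not.
#'
#' @param strain_intervals Named list; each element a 2-column matrix or
#'   data frame of `[start_mb, end_mb)` donor intervals (zero rows = host
#'   genotype).
#' @param marker_positions_mb Marker positions, Mb.
#' @param chromosome_length_mb Chromosome length, Mb.
#' @param marker_prefix Marker names are `<prefix><position>`.
#' @return A [genotype_map()].
#' @export
genotype_map_from_intervals <- function(strain_intervals, marker_positions_mb,
                                        chromosome_length_mb,
                                        marker_prefix = "mk") {
  markers <- tibble(marker = paste0(marker_prefix,
                                    format(marker_positions_mb, trim = TRUE)),
                    position_mb = marker_positions_mb)
  grid <- c(0, (marker_positions_mb[-length(marker_positions_mb)] +
                  marker_positions_mb[-1]) / 2, chromosome_length_mb)
  al <- matrix("B", nrow = length(strain_intervals),
               ncol = length(marker_positions_mb),
               dimnames = list(names(strain_intervals), markers$marker))
  for (s in names(strain_intervals)) {
    iv <- as.data.frame(strain_intervals[[s]])
    if (nrow(iv) > 0) {
      names(iv)[1:2] <- c("start_mb", "end_mb")
      bad <- !sapply(c(iv$start_mb, iv$end_mb), function(e)
        any(abs(grid - e) < 1e-6))
      if (any(bad)) {
        abort(sprintf(
          "strain '%s': interval endpoints not on the breakpoint grid (chromosome ends and marker midpoints).", s))
      }
      if (any(iv$end_mb <= iv$start_mb) ||
          any(iv$start_mb < 0) || any(iv$end_mb > chromosome_length_mb)) {
        abort(sprintf("strain '%s': invalid interval coordinates.", s))
      }
      al[s, ] <- intervals_to_alleles(iv, marker_positions_mb)
    }
  }
  genotype_map(markers, al, chromosome_length_mb)
}
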