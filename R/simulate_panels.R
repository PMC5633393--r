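#' Default strain means for the simulated panels
#'
#' Typical 10-week proximal-tibia values for the host strain (B6-like) and
#' the wild-derived donor strain (MSM-like): the donor has markedly lower
#' bone volume fraction, trabecular number and connectivity, higher
#' separation and SMI, and essentially unchanged trabecular thickness.
#'
#' @return Named numeric vector over the six parameters.
#' @export
default_control_mean <- function() {
  c(BVTV = 0.14, TbN = 4.2, ConnD = 120, TbSp = 0.22, SMI = 1.8, TbTh = 0.042)
}

#' @rdname default_control_mean
#' @export
default_donor_mean <- function() {
  c(BVTV = 0.05, TbN = 2.6, ConnD = 40, TbSp = 0.38, SMI = 2.7, TbTh = 0.042)
}

#' @rdname default_control_mean
#' @export
default_noise_sd <- function() {
  c(BVTV = 0.012, TbN = 0.25, ConnD = 12, TbSp = 0.02, SMI = 0.15,
    TbTh = 0.003)
}

# 26 consomic strain labels: autosomes (some split into centromeric "C" and
# telomeric "T" halves), X, Y and the mitochondrial genome
consomic_strain_labels <- function() {
  c("C1", "C2C", "C2T", "C3", "C4", "C5", "C6C", "C6T",
    "C7", "C8", "C9", "C10", "C11", "C12C", "C12T", "C13C", "C13T",
    "C14", "C15", "C16", "C17", "C18", "C19", "CX", "CY", "CMt")
}

#' Default per-chromosome effect matrix for the consomic simulator
#'
#' Builds signed single-substitution effects with the nonadditive signature
#' of consomic panels: 22 of the 26 strains carry a nonzero effect whose
#' column sums equal `nonadditivity[p] * (donor_mean[p] - control_mean[p])`,
#' so the planted nonadditivity index of each parameter is the given
#' coefficient.  The weights are linearly spread (0.5x to 1.5x the mean
#' effect) with the largest effect assigned to strain `C15`, mirroring a
#' panel in which a single chromosome dominates.  `TbTh` is the exception:
#' all effects are zero except a negative effect for `C14`.
#'
#' @param control_mean,donor_mean Named parameter means.
#' @param nonadditivity Named (or scalar) planted nonadditivity
#'   coefficients; 13.90 for BV/TV and 12.91 for Tb.N by default.
#' @param inactive Strains with zero effect on all parameters but TbTh.
#' @return Numeric matrix, strains x parameters.
#' @export
default_chromosome_effects <- function(control_mean = default_control_mean(),
                                       donor_mean = default_donor_mean(),
                                       nonadditivity = c(BVTV = 13.90,
                                                         TbN = 12.91,
                                                         ConnD = 8, TbSp = 6,
                                                         SMI = 6, TbTh = 0),
                                       inactive = c("C3", "C7", "C11", "CX")) {
  pars <- trab_parameters()
  strains <- consomic_strain_labels()
  if (length(nonadditivity) == 1L) {
    nonadditivity <- setNames(rep(nonadditivity, 6), pars)
  }
  eff <- matrix(0, nrow = length(strains), ncol = length(pars),
                dimnames = list(strains, pars))
  active <- setdiff(strains, inactive)
  k <- length(active)
  w <- seq(0.5, 1.5, length.out = k) / k
  # largest weight on C15, remaining weights in label order
  names(w) <- c(setdiff(active, "C15"), "C15")
  for (p in setdiff(pars, "TbTh")) {
    eff[names(w), p] <- w * nonadditivity[p] *
      (donor_mean[p] - control_mean[p])
  }
  eff["C14", "TbTh"] <- -0.006
  eff
}

#' Consomic panel specification
#'
#' Study conditions for the simulated chromosome-substitution screen:
#' 26 consomic strains plus the two parents, with per-strain replicate
#' animals, per-chromosome additive effects, a nonadditive (epistatic)
#' relationship between the summed effects and the parental difference,
#' and Gaussian measurement noise.
#'
#' The generative model is: a consomic strain carrying substitution `c`
#' has mean `control_mean + effect[c, ]`, while the donor parent sits at
#' `donor_mean`.  Epistasis enters as a shrinkage of the joint genotype:
#' the single-substitution effects sum to `epistasis_coefficient` times
#' the parental difference, so summing them wildly overshoots what the
#' full donor genome actually does.
#'
#' @param replicates_per_strain Animals per strain (>= 2).
#' @param control_mean,donor_mean,noise_sd Named vectors over the six
#'   parameters.
#' @param per_chromosome_effects Strains x parameters effect matrix, or
#'   `NULL` to build [default_chromosome_effects()] from
#'   `epistasis_coefficient`.
#' @param epistasis_coefficient Planted nonadditivity coefficient(s) used
#'   when `per_chromosome_effects` is `NULL`.
#' @param control,donor Parent strain labels.
#' @param age_wk Recorded age of the animals.
#' @param seed Integer seed making the simulated panel reproducible.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(replicates_per_strain = 8L,
                       control_mean = default_control_mean(),
                       donor_mean = default_donor_mean(),
                       noise_sd = default_noise_sd(),
                       per_chromosome_effects = NULL,
                       epistasis_coefficient = c(BVTV = 13.90, TbN = 12.91,
                                                 ConnD = 8, TbSp = 6,
                                                 SMI = 6, TbTh = 0),
                       control = "B6", donor = "MSM",
                       age_wk = 10, seed = 1L) {
  if (replicates_per_strain < 2) abort("`replicates_per_strain` must be >= 2.")
  pars <- trab_parameters()
  for (v in list(control_mean, donor_mean, noise_sd)) {
    if (!all(pars %in% names(v))) {
      abort("means and noise_sd must be named over the six parameters.")
    }
  }
  if (any(noise_sd[pars] <= 0)) abort("`noise_sd` must be positive.")
  if (is.null(per_chromosome_effects)) {
    per_chromosome_effects <- default_chromosome_effects(
      control_mean, donor_mean, nonadditivity = epistasis_coefficient)
  }
  if (is.null(rownames(per_chromosome_effects)) ||
      !all(pars %in% colnames(per_chromosome_effects))) {
    abort("`per_chromosome_effects` needs strain rownames and parameter columns.")
  }
  structure(list(replicates_per_strain = as.integer(replicates_per_strain),
                 control_mean = control_mean[pars],
                 donor_mean = donor_mean[pars],
                 noise_sd = noise_sd[pars],
                 per_chromosome_effects = per_chromosome_effects[, pars,
                                                                 drop = FALSE],
                 control = control, donor = donor,
                 age_wk = age_wk, seed = as.integer(seed)),
            class = "panel_spec")
}

simulate_strain_rows <- function(strain, means, n, noise_sd, age_wk) {
  pars <- trab_parameters()
  vals <- vapply(pars, function(p) means[p] + rnorm(n, 0, noise_sd[p]),
                 numeric(n))
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, pars))
  dplyr::bind_cols(
    tibble(strain = strain,
           animal_id = sprintf("%s_%02d", strain, seq_len(n)),
           age_wk = age_wk),
    as_tibble(vals))
}

#' Simulate a consomic screening panel
#'
#' Generates the per-animal phenotype table of a chromosome-substitution
#' panel under a [panel_spec()]: parents plus one strain per substituted
#' chromosome, each animal's value being strain mean plus independent
#' Gaussian noise.  Byte-identical output given the same spec (and seed).
#'
#' @param spec A [panel_spec()].
#' @return A tibble with columns `strain`, `animal_id`, `age_wk` and the
#'   six parameters (one row per animal).
#' @examples
#' pheno <- simulate_consomic_panel(panel_spec(seed = 7))
#' nrow(pheno) # 28 strains x 8 animals = 224
#' @export
simulate_consomic_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  eff <- spec$per_chromosome_effects
  withr::with_seed(spec$seed, {
    rows <- list(simulate_strain_rows(spec$control, spec$control_mean,
                                      spec$replicates_per_strain,
                                      spec$noise_sd, spec$age_wk),
                 simulate_strain_rows(spec$donor, spec$donor_mean,
                                      spec$replicates_per_strain,
                                      spec$noise_sd, spec$age_wk))
    for (s in rownames(eff)) {
      rows[[length(rows) + 1L]] <- simulate_strain_rows(
        s, spec$control_mean + eff[s, ], spec$replicates_per_strain,
        spec$noise_sd, spec$age_wk)
    }
    dplyr::bind_rows(rows)
  })
}

#' Subconsomic panel specification
#'
#' Study conditions for the single-chromosome dissection: a small number of
#' strains carrying donor sub-segments of one chromosome, a marker grid
#' defining the representable breakpoints, and block-level planted QTL with
#' signed effects.  The default emulates the published design scale: eight
#' subconsomic strains plus the two parents (host genome, and the full
#' donor chromosome), with a nested ladder of donor segments so every
#' neighboring pair differs in exactly one block, and four planted QTL
#' (one increasing TbTh, one increasing BVTV, two decreasing BVTV and TbN).
#'
#' @param chromosome_length_mb Chromosome length, Mb.
#' @param marker_positions_mb Sorted marker positions, Mb.
#' @param strain_intervals Named list of donor-interval matrices (see
#'   [genotype_map_from_intervals()]); parents are added automatically.
#' @param planted_qtl Tibble with columns `start_mb`, `end_mb`,
#'   `parameter`, `effect`; each row one planted block-level effect.
#'   Blocks must be representable on the breakpoint grid.
#' @param control_mean,noise_sd Named vectors over the six parameters.
#' @param replicates Animals per strain.
#' @param host,donor Parent labels (host carries no donor segment, donor
#'   the full chromosome).
#' @param age_wk Recorded age.
#' @param seed Integer seed.
#' @return A list of class `subconsomic_spec`.
#' @export
subconsomic_spec <- function(chromosome_length_mb = 100,
                             marker_positions_mb = seq(5, 95, by = 10),
                             strain_intervals = NULL,
                             planted_qtl = NULL,
                             control_mean = default_control_mean(),
                             noise_sd = default_noise_sd(),
                             replicates = 8L,
                             host = "B6", donor = "C15",
                             age_wk = 6, seed = 1L) {
  if (replicates < 2) abort("`replicates` must be >= 2.")
  if (is.null(strain_intervals)) {
    starts <- seq(10, 80, by = 10)
    strain_intervals <- lapply(starts, function(s)
      cbind(start_mb = s, end_mb = chromosome_length_mb))
    names(strain_intervals) <- sprintf("Sub%d", seq_along(starts))
  }
  if (is.null(planted_qtl)) {
    planted_qtl <- tibble(
      start_mb = c(10, 40, 60, 60, 80, 80),
      end_mb   = c(20, 50, 70, 70, 100, 100),
      parameter = c("TbTh", "BVTV", "BVTV", "TbN", "BVTV", "TbN"),
      effect = c(0.012, 0.03, -0.04, -0.5, -0.05, -0.6))
  }
  planted_qtl <- as_tibble(planted_qtl)
  stopifnot(all(c("start_mb", "end_mb", "parameter", "effect") %in%
                  names(planted_qtl)))
  if (!all(planted_qtl$parameter %in% trab_parameters())) {
    abort("planted QTL parameters must be among the six trabecular parameters.")
  }
  if (any(!is.finite(planted_qtl$effect))) abort("planted effects must be finite.")
  pars <- trab_parameters()
  if (length(noise_sd) == 1L) noise_sd <- setNames(rep(noise_sd, 6), pars)
  if (any(noise_sd[pars] <= 0)) abort("`noise_sd` must be positive.")
  structure(list(chromosome_length_mb = chromosome_length_mb,
                 marker_positions_mb = marker_positions_mb,
                 strain_intervals = strain_intervals,
                 planted_qtl = planted_qtl,
                 control_mean = control_mean[pars],
                 noise_sd = noise_sd[pars],
                 replicates = as.integer(replicates),
                 host = host, donor = donor,
                 age_wk = age_wk, seed = as.integer(seed)),
            class = "subconsomic_spec")
}

# does the strain's interval set cover [start, end) entirely?
covers_block <- function(intervals, start, end) {
  if (nrow(intervals) == 0) return(FALSE)
  any(intervals$start_mb <= start + 1e-9 & intervals$end_mb >= end - 1e-9)
}

#' Simulate a subconsomic panel
#'
#' Builds the genotype map (parents included) and a per-animal phenotype
#' table in which a strain's mean equals the control mean plus the sum of
#' planted QTL effects whose block is fully covered by one of its donor
#' segments, plus Gaussian noise.
#'
#' @param spec A [subconsomic_spec()].
#' @return A list with elements `genotype` (a [genotype_map()]) and
#'   `phenotype` (a tibble in the standard panel schema).
#' @export
simulate_subconsomic_panel <- function(spec) {
  stopifnot(inherits(spec, "subconsomic_spec"))
  ivs <- spec$strain_intervals
  ivs[[spec$host]] <- cbind(start_mb = numeric(0), end_mb = numeric(0))
  ivs[[spec$donor]] <- cbind(start_mb = 0, end_mb = spec$chromosome_length_mb)
  gmap <- genotype_map_from_intervals(ivs, spec$marker_positions_mb,
                                      spec$chromosome_length_mb)
  grid <- breakpoint_grid(gmap)
  qtl_ok <- sapply(c(spec$planted_qtl$start_mb, spec$planted_qtl$end_mb),
                   function(e) any(abs(grid - e) < 1e-6))
  if (!all(qtl_ok)) {
    abort("planted QTL block not aligned to the marker breakpoint grid.")
  }
  derived <- strain_intervals(gmap)
  pheno <- withr::with_seed(spec$seed, {
    rows <- lapply(map_strains(gmap), function(s) {
      iv <- derived[derived$strain == s, , drop = FALSE]
      means <- spec$control_mean
      for (i in seq_len(nrow(spec$planted_qtl))) {
        q <- spec$planted_qtl[i, ]
        if (covers_block(iv, q$start_mb, q$end_mb)) {
          means[q$parameter] <- means[q$parameter] + q$effect
        }
      }
      simulate_strain_rows(s, means, spec$replicates, spec$noise_sd,
                           spec$age_wk)
    })
    dplyr::bind_rows(rows)
  })
  list(genotype = gmap, phenotype = pheno)
}
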