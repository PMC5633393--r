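# Independent oracles used across the suite.  These deliberately share no
# code with the package implementations they check.

# Euler characteristic of the union of closed unit cubes, by explicit
# enumeration of the cell complex: chi = V - E + F - C.  Each foreground
# voxel contributes its 8 vertices, 12 edges and 6 faces to sets keyed by
# lattice coordinates (doubled so that half-integer element centres are
# integers).
oracle_euler <- function(mask) {
  verts <- new.env(); edges <- new.env(); faces <- new.env()
  put <- function(env, key) assign(key, TRUE, envir = env)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    # cube spans [i-1,i] x [j-1,j] x [k-1,k]; use doubled coordinates
    for (a in c(-1, 1)) for (b in c(-1, 1)) for (cc in c(-1, 1)) {
      put(verts, paste(2 * i - 1 + a, 2 * j - 1 + b, 2 * k - 1 + cc))
    }
    for (a in c(-1, 1)) for (b in c(-1, 1)) {
      put(edges, paste(2 * i - 1, 2 * j - 1 + a, 2 * k - 1 + b))
      put(edges, paste(2 * i - 1 + a, 2 * j - 1, 2 * k - 1 + b))
      put(edges, paste(2 * i - 1 + a, 2 * j - 1 + b, 2 * k - 1))
    }
    for (a in c(-1, 1)) {
      put(faces, paste(2 * i - 1 + a, 2 * j - 1, 2 * k - 1))
      put(faces, paste(2 * i - 1, 2 * j - 1 + a, 2 * k - 1))
      put(faces, paste(2 * i - 1, 2 * j - 1, 2 * k - 1 + a))
    }
  }
  # V - E + F - C, with C = number of foreground voxels
  length(ls(verts)) - length(ls(edges)) + length(ls(faces)) - nrow(idx)
}

# Spearman rho by the definition: rank both variables (midranks for ties)
# and take the Pearson correlation of the ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Exhaustive minimum total adjacent distance over all linear orders,
# optionally with fixed first/last elements.
oracle_best_order_cost <- function(D, first = NULL, last = NULL) {
  n <- nrow(D)
  perms <- all_perms(n)
  keep <- rep(TRUE, nrow(perms))
  if (!is.null(first)) keep <- keep & perms[, 1] == first
  if (!is.null(last)) keep <- keep & perms[, n] == last
  perms <- perms[keep, , drop = FALSE]
  costs <- rep(0, nrow(perms))
  for (i in seq_len(n - 1)) {
    costs <- costs + D[cbind(perms[, i], perms[, i + 1])]
  }
  min(costs)
}

# random genotype map on a marker grid (interval endpoints on the midpoint
# breakpoint grid, as the package requires)
random_gmap <- function(n_strains, n_markers = 9, L = 100) {
  pos <- seq(5, by = 10, length.out = n_markers)
  grid <- c(0, (pos[-n_markers] + pos[-1]) / 2, L)
  ivs <- lapply(seq_len(n_strains), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(cbind(start_mb = numeric(0), end_mb = numeric(0)))
    pts <- sort(sample(grid, 2 * k))
    cbind(start_mb = pts[seq(1, 2 * k, 2)], end_mb = pts[seq(2, 2 * k, 2)])
  })
  names(ivs) <- sprintf("S%02d", seq_len(n_strains))
  ivs <- ivs[!duplicated(lapply(ivs, function(m) paste(m, collapse = ",")))]
  genotype_map_from_intervals(ivs, pos, L)
}

# standard-schema phenotype table with given strain means for one
# parameter and near-zero noise on the rest
make_pheno <- function(means, n = 4, sd = 1e-6, parameter = "BVTV",
                       age_wk = 10, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(names(means), function(s) {
      base <- tibble::tibble(
        strain = s, animal_id = sprintf("%s_%d", s, seq_len(n)),
        age_wk = age_wk, BVTV = 0.5, TbN = 1, ConnD = 1, TbSp = 1,
        SMI = 1, TbTh = 1)
      base[[parameter]] <- rnorm(n, means[[s]], sd)
      for (p in setdiff(trabqtl:::trab_parameters(), parameter)) {
        base[[p]] <- base[[p]] + rnorm(n, 0, 1e-6)
      }
      base
    })
  })
}
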