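# atoms of the partition generated by all interval endpoints; returns
# list(bounds, pattern) where pattern is strains x atoms coverage
interval_atoms <- function(gmap) {
  iv <- strain_intervals(gmap)
  bounds <- sort(unique(c(0, gmap$chromosome_length_mb,
                          iv$start_mb, iv$end_mb)))
  mids <- (bounds[-length(bounds)] + bounds[-1]) / 2
  strains <- map_strains(gmap)
  pat <- matrix(FALSE, length(strains), length(mids),
                dimnames = list(strains, NULL))
  for (s in strains) {
    ivs <- iv[iv$strain == s, , drop = FALSE]
    if (nrow(ivs) > 0) {
      pat[s, ] <- vapply(mids, function(m)
        any(ivs$start_mb <= m & m < ivs$end_mb), logical(1))
    }
  }
  list(bounds = bounds, pattern = pat)
}

# symmetric-difference length (Mb) between the donor sets of all strains
symdiff_matrix <- function(gmap) {
  at <- interval_atoms(gmap)
  len <- diff(at$bounds)
  pat <- at$pattern
  m <- nrow(pat)
  D <- matrix(0, m, m, dimnames = list(rownames(pat), rownames(pat)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      D[i, j] <- sum(len[pat[i, ] != pat[j, ]])
    }
  }
  D
}

# exact minimum Hamiltonian path by subset dynamic programming;
# dp is computed from the path tail so the order can be reconstructed
# front-to-back taking the lexicographically first optimal continuation
hk_path <- function(D, start = NULL, end = NULL) {
  m <- nrow(D)
  labels <- rownames(D)
  idx <- order(labels) # lexicographic preference
  free <- setdiff(seq_len(m), c(start, end))
  nf <- length(free)
  if (nf == 0) return(labels[c(start, end)])
  # dp[S, j]: min cost of a path starting at free node j, visiting exactly
  # the free-set S (j in S), then ending at `end` (or stopping, if none)
  nS <- bitwShiftL(1L, nf)
  dp <- matrix(Inf, nS, nf)
  for (jj in seq_len(nf)) {
    dp[bitwShiftL(1L, jj - 1L) + 1L, jj] <-
      if (is.null(end)) 0 else D[free[jj], end]
  }
  sets <- order(vapply(0:(nS - 1L), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(nf - 1L))) > 0), numeric(1)))
  for (S in sets) {
    s <- S - 1L
    if (s == 0L) next
    members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(nf) - 1L)) > 0L)
    if (length(members) < 2) next
    for (jj in members) {
      rest <- bitwAnd(s, bitwNot(bitwShiftL(1L, jj - 1L)))
      best <- Inf
      for (kk in members[members != jj]) {
        v <- D[free[jj], free[kk]] + dp[rest + 1L, kk]
        if (v < best) best <- v
      }
      dp[S, jj] <- best
    }
  }
  full <- nS - 1L
  # choose the first node
  firsts <- seq_len(nf)
  costs <- vapply(firsts, function(jj) {
    base <- dp[full + 1L, jj]
    if (is.null(start)) base else D[start, free[jj]] + base
  }, numeric(1))
  opt <- min(costs)
  ordpref <- order(labels[free]) # lex order among free nodes
  path <- integer(0)
  cur <- ordpref[which(abs(costs[ordpref] - opt) < 1e-9)[1]]
  s <- full
  path <- c(path, cur)
  while (length(path) < nf) {
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, cur - 1L)))
    members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(nf) - 1L)) > 0L)
    target <- dp[bitwOr(s, bitwShiftL(1L, cur - 1L)) + 1L, cur] -
      0 # cost from cur through s
    # pick lexicographically first k achieving dp[cur over s] =
    # D[cur,k] + dp[s, k]
    cand <- members[order(labels[free[members]])]
    nxt <- NA_integer_
    for (kk in cand) {
      if (abs(D[free[cur], free[kk]] + dp[s + 1L, kk] - target) < 1e-9) {
        nxt <- kk
        break
      }
    }
    if (is.na(nxt)) nxt <- cand[1] # numeric safety net
    path <- c(path, nxt)
    cur <- nxt
  }
  labels[c(start, free[path], end)]
}

#' Order strains to minimize neighbor genotype differences
#'
#' Finds the linear arrangement of the panel minimizing the total
#' symmetric-difference length (Mb) between the donor-segment sets of
#' adjacent strains — the alignment in which neighboring strains are the
#' most genetically similar, so each neighbor comparison isolates the
#' fewest possible blocks.  The exact optimum is found by subset dynamic
#' programming for up to `exact_limit` strains (ties resolved to the
#' lexicographically first optimal order); larger panels fall back to a
#' nearest-neighbour heuristic with a warning.  By default the host parent
#' (no donor segment) is anchored at one end and the full-donor parent at
#' the other, as such panels are conventionally drawn.
#'
#' @param gmap A [genotype_map()].
#' @param anchor_parents Anchor the all-host strain last and the
#'   full-donor strain first, when both are present.
#' @param exact_limit Maximum panel size for the exact search.
#' @return Character vector: the ordered strain labels.
#' @export
order_by_similarity <- function(gmap, anchor_parents = TRUE,
                                exact_limit = 12L) {
  stopifnot(inherits(gmap, "genotype_map"))
  strains <- map_strains(gmap)
  if (length(strains) < 2) abort("need at least 2 strains to order.")
  D <- symdiff_matrix(gmap)
  start <- end <- NULL
  if (anchor_parents) {
    allM <- strains[apply(gmap$alleles == "M", 1, all)]
    allB <- strains[apply(gmap$alleles == "B", 1, all)]
    if (length(allM) >= 1) start <- match(sort(allM)[1], strains)
    if (length(allB) >= 1) end <- match(sort(allB)[1], strains)
  }
  if (length(strains) <= exact_limit) {
    hk_path(D, start = start, end = end)
  } else {
    warn(sprintf("more than %d strains: using the greedy nearest-neighbour heuristic.",
                 exact_limit))
    cur <- if (!is.null(start)) start else which.min(apply(D, 1, sum))
    left <- setdiff(seq_along(strains), c(cur, end))
    path <- cur
    while (length(left) > 0) {
      nxt <- left[order(D[cur, left], strains[left])][1]
      path <- c(path, nxt)
      left <- setdiff(left, nxt)
      cur <- nxt
    }
    strains[c(path, end)]
  }
}

#' Total adjacent symmetric-difference length of an order
#'
#' @param gmap A [genotype_map()].
#' @param order Character vector of strain labels.
#' @return Total Mb of genotype difference between adjacent strains.
#' @export
order_cost <- function(gmap, order) {
  D <- symdiff_matrix(gmap)
  sum(D[cbind(order[-length(order)], order[-1])])
}

#' Partition the chromosome into blocks
#'
#' The atoms generated by all donor-interval endpoints across the panel,
#' with adjacent atoms merged when no strain distinguishes them; the
#' resulting blocks tile the chromosome and are numbered `Block1`,
#' `Block2`, ... from the centromeric end (position 0).
#'
#' @param gmap A [genotype_map()].
#' @param order Optional strain order (retained in the result for
#'   downstream reporting; the partition itself depends only on the map).
#' @return An object of class `block_partition`: a tibble with `block`,
#'   `start_mb`, `end_mb`, plus a strains x blocks coverage matrix in the
#'   `pattern` attribute.
#' @export
partition_blocks <- function(gmap, order = NULL) {
  stopifnot(inherits(gmap, "genotype_map"))
  if (nrow(gmap$alleles) == 0) abort("empty genotype map.")
  at <- interval_atoms(gmap)
  n_atoms <- ncol(at$pattern)
  keep_start <- c(TRUE, vapply(seq_len(n_atoms - 1) + 1L, function(j)
    !identical(at$pattern[, j], at$pattern[, j - 1L]), logical(1)))
  grp <- cumsum(keep_start)
  starts <- at$bounds[-length(at$bounds)][keep_start]
  ends <- c(starts[-1], gmap$chromosome_length_mb)
  pat <- at$pattern[, keep_start, drop = FALSE]
  blocks <- tibble(block = paste0("Block", seq_along(starts)),
                   start_mb = starts, end_mb = ends)
  colnames(pat) <- blocks$block
  structure(blocks, pattern = pat, order = order,
            class = c("block_partition", class(blocks)))
}

#' Welch tests between neighboring strains
#'
#' Two-sided Welch two-sample t-test for every adjacent pair of the
#' aligned panel, for each requested parameter.  The per-test significance
#' threshold is `alpha_family / (number of pairs)` (Bonferroni over the
#' realized pair list).
#'
#' @param order Strain order, e.g. from [order_by_similarity()].
#' @param table Phenotype tibble in the standard schema.
#' @param parameters Parameters to test.
#' @param alpha_family Family-wise level before Bonferroni division.
#' @param extra_pairs Optional 2-column matrix / data frame of additional
#'   strain pairs to test beyond the adjacent ones (both conventions for a
#'   panel's "extra" comparison can be reproduced this way).
#' @return An object of class `trabqtl_neighbors`.
#' @export
neighbor_tests <- function(order, table,
                           parameters = c("BVTV", "TbN", "TbTh"),
                           alpha_family = 0.05, extra_pairs = NULL) {
  table <- as_tibble(table)
  missing <- setdiff(order, unique(table$strain))
  if (length(missing) > 0) {
    abort(sprintf("strain(s) missing from the phenotype table: %s",
                  paste(missing, collapse = ", ")))
  }
  pairs <- tibble(strain1 = order[-length(order)], strain2 = order[-1])
  if (!is.null(extra_pairs)) {
    ep <- as.data.frame(extra_pairs)
    names(ep)[1:2] <- c("strain1", "strain2")
    pairs <- dplyr::bind_rows(pairs, as_tibble(ep[, 1:2]))
  }
  n_pairs <- nrow(pairs)
  threshold <- alpha_family / n_pairs
  res <- purrr::pmap_dfr(pairs, function(strain1, strain2) {
    purrr::map_dfr(parameters, function(p) {
      x <- table[[p]][table$strain == strain1]
      y <- table[[p]][table$strain == strain2]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        abort(sprintf("pair (%s, %s): need >= 2 animals per strain.",
                      strain1, strain2))
      }
      tt <- t.test(x, y)
      tibble(strain1 = strain1, strain2 = strain2, parameter = p,
             mean1 = mean(x), mean2 = mean(y),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, significant = tt$p.value < threshold)
    })
  })
  structure(list(order = order, pairs = pairs, results = res,
                 alpha_family = alpha_family, threshold = threshold),
            class = "trabqtl_neighbors")
}

#' @export
print.trabqtl_neighbors <- function(x, ...) {
  cat(sprintf("<trabqtl_neighbors> %d pairs, per-test threshold %.4g\n",
              nrow(x$pairs), x$threshold))
  sig <- x$results[x$results$significant, ]
  if (nrow(sig) == 0) {
    cat("  no significant neighbor differences\n")
  } else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s vs %s  %-5s p = %.3g\n", sig$strain1[i],
                  sig$strain2[i], sig$parameter[i], sig$p[i]))
    }
  }
  invisible(x)
}

#' @rdname tidy.trabqtl_screen
#' @export
tidy.trabqtl_neighbors <- function(x, ...) x$results

#' Assign QTL to chromosomal blocks
#'
#' For each significant neighbor pair and parameter, identifies the blocks
#' on which the two genotypes differ.  A pair differing in exactly one
#' block localizes the QTL to it; a pair differing in several blocks
#' yields one call per candidate block flagged `ambiguous`.  The
#' donor-allele effect direction is the sign of (donor-carrying strain
#' mean - other strain mean) for that block.
#'
#' @param report A `trabqtl_neighbors` result.
#' @param partition A [partition_blocks()] result from the same map.
#' @param gmap The [genotype_map()] both were computed from.
#' @return A tibble of class `trabqtl_qtl` with one row per (pair,
#'   parameter, candidate block): `block`, `start_mb`, `end_mb`,
#'   `parameter`, `direction`, `effect`, `strain1`, `strain2`, `p`,
#'   `threshold`, `n_candidate_blocks`, `ambiguous`.
#' @export
assign_qtl <- function(report, partition, gmap) {
  stopifnot(inherits(report, "trabqtl_neighbors"),
            inherits(partition, "block_partition"))
  pat <- attr(partition, "pattern")
  sig <- report$results[report$results$significant, , drop = FALSE]
  calls <- purrr::pmap_dfr(sig, function(strain1, strain2, parameter,
                                         mean1, mean2, statistic, df, p,
                                         significant) {
    diffb <- which(pat[strain1, ] != pat[strain2, ])
    if (length(diffb) == 0) {
      abort(sprintf(
        "pair (%s, %s) is significant but genotypically identical: inconsistent inputs.",
        strain1, strain2))
    }
    purrr::map_dfr(diffb, function(b) {
      carrier <- if (pat[strain1, b]) strain1 else strain2
      eff <- if (carrier == strain1) mean1 - mean2 else mean2 - mean1
      tibble(block = colnames(pat)[b],
             start_mb = partition$start_mb[b],
             end_mb = partition$end_mb[b],
             parameter = parameter,
             direction = ifelse(eff > 0, "increase", "decrease"),
             effect = eff,
             strain1 = strain1, strain2 = strain2, p = p,
             threshold = report$threshold,
             n_candidate_blocks = length(diffb),
             ambiguous = length(diffb) > 1)
    })
  })
  class(calls) <- c("trabqtl_qtl", class(calls))
  calls
}

#' Map QTL blocks on a subconsomic panel
#'
#' End-to-end convenience wrapper: orders the strains by genotype
#' similarity, partitions the chromosome into blocks, runs the Welch
#' neighbor tests and assigns QTL calls.
#'
#' @param gmap A [genotype_map()].
#' @param table Phenotype tibble.
#' @inheritParams neighbor_tests
#' @inheritParams order_by_similarity
#' @return A list of class `trabqtl_block_map` with elements `order`,
#'   `partition`, `neighbors`, `qtl`.
#' @examples
#' sim <- simulate_subconsomic_panel(subconsomic_spec(seed = 3))
#' bm <- map_blocks(sim$genotype, sim$phenotype)
#' tidy(bm)
#' @export
map_blocks <- function(gmap, table, parameters = c("BVTV", "TbN", "TbTh"),
                       alpha_family = 0.05, anchor_parents = TRUE,
                       extra_pairs = NULL) {
  ord <- order_by_similarity(gmap, anchor_parents = anchor_parents)
  part <- partition_blocks(gmap, ord)
  nb <- neighbor_tests(ord, table, parameters = parameters,
                       alpha_family = alpha_family,
                       extra_pairs = extra_pairs)
  qtl <- assign_qtl(nb, part, gmap)
  structure(list(order = ord, partition = part, neighbors = nb, qtl = qtl),
            class = "trabqtl_block_map")
}

#' @export
print.trabqtl_block_map <- function(x, ...) {
  cat(sprintf("<trabqtl_block_map> %d strains, %d blocks, %d QTL call row(s)\n",
              length(x$order), nrow(x$partition), nrow(x$qtl)))
  print(x$neighbors)
  invisible(x)
}

#' @rdname tidy.trabqtl_screen
#' @export
tidy.trabqtl_block_map <- function(x, ...) as_tibble(x$qtl)

#' @rdname tidy.trabqtl_screen
#' @export
glance.trabqtl_block_map <- function(x, ...) {
  tibble(n_strains = length(x$order),
         n_blocks = nrow(x$partition),
         n_pairs = nrow(x$neighbors$pairs),
         n_significant_pairs = x$neighbors$results |>
           dplyr::filter(.data$significant) |>
           dplyr::distinct(.data$strain1, .data$strain2) |> nrow(),
         n_qtl = nrow(x$qtl),
         threshold = x$neighbors$threshold)
}

#' Text rendering of the strain alignment
#'
#' One line per strain in panel order, showing which blocks carry the
#' donor allele (`M`) versus the host allele (`.`).
#'
#' @param gmap A [genotype_map()].
#' @param order Strain order.
#' @return Character vector of alignment lines (also printed invisibly).
#' @export
format_genotype_alignment <- function(gmap, order = order_by_similarity(gmap)) {
  part <- partition_blocks(gmap, order)
  pat <- attr(part, "pattern")
  width <- max(nchar(order))
  header <- sprintf("%-*s %s", width, "",
                    paste(sprintf("%4.0f", part$start_mb), collapse = ""))
  lines <- vapply(order, function(s) {
    sprintf("%-*s %s", width, s,
            paste(sprintf("%4s", ifelse(pat[s, ], "M", ".")), collapse = ""))
  }, character(1))
  c(header, lines)
}

#' Plot a block map
#'
#' Strains as rows (panel order), donor segments as filled spans, block
#' boundaries as vertical lines, and QTL calls marked on the affected
#' blocks.
#'
#' @param object A `trabqtl_block_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trabqtl_block_map <- function(object, ...) {
  part <- object$partition
  pat <- attr(part, "pattern")
  ord <- rev(object$order)
  seg <- as.data.frame(as.table(pat))
  names(seg) <- c("strain", "block", "donor")
  seg <- dplyr::left_join(seg, as_tibble(part), by = "block")
  seg$strain <- factor(seg$strain, levels = ord)
  qtl <- as_tibble(object$qtl)
  gg <- ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_mb,
                                    xmax = .data$end_mb,
                                    ymin = as.integer(.data$strain) - 0.4,
                                    ymax = as.integer(.data$strain) + 0.4,
                                    fill = .data$donor), colour = "grey40",
                       linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "white"),
                               labels = c(`TRUE` = "donor", `FALSE` = "host"),
                               name = NULL) +
    ggplot2::scale_y_continuous(breaks = seq_along(ord), labels = ord) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(qtl) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = qtl,
      ggplot2::aes(x = (.data$start_mb + .data$end_mb) / 2,
                   y = length(ord) + 0.8,
                   shape = .data$parameter), size = 3, colour = "firebrick")
  }
  gg
}
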