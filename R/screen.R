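#' Screen a consomic panel against the host strain
#'
#' Dunnett many-to-one comparison of every strain against the control
#' (host) strain, per parameter.  The test statistic uses the pooled
#' within-strain variance with `N - k` degrees of freedom; the family-wise
#' adjusted p-value of each comparison is computed from the equicorrelated
#' multivariate-t distribution with the exact (possibly unbalanced)
#' correlation `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`, integrated with
#' `mvtnorm::pmvt` (two-sided).  The per-strain Welch p-value against the
#' control is reported alongside for reference.
#'
#' Strains whose data are degenerate (zero pooled variance) get an adjusted
#' p of 1 and a `degenerate` flag with a warning.  Rows with a missing
#' value are dropped listwise per parameter.
#'
#' @param table Phenotype tibble in the standard schema (`strain`,
#'   `animal_id`, `age_wk`, six parameter columns).
#' @param control,donor Parent strain labels; the control must be present.
#' @param alpha Family-wise significance level.
#' @param parameters Parameter columns to screen.
#' @param seed Seed for the quasi-Monte-Carlo multivariate-t integration
#'   (makes adjusted p-values reproducible).
#' @return An object of class `trabqtl_screen`; see [tidy.trabqtl_screen()].
#' @examples
#' pheno <- simulate_consomic_panel(panel_spec(seed = 7))
#' scr <- dunnett_screen(pheno, control = "B6", donor = "MSM")
#' head(tidy(scr))
#' @export
dunnett_screen <- function(table, control = "B6", donor = "MSM",
                           alpha = 0.05,
                           parameters = intersect(trab_parameters(),
                                                  names(table)),
                           seed = 1L) {
  table <- as_tibble(table)
  if (!control %in% table$strain) {
    abort(sprintf("control strain '%s' not in the table.", control))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  res <- withr::with_seed(seed, purrr::map_dfr(parameters, function(p) {
    dat <- table[!is.na(table[[p]]), c("strain", p)]
    names(dat)[2] <- "y"
    st <- dat |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                       var = stats::var(.data$y), .groups = "drop")
    if (any(st$n < 2)) {
      abort(sprintf("every strain needs >= 2 animals for '%s'.", p))
    }
    i0 <- which(st$strain == control)
    k <- nrow(st)
    df <- sum(st$n) - k
    sp2 <- sum((st$n - 1) * st$var) / df
    comp <- st[-i0, ]
    degenerate <- sp2 <= 0
    lam <- sqrt(comp$n / (comp$n + st$n[i0]))
    Rmat <- tcrossprod(lam)
    diag(Rmat) <- 1
    if (degenerate) {
      warn(sprintf("zero pooled variance for '%s'; p-values set to 1.", p))
      tstat <- rep(NA_real_, nrow(comp))
      padj <- rep(1, nrow(comp))
    } else {
      tstat <- (comp$mean - st$mean[i0]) /
        sqrt(sp2 * (1 / comp$n + 1 / st$n[i0]))
      padj <- vapply(abs(tstat), function(tt) {
        if (!is.finite(tt)) return(1)
        1 - mvtnorm::pmvt(lower = rep(-tt, k - 1), upper = rep(tt, k - 1),
                          df = df, corr = Rmat)[1]
      }, numeric(1))
      padj <- pmin(pmax(padj, 0), 1)
    }
    welch <- vapply(comp$strain, function(s) {
      x <- dat$y[dat$strain == s]
      y0 <- dat$y[dat$strain == control]
      if (sd(x) == 0 && sd(y0) == 0) return(1)
      t.test(x, y0)$p.value
    }, numeric(1))
    dplyr::bind_rows(
      tibble(strain = control, parameter = p, n = st$n[i0],
             mean = st$mean[i0], se = sqrt(st$var[i0] / st$n[i0]),
             t = NA_real_, p_welch = NA_real_, p_adj = NA_real_,
             significant = NA, degenerate = degenerate),
      tibble(strain = comp$strain, parameter = p, n = comp$n,
             mean = comp$mean, se = sqrt(comp$var / comp$n),
             t = tstat, p_welch = welch, p_adj = padj,
             significant = padj < alpha, degenerate = degenerate))
  }))
  structure(list(results = res, control = control, donor = donor,
                 alpha = alpha, parameters = parameters),
            class = "trabqtl_screen")
}

#' @export
print.trabqtl_screen <- function(x, ...) {
  nsig <- x$results |>
    dplyr::filter(!is.na(.data$significant)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(sig = sum(.data$significant), total = dplyr::n())
  cat(sprintf("<trabqtl_screen> control %s, donor %s, alpha %.3g\n",
              x$control, x$donor, x$alpha))
  for (i in seq_len(nrow(nsig))) {
    cat(sprintf("  %-6s %d / %d strains significant vs %s\n",
                nsig$parameter[i], nsig$sig[i], nsig$total[i], x$control))
  }
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `trabqtl_screen`.
#' @param ... Unused.
#' @return Tibble with one row per (strain, parameter): `n`, `mean`, `se`,
#'   `t`, `p_welch`, `p_adj`, `significant`, `degenerate`.
#' @export
tidy.trabqtl_screen <- function(x, ...) x$results

#' @rdname tidy.trabqtl_screen
#' @export
glance.trabqtl_screen <- function(x, ...) {
  r <- x$results |> dplyr::filter(!is.na(.data$significant))
  tibble(n_strains = dplyr::n_distinct(x$results$strain),
         n_parameters = length(x$parameters),
         n_significant = sum(r$significant),
         alpha = x$alpha)
}

#' Ascending strain order for one parameter
#'
#' Strains (parents included) sorted by increasing mean value, as the
#' screen figures are laid out; ties are broken lexicographically.
#'
#' @param result A `trabqtl_screen`.
#' @param parameter One parameter name.
#' @return Character vector of strain labels, ascending by mean.
#' @export
order_strains <- function(result, parameter) {
  stopifnot(inherits(result, "trabqtl_screen"))
  r <- result$results[result$results$parameter == parameter, ]
  if (nrow(r) == 0) abort(sprintf("parameter '%s' was not screened.", parameter))
  r$strain[order(r$mean, r$strain)]
}

#' Spearman correlation matrix of the six parameters
#'
#' Rank correlation (midranks for ties) between every pair of trabecular
#' parameters, across all individual animals of the panel pooled (the
#' default) or across strain means.
#'
#' @param table Phenotype tibble in the standard schema.
#' @param parameters Parameter columns to correlate.
#' @param by `"individual"` (pooled animals) or `"strain_mean"`.
#' @return An object of class `trabqtl_corr`: tidy pairs via [tidy()], full
#'   matrices in attributes `rho` and `p`.
#' @export
spearman_matrix <- function(table, parameters = intersect(trab_parameters(),
                                                          names(table)),
                            by = c("individual", "strain_mean")) {
  by <- match.arg(by)
  table <- as_tibble(table)
  dat <- if (by == "strain_mean") {
    table |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(parameters), mean),
                       .groups = "drop")
  } else {
    table
  }
  if (nrow(dat) < 3) abort("need at least 3 observations.")
  k <- length(parameters)
  rho <- matrix(1, k, k, dimnames = list(parameters, parameters))
  pmat <- matrix(NA_real_, k, k, dimnames = list(parameters, parameters))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- dat[[parameters[i]]]
      y <- dat[[parameters[j]]]
      if (sd(x) == 0 || sd(y) == 0) {
        warn(sprintf("constant column in pair (%s, %s); rho undefined.",
                     parameters[i], parameters[j]))
        r <- NA_real_; pv <- NA_real_
      } else {
        ct <- suppressWarnings(
          cor.test(x, y, method = "spearman", exact = FALSE))
        r <- unname(ct$estimate); pv <- ct$p.value
      }
      rho[i, j] <- rho[j, i] <- r
      pmat[i, j] <- pmat[j, i] <- pv
      pairs[[length(pairs) + 1L]] <- tibble(
        parameter1 = parameters[i], parameter2 = parameters[j],
        rho = r, p = pv, n = nrow(dat))
    }
  }
  structure(list(pairs = dplyr::bind_rows(pairs), by = by),
            rho = rho, p = pmat, class = "trabqtl_corr")
}

#' @export
print.trabqtl_corr <- function(x, ...) {
  cat(sprintf("<trabqtl_corr> Spearman rho over %s data\n",
              ifelse(x$by == "individual", "pooled individual", "strain-mean")))
  print(round(attr(x, "rho"), 2))
  invisible(x)
}

#' @rdname tidy.trabqtl_screen
#' @export
tidy.trabqtl_corr <- function(x, ...) x$pairs

#' Nonadditivity (epistasis) index
#'
#' Summed phenotypic effects of the significant consomic strains, as a
#' percentage of the parental difference:
#' `100 * sum(mean_s - mean_control) / (mean_donor - mean_control)` over
#' strains flagged significant (parents excluded).  Values far above 100%
#' indicate that single-chromosome effects combine nonadditively in the
#' full donor genome.
#'
#' @param result A `trabqtl_screen` (the donor strain must have been
#'   screened so its mean is available).
#' @param parameter One parameter name.
#' @param include_all Include all strains instead of only the significant
#'   ones.
#' @return Percentage (scalar).
#' @export
nonadditivity_index <- function(result, parameter, include_all = FALSE) {
  stopifnot(inherits(result, "trabqtl_screen"))
  r <- result$results[result$results$parameter == parameter, ]
  if (nrow(r) == 0) abort(sprintf("parameter '%s' was not screened.", parameter))
  m0 <- r$mean[r$strain == result$control]
  m1 <- r$mean[r$strain == result$donor]
  if (length(m1) == 0) abort("donor strain not present in the screen.")
  if (m1 == m0) abort("zero parental difference; index undefined.")
  cand <- r[!(r$strain %in% c(result$control, result$donor)), ]
  if (!include_all) cand <- cand[cand$significant %in% TRUE, ]
  100 * sum(cand$mean - m0) / (m1 - m0)
}

#' Plot a screen result as ordered strain means
#'
#' One panel per parameter, strains in ascending order of their mean with
#' mean +/- SE bars; significant strains are highlighted and the parents
#' labelled by colour.
#'
#' @param object A `trabqtl_screen`.
#' @param parameters Parameters to show (default: all screened).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trabqtl_screen <- function(object, parameters = object$parameters,
                                    ...) {
  df <- object$results |>
    dplyr::filter(.data$parameter %in% parameters) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::arrange(.data$mean, .data$strain, .by_group = TRUE) |>
    dplyr::mutate(pos = dplyr::row_number(),
                  role = dplyr::case_when(
                    .data$strain == object$control ~ "control",
                    .data$strain == object$donor ~ "donor",
                    .data$significant %in% TRUE ~ "significant",
                    TRUE ~ "n.s.")) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$mean, colour = .data$role)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(control = "black",
                                            donor = "firebrick",
                                            significant = "steelblue",
                                            `n.s.` = "grey60")) +
    ggplot2::labs(x = "strains, ascending mean", y = "mean ± SE",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a trait correlation matrix
#'
#' @param object A `trabqtl_corr`.
#' @param ... Unused.
#' @return A ggplot heatmap of Spearman rho.
#' @export
autoplot.trabqtl_corr <- function(object, ...) {
  rho <- attr(object, "rho")
  df <- as.data.frame(as.table(rho))
  names(df) <- c("p1", "p2", "rho")
  ggplot2::ggplot(df, ggplot2::aes(.data$p1, .data$p2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", mid = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}
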