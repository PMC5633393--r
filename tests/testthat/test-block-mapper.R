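ladder_map <- function() {
  simulate_subconsomic_panel(subconsomic_spec(seed = 1))$genotype
}

test_that("two strains yield the unique order", {
  gm <- genotype_map_from_intervals(
    list(A = cbind(0, 100), B = cbind(start_mb = numeric(0),
                                      end_mb = numeric(0))),
    seq(5, 95, by = 10), 100)
  expect_identical(order_by_similarity(gm), c("A", "B")) # donor end first
})

test_that("similarity ordering attains the exhaustive-search optimum", {
  withr::with_seed(13, {
    for (i in 1:20) {
      gm <- random_gmap(sample(4:6, 1))
      ord <- order_by_similarity(gm, anchor_parents = FALSE)
      D <- trabqtl:::symdiff_matrix(gm)
      expect_equal(order_cost(gm, ord), oracle_best_order_cost(D))
    }
  })
})

test_that("anchored ordering respects the parent ends and stays optimal", {
  withr::with_seed(29, {
    for (i in 1:10) {
      ivs <- c(list(B6 = cbind(start_mb = numeric(0), end_mb = numeric(0)),
                    C15 = cbind(0, 100)),
               lapply(setNames(1:4, paste0("S", 1:4)), function(j) {
                 s <- sample(seq(0, 80, 10), 1)
                 cbind(s, sample(seq(s + 10, 100, 10), 1))
               }))
      gm <- genotype_map_from_intervals(ivs, seq(5, 95, by = 10), 100)
      ord <- order_by_similarity(gm)
      expect_identical(ord[1], "C15")
      expect_identical(ord[length(ord)], "B6")
      D <- trabqtl:::symdiff_matrix(gm)
      expect_equal(order_cost(gm, ord),
                   oracle_best_order_cost(D,
                                          first = match("C15", rownames(D)),
                                          last = match("B6", rownames(D))))
    }
  })
})

test_that("nested donor segments order by containment", {
  ivs <- lapply(setNames(seq(10, 80, 10), paste0("Sub", 1:8)), function(s)
    cbind(s, 100))
  gm <- genotype_map_from_intervals(
    c(ivs, list(B6 = cbind(start_mb = numeric(0), end_mb = numeric(0)),
                C15 = cbind(0, 100))),
    seq(5, 95, by = 10), 100)
  expect_identical(order_by_similarity(gm),
                   c("C15", paste0("Sub", 1:8), "B6"))
})

test_that("oversized panels fall back to a greedy order with a warning", {
  ivs <- lapply(setNames(seq(5, 65, by = 5), sprintf("S%02d", 1:13)),
                function(s) cbind(s - 5, 100))
  gm <- genotype_map_from_intervals(ivs, seq(2.5, 97.5, by = 5), 100)
  expect_warning(ord <- order_by_similarity(gm, anchor_parents = FALSE),
                 "greedy")
  expect_setequal(ord, names(ivs))
})

test_that("block partition enumerates and merges endpoint atoms", {
  gm1 <- genotype_map_from_intervals(list(A = cbind(30, 70)),
                                     seq(5, 95, by = 10), 100)
  p1 <- partition_blocks(gm1)
  expect_identical(nrow(p1), 3L)
  expect_equal(p1$start_mb, c(0, 30, 70))
  expect_equal(p1$end_mb, c(30, 70, 100))
  expect_identical(p1$block, paste0("Block", 1:3))

  gm2 <- genotype_map_from_intervals(list(A = cbind(30, 70),
                                          B = cbind(30, 70)),
                                     seq(5, 95, by = 10), 100)
  p2 <- partition_blocks(gm2)
  expect_identical(nrow(p2), 3L) # identical strains add no breakpoints
  expect_error(
    genotype_map(tibble::tibble(marker = "m1", position_mb = 5),
                 matrix(character(0), 0, 1), 100),
    "rownames")
})

test_that("random partitions tile the chromosome and match atom enumeration", {
  withr::with_seed(31, {
    for (i in 1:15) {
      gm <- random_gmap(sample(3:6, 1))
      part <- partition_blocks(gm)
      expect_equal(part$start_mb[1], 0)
      expect_equal(part$end_mb[nrow(part)], gm$chromosome_length_mb)
      expect_equal(part$start_mb[-1], part$end_mb[-nrow(part)]) # no gaps
      # oracle: every derived interval endpoint is a block boundary
      iv <- strain_intervals(gm)
      ends <- setdiff(unique(c(iv$start_mb, iv$end_mb)),
                      c(0, gm$chromosome_length_mb))
      expect_true(all(ends %in% part$start_mb))
    }
  })
})

test_that("neighbor tests apply the Bonferroni threshold over realized pairs", {
  sim <- simulate_subconsomic_panel(subconsomic_spec(seed = 6))
  ord <- order_by_similarity(sim$genotype)
  nb <- neighbor_tests(ord, sim$phenotype, parameters = "BVTV")
  expect_identical(nrow(nb$pairs), length(ord) - 1L)
  expect_equal(nb$threshold, 0.05 / 9)
  nb2 <- neighbor_tests(ord, sim$phenotype, parameters = "BVTV",
                        extra_pairs = cbind("C15", "B6"))
  expect_identical(nrow(nb2$pairs), 10L)
  expect_equal(nb2$threshold, 0.05 / 10)
  expect_error(neighbor_tests(c(ord, "SubX"), sim$phenotype),
               "SubX")
})

test_that("a planted shift between one pair is flagged, null pairs are not", {
  means <- c(C15 = 0.5, S1 = 0.5, S2 = 0.42, B6 = 0.42) # 8 SD step at S1/S2
  ivs <- list(S1 = cbind(0, 60), S2 = cbind(0, 40))
  gm <- genotype_map_from_intervals(
    c(list(C15 = cbind(0, 100)), ivs,
      list(B6 = cbind(start_mb = numeric(0), end_mb = numeric(0)))),
    seq(5, 95, by = 10), 100)
  tab <- make_pheno(means, n = 6, sd = 0.01, parameter = "BVTV", seed = 4)
  nb <- neighbor_tests(c("C15", "S1", "S2", "B6"), tab,
                       parameters = "BVTV")
  res <- nb$results
  expect_true(res$significant[res$strain1 == "S1" & res$strain2 == "S2"])
  expect_false(res$significant[res$strain1 == "C15"])
  expect_false(res$significant[res$strain1 == "S2"])
})

test_that("QTL are assigned to differing blocks with donor-side directions", {
  ivs <- list(S1 = cbind(0, 60), S2 = cbind(0, 40))
  gm <- genotype_map_from_intervals(
    c(list(C15 = cbind(0, 100)), ivs,
      list(B6 = cbind(start_mb = numeric(0), end_mb = numeric(0)))),
    seq(5, 95, by = 10), 100)
  part <- partition_blocks(gm)
  # S1 carries donor allele on [40,60) and has the LOWER value -> decrease
  tab <- make_pheno(c(C15 = 0.5, S1 = 0.42, S2 = 0.5, B6 = 0.5), n = 6,
                    sd = 0.01, parameter = "BVTV", seed = 9)
  nb <- neighbor_tests(c("C15", "S1", "S2", "B6"), tab, parameters = "BVTV",
                       extra_pairs = cbind("S1", "B6"))
  calls <- assign_qtl(nb, part, gm)
  one <- calls[calls$strain1 == "S1" & calls$strain2 == "S2", ]
  expect_identical(nrow(one), 1L)
  expect_equal(one$start_mb, 40)
  expect_equal(one$end_mb, 60)
  expect_identical(one$direction, "decrease")
  expect_false(one$ambiguous)
  # S1 vs B6 differ in [0,40) and [40,60): ambiguous two-block candidates
  multi <- calls[calls$strain1 == "S1" & calls$strain2 == "B6", ]
  expect_identical(nrow(multi), 2L)
  expect_true(all(multi$ambiguous))
  expect_true(all(multi$n_candidate_blocks == 2L))
})

test_that("a significant pair with identical genotypes is inconsistent", {
  gm <- genotype_map_from_intervals(
    list(A = cbind(0, 60), B = cbind(0, 60)), seq(5, 95, by = 10), 100)
  part <- partition_blocks(gm)
  tab <- make_pheno(c(A = 0.5, B = 0.3), n = 6, sd = 0.01,
                    parameter = "BVTV", seed = 2)
  nb <- neighbor_tests(c("A", "B"), tab, parameters = "BVTV")
  expect_true(any(nb$results$significant))
  expect_error(assign_qtl(nb, part, gm), "identical")
})

test_that("lowering the family alpha never adds a QTL call", {
  sim <- simulate_subconsomic_panel(subconsomic_spec(seed = 12))
  bm1 <- map_blocks(sim$genotype, sim$phenotype, alpha_family = 0.05)
  bm2 <- map_blocks(sim$genotype, sim$phenotype, alpha_family = 0.005)
  key <- function(x) paste(x$block, x$parameter, x$strain1, x$strain2)
  expect_true(all(key(tidy(bm2)) %in% key(tidy(bm1))))
})

test_that("the default simulated panel recovers its planted architecture", {
  sim <- simulate_subconsomic_panel(subconsomic_spec(seed = 3))
  bm <- map_blocks(sim$genotype, sim$phenotype)
  expect_identical(bm$order, c("C15", paste0("Sub", 1:8), "B6"))
  expect_identical(nrow(bm$partition), 9L)
  calls <- tidy(bm)
  # the two strong BV/TV-decreasing QTL are always recovered
  expect_true(any(calls$block == "Block7" & calls$parameter == "BVTV" &
                    calls$direction == "decrease"))
  expect_true(any(calls$block == "Block9" & calls$parameter == "BVTV" &
                    calls$direction == "decrease"))
  # the thickness-increasing QTL near the centromere
  expect_true(any(calls$block == "Block2" & calls$parameter == "TbTh" &
                    calls$direction == "increase"))
})

test_that("the text alignment renders donor segments in panel order", {
  sim <- simulate_subconsomic_panel(subconsomic_spec(seed = 1))
  lines <- format_genotype_alignment(sim$genotype)
  expect_length(lines, 11L) # header + 10 strains
  expect_match(lines[2], "^C15")
  expect_match(lines[11], "^B6")
  expect_false(grepl("M", lines[11]))
})
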