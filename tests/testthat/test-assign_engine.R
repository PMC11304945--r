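toy_trio <- function() {
  markers <- paste0("M", 1:10)
  set.seed(21)
  sires <- simulate_parents(3, runif(10, 0.2, 0.5),
                            ids = paste0("S", 1:3), markers = markers)
  dams <- simulate_parents(3, runif(10, 0.2, 0.5),
                           ids = paste0("D", 1:3), markers = markers)
  cross <- data.frame(sire = rep(sires$ids, 2), dam = rep(dams$ids, 2))
  off <- simulate_offspring(sires, dams, cross)$offspring
  off$calls[1, 3] <- NA   # one missing offspring call
  list(off = off, sires = sires, dams = dams)
}

test_that("pair scores decompose into per-marker table sums", {
  d <- toy_trio()
  params <- table_params(suppressWarnings(allele_frequencies(d$off)),
                         r = 0.4)
  sc <- score_all_pairs(d$off, d$sires, d$dams, params)
  for (i in seq_along(d$off$ids)) {
    for (si in seq_along(d$sires$ids)) for (di in seq_along(d$dams$ids)) {
      pair <- (di - 1L) * 3L + si
      used <- !is.na(d$off$calls[i, sc$markers])
      liks <- mms <- numeric(0)
      for (mk in sc$markers[used]) {
        s <- d$sires$calls[si, mk]
        dd <- d$dams$calls[di, mk]
        liks <- c(liks, log10(triploid_likelihood(
          d$off$calls[i, mk], s, dd, params, mk)))
        mms <- c(mms, triploid_mismatches(d$off$calls[i, mk], s, dd))
      }
      expect_equal(sc$mean_log10_lik[i, pair] * sc$n_used[i], sum(liks))
      expect_equal(sc$mismatches[i, pair], sum(mms))
      expect_identical(sc$n_used[i], sum(used))
    }
  }
  expect_true(all(sc$mean_log10_lik <= 0))
  expect_true(all(sc$mismatches <= 2 * sc$n_used))
})

test_that("single-marker scores hit the table corner cases", {
  off <- gm(list(T1 = "A/A/A"), "M1", ploidy = 3)
  sires <- gm(list(S1 = "A/A", S2 = "B/B"), "M1", ploidy = 2)
  dams <- gm(list(D1 = "A/A", D2 = "B/B"), "M1", ploidy = 2)
  params <- table_params(list(M1 = c(A = 1)), e = 0.01)
  sc <- score_all_pairs(off, sires, dams, params)
  expect_equal(sc$mean_log10_lik[1, 1], 0)        # AA x AA: log10(1)
  expect_equal(sc$mismatches[1, 1], 0)
  expect_equal(sc$mean_log10_lik[1, 4], -2)       # BB x BB: log10(e)
  expect_equal(sc$mismatches[1, 4], 2)
})

test_that("the BLAS contraction agrees with the reference gather kernel", {
  set.seed(31)
  ds <- simulate_dataset(sim_config(n_sires = 8, n_dams = 9,
                                    n_offspring = 25, n_markers = 40,
                                    maf = c(0.05, 0.5), seed = 31))
  ds$offspring$calls[cbind(sample(25, 10, TRUE), sample(40, 10, TRUE))] <- NA
  sc <- score_all_pairs(ds$offspring, ds$sires, ds$dams)
  enc <- sc$encoding
  ref <- score_pairs_cpp(enc$off_codes, enc$sire_codes, enc$dam_codes,
                         lapply(enc$tabs, `[[`, "log10_lik"), enc$mm)
  expect_equal(sc$mean_log10_lik, ref$lik_sum / pmax(ref$n_used, 1),
               ignore_attr = TRUE)
  expect_equal(sc$mismatches, ref$mm_sum, ignore_attr = TRUE,
               tolerance = 0)
})

test_that("exclusion assigns unique minimal pairs and refuses ties", {
  markers <- paste0("M", 1:40)
  set.seed(22)
  sires <- simulate_parents(4, rep(0.5, 40), ids = paste0("S", 1:4),
                            markers = markers)
  dams <- simulate_parents(4, rep(0.5, 40), ids = paste0("D", 1:4),
                           markers = markers)
  # duplicate dam D4 = D3 to force a tie for offspring of D3
  dams$calls[4, ] <- dams$calls[3, ]
  cross <- data.frame(sire = c("S1", "S2"), dam = c("D1", "D3"))
  off <- simulate_offspring(sires, dams, cross)$offspring
  sc <- score_all_pairs(off, sires, dams)
  asg <- assign_exclusion(sc, threshold = 0)
  expect_true(asg$assigned[1])
  expect_identical(asg$sire[1], "S1")
  expect_identical(asg$dam[1], "D1")
  expect_false(asg$assigned[2])   # D3/D4 tie at the minimum
})

test_that("the automated mismatch allowance finds the histogram valley", {
  expect_identical(auto_mismatch_threshold(c(0, 0, 1, 0, 2, 1, 40, 41, 38),
                                           n_markers = 100), 2L)
  expect_identical(auto_mismatch_threshold(rep(0L, 50), n_markers = 100), 0L)
  # low cluster not anchored at zero
  expect_identical(auto_mismatch_threshold(c(1, 1, 2, 40), n_markers = 100),
                   2L)
  # no valley: binomial fallback at twice the error floor
  expect_identical(auto_mismatch_threshold(0:12, n_markers = 100, e = 0.01),
                   as.integer(qbinom(0.999, 100, 0.02)))
})

test_that("likelihood assignment honours ties and the error-rate limit", {
  set.seed(23)
  ds <- simulate_dataset(sim_config(n_sires = 10, n_dams = 10,
                                    n_offspring = 60, n_markers = 60,
                                    maf = 0.4, error_rate = 0, seed = 23))
  sc <- score_all_pairs(ds$offspring, ds$sires, ds$dams)
  # error_rate -> 1: threshold collapses towards the null minimum and
  # everything with a unique best pair is assigned
  asg <- assign_likelihood(sc, error_rate = 0.999, seed = 5)
  expect_true(all(asg$assigned))
  expect_identical(asg$sire, ds$truth$sire)
  expect_identical(asg$dam, ds$truth$dam)

  # a duplicated sire forces an exact tie -> unassigned
  sires2 <- ds$sires
  sires2$calls[2, ] <- sires2$calls[1, ]
  sc2 <- score_all_pairs(ds$offspring, sires2, ds$dams)
  asg2 <- assign_likelihood(sc2, error_rate = 0.999, seed = 5)
  kids_of_s1 <- ds$truth$sire == "S001"
  expect_true(all(!asg2$assigned[kids_of_s1]))
  expect_error(assign_likelihood(sc, error_rate = 1.2), "error_rate")
})

test_that("assignments are deterministic under a fixed seed", {
  set.seed(24)
  ds <- simulate_dataset(sim_config(n_sires = 6, n_dams = 6,
                                    n_offspring = 20, n_markers = 30,
                                    seed = 24))
  sc <- score_all_pairs(ds$offspring, ds$sires, ds$dams)
  a1 <- assign_likelihood(sc, seed = 99)
  a2 <- assign_likelihood(sc, seed = 99)
  expect_identical(a1, a2)
  expect_identical(assign_exclusion(sc), assign_exclusion(sc))
})

test_that("exclusion output never depends on the recombination parameter", {
  set.seed(25)
  ds <- simulate_dataset(sim_config(n_sires = 8, n_dams = 8,
                                    n_offspring = 40, n_markers = 50,
                                    error_rate = 0.02, seed = 25))
  f <- allele_frequencies(ds$offspring)
  sc_lo <- score_all_pairs(ds$offspring, ds$sires, ds$dams,
                           table_params(f, r = 0.1))
  sc_hi <- score_all_pairs(ds$offspring, ds$sires, ds$dams,
                           table_params(f, r = 0.9))
  a_lo <- assign_exclusion(sc_lo)
  a_hi <- assign_exclusion(sc_hi)
  # the decision (and everything it is based on) is r-free; only the
  # reported likelihood of the best pair changes with r
  keep <- setdiff(names(a_lo), c("mean_log10_lik", "second_log10_lik"))
  expect_identical(a_lo[keep], a_hi[keep])
  expect_identical(attr(a_lo, "threshold"), attr(a_hi, "threshold"))
})

test_that("a separable noise-free panel yields perfect exclusion", {
  set.seed(26)
  ds <- simulate_dataset(sim_config(n_sires = 20, n_dams = 20,
                                    n_offspring = 100, n_markers = 192,
                                    maf = 0.5, error_rate = 0, seed = 26))
  sc <- score_all_pairs(ds$offspring, ds$sires, ds$dams)
  asg <- assign_exclusion(sc, threshold = 0)
  met <- evaluate_assignments(asg, ds$truth)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$fdr, 0)
  expect_identical(attr(assign_exclusion(sc), "threshold"), 0L)  # auto too
})

test_that("likelihood FDR is bounded for offspring lacking both parents", {
  # negatives are unrelated to every candidate, matching the gene-drop null
  set.seed(27)
  mafs <- runif(120, 0.2, 0.5)
  sires <- simulate_parents(30, mafs, ids = sprintf("S%02d", 1:30))
  dams <- simulate_parents(30, mafs, ids = sprintf("D%02d", 1:30))
  ghost_s <- simulate_parents(10, mafs, ids = sprintf("GS%02d", 1:10))
  ghost_d <- simulate_parents(10, mafs, ids = sprintf("GD%02d", 1:10))
  cross <- rbind(
    data.frame(sire = sample(sires$ids, 300, TRUE),
               dam = sample(dams$ids, 300, TRUE)),
    data.frame(sire = sample(ghost_s$ids, 100, TRUE),
               dam = sample(ghost_d$ids, 100, TRUE)))
  all_s <- pool_parents(sires, ghost_s)   # ploidy-2 rbind helper
  all_d <- pool_parents(dams, ghost_d)
  off <- inject_errors(simulate_offspring(all_s, all_d, cross)$offspring,
                       0.01)
  sc <- score_all_pairs(off, sires, dams)
  asg <- assign_likelihood(sc, error_rate = 0.05, seed = 8)
  truth <- data.frame(offspring = off$ids, sire = cross$sire,
                      dam = cross$dam)
  met <- evaluate_assignments(asg, truth)
  expect_equal(met$positives, 300)
  expect_equal(met$negatives, 100)
  expect_gt(met$sensitivity, 0.95)
  expect_lte(met$fdr, 2 * 0.05)
})

test_that("the single-parent comparator excludes opposed homozygotes", {
  off <- gm(list(T1 = c("A/A/A", "A/A/B", "A/B/B")),
            paste0("M", 1:3), ploidy = 3)
  parents <- gm(list(P1 = c("A/A", "A/B", "A/B"),
                     P2 = c("A/A", "A/B", "B/B"),
                     P3 = c("B/B", "B/B", "B/B"),
                     P4 = c("B/B", "A/A", "B/B")),
                paste0("M", 1:3), ploidy = 2)
  expect_error(grashei_assign(off, parents$calls), "genotype_matrix")
  asg <- grashei_assign(off, parents)
  # P3 and P4 carry opposed homozygotes (B/B against A/A/A), so the
  # dataset-wide third-ranked threshold is positive and P1/P2 are retained
  expect_true(asg$assigned[1])
  expect_setequal(c(asg$sire[1], asg$dam[1]), c("P1", "P2"))
  expect_gt(attr(asg, "threshold"), 0)

  few <- gm(list(P1 = "A/A", P2 = "A/A"), "M1", ploidy = 2)
  off1 <- gm(list(T1 = "A/A/A"), "M1", ploidy = 3)
  expect_error(grashei_assign(off1, few), "at least 3")
})
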