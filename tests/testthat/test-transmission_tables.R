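biallelic_params <- function(fA = 0.6, r = 0.5, e = 0.01) {
  table_params(list(M1 = c(A = fA, B = 1 - fA)), r = r, e = e)
}

test_that("likelihood cells match hand-checked values", {
  p <- biallelic_params(fA = 0.6, r = 0.5)
  expect_equal(triploid_likelihood("A/A/A", "A/A", "A/A", p, "M1"), 1)
  expect_equal(triploid_likelihood("A/A/A", "A/B", "A/B", p, "M1"), 0.125)
  expect_equal(triploid_likelihood("A/B/B", "B/B", "A/B", p, "M1"), 0.5)
  expect_equal(triploid_likelihood("A/A/A", "B/B", "A/A", p, "M1"), 0.01)
  # sire AA, dam unknown: r * fA^2 + (1 - r) * fA
  expect_equal(triploid_likelihood("A/A/A", "A/A", NA, p, "M1"), 0.48)
  p3 <- biallelic_params(fA = 0.6, r = 0.3)
  # het x het: recombinant route adds 0.5 * r to 0.25 * (1 - r)
  expect_equal(triploid_likelihood("A/B/B", "A/B", "A/B", p3, "M1"), 0.325)
})

test_that("exclusion cells match the published counts", {
  expect_identical(triploid_mismatches("A/A/A", "B/B", "B/B"), 2L)
  expect_identical(triploid_mismatches("A/B/B", "A/A", "A/A"), 1L)
  expect_identical(triploid_mismatches("A/B/C", "A/A", "B/C"), 0L)
  expect_identical(triploid_mismatches("A/B/C", "D/D", "E/E"), 2L)
  expect_identical(triploid_mismatches("A/A/A", "B/B", NA), 1L)
  expect_identical(triploid_mismatches("A/B/B", NA, "A/A"), 1L)
  expect_identical(triploid_mismatches("A/A/B", "A/A", "A/A"), 1L)
})

test_that("the meiosis oracle reproduces the stated gamete model", {
  expect_equal(dam_gametes("A/B", 0), c("A/A" = 0.5, "B/B" = 0.5,
                                        "A/B" = 0))
  expect_equal(dam_gametes("A/B", 1), c("A/A" = 0, "B/B" = 0, "A/B" = 1))
  expect_equal(dam_gametes("A/A", 0.3), c("A/A" = 1))
  d <- meiosis_oracle("A/B", "A/B", 0.5)
  expect_equal(d[["A/A/A"]], 0.125)
  expect_equal(sum(d), 1)
  for (r in c(0, 0.25, 0.7, 1)) {
    expect_equal(sum(meiosis_oracle("A/B", "A/B", r)), 1)
  }
})

test_that("likelihood equals the enumeration oracle on the biallelic grid", {
  e <- 0.01
  parents <- c("A/A", "A/B", "B/B")
  offs <- all_trio_calls(c("A", "B"))
  # structural zeros: impossible for every r strictly inside (0, 1)
  structural <- function(off, s, d) {
    oracle_prob(off, s, d, c(A = 0.5, B = 0.5), 0.5) == 0
  }
  for (r in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- biallelic_params(fA = 0.37, r = r, e = e)
    for (s in parents) for (d in parents) {
      dist <- meiosis_oracle(s, d, r)
      total <- 0
      for (off in offs) {
        cell <- triploid_likelihood(off, s, d, p, "M1")
        truth <- if (off %in% names(dist)) dist[[off]] else 0
        if (structural(off, s, d)) {
          expect_identical(cell, e)
        } else {
          expect_equal(cell, truth)
          total <- total + cell
        }
      }
      # compatible cells form a probability distribution
      expect_equal(total, 1)
    }
  }
})

test_that("a mismatch is counted exactly where transmission is impossible", {
  # biallelic and triallelic offspring against every parent pair over a
  # 4-allele universe (the 4th allele plays the tables' 'other' letter)
  freqs <- c(a = 0.4, b = 0.3, c = 0.2, z = 0.1)
  pairs <- all_pair_calls(names(freqs))
  for (off in c("a/a/a", "a/b/b", "a/b/c")) {
    for (s in pairs) for (d in pairs) {
      mm <- triploid_mismatches(off, s, d)
      possible <- oracle_prob(off, s, d, freqs, 0.5) > 0
      expect_identical(mm >= 1L, !possible)
      # count 2 means each parent alone is already impossible
      sire_ok <- oracle_prob(off, s, NULL, freqs, 0.5) > 0
      dam_ok <- oracle_prob(off, NULL, d, freqs, 0.5) > 0
      expect_identical(mm == 2L, !sire_ok && !dam_ok)
    }
  }
})

test_that("likelihood cells are affine in the recombination rate", {
  freqs <- c(A = 0.55, B = 0.3, C = 0.15)
  pairs <- c(all_pair_calls(names(freqs)), NA)
  at_r <- function(off, s, d, r) {
    p <- table_params(list(M1 = freqs), r = r, e = 0.01)
    triploid_likelihood(off, s, d, p, "M1")
  }
  for (off in c("A/A/A", "A/B/B", "A/B/C")) {
    for (s in pairs) for (d in pairs) {
      v0 <- at_r(off, s, d, 0)
      v1 <- at_r(off, s, d, 1)
      for (r in c(0.2, 0.35, 0.8)) {
        expect_equal(at_r(off, s, d, r), v0 + r * (v1 - v0),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("materialised lookup tables equal the direct cell functions", {
  params <- table_params(list(SNP = c(A = 0.7, B = 0.3),
                              MSAT = c("148" = 0.5, "152" = 0.3,
                                       "156" = 0.2)),
                        r = 0.35, e = 0.01)
  tabs <- build_marker_tables(params)
  for (mk in names(tabs)) {
    tb <- tabs[[mk]]
    expect_true(all(tb$mismatch %in% 0:2))
    for (og in tb$off_genotypes) {
      for (sg in tb$parent_genotypes) for (dg in tb$parent_genotypes) {
        s <- if (sg == "MISSING") NA else sg
        d <- if (dg == "MISSING") NA else dg
        expect_identical(tb$log10_lik[og, sg, dg],
                         log10(triploid_likelihood(og, s, d, params, mk)))
        expect_identical(tb$mismatch[og, sg, dg],
                         triploid_mismatches(og, s, d))
      }
    }
  }
  # a fully homozygous compatible cell scores log10(1) = 0
  expect_identical(tabs$SNP$log10_lik["A/A/A", "A/A", "A/A"], 0)
  # markers without frequencies are dropped with a warning
  p2 <- table_params(list(M1 = c(A = 1), M2 = setNames(numeric(0),
                                                       character(0))))
  expect_warning(t2 <- build_marker_tables(p2), "M2")
  expect_named(t2, "M1")
})
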