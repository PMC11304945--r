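## Core math: per-marker Mendelian transmission probabilities and exclusion
## counts for a triploid offspring (2 maternal + 1 paternal chromosome sets,
## from second-polar-body retention) given a candidate diploid sire and dam.
##
## Offspring genotypes classify as AAA, ABB (singleton A, duplicated B) or
## ABC. Parent genotypes are re-expressed through the offspring's letters;
## any parent allele not carried by the offspring maps to the "other" letter
## (B for AAA, C for ABB, D for ABC). The likelihood tables are degree-1 in
## the marker-centromere recombination rate r; incompatible cells carry the
## error floor e. The exclusion tables count how many of the two parental
## genotypes (or their combination) the offspring is incompatible with,
## treating recombination as always possible, so they do not depend on r.

# letter used for parent alleles foreign to the offspring genotype
OTHER_LETTER <- c(AAA = "B", ABB = "C", ABC = "D")

as_genotype_class <- function(x, ploidy) {
  if (is.list(x) && !is.null(x$pattern)) return(x)
  classify_genotype(x, ploidy)
}

# Re-express a diploid parent class through the offspring's role_map.
# Returns "MISSING" or a two-letter class such as "AB", "BC", "DD".
rel_parent_class <- function(parent, off) {
  if (parent$pattern == "MISSING") return("MISSING")
  tokens <- if (parent$pattern == "AA") {
    rep(parent$role_map[["A"]], 2L)
  } else {
    c(parent$role_map[["A"]], parent$role_map[["B"]])
  }
  other <- OTHER_LETTER[[off$pattern]]
  letters2 <- vapply(tokens, function(tok) {
    hit <- names(off$role_map)[match(tok, off$role_map)]
    if (is.na(hit)) other else hit
  }, character(1), USE.NAMES = FALSE)
  paste(sort(letters2), collapse = "")
}

# P(dam transmits an AA gamete) and P(dam transmits an AB gamete) when the
# dam genotype is unknown, under Hardy-Weinberg at the offspring-population
# frequencies. Used by the Missing rows/columns of the likelihood tables.
#  - doubled gamete XX: dam XX always; dam X+other het with prob 0.5*(1-r)
#  - heterozygous gamete XY: dam XY with prob r (one crossover between
#    centromere and marker makes the egg retain both alleles)

lik_cell_AAA <- function(s, d, fA, r, e) {
  pAA <- r * fA^2 + (1 - r) * fA          # P(dam gamete AA | dam unknown)
  v <- switch(s,
    AA = switch(d, AA = 1, AB = 0.5 * (1 - r), BB = e, MISSING = pAA),
    AB = switch(d, AA = 0.5, AB = 0.25 * (1 - r), BB = e,
                MISSING = 0.5 * pAA),
    BB = e,
    MISSING = switch(d, AA = fA, AB = 0.5 * (1 - r) * fA, BB = e,
                     MISSING = fA * pAA))
  if (is.null(v)) stop("undefined parent class for AAA offspring: ", s, "/", d)
  v
}

lik_cell_ABB <- function(s, d, fA, fB, fC, r, e) {
  pBB <- fB^2 + (1 - r) * fA * fB + (1 - r) * fB * fC  # dam gamete BB
  pAB <- 2 * r * fA * fB                               # dam gamete AB
  v <- switch(s,
    AA = switch(d, AA = e, AB = 0.5 * (1 - r), BB = 1, AC = e,
                BC = 0.5 * (1 - r), CC = e, MISSING = pBB),
    AB = switch(d, AA = e, AB = 0.5 - 0.25 * (1 - r), BB = 0.5, AC = e,
                BC = 0.25 * (1 - r), CC = e,
                MISSING = 0.5 * pBB + 0.5 * pAB),
    BB = switch(d, AA = e, AB = r, BB = e, AC = e, BC = e, CC = e,
                MISSING = pAB),
    AC = switch(d, AA = e, AB = 0.25 * (1 - r), BB = 0.5, AC = e,
                BC = 0.25 * (1 - r), CC = e, MISSING = 0.5 * pBB),
    BC = switch(d, AA = e, AB = 0.5 * r, BB = e, AC = e, BC = e, CC = e,
                MISSING = 0.5 * pAB),
    CC = e,
    MISSING = switch(d, AA = e, AB = 0.5 * (1 - r) * fA + r * fB, BB = fA,
                     AC = e, BC = 0.5 * (1 - r) * fA, CC = e,
                     MISSING = fA * pBB + fB * pAB))
  if (is.null(v)) stop("undefined parent class for ABB offspring: ", s, "/", d)
  v
}

lik_cell_ABC <- function(s, d, fA, fB, fC, r, e) {
  # The dam must transmit a heterozygous (recombinant) gamete AB, AC or BC;
  # the sire supplies the remaining allele. Every compatible cell therefore
  # carries a factor r.
  v <- switch(s,
    AA = switch(d, BC = r, MISSING = 2 * fB * fC * r, e),
    AB = switch(d, AC = 0.5 * r, BC = 0.5 * r,
                MISSING = fB * fC * r + fA * fC * r, e),
    BB = switch(d, AC = r, MISSING = 2 * fA * fC * r, e),
    AC = switch(d, AB = 0.5 * r, BC = 0.5 * r,
                MISSING = fA * fB * r + fB * fC * r, e),
    BC = switch(d, AB = 0.5 * r, AC = 0.5 * r,
                MISSING = fA * fB * r + fA * fC * r, e),
    CC = switch(d, AB = r, MISSING = 2 * fA * fB * r, e),
    AD = switch(d, BC = 0.5 * r, MISSING = fB * fC * r, e),
    BD = switch(d, AC = 0.5 * r, MISSING = fA * fC * r, e),
    CD = switch(d, AB = 0.5 * r, MISSING = fA * fB * r, e),
    DD = e,
    MISSING = switch(d, AB = r * fC, AC = r * fB, BC = r * fA,
                     MISSING = 6 * r * fA * fB * fC, e))
  if (is.null(v)) stop("undefined parent class for ABC offspring: ", s, "/", d)
  v
}

# Exclusion tables: 0 = compatible; 1 = incompatible with one parental
# genotype or with the combination of the parental genotypes; 2 = incompatible
# with either parental genotype taken alone.
mk_mm <- function(classes, rows) {
  m <- matrix(unlist(rows), nrow = length(classes), byrow = TRUE,
              dimnames = list(classes, classes))
  storage.mode(m) <- "integer"
  m
}

MM_AAA <- mk_mm(c("AA", "AB", "BB", "MISSING"), list(
  c(0, 0, 1, 0),
  c(0, 0, 1, 0),
  c(1, 1, 2, 1),
  c(0, 0, 1, 0)))

MM_ABB <- mk_mm(c("AA", "AB", "BB", "AC", "BC", "CC", "MISSING"), list(
  c(1, 0, 0, 1, 0, 1, 0),
  c(1, 0, 0, 1, 0, 1, 0),
  c(1, 0, 1, 1, 1, 1, 0),
  c(1, 0, 0, 1, 0, 1, 0),
  c(1, 0, 1, 1, 1, 1, 0),
  c(2, 1, 1, 2, 1, 2, 1),
  c(1, 0, 0, 1, 0, 1, 0)))

MM_ABC <- mk_mm(c("AA", "AB", "BB", "AC", "BC", "CC",
                  "AD", "BD", "CD", "DD", "MISSING"), list(
  c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 0),
  c(1, 1, 1, 0, 0, 1, 1, 1, 1, 1, 0),
  c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0),
  c(1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 0),
  c(1, 0, 1, 0, 1, 1, 1, 1, 1, 1, 0),
  c(1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0),
  c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 0),
  c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0),
  c(1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0),
  c(2, 1, 2, 1, 1, 2, 2, 2, 2, 2, 1),
  c(1, 0, 1, 0, 0, 1, 1, 1, 1, 1, 0)))

#' Mendelian transmission probability of a triploid offspring genotype
#'
#' Probability of the offspring genotype at one marker conditional on the
#' genotypes of a candidate sire and dam, for triploids carrying one paternal
#' and two maternal allele copies. A heterozygous dam transmits a doubled
#' allele (each with probability `0.5 * (1 - r)`) unless a crossover occurred
#' between the centromere and the marker, in which case she transmits both of
#' her alleles (probability `r`). Missing parent genotypes are marginalised
#' under Hardy-Weinberg at the offspring-population allele frequencies.
#' Incompatible combinations return the error floor `params$e`.
#'
#' @param off,sire,dam genotype calls (character, e.g. `"A/B/B"`) or the
#'   result of [classify_genotype()]. `off` must be a non-missing triploid
#'   call; parents may be `NA` (missing).
#' @param params a [table_params()] object.
#' @param marker marker name (selects the allele-frequency vector).
#' @return A single probability.
#' @export
triploid_likelihood <- function(off, sire, dam, params, marker) {
  stopifnot(inherits(params, "table_params"))
  off <- as_genotype_class(off, 3L)
  if (off$pattern == "MISSING") {
    stop("offspring call is missing; the marker must be skipped upstream")
  }
  sire <- as_genotype_class(sire, 2L)
  dam <- as_genotype_class(dam, 2L)
  f <- params$freqs[[marker]]
  if (is.null(f)) stop("no allele frequencies for marker ", marker)
  fq <- function(letter) {
    tok <- off$role_map[[letter]]
    if (tok %in% names(f)) unname(f[[tok]]) else 0
  }
  s <- rel_parent_class(sire, off)
  d <- rel_parent_class(dam, off)
  r <- params$r
  e <- params$e
  switch(off$pattern,
    AAA = lik_cell_AAA(s, d, fA = fq("A"), r = r, e = e),
    ABB = {
      fA <- fq("A"); fB <- fq("B")
      lik_cell_ABB(s, d, fA = fA, fB = fB, fC = max(0, 1 - fA - fB),
                   r = r, e = e)
    },
    ABC = lik_cell_ABC(s, d, fA = fq("A"), fB = fq("B"), fC = fq("C"),
                       r = r, e = e))
}

#' Exclusion mismatch count for a triploid offspring and a parent pair
#'
#' Number of parental genotypes the offspring genotype is incompatible with
#' at one marker: 0 when compatible, 1 when incompatible with one parental
#' genotype or with the combination of the two, 2 when incompatible with
#' either parental genotype taken alone. Recombination is treated as always
#' possible, so the count does not depend on the recombination rate. Missing
#' parents use the always-compatible Missing row/column.
#'
#' @inheritParams triploid_likelihood
#' @return Integer 0, 1 or 2.
#' @export
triploid_mismatches <- function(off, sire, dam) {
  off <- as_genotype_class(off, 3L)
  if (off$pattern == "MISSING") {
    stop("offspring call is missing; the marker must be skipped upstream")
  }
  sire <- as_genotype_class(sire, 2L)
  dam <- as_genotype_class(dam, 2L)
  s <- rel_parent_class(sire, off)
  d <- rel_parent_class(dam, off)
  tab <- switch(off$pattern, AAA = MM_AAA, ABB = MM_ABB, ABC = MM_ABC)
  tab[s, d]
}

#' Gamete distribution of a diploid dam under second-polar-body retention
#'
#' A homozygous dam transmits her doubled allele. A heterozygous dam
#' transmits a doubled allele (each of her alleles with probability
#' `0.5 * (1 - r)`) when no crossover occurred between the centromere and the
#' marker, and both of her alleles (one heterozygous gamete) with
#' probability `r` when one did.
#'
#' @param dam diploid call (character or token vector).
#' @param r marker-centromere recombination rate in `[0, 1]`.
#' @return Named numeric vector: canonical two-allele gamete (sorted, joined
#'   by `/`) -> probability.
#' @export
dam_gametes <- function(dam, r) {
  stopifnot(r >= 0, r <= 1)
  cls <- as_genotype_class(dam, 2L)
  if (cls$pattern == "MISSING") stop("dam call is missing")
  if (cls$pattern == "AA") {
    a <- cls$role_map[["A"]]
    return(stats::setNames(1, paste(a, a, sep = "/")))
  }
  a <- cls$role_map[["A"]]; b <- cls$role_map[["B"]]
  g <- c(0.5 * (1 - r), 0.5 * (1 - r), r)
  names(g) <- c(paste(a, a, sep = "/"), paste(b, b, sep = "/"),
                paste(sort(c(a, b)), collapse = "/"))
  g
}

#' Brute-force meiosis oracle
#'
#' Enumerates the exact distribution of triploid offspring genotypes from a
#' diploid sire (each allele transmitted with probability 0.5) and a diploid
#' dam whose double contribution follows [dam_gametes()]. Serves as an
#' independent check of the likelihood tables and as the transmission model
#' of the simulator.
#'
#' @param sire,dam diploid calls.
#' @param r marker-centromere recombination rate.
#' @return Named numeric vector: canonical triploid call -> probability
#'   (summing to 1).
#' @export
meiosis_oracle <- function(sire, dam, r) {
  scls <- as_genotype_class(sire, 2L)
  if (scls$pattern == "MISSING") stop("sire call is missing")
  s_alleles <- if (scls$pattern == "AA") {
    stats::setNames(1, scls$role_map[["A"]])
  } else {
    stats::setNames(c(0.5, 0.5), c(scls$role_map[["A"]],
                                   scls$role_map[["B"]]))
  }
  gam <- dam_gametes(dam, r)
  out <- numeric(0)
  for (sa in names(s_alleles)) for (g in names(gam)) {
    p <- s_alleles[[sa]] * gam[[g]]
    trio <- paste(sort(c(sa, strsplit(g, "/", fixed = TRUE)[[1L]])),
                  collapse = "/")
    out[trio] <- (if (trio %in% names(out)) out[[trio]] else 0) + p
  }
  out
}

#' Materialise per-marker likelihood and exclusion lookup tables
#'
#' Precomputes, for each marker, `log10` transmission probabilities and
#' mismatch counts for every triploid offspring genotype constructible from
#' the marker's alleles crossed with every diploid parent genotype (plus
#' Missing), so that pair scoring reduces to table indexing. Values are
#' bit-identical to [triploid_likelihood()] / [triploid_mismatches()].
#'
#' @param params a [table_params()] object.
#' @param markers markers to materialise (default: all with frequencies).
#' @param extra_alleles optional named list of additional allele tokens seen
#'   in parents but absent from the offspring population (frequency 0).
#' @return Named list per marker with elements `alleles`, `off_genotypes`,
#'   `parent_genotypes` (last element `"MISSING"`), `log10_lik` and
#'   `mismatch` (3-d arrays indexed offspring x sire x dam). Markers whose
#'   frequency table is empty are excluded with a warning.
#' @export
build_marker_tables <- function(params, markers = names(params$freqs),
                                extra_alleles = NULL) {
  stopifnot(inherits(params, "table_params"))
  empty <- markers[lengths(params$freqs[markers]) == 0L]
  if (length(empty)) {
    warning("excluding marker(s) with no allele frequencies: ",
            paste(empty, collapse = ", "))
    markers <- setdiff(markers, empty)
  }
  out <- lapply(markers, function(mk) {
    alleles <- sort(unique(c(names(params$freqs[[mk]]),
                             extra_alleles[[mk]])))
    k <- length(alleles)
    # all triploid multisets and diploid pairs over the allele set
    off_g <- character(0)
    for (i in seq_len(k)) for (j in i:k) for (l in j:k) {
      off_g <- c(off_g, paste(alleles[c(i, j, l)], collapse = "/"))
    }
    par_g <- character(0)
    for (i in seq_len(k)) for (j in i:k) {
      par_g <- c(par_g, paste(alleles[c(i, j)], collapse = "/"))
    }
    par_g <- c(par_g, "MISSING")
    lik <- array(NA_real_, dim = c(length(off_g), length(par_g),
                                   length(par_g)),
                 dimnames = list(off_g, par_g, par_g))
    mm <- array(NA_integer_, dim = dim(lik), dimnames = dimnames(lik))
    par_cls <- lapply(par_g, function(p) {
      if (p == "MISSING") list(pattern = "MISSING", role_map = character(0))
      else classify_genotype(p, 2L)
    })
    for (oi in seq_along(off_g)) {
      ocls <- classify_genotype(off_g[oi], 3L)
      for (si in seq_along(par_g)) for (di in seq_along(par_g)) {
        lik[oi, si, di] <- log10(triploid_likelihood(
          ocls, par_cls[[si]], par_cls[[di]], params, mk))
        mm[oi, si, di] <- triploid_mismatches(ocls, par_cls[[si]],
                                              par_cls[[di]])
      }
    }
    list(alleles = alleles, off_genotypes = off_g, parent_genotypes = par_g,
         log10_lik = lik, mismatch = mm)
  })
  names(out) <- markers
  out
}
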