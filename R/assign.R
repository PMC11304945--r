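## Assignment methods: likelihood (error-rate-controlled delta threshold),
## exclusion (automated mismatch allowance), and the single-parent exclusion
## comparator that pools parents without sex information.

best2 <- function(mat, minimize = FALSE) {
  best2_rows_cpp(mat, minimize)
}

assignment_frame <- function(scores, idx) {
  data.frame(
    offspring = scores$offspring_ids,
    sire = pair_sire(scores, idx$best_idx),
    dam = pair_dam(scores, idx$best_idx),
    stringsAsFactors = FALSE
  )
}

finish_assignment <- function(df, method, threshold, scores) {
  attr(df, "method") <- method
  attr(df, "threshold") <- threshold
  attr(df, "candidate_sires") <- scores$sire_ids
  attr(df, "candidate_dams") <- scores$dam_ids
  df
}

#' Likelihood-based parentage assignment
#'
#' Each offspring's best-scoring pair (highest mean log10 transmission
#' probability) is accepted when the gap (`delta`) between the best and the
#' runner-up pair exceeds a threshold calibrated to a tolerated assignment
#' error rate: the threshold is the `1 - error_rate` quantile of the delta
#' distribution of pseudo-offspring gene-dropped from the marker allele
#' frequencies (unrelated to every candidate, with the missingness profile of
#' the real offspring) and scored against the same parents. Offspring whose
#' two best pairs tie exactly are left unassigned.
#'
#' @param scores a [score_all_pairs()] result.
#' @param error_rate tolerated assignment error rate in `(0, 1)`;
#'   default 0.05.
#' @param seed optional integer seed for the gene-dropped null.
#' @param n_null number of pseudo-offspring for the null; default
#'   `max(1000, n_offspring)`.
#' @return A data.frame with one row per offspring: best pair, runner-up
#'   score, `delta`, mismatch count of the best pair, `assigned` flag.
#'   Attributes record the method, threshold and candidate sets.
#' @export
assign_likelihood <- function(scores, error_rate = 0.05, seed = NULL,
                              n_null = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate <= 0 || error_rate >= 1) {
    stop("error_rate must be a single value strictly inside (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n_off <- length(scores$offspring_ids)
  if (is.null(n_null)) n_null <- max(1000L, n_off)

  top <- best2(scores$mean_log10_lik, minimize = FALSE)
  delta <- top$best - top$second

  null_delta <- null_deltas(scores, n_null)
  threshold <- stats::quantile(null_delta, probs = 1 - error_rate,
                               names = FALSE, type = 7)

  idx <- cbind(seq_len(n_off), top$best_idx)
  df <- assignment_frame(scores, top)
  df$mean_log10_lik <- top$best
  df$second_log10_lik <- top$second
  df$delta <- delta
  df$mismatches <- scores$mismatches[idx]
  df$n_markers <- scores$n_used
  df$assigned <- !is.na(delta) & top$n_tied == 1L & delta > threshold
  df$sire[!df$assigned] <- NA_character_
  df$dam[!df$assigned] <- NA_character_
  df$method <- "likelihood"
  finish_assignment(df, "likelihood", threshold, scores)
}

# Gene-drop n_null pseudo-offspring from the per-marker allele frequencies
# (sire allele from the frequencies; dam genotype Hardy-Weinberg, transmitted
# through the polar-body-retention meiosis at the params' r), give them the
# missingness profile of randomly chosen real offspring, score them against
# the candidate parents and return their best-minus-runner-up deltas.
null_deltas <- function(scores, n_null) {
  enc <- scores$encoding
  markers <- scores$markers
  r <- scores$params$r
  codes <- matrix(0L, nrow = n_null, ncol = length(markers))
  for (j in seq_along(markers)) {
    tab <- enc$tabs[[markers[j]]]
    f <- scores$params$freqs[[markers[j]]]
    alleles <- names(f)
    sa <- sample(alleles, n_null, replace = TRUE, prob = f)
    d1 <- sample(alleles, n_null, replace = TRUE, prob = f)
    d2 <- sample(alleles, n_null, replace = TRUE, prob = f)
    het <- d1 != d2
    recomb <- stats::runif(n_null) < r
    keep1 <- stats::runif(n_null) < 0.5
    g1 <- ifelse(het & !recomb, ifelse(keep1, d1, d2), d1)
    g2 <- ifelse(het & !recomb, g1, d2)
    a <- pmin(g1, g2); b <- pmax(g1, g2)
    lo <- pmin(a, sa)
    hi <- pmax(b, sa)
    mid <- pmin(b, pmax(a, sa))
    codes[, j] <- match(paste(lo, mid, hi, sep = "/"), tab$off_genotypes)
  }
  profile <- sample(nrow(enc$off_codes), n_null, replace = TRUE)
  codes[enc$off_codes[profile, , drop = FALSE] == 0L] <- 0L
  res <- score_pairs_blas(codes, enc$sire_codes, enc$dam_codes,
                          enc$lik, enc$mm, want_mm = FALSE)
  mean_lik <- res$lik_sum / pmax(res$n_used, 1L)
  mean_lik[res$n_used == 0L, ] <- NA_real_
  top <- best2(mean_lik, minimize = FALSE)
  d <- top$best - top$second
  d[!is.na(d)]
}

#' Automated mismatch allowance for exclusion assignment
#'
#' Determines how many mismatches to tolerate from the unit-bin histogram of
#' per-offspring minimum mismatch counts: true-pair counts (a few genotyping
#' errors) cluster near zero while unrelated-pair minima cluster far higher,
#' so the allowance is the largest count before the first empty bin after the
#' low cluster. When the histogram has no such valley the allowance falls
#' back to the 99.9% quantile of `Binomial(n_markers, 2 * e)`, an upper bound
#' on the error-induced mismatch count of a true pair.
#'
#' @param min_mismatch_per_offspring integer vector of per-offspring minimum
#'   mismatch counts.
#' @param n_markers panel size (markers scored).
#' @param e error floor of the transmission tables (default 0.01).
#' @return Integer threshold.
#' @export
auto_mismatch_threshold <- function(min_mismatch_per_offspring, n_markers,
                                    e = 0.01) {
  m <- min_mismatch_per_offspring
  stopifnot(length(m) > 0, all(m >= 0))
  mx <- max(m)
  if (mx == 0L) return(0L)
  h <- tabulate(m + 1L, nbins = mx + 1L)    # bins for counts 0..mx
  first_occ <- which(h > 0L)[1L]
  gap <- which(h == 0L)
  gap <- gap[gap > first_occ]
  if (!length(gap)) {
    return(as.integer(stats::qbinom(0.999, n_markers, 2 * e)))
  }
  as.integer(gap[1L] - 2L)                  # count just below the empty bin
}

#' Exclusion-based parentage assignment
#'
#' Each offspring is assigned to the pair with the fewest mismatches when
#' that minimum does not exceed the allowance and the runner-up pair has
#' strictly more mismatches; ambiguous minima leave the offspring
#' unassigned. The allowance is either a fixed integer or `"auto"`
#' ([auto_mismatch_threshold()] on the per-offspring minima). Exclusion
#' counts treat recombination as always possible, so results do not depend
#' on the recombination-rate parameter.
#'
#' @param scores a [score_all_pairs()] result.
#' @param threshold `"auto"` (default) or a non-negative integer.
#' @return A data.frame as in [assign_likelihood()]; `delta` is the
#'   runner-up-minus-best mismatch gap.
#' @export
assign_exclusion <- function(scores, threshold = "auto") {
  stopifnot(inherits(scores, "score_matrix"))
  mm <- scores$mismatches
  storage.mode(mm) <- "double"
  mm[scores$n_used == 0L, ] <- NA_real_
  top <- best2(mm, minimize = TRUE)
  if (identical(threshold, "auto") || identical(threshold, "AUTO")) {
    ok <- !is.na(top$best)
    threshold <- auto_mismatch_threshold(as.integer(top$best[ok]),
                                         n_markers = length(scores$markers),
                                         e = scores$params$e)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)

  n_off <- length(scores$offspring_ids)
  idx <- cbind(seq_len(n_off), top$best_idx)
  df <- assignment_frame(scores, top)
  df$mean_log10_lik <- scores$mean_log10_lik[idx]
  df$second_log10_lik <- NA_real_
  df$delta <- top$second - top$best
  df$mismatches <- as.integer(top$best)
  df$n_markers <- scores$n_used
  df$assigned <- !is.na(top$best) & top$n_tied == 1L & top$best <= threshold
  df$sire[!df$assigned] <- NA_character_
  df$dam[!df$assigned] <- NA_character_
  df$method <- "exclusion"
  finish_assignment(df, "exclusion", threshold, scores)
}

#' Pool sire and dam candidates into one unsexed parent set
#'
#' @param sires,dams diploid [genotype_matrix()] objects with disjoint ids
#'   and shared markers.
#' @return A diploid [genotype_matrix()] of all parents.
#' @export
pool_parents <- function(sires, dams) {
  stopifnot(inherits(sires, "genotype_matrix"),
            inherits(dams, "genotype_matrix"),
            sires$ploidy == 2L, dams$ploidy == 2L)
  markers <- intersect(sires$markers, dams$markers)
  if (!length(markers)) stop("sires and dams share no markers")
  genotype_matrix(rbind(sires$calls[, markers, drop = FALSE],
                        dams$calls[, markers, drop = FALSE]),
                  ids = c(sires$ids, dams$ids), markers = markers,
                  ploidy = 2L)
}

#' Single-parent exclusion comparator (after Grashei et al. 2018)
#'
#' Assigns offspring to parents, not pairs, without using the parents' sex:
#' a parent is excluded at a marker only when the offspring genotype is
#' impossible with that parent whichever role (sire or dam) it takes, the
#' other parent being unknown -- the opposed-homozygote signal. Parents are
#' ranked per offspring by their exclusion proportion; the two top-ranked
#' parents are retained as the parental pair provided their proportions are
#' strictly below the threshold, taken as the lowest exclusion proportion
#' observed for a third-ranked parent across the whole offspring set. Dam and
#' sire roles are then oriented by dam-specific exclusions (genotypes
#' impossible for a dam but possible for a sire, e.g. a homozygous parent at
#' a marker where the triploid offspring carries one copy of that allele).
#'
#' @param offspring triploid [genotype_matrix()].
#' @param parents pooled diploid [genotype_matrix()] of at least 3
#'   candidates (see [pool_parents()]).
#' @return A data.frame with one row per offspring: retained pair (oriented
#'   when roles could be resolved), exclusion proportions, threshold,
#'   `n_retained` (0, 1 or 2 -- partial assignment allowed) and `assigned`
#'   (both parents retained).
#' @export
grashei_assign <- function(offspring, parents) {
  stopifnot(inherits(offspring, "genotype_matrix"), offspring$ploidy == 3L,
            inherits(parents, "genotype_matrix"), parents$ploidy == 2L)
  if (length(parents$ids) < 3L) {
    stop("the comparator needs at least 3 candidate parents ",
         "(threshold is set by the third-ranked parent)")
  }
  markers <- intersect(offspring$markers, parents$markers)
  if (!length(markers)) stop("no shared markers")
  off_sub <- offspring
  off_sub$calls <- off_sub$calls[, markers, drop = FALSE]
  off_sub$markers <- markers
  freqs <- suppressWarnings(allele_frequencies(off_sub))
  params <- table_params(freqs)
  markers <- markers[lengths(freqs) > 0L]
  extra <- observed_alleles(list(offspring, parents), markers)
  tabs <- build_marker_tables(params, markers, extra_alleles = extra)

  off_codes <- encode_against_tables(offspring, tabs, "off_genotypes")
  par_codes <- encode_against_tables(parents, tabs, "parent_genotypes")
  excl <- lapply(tabs, function(tb) {
    p_miss <- length(tb$parent_genotypes)
    as_sire <- tb$mismatch[, , p_miss] >= 1L   # excluded with dam unknown
    as_dam <- tb$mismatch[, p_miss, ] >= 1L    # excluded with sire unknown
    m <- (as_sire & as_dam) * 1L
    storage.mode(m) <- "integer"
    m
  })
  damspec <- lapply(tabs, function(tb) {
    p_miss <- length(tb$parent_genotypes)
    m <- (tb$mismatch[, p_miss, ] >= 1L & tb$mismatch[, , p_miss] == 0L) * 1L
    storage.mode(m) <- "integer"
    m
  })
  miss_code <- vapply(tabs, function(tb) length(tb$parent_genotypes),
                      integer(1))
  cnt <- single_parent_counts_cpp(off_codes, par_codes, excl, damspec,
                                  miss_code)
  prop <- cnt$n_excl / pmax(cnt$n_compared, 1L)
  prop[cnt$n_compared == 0L] <- Inf

  n_off <- length(offspring$ids)
  ord <- t(apply(prop, 1L, order))            # per offspring, ascending
  third <- prop[cbind(seq_len(n_off), ord[, 3L])]
  tau <- min(third)

  p1 <- ord[, 1L]; p2 <- ord[, 2L]
  v1 <- prop[cbind(seq_len(n_off), p1)]
  v2 <- prop[cbind(seq_len(n_off), p2)]
  # second-ranked parent ambiguous when tied with the third-ranked value
  ambiguous2 <- v2 == third
  keep1 <- v1 < tau
  keep2 <- v2 < tau & !ambiguous2
  n_retained <- keep1 + (keep1 & keep2)

  ds1 <- cnt$n_damspec[cbind(seq_len(n_off), p1)]
  ds2 <- cnt$n_damspec[cbind(seq_len(n_off), p2)]
  # the parent with dam-specific exclusions cannot be the dam
  roles_resolved <- ds1 != ds2
  first_is_sire <- ds1 > ds2

  sire <- ifelse(first_is_sire, parents$ids[p1], parents$ids[p2])
  dam <- ifelse(first_is_sire, parents$ids[p2], parents$ids[p1])
  assigned <- keep1 & keep2
  sire[!assigned] <- NA_character_
  dam[!assigned] <- NA_character_

  df <- data.frame(
    offspring = offspring$ids,
    sire = sire,
    dam = dam,
    partial_parent = ifelse(!assigned & keep1, parents$ids[p1],
                            NA_character_),
    excl_prop_best = v1,
    excl_prop_second = v2,
    n_retained = as.integer(n_retained),
    roles_resolved = roles_resolved & assigned,
    assigned = assigned,
    method = "grashei",
    stringsAsFactors = FALSE
  )
  attr(df, "method") <- "grashei"
  attr(df, "threshold") <- tau
  attr(df, "candidate_parents") <- parents$ids
  df
}
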