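## Assignment-quality metrics and replicated experimental grids.

#' Evaluate assignments against a known pedigree
#'
#' An offspring is a positive when both of its true parents are in the
#' candidate set, and a negative otherwise (e.g. when a true parent was
#' masked). True positives are offspring assigned to exactly their true
#' pair; any other accepted pair is a false positive (assigning a pair that
#' contains just one true parent counts as false); true negatives are
#' negatives left unassigned.
#'
#' @param assignments data.frame from [assign_likelihood()],
#'   [assign_exclusion()] or [grashei_assign()] (candidate sets travel as
#'   attributes; the comparator's pairs are compared without parent order
#'   since it does not use sex information).
#' @param truth data.frame with columns `offspring`, `sire`, `dam`.
#' @param candidate_sires,candidate_dams optional candidate id vectors
#'   overriding the attributes.
#' @return One-row data.frame: `sensitivity` (= TP / positives), `fdr`
#'   (= FP / (TP + FP)), `specificity` (= TN / negatives) -- `NA` when a
#'   denominator is zero -- and the underlying counts.
#' @export
evaluate_assignments <- function(assignments, truth,
                                 candidate_sires = NULL,
                                 candidate_dams = NULL) {
  stopifnot(all(c("offspring", "sire", "dam", "assigned") %in%
                  names(assignments)),
            all(c("offspring", "sire", "dam") %in% names(truth)))
  i <- match(assignments$offspring, truth$offspring)
  if (anyNA(i)) {
    stop("offspring not in the truth pedigree: ",
         paste(assignments$offspring[is.na(i)], collapse = ", "))
  }
  true_sire <- truth$sire[i]
  true_dam <- truth$dam[i]

  pooled <- attr(assignments, "candidate_parents")
  if (is.null(candidate_sires)) {
    candidate_sires <- attr(assignments, "candidate_sires") %||% pooled
  }
  if (is.null(candidate_dams)) {
    candidate_dams <- attr(assignments, "candidate_dams") %||% pooled
  }
  if (is.null(candidate_sires) || is.null(candidate_dams)) {
    stop("candidate parent sets are required (attributes or arguments)")
  }
  positive <- true_sire %in% candidate_sires & true_dam %in% candidate_dams

  unordered <- identical(attr(assignments, "method"), "grashei")
  asg <- assignments$assigned
  correct <- if (unordered) {
    (assignments$sire == true_sire & assignments$dam == true_dam) |
      (assignments$sire == true_dam & assignments$dam == true_sire)
  } else {
    assignments$sire == true_sire & assignments$dam == true_dam
  }
  correct[is.na(correct)] <- FALSE

  tp <- sum(asg & correct)
  fp <- sum(asg & !correct)
  tn <- sum(!positive & !asg)
  pos <- sum(positive)
  neg <- sum(!positive)
  data.frame(
    sensitivity = if (pos > 0) tp / pos else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
    specificity = if (neg > 0) tn / neg else NA_real_,
    tp = tp, fp = fp, tn = tn,
    positives = pos, negatives = neg,
    n_assigned = sum(asg)
  )
}

#' Rank markers by call rate and minor allele frequency
#'
#' Deterministic "best markers" ordering: descending call rate, then
#' descending MAF in the population, ties broken by marker name.
#'
#' @param x a [genotype_matrix()] (conventionally the offspring).
#' @return Character vector of marker names, best first, with a `stats`
#'   attribute holding the per-marker call rate and MAF.
#' @export
rank_markers <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  cr <- call_rates(x)
  freqs <- suppressWarnings(allele_frequencies(x))
  maf <- vapply(freqs, function(f) {
    if (!length(f)) 0 else 1 - max(f)
  }, numeric(1))
  ord <- order(-cr, -maf, x$markers)
  out <- x$markers[ord]
  attr(out, "stats") <- data.frame(marker = x$markers, call_rate = cr,
                                   maf = maf, row.names = NULL)[ord, ]
  out
}

#' Run a replicated assignment experiment grid
#'
#' Simulates populations and assigns them across a grid of marker counts,
#' missing-parent fractions, methods, recombination-rate parameter values
#' and replicates, returning one tidy row of metrics per combination. Within
#' a replicate the largest marker panel is simulated once and nested subsets
#' are used for the smaller counts (markers are independent, so the first
#' `n` are an unbiased subset). The recombination sweep (`r_assign`) applies
#' to the likelihood method only; exclusion does not use `r`.
#'
#' @param n_sires,n_dams,n_offspring population sizes.
#' @param n_markers integer vector of marker-panel sizes.
#' @param maf MAF specification as in [sim_config()].
#' @param design mating design as in [sim_config()].
#' @param r_true numeric vector of generating recombination rates (one
#'   population per value).
#' @param r_assign numeric vector of recombination-rate parameter values for
#'   the likelihood tables.
#' @param error_rate simulated per-copy genotyping error rate.
#' @param parent_fraction numeric vector of fractions of parents kept.
#' @param methods subset of `c("exclusion", "likelihood", "grashei")`.
#' @param replicates number of replicates; replicate `k` of each population
#'   is seeded with `seed + k`.
#' @param error_rate_tolerated tolerated assignment error rate for the
#'   likelihood threshold.
#' @param mismatch_threshold `"auto"` or integer, for exclusion.
#' @param e error floor of the likelihood tables.
#' @param seed base seed.
#' @return data.frame with one row per
#'   (method, r_assign, n_markers, parent_fraction, r_true, replicate).
#' @export
run_experiment <- function(n_sires = 100L, n_dams = 100L,
                           n_offspring = 1000L, n_markers = 100L,
                           maf = 0.5, design = "full_factorial",
                           r_true = 0.5, r_assign = 0.5, error_rate = 0.01,
                           parent_fraction = 1, methods = "exclusion",
                           replicates = 1L, error_rate_tolerated = 0.05,
                           mismatch_threshold = "auto", e = 0.01, seed = 1L) {
  methods <- match.arg(methods, c("exclusion", "likelihood", "grashei"),
                       several.ok = TRUE)
  rows <- list()
  for (rt_i in seq_along(r_true)) {
    for (rep_i in seq_len(replicates)) {
      cfg <- sim_config(n_sires = n_sires, n_dams = n_dams, design = design,
                        n_offspring = n_offspring,
                        n_markers = max(n_markers), maf = maf,
                        r_true = r_true[rt_i], error_rate = error_rate,
                        seed = seed + 1000L * (rt_i - 1L) + rep_i)
      ds <- simulate_dataset(cfg)
      for (nm in sort(n_markers)) {
        mk <- ds$offspring$markers[seq_len(nm)]
        off <- subset_markers(ds$offspring, mk)
        sires_full <- subset_markers(ds$sires, mk)
        dams_full <- subset_markers(ds$dams, mk)
        freqs <- suppressWarnings(allele_frequencies(off))
        for (pf in parent_fraction) {
          sires <- mask_parents(sires_full, pf)$parents
          dams <- mask_parents(dams_full, pf)$parents
          for (method in methods) {
            if (method == "grashei") {
              asg <- grashei_assign(off, pool_parents(sires, dams))
              met <- evaluate_assignments(asg, ds$truth)
              rows[[length(rows) + 1L]] <- cbind(
                data.frame(method = method, r_assign = NA_real_,
                           n_markers = nm, parent_fraction = pf,
                           r_true = r_true[rt_i], replicate = rep_i,
                           threshold = attr(asg, "threshold")), met)
              next
            }
            r_vals <- if (method == "likelihood") r_assign else NA_real_
            for (ra in r_vals) {
              params <- table_params(freqs,
                                     r = if (is.na(ra)) 0.5 else ra, e = e)
              sc <- score_all_pairs(off, sires, dams, params)
              asg <- if (method == "likelihood") {
                assign_likelihood(sc, error_rate = error_rate_tolerated)
              } else {
                assign_exclusion(sc, threshold = mismatch_threshold)
              }
              met <- evaluate_assignments(asg, ds$truth)
              rows[[length(rows) + 1L]] <- cbind(
                data.frame(method = method, r_assign = ra, n_markers = nm,
                           parent_fraction = pf, r_true = r_true[rt_i],
                           replicate = rep_i,
                           threshold = attr(asg, "threshold")), met)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restrict a genotype matrix to a marker subset
#'
#' @param x a [genotype_matrix()].
#' @param markers marker names to keep (order preserved as given).
#' @return A [genotype_matrix()].
#' @export
subset_markers <- function(x, markers) {
  stopifnot(inherits(x, "genotype_matrix"), all(markers %in% x$markers))
  genotype_matrix(x$calls[, markers, drop = FALSE], ids = x$ids,
                  markers = markers, ploidy = x$ploidy)
}
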