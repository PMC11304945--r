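## Breeding-design simulator: diploid parents under Hardy-Weinberg, triploid
## offspring produced by the polar-body-retention meiosis, genotyping error
## injection and parent masking.

#' Simulation configuration
#'
#' @param n_sires,n_dams numbers of candidate parents.
#' @param design `"full_factorial"` / `"random_pairs"` (every offspring draws
#'   a sire and dam uniformly, so any of the `n_sires * n_dams` families can
#'   occur), or a data.frame of allowed crosses with columns `sire`, `dam`
#'   and optional weight `n` (partial factorial).
#' @param n_offspring total number of offspring.
#' @param n_markers number of biallelic markers.
#' @param maf minor allele frequency: a single fixed value, or a length-2
#'   range from which per-marker MAFs are drawn uniformly.
#' @param r_true marker-centromere recombination rate used to generate dam
#'   gametes.
#' @param error_rate per-allele-copy genotyping error probability in the
#'   offspring (each hit is replaced by a uniform draw from the marker's two
#'   alleles, so half of the events are silent).
#' @param missing_parent_fraction fraction of parents (per sex) removed from
#'   the candidate set after simulation.
#' @param seed optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 100L, n_dams = 100L,
                       design = "full_factorial", n_offspring = 1000L,
                       n_markers = 100L, maf = 0.5, r_true = 0.5,
                       error_rate = 0.01, missing_parent_fraction = 0,
                       seed = NULL) {
  stopifnot(n_sires >= 1L, n_dams >= 1L, n_offspring >= 1L, n_markers >= 1L,
            all(maf >= 0), all(maf <= 0.5), length(maf) %in% 1:2,
            r_true >= 0, r_true <= 1, error_rate >= 0, error_rate <= 1,
            missing_parent_fraction >= 0, missing_parent_fraction <= 1)
  if (is.data.frame(design)) {
    stopifnot(all(c("sire", "dam") %in% names(design)))
  } else {
    design <- match.arg(design, c("full_factorial", "random_pairs"))
  }
  structure(list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 design = design, n_offspring = as.integer(n_offspring),
                 n_markers = as.integer(n_markers), maf = maf,
                 r_true = r_true, error_rate = error_rate,
                 missing_parent_fraction = missing_parent_fraction,
                 seed = seed),
            class = "sim_config")
}

draw_mafs <- function(n_markers, maf) {
  if (length(maf) == 2L && maf[1L] != maf[2L]) {
    stats::runif(n_markers, min(maf), max(maf))
  } else {
    rep(maf[1L], n_markers)
  }
}

#' Simulate diploid parents under Hardy-Weinberg equilibrium
#'
#' Each allele copy is drawn independently: token `"B"` (the minor allele)
#' with the marker's MAF, `"A"` otherwise.
#'
#' @param n number of parents.
#' @param mafs numeric vector of per-marker minor allele frequencies.
#' @param ids individual identifiers (default `P1..Pn`).
#' @param markers marker names (default `M1..`).
#' @return A diploid [genotype_matrix()].
#' @export
simulate_parents <- function(n, mafs, ids = paste0("P", seq_len(n)),
                             markers = paste0("M", seq_along(mafs))) {
  stopifnot(n >= 1L, all(mafs >= 0), all(mafs <= 1))
  m <- length(mafs)
  draw <- function() {
    b <- stats::runif(n * m) < rep(mafs, each = n)
    matrix(ifelse(b, "B", "A"), nrow = n)
  }
  a1 <- draw(); a2 <- draw()
  calls <- matrix(paste(pmin(a1, a2), pmax(a1, a2), sep = "/"), nrow = n,
                  dimnames = list(ids, markers))
  genotype_matrix(calls, ids = ids, markers = markers, ploidy = 2L)
}

resolve_crosses <- function(cfg, sire_ids, dam_ids) {
  n <- cfg$n_offspring
  if (is.data.frame(cfg$design)) {
    w <- if ("n" %in% names(cfg$design)) cfg$design$n else
      rep(1, nrow(cfg$design))
    rows <- sample(nrow(cfg$design), n, replace = TRUE, prob = w)
    data.frame(sire = as.character(cfg$design$sire[rows]),
               dam = as.character(cfg$design$dam[rows]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sire = sample(sire_ids, n, replace = TRUE),
               dam = sample(dam_ids, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
}

#' Simulate triploid offspring from diploid parents
#'
#' At each marker every offspring receives one sire allele (each of the two
#' with probability 0.5) and a dam gamete of two alleles: a heterozygous dam
#' transmits both of her alleles when a crossover occurred between the
#' centromere and the marker (probability `r_true`), otherwise a doubled
#' allele (each with probability 0.5); a homozygous dam always transmits her
#' doubled allele. Genotyping error is not applied here (see
#' [inject_errors()]).
#'
#' @param sires,dams diploid [genotype_matrix()] objects.
#' @param crosses data.frame with one row per offspring: columns `sire`,
#'   `dam` (parent ids).
#' @param r_true marker-centromere recombination rate.
#' @param ids offspring identifiers (default `T1..`).
#' @return A list: `offspring` (triploid [genotype_matrix()]) and `truth`
#'   (data.frame `offspring`, `sire`, `dam`).
#' @export
simulate_offspring <- function(sires, dams, crosses, r_true = 0.5,
                               ids = paste0("T", seq_len(nrow(crosses)))) {
  stopifnot(inherits(sires, "genotype_matrix"), sires$ploidy == 2L,
            inherits(dams, "genotype_matrix"), dams$ploidy == 2L,
            r_true >= 0, r_true <= 1,
            all(c("sire", "dam") %in% names(crosses)))
  si <- match(crosses$sire, sires$ids)
  di <- match(crosses$dam, dams$ids)
  if (anyNA(si) || anyNA(di)) {
    bad <- unique(c(crosses$sire[is.na(si)], crosses$dam[is.na(di)]))
    stop("cross references unknown parent(s): ", paste(bad, collapse = ", "))
  }
  markers <- intersect(sires$markers, dams$markers)
  ssp <- split_calls(sires)
  dsp <- split_calls(dams)
  n <- nrow(crosses)
  m <- length(markers)
  sa1 <- ssp[[1L]][si, markers, drop = FALSE]
  sa2 <- ssp[[2L]][si, markers, drop = FALSE]
  da1 <- dsp[[1L]][di, markers, drop = FALSE]
  da2 <- dsp[[2L]][di, markers, drop = FALSE]

  pick <- matrix(stats::runif(n * m) < 0.5, nrow = n)
  pat <- ifelse(pick, sa1, sa2)                     # paternal allele
  het <- da1 != da2
  recomb <- matrix(stats::runif(n * m) < r_true, nrow = n)
  keep1 <- matrix(stats::runif(n * m) < 0.5, nrow = n)
  g1 <- ifelse(het & !recomb, ifelse(keep1, da1, da2), da1)
  g2 <- ifelse(het & !recomb, g1, da2)              # maternal gamete (2)

  a <- pmin(g1, g2); b <- pmax(g1, g2)
  lo <- pmin(a, pat); hi <- pmax(b, pat)
  mid <- pmin(b, pmax(a, pat))
  calls <- matrix(paste(lo, mid, hi, sep = "/"), nrow = n,
                  dimnames = list(ids, markers))
  calls[is.na(pat) | is.na(g1) | is.na(g2)] <- NA_character_
  off <- genotype_matrix(calls, ids = ids, markers = markers, ploidy = 3L)
  list(offspring = off,
       truth = data.frame(offspring = ids, sire = crosses$sire,
                          dam = crosses$dam, stringsAsFactors = FALSE))
}

#' Inject genotyping errors
#'
#' Each allele copy is independently replaced, with probability
#' `error_rate`, by a uniform draw from the marker's allele set (default the
#' biallelic `{A, B}`) -- so about half of the error events leave the
#' genotype unchanged.
#'
#' @param x a [genotype_matrix()].
#' @param error_rate per-copy error probability in `[0, 1]`.
#' @param alleles tokens the erroneous reading is drawn from.
#' @return A [genotype_matrix()] with errors applied; missing calls stay
#'   missing.
#' @export
inject_errors <- function(x, error_rate, alleles = c("A", "B")) {
  stopifnot(inherits(x, "genotype_matrix"), error_rate >= 0, error_rate <= 1)
  if (error_rate == 0) return(x)
  sp <- split_calls(x)
  flat <- lapply(sp, as.vector)
  for (k in seq_along(flat)) {
    hit <- stats::runif(length(flat[[k]])) < error_rate & !is.na(flat[[k]])
    flat[[k]][hit] <- sample(alleles, sum(hit), replace = TRUE)
  }
  joined <- if (x$ploidy == 2L) {
    paste(pmin(flat[[1L]], flat[[2L]]), pmax(flat[[1L]], flat[[2L]]),
          sep = "/")
  } else {
    a <- pmin(flat[[1L]], flat[[2L]]); b <- pmax(flat[[1L]], flat[[2L]])
    lo <- pmin(a, flat[[3L]]); hi <- pmax(b, flat[[3L]])
    paste(lo, pmin(b, pmax(a, flat[[3L]])), hi, sep = "/")
  }
  calls <- matrix(joined, nrow = nrow(x$calls), dimnames = dimnames(x$calls))
  calls[is.na(x$calls)] <- NA_character_
  genotype_matrix(calls, ids = x$ids, markers = x$markers, ploidy = x$ploidy)
}

#' Mask a fraction of parents from the candidate set
#'
#' Keeps a uniformly sampled `floor(fraction * n)` of the parents and
#' records the rest as masked (their offspring become negatives in the
#' evaluation). Call once per sex.
#'
#' @param parents a diploid [genotype_matrix()].
#' @param fraction fraction of parents to keep, in `[0, 1]`.
#' @return A list: `parents` (kept subset) and `masked_ids`.
#' @export
mask_parents <- function(parents, fraction) {
  stopifnot(inherits(parents, "genotype_matrix"), fraction >= 0,
            fraction <= 1)
  n <- length(parents$ids)
  n_keep <- floor(fraction * n)
  keep <- sort(sample(n, n_keep))
  kept <- genotype_matrix(parents$calls[keep, , drop = FALSE],
                          ids = parents$ids[keep],
                          markers = parents$markers, ploidy = 2L)
  list(parents = kept, masked_ids = parents$ids[-keep])
}

#' Simulate a complete dataset
#'
#' Draws marker MAFs, parents, matings, triploid offspring, genotyping
#' errors and parent masking from a [sim_config()].
#'
#' @param cfg a [sim_config()].
#' @return A list: `sires`, `dams` (candidate sets after masking),
#'   `offspring`, `truth`, `masked_sires`, `masked_dams`, `mafs`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mafs <- draw_mafs(cfg$n_markers, cfg$maf)
  markers <- paste0("M", seq_len(cfg$n_markers))
  sires <- simulate_parents(cfg$n_sires, mafs,
                            ids = sprintf("S%03d", seq_len(cfg$n_sires)),
                            markers = markers)
  dams <- simulate_parents(cfg$n_dams, mafs,
                           ids = sprintf("D%03d", seq_len(cfg$n_dams)),
                           markers = markers)
  crosses <- resolve_crosses(cfg, sires$ids, dams$ids)
  sim <- simulate_offspring(sires, dams, crosses, r_true = cfg$r_true)
  off <- inject_errors(sim$offspring, cfg$error_rate)
  keep <- 1 - cfg$missing_parent_fraction
  ms <- mask_parents(sires, keep)
  md <- mask_parents(dams, keep)
  list(sires = ms$parents, dams = md$parents, offspring = off,
       truth = sim$truth, masked_sires = ms$masked_ids,
       masked_dams = md$masked_ids, mafs = mafs, cfg = cfg)
}
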