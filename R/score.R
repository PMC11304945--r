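## Vectorised pair scoring: genotypes are encoded once per marker as integer
## indices into the materialised lookup tables of build_marker_tables(), and
## a compiled kernel sums log10 transmission probabilities and mismatch
## counts over markers for every offspring x (sire, dam) combination.

split_calls <- function(gm) {
  p <- gm$ploidy
  flat <- as.vector(gm$calls)
  flat[is.na(flat)] <- paste(rep(NA_character_, p), collapse = "/")
  tok <- matrix(unlist(strsplit(flat, "/", fixed = TRUE),
                       use.names = FALSE), nrow = p)
  tok[tok == "NA"] <- NA_character_
  lapply(seq_len(p), function(k) {
    m <- matrix(tok[k, ], nrow = nrow(gm$calls))
    dimnames(m) <- dimnames(gm$calls)
    m
  })
}

observed_alleles <- function(mats, markers) {
  out <- lapply(markers, function(mk) {
    tok <- unlist(lapply(mats, function(gm) {
      col <- gm$calls[, mk]
      unique(col[!is.na(col)])
    }))
    sort(unique(unlist(strsplit(tok, "/", fixed = TRUE))))
  })
  names(out) <- markers
  out
}

encode_against_tables <- function(gm, tabs, genotype_slot) {
  markers <- names(tabs)
  codes <- matrix(0L, nrow = length(gm$ids), ncol = length(markers),
                  dimnames = list(gm$ids, markers))
  for (mk in markers) {
    g <- tabs[[mk]][[genotype_slot]]
    col <- match(gm$calls[, mk], g)
    if (genotype_slot == "parent_genotypes") {
      col[is.na(col)] <- length(g)  # Missing class is the last entry
    } else {
      col[is.na(col)] <- 0L         # offspring missing: marker skipped
    }
    codes[, mk] <- col
  }
  codes
}

#' Score every offspring against all sire x dam candidate pairs
#'
#' For each offspring and each candidate pair, sums per-marker `log10`
#' Mendelian transmission probabilities ([triploid_likelihood()]) and
#' exclusion mismatch counts ([triploid_mismatches()]) over the markers where
#' the offspring call is non-missing; parent missing calls use the tables'
#' Missing row/column. Scoring is table-indexed, so a 1,000-offspring x
#' 100 x 100 factorial at a few hundred markers completes in seconds.
#'
#' @param offspring triploid [genotype_matrix()].
#' @param sires,dams diploid [genotype_matrix()] objects of candidate parents.
#' @param params a [table_params()]; defaults to offspring-population allele
#'   frequencies with `r = 0.5`, `e = 0.01`.
#' @return An object of class `score_matrix`: mean log10 likelihood and
#'   summed mismatch count per offspring x pair (pair index runs sire-fastest:
#'   `pair = (dam_index - 1) * n_sires + sire_index`), plus `n_used`, the
#'   number of markers scored per offspring.
#' @export
score_all_pairs <- function(offspring, sires, dams,
                            params = table_params(
                              allele_frequencies(offspring))) {
  stopifnot(inherits(offspring, "genotype_matrix"), offspring$ploidy == 3L,
            inherits(sires, "genotype_matrix"), sires$ploidy == 2L,
            inherits(dams, "genotype_matrix"), dams$ploidy == 2L,
            inherits(params, "table_params"))
  markers <- Reduce(intersect, list(offspring$markers, sires$markers,
                                    dams$markers, names(params$freqs)))
  markers <- markers[lengths(params$freqs[markers]) > 0L]
  if (!length(markers)) stop("no shared markers with allele frequencies")

  extra <- observed_alleles(list(offspring, sires, dams), markers)
  tabs <- build_marker_tables(params, markers, extra_alleles = extra)

  off_codes <- encode_against_tables(offspring, tabs, "off_genotypes")
  sire_codes <- encode_against_tables(sires, tabs, "parent_genotypes")
  dam_codes <- encode_against_tables(dams, tabs, "parent_genotypes")
  # transmission probabilities of exactly zero can only arise at the r = 0/1
  # boundaries; floor their log10 so pair sums stay finite (such pairs still
  # rank far below any compatible pair)
  lik <- lapply(tabs, function(tb) {
    a <- tb$log10_lik
    a[!is.finite(a)] <- -400
    a
  })
  mm <- lapply(tabs, `[[`, "mismatch")

  res <- score_pairs_blas(off_codes, sire_codes, dam_codes, lik, mm,
                          want_mm = TRUE)
  n_used <- res$n_used
  if (any(n_used == 0L)) {
    warning("offspring with no usable markers (unassignable): ",
            paste(offspring$ids[n_used == 0L], collapse = ", "))
  }
  mean_lik <- res$lik_sum / pmax(n_used, 1L)
  mean_lik[n_used == 0L, ] <- NA_real_
  structure(list(
    offspring_ids = offspring$ids,
    sire_ids = sires$ids,
    dam_ids = dams$ids,
    mean_log10_lik = mean_lik,
    mismatches = res$mm_sum,
    n_used = n_used,
    markers = markers,
    params = params,
    encoding = list(tabs = tabs, off_codes = off_codes,
                    sire_codes = sire_codes, dam_codes = dam_codes,
                    lik = lik, mm = mm)
  ), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix: ", length(x$offspring_ids), " offspring x ",
      length(x$sire_ids), " sires x ", length(x$dam_ids), " dams, ",
      length(x$markers), " markers (r = ", x$params$r,
      ", e = ", x$params$e, ")\n", sep = "")
  invisible(x)
}

pair_sire <- function(scores, pair_idx) {
  scores$sire_ids[(pair_idx - 1L) %% length(scores$sire_ids) + 1L]
}

pair_dam <- function(scores, pair_idx) {
  scores$dam_ids[(pair_idx - 1L) %/% length(scores$sire_ids) + 1L]
}
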