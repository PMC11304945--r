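# Independent marginalisation oracle: probability of a triploid offspring
# call given sire/dam calls, with NULL parents summed out under
# Hardy-Weinberg at the supplied allele frequencies. Built on enumeration
# only (meiosis_oracle), never on the table formulas it checks.

hw_diploid_genotypes <- function(freqs) {
  al <- names(freqs)
  k <- length(al)
  out <- list()
  for (i in seq_len(k)) for (j in i:k) {
    p <- if (i == j) freqs[[i]]^2 else 2 * freqs[[i]] * freqs[[j]]
    out[[length(out) + 1L]] <- list(call = paste(sort(c(al[i], al[j])),
                                                 collapse = "/"), p = p)
  }
  out
}

oracle_prob <- function(off_call, sire_call, dam_call, freqs, r) {
  sires <- if (is.null(sire_call)) hw_diploid_genotypes(freqs) else
    list(list(call = sire_call, p = 1))
  dams <- if (is.null(dam_call)) hw_diploid_genotypes(freqs) else
    list(list(call = dam_call, p = 1))
  key <- paste(sort(strsplit(off_call, "/", fixed = TRUE)[[1L]]),
               collapse = "/")
  total <- 0
  for (s in sires) for (d in dams) {
    dist <- meiosis_oracle(s$call, d$call, r)
    if (key %in% names(dist)) total <- total + s$p * d$p * dist[[key]]
  }
  total
}

# all triploid multisets over an allele set
all_trio_calls <- function(alleles) {
  out <- character(0)
  k <- length(alleles)
  for (i in seq_len(k)) for (j in i:k) for (l in j:k) {
    out <- c(out, paste(alleles[c(i, j, l)], collapse = "/"))
  }
  out
}

all_pair_calls <- function(alleles) {
  out <- character(0)
  k <- length(alleles)
  for (i in seq_len(k)) for (j in i:k) {
    out <- c(out, paste(alleles[c(i, j)], collapse = "/"))
  }
  out
}

# tiny genotype matrix from a named list of call vectors
gm <- function(calls_by_id, markers, ploidy) {
  m <- do.call(rbind, calls_by_id)
  colnames(m) <- markers
  genotype_matrix(m, ids = names(calls_by_id), markers = markers,
                  ploidy = ploidy)
}
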