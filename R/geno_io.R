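#' Build a genotype matrix
#'
#' Container for diploid or triploid genotypes at co-dominant markers (SNPs or
#' microsatellites). A call is an unordered multiset of `ploidy` allele tokens,
#' stored canonically as the tokens sorted and joined by `"/"`; a missing call
#' is `NA`. A call in which any single allele is missing is treated as fully
#' missing (conservative: a partially observed triploid call cannot be placed
#' in the transmission tables).
#'
#' @param calls character matrix (individuals x markers) of `"a/b"` or
#'   `"a/b/c"` calls; `NA` or `"NA/NA"`-style entries are missing.
#' @param ids character vector of individual identifiers (unique).
#' @param markers character vector of marker names (unique).
#' @param ploidy 2 (parents) or 3 (offspring).
#' @return An object of class `genotype_matrix`: a list with elements `ids`,
#'   `markers`, `ploidy` and `calls` (canonicalised character matrix).
#' @export
genotype_matrix <- function(calls, ids = rownames(calls),
                            markers = colnames(calls), ploidy) {
  stopifnot(ploidy %in% c(2L, 3L))
  calls <- as.matrix(calls)
  if (is.null(ids)) stop("individual ids are required")
  if (is.null(markers)) stop("marker names are required")
  ids <- as.character(ids)
  markers <- as.character(markers)
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(markers)) stop("duplicate marker names")
  if (nrow(calls) != length(ids) || ncol(calls) != length(markers)) {
    stop("calls must be a ", length(ids), " x ", length(markers), " matrix")
  }
  storage.mode(calls) <- "character"
  canon <- canonicalise_calls(calls, ploidy)
  dimnames(canon) <- list(ids, markers)
  structure(list(ids = ids, markers = markers, ploidy = as.integer(ploidy),
                 calls = canon),
            class = "genotype_matrix")
}

# Sort tokens within each call and normalise missing to NA. Errors name the
# offending individual/marker.
canonicalise_calls <- function(calls, ploidy) {
  out <- calls
  flat <- as.vector(calls)
  miss <- is.na(flat) | flat == "" | flat == "NA"
  uniq <- unique(flat[!miss])
  if (length(uniq)) {
    parts <- strsplit(uniq, "/", fixed = TRUE)
    canon <- vapply(seq_along(uniq), function(k) {
      tok <- parts[[k]]
      if (any(tok == "NA")) return(NA_character_)  # partial missing -> missing
      if (length(tok) != ploidy || any(tok == "")) {
        bad <- which(calls == uniq[k], arr.ind = TRUE)[1L, ]
        stop("malformed call '", uniq[k], "' (expected ", ploidy,
             " alleles) for individual ", rownames(calls)[bad[1L]] %||% bad[1L],
             ", marker ", colnames(calls)[bad[2L]] %||% bad[2L])
      }
      paste(sort(tok), collapse = "/")
    }, character(1))
    out[] <- canon[match(flat, uniq)]
  } else {
    out[] <- NA_character_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$ids), " individuals x ",
      length(x$markers), " markers, ploidy ", x$ploidy, "\n", sep = "")
  cr <- mean(!is.na(x$calls))
  cat(sprintf("overall call rate: %.3f\n", cr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read genotypes from a tab-separated file
#'
#' Dialect: a header line `id<TAB>marker1<TAB>...`, one row per individual,
#' calls written as allele tokens joined by `"/"` (e.g. `A/B/B`), missing as
#' `NA` repeated to the ploidy (`NA/NA/NA`). Lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @param ploidy expected ploidy (2 or 3); rows whose calls have a different
#'   number of alleles raise a parse error.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, ploidy) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (ncol(df) < 2L) stop("genotype file needs an id column and >=1 marker")
  calls <- as.matrix(df[, -1L, drop = FALSE])
  rownames(calls) <- df[[1L]]
  genotype_matrix(calls, ids = df[[1L]], markers = colnames(df)[-1L],
                  ploidy = ploidy)
}

#' Write genotypes to the tab-separated dialect
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param header_comments optional character vector written as `#`-prefixed
#'   lines before the header (provenance: config, seed, version).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, header_comments = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  out <- x$calls
  out[is.na(out)] <- paste(rep("NA", x$ploidy), collapse = "/")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  writeLines(paste(c("id", x$markers), collapse = "\t"), con)
  writeLines(paste(x$ids, apply(out, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Estimate per-marker allele frequencies
#'
#' Counts allele copies over non-missing calls at each marker and divides by
#' the total number of copies. By convention frequencies are computed in the
#' offspring population to be assigned; parent-based frequencies can be
#' obtained by simply passing a parent matrix instead (useful for sensitivity
#' analyses).
#'
#' @param x a [genotype_matrix()].
#' @return Named list, one element per marker: a named numeric vector of
#'   allele frequencies summing to 1. Markers with all calls missing yield an
#'   empty vector, with a warning.
#' @export
allele_frequencies <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  out <- lapply(seq_along(x$markers), function(j) {
    col <- x$calls[, j]
    col <- col[!is.na(col)]
    if (!length(col)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(unlist(strsplit(col, "/", fixed = TRUE)))
    f <- as.numeric(tab) / sum(tab)
    stats::setNames(f, names(tab))
  })
  names(out) <- x$markers
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning("all calls missing at marker(s): ",
            paste(x$markers[empty], collapse = ", "))
  }
  out
}

#' Per-marker call rate
#'
#' Fraction of individuals with a non-missing call at each marker.
#'
#' @param x a [genotype_matrix()].
#' @return Named numeric vector.
#' @export
call_rates <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  stats::setNames(colMeans(!is.na(x$calls)), x$markers)
}

#' Classify a genotype call into its canonical pattern
#'
#' Diploid calls classify as `AA` or `AB`; triploid calls as `AAA`
#' (three identical alleles), `ABB` (a singleton plus a duplicated allele:
#' the singleton maps to pattern letter A, the duplicated allele to B), or
#' `ABC` (three distinct alleles, assigned to letters A, B, C in lexicographic
#' token order). The `role_map` records which concrete allele token plays each
#' pattern letter; classification is invariant to the order of alleles within
#' the call.
#'
#' @param call allele tokens: a character vector of length `ploidy`, or a
#'   single `"a/b/c"` string; `NA` for missing.
#' @param ploidy 2 or 3.
#' @return A list with `pattern` (one of `"AA"`, `"AB"`, `"AAA"`, `"ABB"`,
#'   `"ABC"`, `"MISSING"`) and `role_map` (named character vector,
#'   pattern letter -> allele token).
#' @export
classify_genotype <- function(call, ploidy) {
  stopifnot(ploidy %in% c(2L, 3L))
  if (length(call) == 1L && !is.na(call) && grepl("/", call, fixed = TRUE)) {
    call <- strsplit(call, "/", fixed = TRUE)[[1L]]
  }
  if (all(is.na(call)) || any(call == "NA")) {
    return(list(pattern = "MISSING", role_map = character(0)))
  }
  if (length(call) != ploidy) {
    stop("call has ", length(call), " alleles, expected ", ploidy)
  }
  tab <- sort(table(call), decreasing = TRUE)
  tok <- names(tab)
  if (ploidy == 2L) {
    if (length(tab) == 1L) {
      return(list(pattern = "AA", role_map = c(A = tok[1L])))
    }
    tok <- sort(tok)
    return(list(pattern = "AB", role_map = c(A = tok[1L], B = tok[2L])))
  }
  if (length(tab) == 1L) {
    list(pattern = "AAA", role_map = c(A = tok[1L]))
  } else if (length(tab) == 2L) {
    # singleton allele is the pattern's A, duplicated allele its B
    list(pattern = "ABB", role_map = c(A = tok[2L], B = tok[1L]))
  } else {
    tok <- sort(tok)
    list(pattern = "ABC", role_map = c(A = tok[1L], B = tok[2L], C = tok[3L]))
  }
}

#' Transmission-table parameters
#'
#' @param freqs per-marker allele frequencies, as returned by
#'   [allele_frequencies()] (conventionally computed in the offspring
#'   population analysed).
#' @param r marker-centromere recombination rate used in the likelihood
#'   tables, a single value in `[0, 1]` applied to all markers. Defaults to
#'   0.5, an average value suitable when marker-centromere distances are
#'   unknown.
#' @param e error floor in `(0, 1)`: the probability substituted for
#'   zero-likelihood (incompatible) table cells so that a single
#'   incompatibility, possibly a genotyping error, does not veto a true pair.
#'   Default 0.01.
#' @return An object of class `table_params`.
#' @export
table_params <- function(freqs, r = 0.5, e = 0.01) {
  stopifnot(is.list(freqs), length(r) == 1L, r >= 0, r <= 1,
            length(e) == 1L, e > 0, e < 1)
  structure(list(freqs = freqs, r = r, e = e), class = "table_params")
}

#' @export
print.table_params <- function(x, ...) {
  cat("table_params: ", length(x$freqs), " markers, r = ", x$r,
      ", e = ", x$e, "\n", sep = "")
  invisible(x)
}
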