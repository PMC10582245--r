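#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()];
#' `complement(N) = N`.
#'
#' @param seq character vector over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Canonical strand-folded key of a read pair
#'
#' The identity unit of all set operations: a pair and its
#' reverse-complemented, mate-swapped twin receive the same key, so exact
#' matching automatically includes reverse complementary sequences. Let
#' `fwd = r1 '#' r2` and `rev = revcomp(r2) '#' revcomp(r1)`; the key is the
#' lexicographic minimum of the two (byte order; `'#'` is a non-nucleotide
#' separator so mate boundaries can never be confused).
#'
#' @param r1_seq,r2_seq character vectors of mate sequences over
#'   `{A,C,G,T,N}`.
#' @return character vector of canonical keys.
#' @export
canonical_key <- function(r1_seq, r2_seq) {
  stopifnot(length(r1_seq) == length(r2_seq))
  if (length(r1_seq) == 0) return(character(0))
  if (any(grepl("[^ACGTN]", c(r1_seq, r2_seq)))) {
    stop("invalid nucleotide: sequences must be over {A,C,G,T,N}")
  }
  fwd <- paste0(r1_seq, "#", r2_seq)
  rev <- paste0(revcomp(r2_seq), "#", revcomp(r1_seq))
  ifelse(fwd <= rev, fwd, rev)
}

#' Unique-read counts for one PCR duplicate
#'
#' Collapses a filtered read-pair stream into a multiset of canonical keys
#' with multiplicities — the per-library counts to which the "more than 10
#' identical copies" threshold is applied. Forward and reverse-complement
#' observations of the same fragment pool into one key (disable with
#' `strand_pool = FALSE` to count orientations separately before folding;
#' the high-quality threshold then applies per orientation).
#'
#' @param pairs a [read_pairs()] collection (already filtered).
#' @param sample_id,duplicate_id identifiers recorded on the result.
#' @param strand_pool pool both orientations into one multiplicity
#'   (default `TRUE`).
#' @return a `unique_read_counts` object: list with `sample_id`,
#'   `duplicate_id`, and `counts` (named integer vector, names sorted).
#' @export
count_unique <- function(pairs, sample_id = "sample", duplicate_id = "dup",
                         strand_pool = TRUE) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (strand_pool) {
    keys <- canonical_key(pairs$r1_seq, pairs$r2_seq)
    counts <- table(keys)
  } else {
    # count orientations separately, then fold each orientation's count
    # under its canonical key without merging them
    fwd <- paste0(pairs$r1_seq, "#", pairs$r2_seq)
    tab <- table(fwd)
    parts <- strsplit(names(tab), "#", fixed = TRUE)
    k <- canonical_key(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
    counts <- tapply(as.integer(tab), k, max)
  }
  nm <- names(counts)
  if (is.null(nm)) nm <- character(0)
  counts <- as.integer(counts)[order(nm)]
  out <- list(sample_id = sample_id, duplicate_id = duplicate_id,
              counts = stats::setNames(counts, sort(nm)))
  class(out) <- "unique_read_counts"
  out
}

#' @export
print.unique_read_counts <- function(x, ...) {
  cat(sprintf("unique_read_counts: sample %s, duplicate %s — %d unique key(s), %d read pair(s)\n",
              x$sample_id, x$duplicate_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' High-quality key set of one duplicate
#'
#' Keys observed strictly more than ten times (by default) in a library:
#' `min_copies = 11` implements "more than 10 identical whole-length copies";
#' a key seen exactly 10 times does not qualify.
#'
#' @param counts a [count_unique()] result.
#' @param min_copies minimum multiplicity to qualify (default 11).
#' @return sorted character vector of qualifying keys.
#' @export
high_quality_set <- function(counts, min_copies = 11L) {
  stopifnot(inherits(counts, "unique_read_counts"), min_copies >= 1)
  sort(names(counts$counts)[counts$counts >= min_copies])
}

#' Super high-quality reference set of a sample
#'
#' The intersection of the high-quality sets of a sample's PCR duplicates:
#' a key must exceed the copy threshold independently in every duplicate.
#' Agreement between independent libraries is what separates true genomic
#' fragments from PCR and sequencing artifacts, so by default at least two
#' duplicates are required.
#'
#' @param hq_sets list of character vectors from [high_quality_set()], one
#'   per duplicate.
#' @param sample_id identifier recorded on the result.
#' @param provenance duplicate identifiers contributing, recorded on the
#'   result.
#' @param allow_single permit a single duplicate (a deviation from the
#'   method's design; logged with a warning).
#' @return a `reference_set`: list with `sample_id`, `shq` (sorted keys),
#'   `provenance`.
#' @export
super_high_quality_set <- function(hq_sets, sample_id = "sample",
                                   provenance = NULL, allow_single = FALSE) {
  stopifnot(is.list(hq_sets), length(hq_sets) >= 1)
  if (length(hq_sets) < 2) {
    if (!allow_single) stop("need >=2 PCR duplicates to build a reference set")
    warning(sprintf("sample %s: reference built from a single duplicate (reduced artifact control)",
                    sample_id))
  }
  shq <- Reduce(intersect, hq_sets)
  out <- list(sample_id = sample_id, shq = sort(shq),
              provenance = if (is.null(provenance))
                paste0("dup", seq_along(hq_sets)) else provenance)
  class(out) <- "reference_set"
  out
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: sample %s — %d super high-quality key(s) from duplicates %s\n",
              x$sample_id, length(x$shq), paste(x$provenance, collapse = ", ")))
  invisible(x)
}

#' Comprehensive key set of a sample
#'
#' Every key appearing at least once in any of the sample's PCR duplicates —
#' the query set, deliberately permissive so that a true fragment present in
#' the sample is never missed when searching it for another sample's
#' reference reads. Always a superset of the same sample's super high-quality
#' set.
#'
#' @param counts_list list of [count_unique()] results for one sample.
#' @return a `comprehensive_set`: list with `sample_id`, `keys` (sorted).
#' @export
comprehensive_set <- function(counts_list) {
  stopifnot(is.list(counts_list), length(counts_list) >= 1)
  sids <- unique(vapply(counts_list, `[[`, "", "sample_id"))
  if (length(sids) != 1) {
    stop(sprintf("comprehensive_set: counts span multiple samples: %s",
                 paste(sids, collapse = ", ")))
  }
  keys <- sort(unique(unlist(lapply(counts_list, function(x) names(x$counts)),
                             use.names = FALSE)))
  if (is.null(keys)) keys <- character(0)
  out <- list(sample_id = sids, keys = keys)
  class(out) <- "comprehensive_set"
  out
}

#' @export
print.comprehensive_set <- function(x, ...) {
  cat(sprintf("comprehensive_set: sample %s — %d key(s)\n",
              x$sample_id, length(x$keys)))
  invisible(x)
}

#' Serialize a key set to a plain-text file
#'
#' Sets are written as a small `#key=value` header (sample, type, provenance,
#' threshold, tool version) followed by one sorted canonical key per line —
#' bit-exact reproducible given identical inputs, and diffable.
#'
#' @param x a `reference_set` or `comprehensive_set`.
#' @param path output path.
#' @param min_copies threshold recorded in the header (reference sets only).
#' @param cultivar optional cultivar label recorded in the header.
#' @return invisibly, `path`.
#' @export
write_key_set <- function(x, path, min_copies = NULL, cultivar = NULL) {
  if (inherits(x, "reference_set")) {
    keys <- x$shq
    hdr <- c(paste0("#sample_id=", x$sample_id),
             "#type=shq",
             paste0("#provenance=", paste(x$provenance, collapse = ",")),
             if (!is.null(min_copies)) paste0("#min_copies=", min_copies))
  } else if (inherits(x, "comprehensive_set")) {
    keys <- x$keys
    hdr <- c(paste0("#sample_id=", x$sample_id), "#type=comprehensive")
  } else stop("write_key_set: unsupported object")
  if (!is.null(cultivar)) hdr <- c(hdr, paste0("#cultivar=", cultivar))
  hdr <- c(hdr, paste0("#tool=idna ",
                       as.character(utils::packageVersion("idna"))))
  con <- file(path, "wb")  # binary mode: fixed LF endings, byte-reproducible
  on.exit(close(con))
  writeLines(c(hdr, keys), con, sep = "\n")
  invisible(path)
}

#' Read a serialized key set
#'
#' @param path a file written by [write_key_set()].
#' @return the `reference_set` or `comprehensive_set` it encodes.
#' @export
read_key_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("key set file not found: '%s'", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  keys <- lines[!is_hdr]
  keys <- keys[nzchar(keys)]
  field <- function(name) {
    m <- grep(paste0("^#", name, "="), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^#", name, "="), "", m[1])
  }
  type <- field("type")
  if (identical(type, "shq")) {
    out <- list(sample_id = field("sample_id"), shq = keys,
                provenance = strsplit(field("provenance"), ",")[[1]])
    class(out) <- "reference_set"
  } else if (identical(type, "comprehensive")) {
    out <- list(sample_id = field("sample_id"), keys = keys)
    class(out) <- "comprehensive_set"
  } else {
    stop(sprintf("'%s': unknown or missing #type header", path))
  }
  out$cultivar <- field("cultivar")
  out
}
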