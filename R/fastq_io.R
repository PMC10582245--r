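#' Construct a paired-read collection
#'
#' `read_pairs()` builds the package's central in-memory container: a
#' column-oriented set of paired-end reads, each with an optional index
#' (barcode) read. Sequences are uppercase DNA over `{A,C,G,T,N}`; qualities
#' are stored as Phred+33 strings, the encoding MiSeq FASTQ uses (decode with
#' [decode_quality()]).
#'
#' @param id character vector of read identifiers.
#' @param r1_seq,r2_seq character vectors of mate sequences.
#' @param r1_qual,r2_qual character vectors of Phred+33 quality strings,
#'   same per-element width as the corresponding sequence.
#' @param index_seq,index_qual character vectors for the index (barcode) read;
#'   default empty strings when no index is available.
#' @return An object of class `read_pairs`: a list of the seven parallel
#'   vectors with a `length()` method counting pairs.
#' @export
read_pairs <- function(id, r1_seq, r1_qual, r2_seq, r2_qual,
                       index_seq = character(length(id)),
                       index_qual = character(length(id))) {
  index_seq[is.na(index_seq)] <- ""
  index_qual[is.na(index_qual)] <- ""
  n <- length(id)
  fields <- list(id = as.character(id),
                 r1_seq = as.character(r1_seq), r1_qual = as.character(r1_qual),
                 r2_seq = as.character(r2_seq), r2_qual = as.character(r2_qual),
                 index_seq = as.character(index_seq),
                 index_qual = as.character(index_qual))
  lens <- vapply(fields, length, integer(1))
  if (any(lens != n)) stop("read_pairs: fields must have equal length")
  for (side in c("r1", "r2", "index")) {
    ls <- nchar(fields[[paste0(side, "_seq")]])
    lq <- nchar(fields[[paste0(side, "_qual")]])
    if (any(ls != lq)) {
      stop(sprintf("read_pairs: %s sequence/quality length mismatch at record %d",
                   side, which(ls != lq)[1]))
    }
  }
  structure(fields, class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs with %d pair(s)\n", length(x)))
  if (length(x) > 0) {
    k <- min(3L, length(x))
    for (i in seq_len(k)) {
      cat(sprintf("  %s  R1[%d] R2[%d] I[%d]\n", x$id[i],
                  nchar(x$r1_seq[i]), nchar(x$r2_seq[i]), nchar(x$index_seq[i])))
    }
    if (length(x) > k) cat(sprintf("  ... and %d more\n", length(x) - k))
  }
  invisible(x)
}

#' Subset a read_pairs collection
#' @param x a `read_pairs` object.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.read_pairs` <- function(x, i, ...) {
  structure(lapply(unclass(x), `[`, i), class = "read_pairs")
}

#' Decode a Phred+33 quality string
#'
#' Maps each character to `ASCII code - 33`, the Illumina/MiSeq FASTQ dialect.
#' Characters below `'!'` (ASCII 33) cannot occur in a valid Phred+33 string
#' and are rejected rather than silently interpreted as Phred+64.
#'
#' @param qual_text a single quality string.
#' @return integer vector of per-base quality values (QV), one per character.
#' @examples
#' decode_quality("?II")  # QV 30 at the '?' boundary, then two QV 40 bases
#' @export
decode_quality <- function(qual_text) {
  stopifnot(is.character(qual_text), length(qual_text) == 1L)
  v <- utf8ToInt(qual_text) - 33L
  if (any(v < 0L)) stop("invalid quality encoding: character below ASCII 33 ('!')")
  v
}

#' Encode integer quality values as a Phred+33 string
#' @param qv integer vector of quality values in `[0, 93]`.
#' @return a single Phred+33 string.
#' @export
encode_quality <- function(qv) {
  stopifnot(all(qv >= 0), all(qv <= 93))
  intToUtf8(as.integer(qv) + 33L)
}

# Decode equal-width Phred+33 strings into an n x L integer matrix.
# Fast path used by the window-quality filter on fixed-length libraries.
phred_matrix <- function(qual_strings) {
  L <- unique(nchar(qual_strings))
  stopifnot(length(L) == 1L)
  v <- utf8ToInt(paste(qual_strings, collapse = "")) - 33L
  matrix(v, nrow = length(qual_strings), ncol = L, byrow = TRUE)
}

read_fastq_file <- function(path) {
  out <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("[ \t].*$", "", names(x)),
         comment = sub("^[^ \t]+[ \t]?", "", names(x)),
         seq = toupper(as.character(x)),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) {
    stop(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  bad <- nchar(out$seq, type = "bytes") != nchar(out$qual, type = "bytes") |
    grepl("[^\x21-\x7e]", out$qual, useBytes = TRUE)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ in '%s': record %d has an invalid or truncated quality line",
                 path, which(bad)[1]), call. = FALSE)
  }
  out
}

#' Read paired-end FASTQ files (with optional index reads)
#'
#' Reads positionally synchronised R1/R2 (and optionally I1) FASTQ files,
#' plain or gzipped, into a [read_pairs()] collection. When `index_path` is
#' absent, the barcode is taken from the read header if the comment field ends
#' in `:<ACGTN+>` (the bcl2fastq "barcode in header" dialect); its quality is
#' then unknown and assumed QV 40, with a warning. Otherwise the index fields
#' are left empty.
#'
#' @param r1_path,r2_path paths to the mate FASTQ files.
#' @param index_path optional path to the index-read FASTQ file.
#' @return a `read_pairs` object in file order.
#' @export
read_paired_fastq <- function(r1_path, r2_path, index_path = NULL) {
  for (p in c(r1_path, r2_path, index_path)) {
    if (!file.exists(p)) stop(sprintf("FASTQ file not found: '%s'", p))
  }
  r1 <- read_fastq_file(r1_path)
  r2 <- read_fastq_file(r2_path)
  if (length(r1$id) != length(r2$id)) {
    stop(sprintf("record count mismatch between '%s' (%d) and '%s' (%d)",
                 r1_path, length(r1$id), r2_path, length(r2$id)))
  }
  n <- length(r1$id)
  if (!is.null(index_path)) {
    ix <- read_fastq_file(index_path)
    if (length(ix$id) != n) {
      stop(sprintf("record count mismatch between '%s' (%d) and '%s' (%d)",
                   r1_path, n, index_path, length(ix$id)))
    }
    index_seq <- ix$seq
    index_qual <- ix$qual
  } else {
    has_bc <- grepl(":[ACGTN]+$", r1$comment)
    index_seq <- character(n)
    index_seq[has_bc] <- regmatches(r1$comment[has_bc],
                                    regexpr("[ACGTN]+$", r1$comment[has_bc]))
    index_qual <- strrep(encode_quality(40L), nchar(index_seq))
    if (any(has_bc)) {
      warning("index read file absent; barcodes taken from read headers with qualities assumed QV 40")
    }
  }
  read_pairs(id = r1$id, r1_seq = r1$seq, r1_qual = r1$qual,
             r2_seq = r2$seq, r2_qual = r2$qual,
             index_seq = index_seq, index_qual = index_qual)
}

write_fastq_file <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  q <- Biostrings::BStringSet(qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a read_pairs collection to paired FASTQ files
#'
#' Inverse of [read_paired_fastq()]: round-tripping preserves identifiers,
#' sequences and qualities. Paths ending in `.gz` are gzip-compressed.
#'
#' @param pairs a `read_pairs` object.
#' @param r1_path,r2_path output paths for the two mates.
#' @param index_path optional output path for the index reads; written only
#'   when all index sequences are nonempty.
#' @return invisibly, the vector of paths written.
#' @export
write_paired_fastq <- function(pairs, r1_path, r2_path, index_path = NULL) {
  stopifnot(inherits(pairs, "read_pairs"))
  write_fastq_file(pairs$id, pairs$r1_seq, pairs$r1_qual, r1_path)
  write_fastq_file(pairs$id, pairs$r2_seq, pairs$r2_qual, r2_path)
  written <- c(r1_path, r2_path)
  if (!is.null(index_path)) {
    if (any(nchar(pairs$index_seq) == 0)) {
      stop("cannot write index FASTQ: some pairs have empty index sequences")
    }
    write_fastq_file(pairs$id, pairs$index_seq, pairs$index_qual, index_path)
    written <- c(written, index_path)
  }
  invisible(written)
}

#' Read a sample manifest
#'
#' The manifest is a TSV with header columns `sample_id`, `cultivar`,
#' `duplicate_id`, `r1_path`, `r2_path`, `index_path`, `barcode`; one row per
#' (sample, PCR duplicate) library. Relative paths are resolved against the
#' manifest's own directory. Each sample needs at least two PCR duplicates
#' unless `require_duplicates = FALSE`.
#'
#' @param path path to the manifest TSV.
#' @param require_duplicates if `TRUE` (default), error when any sample has
#'   fewer than two duplicates.
#' @return a data.frame with the manifest columns.
#' @export
read_manifest <- function(path, require_duplicates = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("sample_id", "cultivar", "duplicate_id", "r1_path", "r2_path", "barcode")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    stop(sprintf("manifest '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (!"index_path" %in% names(m)) m$index_path <- NA_character_
  m$index_path[m$index_path == ""] <- NA_character_
  key <- paste(m$sample_id, m$duplicate_id)
  if (anyDuplicated(key)) {
    stop(sprintf("manifest '%s': duplicated (sample_id, duplicate_id): %s",
                 path, key[duplicated(key)][1]))
  }
  ndup <- table(m$sample_id)
  if (require_duplicates && any(ndup < 2)) {
    stop(sprintf("sample(s) with fewer than 2 PCR duplicates: %s (enable single-duplicate mode to proceed)",
                 paste(names(ndup)[ndup < 2], collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  for (col in c("r1_path", "r2_path", "index_path")) {
    rel <- !is.na(m[[col]]) & !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}
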