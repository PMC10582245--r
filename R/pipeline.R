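#' Run the filtering stage over a manifest
#'
#' Applies the stringent filters to every (sample, duplicate) library in the
#' manifest, writes one filtered FASTQ pair per library plus a per-library
#' `filter_report.tsv`, and emits a filtered manifest pointing at the new
#' files. The report satisfies the conservation identity per row.
#'
#' @param manifest_path path to a manifest TSV (see [read_manifest()]).
#' @param config a [filter_config()].
#' @param out_dir output directory.
#' @param require_duplicates passed to [read_manifest()].
#' @return invisibly, a list with `manifest` (path to the filtered manifest)
#'   and `report` (data.frame, one row per library).
#' @export
run_filter <- function(manifest_path, config = filter_config(), out_dir,
                       require_duplicates = TRUE) {
  m <- read_manifest(manifest_path, require_duplicates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  echo_config(out_dir, c(list(stage = "filter", manifest = manifest_path),
                         unclass(config)))
  reports <- list(); rows <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    for (p in c(row$r1_path, row$r2_path)) {
      if (!file.exists(p)) {
        stop(sprintf("manifest row %d (%s %s): file not found '%s'",
                     i, row$sample_id, row$duplicate_id, p))
      }
    }
    pairs <- read_paired_fastq(row$r1_path, row$r2_path,
                               if (!is.na(row$index_path)) row$index_path)
    res <- filter_read_pairs(pairs, row$barcode, config)
    prefix <- file.path(normalizePath(out_dir),
                        paste(row$sample_id, row$duplicate_id, "filtered",
                              sep = "_"))
    r1 <- paste0(prefix, "_R1.fastq"); r2 <- paste0(prefix, "_R2.fastq")
    if (length(res$kept) > 0) {
      write_paired_fastq(res$kept, r1, r2)
    } else {
      writeLines(character(0), r1); writeLines(character(0), r2)
    }
    reports[[i]] <- cbind(data.frame(sample_id = row$sample_id,
                                     duplicate_id = row$duplicate_id),
                          res$report)
    rows[[i]] <- data.frame(sample_id = row$sample_id, cultivar = row$cultivar,
                            duplicate_id = row$duplicate_id,
                            r1_path = r1, r2_path = r2,
                            index_path = NA_character_, barcode = row$barcode)
  }
  report <- do.call(rbind, reports)
  write_tsv_lf(report, file.path(out_dir, "filter_report.tsv"))
  fm <- do.call(rbind, rows)
  fm_path <- file.path(out_dir, "manifest_filtered.tsv")
  write_tsv_lf(fm, fm_path)
  invisible(list(manifest = fm_path, report = report))
}

#' Build reference and comprehensive sets per sample
#'
#' Counts unique canonical keys per PCR duplicate from filtered FASTQ files,
#' forms each duplicate's high-quality set (`>= min_copies` identical
#' copies), intersects duplicates into the sample's super high-quality
#' reference, unions all observed keys into its comprehensive set, and
#' serializes both as plain-text key files.
#'
#' @param manifest_path path to the filtered manifest from [run_filter()]
#'   (any manifest of filtered FASTQs works).
#' @param min_copies copy threshold for the high-quality sets (default 11,
#'   i.e. more than 10 identical copies).
#' @param out_dir output directory for the `.keys` files.
#' @param allow_single permit samples with a single duplicate.
#' @param strand_pool see [count_unique()].
#' @return invisibly, a list per sample with elements `ref`
#'   (`reference_set`), `comp` (`comprehensive_set`) and `cultivar`.
#' @export
run_build <- function(manifest_path, min_copies = 11L, out_dir,
                      allow_single = FALSE, strand_pool = TRUE) {
  m <- read_manifest(manifest_path, require_duplicates = !allow_single)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  echo_config(out_dir, list(stage = "build", manifest = manifest_path,
                            min_copies = min_copies,
                            strand_pool = strand_pool))
  out <- list()
  for (sid in unique(m$sample_id)) {
    rows <- m[m$sample_id == sid, , drop = FALSE]
    counts_list <- lapply(seq_len(nrow(rows)), function(i) {
      pairs <- read_filtered_fastq(rows$r1_path[i], rows$r2_path[i])
      count_unique(pairs, sid, rows$duplicate_id[i], strand_pool = strand_pool)
    })
    hq <- lapply(counts_list, high_quality_set, min_copies = min_copies)
    ref <- super_high_quality_set(hq, sample_id = sid,
                                  provenance = rows$duplicate_id,
                                  allow_single = allow_single)
    comp <- comprehensive_set(counts_list)
    stopifnot(all(ref$shq %in% comp$keys))
    write_key_set(ref, file.path(out_dir, paste0(sid, ".shq.keys")),
                  min_copies = min_copies, cultivar = rows$cultivar[1])
    write_key_set(comp, file.path(out_dir, paste0(sid, ".comprehensive.keys")),
                  cultivar = rows$cultivar[1])
    out[[sid]] <- list(ref = ref, comp = comp, cultivar = rows$cultivar[1])
  }
  invisible(out)
}

# Filtered FASTQs carry no index read; an empty file is an empty library.
read_filtered_fastq <- function(r1_path, r2_path) {
  if (file.size(r1_path) == 0 && file.size(r2_path) == 0) {
    return(read_pairs(character(0), character(0), character(0),
                      character(0), character(0)))
  }
  read_paired_fastq(r1_path, r2_path)
}

#' Compare all samples: similarity matrix and summaries
#'
#' Loads serialized key sets (or takes the in-memory result of
#' [run_build()]), computes the full asymmetric matrix of exact matching
#' rates, and writes the tabular outputs of [render_outputs()].
#'
#' @param sets either the list returned by [run_build()], or a directory
#'   containing `<sample>.shq.keys` / `<sample>.comprehensive.keys` files.
#' @param cultivars optional named character vector sample_id -> cultivar;
#'   when `sets` is a [run_build()] result its cultivar labels are used by
#'   default.
#' @param out_dir output directory.
#' @param heatmap also render a PNG heatmap.
#' @return invisibly, the [similarity_matrix()].
#' @export
run_compare <- function(sets, cultivars = NULL, out_dir, heatmap = FALSE) {
  if (is.character(sets)) {
    shq_files <- sort(list.files(sets, pattern = "\\.shq\\.keys$",
                                 full.names = TRUE))
    if (length(shq_files) == 0) {
      stop(sprintf("no .shq.keys files found in '%s'", sets))
    }
    refs <- lapply(shq_files, read_key_set)
    comps <- lapply(refs, function(r) {
      read_key_set(file.path(sets, paste0(r$sample_id, ".comprehensive.keys")))
    })
    ids <- vapply(refs, `[[`, "", "sample_id")
    if (is.null(cultivars)) {
      cv <- vapply(refs, function(r) r$cultivar, character(1))
      if (!anyNA(cv)) cultivars <- stats::setNames(cv, ids)
    }
  } else {
    refs <- lapply(sets, `[[`, "ref")
    comps <- lapply(sets, `[[`, "comp")
    ids <- vapply(refs, `[[`, "", "sample_id")
    if (is.null(cultivars)) {
      cultivars <- stats::setNames(vapply(sets, `[[`, "", "cultivar"), ids)
    }
  }
  if (length(refs) < 2) stop("need >=2 samples to compare")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  echo_config(out_dir, list(stage = "compare", n_samples = length(refs)))
  mat <- similarity_matrix(comps, refs, cultivars)
  render_outputs(mat, out_dir, heatmap = heatmap)
  invisible(mat)
}

#' Run the whole pipeline: filter, build, compare
#'
#' Composes [run_filter()], [run_build()] and [run_compare()]; intermediate
#' artifacts (filtered FASTQs, key-set files) are kept under `out_dir` so a
#' stored reference panel can later be queried against new samples.
#'
#' @param manifest_path path to the cohort manifest.
#' @param config a [filter_config()].
#' @param min_copies copy threshold for reference construction.
#' @param out_dir output directory; subdirectories `filtered/`, `sets/`,
#'   `compare/` are created.
#' @param heatmap also render a PNG heatmap.
#' @param allow_single permit single-duplicate samples.
#' @return invisibly, a list with `filter` (report), `sets`, and `matrix`.
#' @export
run_pipeline <- function(manifest_path, config = filter_config(),
                         min_copies = 11L, out_dir, heatmap = FALSE,
                         allow_single = FALSE) {
  fl <- run_filter(manifest_path, config, file.path(out_dir, "filtered"),
                   require_duplicates = !allow_single)
  sets <- run_build(fl$manifest, min_copies, file.path(out_dir, "sets"),
                    allow_single = allow_single)
  mat <- run_compare(sets, out_dir = file.path(out_dir, "compare"),
                     heatmap = heatmap)
  invisible(list(filter = fl$report, sets = sets, matrix = mat))
}

# Echo the resolved configuration into the output directory before any
# computation, so a run is re-executable from its own outputs.
echo_config <- function(out_dir, values) {
  values$tool_version <- as.character(utils::packageVersion("idna"))
  lines <- vapply(names(values), function(k) {
    paste0(k, "=", paste(format(values[[k]]), collapse = ","))
  }, character(1))
  con <- file(file.path(out_dir, paste0("config_", values$stage, ".txt")), "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

write_tsv_lf <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
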