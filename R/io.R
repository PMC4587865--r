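#' Read / write a log2 expression matrix with sample annotations
#'
#' The matrix is tab-delimited with probe ids in the first column and sample
#' ids in the header; the annotation is a sidecar CSV with columns `sample`,
#' `cell_line`, `class`, `treatment`, `replicate`. Writers and readers
#' round-trip losslessly (up to numeric print precision).
#'
#' @param matrix_path path to the tab-delimited matrix.
#' @param annotation_path path to the annotation CSV.
#' @return `read_expression_matrix`: list with `matrix` and `annotation`.
#' @export
read_expression_matrix <- function(matrix_path, annotation_path) {
  df <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a probe column plus samples: ",
                          matrix_path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  if (anyNA(suppressWarnings(as.numeric(mat))))
    stop("non-numeric values in expression matrix: ", matrix_path)
  storage.mode(mat) <- "double"
  ann <- read.csv(annotation_path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "class", "treatment")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation ", annotation_path,
                         " lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(ann$sample, colnames(mat)))
    stop("annotation samples do not match matrix columns")
  ann <- ann[match(colnames(mat), ann$sample), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = mat, annotation = ann)
}

#' @rdname read_expression_matrix
#' @param mat probes x samples numeric matrix.
#' @param annotation annotation data.frame.
#' @export
write_expression_matrix <- function(mat, annotation, matrix_path,
                                    annotation_path) {
  df <- data.frame(probe = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(annotation, annotation_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read / write clone FASTA files
#'
#' Thin wrappers over `Biostrings` FASTA I/O returning plain named character
#' vectors, which is how clone sets travel through the bisulfite module.
#'
#' @param path FASTA path.
#' @return `read_clone_fasta`: named character vector of sequences.
#' @export
read_clone_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_clone_fasta
#' @param sequences named character vector.
#' @export
write_clone_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write a cohort table CSV
#'
#' The cohort CSV carries one row per sample: `sample`, `group`
#' (`tumor`/`normal`), the raw probe score columns, and optional `dataset`,
#' `grade`, `er`, `pr`, `her2`, `rfs_time`, `rfs_event` columns.
#'
#' @param path CSV path.
#' @param probe_ids probe column names that must be present.
#' @return `read_cohort_csv`: data.frame.
#' @export
read_cohort_csv <- function(path, probe_ids = c("probe_a", "probe_b")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", probe_ids)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), c("tumor", "normal"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_cohort_csv
#' @param table cohort data.frame.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write CpG islands as a BED track
#'
#' Coordinates are already 0-based half-open, matching BED.
#'
#' @param islands data.frame from [find_cpg_islands()].
#' @param path output path.
#' @param chrom chromosome/sequence name for the BED records.
#' @export
write_islands_bed <- function(islands, path, chrom = "region") {
  bed <- data.frame(chrom = chrom, start = islands$start, end = islands$end,
                    name = sprintf("CpG_island_%d", seq_len(nrow(islands))),
                    score = round(islands$obs_exp_cpg * 1000))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for an analysis step
#'
#' Records inputs, parameters, seed, outputs and the package version as a
#' JSON manifest, so any analysis output can be regenerated from its
#' manifest alone.
#'
#' @param path manifest path (JSON).
#' @param step analysis step name.
#' @param inputs,outputs character vectors of file paths (may be empty).
#' @param parameters named list of parameters (must include any seed used).
#' @param seed the seed driving the step's randomness (NA when
#'   deterministic).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, step, inputs = character(0),
                           outputs = character(0), parameters = list(),
                           seed = NA) {
  manifest <- list(step = step,
                   tool = "methmark",
                   version = as.character(utils::packageVersion("methmark")),
                   seed = seed,
                   parameters = parameters,
                   inputs = inputs,
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
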