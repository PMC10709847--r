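# Input handling for 450K-style beta matrices, sample manifests and probe
# annotations. A beta matrix is an ordinary numeric matrix with CpG probes as
# rows (rownames = probe ids) and samples as columns (colnames = sample ids);
# all non-missing values lie in [0, 1).

#' Compute methylation beta values from intensity pairs
#'
#' The beta value estimates the methylation fraction at a CpG from the
#' methylated (M) and unmethylated (U) probe intensities as
#' `M / (M + U + 100)`. The pseudo-count of 100 in the denominator stabilises
#' low-intensity probes and guarantees the result is strictly below 1.
#'
#' @param methylated Non-negative methylated intensity (vectorised).
#' @param unmethylated Non-negative unmethylated intensity, recycled against
#'   `methylated`.
#' @return Numeric vector of beta values in `[0, 1)`.
#' @examples
#' compute_beta(900, 0)   # 0.9
#' compute_beta(100, 100) # 1/3
#' @export
compute_beta <- function(methylated, unmethylated) {
  if (!is.numeric(methylated) || !is.numeric(unmethylated))
    stop("intensities must be numeric")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("negative intensity: M and U must be >= 0")
  methylated / (methylated + unmethylated + 100)
}

#' Validate a beta matrix
#'
#' Checks the container invariants: a numeric matrix with unique probe
#' rownames, unique sample colnames, and all non-missing values in `[0, 1)`.
#'
#' @param x Numeric matrix, probes x samples.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix (probes x samples)")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("beta matrix must have unique probe rownames")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("beta matrix must have unique sample colnames")
  v <- x[is.finite(x)]
  if (length(v) && (min(v) < 0 || max(v) >= 1))
    stop("beta values must lie in [0, 1)")
  invisible(x)
}

#' Read a beta matrix from TSV/CSV
#'
#' Expects probes as rows and samples as columns with the first column holding
#' probe ids (Xena-style). If the row ids do not look like CpG probe ids
#' ("cg"/"ch." prefixes) but the column names do, the matrix is transposed with
#' a warning. Reading is gzip-transparent. Missing cells may be empty or "NA".
#'
#' @param path Path to a delimited text file (.tsv/.csv, optionally .gz).
#' @return Numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""))
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  looks_probe <- function(z) mean(grepl("^(cg|ch\\.)", z)) > 0.5
  if (!looks_probe(ids) && looks_probe(colnames(m))) {
    warning("input appears transposed (samples as rows); transposing")
    m <- t(m)
  }
  validate_beta_matrix(m)
  m
}

#' Write a beta matrix as TSV
#'
#' Probes as rows, first column `probe_id`, header row of sample ids; missing
#' values written as "NA".
#'
#' @param x Beta matrix (probes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  validate_beta_matrix(x)
  dt <- data.table::data.table(probe_id = rownames(x), x)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

manifest_cols <- c("sample_id", "cancer_type", "subtype", "cohort")

#' Read a sample manifest
#'
#' A manifest is a TSV/CSV with required columns `sample_id`, `cancer_type`,
#' `subtype`, `cohort`; an optional `split` column (train/test/unassigned) is
#' added as "unassigned" when absent.
#'
#' @param path Path to the manifest file.
#' @return data.frame with the manifest columns; `sample_id`s unique.
#' @export
read_manifest <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE,
                                        colClasses = "character"))
  missing <- setdiff(manifest_cols, names(df))
  if (length(missing))
    stop("manifest lacks required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("manifest sample_id values must be unique")
  if (!"split" %in% names(df)) df$split <- "unassigned"
  df
}

#' Write a sample manifest as TSV
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' TSV/CSV with columns `probe_id` and `chromosome` (e.g. "chr1", "chrX").
#'
#' @param path Path to the annotation file.
#' @return data.frame with unique `probe_id`.
#' @export
read_probe_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE,
                                        colClasses = "character"))
  if (!all(c("probe_id", "chromosome") %in% names(df)))
    stop("annotation requires columns probe_id, chromosome")
  if (anyDuplicated(df$probe_id)) stop("annotation probe_id values must be unique")
  df
}

#' Filter probes to the usable, shared autosomal set
#'
#' Restricts a beta matrix to probes that (i) are present in every cohort's
#' probe set, (ii) are not annotated to the sex chromosomes, and (iii) have no
#' missing values in any sample. Probes absent from the annotation are treated
#' as autosomal and kept, with a warning. Probe order of the input is
#' preserved; the sample set is unchanged. The operation is idempotent.
#'
#' @param x Beta matrix (probes x samples).
#' @param annotation Probe annotation data.frame (`probe_id`, `chromosome`),
#'   or NULL to skip the sex-chromosome filter.
#' @param cohort_probe_sets Optional list of character vectors, one per
#'   cohort/platform; only probes in the intersection of all sets are kept.
#' @return Filtered beta matrix.
#' @export
filter_probes <- function(x, annotation = NULL, cohort_probe_sets = NULL) {
  validate_beta_matrix(x)
  keep <- rownames(x)
  if (!is.null(cohort_probe_sets) && length(cohort_probe_sets)) {
    shared <- Reduce(intersect, cohort_probe_sets)
    keep <- keep[keep %in% shared]
  }
  if (!is.null(annotation)) {
    unann <- setdiff(keep, annotation$probe_id)
    if (length(unann))
      warning(length(unann), " probe(s) missing from annotation; kept as autosomal")
    sex <- annotation$probe_id[annotation$chromosome %in%
                                 c("chrX", "chrY", "X", "Y")]
    keep <- setdiff(keep, sex)
  }
  m <- x[keep, , drop = FALSE]
  complete <- rowSums(!is.finite(m)) == 0
  m <- m[complete, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("probe filtering removed all probes (empty panel)")
  m
}

#' Drop under-represented clinical subtypes
#'
#' Removes samples whose subtype has fewer than `min_count` samples or
#' contributes less than `min_fraction` of its cancer type's samples.
#' Subtypes named in `exclude` (e.g. ambiguously annotated ones) are removed
#' unconditionally. A cancer type that loses all its subtypes is dropped with
#' a warning.
#'
#' @param manifest Manifest data.frame.
#' @param min_count Minimum samples per subtype (default 5).
#' @param min_fraction Minimum share of the cancer type's samples
#'   (default 0.10).
#' @param exclude Character vector of subtype labels to drop outright.
#' @return Filtered manifest with attribute `"removed_subtypes"` listing what
#'   was dropped and why.
#' @export
filter_subtypes <- function(manifest, min_count = 5, min_fraction = 0.10,
                            exclude = character()) {
  stopifnot(all(manifest_cols %in% names(manifest)))
  key <- paste(manifest$cancer_type, manifest$subtype, sep = "\r")
  n_sub <- table(key)[key]
  n_type <- table(manifest$cancer_type)[manifest$cancer_type]
  small <- as.vector(n_sub) < min_count
  rare <- as.vector(n_sub) / as.vector(n_type) < min_fraction
  listed <- manifest$subtype %in% exclude
  drop <- small | rare | listed
  removed <- unique(data.frame(
    cancer_type = manifest$cancer_type[drop],
    subtype = manifest$subtype[drop],
    reason = ifelse(listed[drop], "excluded",
                    ifelse(small[drop], "count", "fraction"))))
  kept <- manifest[!drop, , drop = FALSE]
  lost_types <- setdiff(manifest$cancer_type, kept$cancer_type)
  if (length(lost_types))
    warning("cancer type(s) lost all subtypes and were dropped: ",
            paste(lost_types, collapse = ", "))
  attr(kept, "removed_subtypes") <- removed
  rownames(kept) <- NULL
  kept
}

#' Stratified train/test split
#'
#' Assigns each sample to the training or test set, stratified by cancer type.
#' Per type, `floor(ratio * n)` samples (at least 1, at most n - 1) are drawn
#' for training and the remainder goes to the test set, so every type keeps at
#' least one test sample. The assignment is a deterministic function of
#' `seed`.
#'
#' @param manifest Manifest data.frame.
#' @param ratio Training fraction (default 0.8, the 4:1 split).
#' @param seed Integer seed.
#' @return Manifest with the `split` column filled with "train"/"test".
#' @export
stratified_split <- function(manifest, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  counts <- table(manifest$cancer_type)
  if (any(counts < 2))
    stop("cancer type(s) with a single sample cannot be split: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  rng <- local_rng(seed)
  manifest$split <- "test"
  for (ty in sort(unique(manifest$cancer_type))) {
    idx <- which(manifest$cancer_type == ty)
    n_train <- max(1L, min(length(idx) - 1L, floor(ratio * length(idx))))
    manifest$split[sample(idx, n_train)] <- "train"
  }
  manifest
}
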