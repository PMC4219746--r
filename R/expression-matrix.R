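#' Log-scale expression matrix with probe annotation and sample metadata
#'
#' Lightweight container pairing a probes x samples numeric matrix (assumed
#' already normalised and on log2 scale) with a probe-to-gene map and one
#' metadata row per sample. No re-normalisation is ever applied.
#'
#' @param values numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param probes data.frame with columns `probe_id`, `gene`; one row per
#'   probe. Defaults to probe IDs used directly as gene symbols.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `condition_class`, `tissue`, `stage`, `perturbed_entity`,
#'   `replicate_group` (an optional `role` column distinguishes case and
#'   control arrays of a perturbation experiment). Exactly one row per
#'   matrix column.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, probes = NULL, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (is.null(probes)) {
    probes <- data.frame(probe_id = rownames(values),
                         gene = rownames(values),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("probe_id", "gene") %in% names(probes)))
    stop("`probes` needs columns probe_id, gene")
  missing_probe <- setdiff(rownames(values), probes$probe_id)
  if (length(missing_probe))
    stop("probes missing from annotation: ",
         paste(head(missing_probe, 5), collapse = ", "))
  probes <- probes[match(rownames(values), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          condition_class = "time_series",
                          tissue = "tissue", stage = "stage",
                          perturbed_entity = "", replicate_group = "",
                          stringsAsFactors = FALSE)
  }
  samples <- validate_sample_metadata(samples, colnames(values))
  structure(list(values = values, probes = probes, samples = samples),
            class = "expr_matrix")
}

condition_classes <- c("time_series", "genetic_perturbation",
                       "signalling_stimulation", "phenotype_difference")
perturbation_classes <- c("genetic_perturbation", "signalling_stimulation")

validate_sample_metadata <- function(samples, sample_ids) {
  required <- c("sample_id", "condition_class", "tissue", "stage",
                "perturbed_entity", "replicate_group")
  missing_col <- setdiff(required, names(samples))
  if (length(missing_col))
    stop("sample metadata missing column(s): ",
         paste(missing_col, collapse = ", "))
  absent <- setdiff(sample_ids, samples$sample_id)
  if (length(absent))
    stop("sample(s) in matrix absent from metadata: ",
         paste(absent, collapse = ", "))
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad_class <- setdiff(unique(samples$condition_class), condition_classes)
  if (length(bad_class))
    stop("unknown condition_class: ", paste(bad_class, collapse = ", "))
  is_pert <- samples$condition_class %in% perturbation_classes
  if (any(is_pert & !nzchar(samples$perturbed_entity)))
    stop("perturbation/stimulation samples must name a perturbed_entity")
  if (any(!is_pert & nzchar(samples$perturbed_entity)))
    stop("perturbed_entity must be empty outside perturbation classes")
  samples
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$probes$gene))))
  cat("condition classes:",
      paste(sprintf("%s=%d", names(table(x$samples$condition_class)),
                    table(x$samples$condition_class)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix (TSV) with its sample metadata
#'
#' @param path TSV file: first column probe IDs, remaining columns one per
#'   sample, header row of sample IDs. Values must be numeric (log2 scale
#'   as produced upstream); probes with any non-numeric cell are rejected.
#' @param metadata_path TSV keyed by `sample_id` with the metadata columns
#'   documented in [expr_matrix()].
#' @param probe_annotation optional TSV with columns `probe_id`, `gene`.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, metadata_path,
                                   probe_annotation = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs probe column + >=1 sample")
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(probe_ids, colnames(mat))))
  bad <- rowSums(is.na(num) & !is.na(mat)) > 0
  if (any(bad))
    stop("non-numeric expression values for probe(s): ",
         paste(probe_ids[bad], collapse = ", "))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  probes <- if (!is.null(probe_annotation))
    read.delim(probe_annotation, stringsAsFactors = FALSE) else NULL
  expr_matrix(num, probes = probes, samples = meta)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' @param x an `expr_matrix`.
#' @param path,metadata_path output TSV paths.
#' @param probe_annotation optional path for the probe-to-gene map.
#' @export
write_expression_matrix <- function(x, path, metadata_path,
                                    probe_annotation = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(probe_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(probe_annotation))
    write.table(x$probes, probe_annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(x)
}

#' Collapse a probe-level matrix to gene level
#'
#' Multi-probe genes are represented by their most variable probe; this is
#' the representation used by the mutual-information and tree-importance
#' networks (pairwise statistics instead reduce probe pairs by maximum
#' absolute statistic, see [pairwise_correlation()]).
#'
#' @param x an `expr_matrix`.
#' @return numeric matrix, genes x samples.
#' @export
gene_level_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- apply(x$values, 1, var)
  ord <- order(x$probes$gene, -v)
  keep <- ord[!duplicated(x$probes$gene[ord])]
  m <- x$values[keep, , drop = FALSE]
  rownames(m) <- x$probes$gene[keep]
  m
}
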