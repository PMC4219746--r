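# Readers/writers for curated-evidence CSV, SIF / edge-list networks and
# scored edge-list TSVs. Controlled vocabulary (gain/loss, up/none/down) is
# case-folded on read; gene symbols never are (mouse symbols are
# case-sensitive identifiers).

#' The 11 curated-evidence fields
#'
#' One literature observation records the perturbation of a regulator and
#' the observed response of a target together with its experimental
#' context.
#' @export
evidence_fields <- c("regulator", "target", "perturbation", "effect",
                     "species", "stage", "tissue_perturbed",
                     "tissue_measured", "technique", "molecule", "citation")

perturbation_tokens <- c("gain", "loss")
effect_tokens <- c("up", "none", "down")
molecule_tokens <- c("mRNA", "protein")

#' Read a curated perturbation-evidence table
#'
#' Comma-separated, UTF-8, header required; field order is free (columns
#' are keyed by header name). `perturbation` must be one of `gain`/`loss`
#' (`gain` = over-expression or stimulation, `loss` = knock-out or
#' knock-down), `effect` one of `up`/`none`/`down`; both are case-folded.
#' Autoregulation (regulator == target) is permitted.
#'
#' @param path CSV file with (at least) the 11 [evidence_fields] columns.
#' @param strict if `TRUE` (default) any malformed row aborts with its line
#'   number; if `FALSE` malformed rows are dropped with a message and the
#'   dropped count is attached as attribute `n_dropped`.
#' @return data.frame of validated evidence records.
#' @export
read_evidence_table <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_col <- setdiff(evidence_fields, names(df))
  if (length(missing_col))
    stop("evidence table missing field(s): ",
         paste(missing_col, collapse = ", "))
  df <- df[, evidence_fields, drop = FALSE]
  validate_evidence(df, strict = strict, origin = path)
}

validate_evidence <- function(df, strict = TRUE, origin = "evidence") {
  df$perturbation <- tolower(trimws(df$perturbation))
  df$effect <- tolower(trimws(df$effect))
  problems <- character(nrow(df))
  bad_pert <- !(df$perturbation %in% perturbation_tokens)
  bad_eff <- !(df$effect %in% effect_tokens)
  bad_gene <- !nzchar(trimws(df$regulator)) | !nzchar(trimws(df$target))
  problems[bad_pert] <- paste0("unknown perturbation token '",
                               df$perturbation[bad_pert], "'")
  problems[bad_eff] <- paste0("unknown effect token '", df$effect[bad_eff], "'")
  problems[bad_gene] <- "empty regulator or target"
  bad <- nzchar(problems)
  if (any(bad)) {
    # +1 for the header line of the source file
    msg <- paste(sprintf("line %d: %s", which(bad) + 1L, problems[bad]),
                 collapse = "; ")
    if (strict) stop("malformed evidence in ", origin, " -- ", msg)
    message("dropping ", sum(bad), " malformed evidence row(s): ", msg)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "n_dropped") <- sum(bad)
    return(df)
  }
  rownames(df) <- NULL
  df
}

#' Write a curated-evidence table to CSV
#' @param df data.frame of evidence records ([evidence_fields] columns).
#' @param path output CSV path.
#' @export
write_evidence_table <- function(df, path) {
  stopifnot(all(evidence_fields %in% names(df)))
  utils::write.csv(df[, evidence_fields], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(df)
}

#' Read a SIF or two-column edge-list network file
#'
#' SIF lines are `source <relation> target [target2 ...]`; two-column
#' lines are `source target`. The dialect must be uniform across the
#' file. Duplicate edges are collapsed (count reported via message);
#' self-loops are preserved but flagged — they are only removed at
#' network-comparison time.
#'
#' @param path file path.
#' @return data.frame with columns `source`, `target`, `self_loop`.
#' @export
read_sif_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(source = character(),
                                        target = character(),
                                        self_loop = logical()))
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_tok <- lengths(toks)
  if (any(n_tok < 2))
    stop("line ", which(n_tok < 2)[1], ": fewer than 2 tokens")
  if (any(n_tok == 2) && any(n_tok >= 3))
    stop("mixed SIF and 2-column dialects in ", path)
  if (all(n_tok == 2)) {
    edges <- data.frame(source = vapply(toks, `[`, "", 1),
                        target = vapply(toks, `[`, "", 2),
                        stringsAsFactors = FALSE)
  } else {
    edges <- do.call(rbind, lapply(toks, function(t)
      data.frame(source = t[1], target = t[-(1:2)],
                 stringsAsFactors = FALSE)))
  }
  n_raw <- nrow(edges)
  edges <- unique(edges)
  if (nrow(edges) < n_raw)
    message("collapsed ", n_raw - nrow(edges), " duplicate edge line(s)")
  edges$self_loop <- edges$source == edges$target
  rownames(edges) <- NULL
  edges
}

#' Write a scored edge list to TSV
#' @param edges data.frame with at least `source`, `target` columns.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read a scored edge-list TSV (as written by [write_edge_list()])
#' @param path input path.
#' @return data.frame.
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
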