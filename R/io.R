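#' Normalize a printed UniProt-style accession
#'
#' Printed accession tables carry typographic artifacts: footnote stars,
#' section marks, stray whitespace, lower case, and occasionally a
#' multiplication sign where the letter X belongs (e.g. `"Q9Z2 x 5"` printed
#' with a times sign). This strips all of them and upper-cases the result.
#'
#' @param raw character vector of raw accession strings.
#' @return character vector of cleaned accessions.
#' @examples
#' normalize_accession(c("Q4VSI4 *", "p12001", "Q9Z2 × 5"))
#' @export
normalize_accession <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(trimws(raw))))
  acc <- gsub("×", "X", raw)
  acc <- gsub("[*§]", "", acc)     # footnote markers
  acc <- gsub("[[:space:]]", "", acc)
  acc <- toupper(acc)
  bad <- !grepl("^[A-Z][A-Z0-9]{5,9}$", acc)
  if (any(bad)) {
    stop("not a valid accession after normalization: ",
         paste(sprintf("'%s' (row %d)", raw[bad], which(bad)), collapse = ", "))
  }
  acc
}

#' Read a tab-separated table with a mandatory header
#'
#' All pipeline I/O is plain TSV: UTF-8, header line, tab separator, no
#' quoting, so outputs diff cleanly between runs.
#'
#' @param path file path.
#' @param required_cols character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop("file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  # doubles serialized at 17 significant digits so values round-trip exactly
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a behavioral trial table
#'
#' Expected columns: `rat_id`, `cohort`, `day`, `trial`, `escape_latency_s`.
#'
#' @param path TSV file path.
#' @return data.frame with validated types.
#' @export
read_behavior <- function(path) {
  df <- read_tsv(path, c("rat_id", "cohort", "day", "trial", "escape_latency_s"))
  validate_behavior(df)
}

validate_behavior <- function(df) {
  stopifnot(is.numeric(df$escape_latency_s), is.numeric(df$day),
            is.numeric(df$trial))
  if (any(df$escape_latency_s < 0)) stop("negative escape latency in input")
  key <- paste(df$rat_id, df$day, df$trial, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (rat_id, day, trial) rows in behavioral table")
  df
}

#' Read a replicate-level protein quantification table
#'
#' Expected columns: `rat_id`, `cohort`, `accession`, `tech_rep`, `auc`.
#' A row means the protein was detected in that technical replicate; absence
#' of a row means no detection (zero-AUC rows are not accepted).
#'
#' @param path TSV file path.
#' @return data.frame with validated types.
#' @export
read_quant <- function(path) {
  df <- read_tsv(path, c("rat_id", "cohort", "accession", "tech_rep", "auc"))
  validate_quant(df)
}

validate_quant <- function(df) {
  stopifnot(is.numeric(df$auc), is.numeric(df$tech_rep))
  if (any(df$auc <= 0)) stop("AUC values must be positive (absence = no row)")
  key <- paste(df$rat_id, df$accession, df$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (rat_id, accession, tech_rep) rows in quantification table")
  }
  df
}

#' Read a UPS function-annotation table
#'
#' Expected columns: `accession`, `function_label`, `impact_class`, one row
#' per ubiquitin-related function of a protein.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_ups_annotations <- function(path) {
  df <- read_tsv(path, c("accession", "function_label", "impact_class"))
  bad <- setdiff(unique(df$impact_class), names(ups_impact_values()))
  if (length(bad) > 0) stop("unknown impact class: ", paste(bad, collapse = ", "))
  df
}

#' Read a GO annotation table
#'
#' Expected columns: `accession`, `go_id`; flat accession-to-term map, no
#' ontology traversal.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_go_annotations <- function(path) {
  read_tsv(path, c("accession", "go_id"))
}

#' Read a UPS reference accession list
#'
#' Plain text, one accession per line.
#'
#' @param path file path.
#' @return character vector of normalized accessions.
#' @export
read_ups_reference <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  normalize_accession(raw[nzchar(trimws(raw))])
}
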