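#' Per-process annotation percentages for one signature
#'
#' For every GO process annotated to at least one signature member, the
#' percentage of the signature linked to that process. Two denominator
#' conventions are offered: `"mappable"` divides by the number of signature
#' members carrying at least one GO annotation (the convention of
#' database-backed enrichment tools, and the default), `"signature"` divides
#' by the full signature size, so unannotated members dilute every
#' percentage.
#'
#' @param members character vector of signature accessions, nonempty.
#' @param go_map data.frame with columns `accession`, `go_id`.
#' @param denominator `"mappable"` or `"signature"`.
#' @return data.frame with columns `go_id`, `n_members`, `percentage`,
#'   sorted by decreasing percentage.
#' @export
process_percentages <- function(members, go_map,
                                denominator = c("mappable", "signature")) {
  denominator <- match.arg(denominator)
  members <- unique(as.character(members))
  if (length(members) == 0) stop("signature is empty")
  stopifnot(all(c("accession", "go_id") %in% names(go_map)))
  ann <- unique(go_map[go_map$accession %in% members, c("accession", "go_id")])
  denom <- switch(denominator,
                  mappable = length(unique(ann$accession)),
                  signature = length(members))
  if (nrow(ann) == 0) {
    return(data.frame(go_id = character(), n_members = integer(),
                      percentage = numeric()))
  }
  counts <- table(ann$go_id)
  out <- data.frame(go_id = names(counts),
                    n_members = as.integer(counts),
                    percentage = 100 * as.integer(counts) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percentage, out$go_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Process inclusion criterion
#'
#' A GO process is retained when at least `min_signatures` of the signatures
#' reach `min_pct` percent of members linked to it (both bounds inclusive).
#'
#' @param percentages numeric vector, one percentage per signature (use 0 for
#'   a signature in which the process does not occur).
#' @param min_pct percentage bound (default 10).
#' @param min_signatures minimum number of qualifying signatures (default 2).
#' @return logical.
#' @export
apply_inclusion <- function(percentages, min_pct = 10, min_signatures = 2) {
  stopifnot(is.numeric(percentages), all(percentages >= 0),
            all(percentages <= 100))
  sum(percentages >= min_pct) >= min_signatures
}

#' Screen GO processes across the four signatures
#'
#' Computes per-signature percentages for every process seen in any
#' signature and applies the inclusion criterion.
#'
#' @param signature_sets named list of four character vectors of accessions;
#'   names must be `SHAM_ONLY`, `TEM`, `SMI`, `PSM`.
#' @param go_map data.frame with columns `accession`, `go_id`.
#' @param min_pct,min_signatures see [apply_inclusion()].
#' @param denominator see [process_percentages()].
#' @return data.frame with columns `go_id`, `pct_sham`, `pct_tem`, `pct_smi`,
#'   `pct_psm`, `included`.
#' @export
enrichment_table <- function(signature_sets, go_map, min_pct = 10,
                             min_signatures = 2,
                             denominator = c("mappable", "signature")) {
  denominator <- match.arg(denominator)
  need <- c("SHAM_ONLY", "TEM", "SMI", "PSM")
  stopifnot(all(need %in% names(signature_sets)))
  pcts <- lapply(signature_sets[need], process_percentages, go_map = go_map,
                 denominator = denominator)
  go_ids <- sort(unique(unlist(lapply(pcts, `[[`, "go_id"))))
  pct_of <- function(p, id) {
    v <- p$percentage[match(id, p$go_id)]
    ifelse(is.na(v), 0, v)
  }
  out <- data.frame(
    go_id = go_ids,
    pct_sham = pct_of(pcts$SHAM_ONLY, go_ids),
    pct_tem = pct_of(pcts$TEM, go_ids),
    pct_smi = pct_of(pcts$SMI, go_ids),
    pct_psm = pct_of(pcts$PSM, go_ids),
    stringsAsFactors = FALSE)
  out$included <- apply(out[, c("pct_sham", "pct_tem", "pct_smi", "pct_psm")],
                        1, apply_inclusion, min_pct = min_pct,
                        min_signatures = min_signatures)
  out
}
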