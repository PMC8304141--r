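# Impact values for ubiquitin-regulated function classes. Primary
# (de)ubiquitination activity scores a full point; functions adjacent to the
# pathway (ligase components, proteasome subunits, catabolic regulators)
# half a point; proteins whose impact is unconfirmed score zero.
ups_impact_values <- function() {
  c(PRIMARY_UBIQ = 1, PRIMARY_DEUBIQ = -1,
    NONPRIMARY_UBIQ = 0.5, NONPRIMARY_DEUBIQ = -0.5,
    AMBIVALENT = 0)
}

#' Overlap of a signature with the UPS reference set
#'
#' Reports how many signature members belong to the ubiquitin-proteasome
#' system reference list, as a count out of the signature size and as a
#' percentage. Percentages are rounded half away from zero — to the nearest
#' integer for single signatures and to one decimal for combined (union)
#' signatures, matching the reporting convention for the two kinds of
#' column.
#'
#' @param members character vector of signature accessions, nonempty.
#' @param ups_reference character vector of UPS accessions.
#' @param combined logical: is this a combined (union-of-two) signature?
#' @return list with `ups_members` (sorted), `k`, `n`, `percent` (rounded),
#'   `formatted` (text `"k/n (p%)"`).
#' @export
match_ups <- function(members, ups_reference, combined = FALSE) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("signature is empty")
  hits <- sort(intersect(members, ups_reference))
  k <- length(hits)
  n <- length(members)
  digits <- if (combined) 1L else 0L
  pct <- round_half_up(100 * k / n, digits)
  fmt <- sprintf("%d/%d (%s%%)", k, n,
                 formatC(pct, format = "f", digits = digits))
  list(ups_members = hits, k = k, n = n, percent = pct, formatted = fmt)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Union of two signatures
#'
#' Phenotype-level signatures combine two presence/absence signatures, e.g.
#' the impaired phenotype is the union of the exposure-marker and
#' impairment signatures, and the functional phenotype the union of the
#' exposure-marker and preservation signatures.
#'
#' @param members_a,members_b character vectors of accessions.
#' @return sorted, deduplicated union.
#' @export
combine_signatures <- function(members_a, members_b) {
  sort(union(as.character(members_a), as.character(members_b)))
}

#' Ubiquitin-impact score of one protein
#'
#' Sums the impact values of every ubiquitin-regulated function listed for
#' the protein: +1 per primary ubiquitination function, -1 per primary
#' deubiquitination function, +/-0.5 for non-primary functions, 0 for
#' functions of unconfirmed impact. Scoring is per function instance, so a
#' protein listing two primary ubiquitination functions contributes +2.
#'
#' @param impact_classes character vector of impact class labels, one per
#'   function instance; must be nonempty.
#' @return numeric score.
#' @export
protein_score <- function(impact_classes) {
  stopifnot(length(impact_classes) >= 1)
  vals <- ups_impact_values()[impact_classes]
  if (anyNA(vals)) {
    stop("unknown impact class: ",
         paste(unique(impact_classes[is.na(vals)]), collapse = ", "))
  }
  sum(vals)
}

#' Net ubiquitin homeostasis score of a signature
#'
#' Totals the per-protein impact scores over the signature members matched
#' to the UPS annotation table. Members without an annotation contribute 0
#' (with a warning), mirroring the tolerance of proteins whose role in the
#' pathway is unconfirmed. A positive net score indicates a
#' pro-ubiquitination balance, a negative one a pro-deubiquitination
#' balance.
#'
#' @param members character vector of signature accessions (typically the
#'   UPS-matched members from [match_ups()]).
#' @param annotations data.frame with columns `accession`, `function_label`,
#'   `impact_class`, one row per function instance.
#' @return list with `net_score` and `direction`
#'   (`"PRO_UBIQUITINATION"`, `"PRO_DEUBIQUITINATION"` or `"NEUTRAL"`).
#' @export
homeostasis_score <- function(members, annotations) {
  members <- unique(as.character(members))
  stopifnot(all(c("accession", "impact_class") %in% names(annotations)))
  unannotated <- setdiff(members, annotations$accession)
  if (length(unannotated) > 0) {
    warning("no UPS annotation for ", length(unannotated),
            " member(s); they score 0: ",
            paste(utils::head(unannotated, 5), collapse = ", "))
  }
  scored <- intersect(members, annotations$accession)
  net <- sum(vapply(scored, function(acc) {
    protein_score(annotations$impact_class[annotations$accession == acc])
  }, numeric(1)))
  direction <- if (net > 0) "PRO_UBIQUITINATION" else
    if (net < 0) "PRO_DEUBIQUITINATION" else "NEUTRAL"
  list(net_score = net, direction = direction)
}
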