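#' Path to a bundled data file
#'
#' @param filename file name under the package's `extdata` directory; empty
#'   to list the directory.
#' @return absolute path.
#' @export
protsig_extdata <- function(filename = "") {
  system.file("extdata", filename, package = "protsig", mustWork = TRUE)
}

# expected shapes of the transcribed printed tables, used as load-time
# integrity checks
fixture_spec <- function() {
  list(
    SHAM_ONLY = list(file = "sham_only_signature.tsv", rows = 88, unique = 88, ups = 15),
    TEM       = list(file = "tem_signature.tsv",       rows = 20, unique = 20, ups = 5),
    SMI       = list(file = "smi_signature.tsv",       rows = 73, unique = 37, ups = 10),
    PSM       = list(file = "psm_signature.tsv",       rows = 55, unique = 41, ups = 7)
  )
}

#' Load the transcribed signature tables
#'
#' Loads the four published signature tables bundled with the package (sham
#' only, exposure marker, impairment, preservation), each with a
#' `membership_class` column (`UNIQUE` = found only in that signature,
#' `UPREGULATED` = detected more broadly but upregulated against sham,
#' `BOTH` = both marks) and a `ups_matched` flag. Integrity checks run at
#' load: expected row counts, expected `UNIQUE` counts, UPS-flag counts
#' consistent with the published overlap table, valid accession syntax, and
#' pairwise disjointness of the four accession sets.
#'
#' @return named list of data.frames (`SHAM_ONLY`, `TEM`, `SMI`, `PSM`),
#'   each with columns `accession`, `membership_class`, `ups_matched`.
#' @export
load_signature_fixtures <- function() {
  spec <- fixture_spec()
  out <- lapply(spec, function(fx) {
    df <- read_tsv(protsig_extdata(fx$file),
                   c("accession", "membership_class", "ups_matched"))
    df$accession <- normalize_accession(df$accession)
    df$ups_matched <- as.logical(df$ups_matched)
    if (nrow(df) != fx$rows) {
      stop(fx$file, ": expected ", fx$rows, " rows, found ", nrow(df))
    }
    if (sum(df$membership_class == "UNIQUE") != fx$unique) {
      stop(fx$file, ": expected ", fx$unique, " UNIQUE members")
    }
    if (sum(df$ups_matched) != fx$ups) {
      stop(fx$file, ": expected ", fx$ups, " UPS-matched members")
    }
    if (anyDuplicated(df$accession)) stop(fx$file, ": duplicated accession")
    df
  })
  accs <- lapply(out, `[[`, "accession")
  if (length(unlist(accs)) != length(unique(unlist(accs)))) {
    stop("signature fixtures are not pairwise disjoint")
  }
  out
}

#' Load the published UPS overlap columns
#'
#' The published overlap table lists, for each of six signatures (four
#' single plus the impaired and functional phenotype unions), the member
#' accessions matched to the UPS reference.
#'
#' @return data.frame with columns `signature`, `accession`.
#' @export
load_ups_overlap_fixture <- function() {
  df <- read_tsv(protsig_extdata("ups_overlap_published.tsv"),
                 c("signature", "accession"))
  df$accession <- normalize_accession(df$accession)
  df
}

#' Load the bundled UPS reference accession list
#'
#' The union of the published UPS overlap columns; a pluggable stand-in for
#' a full UPS reference database.
#'
#' @return character vector of accessions.
#' @export
load_ups_reference <- function() {
  read_ups_reference(protsig_extdata("ups_reference.txt"))
}
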