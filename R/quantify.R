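#' Presence call for one rat and one protein
#'
#' A protein is "present" in a rat when it is detected in at least two of
#' three technical replicates; for other replicate counts the rule
#' generalizes to at least ceiling(2/3 * n) detections. The per-rat mean AUC
#' is taken over the detected replicates only.
#'
#' @param aucs numeric vector of AUC values, one per replicate in which the
#'   protein was detected (possibly empty).
#' @param n_tech_reps total number of technical replicates run (default 3).
#' @return list with `n_detected`, `n_tech_reps`, `present` (logical) and
#'   `mean_auc` (`NA` when absent).
#' @export
call_presence <- function(aucs, n_tech_reps = 3) {
  stopifnot(is.numeric(n_tech_reps), n_tech_reps >= 1)
  stopifnot(is.numeric(aucs) || length(aucs) == 0)
  if (length(aucs) > n_tech_reps) {
    stop("more detections (", length(aucs), ") than technical replicates (",
         n_tech_reps, ")")
  }
  n_det <- length(aucs)
  present <- n_det >= ceiling(2 / 3 * n_tech_reps)
  list(n_detected = n_det, n_tech_reps = n_tech_reps, present = present,
       mean_auc = if (present) mean(aucs) else NA_real_)
}

#' Biological-replicate inclusion rule
#'
#' A protein enters a cohort's profile only when it is present (per
#' [call_presence()]) in strictly more than `fraction` of the cohort's rats.
#' With the default 2/3, 6 of 8 rats (75%) qualifies and 5 of 8 (62.5%) does
#' not.
#'
#' @param n_present number of rats in which the protein is present.
#' @param n_total number of rats in the cohort (>= 1).
#' @param fraction inclusion fraction, strict lower bound (default 2/3).
#' @return logical.
#' @export
cohort_inclusion <- function(n_present, n_total, fraction = 2 / 3) {
  stopifnot(n_total >= 1, n_present >= 0, n_present <= n_total,
            fraction >= 0, fraction <= 1)
  n_present / n_total > fraction
}

#' Cohort-level abundance for one protein
#'
#' The cohort mean AUC is the mean of the per-rat mean AUCs of the rats in
#' which the protein is present; the SEM uses the sample (n-1) standard
#' deviation. With a single contributing rat the SEM is undefined (`NA`).
#'
#' @param rat_means numeric vector of per-rat mean AUCs (present rats only),
#'   nonempty.
#' @return list with `mean_auc`, `sem_auc`, `n`.
#' @export
aggregate_cohort <- function(rat_means) {
  stopifnot(is.numeric(rat_means))
  if (length(rat_means) == 0) {
    stop("no present rats: this protein must be routed to a sentinel entry")
  }
  n <- length(rat_means)
  list(mean_auc = mean(rat_means),
       sem_auc = if (n > 1) stats::sd(rat_means) / sqrt(n) else NA_real_,
       n = n)
}

#' SEM-versus-mean quality filter
#'
#' Proteins whose cohort SEM strictly exceeds the cohort mean AUC are too
#' variable to quantify and are removed from further analysis. A protein with
#' SEM equal to its mean is kept ("exceeds" is strict), as is a protein with
#' undefined SEM (single contributing rat).
#'
#' @param mean_auc cohort mean AUC (> 0).
#' @param sem_auc cohort SEM, or `NA`.
#' @return logical: keep the protein?
#' @export
sem_filter <- function(mean_auc, sem_auc) {
  stopifnot(is.numeric(mean_auc), mean_auc > 0)
  if (is.na(sem_auc)) return(TRUE)
  sem_auc <= mean_auc
}

#' Per-rat presence calls for a quantification table
#'
#' Applies [call_presence()] to every (rat, accession) pair in the input.
#'
#' @param quant data.frame with columns `rat_id`, `cohort`, `accession`,
#'   `tech_rep`, `auc`.
#' @param n_tech_reps technical replicates run per rat (default 3).
#' @return data.frame with one row per (rat, accession): `rat_id`, `cohort`,
#'   `accession`, `n_detected`, `present`, `mean_auc`.
#' @export
rat_protein_calls <- function(quant, n_tech_reps = 3) {
  validate_quant(quant)
  if (any(quant$tech_rep > n_tech_reps)) {
    stop("tech_rep index exceeds n_tech_reps = ", n_tech_reps)
  }
  key <- interaction(quant$rat_id, quant$accession, drop = TRUE, sep = "\r")
  first <- !duplicated(key)
  n_det <- as.vector(table(key)[levels(key)])
  sums <- tapply(quant$auc, key, sum)[levels(key)]
  idx <- match(levels(key), key)
  present <- n_det >= ceiling(2 / 3 * n_tech_reps)
  data.frame(rat_id = quant$rat_id[idx], cohort = quant$cohort[idx],
             accession = quant$accession[idx],
             n_detected = n_det, present = present,
             mean_auc = ifelse(present, as.vector(sums) / n_det, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build filtered per-cohort protein abundance matrices
#'
#' Runs the full filtering chain on a replicate-level quantification table:
#' per-rat presence calls (two-of-three rule), the >66% biological-replicate
#' inclusion rule, cohort mean/SEM aggregation over present rats, the
#' SEM-exceeds-mean removal, and finally sentinel assignment — a protein that
#' survives in at least one cohort but not in another receives a placeholder
#' entry with `mean_auc = 1` in the cohorts where it is undetectable, so
#' that cross-cohort expression ratios remain defined.
#'
#' @param quant replicate-level quantification data.frame (see [read_quant()]).
#' @param n_tech_reps technical replicates per rat (default 3).
#' @param inclusion_fraction strict biological-replicate inclusion fraction
#'   (default 2/3).
#' @return data.frame with one row per (cohort, accession) for every
#'   accession included somewhere: `cohort`, `accession`, `n_rats_present`,
#'   `n_rats_total`, `mean_auc`, `sem_auc`, `included`, `sentinel`.
#' @export
build_cohort_matrix <- function(quant, n_tech_reps = 3,
                                inclusion_fraction = 2 / 3) {
  calls <- rat_protein_calls(quant, n_tech_reps)
  cohorts <- sort(unique(quant$cohort))
  rats_per_cohort <- lapply(stats::setNames(cohorts, cohorts), function(ch) {
    unique(quant$rat_id[quant$cohort == ch])
  })

  rows <- list()
  for (ch in cohorts) {
    cc <- calls[calls$cohort == ch & calls$present, , drop = FALSE]
    n_total <- length(rats_per_cohort[[ch]])
    for (acc in unique(cc$accession)) {
      means <- cc$mean_auc[cc$accession == acc]
      n_present <- length(means)
      if (!cohort_inclusion(n_present, n_total, inclusion_fraction)) next
      agg <- aggregate_cohort(means)
      if (!sem_filter(agg$mean_auc, agg$sem_auc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = ch, accession = acc, n_rats_present = n_present,
        n_rats_total = n_total, mean_auc = agg$mean_auc,
        sem_auc = agg$sem_auc, included = TRUE, sentinel = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cohort = character(), accession = character(),
               n_rats_present = integer(), n_rats_total = integer(),
               mean_auc = numeric(), sem_auc = numeric(),
               included = logical(), sentinel = logical())

  # sentinel entries: accession included in >= 1 cohort but not this one
  universe <- unique(mat$accession)
  for (ch in cohorts) {
    have <- mat$accession[mat$cohort == ch]
    missing <- setdiff(universe, have)
    if (length(missing) == 0) next
    mat <- rbind(mat, data.frame(
      cohort = ch, accession = missing, n_rats_present = 0L,
      n_rats_total = length(rats_per_cohort[[ch]]), mean_auc = 1,
      sem_auc = NA_real_, included = FALSE, sentinel = TRUE,
      stringsAsFactors = FALSE))
  }
  mat <- mat[order(mat$cohort, mat$accession), , drop = FALSE]
  row.names(mat) <- NULL
  mat
}

#' Included accession set of one cohort
#'
#' @param cohort_matrix output of [build_cohort_matrix()].
#' @param cohort cohort name.
#' @return character vector of accessions included with data (sentinels
#'   excluded — a sentinel marks absence, not detection).
#' @export
included_set <- function(cohort_matrix, cohort) {
  sel <- cohort_matrix$cohort == cohort & cohort_matrix$included
  sort(cohort_matrix$accession[sel])
}
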