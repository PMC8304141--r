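#' Three-way Venn partition of cohort protein sets
#'
#' Partitions the union of the sham, functional and impaired included sets
#' into the seven standard Venn regions, five of which carry the pipeline's
#' signature names: proteins lost in every irradiated cohort (`SHAM_ONLY`),
#' de novo proteins common to both irradiated cohorts (`TEM`, the exposure
#' marker), proteins unique to the impaired cohort (`SMI_UNIQUE`), proteins
#' unique to the functional cohort (`PSM_UNIQUE`) and proteins detected in
#' all three cohorts (`COMMON`). The remaining two regions
#' (`SHAM_FUNCTIONAL`, `SHAM_IMPAIRED`) are reported so the regions cover
#' the universe.
#'
#' @param sham_set,functional_set,impaired_set character vectors of accessions.
#' @return named list of seven character vectors, pairwise disjoint, whose
#'   union equals the union of the inputs.
#' @export
venn_partition <- function(sham_set, functional_set, impaired_set) {
  s <- unique(as.character(sham_set))
  f <- unique(as.character(functional_set))
  i <- unique(as.character(impaired_set))
  list(
    SHAM_ONLY       = sort(setdiff(s, union(f, i))),
    TEM             = sort(setdiff(intersect(f, i), s)),
    SMI_UNIQUE      = sort(setdiff(i, union(s, f))),
    PSM_UNIQUE      = sort(setdiff(f, union(s, i))),
    COMMON          = sort(intersect(s, intersect(f, i))),
    SHAM_FUNCTIONAL = sort(setdiff(intersect(s, f), i)),
    SHAM_IMPAIRED   = sort(setdiff(intersect(s, i), f))
  )
}

#' Expression index of an irradiated cohort relative to sham
#'
#' @param irr_mean_auc mean AUC in the irradiated cohort.
#' @param sham_mean_auc mean AUC in the sham cohort, must be > 0.
#' @param sham_sentinel logical: is the sham value the unit-AUC sentinel for
#'   an undetectable protein? Indices formed against a sentinel are reported
#'   but flagged, since their magnitude is an artifact of the placeholder.
#' @return list with `index` and `sham_sentinel`.
#' @export
expression_index <- function(irr_mean_auc, sham_mean_auc, sham_sentinel = FALSE) {
  stopifnot(is.numeric(irr_mean_auc), is.numeric(sham_mean_auc))
  if (any(sham_mean_auc <= 0)) stop("sham mean AUC must be positive")
  list(index = irr_mean_auc / sham_mean_auc, sham_sentinel = sham_sentinel)
}

#' Direction call from an expression index
#'
#' Upregulated at index >= `fold_up` (default 1.5), downregulated at
#' index <= `fold_down` (default 0.66), otherwise unchanged. Both bounds are
#' inclusive, following the usual reading of the printed thresholds.
#'
#' @param index numeric vector of expression indices.
#' @param fold_up,fold_down fold-change bounds.
#' @return character vector: `"UP"`, `"DOWN"` or `"UNCHANGED"`.
#' @export
classify_regulation <- function(index, fold_up = 1.5, fold_down = 0.66) {
  stopifnot(fold_down < 1, 1 < fold_up)
  ifelse(index >= fold_up, "UP", ifelse(index <= fold_down, "DOWN", "UNCHANGED"))
}

#' Per-protein differential test between sham and an irradiated cohort
#'
#' Two-sided Wilcoxon-Mann-Whitney on the per-rat mean AUCs, sharing the
#' engine used for the behavioral cohort comparison. Groups with fewer than
#' two rats are untestable and return `NA`.
#'
#' @param sham_means,irr_means numeric vectors of per-rat mean AUCs.
#' @return two-sided p-value, or `NA_real_` when either group has < 2 values.
#' @export
test_differential <- function(sham_means, irr_means) {
  if (length(sham_means) < 2 || length(irr_means) < 2) return(NA_real_)
  mw_engine(sham_means, irr_means)$p_value
}

#' Build named protein signatures with membership classes
#'
#' Combines the Venn partition of the included sets with regulation calls:
#' each of the `TEM`, `SMI` and `PSM` signatures carries its Venn-unique
#' members (class `UNIQUE`) plus proteins detected in both the relevant
#' irradiated cohort(s) and sham that are upregulated against sham (index >=
#' `fold_up` with Wilcoxon-Mann-Whitney p < `alpha`; class `UPREGULATED`).
#' `SHAM_ONLY` and `COMMON` carry `UNIQUE`/`COMMON` members only. Indices
#' formed against a sham sentinel never qualify as `UPREGULATED` (those
#' proteins are already `UNIQUE` members). A Benjamini-Hochberg adjusted
#' p-value is reported alongside but plays no role in membership.
#'
#' For `TEM` the upregulation condition must hold in both irradiated cohorts;
#' for `SMI` in the impaired cohort and for `PSM` in the functional cohort.
#'
#' @param cohort_matrix output of [build_cohort_matrix()].
#' @param calls per-rat presence calls from [rat_protein_calls()] (for the
#'   rank tests).
#' @param cohorts named character vector mapping roles to cohort labels,
#'   default `c(sham = "SHAM", functional = "TI_FUNCTIONAL",
#'   impaired = "TI_IMPAIRED")`.
#' @param fold_up upregulation bound (default 1.5).
#' @param fold_down downregulation bound (default 0.66, reported only).
#' @param alpha significance level for the rank test (default 0.05,
#'   uncorrected).
#' @return data.frame with columns `signature`, `accession`,
#'   `membership_class` (`UNIQUE`, `UPREGULATED` or `BOTH`),
#'   `expression_index`, `p_value`, `p_adj`, `sham_sentinel`.
#' @export
build_signatures <- function(cohort_matrix, calls,
                             cohorts = c(sham = "SHAM",
                                         functional = "TI_FUNCTIONAL",
                                         impaired = "TI_IMPAIRED"),
                             fold_up = 1.5, fold_down = 0.66, alpha = 0.05) {
  stopifnot(all(c("sham", "functional", "impaired") %in% names(cohorts)))
  inc <- lapply(cohorts, function(ch) included_set(cohort_matrix, ch))
  part <- venn_partition(inc$sham, inc$functional, inc$impaired)

  cm_row <- function(ch, acc) {
    cohort_matrix[cohort_matrix$cohort == ch & cohort_matrix$accession == acc, ,
                  drop = FALSE]
  }
  rat_means <- function(ch, acc) {
    sel <- calls$cohort == ch & calls$accession == acc & calls$present
    calls$mean_auc[sel]
  }

  # regulation calls for every accession detected in sham and in >= 1
  # irradiated cohort
  reg <- list()
  for (role in c("functional", "impaired")) {
    ch <- cohorts[[role]]
    accs <- intersect(inc$sham, inc[[role]])
    for (acc in accs) {
      sham_mean <- cm_row(cohorts[["sham"]], acc)$mean_auc
      irr_mean <- cm_row(ch, acc)$mean_auc
      ei <- expression_index(irr_mean, sham_mean, sham_sentinel = FALSE)
      p <- test_differential(rat_means(cohorts[["sham"]], acc),
                             rat_means(ch, acc))
      reg[[length(reg) + 1L]] <- data.frame(
        role = role, accession = acc, expression_index = ei$index,
        direction = classify_regulation(ei$index, fold_up, fold_down),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  reg <- if (length(reg)) do.call(rbind, reg) else
    data.frame(role = character(), accession = character(),
               expression_index = numeric(), direction = character(),
               p_value = numeric())
  reg$p_adj <- stats::p.adjust(reg$p_value, method = "BH")

  up_in <- function(role) {
    sel <- reg$role == role & reg$direction == "UP" &
      !is.na(reg$p_value) & reg$p_value < alpha
    reg$accession[sel]
  }
  up_f <- up_in("functional")
  up_i <- up_in("impaired")

  upreg <- list(TEM = intersect(up_f, up_i), SMI = up_i, PSM = up_f)
  unique_members <- list(SHAM_ONLY = part$SHAM_ONLY, TEM = part$TEM,
                         SMI = part$SMI_UNIQUE, PSM = part$PSM_UNIQUE,
                         COMMON = part$COMMON)

  reg_lookup <- function(role, acc) {
    r <- reg[reg$role == role & reg$accession %in% acc, , drop = FALSE]
    r[match(acc, r$accession), , drop = FALSE]
  }
  role_of <- c(TEM = "impaired", SMI = "impaired", PSM = "functional")

  out <- list()
  for (lab in c("SHAM_ONLY", "TEM", "SMI", "PSM", "COMMON")) {
    uni <- unique_members[[lab]]
    ups <- if (lab %in% names(upreg)) upreg[[lab]] else character()
    both <- intersect(uni, ups)   # empty by construction (unique => no sham)
    all_acc <- sort(union(uni, ups))
    if (length(all_acc) == 0) next
    cls <- ifelse(all_acc %in% both, "BOTH",
                  ifelse(all_acc %in% uni, "UNIQUE", "UPREGULATED"))
    if (lab %in% names(role_of)) {
      r <- reg_lookup(role_of[[lab]], all_acc)
      ei <- r$expression_index; pv <- r$p_value; pa <- r$p_adj
    } else {
      ei <- rep(NA_real_, length(all_acc))
      pv <- pa <- rep(NA_real_, length(all_acc))
    }
    out[[lab]] <- data.frame(
      signature = lab, accession = all_acc, membership_class = cls,
      expression_index = ei, p_value = pv, p_adj = pa,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Member accessions of one signature
#'
#' @param signatures data.frame from [build_signatures()] or a loaded table
#'   fixture with `signature`/`accession` columns (fixtures use
#'   `membership_class` without a `signature` column; then all rows count).
#' @param label signature label; ignored when the table has no `signature`
#'   column.
#' @param classes membership classes to keep (default all).
#' @return character vector of accessions.
#' @export
signature_members <- function(signatures, label = NULL,
                              classes = c("UNIQUE", "UPREGULATED", "BOTH")) {
  df <- signatures
  if (!is.null(label) && "signature" %in% names(df)) {
    df <- df[df$signature == label, , drop = FALSE]
  }
  sort(unique(df$accession[df$membership_class %in% classes]))
}
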