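#' Pipeline configuration
#'
#' Bundles input paths and every tunable threshold of the pipeline. The
#' defaults are the published analysis constants: phenotype threshold 0.7 on
#' REL3, fold bounds 1.5/0.66, strict >2/3 biological-replicate inclusion,
#' 5% significance for the rank test, and the >=10%-in->=2-signatures GO
#' inclusion criterion.
#'
#' @param quant path to the replicate-level quantification TSV.
#' @param behavior path to the behavioral trial TSV.
#' @param ups_annotations optional path to a UPS function-annotation TSV.
#' @param go_annotations optional path to a GO annotation TSV.
#' @param ups_reference optional path to a UPS reference accession list;
#'   when `NULL` the accessions of the annotation table define the UPS
#'   universe (the bundled published reference is available via
#'   [load_ups_reference()]).
#' @param output_dir directory for stage outputs (created on run).
#' @param rel3_threshold phenotype threshold (default 0.7).
#' @param fold_up,fold_down regulation bounds (defaults 1.5 and 0.66).
#' @param inclusion_fraction strict biological inclusion fraction (2/3).
#' @param alpha rank-test significance level (0.05).
#' @param min_pct,min_signatures GO inclusion criterion (10, 2).
#' @param day_aggregation day-level ESL rule (`"mean"`, `"min"`, `"median"`).
#' @param n_tech_reps technical replicates per rat (3).
#' @param cohorts named character vector mapping the roles `sham`,
#'   `functional`, `impaired` to cohort labels in the input tables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(quant, behavior, ups_annotations = NULL,
                            go_annotations = NULL, ups_reference = NULL,
                            output_dir = tempfile("protsig_out"),
                            rel3_threshold = 0.7, fold_up = 1.5,
                            fold_down = 0.66, inclusion_fraction = 2 / 3,
                            alpha = 0.05, min_pct = 10, min_signatures = 2,
                            day_aggregation = "mean", n_tech_reps = 3,
                            cohorts = c(sham = "SHAM",
                                        functional = "TI_FUNCTIONAL",
                                        impaired = "TI_IMPAIRED")) {
  stopifnot(rel3_threshold > 0, fold_down < 1, 1 < fold_up,
            inclusion_fraction > 0, inclusion_fraction < 1,
            alpha > 0, alpha < 1, min_pct >= 0, min_signatures >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes behavior scoring, abundance filtering, signature derivation, GO
#' screening (when annotations are given) and UPS overlap/homeostasis
#' scoring (when a reference is given), writing one TSV per stage plus a
#' JSON summary to `config$output_dir`. Per-stage discard counts are logged
#' to standard error.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with elements `rel3`, `cohort_comparison`,
#'   `cohort_matrix`, `signatures`, `enrichment` (or `NULL`), `ups` (or
#'   `NULL`) and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$quant, config$behavior, config$ups_annotations,
              config$go_annotations, config$ups_reference)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  # --- behavior ---
  behavior <- read_behavior(config$behavior)
  rel3 <- rel3_table(behavior, config$day_aggregation, config$rel3_threshold)
  sham_rel3 <- rel3$rel3[rel3$cohort == config$cohorts[["sham"]]]
  irr_rel3 <- rel3$rel3[rel3$cohort != config$cohorts[["sham"]]]
  cmp <- if (length(sham_rel3) && length(irr_rel3)) {
    compare_cohorts(irr_rel3, sham_rel3)
  } else NULL
  stage_log("behavior", "%d rats scored; %d impaired",
            nrow(rel3), sum(rel3$phenotype == "IMPAIRED"))
  write_tsv(rel3[, c("rat_id", "cohort", "rel3", "phenotype")],
            file.path(config$output_dir, "rel3.tsv"))

  # --- quantify ---
  quant <- read_quant(config$quant)
  calls <- rat_protein_calls(quant, config$n_tech_reps)
  cm <- build_cohort_matrix(quant, config$n_tech_reps,
                            config$inclusion_fraction)
  n_candidate <- length(unique(quant$accession))
  n_kept <- length(unique(cm$accession))
  stage_log("quantify", "%d accessions observed; %d included in >=1 cohort; %d discarded",
            n_candidate, n_kept, n_candidate - n_kept)
  write_tsv(cm, file.path(config$output_dir, "cohort_matrix.tsv"))

  # --- signatures ---
  sig <- build_signatures(cm, calls, cohorts = config$cohorts,
                          fold_up = config$fold_up,
                          fold_down = config$fold_down, alpha = config$alpha)
  sizes <- table(sig$signature)
  stage_log("signatures", "%s",
            paste(names(sizes), as.integer(sizes), sep = "=", collapse = " "))
  write_tsv(sig, file.path(config$output_dir, "signatures.tsv"))

  sig_sets <- lapply(stats::setNames(nm = c("SHAM_ONLY", "TEM", "SMI", "PSM")),
                     function(lab) signature_members(sig, lab,
                                                     classes = "UNIQUE"))

  # --- enrichment ---
  enr <- NULL
  if (!is.null(config$go_annotations)) {
    go_map <- read_go_annotations(config$go_annotations)
    nonempty <- vapply(sig_sets, length, integer(1)) > 0
    if (all(nonempty)) {
      enr <- enrichment_table(sig_sets, go_map, config$min_pct,
                              config$min_signatures)
      stage_log("enrichment", "%d processes screened; %d included",
                nrow(enr), sum(enr$included))
      write_tsv(enr, file.path(config$output_dir, "enrichment.tsv"))
    } else {
      stage_log("enrichment", "skipped: empty signature(s) %s",
                paste(names(nonempty)[!nonempty], collapse = ","))
    }
  }

  # --- ups ---
  ups <- NULL
  if (!is.null(config$ups_reference) || !is.null(config$ups_annotations)) {
    ann <- if (!is.null(config$ups_annotations)) {
      read_ups_annotations(config$ups_annotations)
    }
    # an explicit reference wins; otherwise the annotated accessions define
    # the UPS universe
    ref <- if (!is.null(config$ups_reference)) {
      read_ups_reference(config$ups_reference)
    } else {
      unique(ann$accession)
    }
    combos <- list(IMPAIRED = combine_signatures(sig_sets$TEM, sig_sets$SMI),
                   FUNCTIONAL = combine_signatures(sig_sets$TEM, sig_sets$PSM))
    all_sets <- c(sig_sets, combos)
    combined <- c(rep(FALSE, length(sig_sets)), rep(TRUE, length(combos)))
    keep <- vapply(all_sets, length, integer(1)) > 0
    overlaps <- mapply(function(mem, comb) match_ups(mem, ref, comb),
                       all_sets[keep], combined[keep], SIMPLIFY = FALSE)
    overlap_df <- do.call(rbind, lapply(names(overlaps), function(lab) {
      o <- overlaps[[lab]]
      data.frame(signature = lab, k = o$k, n = o$n, percent = o$percent,
                 formatted = o$formatted, stringsAsFactors = FALSE)
    }))
    scores <- NULL
    if (!is.null(config$ups_annotations)) {
      scores <- do.call(rbind, lapply(names(overlaps), function(lab) {
        hs <- suppressWarnings(
          homeostasis_score(overlaps[[lab]]$ups_members, ann))
        data.frame(signature = lab, net_score = hs$net_score,
                   direction = hs$direction, stringsAsFactors = FALSE)
      }))
      write_tsv(scores, file.path(config$output_dir, "ups_scores.tsv"))
    }
    stage_log("ups", "%s", paste(overlap_df$signature, overlap_df$formatted,
                                 sep = ": ", collapse = "; "))
    write_tsv(overlap_df, file.path(config$output_dir, "ups_overlap.tsv"))
    ups <- list(overlap = overlap_df, scores = scores)
  }

  summary <- list(
    n_rats = nrow(rel3),
    n_impaired = sum(rel3$phenotype == "IMPAIRED"),
    rel3_sham = if (length(sham_rel3)) cohort_summary(sham_rel3) else NULL,
    rel3_irradiated = if (length(irr_rel3)) cohort_summary(irr_rel3) else NULL,
    rel3_p_value = if (!is.null(cmp)) cmp$p_value else NULL,
    signature_sizes = as.list(sizes),
    unique_sizes = lapply(sig_sets, length),
    ups_overlap = if (!is.null(ups)) ups$overlap else NULL,
    ups_scores = if (!is.null(ups)) ups$scores else NULL)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")

  invisible(list(rel3 = rel3, cohort_comparison = cmp, cohort_matrix = cm,
                 signatures = sig, enrichment = enr, ups = ups,
                 summary = summary))
}
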