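#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: three
#' cohorts (8 sham, 4 irradiated-functional, 4 irradiated-impaired rats by
#' default), triplicate technical replicates, log-normal AUC abundances,
#' per-replicate Bernoulli detection, cohort-structured missingness that
#' plants known presence/absence signatures, and bimodal REL3 outcomes in
#' irradiated animals.
#'
#' @param n_sham,n_functional,n_impaired rats per cohort.
#' @param n_proteins size of the accession universe.
#' @param n_tech_reps technical replicates per rat (default 3).
#' @param baseline_auc_log_mean,baseline_auc_log_sd log10-scale mean and sd
#'   of true protein abundances (AUC units span orders of magnitude).
#' @param tech_cv coefficient of variation of replicate AUCs around the true
#'   rat-level abundance (log-normal noise; 0 gives noiseless replicates).
#' @param detect_prob_present per-replicate detection probability for a
#'   protein truly expressed in the rat's cohort.
#' @param detect_prob_absent per-replicate spurious detection probability
#'   for a protein not expressed in the cohort.
#' @param planted_fraction_sham_only,planted_fraction_tem,planted_fraction_smi,planted_fraction_psm
#'   fractions of the universe assigned to each planted presence/absence
#'   signature; the defaults mirror the proportions of the published study
#'   (roughly 0.15/0.04/0.08/0.09 of the detected universe).
#' @param noise_fraction fraction of the universe expressed in no cohort
#'   (detectable only spuriously); the remainder after all planted fractions
#'   is expressed in every cohort.
#' @param planted_fraction_up,planted_fraction_down fractions of the
#'   commonly-expressed proteins given a planted fold change (x3 and x1/3)
#'   in both irradiated cohorts.
#' @param rel3_mean_functional,rel3_mean_impaired,rel3_sd REL3 distribution
#'   per phenotype. Sham and irradiated-functional rats share the functional
#'   mean. Because the phenotype is defined by the REL3 cutoff, draws are
#'   taken from the normal truncated to the phenotype's side of
#'   `rel3_threshold` (a "functional" rat with REL3 above the cutoff would
#'   contradict its own definition).
#' @param rel3_threshold phenotype cutoff used to truncate the REL3 draws
#'   (default 0.7, the classification threshold).
#' @param day1_range range (seconds) of uniform day-1 trial latencies.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_sham = 8, n_functional = 4, n_impaired = 4,
                              n_proteins = 1000, n_tech_reps = 3,
                              baseline_auc_log_mean = 6,
                              baseline_auc_log_sd = 0.8,
                              tech_cv = 0.1,
                              detect_prob_present = 0.95,
                              detect_prob_absent = 0.02,
                              planted_fraction_sham_only = 0.15,
                              planted_fraction_tem = 0.04,
                              planted_fraction_smi = 0.08,
                              planted_fraction_psm = 0.09,
                              noise_fraction = 0.05,
                              planted_fraction_up = 0.03,
                              planted_fraction_down = 0.03,
                              rel3_mean_functional = 0.5,
                              rel3_mean_impaired = 1.5,
                              rel3_sd = 0.1,
                              rel3_threshold = 0.7,
                              day1_range = c(60, 180),
                              seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(planted_fraction_sham_only, planted_fraction_tem,
          planted_fraction_smi, planted_fraction_psm, noise_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("planted fractions must lie in [0,1] and sum to at most 1")
  }
  if (any(c(planted_fraction_up, planted_fraction_down) < 0) ||
      planted_fraction_up + planted_fraction_down > 1) {
    stop("regulation fractions must be nonnegative and sum to at most 1")
  }
  stopifnot(n_sham > 0, n_functional > 0, n_impaired > 0, n_proteins > 0,
            n_tech_reps >= 1, tech_cv >= 0,
            detect_prob_present >= 0, detect_prob_present <= 1,
            detect_prob_absent >= 0, detect_prob_absent <= 1,
            rel3_sd >= 0, length(day1_range) == 2, day1_range[1] > 0,
            day1_range[2] >= day1_range[1])
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulation_config"
  cfg
}

# log-normal multiplier with unit mean and given coefficient of variation
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Produces the three pipeline input tables (replicate-level protein
#' quantification, behavioral trials, UPS function annotations) together
#' with the planted truth, so every downstream stage can be checked against
#' a known answer. Proteins are assigned to presence/absence signatures
#' (expressed only in the cohorts their label implies); commonly expressed
#' proteins may carry a planted x3 or x1/3 fold change in the irradiated
#' cohorts; detection is an independent Bernoulli per technical replicate;
#' REL3 is simulated directly and day-3 latencies set to REL3 times the
#' day-1 latencies.
#'
#' @param config a [simulation_config()].
#' @return list with elements `quant`, `behavior`, `ups_annotations`
#'   (data.frames in the pipeline input dialects) and `truth` (list with
#'   `assignment`, `true_phenotype`, `true_regulation`, all named vectors).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  # deterministic substreams per table
  sub <- sample.int(.Machine$integer.max - 1L, 4)

  n <- config$n_proteins
  accs <- sprintf("SYN%05d", seq_len(n))

  set.seed(sub[1])
  counts <- c(
    SHAM_ONLY = round(config$planted_fraction_sham_only * n),
    TEM = round(config$planted_fraction_tem * n),
    SMI = round(config$planted_fraction_smi * n),
    PSM = round(config$planted_fraction_psm * n),
    NOISE = round(config$noise_fraction * n))
  counts["COMMON"] <- n - sum(counts)
  assignment <- sample(rep(names(counts), counts))
  names(assignment) <- accs

  common <- accs[assignment == "COMMON"]
  n_up <- round(config$planted_fraction_up * length(common))
  n_down <- round(config$planted_fraction_down * length(common))
  reg_pick <- sample(common, n_up + n_down)
  true_regulation <- stats::setNames(rep("UNCHANGED", n), accs)
  true_regulation[reg_pick[seq_len(n_up)]] <- "UP"
  true_regulation[reg_pick[n_up + seq_len(n_down)]] <- "DOWN"

  rats <- data.frame(
    rat_id = c(sprintf("SHAM%02d", seq_len(config$n_sham)),
               sprintf("TIF%02d", seq_len(config$n_functional)),
               sprintf("TII%02d", seq_len(config$n_impaired))),
    cohort = rep(c("SHAM", "TI_FUNCTIONAL", "TI_IMPAIRED"),
                 c(config$n_sham, config$n_functional, config$n_impaired)),
    stringsAsFactors = FALSE)
  true_phenotype <- stats::setNames(
    ifelse(rats$cohort == "TI_IMPAIRED", "IMPAIRED", "FUNCTIONAL"),
    rats$rat_id)

  expressed_in <- function(label, cohort) {
    switch(label,
           SHAM_ONLY = cohort == "SHAM",
           TEM = cohort != "SHAM",
           SMI = cohort == "TI_IMPAIRED",
           PSM = cohort == "TI_FUNCTIONAL",
           COMMON = TRUE,
           NOISE = FALSE)
  }
  reg_mult <- function(acc, cohort) {
    if (cohort == "SHAM") return(1)
    switch(true_regulation[[acc]], UP = 3, DOWN = 1 / 3, UNCHANGED = 1)
  }

  set.seed(sub[2])
  base_auc <- 10^stats::rnorm(n, config$baseline_auc_log_mean,
                              config$baseline_auc_log_sd)
  names(base_auc) <- accs

  quant_parts <- vector("list", nrow(rats))
  for (r in seq_len(nrow(rats))) {
    cohort <- rats$cohort[r]
    expr <- vapply(assignment, expressed_in, logical(1), cohort = cohort)
    p_det <- ifelse(expr, config$detect_prob_present, config$detect_prob_absent)
    det <- matrix(stats::runif(n * config$n_tech_reps) < p_det,
                  nrow = n, ncol = config$n_tech_reps)
    idx <- which(det, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    acc_i <- accs[idx[, 1]]
    mult <- vapply(acc_i, reg_mult, numeric(1), cohort = cohort)
    auc <- base_auc[idx[, 1]] * mult *
      lnorm_noise(nrow(idx), config$tech_cv)
    quant_parts[[r]] <- data.frame(
      rat_id = rats$rat_id[r], cohort = cohort, accession = acc_i,
      tech_rep = idx[, 2], auc = unname(auc), stringsAsFactors = FALSE)
  }
  quant <- do.call(rbind, quant_parts)
  quant <- quant[order(quant$rat_id, quant$accession, quant$tech_rep), ]
  row.names(quant) <- NULL

  set.seed(sub[3])
  impaired <- true_phenotype[rats$rat_id] == "IMPAIRED"
  rel3_mean <- ifelse(impaired, config$rel3_mean_impaired,
                      config$rel3_mean_functional)
  # truncated normal on the phenotype's side of the cutoff (inverse-cdf)
  lo <- ifelse(impaired, config$rel3_threshold, 0.01)
  hi <- ifelse(impaired, Inf, config$rel3_threshold)
  plo <- stats::pnorm(lo, rel3_mean, config$rel3_sd)
  phi <- stats::pnorm(hi, rel3_mean, config$rel3_sd)
  u <- stats::runif(nrow(rats), plo, phi)
  rel3 <- stats::qnorm(u, rel3_mean, config$rel3_sd)
  beh_parts <- vector("list", nrow(rats))
  for (r in seq_len(nrow(rats))) {
    d1 <- stats::runif(2, config$day1_range[1], config$day1_range[2])
    beh_parts[[r]] <- data.frame(
      rat_id = rats$rat_id[r], cohort = rats$cohort[r],
      day = rep(1:3, each = 2), trial = rep(1:2, 3),
      escape_latency_s = c(d1, sqrt(rel3[r]) * d1, rel3[r] * d1),
      stringsAsFactors = FALSE)
  }
  behavior <- do.call(rbind, beh_parts)
  row.names(behavior) <- NULL

  # UPS annotations: a tenth of the universe gets 1-3 ubiquitin-related
  # function instances with random impact classes
  set.seed(sub[4])
  n_ups <- max(1, round(0.1 * n))
  ups_accs <- sort(sample(accs, n_ups))
  classes <- names(ups_impact_values())
  ann_parts <- lapply(ups_accs, function(acc) {
    k <- sample(1:3, 1)
    data.frame(accession = acc,
               function_label = sprintf("%s_fn%d", acc, seq_len(k)),
               impact_class = sample(classes, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ups_annotations <- do.call(rbind, ann_parts)
  row.names(ups_annotations) <- NULL

  list(quant = quant, behavior = behavior, ups_annotations = ups_annotations,
       truth = list(assignment = assignment,
                    true_phenotype = true_phenotype,
                    true_regulation = true_regulation))
}

#' Write a synthetic dataset to pipeline input files
#'
#' Writes the quantification, behavioral and UPS-annotation TSVs in the
#' pipeline input dialects, plus the planted truth assignment
#' (`accession`/`assignment`).
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(quant = file.path(dir, "quant.tsv"),
             behavior = file.path(dir, "behavior.tsv"),
             ups_annotations = file.path(dir, "ups_annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(dataset$quant, paths["quant"])
  write_tsv(dataset$behavior, paths["behavior"])
  write_tsv(dataset$ups_annotations, paths["ups_annotations"])
  write_tsv(data.frame(accession = names(dataset$truth$assignment),
                       assignment = unname(dataset$truth$assignment),
                       stringsAsFactors = FALSE), paths["truth"])
  invisible(paths)
}

#' Recovery metrics of recovered signatures against the planted truth
#'
#' @param truth the `truth` element of [generate_dataset()] output.
#' @param recovered named list of character vectors: recovered accession
#'   sets per signature label (labels drawn from the planted assignment
#'   labels).
#' @return data.frame with one row per label in `recovered`: `label`,
#'   `n_planted`, `n_recovered`, `n_correct`, `precision` (`NA` when
#'   nothing was recovered), `recall`.
#' @export
truth_report <- function(truth, recovered) {
  stopifnot(is.list(recovered), !is.null(names(recovered)))
  universe <- names(truth$assignment)
  stray <- setdiff(unlist(recovered, use.names = FALSE), universe)
  if (length(stray) > 0) {
    stop("recovered accessions outside the truth universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  rows <- lapply(names(recovered), function(lab) {
    planted <- universe[truth$assignment == lab]
    rec <- unique(recovered[[lab]])
    ok <- length(intersect(rec, planted))
    data.frame(label = lab, n_planted = length(planted),
               n_recovered = length(rec), n_correct = ok,
               precision = if (length(rec) > 0) ok / length(rec) else NA_real_,
               recall = if (length(planted) > 0) ok / length(planted) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
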