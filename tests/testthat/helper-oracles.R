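# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# choose(n_x + n_y, n_x) group assignments of the pooled values (tie-free
# samples only). U is counted as pairs (x_i > y_j).
perm_mw_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  nn <- nx * length(y)
  lo <- min(u_obs, nn - u_obs)
  hi <- nn - lo
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(us <= lo | us >= hi)
}

# Count-based per-protein UPS score: score determined solely by how many
# functions of each class the protein lists.
count_score <- function(classes) {
  tab <- table(factor(classes, levels = c("PRIMARY_UBIQ", "PRIMARY_DEUBIQ",
                                          "NONPRIMARY_UBIQ",
                                          "NONPRIMARY_DEUBIQ", "AMBIVALENT")))
  as.numeric(tab["PRIMARY_UBIQ"] - tab["PRIMARY_DEUBIQ"] +
               0.5 * tab["NONPRIMARY_UBIQ"] - 0.5 * tab["NONPRIMARY_DEUBIQ"])
}

# Replicate-level quantification rows for one rat from a named list
# accession -> vector of (tech_rep = auc) detections.
quant_rows <- function(rat_id, cohort, detections) {
  do.call(rbind, lapply(names(detections), function(acc) {
    d <- detections[[acc]]
    data.frame(rat_id = rat_id, cohort = cohort, accession = acc,
               tech_rep = as.integer(names(d)), auc = unname(d),
               stringsAsFactors = FALSE)
  }))
}

# Noiseless generator configuration: deterministic detection, no replicate
# noise, so the pipeline must recover the planted truth exactly.
noiseless_config <- function(n_proteins = 200, seed = 7, ...) {
  simulation_config(n_proteins = n_proteins, tech_cv = 0,
                    detect_prob_present = 1, detect_prob_absent = 0,
                    seed = seed, ...)
}

run_synthetic_pipeline <- function(dataset, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_dataset(dataset, dir)
  cfg <- pipeline_config(quant = paths[["quant"]],
                         behavior = paths[["behavior"]],
                         output_dir = file.path(dir, "out"), ...)
  suppressMessages(run_pipeline(cfg))
}
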