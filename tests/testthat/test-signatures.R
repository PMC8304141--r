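test_that("Venn partition computes the named regions by set algebra", {
  p <- venn_partition(c("a", "b", "c"), c("b", "d"), c("b", "e"))
  expect_equal(p$COMMON, "b")
  expect_equal(p$SHAM_ONLY, c("a", "c"))
  expect_equal(p$TEM, character(0))
  expect_equal(p$PSM_UNIQUE, "d")
  expect_equal(p$SMI_UNIQUE, "e")

  s <- c("x", "y", "z")
  p <- venn_partition(s, s, s)
  expect_equal(p$COMMON, s)
  expect_true(all(lengths(p[names(p) != "COMMON"]) == 0))
})

test_that("Venn regions are disjoint and cover the universe (random sets)", {
  set.seed(99)
  pool <- sprintf("P%03d", 1:60)
  for (i in 1:30) {
    s <- sample(pool, rbinom(1, 40, 0.5))
    f <- sample(pool, rbinom(1, 40, 0.5))
    im <- sample(pool, rbinom(1, 40, 0.5))
    p <- venn_partition(s, f, im)
    all_members <- unlist(p, use.names = FALSE)
    expect_equal(anyDuplicated(all_members), 0)
    expect_setequal(all_members, union(s, union(f, im)))
    expect_length(intersect(p$SHAM_ONLY, union(f, im)), 0)
  }
})

test_that("expression index and direction calls follow the fold bounds", {
  expect_equal(expression_index(150, 100)$index, 1.5)
  expect_equal(classify_regulation(1.5), "UP")
  expect_equal(classify_regulation(0.66), "DOWN")
  expect_equal(classify_regulation(1.0), "UNCHANGED")
  expect_equal(classify_regulation(expression_index(66, 100)$index), "DOWN")
  expect_error(expression_index(100, 0), "positive")
  expect_true(expression_index(100, 1, sham_sentinel = TRUE)$sham_sentinel)
})

test_that("differential test matches enumeration and handles degenerate groups", {
  expect_equal(test_differential(c(1, 2, 3, 4), c(10, 11, 12, 13)), 2 / 70)
  expect_equal(test_differential(c(1, 2, 3, 4), c(10, 11, 12, 13)),
               perm_mw_p(c(1, 2, 3, 4), c(10, 11, 12, 13)))
  expect_true(is.na(test_differential(5, c(6, 7))))
  set.seed(44)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    if (n1 + n2 > 10) next
    v <- sample(seq(1, 500), n1 + n2)
    expect_equal(test_differential(v[1:n1], v[-(1:n1)]),
                 perm_mw_p(v[1:n1], v[-(1:n1)]), tolerance = 1e-12)
  }
})

test_that("identical groups are not called different", {
  expect_equal(test_differential(c(1, 2, 3), c(1, 2, 3)), 1.0)
})

test_that("signatures combine Venn-unique and upregulated members", {
  # 3 rats/cohort; u1 impaired-only, u2 functional-only, t1 both-irradiated,
  # c1 common upregulated x4 in both TI cohorts, c2 common unchanged
  mk <- function(rat, cohort, base) {
    quant_rows(rat, cohort, lapply(base, function(v)
      stats::setNames(v * c(0.98, 1, 1.02), 1:3)))
  }
  sham_base <- list(c1 = 100, c2 = 200, s1 = 50)
  quant <- rbind(
    mk("s1", "SHAM", lapply(sham_base, `*`, 1.0)),
    mk("s2", "SHAM", lapply(sham_base, `*`, 1.1)),
    mk("s3", "SHAM", lapply(sham_base, `*`, 0.9)),
    mk("f1", "TI_FUNCTIONAL", list(c1 = 410, c2 = 205, u2 = 30, t1 = 60)),
    mk("f2", "TI_FUNCTIONAL", list(c1 = 400, c2 = 195, u2 = 32, t1 = 62)),
    mk("f3", "TI_FUNCTIONAL", list(c1 = 390, c2 = 210, u2 = 31, t1 = 61)),
    mk("i1", "TI_IMPAIRED", list(c1 = 420, c2 = 190, u1 = 80, t1 = 70)),
    mk("i2", "TI_IMPAIRED", list(c1 = 395, c2 = 200, u1 = 82, t1 = 72)),
    mk("i3", "TI_IMPAIRED", list(c1 = 405, c2 = 198, u1 = 81, t1 = 71)))
  cm <- build_cohort_matrix(quant)
  calls <- rat_protein_calls(quant)
  sig <- build_signatures(cm, calls)

  expect_equal(signature_members(sig, "SMI", "UNIQUE"), "u1")
  expect_equal(signature_members(sig, "PSM", "UNIQUE"), "u2")
  expect_equal(signature_members(sig, "TEM", "UNIQUE"), "t1")
  expect_equal(signature_members(sig, "SHAM_ONLY"), "s1")
  # c1 is ~4x sham in both irradiated cohorts with p < 0.05 (3 vs 3 exact
  # p = 0.1 is NOT significant, so c1 must not be UPREGULATED here)
  expect_equal(perm_mw_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_false("c1" %in% signature_members(sig, "SMI"))
  expect_true(all(c("c1", "c2") %in% signature_members(sig, "COMMON")))
})

test_that("upregulated members require both fold and significance at 4v8", {
  # 8 sham rats vs 4 per irradiated cohort: exact 4v8 Mann-Whitney can
  # reach p = 2/495 < 0.05, so a clean 3x shift qualifies
  set.seed(55)
  mk1 <- function(rat, cohort, vals) {
    quant_rows(rat, cohort, lapply(vals, function(v)
      stats::setNames(v * runif(3, 0.97, 1.03), 1:3)))
  }
  rows <- list()
  for (r in 1:8) rows[[length(rows) + 1]] <-
    mk1(paste0("s", r), "SHAM", list(c1 = 100 * (1 + 0.01 * r), u0 = 40))
  for (r in 1:4) rows[[length(rows) + 1]] <-
    mk1(paste0("f", r), "TI_FUNCTIONAL", list(c1 = 300 * (1 + 0.01 * r), u0 = 41))
  for (r in 1:4) rows[[length(rows) + 1]] <-
    mk1(paste0("i", r), "TI_IMPAIRED", list(c1 = 310 * (1 + 0.01 * r), u0 = 39))
  quant <- do.call(rbind, rows)
  cm <- build_cohort_matrix(quant)
  sig <- build_signatures(cm, rat_protein_calls(quant))
  expect_equal(signature_members(sig, "TEM", "UPREGULATED"), "c1")
  expect_equal(signature_members(sig, "SMI", "UPREGULATED"), "c1")
  expect_equal(signature_members(sig, "PSM", "UPREGULATED"), "c1")
  expect_false("u0" %in% sig$accession[sig$membership_class == "UPREGULATED"])
})

test_that("noiseless synthetic data recovers planted signatures exactly", {
  ds <- generate_dataset(noiseless_config(n_proteins = 200, seed = 17))
  cm <- build_cohort_matrix(ds$quant)
  sig <- build_signatures(cm, rat_protein_calls(ds$quant))
  recovered <- list(
    SHAM_ONLY = signature_members(sig, "SHAM_ONLY", "UNIQUE"),
    TEM = signature_members(sig, "TEM", "UNIQUE"),
    SMI = signature_members(sig, "SMI", "UNIQUE"),
    PSM = signature_members(sig, "PSM", "UNIQUE"))
  metrics <- truth_report(ds$truth, recovered)
  expect_equal(metrics$precision, rep(1, 4))
  expect_equal(metrics$recall, rep(1, 4))
  # planted fold changes are recovered as directions
  reg <- ds$truth$true_regulation
  up <- names(reg)[reg == "UP"]
  expect_true(all(up %in% sig$accession[sig$signature %in% c("SMI", "PSM") &
                                          sig$membership_class == "UPREGULATED"]))
})
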