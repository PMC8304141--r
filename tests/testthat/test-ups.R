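test_that("per-protein scores follow the impact values, per function instance", {
  expect_equal(protein_score("PRIMARY_UBIQ"), 1)
  expect_equal(protein_score(c("PRIMARY_DEUBIQ", "NONPRIMARY_UBIQ")), -0.5)
  expect_equal(protein_score("AMBIVALENT"), 0)
  expect_equal(protein_score(c("PRIMARY_UBIQ", "PRIMARY_UBIQ")), 2)
  expect_error(protein_score("DEGRADATION"), "unknown impact class")
  # brute-force oracle over all function lists of length <= 4
  classes <- c("PRIMARY_UBIQ", "PRIMARY_DEUBIQ", "NONPRIMARY_UBIQ",
               "NONPRIMARY_DEUBIQ", "AMBIVALENT")
  for (len in 1:4) {
    grid <- do.call(expand.grid, c(rep(list(classes), len),
                                   stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      fns <- unlist(grid[r, ], use.names = FALSE)
      expect_equal(protein_score(fns), count_score(fns))
    }
  }
})

test_that("homeostasis score totals matched members and reports direction", {
  ann <- data.frame(
    accession = c("a", "a", "b", "c"),
    function_label = c("ligase", "e3", "dub", "unknown"),
    impact_class = c("PRIMARY_UBIQ", "PRIMARY_UBIQ", "NONPRIMARY_DEUBIQ",
                     "AMBIVALENT"),
    stringsAsFactors = FALSE)
  hs <- homeostasis_score(c("a", "b"), ann)
  expect_equal(hs$net_score, 1.5)
  expect_equal(hs$direction, "PRO_UBIQUITINATION")
  expect_equal(homeostasis_score(character(0), ann)$net_score, 0)
  expect_equal(homeostasis_score(character(0), ann)$direction, "NEUTRAL")
  expect_warning(hs2 <- homeostasis_score(c("a", "zz"), ann), "no UPS annotation")
  expect_equal(hs2$net_score, 2)

  # planted net score of -4 is recovered from a constructed annotation set
  planted <- data.frame(
    accession = rep(c("d1", "d2", "d3"), c(2, 2, 1)),
    function_label = paste0("fn", 1:5),
    impact_class = c("PRIMARY_DEUBIQ", "PRIMARY_DEUBIQ", "PRIMARY_DEUBIQ",
                     "NONPRIMARY_DEUBIQ", "NONPRIMARY_DEUBIQ"),
    stringsAsFactors = FALSE)
  hs3 <- homeostasis_score(c("d1", "d2", "d3"), planted)
  expect_equal(hs3$net_score, -4)
  expect_equal(hs3$direction, "PRO_DEUBIQUITINATION")
})

test_that("homeostasis scoring is additive over disjoint member sets", {
  set.seed(13)
  classes <- names(protsig:::ups_impact_values())
  accs <- sprintf("u%02d", 1:30)
  ann <- do.call(rbind, lapply(accs, function(a) {
    k <- sample(1:4, 1)
    data.frame(accession = a, function_label = paste0(a, "_", 1:k),
               impact_class = sample(classes, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  for (i in 1:10) {
    ab <- sample(accs, 20)
    a <- ab[1:10]; b <- ab[11:20]
    expect_equal(homeostasis_score(union(a, b), ann)$net_score,
                 homeostasis_score(a, ann)$net_score +
                   homeostasis_score(b, ann)$net_score)
  }
})

test_that("UPS overlap reports counts and formatted percentages", {
  members <- sprintf("m%02d", 1:20)
  ref <- c(members[1:5], "other1", "other2")
  o <- match_ups(members, ref)
  expect_equal(o$k, 5)
  expect_equal(o$n, 20)
  expect_equal(o$formatted, "5/20 (25%)")
  expect_equal(match_ups(members, c("x", "y"))$formatted, "0/20 (0%)")
  # rounding is half away from zero: 15/88 -> 17%, 10/37 -> 27%
  expect_equal(match_ups(sprintf("a%02d", 1:88),
                         sprintf("a%02d", 1:15))$percent, 17)
  expect_equal(match_ups(sprintf("a%02d", 1:37),
                         sprintf("a%02d", 1:10))$percent, 27)
  # combined signatures get one decimal
  o2 <- match_ups(sprintf("a%02d", 1:57), sprintf("a%02d", 1:15),
                  combined = TRUE)
  expect_equal(o2$formatted, "15/57 (26.3%)")
  expect_error(match_ups(character(0), ref), "empty")
})

test_that("combining signatures is a deduplicating union", {
  tem <- sprintf("t%02d", 1:20)
  smi <- sprintf("s%02d", 1:37)
  expect_length(combine_signatures(tem, smi), 57)
  expect_equal(combine_signatures(tem, tem), sort(tem))
  # disjoint UPS-member unions add their counts
  expect_length(combine_signatures(tem[1:5], smi[1:10]), 15)
})

test_that("combined-phenotype scores add single-signature scores", {
  fx <- load_signature_fixtures()
  ref <- load_ups_reference()
  set.seed(29)
  classes <- names(protsig:::ups_impact_values())
  ann <- do.call(rbind, lapply(ref, function(a) {
    k <- sample(1:3, 1)
    data.frame(accession = a, function_label = paste0(a, "_", 1:k),
               impact_class = sample(classes, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  u <- lapply(fx, function(f) f$accession[f$membership_class == "UNIQUE"])
  s_tem <- homeostasis_score(match_ups(u$TEM, ref)$ups_members, ann)$net_score
  s_smi <- homeostasis_score(match_ups(u$SMI, ref)$ups_members, ann)$net_score
  s_psm <- homeostasis_score(match_ups(u$PSM, ref)$ups_members, ann)$net_score
  imp <- combine_signatures(u$TEM, u$SMI)
  fun <- combine_signatures(u$TEM, u$PSM)
  expect_equal(homeostasis_score(match_ups(imp, ref, TRUE)$ups_members,
                                 ann)$net_score, s_tem + s_smi)
  expect_equal(homeostasis_score(match_ups(fun, ref, TRUE)$ups_members,
                                 ann)$net_score, s_tem + s_psm)
})

test_that("only the sham fixture signature carries deubiquitinase entries", {
  # the two published DUBs sit in the sham-only UPS column and nowhere else
  t6 <- load_ups_overlap_fixture()
  dubs <- c("Q4VSI4", "Q9R085")   # Usp7, Usp15
  expect_true(all(dubs %in% t6$accession[t6$signature == "SHAM_ONLY"]))
  expect_false(any(dubs %in% t6$accession[t6$signature != "SHAM_ONLY"]))
})
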