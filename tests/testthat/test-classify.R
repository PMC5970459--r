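C18 <- "ACGTACGTACGTACGTAG"  # 18 nt toy canonical

test_that("end decomposition follows the taxonomy definitions", {
  # 3' deletion
  ann <- classify_isomir(substr(C18, 1, 17), "m", C18)
  expect_equal(ann$iso_class, "iso3p")
  expect_equal(ann$end3$kind, "deletion")
  expect_equal(ann$end3$n_removed, 1L)
  # 3' addition
  ann <- classify_isomir(paste0(C18, "T"), "m", C18)
  expect_equal(ann$iso_class, "iso3p")
  expect_equal(ann$end3$kind, "addition")
  expect_equal(ann$end3$nts, "T")
  # 3' variation that extends the original length: last base -> two others
  ann <- classify_isomir(paste0(substr(C18, 1, 17), "CC"), "m", C18)
  expect_equal(ann$iso_class, "iso3p")
  expect_equal(ann$end3$kind, "variation")
  expect_equal(ann$end3$nts, "CC")
  expect_equal(ann$end3$n_removed, 1L)
  # terminal substitution with no length change is also a variation
  ann <- classify_isomir(paste0(substr(C18, 1, 17), "C"), "m", C18)
  expect_equal(ann$end3$kind, "variation")
  expect_equal(ann$end3$nts, "C")
  expect_equal(ann$end3$n_removed, 1L)
  # 5' deletion + 3' addition = mixed
  ann <- classify_isomir(paste0(substring(C18, 2), "C"), "m", C18)
  expect_equal(ann$iso_class, "mixed")
  expect_equal(ann$end5$kind, "deletion")
  expect_equal(ann$end3$kind, "addition")
})

test_that("identity classifies as canonical for every toy mature", {
  ref <- toy_reference()
  for (i in seq_len(nrow(ref$matures))) {
    ann <- classify_isomir(ref$matures$sequence[i],
                           ref$matures$mature_id[i],
                           ref$matures$sequence[i])
    expect_equal(ann$iso_class, "canonical")
    expect_equal(ann$end5$kind, "none")
    expect_equal(ann$end3$kind, "none")
    expect_equal(nrow(ann$internal), 0L)
  }
})

test_that("internal substitutions and gaps become polymorphic edits", {
  q <- C18
  substr(q, 10, 10) <- "A"  # ref at 10 is C
  ann <- classify_isomir(q, "m", C18)
  expect_equal(ann$iso_class, "polymorphic")
  expect_equal(ann$internal$pos, 10L)
  expect_equal(ann$internal$ref, "C")
  expect_equal(ann$internal$alt, "A")
  # internal 1 nt deletion: one gap in the trace
  q2 <- paste0(substr(C18, 1, 8), substr(C18, 10, 18))
  ann2 <- classify_isomir(q2, "m", C18)
  expect_equal(ann2$iso_class, "polymorphic")
  expect_equal(ann2$internal$alt, "-")
  aln <- local_align(q2, C18)
  expect_equal(aln$score, r_sw_align(q2, C18)$score)
})

test_that("feature extraction validates its input pair", {
  aln <- local_align(C18, C18)
  expect_error(extract_features(aln, paste0(C18, "T"), C18),
               "does not reference")
})

test_that("template calls read the precursor flank of any placement", {
  plc <- data.frame(mature_id = "m", precursor_id = c("p1", "p2"),
                    start = c(10L, 5L), end = c(28L, 23L),
                    stringsAsFactors = FALSE)
  prec <- c(p1 = paste0(strrep("G", 10), C18, "T", strrep("A", 5)),
            p2 = paste0(strrep("C", 5), C18, "C", strrep("A", 5)))
  expect_equal(is_template_addition("T", "3p", plc[1, ], prec), "template")
  expect_equal(is_template_addition("C", "3p", plc[1, ], prec),
               "nontemplate")
  # any-match rule across two placements
  expect_equal(is_template_addition("C", "3p", plc, prec), "template")
  # no placements: non-template by definition
  expect_equal(is_template_addition("T", "3p", plc[0, ], prec),
               "nontemplate")
  # flank running off the precursor end
  short <- data.frame(mature_id = "m", precursor_id = "p3",
                      start = 0L, end = 18L, stringsAsFactors = FALSE)
  expect_equal(is_template_addition("TT", "3p", short,
                                    c(p3 = paste0(C18, "T"))),
               "nontemplate")
  # 5' flank is read upstream
  expect_equal(is_template_addition("G", "5p", plc[1, ], prec), "template")
  expect_equal(is_template_addition("A", "5p", plc[1, ], prec),
               "nontemplate")
})

test_that("template monotonicity: more placements never revoke template", {
  set.seed(13)
  for (k in 1:50) {
    n_plc <- sample(1:4, 1)
    prec <- stats::setNames(
      vapply(seq_len(n_plc), function(i) rand_seq(60), character(1)),
      paste0("p", seq_len(n_plc)))
    plc <- data.frame(mature_id = "m",
                      precursor_id = names(prec),
                      start = 20L, end = 40L, stringsAsFactors = FALSE)
    nts <- rand_seq(sample(1:2, 1))
    sub <- plc[sample(n_plc, sample(n_plc, 1)), , drop = FALSE]
    r_sub <- is_template_addition(nts, "3p", sub, prec)
    r_all <- is_template_addition(nts, "3p", plc, prec)
    if (r_sub == "template") expect_equal(r_all, "template")
  }
})

test_that("overhangs beyond the cap mark the sequence unclassified", {
  junk <- paste0(C18, "TTTTTTT")  # 7 nt 3' overhang > cap 6
  ann <- classify_isomir(junk, "m", C18)
  expect_equal(ann$iso_class, "unclassified")
  ann2 <- classify_isomir(junk, "m", C18, overhang_cap = 7L)
  expect_equal(ann2$iso_class, "iso3p")
})

test_that("labels are lossless under parse_label round trips", {
  ref <- toy_reference()
  cfg <- sim_config(n_mirnas = 10, seed = 23)
  sim_ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, sim_ref)
  for (i in seq_len(nrow(planted$truth))) {
    lab <- planted$truth$label[i]
    p <- parse_label(lab)
    rebuilt <- make_label(list(mature_id = p$mature_id,
                               iso_class = p$iso_class,
                               end5 = p$end5, end3 = p$end3,
                               internal = p$internal))
    expect_identical(rebuilt, lab)
  }
})

test_that("the five classes are total and mutually exclusive", {
  cfg <- sim_config(n_mirnas = 40, samples_per_group = c(g = 2), seed = 3)
  sim_ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, sim_ref)
  ann <- classify_all(planted$truth$seq, sim_ref$matures,
                      sim_ref$precursors, sim_ref$placements,
                      mature_ids = planted$truth$mature_id)
  classes <- c("canonical", "iso5p", "iso3p", "polymorphic", "mixed",
               "unclassified")
  expect_true(all(ann$iso_class %in% classes))
  expect_equal(sum(table(factor(ann$iso_class, classes))), nrow(ann))
  # invariants per class
  for (i in seq_len(nrow(ann))) {
    n5 <- ann$e5_kind[i] != "none"
    n3 <- ann$e3_kind[i] != "none"
    ni <- ann$n_internal[i] > 0
    expect_equal(ann$iso_class[i],
                 if (!n5 && !n3 && !ni) "canonical"
                 else if (n5 + n3 + ni >= 2) "mixed"
                 else if (n5) "iso5p" else if (n3) "iso3p"
                 else "polymorphic")
  }
})

test_that("planted annotations are recovered exactly (oracle equivalence)", {
  cfg <- sim_config(n_mirnas = 30, samples_per_group = c(g = 2), seed = 17)
  sim_ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, sim_ref)
  ann <- classify_all(planted$truth$seq, sim_ref$matures,
                      sim_ref$precursors, sim_ref$placements)
  expect_identical(ann$label, planted$truth$label)
})
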