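make_mat <- function(values, samples = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(paste0("r", seq_len(nrow(values))), samples)
  values
}

test_that("per-million scaling and its invariances", {
  m <- matrix(c(50, 10), 1, 2, dimnames = list("r1", c("A", "B")))
  norm <- normalize_counts(m, c(A = 1e6, B = 2e5))
  expect_equal(unname(norm["r1", ]), c(50, 50))
  # doubling one sample's counts and total leaves its column unchanged
  m2 <- m; m2[, "A"] <- m2[, "A"] * 2
  norm2 <- normalize_counts(m2, c(A = 2e6, B = 2e5))
  expect_equal(norm2[, "A"], norm[, "A"])
  # all-equal columns unchanged by the median-ratio step
  m3 <- matrix(rep(c(10, 20, 30), 3), 3, 3,
               dimnames = list(paste0("r", 1:3), paste0("s", 1:3)))
  tot <- stats::setNames(rep(1e6, 3), paste0("s", 1:3))
  expect_equal(normalize_counts(m3, tot, "scale_median_ratio"),
               normalize_counts(m3, tot, "scale_only"))
  expect_error(normalize_counts(m, c(A = 0, B = 1)), "non-positive")
})

test_that("abundance/prevalence filter boundaries are strict/inclusive", {
  groups <- stats::setNames(rep(c("g1", "g2"), each = 2),
                            paste0("s", 1:4))
  # mean exactly 5 is removed (strict >)
  m <- make_mat(rbind(c(5, 5, 5, 5),
                      c(6, 6, 6, 6),
                      c(28, 0, 0, 0),
                      c(6, 6, 0, 0)))
  out <- abundance_prevalence_filter(m, groups)
  # r1: mean exactly 5 fails; r2 passes; r3: mean 7, present in 1/2 of g1
  # (50%) -> kept; r4: fully present in g1 but mean 3 -> removed
  expect_setequal(rownames(out), c("r2", "r3"))
  # presence below 50% in every group is removed
  m2 <- make_mat(rbind(c(40, 0, 0, 0)))
  g3 <- stats::setNames(c("g1", "g1", "g1", "g1"), paste0("s", 1:4))
  expect_equal(nrow(abundance_prevalence_filter(m2, g3,
                                                min_group_fraction = 0.5)),
               0L)
  # toy example: means {2, 6, 7, 5}, presence {all, all, one of 4, all}
  m3 <- make_mat(rbind(c(2, 2, 2, 2), c(6, 6, 6, 6),
                       c(28, 0, 0, 0), c(5, 5, 5, 5)))
  out3 <- abundance_prevalence_filter(m3, g3)
  expect_equal(rownames(out3), "r2")
})

test_that("per-miRNA roll-up sums rows and conserves totals exactly", {
  m <- make_mat(rbind(c(3, 1), c(7, 2), c(4, 4), c(9, 9)))
  ids <- c("miR-a", "miR-a", "miR-b", NA)
  roll <- summarize_per_mirna(m, ids)
  expect_equal(unname(roll["miR-a", ]), c(10, 3))
  expect_equal(unname(roll["miR-b", ]), c(4, 4))
  expect_equal(attr(roll, "n_unassigned"), 1L)
  # conservation over assigned rows, raw and normalized
  expect_equal(sum(roll), sum(m[1:3, ]))
  norm <- normalize_counts(m, c(s1 = 1e5, s2 = 2e5))
  rolln <- summarize_per_mirna(norm, ids)
  expect_equal(sum(rolln), sum(norm[1:3, ]))
  # single canonical row is identical after roll-up
  one <- summarize_per_mirna(m[3, , drop = FALSE], "miR-b")
  expect_equal(unname(one[1, ]), unname(m[3, ]))
})

test_that("composition fractions sum to one over their denominators", {
  cfg <- sim_config(n_mirnas = 15, samples_per_group = c(g1 = 3, g2 = 3),
                    seed = 9)
  ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, ref)
  ann <- classify_all(planted$truth$seq, ref$matures, ref$precursors,
                      ref$placements, mature_ids = planted$truth$mature_id)
  arm <- stats::setNames(ref$placements$arm, ref$placements$mature_id)
  prof <- profile_composition(ann, planted$counts, arm_map = arm)
  for (nm in c("class_fractions", "iso3p_breakdown", "added_nt_spectrum",
               "added_nt_spectrum_nontemplate", "polymorphic_pos_hist",
               "polymorphic_change_spectrum")) {
    f <- prof[[nm]]
    if (length(f)) expect_equal(sum(f), 1, tolerance = 1e-9)
  }
  expect_true(prof$addition_template_fraction >= 0 &&
                prof$addition_template_fraction <= 1)
  expect_named(prof$by_arm, c("5p", "3p"))
})

test_that("a one-canonical table gives class fraction 1 and ratio logic", {
  ann <- classify_all("ACGTTGCAGGTCCAATGCAT",
                      data.frame(mature_id = "m1",
                                 sequence = "ACGTTGCAGGTCCAATGCAT",
                                 length = 20L, stringsAsFactors = FALSE),
                      data.frame(precursor_id = "p1",
                                 sequence = paste0("AAA",
                                   "ACGTTGCAGGTCCAATGCAT", "TTT"),
                                 length = 26L, stringsAsFactors = FALSE))
  m <- matrix(10, 1, 1, dimnames = list("ACGTTGCAGGTCCAATGCAT", "s1"))
  prof <- profile_composition(ann, m)
  expect_equal(unname(prof$class_fractions), 1)
  expect_equal(names(prof$class_fractions), "canonical")
  expect_equal(prof$most_abundant_form$top_to_canonical_ratio, 1)
})

test_that("most-abundant-form ratio reports isomiR dominance", {
  cfg <- sim_config(n_mirnas = 5, samples_per_group = c(g = 2), seed = 19)
  ref <- make_reference(cfg)
  can <- ref$matures$sequence[1]
  iso <- paste0(can, "T")
  ann <- classify_all(c(can, iso), ref$matures, ref$precursors,
                      ref$placements)
  m <- matrix(c(2, 1, 36, 18), 2, 2, byrow = TRUE,
              dimnames = list(c(can, iso), c("s1", "s2")))
  prof <- profile_composition(ann, m)
  row <- prof$most_abundant_form
  expect_equal(row$top_seq, iso)
  expect_equal(row$top_class, "iso3p")
  expect_equal(row$top_to_canonical_ratio, 18)
})

test_that("recovered class fractions converge to planted fractions", {
  fracs <- sapply(c(60, 600), function(mu) {
    cfg <- sim_config(n_mirnas = 25, samples_per_group = c(g = 4),
                      count_model = list(mean_log_mu = log(mu),
                                         mean_log_sd = 0.3, size = 10),
                      seed = 29)
    ref <- make_reference(cfg)
    planted <- plant_isomirs(cfg, ref)
    ann <- classify_all(planted$truth$seq, ref$matures, ref$precursors,
                        ref$placements,
                        mature_ids = planted$truth$mature_id)
    prof <- profile_composition(ann, planted$counts)
    prof$class_fractions["iso3p"]
  })
  planted_iso3p <- sum(sim_config(seed = 1)$event_spectrum[
    c("3p_add_template", "3p_add_nontemplate", "3p_del", "3p_var")])
  err <- abs(fracs - planted_iso3p)
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.05)  # deeper data no worse
})
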