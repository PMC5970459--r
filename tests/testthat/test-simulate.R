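test_that("reference generation embeds matures exactly, deterministically", {
  cfg <- sim_config(n_mirnas = 10, seed = 1)
  ref <- make_reference(cfg)
  expect_equal(nrow(ref$matures), 10L)
  for (i in 1:10) {
    expect_identical(
      substr(ref$precursors$sequence[i], ref$placements$start[i] + 1L,
             ref$placements$end[i]),
      ref$matures$sequence[i])
  }
  # both arms represented and consistent with the name suffix
  expect_setequal(unique(ref$placements$arm), c("5p", "3p"))
  expect_equal(ref$placements$arm,
               ifelse(grepl("-5p$", ref$matures$mature_id), "5p", "3p"))
  # same config, same seed: byte-identical FASTA
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference_fasta(make_reference(cfg)$matures,
                        file.path(d1, "m.fa"))
  write_reference_fasta(make_reference(cfg)$matures,
                        file.path(d2, "m.fa"))
  expect_identical(readLines(file.path(d1, "m.fa")),
                   readLines(file.path(d2, "m.fa")))
  # 13-mer uniqueness across matures
  kms <- unlist(lapply(ref$matures$sequence, function(s)
    substring(s, 1:(nchar(s) - 12), 13:nchar(s))))
  expect_equal(anyDuplicated(kms), 0L)
  expect_error(make_reference(sim_config(n_mirnas = 0, seed = 1)),
               "n_mirnas")
})

test_that("planted truths satisfy the annotation invariants by construction", {
  cfg <- sim_config(n_mirnas = 20, samples_per_group = c(g = 2), seed = 2)
  ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, ref)
  tr <- planted$truth
  # one variant per (mature, event type), no sequence collisions
  expect_equal(anyDuplicated(tr$seq), 0L)
  expect_false(any(tr$seq[tr$iso_class != "canonical"] %in%
                     ref$matures$sequence))
  for (i in seq_len(nrow(tr))) {
    n5 <- tr$e5_kind[i] != "none"
    n3 <- tr$e3_kind[i] != "none"
    ni <- tr$n_internal[i] > 0
    cls <- tr$iso_class[i]
    expect_equal(cls, if (!n5 && !n3 && !ni) "canonical"
                 else if (n5 + n3 + ni >= 2) "mixed"
                 else if (n5) "iso5p" else if (n3) "iso3p"
                 else "polymorphic")
    if (tr$e3_kind[i] == "addition") {
      expect_true(tr$e3_template[i] %in% c("template", "nontemplate"))
    }
  }
  # template truth events really copy the precursor flank
  tmpl <- tr[tr$event == "3p_add_template", ]
  for (i in seq_len(nrow(tmpl))) {
    pl <- ref$placements[ref$placements$mature_id == tmpl$mature_id[i], ]
    prec <- ref$precursors$sequence[ref$precursors$precursor_id ==
                                      pl$precursor_id]
    k <- nchar(tmpl$e3_nts[i])
    expect_identical(substr(prec, pl$end + 1L, pl$end + k),
                     tmpl$e3_nts[i])
  }
  # non-template additions differ from the flank
  ntl <- tr[tr$event == "3p_add_nontemplate", ]
  for (i in seq_len(nrow(ntl))) {
    pl <- ref$placements[ref$placements$mature_id == ntl$mature_id[i], ]
    prec <- ref$precursors$sequence[ref$precursors$precursor_id ==
                                      pl$precursor_id]
    expect_false(substr(ntl$e3_nts[i], 1, 1) ==
                   substr(prec, pl$end + 1L, pl$end + 1L))
  }
  # a pure-canonical spectrum plants only canonical sequences
  cfg2 <- sim_config(n_mirnas = 5, samples_per_group = c(g = 2),
                     event_spectrum = c(canonical = 1), seed = 3)
  ref2 <- make_reference(cfg2)
  tr2 <- plant_isomirs(cfg2, ref2)$truth
  expect_true(all(tr2$iso_class == "canonical"))
  expect_identical(sort(tr2$seq), sort(ref2$matures$sequence))
})

test_that("FASTQ emission matches planted counts read-for-read", {
  cfg <- sim_config(n_mirnas = 5, samples_per_group = c(g1 = 2, g2 = 1),
                    seed = 4)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  ss <- sim$sample_sheet
  for (s in seq_len(nrow(ss))) {
    lines <- readLines(ss$fastq[s])
    expect_equal(length(lines) %% 4, 0)
    reads <- lines[seq(2, length(lines), by = 4)]
    expect_true(all(nchar(reads) == cfg$read_length))
    # trimming recovers each planted insert exactly count-many times
    trimmed <- trim_adapter(reads, NULL, cfg$adapter_seq)$seq
    tab <- table(trimmed)
    cnt <- sim$planted$counts[, ss$sample_id[s]]
    for (i in which(cnt > 0)) {
      expect_equal(unname(tab[sim$planted$truth$seq[i]]),
                   unname(cnt[i]))
    }
  }
})

test_that("identical configurations give byte-identical datasets", {
  cfg <- sim_config(n_mirnas = 4, samples_per_group = c(g = 2), seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (f in setdiff(list.files(d1), "samples.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # the sample sheet differs only in the directory of its fastq paths
  expect_identical(s1$sample_sheet[, c("sample_id", "group")],
                   s2$sample_sheet[, c("sample_id", "group")])
})

test_that("a quality spike in 11 samples removes the sequence at threshold 10", {
  cfg <- sim_config(n_mirnas = 3,
                    samples_per_group = c(g1 = 6, g2 = 6),
                    event_spectrum = c(canonical = 0.5, "3p_del" = 0.5),
                    count_model = list(mean_log_mu = log(50),
                                       mean_log_sd = 0.1, size = 50),
                    seed = 12)
  ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, ref)
  victim <- planted$truth$seq[planted$truth$event == "3p_del"][1]
  spike_samples <- planted$sample_sheet$sample_id[1:11]
  ss <- write_fastq(planted, cfg, withr::local_tempdir(),
                    lowq = list(seqs = victim, samples = spike_samples))
  col <- collapse_fastq(ss, cfg$adapter_seq)
  expect_true(victim %in% col$seq)
  expect_equal(sum(col$lowq[victim, ]), 11)
  filtered <- quality_filter(col, max_lowq_samples = 10)
  expect_false(victim %in% filtered$seq)
  # spiked in only 10 samples: retained
  ss2 <- write_fastq(planted, cfg, withr::local_tempdir(),
                     lowq = list(seqs = victim,
                                 samples = spike_samples[1:10]))
  col2 <- collapse_fastq(ss2, cfg$adapter_seq)
  expect_true(victim %in% quality_filter(col2, 10)$seq)
})

test_that("fold changes planted between groups are recovered as flags", {
  base <- sim_config(seed = 1)
  cfg <- sim_config(
    n_mirnas = 6, samples_per_group = c(normal = 10, CRC = 10),
    count_model = list(mean_log_mu = log(300), mean_log_sd = 0.2,
                       size = 8),
    fold_changes = list(CRC = c("sim-miR-1-5p" = 4)),
    seed = 21)
  ref <- make_reference(cfg)
  planted <- plant_isomirs(cfg, ref)
  groups <- stats::setNames(planted$sample_sheet$group,
                            planted$sample_sheet$sample_id)
  per_mir <- summarize_per_mirna(planted$counts, planted$truth$mature_id)
  de <- diffexp_table(per_mir, groups, case = "CRC", control = "normal")
  hit <- de[de$label == "sim-miR-1-5p", ]
  expect_gt(hit$fc, 2)
  expect_equal(hit$flag, "up")
})
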