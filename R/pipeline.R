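#' Resolved pipeline configuration
#'
#' Collects every stage parameter with its default in one range-checked
#' list.  The fully resolved configuration is written into the output
#' directory by [run_pipeline()] for provenance.
#'
#' @param adapter_seq 3' adapter to trim (`NULL` skips trimming).
#' @param qmin Minimum base quality for high-quality read support.
#' @param max_lowq_samples Quality-filter threshold (count or fraction).
#' @param min_len,max_len Inclusive length bounds.
#' @param word_size,gap_open,gap_extend,match,mismatch Alignment
#'   parameters (see [alignment_scoring()]).
#' @param overhang_cap Unaligned end-bases tolerated before a sequence is
#'   unclassifiable.
#' @param min_mean,min_group_fraction Abundance/prevalence filter.
#' @param normalize_method See [normalize_counts()].
#' @param auc_hi,auc_lo,p_max,p_source Differential-expression flags.
#' @param seed RNG seed recorded for provenance.
#' @return A list of class `casmir_run_config`.
#' @export
run_config <- function(adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       qmin = 30L, max_lowq_samples = 10,
                       min_len = 17L, max_len = 25L,
                       word_size = 13L, gap_open = 5, gap_extend = 2,
                       match = 1, mismatch = -3, overhang_cap = 6L,
                       min_mean = 5, min_group_fraction = 0.5,
                       normalize_method = "scale_only",
                       auc_hi = 0.8, auc_lo = 0.2, p_max = 0.01,
                       p_source = "p_fc", seed = 1L) {
  stopifnot(qmin >= 0, max_lowq_samples >= 0, min_len <= max_len,
            word_size >= 4L, gap_open >= 0, gap_extend >= 0,
            match > 0, mismatch < 0, overhang_cap >= 1L,
            min_mean >= 0, min_group_fraction >= 0,
            min_group_fraction <= 1,
            auc_lo < auc_hi, p_max > 0, p_max <= 1)
  structure(list(adapter_seq = adapter_seq, qmin = as.integer(qmin),
                 max_lowq_samples = max_lowq_samples,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 word_size = as.integer(word_size),
                 gap_open = gap_open, gap_extend = gap_extend,
                 match = match, mismatch = mismatch,
                 overhang_cap = as.integer(overhang_cap),
                 min_mean = min_mean,
                 min_group_fraction = min_group_fraction,
                 normalize_method = normalize_method,
                 auc_hi = auc_hi, auc_lo = auc_lo, p_max = p_max,
                 p_source = p_source, seed = as.integer(seed)),
            class = "casmir_run_config")
}

#' Run the full annotation pipeline on a sample sheet
#'
#' Preprocess (trim, collapse, quality and length filters), assign,
#' classify, quantify (normalize, abundance/prevalence filter, per-miRNA
#' roll-up, composition profile) and, when `case`/`control` are given,
#' differential expression.  Every intermediate is written under
#' `outdir` together with a machine-readable manifest holding the
#' resolved parameters and the row count after each stage.
#'
#' @param sample_sheet Data.frame with `sample_id`, `group`, `fastq`, or
#'   the path of such a TSV.
#' @param mature_fa,hairpin_fa Reference FASTA paths.
#' @param outdir Output directory.
#' @param config A [run_config()].
#' @param case,control Optional group labels for differential expression.
#' @return A list with the main in-memory results (`collapsed`,
#'   `annotations`, `norm`, `filtered`, `per_mirna`, `profile`, `de`,
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(sample_sheet, mature_fa, hairpin_fa, outdir,
                         config = run_config(), case = NULL,
                         control = NULL) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1L) {
    sample_sheet <- utils::read.delim(sample_sheet,
                                      stringsAsFactors = FALSE)
  }
  for (f in c(mature_fa, hairpin_fa, sample_sheet$fastq)) {
    if (!file.exists(f)) stop("input file missing: ", f)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scoring <- alignment_scoring(config$match, config$mismatch,
                               config$gap_open, config$gap_extend,
                               config$word_size)
  stage_counts <- list()
  log_stage <- function(name, n) {
    stage_counts[[name]] <<- n
    message(sprintf("[casmir] %s: %d sequences", name, n))
  }

  matures <- load_mature_db(mature_fa)
  precursors <- load_precursor_db(hairpin_fa)
  placements <- map_mature_to_precursors(matures, precursors)

  collapsed <- collapse_fastq(sample_sheet, config$adapter_seq,
                              qmin = config$qmin)
  log_stage("collapsed", length(collapsed$seq))
  collapsed <- quality_filter(collapsed, config$max_lowq_samples)
  log_stage("after_quality_filter", length(collapsed$seq))
  collapsed <- length_filter(collapsed, config$min_len, config$max_len)
  log_stage("after_length_filter", length(collapsed$seq))

  annotations <- classify_all(collapsed$seq, matures, precursors,
                              placements, scoring = scoring,
                              overhang_cap = config$overhang_cap)
  log_stage("annotated", nrow(annotations))

  norm <- normalize_counts(collapsed$counts, collapsed$sample_totals,
                           config$normalize_method)
  groups <- stats::setNames(sample_sheet$group, sample_sheet$sample_id)
  filtered <- abundance_prevalence_filter(norm, groups, config$min_mean,
                                          config$min_group_fraction)
  log_stage("after_abundance_filter", nrow(filtered))
  ann_f <- annotations[match(rownames(filtered), annotations$seq), ,
                       drop = FALSE]
  per_mirna <- summarize_per_mirna(filtered, ann_f$mature_id)
  arm_map <- stats::setNames(
    arm_of(placements$mature_id, placements$start, placements$end,
           stats::setNames(precursors$length,
                           precursors$precursor_id)[placements$precursor_id]),
    placements$mature_id)
  arm_map <- arm_map[!duplicated(names(arm_map))]
  profile <- profile_composition(ann_f, filtered, arm_map = arm_map)

  de <- NULL
  if (!is.null(case) && !is.null(control)) {
    de <- diffexp_table(filtered, groups, case = case, control = control,
                        auc_hi = config$auc_hi, auc_lo = config$auc_lo,
                        p_max = config$p_max, p_source = config$p_source)
  }

  # outputs
  utils::write.table(cbind(seq = rownames(collapsed$counts),
                           as.data.frame(collapsed$counts)),
                     file.path(outdir, "collapsed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(annotations, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(seq = rownames(filtered),
                           as.data.frame(filtered)),
                     file.path(outdir, "normalized_filtered.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(mature_id = rownames(per_mirna),
                           as.data.frame(per_mirna)),
                     file.path(outdir, "per_mirna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass_profile(profile),
                       file.path(outdir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(de)) {
    utils::write.table(de, file.path(outdir, "diffexp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_mirgff3(ann_f, filtered, file.path(outdir, "annotations.gff3"))

  manifest <- list(parameters = unclass(config),
                   inputs = list(mature_fa = mature_fa,
                                 hairpin_fa = hairpin_fa,
                                 samples = sample_sheet$sample_id),
                   stage_counts = stage_counts,
                   n_unassigned = sum(annotations$iso_class == "unassigned"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(collapsed = collapsed, annotations = annotations,
                 norm = norm, filtered = filtered, per_mirna = per_mirna,
                 profile = profile, de = de, manifest = manifest))
}

unclass_profile <- function(p) {
  p <- unclass(p)
  p$most_abundant_form <- NULL
  lapply(p, function(el) if (is.numeric(el) && !is.null(names(el)))
    as.list(el) else el)
}

# class -> mirGFF3 Variant vocabulary.  Lossy projection: the lossless
# feature bundle travels in the UID attribute (the annotation label).
variant_attr <- function(ann_row) {
  if (ann_row$iso_class == "canonical") return("NA")
  parts <- character(0)
  if (!is.na(ann_row$e5_kind) && ann_row$e5_kind != "none") {
    parts <- c(parts, switch(ann_row$e5_kind,
      deletion = sprintf("iso_5p:-%d", ann_row$e5_nrem),
      addition = sprintf("iso_5p:+%d", nchar(ann_row$e5_nts)),
      variation = "iso_5p_var"))
  }
  if (!is.na(ann_row$e3_kind) && ann_row$e3_kind != "none") {
    parts <- c(parts, switch(ann_row$e3_kind,
      deletion = sprintf("iso_3p:-%d", ann_row$e3_nrem),
      addition = sprintf("iso_add3p:+%d", nchar(ann_row$e3_nts)),
      variation = "iso_3p_var"))
  }
  if (!is.na(ann_row$n_internal) && ann_row$n_internal > 0L) {
    parts <- c(parts, "iso_snv")
  }
  if (length(parts) == 0L) return("NA")
  paste(parts, collapse = ",")
}

#' Write annotations and counts as mirGFF3
#'
#' One feature line per sequence: `type` is `ref_miRNA` for canonical
#' sequences and `isomiR` otherwise; attributes carry `Read` (the
#' sequence), `UID` (the lossless annotation label), `Parent` (the
#' mature ID), `Variant` (community vocabulary: `iso_5p`, `iso_3p`,
#' `iso_add3p`, `iso_5p_var`, `iso_3p_var`, `iso_snv`) and `Expression`
#' (comma-joined per-sample values in the column order of the
#' `# COLDATA` header line).  Unassigned sequences are skipped.
#'
#' @param annotations Data.frame from [classify_all()].
#' @param counts Matrix with rownames matching `annotations$seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirgff3 <- function(annotations, counts, path) {
  samples <- colnames(counts)
  keep <- annotations$iso_class != "unassigned"
  ann <- annotations[keep, , drop = FALSE]
  lines <- c("## mirGFF3. VERSION 1.2",
             paste0("## source-ontology: casmir"),
             paste0("# COLDATA: ", paste(samples, collapse = ",")))
  for (i in seq_len(nrow(ann))) {
    expr <- paste(counts[ann$seq[i], ], collapse = ",")
    type <- if (ann$iso_class[i] == "canonical") "ref_miRNA" else "isomiR"
    attrs <- sprintf("Read=%s; UID=%s; Parent=%s; Variant=%s; Expression=%s",
                     ann$seq[i], ann$label[i], ann$mature_id[i],
                     variant_attr(ann[i, ]), expr)
    lines <- c(lines, paste(ann$mature_id[i], "casmir", type, "1",
                            nchar(ann$seq[i]), ".", "+", ".", attrs,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a mirGFF3 file written by [write_mirgff3()]
#'
#' Reconstructs the annotation table (via the lossless `UID` label) and
#' the count matrix.  Malformed lines raise an error naming the line
#' number.
#'
#' @param path Path to a mirGFF3 file.
#' @return A list with `annotations` (as from [classify_all()], minus
#'   unassigned rows) and `counts`.
#' @export
read_mirgff3 <- function(path) {
  lines <- readLines(path)
  cold <- grep("^# COLDATA:", lines, value = TRUE)
  if (length(cold) != 1L) stop("mirGFF3 parse error: missing COLDATA header")
  samples <- strsplit(sub("^# COLDATA:\\s*", "", cold), ",")[[1]]
  feat_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  ann_rows <- list()
  cnt_rows <- list()
  for (k in feat_idx) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("mirGFF3 parse error at line ", k, ": expected 9 columns")
    }
    attrs <- strsplit(f[9L], ";\\s*")[[1]]
    kv <- regmatches(attrs, regexec("^([A-Za-z]+)=(.*)$", attrs))
    keys <- vapply(kv, `[`, character(1L), 2L)
    vals <- vapply(kv, `[`, character(1L), 3L)
    names(vals) <- keys
    if (!all(c("Read", "UID", "Expression") %in% keys)) {
      stop("mirGFF3 parse error at line ", k, ": missing attributes")
    }
    lab <- parse_label(vals[["UID"]])
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      seq = vals[["Read"]], mature_id = lab$mature_id,
      iso_class = lab$iso_class,
      e5_kind = lab$end5$kind, e5_nts = lab$end5$nts,
      e5_nrem = lab$end5$n_removed, e5_template = lab$end5$template,
      e3_kind = lab$end3$kind, e3_nts = lab$end3$nts,
      e3_nrem = lab$end3$n_removed, e3_template = lab$end3$template,
      internal = internal_desc(lab$internal),
      n_internal = nrow(lab$internal), label = vals[["UID"]],
      stringsAsFactors = FALSE)
    cnt_rows[[length(cnt_rows) + 1L]] <-
      as.numeric(strsplit(vals[["Expression"]], ",")[[1]])
  }
  annotations <- do.call(rbind, ann_rows)
  counts <- do.call(rbind, cnt_rows)
  if (!is.null(counts)) {
    dimnames(counts) <- list(annotations$seq, samples)
  }
  list(annotations = annotations, counts = counts)
}
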