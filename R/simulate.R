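#' Configuration for the synthetic small RNA study generator
#'
#' Defaults emulate the structure the annotation workflow assumes: three
#' pathology groups of 20 samples each (the sample size the power
#' calculation is built on), miRNA-sized matures embedded in 80 nt
#' hairpins, negative-binomial per-mature abundances, and an event
#' spectrum mirroring the composition reported for colorectal tissue
#' (canonical roughly 31% of miRNA reads, 3' isomiRs the dominant variant
#' class with additions the dominant 3' form, added nucleotides weighted
#' C > U > A).
#'
#' @param n_mirnas Number of simulated miRNAs (default 20).
#' @param precursor_length Hairpin length in nt (default 80).
#' @param mature_length Inclusive range of mature lengths (default 20-23).
#' @param samples_per_group Named integer vector group -> n
#'   (default normal/adenoma/CRC, 20 each).
#' @param event_spectrum Named probabilities over event types
#'   `canonical`, `3p_add_template`, `3p_add_nontemplate`, `3p_del`,
#'   `3p_var`, `5p_add`, `5p_del`, `5p_var`, `internal_sub`, `mixed`;
#'   must sum to 1.
#' @param added_nt_distribution Base weights for non-template draws.
#' @param count_model List: `mean_log_mu`, `mean_log_sd` (lognormal
#'   per-mature mean abundance) and `size` (NB size; smaller = more
#'   overdispersed).
#' @param fold_changes Optional named list group -> named multiplier
#'   vector by mature ID (unlisted matures get 1).
#' @param seq_error_rate Per-base substitution error rate in reads
#'   (default 0).
#' @param adapter_seq 3' adapter appended to every read.
#' @param read_length Fixed sequencer cycle count (default 50).
#' @param seed RNG seed (mandatory).
#' @return A list of class `casmir_sim_config`.
#' @export
sim_config <- function(n_mirnas = 20L,
                       precursor_length = 80L,
                       mature_length = c(20L, 23L),
                       samples_per_group = c(normal = 20L, adenoma = 20L,
                                             CRC = 20L),
                       event_spectrum = c(canonical = 0.31,
                                          "3p_add_template" = 0.164,
                                          "3p_add_nontemplate" = 0.109,
                                          "3p_del" = 0.10,
                                          "3p_var" = 0.041,
                                          "5p_add" = 0.005,
                                          "5p_del" = 0.012,
                                          "5p_var" = 0.003,
                                          internal_sub = 0.01,
                                          mixed = 0.246),
                       added_nt_distribution = c(C = 0.43, T = 0.27,
                                                 A = 0.12, G = 0.18),
                       count_model = list(mean_log_mu = log(200),
                                          mean_log_sd = 1, size = 5),
                       fold_changes = NULL,
                       seq_error_rate = 0,
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       read_length = 50L,
                       seed = 1L) {
  stopifnot(abs(sum(event_spectrum) - 1) < 1e-9,
            all(event_spectrum >= 0), all(event_spectrum <= 1),
            !missing(seed) || is.numeric(seed))
  structure(list(n_mirnas = as.integer(n_mirnas),
                 precursor_length = as.integer(precursor_length),
                 mature_length = as.integer(mature_length),
                 samples_per_group = samples_per_group,
                 event_spectrum = event_spectrum,
                 added_nt_distribution = added_nt_distribution,
                 count_model = count_model,
                 fold_changes = fold_changes,
                 seq_error_rate = seq_error_rate,
                 adapter_seq = adapter_seq,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "casmir_sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Generate a synthetic mature/hairpin reference
#'
#' Random matures (both arms represented, alternating) embedded at known
#' offsets in random hairpins, with at least 3 nt of flank on each side so
#' template and non-template additions can be planted deliberately.
#' 13-mer uniqueness across matures is enforced so canonical assignment
#' at the default word size is unambiguous.
#'
#' @param config A [sim_config()].
#' @return A list with `matures`, `precursors` (data.frames as loaded by
#'   the reference loaders) and `placements` (as from
#'   [map_mature_to_precursors()], with exact planted coordinates).
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  if (config$n_mirnas < 1L) stop("n_mirnas must be >= 1")
  w <- 13L
  seen_kmers <- character(0)
  matures <- character(config$n_mirnas)
  arms <- ifelse(seq_len(config$n_mirnas) %% 2L == 1L, "5p", "3p")
  for (i in seq_len(config$n_mirnas)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      L <- sample(config$mature_length[1]:config$mature_length[2], 1L)
      s <- rand_dna(L)
      kms <- substring(s, seq_len(L - w + 1L), seq(w, L))
      if (anyDuplicated(kms) == 0L && !any(kms %in% seen_kmers)) {
        matures[i] <- s
        seen_kmers <- c(seen_kmers, kms)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not generate matures with unique 13-mers; ",
                  "use fewer or longer matures")
  }
  mat_len <- nchar(matures)
  P <- config$precursor_length
  # 5p arms sit in the first half of the hairpin, 3p arms in the second
  start <- integer(config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    rng <- if (arms[i] == "5p") c(3L, floor(P / 2) - mat_len[i])
           else c(ceiling(P / 2), P - mat_len[i] - 3L)
    start[i] <- sample(rng[1]:rng[2], 1L)
  }
  precursors <- vapply(seq_len(config$n_mirnas), function(i) {
    paste0(substr(rand_dna(P), 1L, start[i]), matures[i],
           substr(rand_dna(P), 1L, P - start[i] - mat_len[i]))
  }, character(1L))
  mature_id <- sprintf("sim-miR-%d-%s", seq_len(config$n_mirnas), arms)
  precursor_id <- sprintf("sim-mir-%d", seq_len(config$n_mirnas))
  list(
    matures = data.frame(mature_id = mature_id, sequence = matures,
                         length = mat_len, stringsAsFactors = FALSE),
    precursors = data.frame(precursor_id = precursor_id,
                            sequence = precursors, length = P,
                            stringsAsFactors = FALSE),
    placements = data.frame(mature_id = mature_id,
                            precursor_id = precursor_id,
                            start = start, end = start + mat_len,
                            arm = arms, stringsAsFactors = FALSE)
  )
}

# Construct one edited sequence + its planted truth annotation.
# Flanks are read off the known planted placement, never via the
# classifier, so the truth stays independent of the code under test.
make_variant <- function(type, canonical, flank5, flank3, add_dist) {
  L <- nchar(canonical)
  bases <- c("A", "C", "G", "T")
  draw <- function(n, exclude_first = NULL) {
    p <- add_dist
    first <- if (is.null(exclude_first)) {
      sample(names(p), 1L, prob = p)
    } else {
      pp <- p[setdiff(names(p), exclude_first)]
      sample(names(pp), 1L, prob = pp)
    }
    if (n == 1L) first else
      paste0(first, sample(names(p), 1L, prob = p))
  }
  e5 <- end_change(); e3 <- end_change(); internal <- empty_internal()
  seq <- canonical
  if (type == "canonical") {
    cls <- "canonical"
  } else if (type == "3p_add_template") {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    nts <- substr(flank3, 1L, k)
    seq <- paste0(canonical, nts)
    e3 <- end_change("addition", nts, 0L, "template")
    cls <- "iso3p"
  } else if (type == "3p_add_nontemplate") {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    nts <- draw(k, exclude_first = substr(flank3, 1L, 1L))
    seq <- paste0(canonical, nts)
    e3 <- end_change("addition", nts, 0L, "nontemplate")
    cls <- "iso3p"
  } else if (type == "3p_del") {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    seq <- substr(canonical, 1L, L - k)
    e3 <- end_change("deletion", "", k)
    cls <- "iso3p"
  } else if (type == "3p_var") {
    last <- substr(canonical, L, L)
    y <- sample(setdiff(bases, last), 1L)
    extend <- stats::runif(1) < 0.3
    nts <- if (extend) paste0(y, sample(bases, 1L)) else y
    seq <- paste0(substr(canonical, 1L, L - 1L), nts)
    e3 <- end_change("variation", nts, 1L)
    cls <- "iso3p"
  } else if (type == "5p_add") {
    nt <- sample(names(add_dist), 1L, prob = add_dist)
    seq <- paste0(nt, canonical)
    tmpl <- if (nt == substr(flank5, nchar(flank5), nchar(flank5)))
      "template" else "nontemplate"
    e5 <- end_change("addition", nt, 0L, tmpl)
    cls <- "iso5p"
  } else if (type == "5p_del") {
    k <- sample(1:2, 1L, prob = c(0.7, 0.3))
    seq <- substr(canonical, k + 1L, L)
    e5 <- end_change("deletion", "", k)
    cls <- "iso5p"
  } else if (type == "5p_var") {
    first <- substr(canonical, 1L, 1L)
    y <- sample(setdiff(bases, first), 1L)
    seq <- paste0(y, substr(canonical, 2L, L))
    e5 <- end_change("variation", y, 1L)
    cls <- "iso5p"
  } else if (type == "internal_sub") {
    # Keep an intact 13-mer so the seeded aligner can reach the sequence,
    # and stay clear of the terminal region where a single substitution is
    # indistinguishable from an end variation (the +1/-3 scoring trims a
    # mismatch unless at least 4 aligned bases flank it) -- such sequences
    # would collide with a different single-event description.
    cand <- seq_len(L)
    cand <- cand[cand >= 5L & cand <= L - 4L &
                   (cand - 1L >= 13L | L - cand >= 13L)]
    p <- sample(cand, 1L)
    ref <- substr(canonical, p, p)
    alt <- sample(setdiff(bases, ref), 1L)
    seq <- paste0(substr(canonical, 1L, p - 1L), alt,
                  substr(canonical, p + 1L, L))
    internal <- data.frame(pos = p, ref = ref, alt = alt, ins = "",
                           stringsAsFactors = FALSE)
    cls <- "polymorphic"
  } else if (type == "mixed") {
    # 5' single-base deletion plus a 3' non-template addition
    nt <- draw(1L, exclude_first = substr(flank3, 1L, 1L))
    seq <- paste0(substr(canonical, 2L, L), nt)
    e5 <- end_change("deletion", "", 1L)
    e3 <- end_change("addition", nt, 0L, "nontemplate")
    cls <- "mixed"
  } else {
    stop("unknown event type: ", type)
  }
  ann <- list(seq = seq, iso_class = cls, end5 = e5, end3 = e3,
              internal = internal)
  ann
}

#' Plant an isomiR population with ground truth
#'
#' For each mature, one variant is constructed per event type with
#' positive probability in the spectrum; per-sample counts are a
#' negative-binomial total per (mature, sample) -- times any group fold
#' change -- split multinomially across that mature's variants by the
#' spectrum.  Sequences colliding with a canonical or with a variant
#' carrying a different truth are re-drawn up to 20 times, then dropped
#' with a message.
#'
#' @param config A [sim_config()].
#' @param reference Result of [make_reference()].
#' @return A list: `truth` (data.frame, same columns as [classify_all()]
#'   output) and `counts` (integer matrix truth rows x samples), plus
#'   `sample_sheet` (`sample_id`, `group`).
#' @export
plant_isomirs <- function(config, reference) {
  set.seed(config$seed + 1L)
  spec <- config$event_spectrum[config$event_spectrum > 0]
  plc <- reference$placements
  prec <- stats::setNames(reference$precursors$sequence,
                          reference$precursors$precursor_id)
  rows <- list()
  probs <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(reference$matures))) {
    seen[[reference$matures$sequence[i]]] <-
      make_label(list(mature_id = reference$matures$mature_id[i],
                      iso_class = "canonical", end5 = end_change(),
                      end3 = end_change(), internal = empty_internal()))
  }
  n_retry <- 0L
  for (i in seq_len(nrow(reference$matures))) {
    m <- reference$matures[i, ]
    pl <- plc[plc$mature_id == m$mature_id, ][1L, ]
    ps <- prec[[pl$precursor_id]]
    flank5 <- substr(ps, max(1L, pl$start - 1L), pl$start)
    flank3 <- substr(ps, pl$end + 1L, min(nchar(ps), pl$end + 2L))
    for (ty in names(spec)) {
      ann <- NULL
      for (try in seq_len(20L)) {
        cand <- make_variant(ty, m$sequence, flank5, flank3,
                             config$added_nt_distribution)
        lab <- make_label(c(list(mature_id = m$mature_id), cand))
        prev <- seen[[cand$seq]]
        if (is.null(prev) || identical(prev, lab)) {
          seen[[cand$seq]] <- lab
          ann <- cand; ann$label <- lab
          break
        }
        n_retry <- n_retry + 1L
      }
      if (is.null(ann)) {
        message("dropping uncreatable variant ", ty, " for ", m$mature_id,
                " after 20 collisions")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(seq = ann$seq, mature_id = m$mature_id,
                   iso_class = ann$iso_class,
                   e5_kind = ann$end5$kind, e5_nts = ann$end5$nts,
                   e5_nrem = ann$end5$n_removed,
                   e5_template = ann$end5$template,
                   e3_kind = ann$end3$kind, e3_nts = ann$end3$nts,
                   e3_nrem = ann$end3$n_removed,
                   e3_template = ann$end3$template,
                   internal = internal_desc(ann$internal),
                   n_internal = nrow(ann$internal),
                   label = ann$label, event = ty,
                   stringsAsFactors = FALSE)
      probs[[length(rows)]] <- unname(spec[ty])
    }
  }
  if (n_retry > 0L) message(n_retry, " collision retry/retries during planting")
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  groups <- rep(names(config$samples_per_group), config$samples_per_group)
  sample_id <- unlist(lapply(names(config$samples_per_group), function(g)
    sprintf("%s_%02d", g, seq_len(config$samples_per_group[[g]]))))
  counts <- matrix(0L, nrow = nrow(truth), ncol = length(sample_id),
                   dimnames = list(truth$seq, sample_id))
  cm <- config$count_model
  mu_m <- stats::setNames(
    stats::rlnorm(nrow(reference$matures), cm$mean_log_mu, cm$mean_log_sd),
    reference$matures$mature_id)
  for (mid in unique(truth$mature_id)) {
    ridx <- which(truth$mature_id == mid)
    p <- unlist(probs[ridx])
    p <- p / sum(p)
    for (s in seq_along(sample_id)) {
      g <- groups[s]
      fc <- 1
      if (!is.null(config$fold_changes) &&
          !is.null(config$fold_changes[[g]]) &&
          mid %in% names(config$fold_changes[[g]])) {
        fc <- config$fold_changes[[g]][[mid]]
      }
      tot <- stats::rnbinom(1L, mu = mu_m[[mid]] * fc, size = cm$size)
      if (tot > 0L) {
        counts[ridx, s] <- counts[ridx, s] +
          as.integer(stats::rmultinom(1L, tot, p))
      }
    }
  }
  list(truth = truth, counts = counts,
       sample_sheet = data.frame(sample_id = sample_id, group = groups,
                                 stringsAsFactors = FALSE))
}

#' Write planted reads as per-sample FASTQ files
#'
#' Each planted sequence is emitted count-many times per sample: the
#' insert plus the full adapter, padded with random bases to the fixed
#' cycle count (as a sequencer reading through the adapter would), with
#' uniform Q40 qualities.  A low-quality spike can be injected for
#' chosen (sequence, sample) pairs to exercise the quality filter: the
#' first base of every supporting read drops to Q29.
#'
#' @param planted Result of [plant_isomirs()].
#' @param config The [sim_config()] used.
#' @param outdir Output directory (created if needed).
#' @param lowq Optional list with `seqs` and `samples`: every listed
#'   sequence is quality-spiked in every listed sample.
#' @return The sample sheet data.frame with a `fastq` path column,
#'   invisibly; files `*.fastq`, `samples.tsv` and `truth.tsv` appear
#'   under `outdir`.
#' @export
write_fastq <- function(planted, config, outdir, lowq = NULL) {
  set.seed(config$seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ss <- planted$sample_sheet
  ss$fastq <- file.path(outdir, paste0(ss$sample_id, ".fastq"))
  rl <- config$read_length
  for (s in seq_len(nrow(ss))) {
    cnt <- planted$counts[, ss$sample_id[s]]
    idx <- rep(seq_along(cnt), cnt)
    if (length(idx) == 0L) {
      file.create(ss$fastq[s])
      next
    }
    ins <- planted$truth$seq[idx]
    reads <- substr(paste0(ins, config$adapter_seq,
                           strrep("A", rl)), 1L, rl)
    # random tail past the adapter, and optional sequencing errors
    need_pad <- nchar(ins) + nchar(config$adapter_seq) < rl
    if (any(need_pad)) {
      for (r in which(need_pad)) {
        from <- nchar(ins[r]) + nchar(config$adapter_seq) + 1L
        substr(reads[r], from, rl) <- rand_dna(rl - from + 1L)
      }
    }
    if (config$seq_error_rate > 0) {
      reads <- vapply(reads, function(rd) {
        hit <- which(stats::runif(nchar(rd)) < config$seq_error_rate)
        for (p in hit) {
          substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(rd, p, p)), 1L)
        }
        rd
      }, character(1L), USE.NAMES = FALSE)
    }
    quals <- strrep("I", nchar(reads))
    if (!is.null(lowq) && ss$sample_id[s] %in% lowq$samples) {
      spike <- planted$truth$seq[idx] %in% lowq$seqs
      if (any(spike)) {
        qs <- quals[spike]
        substr(qs, 1L, 1L) <- ">"  # Q29
        quals[spike] <- qs
      }
    }
    out <- character(4L * length(reads))
    out[seq(1L, by = 4L, length.out = length(reads))] <-
      sprintf("@%s_read%d", ss$sample_id[s], seq_along(reads))
    out[seq(2L, by = 4L, length.out = length(reads))] <- reads
    out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = length(reads))] <- quals
    writeLines(out, ss$fastq[s])
  }
  utils::write.table(ss, file.path(outdir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(planted$truth, planted$counts),
                     file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ss)
}

#' Generate a complete synthetic dataset on disk
#'
#' Reference FASTAs, per-sample FASTQs, sample sheet and ground-truth
#' table; byte-identical for identical configurations.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param lowq Passed to [write_fastq()].
#' @return A list: `reference`, `planted`, `sample_sheet` (with paths),
#'   `mature_fa`, `hairpin_fa`, `outdir`.
#' @export
simulate_dataset <- function(config, outdir, lowq = NULL) {
  reference <- make_reference(config)
  planted <- plant_isomirs(config, reference)
  ss <- write_fastq(planted, config, outdir, lowq = lowq)
  mature_fa <- file.path(outdir, "mature.fa")
  hairpin_fa <- file.path(outdir, "hairpin.fa")
  write_reference_fasta(reference$matures, mature_fa)
  write_reference_fasta(reference$precursors, hairpin_fa)
  list(reference = reference, planted = planted, sample_sheet = ss,
       mature_fa = mature_fa, hairpin_fa = hairpin_fa, outdir = outdir)
}
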