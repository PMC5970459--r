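#' Affine-gap Smith-Waterman local alignment
#'
#' Optimal local alignment with full traceback, used both for canonical
#' assignment and for feature extraction against the assigned canonical.
#' Tie-breaking is deterministic: the first maximal cell in row-major
#' order ends the alignment, and traceback prefers diagonal over up (base
#' consumed from the query) over left (base consumed from the subject).
#'
#' @param query,subject Non-empty DNA strings.
#' @param scoring Scoring list from [alignment_scoring()].
#' @return A list of class `casmir_alignment`: `score`, 0-based half-open
#'   `q_start`/`q_end`/`s_start`/`s_end`, and gapped strings
#'   `q_aln`/`s_aln`.
#' @export
local_align <- function(query, subject, scoring = alignment_scoring()) {
  stopifnot(nzchar(query), nzchar(subject))
  a <- .sw_align_cpp(query, subject, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  a$query <- query
  a$subject <- subject
  class(a) <- "casmir_alignment"
  a
}

#' @export
print.casmir_alignment <- function(x, ...) {
  cat(sprintf("Local alignment score %g (q %d-%d, s %d-%d)\n",
              x$score, x$q_start, x$q_end, x$s_start, x$s_end))
  cat(" query:  ", x$q_aln, "\n subject:", x$s_aln, "\n")
  invisible(x)
}

end_change <- function(kind = "none", nts = "", n_removed = 0L,
                       template = "not_applicable") {
  list(kind = kind, nts = nts, n_removed = as.integer(n_removed),
       template = template)
}

#' Decompose an alignment into end changes and internal edits
#'
#' Applies the sequence-level isomiR definitions to a local alignment of a
#' read against its canonical form.  Per end: unaligned canonical bases
#' with no query overhang are a deletion; a query overhang with the
#' canonical end fully covered is an addition; both at once (which is also
#' how a substituted terminal base presents, since the local aligner trims
#' terminal mismatches) is a variation, which may lengthen the sequence
#' beyond the canonical.  Mismatches and gaps strictly between the first
#' and last canonical positions become internal (polymorphic) edits on
#' 1-based canonical coordinates.
#'
#' Query or canonical overhangs longer than `overhang_cap` mark the
#' sequence unclassifiable (likely degradation or chimera) rather than
#' forcing it into the taxonomy.
#'
#' @param alignment A `casmir_alignment` from [local_align()].
#' @param seq,canonical The aligned sequences (must match the alignment).
#' @param overhang_cap Maximum unaligned bases tolerated per end
#'   (default 6).
#' @return A list with `end5`, `end3` (each with `kind`, `nts`,
#'   `n_removed`, `template`), `internal` (data.frame `pos`, `ref`, `alt`,
#'   `ins`) and logical `unclassifiable`.
#' @export
extract_features <- function(alignment, seq, canonical, overhang_cap = 6L) {
  if (!identical(alignment$query, seq) ||
      !identical(alignment$subject, canonical)) {
    stop("alignment does not reference the given sequence pair")
  }
  L <- nchar(seq)
  Lc <- nchar(canonical)
  q5 <- as.integer(alignment$q_start)
  s5 <- as.integer(alignment$s_start)
  q3 <- L - as.integer(alignment$q_end)
  s3 <- Lc - as.integer(alignment$s_end)
  if (alignment$score <= 0 ||
      max(q5, q3, s5, s3) > overhang_cap) {
    return(list(end5 = end_change(), end3 = end_change(),
                internal = empty_internal(), unclassifiable = TRUE))
  }
  decompose_end <- function(q_over, s_over, nts) {
    if (q_over == 0L && s_over == 0L) end_change()
    else if (q_over == 0L) end_change("deletion", "", s_over)
    else if (s_over == 0L) end_change("addition", nts, 0L)
    else end_change("variation", nts, s_over)
  }
  end5 <- decompose_end(q5, s5, substr(seq, 1L, q5))
  end3 <- decompose_end(q3, s3, substr(seq, alignment$q_end + 1L, L))

  qa <- strsplit(alignment$q_aln, "")[[1]]
  sa <- strsplit(alignment$s_aln, "")[[1]]
  pos <- s5  # 0-based canonical position of the last consumed canonical base
  edits <- list()
  for (k in seq_along(qa)) {
    if (sa[k] != "-") {
      pos <- pos + 1L
      if (qa[k] == "-") {
        edits[[length(edits) + 1L]] <-
          data.frame(pos = pos, ref = sa[k], alt = "-", ins = "",
                     stringsAsFactors = FALSE)
      } else if (qa[k] != sa[k]) {
        edits[[length(edits) + 1L]] <-
          data.frame(pos = pos, ref = sa[k], alt = qa[k], ins = "",
                     stringsAsFactors = FALSE)
      }
    } else {
      # insertion in the query, attached to the preceding canonical base
      if (length(edits) &&
          edits[[length(edits)]]$pos == pos &&
          edits[[length(edits)]]$alt != "-") {
        edits[[length(edits)]]$ins <-
          paste0(edits[[length(edits)]]$ins, qa[k])
      } else {
        edits[[length(edits) + 1L]] <-
          data.frame(pos = pos, ref = substr(canonical, pos, pos),
                     alt = substr(canonical, pos, pos), ins = qa[k],
                     stringsAsFactors = FALSE)
      }
    }
  }
  internal <- if (length(edits)) do.call(rbind, edits) else empty_internal()
  list(end5 = end5, end3 = end3, internal = internal,
       unclassifiable = FALSE)
}

empty_internal <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             ins = character(), stringsAsFactors = FALSE)
}

#' Decide whether appended end bases are template or non-template
#'
#' Reads the precursor bases immediately flanking the mature placement
#' (upstream for a 5' addition, downstream for a 3' addition) in every
#' placement of the mature.  The addition is template if and only if the
#' added bases exactly match the flank of any placement; additions for a
#' mature with no placement, or whose flank runs off the precursor end,
#' are non-template.
#'
#' @param added_nts Non-empty added bases (query orientation).
#' @param side `"5p"` or `"3p"`.
#' @param placements Placement rows for this mature (possibly 0 rows).
#' @param precursor_seqs Named character vector of precursor sequences.
#' @return `"template"` or `"nontemplate"`.
#' @export
is_template_addition <- function(added_nts, side, placements,
                                 precursor_seqs) {
  stopifnot(nzchar(added_nts), side %in% c("5p", "3p"))
  k <- nchar(added_nts)
  if (is.null(placements) || nrow(placements) == 0L) return("nontemplate")
  for (r in seq_len(nrow(placements))) {
    prec <- precursor_seqs[[placements$precursor_id[r]]]
    flank <- if (side == "3p") {
      if (placements$end[r] + k > nchar(prec)) next
      substr(prec, placements$end[r] + 1L, placements$end[r] + k)
    } else {
      if (placements$start[r] - k < 0L) next
      substr(prec, placements$start[r] - k + 1L, placements$start[r])
    }
    if (flank == added_nts) return("template")
  }
  "nontemplate"
}

#' Classify one sequence against its canonical mature form
#'
#' Runs [local_align()], [extract_features()] and, for additions,
#' [is_template_addition()], then assigns the unique class of the
#' five-class taxonomy: `canonical` (exact match), `iso5p` / `iso3p`
#' (single-end change), `polymorphic` (internal edits only), `mixed` (at
#' least two of 5' change, 3' change, internal edits), or `unclassified`
#' when an end overhang exceeds the cap.
#'
#' @param seq Sequence to classify.
#' @param mature_id Canonical mature assigned by [select_canonical()].
#' @param canonical Canonical sequence of `mature_id`.
#' @param placements Placement rows of this mature
#'   (from [map_mature_to_precursors()]).
#' @param precursor_seqs Named character vector of precursor sequences.
#' @param scoring Scoring list from [alignment_scoring()].
#' @param overhang_cap See [extract_features()].
#' @return A list of class `casmir_annotation`: `seq`, `mature_id`,
#'   `iso_class`, `end5`, `end3`, `internal`, `label`.
#' @export
classify_isomir <- function(seq, mature_id, canonical, placements = NULL,
                            precursor_seqs = character(),
                            scoring = alignment_scoring(),
                            overhang_cap = 6L) {
  if (identical(seq, canonical)) {
    feats <- list(end5 = end_change(), end3 = end_change(),
                  internal = empty_internal(), unclassifiable = FALSE)
    cls <- "canonical"
  } else {
    aln <- local_align(seq, canonical, scoring)
    feats <- extract_features(aln, seq, canonical, overhang_cap)
    for (side in c("end5", "end3")) {
      if (feats[[side]]$kind == "addition") {
        feats[[side]]$template <- is_template_addition(
          feats[[side]]$nts, if (side == "end5") "5p" else "3p",
          placements, precursor_seqs)
      }
    }
    n5 <- feats$end5$kind != "none"
    n3 <- feats$end3$kind != "none"
    ni <- nrow(feats$internal) > 0L
    cls <- if (feats$unclassifiable) "unclassified"
      else if (n5 + n3 + ni >= 2L) "mixed"
      else if (n5) "iso5p"
      else if (n3) "iso3p"
      else if (ni) "polymorphic"
      else "unclassified"  # differs from canonical but no feature: degenerate
  }
  ann <- list(seq = seq, mature_id = mature_id, iso_class = cls,
              end5 = feats$end5, end3 = feats$end3,
              internal = feats$internal)
  ann$label <- make_label(ann)
  class(ann) <- "casmir_annotation"
  ann
}

#' @export
print.casmir_annotation <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}

# --- label grammar ---------------------------------------------------------
# {mature_id}|{class}|5p:{end}|3p:{end}|int:{edits}
#   end:   "=" | "-n" | "+NTS(template|nontemplate)" | "~NTS/n"
#   edits: comma-joined "{pos}{ref}>{alt}" with optional "+{ins}"; "=" if none

end_desc <- function(e) {
  switch(e$kind,
         none = "=",
         deletion = paste0("-", e$n_removed),
         addition = paste0("+", e$nts, "(", e$template, ")"),
         variation = paste0("~", e$nts, "/", e$n_removed))
}

internal_desc <- function(internal) {
  if (nrow(internal) == 0L) return("=")
  paste(sprintf("%d%s>%s%s", internal$pos, internal$ref, internal$alt,
                ifelse(nzchar(internal$ins),
                       paste0("+", internal$ins), "")),
        collapse = ",")
}

#' Build the stable annotation label
#'
#' A deterministic, lossless one-line grammar for the full feature bundle,
#' e.g. `hsa-miR-21-5p|iso3p|5p:=|3p:+C(nontemplate)|int:=`.
#' [parse_label()] inverts it exactly.
#'
#' @param ann A `casmir_annotation` (or list with the same fields).
#' @return The label string.
#' @export
make_label <- function(ann) {
  paste0(ann$mature_id, "|", ann$iso_class,
         "|5p:", end_desc(ann$end5),
         "|3p:", end_desc(ann$end3),
         "|int:", internal_desc(ann$internal))
}

parse_end_desc <- function(d) {
  if (d == "=") return(end_change())
  if (startsWith(d, "-")) {
    return(end_change("deletion", "", as.integer(substring(d, 2L))))
  }
  if (startsWith(d, "+")) {
    m <- regmatches(d, regexec("^\\+([ACGT]+)\\((template|nontemplate)\\)$",
                               d))[[1]]
    if (length(m) != 3L) stop("bad end descriptor: ", d)
    return(end_change("addition", m[2L], 0L, m[3L]))
  }
  if (startsWith(d, "~")) {
    m <- regmatches(d, regexec("^~([ACGT]+)/([0-9]+)$", d))[[1]]
    if (length(m) != 3L) stop("bad end descriptor: ", d)
    return(end_change("variation", m[2L], as.integer(m[3L])))
  }
  stop("bad end descriptor: ", d)
}

#' Parse an annotation label back into its feature bundle
#'
#' @param label A label produced by [make_label()].
#' @return A list with `mature_id`, `iso_class`, `end5`, `end3`,
#'   `internal` identical in content to the annotated original.
#' @export
parse_label <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L) stop("bad label: ", label)
  stopifnot(startsWith(parts[3L], "5p:"), startsWith(parts[4L], "3p:"),
            startsWith(parts[5L], "int:"))
  int_s <- substring(parts[5L], 5L)
  internal <- empty_internal()
  if (int_s != "=") {
    for (tok in strsplit(int_s, ",", fixed = TRUE)[[1]]) {
      m <- regmatches(tok,
        regexec("^([0-9]+)([ACGT])>([ACGT-])(\\+([ACGT]+))?$", tok))[[1]]
      if (length(m) == 0L) stop("bad internal edit: ", tok)
      internal <- rbind(internal,
        data.frame(pos = as.integer(m[2L]), ref = m[3L], alt = m[4L],
                   ins = m[6L], stringsAsFactors = FALSE))
    }
  }
  list(mature_id = parts[1L], iso_class = parts[2L],
       end5 = parse_end_desc(substring(parts[3L], 4L)),
       end3 = parse_end_desc(substring(parts[4L], 4L)),
       internal = internal)
}

#' Annotate a whole set of sequences
#'
#' Assigns each sequence to its canonical mature (unless `mature_ids` is
#' supplied) and classifies it, returning one row per sequence.
#' Unassigned sequences (no seeded alignment above the score floor) get
#' class `"unassigned"` and are excluded from per-miRNA totals downstream.
#'
#' @param seqs Character vector of unique sequences.
#' @param matures,precursors,placements Reference tables from the
#'   `reference_db` functions; `placements` defaults to
#'   [map_mature_to_precursors()] of the two databases.
#' @param mature_ids Optional pre-computed assignment (NA = unassigned).
#' @param scoring Scoring list from [alignment_scoring()].
#' @param overhang_cap See [extract_features()].
#' @return A data.frame with columns `seq`, `mature_id`, `iso_class`,
#'   `e5_kind`, `e5_nts`, `e5_nrem`, `e5_template`, `e3_kind`, `e3_nts`,
#'   `e3_nrem`, `e3_template`, `internal` (encoded edit string or `"="`),
#'   `n_internal`, `label`.
#' @export
classify_all <- function(seqs, matures, precursors, placements = NULL,
                         mature_ids = NULL,
                         scoring = alignment_scoring(), overhang_cap = 6L) {
  if (is.null(placements)) {
    placements <- map_mature_to_precursors(matures, precursors)
  }
  if (is.null(mature_ids)) {
    mature_ids <- assign_canonical(seqs, matures, scoring)
  }
  canon <- stats::setNames(matures$sequence, matures$mature_id)
  prec_seqs <- stats::setNames(precursors$sequence, precursors$precursor_id)
  plc_by_mature <- split(placements, placements$mature_id)
  rows <- lapply(seq_along(seqs), function(i) {
    mid <- mature_ids[i]
    if (is.na(mid)) {
      return(data.frame(seq = seqs[i], mature_id = NA_character_,
                        iso_class = "unassigned",
                        e5_kind = NA, e5_nts = NA, e5_nrem = NA,
                        e5_template = NA, e3_kind = NA, e3_nts = NA,
                        e3_nrem = NA, e3_template = NA, internal = NA,
                        n_internal = NA_integer_, label = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ann <- classify_isomir(seqs[i], mid, canon[[mid]],
                           plc_by_mature[[mid]], prec_seqs,
                           scoring, overhang_cap)
    data.frame(seq = seqs[i], mature_id = mid, iso_class = ann$iso_class,
               e5_kind = ann$end5$kind, e5_nts = ann$end5$nts,
               e5_nrem = ann$end5$n_removed, e5_template = ann$end5$template,
               e3_kind = ann$end3$kind, e3_nts = ann$end3$nts,
               e3_nrem = ann$end3$n_removed, e3_template = ann$end3$template,
               internal = internal_desc(ann$internal),
               n_internal = nrow(ann$internal), label = ann$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
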