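#' Default alignment scoring scheme
#'
#' Word size, gap-open and gap-extension penalties follow the short-read
#' miRNA alignment convention (word size 13, open 5, extend 2, forward
#' strand only); match/mismatch are blastn-short-like (+1/-3).  A gap of
#' length k costs `gap_open + k * gap_extend`.
#'
#' @param match,mismatch Match reward and mismatch penalty (signed).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param word_size Seed word size.
#' @param score_floor Minimum hit score retained; the default equals the
#'   score of a perfect seed word.
#' @return A list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1, mismatch = -3,
                              gap_open = 5, gap_extend = 2,
                              word_size = 13L, score_floor = NULL) {
  if (is.null(score_floor)) score_floor <- word_size * match
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       word_size = as.integer(word_size), score_floor = score_floor)
}

#' Build an exact k-mer seed index over the mature database
#'
#' Forward-strand only.  Matures shorter than the word size contribute no
#' k-mers and are unreachable by seeded alignment (warned).
#'
#' @param matures Data.frame from [load_mature_db()].
#' @param word_size Seed length (default 13).
#' @return An object of class `casmir_seed_index`: an environment mapping
#'   each k-mer to the integer indices of matures containing it, plus the
#'   mature table.
#' @export
build_seed_index <- function(matures, word_size = 13L) {
  word_size <- as.integer(word_size)
  stopifnot(word_size >= 4L)
  short <- matures$length < word_size
  if (any(short)) {
    warning(sum(short), " mature(s) shorter than the word size are ",
            "unreachable: ",
            paste(utils::head(matures$mature_id[short], 5L), collapse = ", "))
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(matures))) {
    s <- matures$sequence[i]
    L <- nchar(s)
    if (L < word_size) next
    for (off in seq_len(L - word_size + 1L)) {
      km <- substr(s, off, off + word_size - 1L)
      cur <- env[[km]]
      if (is.null(cur) || cur[length(cur)] != i) env[[km]] <- c(cur, i)
    }
  }
  structure(list(index = env, matures = matures, word_size = word_size),
            class = "casmir_seed_index")
}

#' Align a sequence to candidate mature miRNAs (seed and extend)
#'
#' Seeds with exact k-mer lookups, then runs a full affine-gap
#' Smith-Waterman local alignment against every seeded mature.  Because
#' both sequences are short, extension is a complete DP, so seeded results
#' are identical to exhaustive Smith-Waterman whenever a seed exists.
#'
#' @param seq Query sequence (DNA, uppercase).
#' @param index A `casmir_seed_index`.
#' @param scoring Scoring list from [alignment_scoring()].
#' @return A data.frame of hits (possibly 0 rows) with columns `mature_id`,
#'   `score`, `q_start`, `q_end`, `s_start`, `s_end`, `n_mismatch`,
#'   `n_gap`, `end_offset`, sorted by decreasing score then `mature_id`.
#' @export
align_to_mature <- function(seq, index, scoring = alignment_scoring()) {
  w <- index$word_size
  L <- nchar(seq)
  empty <- data.frame(mature_id = character(), score = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      n_mismatch = integer(), n_gap = integer(),
                      end_offset = integer(), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  cand <- integer(0)
  for (off in seq_len(L - w + 1L)) {
    km <- substr(seq, off, off + w - 1L)
    cand <- c(cand, index$index[[km]])
  }
  cand <- sort(unique(cand))
  if (length(cand) == 0L) return(empty)
  hits <- lapply(cand, function(i) {
    m <- index$matures[i, ]
    a <- local_align(seq, m$sequence, scoring)
    ed <- count_alignment_edits(a)
    data.frame(mature_id = m$mature_id, score = a$score,
               q_start = a$q_start, q_end = a$q_end,
               s_start = a$s_start, s_end = a$s_end,
               n_mismatch = ed["mismatch"], n_gap = ed["gap"],
               end_offset = a$q_start + a$s_start +
                 (L - a$q_end) + (m$length - a$s_end),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$score >= scoring$score_floor, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$mature_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

count_alignment_edits <- function(a) {
  qa <- strsplit(a$q_aln, "")[[1]]
  sa <- strsplit(a$s_aln, "")[[1]]
  gap <- qa == "-" | sa == "-"
  c(mismatch = sum(!gap & qa != sa), gap = sum(gap))
}

#' Select the canonical mature for a set of alignment hits
#'
#' Deterministic resolution: highest score; ties broken by smallest total
#' unaligned end offset, then fewest mismatches plus gaps, then
#' lexicographically smallest mature ID.  Each sequence is assigned to
#' exactly one canonical (no fractional multi-mapping).
#'
#' @param hits Data.frame from [align_to_mature()].
#' @return A single `mature_id`, or `NA_character_` for an empty hit list
#'   (the sequence is left unassigned).
#' @export
select_canonical <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NA_character_)
  o <- order(-hits$score, hits$end_offset, hits$n_mismatch + hits$n_gap,
             hits$mature_id)
  hits$mature_id[o[1L]]
}

#' Assign every collapsed sequence to a canonical mature miRNA
#'
#' @param seqs Character vector of unique sequences.
#' @param matures Data.frame from [load_mature_db()].
#' @param scoring Scoring list from [alignment_scoring()].
#' @return Character vector of mature IDs (NA = unassigned), parallel to
#'   `seqs`.
#' @export
assign_canonical <- function(seqs, matures, scoring = alignment_scoring()) {
  index <- build_seed_index(matures, scoring$word_size)
  vapply(seqs, function(s) select_canonical(align_to_mature(s, index, scoring)),
         character(1L), USE.NAMES = FALSE)
}
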