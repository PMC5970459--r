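#' Load a mature miRNA FASTA database
#'
#' Reads a miRBase-dialect FASTA file (RNA or DNA alphabet, headers of the
#' form `>name accession description`), canonicalizes every sequence to
#' uppercase DNA (U converted to T) and applies the mature-length gate.
#' Records outside 15--30 nt are rejected with a warning: shorter entries are
#' typically fragments or annotation errors and longer ones are not mature
#' miRNAs.
#'
#' @param fasta_path Path to the FASTA file.
#' @param species Optional species prefix (e.g. `"hsa"`); when given, only
#'   IDs starting with `species` followed by `-` are kept.
#' @param min_len,max_len Length gate applied after parsing (defaults 15, 30).
#' @return A data.frame with columns `mature_id`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy-miR-1 ACC001", "ACGUACGUACGUACGUAG"), fa)
#' load_mature_db(fa)
#' @export
load_mature_db <- function(fasta_path, species = NULL,
                           min_len = 15L, max_len = 30L) {
  db <- read_fasta_db(fasta_path, what = "mature")
  if (!is.null(species)) {
    db <- db[startsWith(db$id, paste0(species, "-")), , drop = FALSE]
  }
  bad <- db$length < min_len | db$length > max_len
  if (any(bad)) {
    warning(sprintf("rejected %d mature record(s) outside %d-%d nt: %s",
                    sum(bad), min_len, max_len,
                    paste(utils::head(db$id[bad], 5L), collapse = ", ")))
    db <- db[!bad, , drop = FALSE]
  }
  data.frame(mature_id = db$id, sequence = db$sequence, length = db$length,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Load a precursor (hairpin) FASTA database
#'
#' Same parsing and RNA-to-DNA canonicalization as [load_mature_db()] but
#' without a length gate.
#'
#' @inheritParams load_mature_db
#' @return A data.frame with columns `precursor_id`, `sequence`, `length`.
#' @export
load_precursor_db <- function(fasta_path, species = NULL) {
  db <- read_fasta_db(fasta_path, what = "precursor")
  if (!is.null(species)) {
    db <- db[startsWith(db$id, paste0(species, "-")), , drop = FALSE]
  }
  data.frame(precursor_id = db$id, sequence = db$sequence, length = db$length,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Shared FASTA reader: first whitespace-delimited header token is the ID,
# U -> T, uppercase, strict [ACGT]+ validation, duplicate IDs rejected.
read_fasta_db <- function(fasta_path, what = "sequence") {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  set <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e) {
                    stop("malformed FASTA '", fasta_path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) {
    stop("empty FASTA file: ", fasta_path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate ", what, " ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  ok <- grepl("^[ACGT]+$", seqs)
  if (!all(ok)) {
    stop("non-ACGU/ACGT characters in ", what, " record(s): ",
         paste(utils::head(ids[!ok], 5L), collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write a reference database back to FASTA
#'
#' Plain single-line FASTA in DNA alphabet; re-parsing the file with the
#' loaders reproduces the input records exactly.
#'
#' @param db A data.frame from [load_mature_db()] or [load_precursor_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  id_col <- intersect(c("mature_id", "precursor_id", "id"), names(db))[1L]
  if (is.na(id_col)) stop("no ID column in database")
  writeLines(paste0(">", db[[id_col]], "\n", db$sequence), path, sep = "\n")
  invisible(path)
}

#' Map mature miRNAs onto their precursor hairpins
#'
#' Exact substring search of every mature sequence in every precursor.
#' All occurrences are kept: a mature found in two hairpins, or twice within
#' one hairpin, yields one placement per occurrence.  Matures absent from
#' every precursor are retained in the database but flagged; for these,
#' template-form calls are impossible and end additions default to
#' non-template downstream.
#'
#' @param matures Data.frame from [load_mature_db()].
#' @param precursors Data.frame from [load_precursor_db()].
#' @return A data.frame of placements with columns `mature_id`,
#'   `precursor_id`, `start`, `end` (0-based half-open coordinates inside
#'   the precursor) and `arm`.  The character vector of unplaced mature IDs
#'   is attached as attribute `"unplaced"`.
#' @export
map_mature_to_precursors <- function(matures, precursors) {
  prec_set <- Biostrings::DNAStringSet(stats::setNames(precursors$sequence,
                                                       precursors$precursor_id))
  out <- vector("list", nrow(matures))
  for (k in seq_len(nrow(matures))) {
    hits <- lapply(seq_along(prec_set), function(p) {
      mp <- Biostrings::matchPattern(matures$sequence[k], prec_set[[p]])
      if (length(mp) == 0L) return(NULL)
      data.frame(mature_id = matures$mature_id[k],
                 precursor_id = precursors$precursor_id[p],
                 start = Biostrings::start(mp) - 1L,
                 end = Biostrings::end(mp),
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, hits)
  }
  plc <- do.call(rbind, out)
  if (is.null(plc)) {
    plc <- data.frame(mature_id = character(), precursor_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  prec_len <- stats::setNames(precursors$length, precursors$precursor_id)
  plc$arm <- arm_of(plc$mature_id, plc$start, plc$end,
                    prec_len[plc$precursor_id])
  unplaced <- setdiff(matures$mature_id, plc$mature_id)
  if (length(unplaced)) {
    message(length(unplaced), " mature(s) not found in any precursor; ",
            "additions for these will be called non-template: ",
            paste(utils::head(unplaced, 5L), collapse = ", "))
  }
  attr(plc, "unplaced") <- unplaced
  rownames(plc) <- NULL
  plc
}

#' Determine the hairpin arm of a mature miRNA
#'
#' Uses the `-5p`/`-3p` name suffix when present; otherwise the placement
#' midpoint relative to the precursor midpoint (first half = 5p, second
#' half = 3p); `"unknown"` when neither rule applies.
#'
#' @param mature_id Character vector of mature IDs.
#' @param start,end Optional 0-based half-open placement coordinates.
#' @param precursor_length Optional precursor length(s), recycled.
#' @return Character vector in `c("5p", "3p", "unknown")`.
#' @export
arm_of <- function(mature_id, start = NULL, end = NULL,
                   precursor_length = NULL) {
  arm <- rep("unknown", length(mature_id))
  arm[grepl("-5p$", mature_id)] <- "5p"
  arm[grepl("-3p$", mature_id)] <- "3p"
  if (!is.null(start) && length(start)) {
    mid <- (start + end) / 2
    pos_arm <- ifelse(mid < precursor_length / 2, "5p", "3p")
    use <- arm == "unknown" & !is.na(mid) & !is.na(precursor_length)
    arm[use] <- pos_arm[use]
  }
  arm
}
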