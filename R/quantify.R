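#' Normalize raw counts to reads per million trimmed reads
#'
#' Each count is scaled by 1e6 / (total trimmed reads of its sample).  An
#' optional second step (`"scale_median_ratio"`) additionally divides each
#' sample by the median ratio of its nonzero counts to the row-wise
#' geometric mean, a median-of-ratios correction for composition shifts
#' between libraries.  The default is scale-only.
#'
#' @param counts Numeric matrix (sequences x samples) of raw counts, or a
#'   `casmir_collapsed` object.
#' @param sample_totals Named vector of total trimmed reads per sample;
#'   taken from the collapsed object when omitted.
#' @param method `"scale_only"` (default) or `"scale_median_ratio"`.
#' @return A numeric matrix on the per-million scale, same dimnames.
#' @export
normalize_counts <- function(counts, sample_totals = NULL,
                             method = c("scale_only", "scale_median_ratio")) {
  method <- match.arg(method)
  if (inherits(counts, "casmir_collapsed")) {
    if (is.null(sample_totals)) sample_totals <- counts$sample_totals
    counts <- counts$counts
  }
  if (is.null(sample_totals)) stop("sample_totals required")
  sample_totals <- sample_totals[colnames(counts)]
  if (any(is.na(sample_totals)) || any(sample_totals <= 0)) {
    bad <- colnames(counts)[is.na(sample_totals) | sample_totals <= 0]
    stop("non-positive or missing total for sample(s): ",
         paste(bad, collapse = ", "))
  }
  norm <- sweep(counts, 2L, sample_totals, "/") * 1e6
  if (method == "scale_median_ratio") {
    use <- rowSums(norm > 0) == ncol(norm)  # rows observed everywhere
    geo <- exp(rowMeans(log(norm[use, , drop = FALSE])))
    if (length(geo)) {
      sf <- apply(norm[use, , drop = FALSE], 2L, function(col) {
        r <- col / geo
        stats::median(r[col > 0])
      })
      sf[is.na(sf) | sf <= 0] <- 1
      norm <- sweep(norm, 2L, sf, "/")
    }
  }
  norm
}

#' Abundance and prevalence filter
#'
#' Keeps rows whose mean normalized value over all samples is strictly
#' above `min_mean` and which are present (value > 0) in at least
#' `min_group_fraction` of the samples of at least one phenotype group.
#'
#' @param mat Normalized matrix (rows x samples).
#' @param groups Named character vector mapping sample ID to group.
#' @param min_mean Strict lower bound on the all-sample mean (default 5).
#' @param min_group_fraction Minimum within-group presence fraction
#'   (default 0.5).
#' @return The filtered matrix; rows removed in attribute `"n_removed"`.
#' @export
abundance_prevalence_filter <- function(mat, groups, min_mean = 5,
                                        min_group_fraction = 0.5) {
  groups <- groups[colnames(mat)]
  if (any(is.na(groups))) stop("groups must cover every sample column")
  mean_ok <- rowMeans(mat) > min_mean
  pres_ok <- rep(FALSE, nrow(mat))
  for (g in unique(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    pres_ok <- pres_ok | rowMeans(sub > 0) >= min_group_fraction
  }
  keep <- mean_ok & pres_ok
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Roll isomiR counts up to per-miRNA totals
#'
#' Sums all rows assigned to the same canonical mature, preserving sample
#' columns; unassigned rows are excluded and reported via the
#' `"n_unassigned"` attribute.  This is the per-miRNA quantity comparable
#' to name-level quantifiers such as miRDeep2, and the roll-up conserves
#' total assigned reads exactly.
#'
#' @param mat Count matrix (raw or normalized) with one row per sequence.
#' @param mature_ids Character vector parallel to the rows (NA =
#'   unassigned).
#' @return A matrix with one row per mature, attribute `"n_unassigned"`.
#' @export
summarize_per_mirna <- function(mat, mature_ids) {
  stopifnot(length(mature_ids) == nrow(mat))
  keep <- !is.na(mature_ids)
  out <- rowsum(mat[keep, , drop = FALSE], group = mature_ids[keep],
                reorder = TRUE)
  attr(out, "n_unassigned") <- sum(!keep)
  out
}

read_weight <- function(mat) rowSums(mat)

frac_table <- function(w, key) {
  keep <- !is.na(key) & w > 0
  if (!any(keep)) return(numeric(0))
  tot <- tapply(w[keep], key[keep], sum)
  s <- sum(tot)
  if (s == 0) return(numeric(0))
  sort(tot / s, decreasing = TRUE)
}

#' Read-weighted isomiR composition profile
#'
#' Computes the composition statistics of an annotated count table:
#' class fractions among total miRNA reads; the addition / deletion /
#' variation breakdown of 3' isomiR reads; the template fraction of 3'
#' additions; added-nucleotide spectra for all and for non-template 3'
#' additions; the polymorphic position histogram and substitution
#' spectrum (read-weighted incidences on canonical coordinates); and
#' per-mature most-abundant-form statistics (top sequence, its class, and
#' the ratio of its reads to canonical reads).  Each map is normalized
#' over its own denominator; maps with a zero denominator are empty.
#' `unclassified` and `unassigned` rows are excluded from all
#' denominators.  Mixed-class reads count once, under `mixed`, and enter
#' none of the single-class breakdowns.
#'
#' @param annotations Data.frame from [classify_all()].
#' @param mat Normalized count matrix, rows aligned with `annotations`
#'   (matched by row name = sequence when available).
#' @param arm_map Optional named vector mature_id -> arm (`"5p"`/`"3p"`);
#'   enables per-arm stratification.
#' @return A list of class `casmir_profile`.
#' @export
profile_composition <- function(annotations, mat, arm_map = NULL) {
  if (!is.null(rownames(mat))) {
    idx <- match(annotations$seq, rownames(mat))
    if (any(is.na(idx))) stop("annotation sequences missing from matrix")
    mat <- mat[idx, , drop = FALSE]
  }
  stopifnot(nrow(mat) == nrow(annotations))
  w <- read_weight(mat)
  ann <- annotations
  ok <- !(ann$iso_class %in% c("unassigned", "unclassified"))

  profile_for <- function(sel) {
    a <- ann[sel, , drop = FALSE]
    wt <- w[sel]
    is3 <- a$iso_class == "iso3p"
    add3 <- is3 & a$e3_kind == "addition"
    tmpl3 <- add3 & a$e3_template == "template"
    poly <- a$iso_class == "polymorphic"
    # read-weighted incidence of internal edits, expanded per edit
    poly_pos <- integer(0); poly_w <- numeric(0)
    poly_chg_k <- character(0); poly_chg_w <- numeric(0)
    for (i in which(poly & wt > 0)) {
      ed <- parse_label(a$label[i])$internal
      if (nrow(ed)) {
        poly_pos <- c(poly_pos, ed$pos)
        poly_w <- c(poly_w, rep(wt[i], nrow(ed)))
      }
      sub <- ed[ed$alt != "-" & ed$alt != ed$ref, , drop = FALSE]
      if (nrow(sub)) {
        poly_chg_k <- c(poly_chg_k, paste0(sub$ref, "-to-", sub$alt))
        poly_chg_w <- c(poly_chg_w, rep(wt[i], nrow(sub)))
      }
    }
    list(
      class_fractions = frac_table(wt, a$iso_class),
      iso3p_breakdown = frac_table(wt[is3], a$e3_kind[is3]),
      addition_template_fraction =
        if (sum(wt[add3]) > 0) sum(wt[tmpl3]) / sum(wt[add3]) else NA_real_,
      added_nt_spectrum = frac_table(wt[add3], a$e3_nts[add3]),
      added_nt_spectrum_nontemplate =
        frac_table(wt[add3 & a$e3_template == "nontemplate"],
                   a$e3_nts[add3 & a$e3_template == "nontemplate"]),
      polymorphic_pos_hist = frac_table(poly_w, poly_pos),
      polymorphic_change_spectrum = frac_table(poly_chg_w, poly_chg_k)
    )
  }

  prof <- profile_for(ok)
  prof$by_arm <- NULL
  if (!is.null(arm_map)) {
    arms <- arm_map[ann$mature_id]
    prof$by_arm <- lapply(c("5p", "3p"), function(a)
      profile_for(ok & !is.na(arms) & arms == a))
    names(prof$by_arm) <- c("5p", "3p")
  }

  # most-abundant-form statistics per mature
  assigned <- ok & !is.na(ann$mature_id)
  tops <- lapply(split(which(assigned), ann$mature_id[assigned]), function(ix) {
    wi <- w[ix]
    top <- ix[order(-wi, ann$seq[ix])[1L]]
    can <- ix[ann$iso_class[ix] == "canonical"]
    can_w <- if (length(can)) sum(w[can]) else 0
    data.frame(mature_id = ann$mature_id[top], top_seq = ann$seq[top],
               top_class = ann$iso_class[top], top_reads = w[top],
               canonical_reads = can_w,
               top_to_canonical_ratio =
                 if (can_w > 0) w[top] / can_w else Inf,
               stringsAsFactors = FALSE)
  })
  prof$most_abundant_form <- do.call(rbind, c(tops,
                                              make.row.names = FALSE))
  class(prof) <- "casmir_profile"
  prof
}

#' @export
print.casmir_profile <- function(x, digits = 3, ...) {
  cat("isomiR composition profile (read-weighted fractions)\n")
  cat("  classes: ",
      paste(sprintf("%s=%.1f%%", names(x$class_fractions),
                    100 * x$class_fractions), collapse = " "), "\n")
  if (length(x$iso3p_breakdown)) {
    cat("  3' breakdown:",
        paste(sprintf("%s=%.1f%%", names(x$iso3p_breakdown),
                      100 * x$iso3p_breakdown), collapse = " "), "\n")
  }
  if (!is.na(x$addition_template_fraction)) {
    cat(sprintf("  3' additions template: %.1f%%\n",
                100 * x$addition_template_fraction))
  }
  if (length(x$added_nt_spectrum)) {
    cat("  added nt:",
        paste(sprintf("%s=%.1f%%", names(x$added_nt_spectrum),
                      100 * x$added_nt_spectrum), collapse = " "), "\n")
  }
  invisible(x)
}
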