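#' Assign tags to known mature miRNAs under the tolerance rule
#'
#' A tag is assigned to a reference mature when it matches exactly, or
#' with at most 2 mismatches confined to the last 2 nt of its 3' end, or
#' with at most 1 internal mismatch, allowing up to 2 nt total length
#' difference (isomiR end variation). Each tag is assigned to at most one
#' miRNA: best match by fewest mismatches, then smallest length
#' difference, then lexicographically smallest reference id. Counts are
#' summed over assigned tags per miRNA per library.
#'
#' @param tags data.frame with `sequence`, `count`, `library_id`.
#' @param mature_reference named character vector of mature miRNAs.
#' @param config a [pipeline_config()].
#' @return list with `assignments` (per-tag: `tag_id`, `mirna_id`,
#'   `mismatches`) and `counts` (per miRNA x library raw counts, wide:
#'   `mirna_id`, one column per library).
#' @export
assign_conserved <- function(tags, mature_reference,
                             config = pipeline_config()) {
  if (!length(mature_reference)) {
    stop("mature miRNA reference set is empty")
  }
  ord <- order(names(mature_reference))
  mat <- mature_reference[ord]
  asg <- .assign_mature_cpp(tags$sequence, unname(mat),
                            config$homolog_shift, config$homolog_len_diff,
                            config$homolog_end_mm,
                            config$homolog_internal_mm)
  hit <- asg$ref > 0L
  assignments <- data.frame(
    tag_id = tags$tag_id[hit],
    library_id = tags$library_id[hit],
    count = tags$count[hit],
    mirna_id = names(mat)[asg$ref[hit]],
    mismatches = asg$mismatches[hit],
    stringsAsFactors = FALSE)
  libs <- sort(unique(tags$library_id))
  counts <- data.frame(mirna_id = sort(names(mature_reference)),
                       stringsAsFactors = FALSE)
  for (lib in libs) {
    sub <- assignments[assignments$library_id == lib, , drop = FALSE]
    agg <- tapply(sub$count, sub$mirna_id, sum)
    counts[[paste0("count_", lib)]] <-
      as.integer(ifelse(is.na(agg[counts$mirna_id]), 0L,
                        agg[counts$mirna_id]))
  }
  stage_log("assign_conserved", nrow(tags), nrow(assignments))
  list(assignments = assignments, counts = counts)
}

#' Detect star-strand reads against reference precursors
#'
#' A tag is a star read of a reference miRNA when it aligns (<= 1
#' mismatch) within the precursor hairpin on the arm opposite the
#' annotated mature: the landing interval must cover the fold-predicted
#' star region (the positions paired to the mature, 3' extended by the
#' Dicer overhang) for at least half of the tag and must not overlap the
#' mature.
#'
#' @param tags data.frame with `sequence`, `count`, `library_id`.
#' @param precursors data.frame with `mirna_id`, `sequence`,
#'   `mature_start`, `mature_end` (1-based within the precursor).
#' @param config a [pipeline_config()].
#' @return data.frame per miRNA x library: `mirna_id`, `library_id`,
#'   `star_count`.
#' @export
detect_star <- function(tags, precursors, config = pipeline_config()) {
  out <- list()
  for (i in seq_len(nrow(precursors))) {
    pre <- precursors$sequence[i]
    ms <- precursors$mature_start[i]
    me <- precursors$mature_end[i]
    if (is.na(ms) || is.na(me)) {
      warning("precursor ", precursors$mirna_id[i],
              " lacks mature coordinates; skipped")
      next
    }
    fold <- fold_hairpin(pre)
    geom <- hairpin_geometry(fold, ms, me, config$star_overhang)
    if (!geom$on_stem) next
    star <- geom$star
    loc <- .locate_batch_cpp(tags$sequence, pre, 1L)
    s <- loc[, 1] + 1L
    e <- loc[, 1] + nchar(tags$sequence)
    cover <- pmax(0L, pmin(e, star[2]) - pmax(s, star[1]) + 1L)
    is_star <- loc[, 1] >= 0L &
      !(s <= me & e >= ms) &                  # must miss the mature arm
      cover >= 0.5 * nchar(tags$sequence)
    if (any(is_star)) {
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = precursors$mirna_id[i],
        library_id = tags$library_id[is_star],
        count = tags$count[is_star], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), library_id = character(0),
                      star_count = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  agg <- stats::aggregate(list(star_count = df$count),
                          by = list(mirna_id = df$mirna_id,
                                    library_id = df$library_id), sum)
  agg
}

# display rounding used in expression tables: half-up to integer
round_half_up <- function(x) floor(x + 0.5)

#' TPM normalisation with the zero -> 0.01 substitution
#'
#' TPM = count x 10^6 / library total, where the total is the per-library
#' sum of conserved-miRNA raw counts (the base under which published
#' per-miRNA normalised values are recovered; switchable to any totals
#' via the `totals` argument). Zero values are substituted with
#' `tpm_pseudo` (0.01) only for ratio computation; records below 1 TPM in
#' both libraries are flagged `excluded` and dropped from comparative
#' analysis. Display values are rounded half-up; full precision is kept
#' internally.
#'
#' @param counts data.frame with `mirna_id`, `count_A`, `count_B`.
#' @param config a [pipeline_config()].
#' @param totals optional named numeric `c(A=,B=)` overriding the
#'   denominators (e.g. total clean reads).
#' @return data.frame of expression records: raw counts, `tpm_A`/`tpm_B`
#'   (full precision), `tpm_A_disp`/`tpm_B_disp` (rounded),
#'   `log2_ratio` (B vs A, after pseudo-substitution), `fold_class`,
#'   `excluded`.
#' @export
tpm_normalize <- function(counts, config = pipeline_config(),
                          totals = NULL) {
  stopifnot(all(c("mirna_id", "count_A", "count_B") %in% names(counts)))
  if (is.null(totals)) {
    totals <- c(A = sum(counts$count_A), B = sum(counts$count_B))
  }
  if (any(totals == 0)) stop("library total is zero; cannot normalise")
  rec <- counts
  rec$tpm_A <- rec$count_A * 1e6 / totals[["A"]]
  rec$tpm_B <- rec$count_B * 1e6 / totals[["B"]]
  rec$tpm_A_disp <- round_half_up(rec$tpm_A)
  rec$tpm_B_disp <- round_half_up(rec$tpm_B)
  rec$excluded <- rec$tpm_A < config$tpm_discard &
                  rec$tpm_B < config$tpm_discard
  a <- ifelse(rec$tpm_A == 0, config$tpm_pseudo, rec$tpm_A)
  b <- ifelse(rec$tpm_B == 0, config$tpm_pseudo, rec$tpm_B)
  rec$log2_ratio <- log2(b / a)
  rec$fold_class <- fold_class(rec$log2_ratio, config)
  rec
}

#' Fold-change class of a log2 expression ratio
#'
#' `within_2fold` for |log2| <= 1 (boundary inclusive: an exactly 2-fold
#' change is "equal or less than 2-fold"), `fold_2_4` for 1 < |log2| <= 2
#' and `over_4fold` beyond.
#'
#' @param log2_ratio numeric vector.
#' @param config a [pipeline_config()] (bounds default to c(1, 2)).
#' @return character vector of classes.
#' @export
fold_class <- function(log2_ratio, config = pipeline_config()) {
  b <- config$fold_class_bounds
  ifelse(abs(log2_ratio) <= b[1], "within_2fold",
         ifelse(abs(log2_ratio) <= b[2], "fold_2_4", "over_4fold"))
}

# family of a miRNA id: strip trailing letter/star suffixes
# (mir-30b -> mir-30, let-7a -> let-7, mir-122 -> mir-122)
mirna_family <- function(id) sub("([a-z]|\\*)+$", "", id)

#' Comparative expression profile report
#'
#' Produces the top-N family table (summed raw counts with per-library
#' percentage shares), the maximum-difference table (records changed by
#' at least `max_diff_fold` in either direction, excluded records
#' dropped), the scatter data, and an average-linkage hierarchical
#' clustering of miRNAs on euclidean distance over log2(TPM + 1), with a
#' Newick serialisation for export.
#'
#' @param records data.frame from [tpm_normalize()].
#' @param config a [pipeline_config()].
#' @return list: `top_families`, `max_difference`, `scatter`,
#'   `clustering` (hclust), `newick` (character).
#' @export
profile_report <- function(records, config = pipeline_config()) {
  rec <- records
  rec$family <- mirna_family(rec$mirna_id)
  fam <- stats::aggregate(rec[, c("count_A", "count_B")],
                          by = list(family = rec$family), sum)
  fam$total <- fam$count_A + fam$count_B
  fam <- fam[order(-fam$total), , drop = FALSE]
  fam$share_A <- round_half_up(100 * fam$count_A / sum(fam$count_A))
  fam$share_B <- round_half_up(100 * fam$count_B / sum(fam$count_B))
  top <- utils::head(fam, config$top_n)

  keep <- !records$excluded
  ratio <- 2 ^ abs(records$log2_ratio)
  maxdiff <- records[keep & ratio >= config$max_diff_fold, , drop = FALSE]
  maxdiff <- maxdiff[order(-abs(maxdiff$log2_ratio)), , drop = FALSE]

  scatter <- records[keep, c("mirna_id", "tpm_A", "tpm_B", "log2_ratio",
                             "fold_class")]

  cl <- NULL
  nwk <- NULL
  if (sum(keep) >= 2L) {
    m <- log2(as.matrix(records[keep, c("tpm_A", "tpm_B")]) + 1)
    rownames(m) <- records$mirna_id[keep]
    cl <- stats::hclust(stats::dist(m), method = "average")
    nwk <- ape::write.tree(ape::as.phylo(cl))
  }
  list(top_families = top, max_difference = maxdiff, scatter = scatter,
       clustering = cl, newick = nwk)
}
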