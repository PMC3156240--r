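#' Find miRNA/miRNA*-like duplex pairs among unmapped tags
#'
#' Every tag with at least `s2_min_reads` reads (the dominant strand) is
#' aligned against the reverse of every other tag under a pairing
#' alphabet in which A-U/T, C-G and the G:U wobble count as paired and
#' any other aligned column is a mismatch. The alignment is gapped; gap
#' runs are bulges, each at most `s2_bulge_max` nt, with total gapped
#' columns bounded by `s2_gap_total`. A pair is kept iff some such
#' alignment has at most `s2_mismatch_max` mismatches. Both strands must
#' be 18-24 nt. A cheap banded upper bound on achievable paired columns
#' prunes hopeless partners before the constrained alignment; the bound
#' is exact from above, so pruning never changes the result.
#'
#' @param tags data.frame of unmapped tags (`tag_id`, `sequence`,
#'   `count`).
#' @param config a [pipeline_config()].
#' @return data.frame of candidate pairs: dominant/partner ids,
#'   sequences, counts, `mismatches`, `pairs`, `gap_total`, `max_bulge`.
#' @export
find_duplex_pairs <- function(tags, config = pipeline_config()) {
  empty <- data.frame(dominant_id = character(0), partner_id = character(0),
                      dominant_sequence = character(0),
                      partner_sequence = character(0),
                      dominant_count = integer(0), partner_count = integer(0),
                      mismatches = integer(0), pairs = integer(0),
                      gap_total = integer(0), max_bulge = integer(0),
                      stringsAsFactors = FALSE)
  len <- nchar(tags$sequence)
  tags <- tags[len >= config$s2_len[1] & len <= config$s2_len[2] &
               tags$count >= config$s2_partner_min_reads, , drop = FALSE]
  if (!nrow(tags)) return(empty)
  dominant <- tags$count >= config$s2_min_reads
  if (!any(dominant)) return(empty)
  raw <- .find_duplex_pairs_cpp(tags$sequence, dominant,
                                config$s2_mismatch_max,
                                config$s2_bulge_max, config$s2_gap_total)
  if (!nrow(raw)) return(empty)
  # orient each pair: the higher-count member is the dominant strand
  # (ties: lexicographically smaller sequence)
  dom_first <- tags$count[raw$dom] > tags$count[raw$partner] |
    (tags$count[raw$dom] == tags$count[raw$partner] &
       tags$sequence[raw$dom] <= tags$sequence[raw$partner])
  di <- ifelse(dom_first, raw$dom, raw$partner)
  pi <- ifelse(dom_first, raw$partner, raw$dom)
  res <- data.frame(
    dominant_id = tags$tag_id[di], partner_id = tags$tag_id[pi],
    dominant_sequence = tags$sequence[di],
    partner_sequence = tags$sequence[pi],
    dominant_count = tags$count[di], partner_count = tags$count[pi],
    mismatches = raw$mismatches, pairs = raw$pairs,
    gap_total = raw$gap_total, max_bulge = raw$max_bulge,
    stringsAsFactors = FALSE)
  # dominant member must itself satisfy the read floor after orientation
  res <- res[res$dominant_count >= config$s2_min_reads, , drop = FALSE]
  res <- res[order(-res$dominant_count, res$dominant_sequence,
                   res$partner_sequence), ]
  rownames(res) <- NULL
  stage_log("find_duplex_pairs", nrow(tags), nrow(res))
  res
}

# Energy parameters for folding linker-joined duplexes: interior loops
# are capped at s2_fold_max_interior (the duplex criteria already bound
# bulges at 4 nt, so structures needing larger interior loops could not
# be accepted anyway); this makes the batch fold several-fold faster.
s2_fold_params <- function(config) {
  p <- fold_params()
  p$max_interior <- config$s2_fold_max_interior
  p
}

# Join two duplex strands with the hairpin-forming linker in both orders,
# fold each, keep the lower-energy order, and measure how much of the
# first strand pairs with the second in the MFE structure.
duplex_join_fold <- function(dominant, partner,
                             config = pipeline_config()) {
  params <- s2_fold_params(config)
  orders <- list(c(dominant, partner), c(partner, dominant))
  best <- NULL
  for (o in orders) {
    joined <- paste0(o[1], config$linker, o[2])
    fold <- fold_hairpin(joined, params)
    if (is.null(best) || fold$dg < best$fold$dg) {
      best <- list(joined = joined, fold = fold, first = o[1],
                   second = o[2])
    }
  }
  n1 <- nchar(best$first)
  nl <- nchar(config$linker)
  # positions of the dominant strand within the joined sequence
  dom_pos <- if (best$first == dominant) seq_len(nchar(dominant))
             else n1 + nl + seq_len(nchar(dominant))
  other_pos <- setdiff(seq_len(nchar(best$joined)),
                       c(dom_pos, n1 + seq_len(nl)))
  partners <- best$fold$pairs[dom_pos]
  frac <- mean(partners %in% other_pos)
  list(joined = best$joined, dg = best$fold$dg, fold = best$fold,
       pair_fraction = frac,
       pairing_ok = frac >= config$s2_pair_frac)
}

#' Build, fold and filter linker-joined duplex hairpins
#'
#' Each candidate pair is joined with the standard hairpin-forming linker
#' in both orders; the order giving the lower folding free energy is
#' retained. A candidate is accepted iff the joined stem-loop folds at or
#' below `s2_dg_max` (default -21 kcal/mol, inclusive) AND at least
#' `s2_pair_frac` of the dominant strand's bases pair with partner bases
#' in the MFE structure.
#'
#' @param pairs data.frame from [find_duplex_pairs()].
#' @param config a [pipeline_config()].
#' @return the input with `joined_sequence`, `dg`, `structure`,
#'   `pair_fraction` and `status` columns added.
#' @export
join_and_fold <- function(pairs, config = pipeline_config()) {
  if (!nrow(pairs)) {
    pairs$joined_sequence <- character(0)
    pairs$dg <- numeric(0)
    pairs$structure <- character(0)
    pairs$pair_fraction <- numeric(0)
    pairs$status <- character(0)
    return(pairs)
  }
  p <- s2_fold_params(config)
  res <- .join_fold_batch_cpp(pairs$dominant_sequence,
                              pairs$partner_sequence, config$linker,
                              p$stack, p$hairpin, p$bulge, p$internal,
                              p$asym, p$asym_max, p$max_interior,
                              p$min_hairpin)
  pairs$joined_sequence <- as.character(res$joined)
  pairs$dg <- res$dg
  pairs$structure <- as.character(res$structure)
  pairs$pair_fraction <- res$pair_fraction
  pairs$status <- ifelse(pairs$dg > config$s2_dg_max, "rejected(energy)",
                  ifelse(pairs$pair_fraction < config$s2_pair_frac,
                         "rejected(pairing)", "accepted"))
  pairs
}

#' Remove mRNA degradation products from duplex candidates
#'
#' Candidates whose dominant strand is a substring (<= 1 mismatch) of a
#' transcriptome contig are re-labelled `mrna_fragment`; survivors are
#' the species-specific novel miRNA calls.
#'
#' @param candidates data.frame from [join_and_fold()].
#' @param transcripts named character vector of transcript contigs.
#' @param config a [pipeline_config()].
#' @return the input with `status` updated.
#' @export
remove_mrna_fragments <- function(candidates, transcripts,
                                  config = pipeline_config()) {
  acc <- which(candidates$status == "accepted")
  if (length(acc) && length(transcripts)) {
    m <- .match_any_ref_cpp(candidates$dominant_sequence[acc],
                            unname(transcripts),
                            config$transcript_mismatch_max)
    candidates$status[acc[m > 0L]] <- "mrna_fragment"
  }
  candidates
}

#' Genome-free novel miRNA discovery (full stage)
#'
#' Duplex search over unmapped tags, linker-joined folding with the
#' energy/pairing filter, transcriptome subtraction, and deduplication:
#' a dominant tag appearing in several candidate pairs keeps its
#' lowest-energy partner.
#'
#' @param tags data.frame of unmapped tags.
#' @param transcripts named character vector.
#' @param config a [pipeline_config()].
#' @return data.frame of duplex candidates with final `status`.
#' @export
run_strategy2 <- function(tags, transcripts, config = pipeline_config()) {
  pairs <- find_duplex_pairs(tags, config)
  if (nrow(pairs) && is.finite(config$s2_fold_per_dominant)) {
    # fold only the most duplex-like pairings of each dominant tag; the
    # true star scores at or near the top of its dominant's list
    pairs <- pairs[order(pairs$dominant_id, -pairs$pairs,
                         pairs$mismatches, -pairs$partner_count), ,
                   drop = FALSE]
    rank <- stats::ave(seq_len(nrow(pairs)), pairs$dominant_id,
                       FUN = seq_along)
    pairs <- pairs[rank <= config$s2_fold_per_dominant, , drop = FALSE]
  }
  cands <- join_and_fold(pairs, config)
  cands <- remove_mrna_fragments(cands, transcripts, config)
  if (nrow(cands)) {
    # deduplicate by dominant tag, keeping the lowest-energy partner
    cands <- cands[order(cands$dominant_id, cands$dg), , drop = FALSE]
    # prefer an accepted pairing over a lower-energy rejected one
    best <- lapply(split(cands, cands$dominant_id), function(g) {
      ga <- g[g$status == "accepted", , drop = FALSE]
      if (nrow(ga)) ga[which.min(ga$dg), ] else g[which.min(g$dg), ]
    })
    cands <- do.call(rbind, best)
    rownames(cands) <- NULL
    cands <- cands[order(-cands$dominant_count, cands$dominant_sequence), ]
  }
  stage_log("strategy2", nrow(tags), sum(cands$status == "accepted"))
  cands
}
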