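#' Excise candidate precursor windows around unannotated clusters
#'
#' For each cluster anchor two genomic windows are excised to test the
#' read as the 5' arm or the 3' arm of a putative precursor:
#' `[start - flank, end + short)` and `[start - short, end + flank)`
#' (defaults 70/15 nt). Minus-strand anchors yield the reverse complement
#' of the genomic slice. Windows running past a chromosome end are
#' truncated and flagged.
#'
#' @param anchors data.frame from [cluster_tags()]`$anchors`.
#' @param genome named character vector.
#' @param config a [pipeline_config()].
#' @return data.frame: one row per (anchor, arm hypothesis) with the
#'   window coordinates, the excised sequence in transcript orientation
#'   and the 1-based mature interval within the window.
#' @export
excise_candidates <- function(anchors, genome, config = pipeline_config()) {
  if (is.null(anchors) || !nrow(anchors)) return(data.frame())
  flank <- config$s1_flank
  short <- config$s1_short
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    chrlen <- nchar(genome[[a$chrom]])
    for (hyp in c("5p", "3p")) {
      # in transcript orientation the mature sits near the window 5' end
      # for the 5p hypothesis; on the minus strand that mirrors in
      # genomic coordinates
      upstream_small <- (hyp == "5p") == (a$strand == "+")
      ws <- a$start - if (upstream_small) short else flank
      we <- a$end + if (upstream_small) flank else short
      truncated <- ws < 0L || we > chrlen
      ws_c <- max(0L, ws)
      we_c <- min(chrlen, we)
      seq <- substr(genome[[a$chrom]], ws_c + 1L, we_c)
      if (a$strand == "-") seq <- revcomp(seq)
      # mature offset within the window, transcript orientation
      m_off <- if (a$strand == "+") a$start - ws_c else we_c - a$end
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = a$cluster_id, hypothesis = hyp, chrom = a$chrom,
        start = ws_c, end = we_c, strand = a$strand,
        sequence = seq, mature_start = m_off + 1L,
        mature_end = m_off + (a$end - a$start),
        truncated = truncated, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Apply the seven genome-anchored hairpin criteria
#'
#' Folds the candidate precursor, extracts the stem geometry around the
#' putative mature and evaluates the acceptance criteria: the mature must
#' reside on the stem; mature length 20-24 nt; mature read count >= 5;
#' folding free energy <= -18 kcal/mol (inclusive at the threshold);
#' largest bulge <= 4 nt; |len(miR) - len(miR*)| <= 4 nt; loop between
#' the arms 5-35 nt; duplex asymmetry <= 5 nt. A verdict object is always
#' returned; `accepted` is true iff every criterion holds.
#'
#' @param precursor character(1) candidate precursor sequence.
#' @param mature_start,mature_end 1-based mature interval within it.
#' @param mature_count read count supporting the mature.
#' @param config a [pipeline_config()].
#' @param fold optional precomputed [fold_hairpin()] result.
#' @return list with `verdicts` (named logicals), `accepted`, `status`,
#'   `dg`, `fold`, `geometry`.
#' @export
apply_strategy1_criteria <- function(precursor, mature_start, mature_end,
                                     mature_count,
                                     config = pipeline_config(),
                                     fold = NULL) {
  if (is.null(fold)) fold <- fold_hairpin(precursor)
  geom <- hairpin_geometry(fold, mature_start, mature_end,
                           config$star_overhang)
  mlen <- mature_end - mature_start + 1L
  v <- c(on_stem = geom$on_stem,
         mature_len = mlen >= config$s1_mature_len[1] &&
                      mlen <= config$s1_mature_len[2],
         min_reads = mature_count >= config$s1_min_reads,
         energy = fold$dg <= config$s1_dg_max,
         bulge = isTRUE(geom$max_bulge <= config$s1_bulge_max),
         len_diff = isTRUE(!is.null(geom$star) &&
           abs((geom$star[2] - geom$star[1] + 1L) - mlen) <=
             config$s1_lendiff_max),
         loop = isTRUE(geom$loop_length >= config$s1_loop[1] &&
                       geom$loop_length <= config$s1_loop[2]),
         asymmetry = isTRUE(geom$asymmetry <= config$s1_asym_max))
  accepted <- all(v)
  status <- if (accepted) "accepted"
            else paste0("rejected(", names(v)[!v][1], ")")
  list(verdicts = v, accepted = accepted, status = status,
       dg = fold$dg, fold = fold, geometry = geom)
}

#' Cross-check accepted candidates against transcripts and known miRNAs
#'
#' A candidate whose mature is a substring (<= 1 mismatch) of a
#' transcriptome contig is re-labelled an mRNA degradation fragment. A
#' candidate matching a known mature under the homolog tolerance rule
#' (<= 2 mismatches confined to the last 2 nt of the 3' end, or <= 1
#' internal mismatch, with <= 2 nt total length difference) is labelled a
#' conserved-family homolog rather than a novel miRNA. Everything else
#' remains accepted (novel).
#'
#' @param candidates data.frame with at least `mature_sequence` and
#'   `status` columns (status `"accepted"` rows are checked).
#' @param transcripts named character vector of transcript contigs.
#' @param known_matures named character vector of known mature miRNAs.
#' @param config a [pipeline_config()].
#' @return the input with `status` updated to `mrna_fragment` /
#'   `known_homolog` where the checks fire, plus an `evidence` column.
#' @export
cross_check <- function(candidates, transcripts, known_matures,
                        config = pipeline_config()) {
  if (!nrow(candidates)) return(candidates)
  if (!"evidence" %in% names(candidates)) {
    candidates$evidence <- NA_character_
  }
  acc <- which(candidates$status == "accepted")
  if (!length(acc)) return(candidates)
  seqs <- candidates$mature_sequence[acc]
  if (length(transcripts)) {
    m <- .match_any_ref_cpp(seqs, unname(transcripts),
                            config$transcript_mismatch_max)
    frag <- m > 0L
    candidates$status[acc[frag]] <- "mrna_fragment"
    candidates$evidence[acc[frag]] <- names(transcripts)[m[frag]]
  }
  acc <- which(candidates$status == "accepted")
  if (length(acc) && length(known_matures)) {
    ord <- order(names(known_matures))
    mat <- known_matures[ord]
    asg <- .assign_mature_cpp(candidates$mature_sequence[acc], unname(mat),
                              config$homolog_shift, config$homolog_len_diff,
                              config$homolog_end_mm,
                              config$homolog_internal_mm)
    hom <- asg$ref > 0L
    candidates$status[acc[hom]] <- "known_homolog"
    candidates$evidence[acc[hom]] <- names(mat)[asg$ref[hom]]
  }
  candidates
}

#' Genome-anchored novel miRNA discovery (full stage)
#'
#' Runs excision, folding and the seven criteria over every unannotated
#' mapped cluster, then the transcript/homolog cross-checks. When both
#' arm-hypothesis windows pass, the lower-free-energy window wins.
#'
#' @param clusters output of [cluster_tags()] restricted to
#'   candidate-category tags.
#' @param genome named character vector.
#' @param transcripts,known_matures reference sets for [cross_check()].
#' @param config a [pipeline_config()].
#' @return data.frame of candidates with verdicts and final status.
#' @export
run_strategy1 <- function(clusters, genome, transcripts, known_matures,
                          config = pipeline_config()) {
  anchors <- clusters$anchors
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      mature_sequence = character(0),
                      mature_count = integer(0), dg = numeric(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (is.null(anchors) || !nrow(anchors)) return(empty)
  windows <- excise_candidates(anchors, genome, config)
  out <- list()
  for (cid in unique(windows$cluster_id)) {
    w <- windows[windows$cluster_id == cid, , drop = FALSE]
    a <- anchors[anchors$cluster_id == cid, ]
    # read support below the floor can never pass; skip the fold work
    best <- NULL
    for (j in seq_len(nrow(w))) {
      if (a$rep_count >= config$s1_min_reads) {
        res <- apply_strategy1_criteria(
          w$sequence[j], w$mature_start[j], w$mature_end[j],
          a$rep_count, config)
      } else {
        res <- list(accepted = FALSE, status = "rejected(min_reads)",
                    dg = NA_real_,
                    verdicts = c(min_reads = FALSE))
      }
      cand <- data.frame(
        cluster_id = cid, hypothesis = w$hypothesis[j],
        chrom = w$chrom[j], start = w$start[j], end = w$end[j],
        strand = w$strand[j], precursor = w$sequence[j],
        mature_sequence = a$rep_sequence, mature_count = a$rep_count,
        dg = res$dg, accepted = res$accepted, status = res$status,
        truncated = w$truncated[j], stringsAsFactors = FALSE)
      if (is.null(best)) {
        best <- cand
      } else if (cand$accepted && !best$accepted) {
        best <- cand
      } else if (cand$accepted && best$accepted &&
                 !is.na(cand$dg) && cand$dg < best$dg) {
        best <- cand   # both arm hypotheses pass: lower-energy window wins
      }
      out[[paste(cid, j)]] <- NULL
    }
    out[[cid]] <- best
  }
  cands <- do.call(rbind, out)
  rownames(cands) <- NULL
  cands <- cross_check(cands, transcripts, known_matures, config)
  stage_log("strategy1", nrow(anchors), sum(cands$status == "accepted"))
  cands
}
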