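#' Map unique tags to the reference genome
#'
#' Reports ALL genomic loci where a tag aligns ungapped over its full
#' length at Hamming distance <= `map_mismatch_max` (default 1), on both
#' strands; minus-strand hits are matches of the tag's reverse complement
#' to the plus-strand sequence. Candidate loci come from an exact k-mer
#' seed index; the seed length is capped so that a tag with one mismatch
#' always retains an intact seed, hence the index only prunes and the
#' result is identical to a brute-force scan of every position.
#'
#' @param tags data.frame with `tag_id` and `sequence`.
#' @param genome named character vector (one element per chromosome).
#' @param config a [pipeline_config()].
#' @return data.frame of hits: `tag_id`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, `mismatches`, `best` (logical: minimal
#'   mismatch count for that tag).
#' @export
map_tags <- function(tags, genome, config = pipeline_config()) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (!nrow(tags)) {
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      best = logical(0), stringsAsFactors = FALSE))
  }
  minlen <- min(nchar(tags$sequence))
  # intact-seed guarantee with one mismatch: k <= ceil((L - 1) / 2)
  k <- min(config$kmer, as.integer(ceiling((minlen - 1) / 2)))
  out <- list()
  for (chrom in names(genome)) {
    hits <- .map_tags_cpp(tags$sequence, genome[[chrom]], k,
                          config$map_mismatch_max)
    if (nrow(hits)) {
      hits$chrom <- chrom
      out[[chrom]] <- hits
    }
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      best = logical(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits$tag_id <- tags$tag_id[hits$tag]
  hits$end <- hits$start + nchar(tags$sequence)[hits$tag]
  hits <- hits[order(hits$tag, hits$chrom, hits$start, hits$strand), ]
  minmm <- tapply(hits$mismatches, hits$tag, min)
  hits$best <- hits$mismatches == minmm[as.character(hits$tag)]
  rownames(hits) <- NULL
  stage_log("map_tags", nrow(tags), length(unique(hits$tag_id)))
  hits[, c("tag_id", "chrom", "start", "end", "strand", "mismatches",
           "best")]
}

#' Annotation cascade for mapped tags
#'
#' Assigns exactly one category per tag with fixed priority:
#' other ncRNA (rRNA/tRNA/snRNA/snoRNA, tag is a substring of a reference
#' at <= 1 mismatch) > rasiRNA (length 24-27 nt with a genomic hit
#' overlapping a repeat interval) > conserved miRNA (tolerance-rule match
#' to a known mature) > candidate (mapped, unannotated). Tags with no
#' genomic hit are `unmapped` and feed the genome-free discovery stage.
#'
#' @param tags data.frame of tags.
#' @param hits data.frame from [map_tags()].
#' @param references list with `ncrna` (named character vector),
#'   `ncrna_class` (named character vector of classes per reference),
#'   `repeats` (data.frame `chrom`,`start`,`end`, 0-based half-open),
#'   `mature` (named character vector of known mature miRNAs).
#' @param config a [pipeline_config()].
#' @return data.frame: `tag_id`, `category`, `evidence`.
#' @export
annotate_cascade <- function(tags, hits, references,
                             config = pipeline_config()) {
  for (need in c("ncrna", "repeats", "mature")) {
    if (is.null(references[[need]])) {
      stop("missing reference set: ", need)
    }
  }
  n <- nrow(tags)
  category <- rep("candidate_mapped", n)
  evidence <- rep(NA_character_, n)

  mapped <- tags$tag_id %in% hits$tag_id
  category[!mapped] <- "unmapped"

  # other ncRNA by substring match
  if (length(references$ncrna)) {
    m <- .match_any_ref_cpp(tags$sequence, unname(references$ncrna),
                            config$ncrna_mismatch_max)
    hit_nc <- mapped & m > 0L
    category[hit_nc] <- unname(
      references$ncrna_class[pmax(m[hit_nc], 1L)])
    evidence[hit_nc] <- names(references$ncrna)[m[hit_nc]]
  }

  # rasiRNA: 24-27 nt with a hit overlapping a repeat interval
  len <- nchar(tags$sequence)
  ras_len <- len >= config$rasirna_len[1] & len <= config$rasirna_len[2]
  open <- category == "candidate_mapped"
  if (nrow(references$repeats) && any(ras_len & open)) {
    rep_ir <- split(
      IRanges::IRanges(references$repeats$start + 1L,
                       references$repeats$end),
      references$repeats$chrom)
    in_repeat <- rep(FALSE, nrow(hits))
    for (chrom in names(rep_ir)) {
      sel <- hits$chrom == chrom
      if (!any(sel)) next
      ir <- IRanges::IRanges(hits$start[sel] + 1L, hits$end[sel])
      in_repeat[sel] <- IRanges::overlapsAny(ir, rep_ir[[chrom]])
    }
    ras_tags <- unique(hits$tag_id[in_repeat])
    sel <- open & ras_len & tags$tag_id %in% ras_tags
    category[sel] <- "rasiRNA"
    evidence[sel] <- "repeat_overlap"
  }

  # conserved miRNA by the tolerance rule
  open <- category == "candidate_mapped"
  if (length(references$mature) && any(open)) {
    ord <- order(names(references$mature))
    mat <- references$mature[ord]
    asg <- .assign_mature_cpp(tags$sequence[open], unname(mat),
                              config$homolog_shift, config$homolog_len_diff,
                              config$homolog_end_mm,
                              config$homolog_internal_mm)
    hit_m <- asg$ref > 0L
    idx <- which(open)[hit_m]
    category[idx] <- "conserved_miRNA"
    evidence[idx] <- names(mat)[asg$ref[hit_m]]
  }

  stage_log("annotate", n, sum(category == "candidate_mapped"))
  data.frame(tag_id = tags$tag_id, category = category,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Cluster candidate tags into isomiR groups around genomic loci
#'
#' Tags share a cluster when they have hits on the same chromosome and
#' strand whose intervals overlap or lie within `shift_max` nt of each
#' other (transitive closure; imprecise Drosha/Dicer processing scatters
#' variants of one locus over a few nt). Each tag contributes its primary
#' hit: the first best hit in deterministic chromosomal order. The
#' cluster representative is the member with the dominant read count
#' (ties: lexicographically smallest sequence).
#'
#' @param tags data.frame of tags (must include `count`).
#' @param hits data.frame from [map_tags()], restricted to the tags to
#'   cluster.
#' @param config a [pipeline_config()].
#' @return list with `members` (data.frame `cluster_id`, `tag_id`) and
#'   `anchors` (one row per cluster: representative tag, its locus and
#'   the cluster span).
#' @export
cluster_tags <- function(tags, hits, config = pipeline_config()) {
  hits <- hits[hits$tag_id %in% tags$tag_id & hits$best, , drop = FALSE]
  if (!nrow(hits)) {
    return(list(members = data.frame(cluster_id = character(0),
                                     tag_id = character(0)),
                anchors = data.frame()))
  }
  # primary hit: first best hit in chromosomal order
  hits <- hits[order(hits$chrom, hits$start, hits$strand), ]
  prim <- hits[!duplicated(hits$tag_id), , drop = FALSE]
  prim$count <- tags$count[match(prim$tag_id, tags$tag_id)]
  prim$sequence <- tags$sequence[match(prim$tag_id, tags$tag_id)]

  members <- list()
  anchors <- list()
  cid <- 0L
  for (key in unique(paste(prim$chrom, prim$strand))) {
    sel <- paste(prim$chrom, prim$strand) == key
    sub <- prim[sel, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start + 1L, sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = config$shift_max + 1L)
    grp <- IRanges::findOverlaps(ir, red,
                                 maxgap = config$shift_max,
                                 select = "first")
    for (gidx in sort(unique(grp))) {
      cid <- cid + 1L
      mem <- sub[grp == gidx, , drop = FALSE]
      rep_i <- order(-mem$count, mem$sequence)[1]
      members[[cid]] <- data.frame(
        cluster_id = sprintf("c%d", cid), tag_id = mem$tag_id,
        stringsAsFactors = FALSE)
      anchors[[cid]] <- data.frame(
        cluster_id = sprintf("c%d", cid),
        chrom = mem$chrom[1], strand = mem$strand[1],
        start = mem$start[rep_i], end = mem$end[rep_i],
        span_start = min(mem$start), span_end = max(mem$end),
        rep_tag_id = mem$tag_id[rep_i], rep_count = mem$count[rep_i],
        rep_sequence = mem$sequence[rep_i],
        total_count = sum(mem$count), n_members = nrow(mem),
        stringsAsFactors = FALSE)
    }
  }
  stage_log("cluster_tags", nrow(prim), cid)
  list(members = do.call(rbind, members), anchors = do.call(rbind, anchors))
}
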