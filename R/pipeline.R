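#' Run the full two-library small RNA analysis
#'
#' Composes all stages over a pair of libraries: clean -> collapse ->
#' map -> annotate -> (conserved profiling + star detection) ->
#' genome-anchored discovery on unannotated mapped clusters ->
#' genome-free duplex discovery on unmapped tags -> comparative TPM
#' expression profile.
#'
#' @param reads_by_lib named list (`A`, `B`) of clean-insert character
#'   vectors, or of lists with `reads` and optional `qualities`.
#' @param genome named character vector of chromosome sequences.
#' @param references list with `mature`, `ncrna`, `ncrna_class`,
#'   `repeats`, `transcripts` and optionally `precursors` (named
#'   character vector of known hairpins) plus `precursor_mature`
#'   (data.frame `mirna_id`, `sequence`, `mature_start`, `mature_end`)
#'   for star detection.
#' @param config a [pipeline_config()].
#' @return list with per-library results (`tags`, `funnel`, `histogram`,
#'   `hits`, `annotation`, `clusters`, `strategy1`, `strategy2`),
#'   combined `expression` records, `star` counts and `profile`.
#' @export
run_pipeline <- function(reads_by_lib, genome, references,
                         config = pipeline_config()) {
  stopifnot(all(c("A", "B") %in% names(reads_by_lib)))
  libs <- c("A", "B")
  per_lib <- list()
  all_tags <- list()
  for (lib in libs) {
    input <- reads_by_lib[[lib]]
    reads <- if (is.list(input)) input$reads else input
    quals <- if (is.list(input)) input$qualities else NULL
    cleaned <- clean_reads(reads, quals, config,
                           fastq_mode = !is.null(config$adapter_3p))
    tags <- collapse_reads(cleaned$reads, lib)
    hist <- length_histogram(tags)
    hits <- map_tags(tags, genome, config)
    ann <- annotate_cascade(tags, hits, references, config)
    # reads matching a known precursor outside the mature (star arms,
    # loop fragments) are set aside so discovery only sees new loci
    if (!is.null(references$precursors)) {
      open <- ann$category == "candidate_mapped"
      if (any(open)) {
        m <- .match_any_ref_cpp(tags$sequence[open],
                                unname(references$precursors),
                                config$ncrna_mismatch_max)
        idx <- which(open)[m > 0L]
        ann$category[idx] <- "conserved_hairpin"
        ann$evidence[idx] <- names(references$precursors)[m[m > 0L]]
      }
    }
    cand_ids <- ann$tag_id[ann$category == "candidate_mapped"]
    cand_tags <- tags[tags$tag_id %in% cand_ids, , drop = FALSE]
    clusters <- cluster_tags(cand_tags, hits, config)
    s1 <- run_strategy1(clusters, genome, references$transcripts,
                        references$mature, config)
    s1 <- dedupe_overlapping_candidates(s1)
    unmapped_ids <- ann$tag_id[ann$category == "unmapped"]
    s2 <- run_strategy2(tags[tags$tag_id %in% unmapped_ids, , drop = FALSE],
                        references$transcripts, config)
    per_lib[[lib]] <- list(tags = tags, funnel = cleaned$funnel,
                           histogram = hist, hits = hits,
                           annotation = ann, clusters = clusters,
                           strategy1 = s1, strategy2 = s2)
    keep <- ann$category %in% c("conserved_miRNA", "conserved_hairpin",
                                "candidate_mapped")
    all_tags[[lib]] <- tags[tags$tag_id %in% ann$tag_id[keep], ,
                            drop = FALSE]
  }

  cons_tags <- do.call(rbind, lapply(libs, function(lib) {
    ann <- per_lib[[lib]]$annotation
    t <- per_lib[[lib]]$tags
    t[t$tag_id %in% ann$tag_id[ann$category == "conserved_miRNA"], ,
      drop = FALSE]
  }))
  asg <- assign_conserved(cons_tags, references$mature, config)
  expr <- tpm_normalize(asg$counts, config)

  star <- NULL
  if (!is.null(references$precursor_mature)) {
    star_tags <- do.call(rbind, all_tags)
    assigned_key <- paste(asg$assignments$library_id,
                          asg$assignments$tag_id)
    star_tags <- star_tags[
      !paste(star_tags$library_id, star_tags$tag_id) %in% assigned_key, ,
      drop = FALSE]
    star <- detect_star(star_tags, references$precursor_mature, config)
    if (nrow(star)) {
      # mature counts side by side with the star counts
      cnt <- asg$counts
      star$mature_count <- mapply(function(id, lib) {
        col <- paste0("count_", lib)
        if (!col %in% names(cnt)) return(NA_integer_)
        v <- cnt[[col]][cnt$mirna_id == id]
        if (length(v)) v else NA_integer_
      }, star$mirna_id, star$library_id)
    }
  }

  profile <- profile_report(expr, config)
  list(libraries = per_lib, expression = expr, star = star,
       profile = profile, assignments = asg)
}

# accepted windows from the two arms of one locus overlap; keep the
# lower-energy candidate per overlapping group (chrom/strand)
dedupe_overlapping_candidates <- function(cands) {
  if (is.null(cands) || !nrow(cands)) return(cands)
  acc <- cands[cands$status == "accepted", , drop = FALSE]
  rest <- cands[cands$status != "accepted", , drop = FALSE]
  if (nrow(acc) < 2L) return(cands)
  keep <- rep(TRUE, nrow(acc))
  for (key in unique(paste(acc$chrom, acc$strand))) {
    sel <- which(paste(acc$chrom, acc$strand) == key)
    if (length(sel) < 2L) next
    ir <- IRanges::IRanges(acc$start[sel] + 1L, acc$end[sel])
    grp <- subjectHits_first(ir)
    for (g in unique(grp)) {
      members <- sel[grp == g]
      if (length(members) > 1L) {
        best <- members[which.min(acc$dg[members])]
        keep[setdiff(members, best)] <- FALSE
      }
    }
  }
  rbind(acc[keep, , drop = FALSE], rest)
}

# connected components of overlapping ranges via reduce
subjectHits_first <- function(ir) {
  red <- IRanges::reduce(ir)
  IRanges::findOverlaps(ir, red, select = "first")
}
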