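#' Pipeline configuration with study-scale defaults
#'
#' Builds the configuration list consumed by every stage. Every analysis
#' constant is a named, overridable field; the defaults are the thresholds
#' of the two-library carp-style small RNA study this pipeline implements:
#' 18-nt read length floor, one-mismatch genome mapping, 24-27 nt
#' rasiRNA window, the seven genome-anchored hairpin criteria (mature
#' 20-24 nt on the stem, >= 5 reads, dG <= -18 kcal/mol, bulge <= 4 nt,
#' miRNA/miRNA* length difference <= 4 nt, loop 5-35 nt, asymmetry <= 5
#' nt), the four genome-free duplex criteria (dominant >= 10 reads, both
#' strands 18-24 nt, <= 4 mismatches with G:U accepted, bulge <= 4 nt)
#' with the GCGGGGACGC hairpin-forming linker and dG <= -21 kcal/mol on
#' the joined fold, and TPM normalisation with the 0 -> 0.01 pseudo-count
#' and the "< 1 TPM in both libraries" exclusion. Free-energy cutoffs are
#' inclusive: a candidate sitting exactly on the threshold passes.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(s2_dg_max = -25)
#' cfg$s2_dg_max
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # preprocessing
    min_read_len = 18L,
    quality_min_mean = 20,
    adapter_3p = NULL,
    adapter_5p = NULL,
    adapter_min_match = 6L,
    adapter_mismatch = 1L,
    # mapping / annotation
    map_mismatch_max = 1L,
    kmer = 9L,
    ncrna_mismatch_max = 1L,
    rasirna_len = c(24L, 27L),
    shift_max = 3L,
    # genome-anchored discovery (strategy 1)
    s1_flank = 70L,
    s1_short = 15L,
    s1_mature_len = c(20L, 24L),
    s1_min_reads = 5L,
    s1_dg_max = -18,
    s1_bulge_max = 4L,
    s1_lendiff_max = 4L,
    s1_loop = c(5L, 35L),
    s1_asym_max = 5L,
    s1_require_star = FALSE,
    # genome-free discovery (strategy 2)
    s2_min_reads = 10L,
    s2_partner_min_reads = 1L,
    s2_len = c(18L, 24L),
    s2_mismatch_max = 4L,
    s2_bulge_max = 4L,
    s2_gap_total = 8L,
    s2_dg_max = -21,
    s2_pair_frac = 0.6,
    s2_fold_per_dominant = 25L,
    s2_fold_max_interior = 12L,
    linker = "GCGGGGACGC",
    # conserved assignment / homolog rule
    homolog_end_mm = 2L,
    homolog_internal_mm = 1L,
    homolog_len_diff = 2L,
    homolog_shift = 2L,
    transcript_mismatch_max = 1L,
    # expression profiling
    tpm_pseudo = 0.01,
    tpm_discard = 1,
    fold_class_bounds = c(1, 2),
    max_diff_fold = 10,
    top_n = 14L,
    star_overhang = 2L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_read_len >= 1L,
    cfg$map_mismatch_max >= 0L,
    cfg$kmer >= 4L,
    cfg$rasirna_len[1] <= cfg$rasirna_len[2],
    cfg$s1_dg_max < 0, cfg$s2_dg_max < 0,
    cfg$s1_min_reads >= 1L, cfg$s2_min_reads >= 1L,
    cfg$s1_loop[1] <= cfg$s1_loop[2],
    cfg$s2_len[1] <= cfg$s2_len[2],
    cfg$s2_pair_frac >= 0, cfg$s2_pair_frac <= 1,
    cfg$tpm_pseudo > 0,
    nchar(cfg$linker) > 0,
    cfg$fold_class_bounds[1] < cfg$fold_class_bounds[2]
  )
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param cfg a `pipeline_config` object.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a collapsed FASTA of unique tags
#'
#' Collapsed small RNA FASTA uses headers of the form `>name_x<count>`;
#' the suffix carries the number of raw reads collapsed into the tag.
#' Sequences are uppercased and U is normalised to T (the pipeline-wide
#' internal alphabet is DNA; folding converts back to RNA at its
#' boundary).
#'
#' @param path FASTA file path.
#' @param library_id library label stored with the tags.
#' @return data.frame with columns `tag_id`, `sequence`, `count`,
#'   `library_id`, ordered by count (decreasing) then sequence.
#' @export
read_collapsed_fasta <- function(path, library_id = NA_character_) {
  if (file.size(path) == 0) {
    return(data.frame(tag_id = character(0), sequence = character(0),
                      count = integer(0), library_id = character(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(tag_id = character(0), sequence = character(0),
                      count = integer(0), library_id = character(0),
                      stringsAsFactors = FALSE))
  }
  nm <- names(seqs)
  m <- regmatches(nm, regexec("^(\\S+)_x(\\d+)\\s*$", nm))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed collapsed-FASTA header (missing _x<count>): ",
         nm[which(bad)[1]])
  }
  tags <- data.frame(
    tag_id = vapply(m, `[`, character(1), 2L),
    sequence = chartr("u", "T", chartr("U", "T",
                      toupper(as.character(seqs)))),
    count = as.integer(vapply(m, `[`, character(1), 3L)),
    library_id = library_id,
    stringsAsFactors = FALSE)
  tags[order(-tags$count, tags$sequence), , drop = FALSE]
}

#' @rdname read_collapsed_fasta
#' @param tags data.frame as returned by [collapse_reads()].
#' @export
write_collapsed_fasta <- function(tags, path) {
  lines <- character(0)
  if (nrow(tags)) {
    lines <- as.vector(rbind(
      paste0(">", tags$tag_id, "_x", tags$count), tags$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Tab-separated report writer/reader
#'
#' All stage reports are plain TSV with a header line; these helpers
#' guarantee a lossless round trip for the column types the pipeline
#' emits.
#'
#' @param records data.frame.
#' @param path file path.
#' @return `read_report` returns a data.frame.
#' @export
write_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED3 / features as GFF3
#'
#' Internally all coordinates are 0-based half-open; BED shares that
#' convention, GFF3 output converts to 1-based inclusive.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param path output path.
#' @param source,type GFF3 source and type columns.
#' @export
write_bed3 <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed3
#' @export
write_gff3 <- function(intervals, path, source = "mirseek",
                       type = "miRNA_primary_transcript") {
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "+"
  id <- if ("id" %in% names(intervals)) intervals$id
        else paste0("feature", seq_len(nrow(intervals)))
  lines <- c("##gff-version 3",
             if (nrow(intervals)) paste(
               intervals$chrom, source, type,
               intervals$start + 1L, intervals$end, ".", strand, ".",
               paste0("ID=", id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#'
#' Convenience wrapper used for genomes, reference sets and transcript
#' contigs; sequences are uppercased with U normalised to T.
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta_seqs <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- chartr("u", "T", chartr("U", "T", toupper(as.character(seqs))))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_fasta_seqs
#' @param seqs named character vector.
#' @export
write_fasta_seqs <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

# one structured log line per stage: records-in -> records-out funnel
stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  invisible(NULL)
}
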