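#' Clean raw small RNA reads
#'
#' Applies the standard small RNA cleaning funnel in a fixed order so the
#' per-filter counts are well defined: (1) low-quality reads (mean Phred
#' below `quality_min_mean`, or any N call) are discarded; (2) the 3'
#' adapter is located (prefix match of at least `adapter_min_match` nt,
#' allowing `adapter_mismatch` mismatches) and trimmed, reads without an
#' adapter hit are discarded as "no 3' adapter"; (3) inserts beginning
#' with the 5' adapter are discarded as 5' adapter contaminants; (4)
#' inserts shorter than `min_read_len` (default 18 nt) are discarded.
#'
#' When `config$adapter_3p` is `NULL` the reads are taken to be
#' adapter-free inserts (collapsed-FASTA style input) and steps 2-3 are
#' skipped; supplying qualities without an adapter is allowed, supplying
#' FASTQ-mode input without a configured adapter is an error.
#'
#' @param reads character vector of read sequences (DNA alphabet).
#' @param qualities optional character vector of Sanger-encoded quality
#'   strings (offset 33), same length as `reads`.
#' @param config a [pipeline_config()].
#' @param fastq_mode logical; TRUE when reads are raw (adaptered)
#'   sequencer output.
#' @return list with `reads` (clean inserts) and `funnel`, a data.frame
#'   of per-stage read counts (`raw`, discarded per filter, `clean`).
#' @export
clean_reads <- function(reads, qualities = NULL, config = pipeline_config(),
                        fastq_mode = !is.null(config$adapter_3p)) {
  n_raw <- length(reads)
  if (fastq_mode && is.null(config$adapter_3p)) {
    stop("FASTQ-mode cleaning requires a 3' adapter sequence in the config")
  }
  drop_quality <- 0L
  if (!is.null(qualities)) {
    mean_q <- vapply(qualities, function(q) {
      mean(as.integer(charToRaw(q))) - 33
    }, numeric(1), USE.NAMES = FALSE)
    low <- mean_q < config$quality_min_mean | grepl("N", reads, fixed = TRUE)
    drop_quality <- sum(low)
    reads <- reads[!low]
  } else {
    low <- grepl("N", reads, fixed = TRUE)
    drop_quality <- sum(low)
    reads <- reads[!low]
  }

  drop_no3p <- 0L
  if (fastq_mode) {
    pos <- find_adapter(reads, config$adapter_3p,
                        config$adapter_min_match, config$adapter_mismatch)
    drop_no3p <- sum(pos == 0L)
    reads <- substr(reads[pos > 0L], 1L, pos[pos > 0L] - 1L)
  }

  drop_5p <- 0L
  if (fastq_mode && !is.null(config$adapter_5p)) {
    probe <- substr(config$adapter_5p, 1L, 8L)
    contam <- startsWith_mm(reads, probe, config$adapter_mismatch)
    drop_5p <- sum(contam)
    reads <- reads[!contam]
  }

  short <- nchar(reads) < config$min_read_len
  drop_short <- sum(short)
  reads <- reads[!short]

  funnel <- data.frame(
    stage = c("raw", "low_quality", "no_3p_adapter", "5p_contaminant",
              "too_short", "clean"),
    reads = c(n_raw, drop_quality, drop_no3p, drop_5p, drop_short,
              length(reads)),
    stringsAsFactors = FALSE)
  stage_log("clean_reads", n_raw, length(reads))
  list(reads = reads, funnel = funnel)
}

# leftmost position where a prefix of `adapter` (>= min_match nt) starts
# in each read, allowing `mismatch` mismatches; 0 = no hit
find_adapter <- function(reads, adapter, min_match = 6L, mismatch = 1L) {
  if (!length(reads)) return(integer(0))
  la <- nchar(adapter)
  maxlen <- max(nchar(reads))
  pos <- integer(length(reads))
  pending <- rep(TRUE, length(reads))
  for (p in seq_len(maxlen)) {
    if (!any(pending)) break
    idx <- which(pending)
    over <- pmin(la, nchar(reads[idx]) - p + 1L)
    ok_len <- over >= min_match
    if (!any(ok_len)) next
    idx <- idx[ok_len]
    over <- over[ok_len]
    frag <- substr(reads[idx], p, p + over - 1L)
    ad <- substring(adapter, 1L, over)
    mm <- hamming_vec(frag, ad)
    hit <- mm <= mismatch
    pos[idx[hit]] <- p
    pending[idx[hit]] <- FALSE
  }
  pos
}

# does each read start with `probe` (allowing mm mismatches)?
startsWith_mm <- function(reads, probe, mm = 1L) {
  lp <- nchar(probe)
  heads <- substr(reads, 1L, lp)
  full <- nchar(heads) == lp
  out <- rep(FALSE, length(reads))
  if (any(full)) out[full] <- hamming_vec(heads[full], probe) <= mm
  out
}

# vectorised Hamming distance between equal-length strings and one probe
# (or two equal-length vectors)
hamming_vec <- function(x, y) {
  if (length(y) == 1L) y <- rep(y, length(x))
  lens <- nchar(x)
  out <- integer(length(x))
  for (l in unique(lens)) {
    sel <- lens == l
    xm <- matrix(unlist(strsplit(x[sel], "")), ncol = l, byrow = TRUE)
    ym <- matrix(unlist(strsplit(y[sel], "")), ncol = l, byrow = TRUE)
    out[sel] <- rowSums(xm != ym)
  }
  out
}

#' Collapse clean reads to unique tags
#'
#' One tag per distinct sequence, with the number of reads collapsed; the
#' sum of counts equals the number of clean reads. Ordering is
#' deterministic: count decreasing, then sequence lexicographic.
#'
#' @param reads character vector of clean insert sequences.
#' @param library_id library label.
#' @return data.frame with `tag_id`, `sequence`, `count`, `library_id`.
#' @export
collapse_reads <- function(reads, library_id = NA_character_) {
  if (!length(reads)) {
    return(data.frame(tag_id = character(0), sequence = character(0),
                      count = integer(0), library_id = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  df$tag_id <- paste0("t", seq_len(nrow(df)))
  df$library_id <- library_id
  rownames(df) <- NULL
  stage_log("collapse", length(reads), nrow(df))
  df[, c("tag_id", "sequence", "count", "library_id")]
}

#' Read-length distribution weighted by tag counts
#'
#' @param tags data.frame from [collapse_reads()].
#' @return data.frame with `length` and `reads` (total read count at that
#'   length); sums to the clean-read total.
#' @export
length_histogram <- function(tags) {
  if (!nrow(tags)) {
    return(data.frame(length = integer(0), reads = integer(0)))
  }
  agg <- stats::aggregate(list(reads = tags$count),
                          by = list(length = nchar(tags$sequence)), sum)
  agg[order(agg$length), , drop = FALSE]
}
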