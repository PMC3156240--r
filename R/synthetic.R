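#' Simulation configuration for two-library small RNA studies
#'
#' Parameters for the mock genome and the pair of species libraries the
#' generator emits. Defaults emulate the statistical structure of a deep
#' two-species study: a shared set of conserved miRNA loci plus a few
#' genome-absent (species-specific) loci, log-normal locus expression,
#' geometric isomiR end-variation around a 21-23 nt modal mature length,
#' a 5% star-strand fraction, 0.1% per-base sequencing error, other-ncRNA
#' and mRNA-degradation contamination, and a handful of planted >= 10-fold
#' between-library expression differences.
#'
#' @param seed integer master seed; every output is a deterministic
#'   function of it.
#' @param n_mirna_loci conserved genomic miRNA loci (present in the mature
#'   reference set).
#' @param n_novel_loci genomic miRNA loci absent from the mature reference
#'   (targets for genome-anchored discovery).
#' @param n_genomefree_loci miRNA loci absent from the genome entirely
#'   (targets for genome-free duplex discovery).
#' @param n_ncrna_loci loci per contaminating ncRNA class (rRNA, tRNA,
#'   snRNA, snoRNA).
#' @param n_repeat_loci genomic copies of repeat units emitting 24-27 nt
#'   repeat-associated siRNAs.
#' @param n_transcript_loci mRNA contigs emitting degradation fragments;
#'   the first one is also inserted into the genome.
#' @param genome_length mock genome size (nt).
#' @param expression_logmean,expression_logsd log-normal parameters for
#'   per-locus relative abundance.
#' @param library_depth reads per library.
#' @param star_fraction probability a miRNA-locus read comes from the star
#'   arm.
#' @param isomir_geom_p geometric parameter for 5'/3' end offsets.
#' @param seq_error_rate per-base substitution probability.
#' @param n_diff_loci conserved loci given a planted between-library fold
#'   difference.
#' @param diff_fold planted fold change (>= 10).
#' @param mirna_share,ncrna_share,rasirna_share,transcript_share expected
#'   read-share of each source class.
#' @param frag_species number of recurrent degradation fragment species
#'   per ncRNA/repeat/transcript locus (degradation is hotspot-like, not
#'   uniform).
#' @param low_quality_fraction fraction of reads flagged low-quality in
#'   FASTQ mode.
#' @param adapter_3p,adapter_5p adapter sequences used in raw-FASTQ mode.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirna_loci = 20L,
                       n_novel_loci = 6L,
                       n_genomefree_loci = 5L,
                       n_ncrna_loci = 3L,
                       n_repeat_loci = 4L,
                       n_transcript_loci = 5L,
                       genome_length = 100000L,
                       expression_logmean = 0,
                       expression_logsd = 1.2,
                       library_depth = 1000000L,
                       star_fraction = 0.05,
                       isomir_geom_p = 0.6,
                       seq_error_rate = 0.001,
                       n_diff_loci = 5L,
                       diff_fold = 16,
                       mirna_share = 0.85,
                       ncrna_share = 0.06,
                       rasirna_share = 0.02,
                       transcript_share = 0.07,
                       frag_species = 30L,
                       low_quality_fraction = 0.02,
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC") {
  cfg <- as.list(environment())
  stopifnot(
    cfg$seed == floor(cfg$seed),
    cfg$n_mirna_loci >= 0, cfg$n_novel_loci >= 0,
    cfg$n_genomefree_loci >= 0, cfg$n_ncrna_loci >= 0,
    cfg$n_repeat_loci >= 0, cfg$n_transcript_loci >= 0,
    cfg$library_depth >= 0,
    cfg$star_fraction >= 0, cfg$star_fraction <= 1,
    cfg$isomir_geom_p > 0, cfg$isomir_geom_p <= 1,
    cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
    cfg$n_diff_loci <= cfg$n_mirna_loci,
    cfg$low_quality_fraction >= 0, cfg$low_quality_fraction < 1
  )
  share <- cfg$mirna_share + cfg$ncrna_share + cfg$rasirna_share +
    cfg$transcript_share
  stopifnot(abs(share - 1) < 1e-8)
  # each planted locus footprint is < 900 nt including the 160 nt spacing
  footprint <- 900L * (cfg$n_mirna_loci + cfg$n_novel_loci +
    4L * cfg$n_ncrna_loci + cfg$n_repeat_loci + 1L)
  if (cfg$genome_length < footprint) {
    stop("genome_length too small for the planted locus footprints")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement (DNA alphabet)
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stem-first precursor construction: draw a mature arm, derive the star
# arm as its reverse complement with 1-3 substitutions and at most one
# <= 2 nt bulge, join with a 6-20 nt loop and 5 nt pads. Guarantees (after
# bounded redraws) that the hairpin satisfies the structural discovery
# criteria, which rejection sampling of random sequence would not.
make_precursor <- function(genomefree = FALSE, pcfg = pipeline_config(),
                           max_tries = 60L) {
  for (try in seq_len(max_tries)) {
    mlen <- sample(20:24, 1L, prob = c(0.10, 0.25, 0.35, 0.20, 0.10))
    mature <- random_seq(mlen)
    # homopolymer runs >= 5 nt make the duplex register ambiguous under
    # folding (slippage), leaving the planted ground truth ill-defined
    if (grepl("A{5,}|C{5,}|G{5,}|T{5,}", mature)) next
    star <- revcomp(mature)
    n_mm <- sample(1:3, 1L)
    pos <- sample.int(nchar(star), n_mm)
    sv <- strsplit(star, "")[[1]]
    for (p in pos) sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1L)
    if (stats::runif(1) < 0.5) {       # one bulge of 1-2 nt in the star arm
      blen <- sample(1:2, 1L)
      if (stats::runif(1) < 0.5) {
        at <- sample(2:(length(sv) - 1L), 1L)
        sv <- append(sv, sample(c("A", "C", "G", "T"), blen, TRUE), after = at)
      } else if (length(sv) - blen >= 18L) {
        at <- sample(2:(length(sv) - blen), 1L)
        sv <- sv[-(at:(at + blen - 1L))]
      }
    }
    star <- paste(sv, collapse = "")
    loop <- random_seq(sample(6:20, 1L))
    pad5 <- random_seq(5L)
    pad3 <- random_seq(5L)
    mature_first <- stats::runif(1) < 0.5
    if (mature_first) {
      prec <- paste0(pad5, mature, loop, star, pad3)
      ms <- 6L
    } else {
      prec <- paste0(pad5, star, loop, mature, pad3)
      ms <- 5L + nchar(star) + nchar(loop) + 1L
    }
    me <- ms + mlen - 1L
    fold <- fold_hairpin(prec)
    geom <- hairpin_geometry(fold, ms, me)
    if (!geom$on_stem) next
    ok <- fold$dg <= pcfg$s1_dg_max &&
      geom$max_bulge <= pcfg$s1_bulge_max &&
      geom$loop_length >= pcfg$s1_loop[1] &&
      geom$loop_length <= pcfg$s1_loop[2] &&
      geom$asymmetry <= pcfg$s1_asym_max &&
      abs((geom$star[2] - geom$star[1] + 1L) - mlen) <= pcfg$s1_lendiff_max
    if (!ok) next
    if (genomefree) {
      # must also be recoverable by the genome-free duplex route
      aln <- .duplex_align_cpp(mature, star, pcfg$s2_mismatch_max,
                               pcfg$s2_bulge_max, pcfg$s2_gap_total)
      if (!aln$feasible) next
      dup <- duplex_join_fold(mature, star, pcfg)
      if (dup$dg > pcfg$s2_dg_max || !dup$pairing_ok) next
      if (nchar(star) < pcfg$s2_len[1] || nchar(star) > pcfg$s2_len[2]) next
    }
    star_s <- if (mature_first) ms + mlen + nchar(loop) else 6L
    return(list(precursor = prec, mature = mature, star = star,
                mature_start = ms, mature_end = me,
                star_start = star_s, star_end = star_s + nchar(star) - 1L))
  }
  stop("could not construct a criteria-satisfying precursor; check config")
}

#' Build the mock genome, reference fixture set and ground truth
#'
#' Plants each genomic precursor exactly once at a recorded coordinate
#' (half on the minus strand), keeps genome-free precursors out of the
#' genome, generates contaminating ncRNA/repeat/transcript sources with
#' recurrent degradation-fragment species, and draws per-locus log-normal
#' expression with `n_diff_loci` conserved loci planted at a
#' `diff_fold`-fold between-library difference (majority higher in
#' library B, mirroring the usual direction asymmetry of such studies).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth`: `genome` (named character vector),
#'   `loci` (data.frame of planted loci with coordinates, sequences and
#'   class), `sources` (read-emitting source table with per-library
#'   probabilities), `refs` (list: `mature`, `ncrna`, `ncrna_class`,
#'   `repeats`, `transcripts`), and `config`.
#' @export
build_mock_references <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pcfg <- pipeline_config()

  loci <- list()
  add_locus <- function(l) loci[[length(loci) + 1L]] <<- l

  fam_letters <- c("a", "b", "c")
  fam_id <- integer(0)
  while (length(fam_id) < config$n_mirna_loci) {
    fam_id <- c(fam_id, rep(length(unique(fam_id)) + 1L,
                            sample(1:3, 1L)))
  }
  fam_id <- fam_id[seq_len(config$n_mirna_loci)]

  mk_mirna <- function(i, class, id) {
    p <- make_precursor(genomefree = (class == "mirna_genomefree"), pcfg)
    c(list(locus_id = id, class = class), p)
  }

  conserved <- lapply(seq_len(config$n_mirna_loci), function(i) {
    fam <- fam_id[i]
    member <- sum(fam_id[seq_len(i)] == fam)
    suffix <- if (sum(fam_id == fam) > 1L) fam_letters[member] else ""
    mk_mirna(i, "mirna_genomic", sprintf("mir-%d%s", fam, suffix))
  })
  novel <- lapply(seq_len(config$n_novel_loci), function(i) {
    mk_mirna(i, "mirna_novel", sprintf("novel-%d", i))
  })
  genomefree <- lapply(seq_len(config$n_genomefree_loci), function(i) {
    mk_mirna(i, "mirna_genomefree", sprintf("gfree-%d", i))
  })

  nc_classes <- c(rRNA = 120L, tRNA = 76L, snRNA = 160L, snoRNA = 90L)
  ncrna <- list()
  for (cls in names(nc_classes)) {
    for (i in seq_len(config$n_ncrna_loci)) {
      ncrna[[length(ncrna) + 1L]] <- list(
        locus_id = sprintf("%s_%d", cls, i), class = cls,
        precursor = random_seq(nc_classes[[cls]]))
    }
  }

  repeat_units <- c(random_seq(200L), random_seq(200L))
  transcripts <- vapply(seq_len(config$n_transcript_loci),
                        function(i) random_seq(400L), character(1))
  names(transcripts) <- sprintf("contig_%d", seq_along(transcripts))

  # ---- assemble the genome with non-overlapping plantings ----
  g <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  occupied <- matrix(numeric(0), ncol = 2)
  # loci are spaced >= 160 nt apart: the +/-70 nt excision windows of one
  # locus never reach a neighbouring feature, and flank redraws during
  # context validation cannot touch another locus's flanks
  place <- function(len) {
    repeat {
      s <- sample.int(config$genome_length - len - 340L, 1L) + 170L
      e <- s + len - 1L
      if (!nrow(occupied) ||
          all(e + 160L < occupied[, 1] | s - 160L > occupied[, 2])) {
        occupied <<- rbind(occupied, c(s, e))
        return(s)
      }
    }
  }
  plant <- function(seq, strand = "+") {
    s <- place(nchar(seq))
    ins <- if (strand == "-") revcomp(seq) else seq
    g[s:(s + nchar(seq) - 1L)] <<- strsplit(ins, "")[[1]]
    s
  }

  loci_df <- list()
  for (l in c(conserved, novel)) {
    strand <- sample(c("+", "-"), 1L)
    s <- plant(l$precursor, strand)
    loci_df[[length(loci_df) + 1L]] <- data.frame(
      locus_id = l$locus_id, class = l$class, chrom = "chr1",
      start = s - 1L, end = s - 1L + nchar(l$precursor), strand = strand,
      precursor = l$precursor, mature = l$mature, star = l$star,
      mature_start = l$mature_start, mature_end = l$mature_end,
      star_start = l$star_start, star_end = l$star_end,
      stringsAsFactors = FALSE)
  }
  for (l in genomefree) {
    loci_df[[length(loci_df) + 1L]] <- data.frame(
      locus_id = l$locus_id, class = "mirna_genomefree", chrom = NA,
      start = NA_integer_, end = NA_integer_, strand = NA,
      precursor = l$precursor, mature = l$mature, star = l$star,
      mature_start = l$mature_start, mature_end = l$mature_end,
      star_start = l$star_start, star_end = l$star_end,
      stringsAsFactors = FALSE)
  }
  for (l in ncrna) {
    s <- plant(l$precursor, "+")
    loci_df[[length(loci_df) + 1L]] <- data.frame(
      locus_id = l$locus_id, class = l$class, chrom = "chr1",
      start = s - 1L, end = s - 1L + nchar(l$precursor), strand = "+",
      precursor = l$precursor, mature = NA, star = NA,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  repeats_bed <- list()
  for (i in seq_len(config$n_repeat_loci)) {
    unit <- repeat_units[(i %% 2L) + 1L]
    s <- plant(unit, "+")
    repeats_bed[[i]] <- data.frame(chrom = "chr1", start = s - 1L,
                                   end = s - 1L + nchar(unit),
                                   stringsAsFactors = FALSE)
    loci_df[[length(loci_df) + 1L]] <- data.frame(
      locus_id = sprintf("repeat_%d", i), class = "repeat", chrom = "chr1",
      start = s - 1L, end = s - 1L + nchar(unit), strand = "+",
      precursor = unit, mature = NA, star = NA,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  # one transcript is genomic (its fragments map), the rest are not
  if (config$n_transcript_loci > 0L) {
    s <- plant(transcripts[[1L]], "+")
    tr_start <- c(s - 1L, rep(NA_integer_, config$n_transcript_loci - 1L))
  } else {
    tr_start <- integer(0)
  }
  for (i in seq_len(config$n_transcript_loci)) {
    loci_df[[length(loci_df) + 1L]] <- data.frame(
      locus_id = names(transcripts)[i], class = "transcript",
      chrom = ifelse(is.na(tr_start[i]), NA, "chr1"),
      start = tr_start[i],
      end = ifelse(is.na(tr_start[i]), NA_integer_,
                   tr_start[i] + nchar(transcripts[i])),
      strand = ifelse(is.na(tr_start[i]), NA, "+"),
      precursor = unname(transcripts[i]), mature = NA, star = NA,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci_df)

  # Excision-context validation: a planted novel locus must be
  # recoverable by the genome-anchored procedure, i.e. the +/-70/15 nt
  # window fold around its mature must still satisfy the structural
  # criteria (flanking genome sequence can extend or reroute the stem).
  # Failing flanks are redrawn; locus spacing guarantees neighbours are
  # untouched.
  for (i in which(loci$class == "mirna_novel")) {
    L <- nchar(loci$precursor[i])
    if (loci$strand[i] == "+") {
      m_gs <- loci$start[i] + loci$mature_start[i] - 1L
      m_ge <- loci$start[i] + loci$mature_end[i]
    } else {
      m_gs <- loci$start[i] + L - loci$mature_end[i]
      m_ge <- loci$start[i] + L - loci$mature_start[i] + 1L
    }
    anchor <- data.frame(cluster_id = "v", chrom = "chr1",
                         strand = loci$strand[i], start = m_gs,
                         end = m_ge, stringsAsFactors = FALSE)
    for (try in 1:40) {
      genome_now <- c(chr1 = paste(g, collapse = ""))
      w <- excise_candidates(anchor, genome_now, pcfg)
      ok <- any(vapply(seq_len(nrow(w)), function(j) {
        apply_strategy1_criteria(w$sequence[j], w$mature_start[j],
                                 w$mature_end[j], 10L, pcfg)$accepted
      }, logical(1)))
      if (ok) break
      for (side in list(c(loci$start[i] - 75L, loci$start[i] - 1L),
                        c(loci$end[i] + 1L, loci$end[i] + 75L))) {
        lo <- max(1L, side[1] + 1L)
        hi <- min(length(g), side[2] + 1L)
        if (lo <= hi) {
          g[lo:hi] <- sample(c("A", "C", "G", "T"), hi - lo + 1L,
                             replace = TRUE)
        }
      }
    }
  }
  genome <- c(chr1 = paste(g, collapse = ""))

  # genome-free precursors (and their arms) must not occur in the genome
  for (i in which(loci$class == "mirna_genomefree")) {
    stopifnot(!grepl(loci$precursor[i], genome, fixed = TRUE),
              !grepl(revcomp(loci$precursor[i]), genome, fixed = TRUE))
  }

  # ---- read-emitting source table with per-library probabilities ----
  mirna_idx <- which(loci$class %in%
                     c("mirna_genomic", "mirna_novel", "mirna_genomefree"))
  w <- stats::rlnorm(length(mirna_idx), config$expression_logmean,
                     config$expression_logsd)
  wA <- w
  wB <- w
  diff_dir <- character(0)
  if (config$n_diff_loci > 0L) {
    cons_pos <- which(loci$class[mirna_idx] == "mirna_genomic")
    # plant fold differences on below-median-abundance loci: the large
    # between-species changes in such studies occur in low-to-mid
    # abundance miRNAs, and planting them on a dominant locus would
    # distort the whole library composition
    low <- cons_pos[w[cons_pos] <= stats::median(w[cons_pos])]
    if (length(low) < config$n_diff_loci) {
      low <- cons_pos[order(w[cons_pos])][seq_len(config$n_diff_loci)]
    }
    picked <- sort(sample(low, config$n_diff_loci))
    diff_dir <- rep(c("B", "B", "B", "B", "A"),
                    length.out = config$n_diff_loci)
    # apply the planted fold symmetrically (x sqrt(f) up, / sqrt(f) down)
    # so library composition, and hence the TPM of unchanged loci, stays
    # comparable between the two libraries
    half <- sqrt(config$diff_fold)
    for (k in seq_along(picked)) {
      up <- diff_dir[k] == "B"
      wB[picked[k]] <- wB[picked[k]] * (if (up) half else 1 / half)
      wA[picked[k]] <- wA[picked[k]] * (if (up) 1 / half else half)
    }
    diff_loci <- loci$locus_id[mirna_idx][picked]
  } else {
    diff_loci <- character(0)
  }

  sources <- list()
  add_src <- function(locus_id, class, arm, seq, wa, wb) {
    sources[[length(sources) + 1L]] <<- data.frame(
      locus_id = locus_id, class = class, arm = arm, sequence = seq,
      wA = wa, wB = wb, stringsAsFactors = FALSE)
  }
  sf <- config$star_fraction
  for (k in seq_along(mirna_idx)) {
    i <- mirna_idx[k]
    base_a <- wA[k] / sum(wA) * config$mirna_share
    base_b <- wB[k] / sum(wB) * config$mirna_share
    add_src(loci$locus_id[i], loci$class[i], "mature", loci$mature[i],
            base_a * (1 - sf), base_b * (1 - sf))
    add_src(loci$locus_id[i], loci$class[i], "star", loci$star[i],
            base_a * sf, base_b * sf)
  }
  frag_sources <- function(idx, share, len_range, n_species) {
    if (!length(idx)) return()
    lw <- stats::rlnorm(length(idx), 0, 1)
    lw <- lw / sum(lw) * share
    for (k in seq_along(idx)) {
      i <- idx[k]
      ref <- loci$precursor[i]
      ns <- min(n_species, nchar(ref) - min(len_range))
      fl <- sample(len_range[1]:len_range[2], ns, replace = TRUE)
      fs <- vapply(fl, function(L) sample.int(nchar(ref) - L + 1L, 1L),
                   integer(1))
      keep <- !duplicated(paste(fs, fl))   # one species per fragment
      fl <- fl[keep]
      fs <- fs[keep]
      ns <- length(fl)
      sw <- stats::rlnorm(ns, 0, 1)
      sw <- sw / sum(sw) * lw[k]
      for (q in seq_len(ns)) {
        add_src(loci$locus_id[i], loci$class[i],
                sprintf("frag_%d_%d", fs[q], fl[q]),
                substr(ref, fs[q], fs[q] + fl[q] - 1L), sw[q], sw[q])
      }
    }
  }
  frag_sources(which(loci$class %in% c("rRNA", "tRNA", "snRNA", "snoRNA")),
               config$ncrna_share, c(18L, 30L), 20L)
  frag_sources(which(loci$class == "repeat"), config$rasirna_share,
               c(24L, 27L), 10L)
  frag_sources(which(loci$class == "transcript"), config$transcript_share,
               c(18L, 28L), config$frag_species)
  sources <- do.call(rbind, sources)
  sources$wA <- sources$wA / sum(sources$wA)
  sources$wB <- sources$wB / sum(sources$wB)

  cons <- loci$class == "mirna_genomic"
  refs <- list(
    mature = stats::setNames(loci$mature[cons], loci$locus_id[cons]),
    precursors = stats::setNames(loci$precursor[cons],
                                 loci$locus_id[cons]),
    precursor_mature = data.frame(
      mirna_id = loci$locus_id[cons], sequence = loci$precursor[cons],
      mature_start = loci$mature_start[cons],
      mature_end = loci$mature_end[cons], stringsAsFactors = FALSE),
    ncrna = stats::setNames(
      loci$precursor[loci$class %in% names(nc_classes)],
      loci$locus_id[loci$class %in% names(nc_classes)]),
    ncrna_class = stats::setNames(
      loci$class[loci$class %in% names(nc_classes)],
      loci$locus_id[loci$class %in% names(nc_classes)]),
    repeats = do.call(rbind, repeats_bed),
    transcripts = transcripts)

  structure(list(genome = genome, loci = loci, sources = sources,
                 refs = refs, diff_loci = diff_loci, diff_dir = diff_dir,
                 config = config),
            class = "sim_truth")
}

#' Simulate one small RNA library from planted ground truth
#'
#' Draws exactly `library_depth` reads multinomially from the source
#' table. miRNA-arm reads receive independent geometric 5'/3' isomiR end
#' offsets (clipped to the precursor); all reads receive per-base
#' substitution errors at `seq_error_rate`. Each read records its source
#' locus, arm and injected error count.
#'
#' @param truth a `sim_truth` from [build_mock_references()].
#' @param library_id `"A"` or `"B"`.
#' @param config the same [sim_config()] used for the truth.
#' @return list with `reads` (character vector, length `library_depth`),
#'   `truth` (per-read data.frame: `locus_id`, `class`, `arm`, `errors`),
#'   `library_id`.
#' @export
simulate_library <- function(truth, library_id = c("A", "B"),
                             config = truth$config) {
  library_id <- match.arg(library_id)
  set.seed((config$seed %% 1000003L) * 131L +
             match(library_id, c("A", "B")))
  depth <- config$library_depth
  src <- truth$sources
  prob <- if (library_id == "A") src$wA else src$wB
  idx <- sample.int(nrow(src), depth, replace = TRUE, prob = prob)

  reads <- src$sequence[idx]
  cls <- src$class[idx]
  is_mir <- cls %in% c("mirna_genomic", "mirna_novel", "mirna_genomefree")

  # isomiR end variation for miRNA-arm reads
  if (any(is_mir) && config$isomir_geom_p < 1) {
    mi <- which(is_mir)
    li <- match(src$locus_id[idx[mi]], truth$loci$locus_id)
    arm <- src$arm[idx[mi]]
    s0 <- ifelse(arm == "mature", truth$loci$mature_start[li],
                 truth$loci$star_start[li])
    e0 <- ifelse(arm == "mature", truth$loci$mature_end[li],
                 truth$loci$star_end[li])
    plen <- nchar(truth$loci$precursor[li])
    gp <- config$isomir_geom_p
    d5 <- stats::rgeom(length(mi), gp) *
      sample(c(-1L, 1L), length(mi), replace = TRUE)
    d3 <- stats::rgeom(length(mi), gp) *
      sample(c(-1L, 1L), length(mi), replace = TRUE)
    s <- pmax(1L, pmin(s0 + d5, e0 - 15L))
    e <- pmin(plen, pmax(e0 + d3, s + 15L))
    reads[mi] <- substr(truth$loci$precursor[li], s, e)
  }

  # sequencing errors: per-read substitution count ~ Binomial(len, rate)
  errors <- integer(depth)
  if (config$seq_error_rate > 0) {
    lens <- nchar(reads)
    k <- stats::rbinom(depth, lens, config$seq_error_rate)
    errors <- k
    for (i in which(k > 0L)) {
      v <- strsplit(reads[i], "")[[1]]
      at <- sample.int(length(v), min(k[i], length(v)))
      for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
      reads[i] <- paste(v, collapse = "")
    }
  }

  stage_log(paste0("simulate_", library_id), depth, depth)
  list(reads = reads,
       truth = data.frame(locus_id = src$locus_id[idx], class = cls,
                          arm = src$arm[idx], errors = errors,
                          stringsAsFactors = FALSE),
       library_id = library_id)
}

#' Write the mock reference fixture set to a directory
#'
#' Emits `genome.fa`, `mature_ref.fa`, `ncrna_ref.fa`, `transcripts.fa`,
#' `repeats.bed` (BED3) and `truth.tsv` so that recovery checks are
#' backend-independent.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mock_references <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_seqs(truth$genome, file.path(dir, "genome.fa"))
  write_fasta_seqs(truth$refs$mature, file.path(dir, "mature_ref.fa"))
  write_fasta_seqs(truth$refs$precursors, file.path(dir, "hairpin_ref.fa"))
  nc <- truth$refs$ncrna
  names(nc) <- paste0(names(nc), " class=", truth$refs$ncrna_class)
  write_fasta_seqs(nc, file.path(dir, "ncrna_ref.fa"))
  write_fasta_seqs(truth$refs$transcripts, file.path(dir, "transcripts.fa"))
  write_bed3(truth$refs$repeats, file.path(dir, "repeats.bed"))
  write_report(truth$loci, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write simulated reads as FASTQ (Sanger offset 33) or collapsed FASTA
#'
#' In FASTQ mode the 3' adapter is appended and reads are truncated to
#' `read_len` cycles; a `low_quality_fraction` of reads receive Phred-2
#' qualities (all other bases are Phred 40), which is how quality
#' filtering is exercised downstream.
#'
#' @param lib result of [simulate_library()].
#' @param path output file.
#' @param format `"fastq"` or `"fasta"` (collapsed, `_x<count>` headers).
#' @param config the [sim_config()].
#' @param read_len sequencing read length for FASTQ mode.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, format = c("fasta", "fastq"),
                          config, read_len = 36L) {
  format <- match.arg(format)
  if (format == "fasta") {
    tags <- collapse_reads(lib$reads, lib$library_id)
    write_collapsed_fasta(tags, path)
  } else {
    raw <- substr(paste0(lib$reads, config$adapter_3p,
                         strrep("A", read_len)), 1L, read_len)
    n <- length(raw)
    qual <- strrep("I", nchar(raw))
    if (config$low_quality_fraction > 0) {
      lq <- stats::runif(n) < config$low_quality_fraction
      qual[lq] <- strrep("#", nchar(raw[lq]))
    }
    lines <- as.vector(rbind(paste0("@read", seq_len(n)), raw,
                             "+", qual))
    writeLines(lines, path)
  }
  invisible(path)
}
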