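#' Fold a putative precursor into its minimum-free-energy hairpin
#'
#' Predicts the MFE secondary structure of a single stem-loop under a
#' nearest-neighbour energy model (Watson-Crick and G:U stacking, hairpin,
#' bulge and internal-loop initiation penalties; see [fold_params()]).
#' The search space is restricted to single-hairpin structures (one nested
#' chain of pairs closed by one terminal loop, no multiloops, no
#' pseudoknots), which is the structure class a pre-miRNA is expected to
#' adopt. Folding is deterministic: energy ties are resolved towards the
#' structure with more pairs, then towards 5'-most pairing.
#'
#' The input may be in DNA or RNA alphabet; T and U are equivalent. If no
#' structure with negative free energy exists the open chain is returned
#' with `dg = 0`.
#'
#' @param sequence character(1), the candidate precursor (A/C/G/T/U).
#' @param params energy parameter list, see [fold_params()].
#' @return An object of class `hairpin_fold`: list with `sequence` (RNA
#'   alphabet), `structure` (dot-bracket), `dg` (kcal/mol), `pairs`
#'   (integer vector; `pairs[i]` is the 1-based partner of position i, 0 if
#'   unpaired).
#' @examples
#' fold_hairpin("GCGCGCGCGCGCGAAAAGCGCGCGCGCGC")
#' @export
fold_hairpin <- function(sequence, params = fold_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rna <- chartr("acgtuT", "ACGUUU", sequence)
  if (grepl("[^ACGU]", rna)) {
    stop("sequence contains non-ACGU/T characters")
  }
  res <- .fold_mfe_cpp(rna, params$stack, params$hairpin, params$bulge,
                       params$internal, params$asym, params$asym_max,
                       params$max_interior, params$min_hairpin)
  structure(list(sequence = rna, structure = res$structure,
                 dg = res$dg, pairs = as.integer(res$pairs)),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$dg),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Stem geometry of a mature miRNA within a folded hairpin
#'
#' Given an MFE fold and the interval occupied by the putative mature
#' miRNA, locates the star arm (the positions paired to the mature arm,
#' with the 3' end extended by the standard 2-nt Dicer overhang), and
#' measures the loop length, the bulge sizes on each side of the
#' miRNA/miRNA* duplex and the duplex asymmetry.
#'
#' A mature arm with fewer than half of its bases paired is not considered
#' to reside on the stem; this is reported as `on_stem = FALSE` rather
#' than as an error, so criteria evaluation can record the verdict.
#'
#' @param fold a `hairpin_fold` object.
#' @param mature_start,mature_end 1-based inclusive interval of the mature
#'   sequence within `fold$sequence`.
#' @param overhang integer, 3' extension applied to the star arm (default
#'   2 nt, the canonical Dicer overhang).
#' @return list with `on_stem` (logical), `mature` and `star` (1-based
#'   inclusive intervals, `star` NULL when off-stem), `loop_length`,
#'   `bulges` (list with per-side maximal unpaired run lengths inside the
#'   duplex), `max_bulge`, `asymmetry` (|unpaired mature side - unpaired
#'   star side|).
#' @export
hairpin_geometry <- function(fold, mature_start, mature_end, overhang = 2L) {
  stopifnot(inherits(fold, "hairpin_fold"))
  n <- nchar(fold$sequence)
  stopifnot(mature_start >= 1L, mature_end <= n, mature_start < mature_end)
  p <- fold$pairs
  idx <- mature_start:mature_end
  partners <- p[idx]
  paired <- partners > 0L
  off <- list(on_stem = FALSE, mature = c(mature_start, mature_end),
              star = NULL, loop_length = NA_integer_,
              bulges = list(mature = integer(0), star = integer(0)),
              max_bulge = NA_integer_, asymmetry = NA_integer_)
  if (mean(paired) < 0.5) return(off)
  # The window fold can extend the stem well past the true Drosha/Dicer
  # boundaries; the star arm is taken as the largest contiguous block of
  # partner positions (blocks split at gaps > 6 nt), and mature bases
  # pairing outside that block are treated as unpaired within the duplex.
  pp <- sort(partners[paired])
  blk <- cumsum(c(1L, diff(pp) > 6L))
  best_blk <- as.integer(names(which.max(table(blk))))
  span <- range(pp[blk == best_blk])
  # the mature arm must pair with a region outside itself (on the stem,
  # not folded back onto the loop / itself)
  if (span[1] <= mature_end && span[2] >= mature_start) return(off)
  star_start <- span[1]
  star_end <- span[2]
  out_of_duplex <- p[idx] > 0L & !(p[idx] >= span[1] & p[idx] <= span[2])
  p[idx[out_of_duplex]] <- 0L
  sidx <- span[1]:span[2]
  out_of_duplex <- p[sidx] > 0L &
    !(p[sidx] >= mature_start & p[sidx] <= mature_end)
  p[sidx[out_of_duplex]] <- 0L
  # canonical 2-nt 3' overhang on the star strand
  if (star_start > mature_end) {
    star_end <- min(n, star_end + overhang)
    five <- c(mature_start, mature_end)   # mature is the 5' arm
    three <- c(star_start, star_end)
  } else {
    star_start <- max(1L, star_start - overhang)
    five <- c(star_start, star_end)
    three <- c(mature_start, mature_end)
  }
  loop_length <- three[1] - five[2] - 1L
  # unpaired runs within the duplex region, per side, flanked by pairs
  runs_inside <- function(from, to) {
    sub <- p[from:to] > 0L
    r <- rle(sub)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !r$values & starts > 1L & ends < length(sub)
    r$lengths[keep]
  }
  mat_runs <- runs_inside(mature_start, mature_end)
  star_runs <- runs_inside(star_start, star_end)
  unpaired_in <- function(from, to) sum(p[from:to] == 0L)
  asym <- abs(unpaired_in(mature_start, mature_end) -
              unpaired_in(star_start, star_end))
  list(on_stem = TRUE, mature = c(mature_start, mature_end),
       star = c(star_start, star_end), loop_length = as.integer(loop_length),
       bulges = list(mature = as.integer(mat_runs),
                     star = as.integer(star_runs)),
       max_bulge = as.integer(max(c(mat_runs, star_runs, 0L))),
       asymmetry = as.integer(asym))
}

# Evaluate the free energy of an explicit single-hairpin pair chain.
# Shared by the folding tests' enumeration oracle and by energy reporting;
# operates purely on the parameter tables, independent of the DP search.
hairpin_energy <- function(rna, pair_list, params = fold_params()) {
  if (length(pair_list) == 0L) return(0)
  b <- strsplit(chartr("T", "U", rna), "")[[1]]
  ord <- order(vapply(pair_list, `[`, integer(1), 1L))
  pl <- pair_list[ord]
  e <- 0
  extrap <- function(last, tab_max, size) last + 1.079 * log(size / tab_max)
  for (h in seq_along(pl)) {
    i <- pl[[h]][1]; j <- pl[[h]][2]
    pij <- pair_type(b[i], b[j])
    if (pij == 0L) stop("illegal pair in structure")
    if (h < length(pl)) {
      k <- pl[[h + 1L]][1]; l <- pl[[h + 1L]][2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      pkl <- pair_type(b[k], b[l])
      if (n1 == 0L && n2 == 0L) {
        e <- e + params$stack[pij, pkl]
      } else if (n1 == 0L || n2 == 0L) {
        nb <- n1 + n2
        be <- if (nb <= length(params$bulge)) params$bulge[nb]
              else extrap(params$bulge[length(params$bulge)],
                          length(params$bulge), nb)
        e <- e + be + if (nb == 1L) params$stack[pij, pkl] else 0
      } else {
        sz <- n1 + n2
        ie <- if (sz <= length(params$internal) + 1L) params$internal[sz - 1L]
              else extrap(params$internal[length(params$internal)],
                          length(params$internal) + 1L, sz)
        e <- e + ie + min(params$asym * abs(n1 - n2), params$asym_max)
      }
    } else {
      size <- j - i - 1L
      if (size < params$min_hairpin) stop("hairpin loop below minimum")
      he <- if (size <= length(params$hairpin) + 2L) params$hairpin[size - 2L]
            else extrap(params$hairpin[length(params$hairpin)],
                        length(params$hairpin) + 2L, size)
      e <- e + he
    }
  }
  e
}
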