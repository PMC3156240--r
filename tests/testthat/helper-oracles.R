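# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive searches/scans sharing no code with the
# package's dynamic programs.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(v) paste(rev(v), collapse = ""),
                character(1)))
}

# all-positions Hamming scan over both strands (0-based starts): the
# mismatch count at every offset is accumulated by shifted whole-genome
# character comparisons, with no seeding or indexing involved
brute_hamming_hits <- function(tag, genome_seq, max_mm = 1L) {
  out <- list()
  gl <- nchar(genome_seq)
  tl <- nchar(tag)
  if (tl > gl) return(data.frame())
  gv <- strsplit(genome_seq, "")[[1]]
  n_pos <- gl - tl + 1L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else revcomp_chr(tag)
    qv <- strsplit(q, "")[[1]]
    mm <- integer(n_pos)
    for (i in seq_len(tl)) {
      mm <- mm + (gv[i:(i + n_pos - 1L)] != qv[i])
    }
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      out[[strand]] <- data.frame(start = hit - 1L, strand = strand,
                                  mismatches = mm[hit],
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# recursive feasibility/min-mismatch search for the duplex alignment:
# global alignment of x against reverse(y), pairing alphabet with G:U
# wobble, gap runs <= B, total gaps <= G, returns min mismatches or Inf
duplex_oracle_mm <- function(x, y, B = 4L, G = 8L) {
  a <- strsplit(x, "")[[1]]
  b <- rev(strsplit(y, "")[[1]])
  m <- length(a); n <- length(b)
  pairable <- function(p, q) {
    (p == "A" && q == "T") || (p == "T" && q == "A") ||
    (p == "C" && q == "G") || (p == "G" && q == "C") ||
    (p == "G" && q == "T") || (p == "T" && q == "G")
  }
  NG <- 2L * B + 1L
  best <- array(Inf, dim = c(m + 2L, n + 2L, G + 1L, NG))
  best_final <- Inf
  rec <- function(i, j, mm, t, g) {
    if (t > G || mm >= best_final) return()
    if (best[i, j, t + 1L, g + 1L] <= mm) return()
    best[i, j, t + 1L, g + 1L] <<- mm
    if (i > m && j > n) { best_final <<- min(best_final, mm); return() }
    if (i <= m && j <= n) rec(i + 1L, j + 1L,
                              mm + !pairable(a[i], b[j]), t, 0L)
    if (i <= m) {
      r <- if (g >= 1L && g <= B) g + 1L else 1L
      if (r <= B) rec(i + 1L, j, mm, t + 1L, r)
    }
    if (j <= n) {
      r <- if (g > B) g - B + 1L else 1L
      if (r <= B) rec(i, j + 1L, mm, t + 1L, B + r)
    }
  }
  rec(1L, 1L, 0L, 0L, 0L)
  best_final
}

# exhaustive enumeration of all single-hairpin pair chains of a short
# sequence; returns the minimum free energy over all of them (0 = open),
# scored independently of the folding DP via hairpin_energy()
enum_fold_oracle <- function(seq, params = fold_params()) {
  rna <- chartr("T", "U", toupper(seq))
  b <- strsplit(rna, "")[[1]]
  n <- length(b)
  pt <- function(i, j) mirseek:::pair_type(b[i], b[j])
  minh <- params$min_hairpin
  maxint <- params$max_interior
  best <- 0
  # chain = outer pair + nested continuation; enumerate every chain
  extend <- function(chain, i, j) {
    # close here as the hairpin loop
    if (j - i - 1 >= minh) {
      e <- mirseek:::hairpin_energy(rna, chain, params)
      if (e < best) best <<- e
    }
    for (k in (i + 1):(j - minh - 1)) {
      if (k > j - minh - 1) break
      n1 <- k - i - 1
      if (n1 > maxint) break
      for (l in (j - 1):(k + minh + 1)) {
        if (l < k + minh + 1) break
        n2 <- j - l - 1
        if (n1 + n2 > maxint) next
        if (pt(k, l) == 0L) next
        extend(c(chain, list(c(k, l))), k, l)
      }
    }
  }
  for (i in 1:(n - minh - 1)) {
    for (j in n:(i + minh + 1)) {
      if (j < i + minh + 1) break
      if (pt(i, j) == 0L) next
      extend(list(c(i, j)), i, j)
    }
  }
  best
}

# a stem-first hairpin with fully controlled geometry, for criteria tests:
# mature + loop + modified reverse complement of the mature
build_test_hairpin <- function(mature, loop_len = 8L, star = NULL) {
  if (is.null(star)) star <- revcomp_chr(mature)
  loop <- paste(rep(c("A", "C"), length.out = loop_len), collapse = "")
  list(precursor = paste0(mature, loop, star),
       mature_start = 1L, mature_end = nchar(mature),
       star_start = nchar(mature) + loop_len + 1L)
}
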