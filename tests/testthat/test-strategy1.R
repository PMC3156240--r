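# genome-anchored discovery: excision windows, seven criteria, cross-checks

anchor_fixture <- function(start, end, strand, genome_len = 5000L,
                           seed = 31) {
  set.seed(seed)
  g <- c(chr1 = rand_seq(genome_len))
  anchors <- data.frame(cluster_id = "c1", chrom = "chr1", strand = strand,
                        start = start, end = end, span_start = start,
                        span_end = end, rep_tag_id = "t1", rep_count = 50L,
                        rep_sequence = substr(g[[1]], start + 1L, end),
                        total_count = 50L, n_members = 1L,
                        stringsAsFactors = FALSE)
  list(genome = g, anchors = anchors)
}

test_that("both arm-hypothesis windows use the 70/15 default arithmetic", {
  fx <- anchor_fixture(1000L, 1022L, "+")
  w <- excise_candidates(fx$anchors, fx$genome)
  expect_equal(sort(w$start), c(930L, 985L))
  expect_equal(sort(w$end), c(1037L, 1092L))
  expect_false(any(w$truncated))
  # the window sequence is the genomic slice
  i <- which(w$start == 930L)
  expect_equal(w$sequence[i], substr(fx$genome[[1]], 931, 1037))
  # mature interval points back at the anchor
  expect_equal(w$sequence[i] |> substr(w$mature_start[i], w$mature_end[i]),
               fx$anchors$rep_sequence)
})

test_that("minus-strand windows are reverse complements of the slice", {
  fx <- anchor_fixture(1000L, 1022L, "-")
  w <- excise_candidates(fx$anchors, fx$genome)
  for (i in seq_len(nrow(w))) {
    expect_equal(w$sequence[i],
                 revcomp_chr(substr(fx$genome[[1]], w$start[i] + 1L,
                                    w$end[i])))
    expect_equal(substr(w$sequence[i], w$mature_start[i], w$mature_end[i]),
                 revcomp_chr(substr(fx$genome[[1]], 1001, 1022)))
  }
})

test_that("windows running past the chromosome start are truncated+flagged", {
  fx <- anchor_fixture(5L, 27L, "+")
  w <- excise_candidates(fx$anchors, fx$genome)
  expect_true(any(w$truncated))
  expect_true(all(w$start >= 0L))
})

test_that("the criteria accept a textbook hairpin, reject each violation", {
  mature <- "GCTAGGCTAGGCATCGATCGTAC"       # 23 nt
  h <- build_test_hairpin(mature, loop_len = 8L)
  ok <- apply_strategy1_criteria(h$precursor, h$mature_start, h$mature_end,
                                 mature_count = 5L)
  expect_true(ok$accepted)
  expect_true(all(ok$verdicts))

  # read floor: 5 passes (just above), 4 fails
  low <- apply_strategy1_criteria(h$precursor, h$mature_start, h$mature_end,
                                  mature_count = 4L)
  expect_false(low$verdicts[["min_reads"]])
  expect_equal(low$status, "rejected(min_reads)")

  # mature length: 24 passes, 25 fails
  m24 <- build_test_hairpin(substr(paste0(mature, "A"), 1, 24), 8L)
  expect_true(apply_strategy1_criteria(m24$precursor, 1L, 24L,
                                       9L)$verdicts[["mature_len"]])
  m25 <- build_test_hairpin(paste0(mature, "AT"), 8L)
  expect_false(apply_strategy1_criteria(m25$precursor, 1L, 25L,
                                        9L)$verdicts[["mature_len"]])

  # loop span: 35 passes, 36 fails
  l35 <- build_test_hairpin(mature, 35L)
  expect_true(apply_strategy1_criteria(l35$precursor, 1L, 23L,
                                       9L)$verdicts[["loop"]])
  l36 <- build_test_hairpin(mature, 36L)
  expect_false(apply_strategy1_criteria(l36$precursor, 1L, 23L,
                                        9L)$verdicts[["loop"]])
  l4 <- build_test_hairpin(mature, 4L)
  expect_false(apply_strategy1_criteria(l4$precursor, 1L, 23L,
                                        9L)$verdicts[["loop"]])

  # bulge: an interior run of 4 passes, 5 fails
  star <- revcomp_chr(mature)
  b4 <- build_test_hairpin(mature, 8L,
                           paste0(substr(star, 1, 11), "AAAA",
                                  substr(star, 12, 23)))
  r4 <- apply_strategy1_criteria(b4$precursor, 1L, 23L, 9L)
  expect_true(r4$verdicts[["bulge"]])
  b5 <- build_test_hairpin(mature, 8L,
                           paste0(substr(star, 1, 11), "AAAAA",
                                  substr(star, 12, 23)))
  r5 <- apply_strategy1_criteria(b5$precursor, 1L, 23L, 9L)
  expect_false(r5$verdicts[["bulge"]])

  # free energy boundary is inclusive: dg itself passes, just above fails
  dg <- ok$dg
  cfg_pass <- pipeline_config(s1_dg_max = dg)
  cfg_fail <- pipeline_config(s1_dg_max = dg - 0.01)
  expect_true(apply_strategy1_criteria(h$precursor, 1L, 23L, 9L,
                                       cfg_pass)$verdicts[["energy"]])
  expect_false(apply_strategy1_criteria(h$precursor, 1L, 23L, 9L,
                                        cfg_fail)$verdicts[["energy"]])
})

test_that("length difference and asymmetry verdicts flip at their bounds", {
  mature <- "GCTAGGCTAGGCATCGATCGTACG"     # 24 nt
  star <- revcomp_chr(mature)
  # two interior deletions of 3 nt: star 6 nt shorter, bulges still <= 4
  s6 <- paste0(substr(star, 1, 5), substr(star, 9, 16),
               substr(star, 20, 24))
  h6 <- build_test_hairpin(mature, 8L, s6)
  r6 <- apply_strategy1_criteria(h6$precursor, 1L, 24L, 9L)
  expect_false(r6$verdicts[["asymmetry"]])   # 6 unpaired on one side
  # one interior deletion of 3: asymmetry 3, length difference small
  s3 <- paste0(substr(star, 1, 10), substr(star, 14, 24))
  h3 <- build_test_hairpin(mature, 8L, s3)
  r3 <- apply_strategy1_criteria(h3$precursor, 1L, 24L, 9L)
  expect_true(r3$verdicts[["asymmetry"]])
  expect_true(r3$verdicts[["len_diff"]])
})

test_that("thresholds are monotone: loosening never shrinks acceptance", {
  set.seed(33)
  cands <- lapply(1:12, function(i) {
    m <- rand_seq(sample(20:24, 1))
    st <- revcomp_chr(m)
    v <- strsplit(st, "")[[1]]
    for (p in sample(length(v), sample(0:4, 1))) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
    build_test_hairpin(m, sample(4:38, 1), paste(v, collapse = ""))
  })
  strict <- pipeline_config()
  loose <- pipeline_config(s1_dg_max = -10, s1_bulge_max = 6L,
                           s1_loop = c(3L, 40L), s1_asym_max = 8L,
                           s1_min_reads = 1L)
  for (h in cands) {
    a_strict <- apply_strategy1_criteria(h$precursor, h$mature_start,
                                         h$mature_end, 5L, strict)$accepted
    a_loose <- apply_strategy1_criteria(h$precursor, h$mature_start,
                                        h$mature_end, 5L, loose)$accepted
    if (a_strict) expect_true(a_loose)
  }
})

test_that("cross-checks demote transcript fragments and known homologs", {
  known <- c(`mir-21` = "TAGCTTATCAGACTGATGTTGA")
  tr <- c(contig1 = paste0(rand_seq(50), "GGGCATCGATCCGGATCGATCC",
                           rand_seq(50)))
  cands <- data.frame(
    mature_sequence = c("GGGCATCGATCCGGATCGATCC",     # transcript substring
                        "TAGCTTATCAGACTGATGTTCT",     # 2 mm at the 3' end
                        "TAGCTTATCGGACTGATGTTGA",     # 1 internal mm
                        "CGCGATTACGCGATCGATTACG"),    # unrelated
    status = "accepted", stringsAsFactors = FALSE)
  out <- cross_check(cands, tr, known)
  expect_equal(out$status, c("mrna_fragment", "known_homolog",
                             "known_homolog", "accepted"))
})

test_that("three internal mismatches to every known mature stay novel", {
  known <- c(`mir-21` = "TAGCTTATCAGACTGATGTTGA")
  m <- known[[1]]
  for (p in c(5L, 11L, 16L)) {
    substr(m, p, p) <- setdiff(c("A", "C", "G", "T"), substr(m, p, p))[1]
  }
  cands <- data.frame(mature_sequence = m, status = "accepted",
                      stringsAsFactors = FALSE)
  expect_equal(cross_check(cands, character(0), known)$status, "accepted")
})
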