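# genome-free duplex discovery

dup_tags <- function(seqs, counts) {
  data.frame(tag_id = paste0("u", seq_along(seqs)), sequence = seqs,
             count = as.integer(counts), library_id = "A",
             stringsAsFactors = FALSE)
}

test_that("a perfect reverse-complement duplex is found with no defects", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  tags <- dup_tags(c(m, revcomp_chr(m)), c(50, 5))
  pairs <- find_duplex_pairs(tags)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mismatches, 0L)
  expect_equal(pairs$max_bulge, 0L)
  expect_equal(pairs$pairs, 22L)
  expect_equal(pairs$dominant_id, "u1")   # higher count is dominant
})

test_that("G facing U counts as pairing, not mismatch", {
  x <- strrep("G", 20)
  y <- strrep("T", 20)
  tags <- dup_tags(c(x, y), c(30, 2))
  pairs <- find_duplex_pairs(tags)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mismatches, 0L)
})

test_that("a tag with nine reads launches no search", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  tags <- dup_tags(c(m, revcomp_chr(m)), c(9, 1))
  expect_equal(nrow(find_duplex_pairs(tags)), 0L)
})

test_that("the mismatch tolerance flips between four and five", {
  # perturb a perfect duplex until the best possible alignment (verified
  # by the recursive oracle) carries exactly 5, then exactly 4 mismatches
  set.seed(40)
  m <- "AACCACAACCAACCACAACCAA"
  star <- revcomp_chr(m)
  found5 <- found4 <- FALSE
  for (i in 1:60) {
    bad <- star
    # the gap budget can bulge around up to four mismatches (two gap
    # columns each), so plant more than the nominal count
    for (p in sample(3:20, sample(8:10, 1))) substr(bad, p, p) <- "C"
    mm <- duplex_oracle_mm(m, bad)
    if (!is.finite(mm)) next
    if (!found5 && mm == 5) {
      # min-mismatch 5 under every allowed gapped alignment: infeasible
      expect_equal(nrow(find_duplex_pairs(dup_tags(c(m, bad),
                                                   c(40, 3)))), 0L)
      found5 <- TRUE
    }
    if (!found4 && is.finite(mm) && mm == 4) {
      p4 <- find_duplex_pairs(dup_tags(c(m, bad), c(40, 3)))
      expect_equal(nrow(p4), 1L)
      expect_equal(p4$mismatches, 4L)   # agrees with the oracle minimum
      found4 <- TRUE
    }
    if (found4 && found5) break
  }
  expect_true(found4 && found5)
})

test_that("joining uses the linker and the energy cutoff is inclusive", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  tags <- dup_tags(c(m, revcomp_chr(m)), c(50, 5))
  pairs <- find_duplex_pairs(tags)
  cands <- join_and_fold(pairs)
  expect_equal(nchar(cands$joined_sequence), 22L + 10L + 22L)
  expect_match(cands$joined_sequence, "GCGGGGACGC")
  # MFE optimality: the fold is at least as low as the explicit full-stem
  # structure evaluated by the independent energy function
  chain <- lapply(1:20, function(i) c(i, 54L - i + 1L))
  bound <- mirseek:::hairpin_energy(
    chartr("T", "U", cands$joined_sequence), chain)
  expect_lte(cands$dg, bound)
  expect_lte(cands$dg, -21)
  expect_equal(cands$status, "accepted")
  # boundary: the measured energy itself passes, a hair above fails
  expect_equal(join_and_fold(pairs, pipeline_config(
    s2_dg_max = cands$dg))$status, "accepted")
  expect_equal(join_and_fold(pairs, pipeline_config(
    s2_dg_max = cands$dg - 0.01))$status, "rejected(energy)")
})

test_that("a weak duplex folding above -21 kcal/mol is rejected", {
  # search a seeded family of AT-rich short duplexes for one with an
  # energy in the rejection band just above the cutoff
  set.seed(41)
  found <- FALSE
  for (len in rep(c(18, 19, 20), each = 120)) {
    m <- paste(sample(c("A", "T", "A", "T", "A", "T", "G", "C"), len,
                      TRUE), collapse = "")
    p <- duplex_join_fold(m, revcomp_chr(m))
    if (p$dg > -21 && p$dg <= -16) {
      tags <- dup_tags(c(m, revcomp_chr(m)), c(30, 2))
      pairs <- find_duplex_pairs(tags)
      if (!nrow(pairs)) next
      cands <- join_and_fold(pairs)
      expect_gt(cands$dg, -21)
      expect_equal(cands$status, "rejected(energy)")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the pair search equals brute-force all-pairs alignment", {
  set.seed(42)
  seqs <- character(0)
  for (i in 1:5) {                      # planted duplexes
    m <- rand_seq(sample(19:23, 1))
    st <- revcomp_chr(m)
    v <- strsplit(st, "")[[1]]
    for (p in sample(length(v), sample(0:3, 1))) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
    seqs <- c(seqs, m, paste(v, collapse = ""))
  }
  seqs <- unique(c(seqs, vapply(1:14, function(i) rand_seq(sample(18:24, 1)),
                                character(1))))
  counts <- sample(c(1:5, 10:60), length(seqs), replace = TRUE)
  tags <- dup_tags(seqs, counts)
  cfg <- pipeline_config()
  mine <- find_duplex_pairs(tags, cfg)
  mine_keys <- sort(paste(pmin(mine$dominant_id, mine$partner_id),
                          pmax(mine$dominant_id, mine$partner_id)))
  brute_keys <- character(0)
  dom <- which(tags$count >= cfg$s2_min_reads)
  len_ok <- nchar(tags$sequence) >= 18 & nchar(tags$sequence) <= 24
  for (d in dom) {
    for (p in seq_len(nrow(tags))) {
      if (p == d || !len_ok[p] || !len_ok[d]) next
      mm <- duplex_oracle_mm(tags$sequence[d], tags$sequence[p],
                             cfg$s2_bulge_max, cfg$s2_gap_total)
      if (mm <= cfg$s2_mismatch_max) {
        brute_keys <- c(brute_keys,
                        paste(pmin(tags$tag_id[d], tags$tag_id[p]),
                              pmax(tags$tag_id[d], tags$tag_id[p])))
      }
    }
  }
  expect_equal(mine_keys, sort(unique(brute_keys)))
})

test_that("the candidate set is invariant under input order", {
  set.seed(43)
  seqs <- character(0)
  for (i in 1:5) {
    m <- rand_seq(21)
    seqs <- c(seqs, m, revcomp_chr(m))
  }
  seqs <- c(seqs, vapply(1:20, function(i) rand_seq(21), character(1)))
  tags <- dup_tags(unique(seqs), sample(c(1, 12, 30),
                                        length(unique(seqs)), TRUE))
  r1 <- run_strategy2(tags, character(0))
  perm <- sample(nrow(tags))
  r2 <- run_strategy2(tags[perm, ], character(0))
  key <- function(r) sort(paste(r$dominant_sequence, r$partner_sequence,
                                r$status))
  expect_equal(key(r1), key(r2))
})

test_that("transcript fragments are removed, others retained", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  tr <- c(contig1 = paste0(rand_seq(30), m, rand_seq(30)))
  tags <- dup_tags(c(m, revcomp_chr(m)), c(50, 5))
  out <- run_strategy2(tags, tr)
  expect_equal(out$status, "mrna_fragment")
  out2 <- run_strategy2(tags, c(contig1 = rand_seq(100)))
  expect_equal(out2$status, "accepted")
})

test_that("no contaminant-derived tag survives to an accepted call", {
  # in simulated libraries the only accepted duplex dominants trace back
  # to planted genome-free miRNA loci; ncRNA, repeat and transcript
  # material is mapped away, subtracted against the transcriptome, or
  # fails the duplex filters
  for (seed in 9:10) {
    cfg <- small_sim(seed = seed, depth = 60000)
    truth <- build_mock_references(cfg)
    lib <- simulate_library(truth, "A", cfg)
    truth_of <- tapply(lib$truth$locus_id, lib$reads,
                       function(x) names(sort(table(x),
                                              decreasing = TRUE))[1])
    tags <- collapse_reads(lib$reads, "A")
    hits <- map_tags(tags, truth$genome)
    ann <- annotate_cascade(tags, hits, truth$refs)
    un <- tags[tags$tag_id %in% ann$tag_id[ann$category == "unmapped"], ]
    out <- run_strategy2(un, truth$refs$transcripts)
    acc <- out[out$status == "accepted", ]
    cls <- truth$loci$class[match(truth_of[acc$dominant_sequence],
                                  truth$loci$locus_id)]
    expect_true(all(cls == "mirna_genomefree"),
                label = paste("seed", seed))
    expect_gt(nrow(acc), 0L)
  }
})

test_that("loci shared between the two libraries appear in both outputs", {
  cfg <- small_sim(seed = 8, depth = 50000)
  truth <- build_mock_references(cfg)
  shared <- truth$loci[truth$loci$class == "mirna_genomefree", ]
  hits <- list()
  for (lib_id in c("A", "B")) {
    lib <- simulate_library(truth, lib_id, cfg)
    tags <- collapse_reads(lib$reads, lib_id)
    hh <- map_tags(tags, truth$genome)
    ann <- annotate_cascade(tags, hh, truth$refs)
    un <- tags[tags$tag_id %in% ann$tag_id[ann$category == "unmapped"], ]
    out <- run_strategy2(un, truth$refs$transcripts)
    acc <- out[out$status == "accepted", ]
    hits[[lib_id]] <- vapply(seq_len(nrow(shared)), function(i) {
      any(adist(acc$dominant_sequence, shared$mature[i]) <= 4) ||
        any(adist(acc$dominant_sequence, shared$star[i]) <= 4)
    }, logical(1))
  }
  both <- hits$A & hits$B
  expect_true(any(both))
  expect_equal(shared$locus_id[hits$A], shared$locus_id[hits$B])
})
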