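# genome mapping, annotation cascade, isomiR clustering

make_tags <- function(seqs, counts = NULL) {
  data.frame(tag_id = paste0("t", seq_along(seqs)), sequence = seqs,
             count = if (is.null(counts)) rep(1L, length(seqs)) else counts,
             library_id = "A", stringsAsFactors = FALSE)
}

test_that("exact, one-mismatch and reverse-complement hits are found", {
  set.seed(21)
  g <- c(chr1 = rand_seq(4000))
  exact <- substr(g[[1]], 1001, 1022)
  mm1 <- exact
  substr(mm1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mm1, 10, 10))[1]
  rc <- revcomp_chr(substr(g[[1]], 2001, 2022))
  tags <- make_tags(c(exact, mm1, rc))
  hits <- map_tags(tags, g)
  h1 <- hits[hits$tag_id == "t1", ]
  expect_true(any(h1$start == 1000 & h1$strand == "+" & h1$mismatches == 0))
  h2 <- hits[hits$tag_id == "t2", ]
  expect_true(any(h2$start == 1000 & h2$mismatches == 1))
  h3 <- hits[hits$tag_id == "t3", ]
  expect_true(any(h3$start == 2000 & h3$strand == "-" & h3$mismatches == 0))
})

test_that("a tag two mismatches from everything stays unmapped", {
  set.seed(22)
  g <- c(chr1 = rand_seq(3000))
  tag <- substr(g[[1]], 501, 522)
  for (p in c(5L, 15L)) {
    substr(tag, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tag, p, p))[1]
  }
  br <- brute_hamming_hits(tag, g[[1]], 1L)
  hits <- map_tags(make_tags(tag), g)
  expect_equal(nrow(hits), nrow(br))
})

test_that("the seed index reproduces the brute-force Hamming scan exactly", {
  set.seed(23)
  g <- c(chr1 = rand_seq(6000))
  seqs <- character(0)
  for (i in 1:15) {                 # planted (with/without mismatch), both strands
    s <- sample(1:(6000 - 24), 1)
    len <- sample(18:24, 1)
    tag <- substr(g[[1]], s, s + len - 1)
    if (i %% 3 == 0) {
      p <- sample(len, 1)
      substr(tag, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, p, p))[1]
    }
    if (i %% 2 == 0) tag <- revcomp_chr(tag)
    seqs <- c(seqs, tag)
  }
  seqs <- c(seqs, vapply(1:10, function(i) rand_seq(sample(18:28, 1)),
                         character(1)))
  tags <- make_tags(unique(seqs))
  hits <- map_tags(tags, g)
  for (i in seq_len(nrow(tags))) {
    br <- brute_hamming_hits(tags$sequence[i], g[[1]], 1L)
    mine <- hits[hits$tag_id == tags$tag_id[i],
                 c("start", "strand", "mismatches")]
    rownames(mine) <- NULL
    if (nrow(br) == 0) {
      expect_equal(nrow(mine), 0L)
    } else {
      br <- br[order(br$start, br$strand), ]
      mine <- mine[order(mine$start, mine$strand), ]
      rownames(br) <- rownames(mine) <- NULL
      expect_equal(mine, br, label = tags$sequence[i])
    }
  }
})

ref_fixture <- function() {
  set.seed(24)
  list(ncrna = c(rrna1 = rand_seq(120), trna1 = rand_seq(76)),
       ncrna_class = c(rrna1 = "rRNA", trna1 = "tRNA"),
       repeats = data.frame(chrom = "chr1", start = 3000L, end = 3200L,
                            stringsAsFactors = FALSE),
       mature = c(`mir-9` = "TCTTTGGTTATCTAGCTGTATGA"))
}

test_that("the annotation cascade assigns one category with priority", {
  refs <- ref_fixture()
  set.seed(25)
  g_body <- rand_seq(5000)
  # plant an rRNA fragment, a repeat-derived 25-mer and a mature match
  rr_frag <- substr(refs$ncrna[["rrna1"]], 11, 32)
  rep_seq <- rand_seq(201)
  g <- c(chr1 = paste0(substr(g_body, 1, 3000), rep_seq,
                       substr(g_body, 3202, 5000)))
  g <- c(chr1 = paste0(substr(g[[1]], 1, 500), rr_frag,
                       substr(g[[1]], 523, nchar(g[[1]]))))
  g <- c(chr1 = paste0(substr(g[[1]], 1, 1000), refs$mature[[1]],
                       substr(g[[1]], 1024, nchar(g[[1]]))))
  ras <- substr(g[[1]], 3051, 3075)      # 25 nt inside the repeat
  cand <- substr(g[[1]], 4001, 4022)     # mapped, no annotation
  tags <- make_tags(c(rr_frag, ras, refs$mature[[1]], cand,
                      rand_seq(22)))     # last one unmapped
  hits <- map_tags(tags, g)
  ann <- annotate_cascade(tags, hits, refs)
  expect_equal(ann$category,
               c("rRNA", "rasiRNA", "conserved_miRNA", "candidate_mapped",
                 "unmapped"))
  # exactly one record per tag, categories partition the tag set
  expect_equal(nrow(ann), nrow(tags))
  expect_equal(sum(table(ann$category)), nrow(tags))
})

test_that("rasiRNA calls need both the 24-27 nt length and repeat overlap", {
  refs <- ref_fixture()
  set.seed(26)
  g <- c(chr1 = rand_seq(4000))
  in_rep <- substr(g[[1]], 3051, 3072)   # 22 nt in repeat: too short
  out_rep <- substr(g[[1]], 101, 126)    # 26 nt outside any repeat
  tags <- make_tags(c(in_rep, out_rep))
  ann <- annotate_cascade(tags, map_tags(tags, g), refs)
  expect_equal(ann$category, c("candidate_mapped", "candidate_mapped"))
})

test_that("a missing reference set is a configuration error", {
  refs <- ref_fixture()
  refs$mature <- NULL
  tags <- make_tags("TCTTTGGTTATCTAGCTGTATGA")
  expect_error(annotate_cascade(tags, data.frame(), refs), "mature")
})

test_that("isomiR variants cluster around one locus with a dominant tag", {
  set.seed(27)
  g <- c(chr1 = rand_seq(3000))
  base <- substr(g[[1]], 1001, 1022)
  shift1 <- substr(g[[1]], 1002, 1023)
  tags <- make_tags(c(base, shift1), counts = c(100L, 7L))
  cl <- cluster_tags(tags, map_tags(tags, g))
  expect_equal(nrow(cl$anchors), 1L)
  expect_equal(cl$anchors$rep_tag_id, "t1")
  expect_equal(cl$anchors$rep_count, 100L)
})

test_that("opposite strands and distant loci form separate clusters", {
  set.seed(28)
  g <- c(chr1 = rand_seq(3000))
  fwd <- substr(g[[1]], 1001, 1022)
  rev <- revcomp_chr(substr(g[[1]], 1003, 1024))
  far <- substr(g[[1]], 1073, 1094)       # 50 nt downstream
  tags <- make_tags(c(fwd, rev, far))
  cl <- cluster_tags(tags, map_tags(tags, g))
  expect_equal(nrow(cl$anchors), 3L)
})

test_that("tags within shift_max merge transitively, beyond it split", {
  set.seed(29)
  g <- c(chr1 = rand_seq(3000))
  a <- substr(g[[1]], 1001, 1022)
  b <- substr(g[[1]], 1026, 1047)   # gap 3 from a: within shift_max
  c_ <- substr(g[[1]], 1051, 1072)  # gap 3 from b: chains transitively
  d <- substr(g[[1]], 1077, 1098)   # gap 4 from c: splits
  tags <- make_tags(c(a, b, c_, d))
  cl <- cluster_tags(tags, map_tags(tags, g))
  expect_equal(nrow(cl$anchors), 2L)
  members <- split(cl$members$tag_id, cl$members$cluster_id)
  sizes <- sort(vapply(members, length, integer(1)))
  expect_equal(unname(sizes), c(1L, 3L))
})

test_that("clustering does not depend on tag input order", {
  set.seed(30)
  g <- c(chr1 = rand_seq(5000))
  seqs <- vapply(1:8, function(i) {
    s <- sample(c(1001, 1003, 1005, 2001, 2004, 3001, 3003, 4001)[i], 1)
    substr(g[[1]], s, s + 21)
  }, character(1))
  tags <- make_tags(seqs, counts = sample(1:50, 8))
  hits <- map_tags(tags, g)
  cl1 <- cluster_tags(tags, hits)
  perm <- sample(nrow(tags))
  cl2 <- cluster_tags(tags[perm, ], hits)
  key <- function(cl) {
    sets <- lapply(split(cl$members$tag_id, cl$members$cluster_id), sort)
    sort(vapply(sets, paste, character(1), collapse = ","))
  }
  expect_equal(key(cl1), key(cl2))
  expect_equal(sort(cl1$anchors$rep_tag_id), sort(cl2$anchors$rep_tag_id))
})
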