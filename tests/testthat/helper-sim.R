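# compact simulation settings for module tests: same statistical
# structure as the defaults, scaled down for speed
small_sim <- function(seed = 1L, depth = 40000L, ...) {
  args <- list(seed = seed, library_depth = as.integer(depth),
               genome_length = 40000L, n_mirna_loci = 10L,
               n_novel_loci = 3L, n_genomefree_loci = 3L,
               n_ncrna_loci = 2L, n_repeat_loci = 2L,
               n_transcript_loci = 3L, n_diff_loci = 3L)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

sim_refs <- function(truth) truth$refs

# realized per-locus, per-arm read counts from a simulated library
locus_arm_counts <- function(lib) {
  stats::aggregate(list(reads = rep(1L, nrow(lib$truth))),
                   by = list(locus_id = lib$truth$locus_id,
                             arm = lib$truth$arm), sum)
}
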