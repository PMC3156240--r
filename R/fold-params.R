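#' Nearest-neighbour energy parameters for hairpin folding
#'
#' Free-energy parameter set (37 degrees C, kcal/mol) used by [fold_hairpin()]:
#' Watson-Crick and G:U stacking energies, hairpin/bulge/internal loop
#' initiation tables and the internal-loop asymmetry penalty. Values follow
#' the Turner nearest-neighbour scale used by the classic mfold-era folding
#' tools, so that free-energy cutoffs quoted on that scale (for instance
#' -18 or -21 kcal/mol for precursor hairpins) are meaningful. Dangling-end
#' and terminal-mismatch terms are omitted; this biases energies by roughly
#' 1-2 kcal/mol towards zero and is documented in the methods vignette.
#'
#' Pair type order used throughout: AU, CG, GC, UA, GU, UG.
#'
#' @return A list with elements `stack` (6x6 matrix, outer pair x inner
#'   pair), `hairpin` (loop sizes 3..30), `bulge` (sizes 1..30), `internal`
#'   (sizes 2..30), `asym` (penalty per unpaired-nt asymmetry),
#'   `asym_max` (cap on the asymmetry penalty), `max_interior` (largest
#'   interior/bulge loop considered), `min_hairpin` (minimum hairpin loop).
#' @export
fold_params <- function() {
  pair_names <- c("AU", "CG", "GC", "UA", "GU", "UG")
  # stack[outer, inner]: helix 5'-XY-3'/3'-WZ-5', outer = X:W, inner = Y:Z
  stack <- matrix(c(
    # inner:  AU    CG    GC    UA    GU    UG
    -0.90, -2.20, -2.10, -1.10, -0.60, -1.40,  # outer AU
    -2.10, -3.30, -2.40, -2.10, -1.40, -2.10,  # outer CG
    -2.40, -3.40, -3.30, -2.20, -1.50, -2.50,  # outer GC
    -1.30, -2.40, -2.10, -0.90, -1.00, -1.30,  # outer UA
    -1.30, -2.50, -2.10, -1.40, -0.50,  1.30,  # outer GU
    -1.00, -1.50, -1.40, -0.60,  0.30, -0.50), # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(pair_names, pair_names))
  hairpin <- c(5.70, 5.60, 5.60, 5.40, 5.90, 5.60, 6.40, 6.50, 6.60,
               6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10, 7.20, 7.20,
               7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.60, 7.60, 7.70,
               7.70)                          # sizes 3..30
  bulge <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.59, 4.70, 4.80,
             4.90, 5.00, 5.10, 5.19, 5.27, 5.34, 5.41, 5.48, 5.54,
             5.60, 5.65, 5.71, 5.76, 5.80, 5.85, 5.89, 5.94, 5.98,
             6.02, 6.05, 6.09)                # sizes 1..30
  internal <- c(1.10, 1.60, 1.70, 2.00, 2.20, 2.30, 2.40, 2.50, 2.60,
                2.67, 2.74, 2.80, 2.86, 2.91, 2.96, 3.01, 3.05, 3.09,
                3.13, 3.17, 3.21, 3.24, 3.27, 3.30, 3.33, 3.36, 3.39,
                3.42, 3.45)                   # sizes 2..30
  list(stack = stack, hairpin = hairpin, bulge = bulge,
       internal = internal, asym = 0.6, asym_max = 3.0,
       max_interior = 30L, min_hairpin = 3L)
}

# Encode a pair type from two RNA bases; 0 = not pairable.
# Order: AU=1 CG=2 GC=3 UA=4 GU=5 UG=6 (G:U wobble is a legal pair).
pair_type <- function(a, b) {
  key <- paste0(a, b)
  idx <- match(key, c("AU", "CG", "GC", "UA", "GU", "UG"))
  ifelse(is.na(idx), 0L, idx)
}
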