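#' Energy parameters for the reduced nearest-neighbour folding model
#'
#' Returns the parameter set used by [fold_rna()]: stacking energies for
#' the six allowed pairs (Watson-Crick plus G:U), size-dependent hairpin,
#' bulge and internal-loop penalties with logarithmic extrapolation beyond
#' the tabulated sizes, a capped internal-loop asymmetry term, and an
#' affine multiloop cost. Values are in kcal/mol and are a reduced,
#' self-contained variant of the standard nearest-neighbour tables; the
#' absolute free energies it produces are therefore model-specific and
#' should only be compared against thresholds calibrated for this model
#' (e.g. the novel-miRNA cutoff of [call_novel()]).
#'
#' The stack table is symmetrised so that a stacked duplex has the same
#' energy read from either strand, which makes the fold of a perfect
#' palindromic stem invariant under reverse complementation.
#'
#' @param max_size largest loop size (nt) to tabulate; loops above the
#'   anchor sizes are extrapolated as `E(anchor) + 1.08 * log(n / anchor)`.
#' @return a list with elements `stack` (6x6 matrix, pair order AU, CG,
#'   GC, UA, GU, UG), `hairpin`, `bulge`, `internal` (numeric vectors
#'   indexed by loop size), `asym_coef`, `asym_max`, `ml_close`,
#'   `ml_branch`, `ml_unpaired`, `max_interior`, `min_loop`.
#' @export
#' @examples
#' p <- fold_params()
#' p$stack["CG", "CG"]
fold_params <- function(max_size = 400) {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # on:  AU    CG    GC    UA    GU    UG     (inner pair)
    -0.9, -2.2, -2.1, -1.1, -0.6, -1.4,  # outer AU
    -2.1, -3.3, -2.4, -2.1, -1.4, -2.1,  # outer CG
    -2.4, -3.4, -3.3, -2.2, -1.5, -2.5,  # outer GC
    -1.3, -2.4, -2.1, -0.9, -1.0, -1.3,  # outer UA
    -1.3, -2.5, -2.1, -1.4, -0.5, 1.3,   # outer GU
    -1.0, -1.5, -1.4, -0.6, 0.3, -0.5    # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  # strand-flip symmetry: E(p on q) must equal E(flip(q) on flip(p))
  flip <- c(AU = "UA", CG = "GC", GC = "CG", UA = "AU", GU = "UG", UG = "GU")
  sym <- stack
  for (p in pairs) for (q in pairs) {
    sym[p, q] <- round((stack[p, q] + stack[flip[q], flip[p]]) / 2, 1)
  }

  extrap <- function(anchors, max_size) {
    n0 <- length(anchors)
    out <- numeric(max_size)
    out[seq_len(n0)] <- anchors
    if (max_size > n0) {
      idx <- (n0 + 1):max_size
      out[idx] <- round(anchors[n0] + 1.08 * log(idx / n0), 1)
    }
    out
  }
  # hairpin sizes 1..2 are geometrically impossible (min_loop = 3)
  hairpin <- extrap(c(Inf, Inf, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4), max_size)
  bulge <- extrap(c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4), max_size)
  internal <- extrap(c(Inf, 1.7, 1.8, 2.0, 2.2, 2.5), max_size)

  list(
    stack = sym, hairpin = hairpin, bulge = bulge, internal = internal,
    asym_coef = 0.5, asym_max = 3.0,
    ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.0,
    max_interior = 30L, min_loop = 3L
  )
}

#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Computes the MFE structure by dynamic programming over the model
#' described in [fold_params()]: nested structures only (no pseudoknots),
#' minimum hairpin loop of `min_loop` nucleotides, interior loops bounded
#' at `max_interior` unpaired bases. Energies are evaluated in integer
#' tenths of a kcal/mol, so results are exactly reproducible and directly
#' comparable to exhaustive enumeration.
#'
#' @param seq a single RNA/DNA sequence (A, C, G, U/T; case-insensitive).
#' @param params parameter list from [fold_params()].
#' @return an object of class `hairpin_structure`: a list with `seq`,
#'   `structure` (dot-bracket), `mfe` (kcal/mol, 0 for an unfolded
#'   sequence), `pairs` (integer vector of 1-based partners, `NA` when
#'   unpaired), and `loops` (a matrix of hairpin-loop spans, one row per
#'   terminal loop).
#' @export
#' @examples
#' fold_rna("GGGGAAAACCCC")$structure
fold_rna <- function(seq, params = fold_params()) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  seq <- toupper(seq)
  res <- .fold_engine(chartr("T", "U", seq), params)
  pairs <- res$pairs
  loops <- hairpin_loops(pairs)
  structure(
    list(seq = seq, structure = res$structure, mfe = res$mfe,
         pairs = pairs, loops = loops),
    class = "hairpin_structure"
  )
}

# Terminal (hairpin) loops of a pairing map: pairs (i, j) enclosing no
# other pair. Returns a matrix with columns start, end (the unpaired span).
hairpin_loops <- function(pairs) {
  n <- length(pairs)
  out <- NULL
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (is.na(j) || j <= i) next
    inner <- if (j - i >= 2) pairs[(i + 1):(j - 1)] else integer(0)
    if (!any(!is.na(inner))) {
      out <- rbind(out, c(start = i + 1, end = j - 1))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end")))
  out
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("MFE: %.1f kcal/mol, %d pairs, %d terminal loop(s)\n",
              x$mfe, sum(!is.na(x$pairs)) / 2, nrow(x$loops)))
  invisible(x)
}
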