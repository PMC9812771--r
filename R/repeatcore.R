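#' @useDynLib tropicr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reverse complement of a DNA string
#'
#' @param x Character vector of uppercase DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Canonical repeat motif
#'
#' Reduces a repeat unit to its primitive form (e.g. \code{ATAT} to \code{AT})
#' and returns the lexicographic minimum over all rotations of the unit and of
#' its reverse complement, so that every description of the same tandem repeat
#' on either strand maps to one stable key. Canonicalization is idempotent.
#'
#' @param unit Character vector of repeat units (uppercase A/C/G/T, primitive
#'   length 2-20).
#' @return Character vector of canonical motifs.
#' @examples
#' canonical_motif("GAAA")  # "AAAG"
#' canonical_motif("CAG")   # "AGC" (CAG and CTG collapse)
#' canonical_motif("ATAT")  # "AT"
#' @export
canonical_motif <- function(unit) {
  if (length(unit) == 0) return(character(0))
  unit <- toupper(as.character(unit))
  bad <- !grepl("^[ACGT]+$", unit)
  if (any(bad)) {
    stop("non-ACGT characters in repeat unit(s): ",
         paste(utils::head(unit[bad], 3), collapse = ", "))
  }
  out <- cpp_canonical_motif(unit, 2L, 20L)
  if (anyNA(out)) {
    stop("repeat unit(s) with primitive length outside 2-20 ",
         "(homopolymers and units longer than 20 bp are not supported): ",
         paste(utils::head(unit[is.na(out)], 3), collapse = ", "))
  }
  out
}

#' Tandem tiling purity of a read against a motif
#'
#' Fraction of read bases matching a perfect tandem tiling of \code{motif},
#' maximized over both strands and all tiling phases. Ambiguous bases (N)
#' count as mismatches.
#'
#' @param read_seq Character vector of read sequences.
#' @param motif A single motif (canonicalized internally).
#' @return Numeric vector of purities in \[0, 1\].
#' @export
repeat_purity <- function(read_seq, motif) {
  read_seq <- toupper(as.character(read_seq))
  if (any(!nzchar(read_seq))) stop("empty read sequence")
  motif <- canonical_motif(motif)
  if (length(motif) != 1L) stop("motif must be a single unit")
  if (any(nchar(read_seq) < nchar(motif)))
    stop("read shorter than motif")
  cpp_tile_purity(read_seq, motif)
}

#' Classify reads as in-repeat reads (IRRs)
#'
#' A read is an in-repeat read when some motif of unit length
#' \code{unit_range} tiles it with purity at least \code{min_purity}.
#' Candidate motifs are proposed from the read's own k-mers; an exact
#' self-correlation bound prunes unit lengths that provably cannot reach
#' \code{min_purity}, so degenerate reads are rejected cheaply.
#'
#' @param read_seq Character vector of read sequences.
#' @param min_purity Minimum tiling purity to call a read in-repeat
#'   (default 0.9).
#' @param unit_range Integer vector; the range of motif unit lengths
#'   considered (default \code{c(2L, 20L)}).
#' @return A data.frame with one row per read: \code{is_irr} (logical),
#'   \code{motif} (canonical motif or NA), \code{purity} (best tiling purity
#'   or NA).
#' @export
detect_irr <- function(read_seq, min_purity = 0.9, unit_range = c(2L, 20L)) {
  read_seq <- toupper(as.character(read_seq))
  if (length(read_seq) == 0)
    return(data.frame(is_irr = logical(0), motif = character(0),
                      purity = numeric(0), stringsAsFactors = FALSE))
  if (any(!nzchar(read_seq))) stop("empty read sequence")
  kmin <- as.integer(min(unit_range)); kmax <- as.integer(max(unit_range))
  if (kmin < 2L || kmax > 20L) stop("unit_range must lie within 2..20")
  if (any(nchar(read_seq) < 2L * kmin))
    stop("read shorter than twice the smallest unit length")
  res <- cpp_detect_irr(read_seq, min_purity, kmin, kmax)
  data.frame(is_irr = res$is_irr, motif = as.character(res$motif),
             purity = res$purity, stringsAsFactors = FALSE)
}
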