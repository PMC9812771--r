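#' Local read depth around a repeat locus
#'
#' Mean per-base aligned coverage over the window
#' \code{[start - flank, end + flank)} (clipped to chromosome bounds).
#' Coverage counts every primary alignment regardless of mapping quality:
#' chromosomal amplification inflates all reads, including the low-MAPQ
#' in-repeat mates, and that inflation is exactly what this statistic must
#' capture.
#'
#' @param alignments An alignment table (coordinate-sorted data.frame, see
#'   [scan_alignments()] for the required columns).
#' @param locus One-row data.frame (or list) with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param flank Flank added on each side of the locus (default 250 bp, i.e.
#'   a 500-bp region encompassing the repeat's start and stop positions).
#' @return A one-row data.frame: \code{chrom}, \code{window_start},
#'   \code{window_end}, \code{local_depth}.
#' @export
local_depth <- function(alignments, locus, flank = 250L) {
  lens <- attr(alignments, "chrom_lengths")
  chrom <- locus$chrom
  if (!is.null(lens) && !(chrom %in% names(lens)))
    stop("chromosome ", chrom, " absent from alignment input")
  clen <- if (!is.null(lens)) lens[[chrom]] else Inf
  ws <- max(0L, as.integer(locus$start) - as.integer(flank))
  we <- min(clen, as.integer(locus$end) + as.integer(flank))
  if (we <= ws) stop("empty window")
  aln <- alignments[alignments$chrom == chrom & !alignments$secondary &
                      !alignments$supplementary & !alignments$duplicate, ,
                    drop = FALSE]
  if (nrow(aln) == 0) {
    depth <- 0
  } else {
    rs <- aln$pos
    re <- aln$pos + nchar(aln$seq)
    ov <- pmax(0, pmin(re, we) - pmax(rs, ws))
    depth <- sum(as.numeric(ov)) / (we - ws)
  }
  data.frame(chrom = chrom, window_start = as.integer(ws),
             window_end = as.integer(we), local_depth = depth,
             stringsAsFactors = FALSE)
}

#' Locally depth-normalized anchored IRR value
#'
#' Divides a raw anchored IRR count by the local read depth at the locus,
#' removing copy-number inflation that global normalization cannot see.
#' A zero local depth leaves the value undefined (\code{NA} with a warning);
#' callers flag such loci rather than treating them as zero signal.
#'
#' @param raw_air Raw anchored IRR count(s).
#' @param local_depth Local read depth(s) from [local_depth()].
#' @return \code{raw_air / local_depth}, \code{NA} where depth is zero.
#' @export
local_normalize <- function(raw_air, local_depth) {
  if (any(local_depth < 0)) stop("negative local depth")
  out <- ifelse(local_depth > 0, raw_air / local_depth, NA_real_)
  if (anyNA(out))
    warning("zero local depth: locally normalized value undefined, flagged NA")
  out
}

#' Add locally normalized values to a cohort matrix
#'
#' Computes the local read depth of every locus in every sample and stores
#' the loci-by-samples local-depth and locally normalized anchored IRR
#' matrices on the cohort object.
#'
#' @param cohort A \code{cohort_matrix} from [build_cohort_matrix()].
#' @param alignments Named list of alignment tables, one per sample
#'   (names matching \code{cohort$samples$sample_id}).
#' @param flank Window flank in bp (default 250).
#' @return The \code{cohort_matrix} with \code{local_depth} and \code{local}
#'   matrices filled in (\code{NA} where a window has zero depth).
#' @export
add_local_values <- function(cohort, alignments, flank = 250L) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  sids <- cohort$samples$sample_id
  missing_aln <- setdiff(sids, names(alignments))
  if (length(missing_aln))
    stop("alignments missing for: ", paste(missing_aln, collapse = ", "))
  ld <- matrix(NA_real_, nrow(cohort$loci), length(sids),
               dimnames = dimnames(cohort$raw))
  for (s in sids) {
    aln <- alignments[[s]]
    for (i in seq_len(nrow(cohort$loci))) {
      ld[i, s] <- local_depth(aln, cohort$loci[i, ], flank)$local_depth
    }
  }
  suppressWarnings(local <- ifelse(ld > 0, cohort$raw / ld, NA_real_))
  cohort$local_depth <- ld
  cohort$local <- local
  cohort
}
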