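#' Configuration for population-frequency estimation
#'
#' @param intercept,slope Linear conversion of anchored IRR values between
#'   read lengths: a 150-bp value \code{v} maps to \code{intercept + slope*v}
#'   on the 100-bp scale (defaults 0.5 and 1.5).
#' @param pad Interval padding applied to both loci before testing overlap
#'   (default 1000 bp).
#' @param percentile Reference percentile that defines the expansion
#'   threshold (default 99).
#' @return A \code{popfreq_config} list.
#' @export
popfreq_config <- function(intercept = 0.5, slope = 1.5, pad = 1000L,
                           percentile = 99) {
  if (slope <= 0) stop("slope must be positive")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  if (pad < 0) stop("pad must be non-negative")
  structure(list(intercept = intercept, slope = slope, pad = as.integer(pad),
                 percentile = percentile), class = "popfreq_config")
}

#' Convert anchored IRR values between read lengths
#'
#' Shorter reads satisfy the in-repeat purity criterion more readily, so the
#' same locus yields systematically more anchored IRRs at 100 bp than at
#' 150 bp. A linear map places 150-bp values on the 100-bp scale:
#' \code{0.5 + 1.5 * value}. Values already on the target scale pass through
#' unchanged.
#'
#' @param air Anchored IRR value(s).
#' @param from,to Read lengths of the source and target scales
#'   (only 150 -> 100 and 100 -> 100 are defined).
#' @param config A \code{popfreq_config}.
#' @return Converted value(s).
#' @export
convert_air_read_length <- function(air, from = 150L, to = 100L,
                                    config = popfreq_config()) {
  if (any(air < 0)) stop("anchored IRR values must be non-negative")
  if (to != 100L) stop("only conversion onto the 100-bp scale is defined")
  if (from == 100L) return(air)
  if (from != 150L) stop("no conversion defined from read length ", from)
  config$intercept + config$slope * air
}

#' Match query loci against a reference locus catalogue
#'
#' Two loci match when their \code{pad}-extended half-open intervals overlap
#' on the same chromosome and their canonical motifs are identical. All
#' matches are reported; a query can hit several reference loci.
#'
#' @param query,reference data.frames with columns \code{locus_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{motif}.
#' @param config A \code{popfreq_config} (supplies \code{pad}).
#' @return data.frame: \code{query_id}, \code{reference_id}.
#' @export
match_loci <- function(query, reference, config = popfreq_config()) {
  for (d in list(query, reference)) {
    need <- c("locus_id", "chrom", "start", "end", "motif")
    if (!all(need %in% names(d)))
      stop("loci need columns: ", paste(need, collapse = ", "))
  }
  empty <- data.frame(query_id = character(0), reference_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(query) == 0 || nrow(reference) == 0) return(empty)
  pad <- config$pad
  # shared seqlevel universe so disjoint chromosome sets compare silently
  levels <- union(unique(query$chrom), unique(reference$chrom))
  mk <- function(d) GenomicRanges::GRanges(
    factor(d$chrom, levels = levels),
    IRanges::IRanges(start = pmax(0L, as.integer(d$start) - pad) + 1L,
                     end = as.integer(d$end) + pad))
  hits <- GenomicRanges::findOverlaps(mk(query), mk(reference))
  qi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  same <- canonical_motif(query$motif[qi]) ==
    canonical_motif(reference$motif[ri])
  data.frame(query_id = query$locus_id[qi[same]],
             reference_id = reference$locus_id[ri[same]],
             stringsAsFactors = FALSE)
}

#' Population frequency of expanded alleles at a locus
#'
#' The expansion threshold is the \code{percentile}-th percentile (linear
#' interpolation) of the reference-population anchored IRR values; the
#' population frequency is the fraction of individuals whose value strictly
#' exceeds that threshold. Values from other read lengths must be converted
#' with [convert_air_read_length()] before calling.
#'
#' @param air_values Anchored IRR values of the population at one locus
#'   (one value per individual, on a common read-length scale).
#' @param config A \code{popfreq_config}.
#' @return List: \code{threshold}, \code{frequency}, \code{n},
#'   \code{n_expanded}.
#' @export
population_frequency <- function(air_values, config = popfreq_config()) {
  v <- as.numeric(air_values)
  if (length(v) == 0) stop("empty reference population")
  if (anyNA(v)) stop("missing values in population anchored IRR values")
  thr <- as.numeric(stats::quantile(v, config$percentile / 100, type = 7))
  n_exp <- sum(v > thr)
  list(threshold = thr, frequency = n_exp / length(v), n = length(v),
       n_expanded = n_exp)
}
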