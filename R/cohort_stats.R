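#' Configuration of the prioritization cascade
#'
#' Houses every threshold of the tumour-normal prioritization cascade. All
#' comparisons against these thresholds are strict (\code{>}, \code{<}).
#'
#' @param min_anchor_mapq Minimum anchor mapping quality (default 50).
#' @param max_irr_mapq Maximum in-repeat-read mapping quality (default 40).
#' @param air_cap Theoretical maximum normalized anchored IRR value
#'   (default 40).
#' @param air_cap_fraction A locus is removed when more than this fraction of
#'   its values exceeds \code{air_cap} (default 0.10).
#' @param fdr_candidate FDR threshold for candidate loci (default 0.10).
#' @param fdr_somatic FDR threshold for somatic expansion loci (default 0.05).
#' @param aiq_threshold Anchored IRR quotient call threshold (default 2.5).
#' @param frequency_threshold Minimum fraction of pairs with a quotient call
#'   (default 0.05).
#' @param merge_distance Event clustering distance (default 500 bp).
#' @param flank Local-depth window flank (default 250 bp).
#' @param allowed_chromosomes Chromosomes kept for analysis
#'   (default 1-22, X, Y).
#' @param target_depth Global normalization target depth (default 40).
#' @param min_purity In-repeat-read tiling purity threshold (default 0.9).
#' @return A \code{tropic_config} list.
#' @export
tropic_config <- function(min_anchor_mapq = 50L, max_irr_mapq = 40L,
                          air_cap = 40, air_cap_fraction = 0.10,
                          fdr_candidate = 0.10, fdr_somatic = 0.05,
                          aiq_threshold = 2.5, frequency_threshold = 0.05,
                          merge_distance = 500L, flank = 250L,
                          allowed_chromosomes = c(as.character(1:22), "X", "Y"),
                          target_depth = 40, min_purity = 0.9) {
  cfg <- list(min_anchor_mapq = min_anchor_mapq, max_irr_mapq = max_irr_mapq,
              air_cap = air_cap, air_cap_fraction = air_cap_fraction,
              fdr_candidate = fdr_candidate, fdr_somatic = fdr_somatic,
              aiq_threshold = aiq_threshold,
              frequency_threshold = frequency_threshold,
              merge_distance = merge_distance, flank = flank,
              allowed_chromosomes = allowed_chromosomes,
              target_depth = target_depth, min_purity = min_purity)
  num <- vapply(cfg[c("air_cap", "air_cap_fraction", "fdr_candidate",
                      "fdr_somatic", "aiq_threshold", "frequency_threshold",
                      "merge_distance", "flank", "target_depth",
                      "min_purity")], as.numeric, numeric(1))
  if (any(num <= 0)) stop("all thresholds must be positive")
  if (cfg$fdr_somatic > cfg$fdr_candidate)
    stop("fdr_somatic must not exceed fdr_candidate")
  structure(cfg, class = "tropic_config")
}

#' Remove loci with saturated anchored IRR values
#'
#' A normalized anchored IRR value has a theoretical maximum near the
#' normalization target depth; loci where more than \code{max_fraction} of
#' values exceed \code{cap} are artefacts and are removed. The comparison is
#' strict: a locus at exactly the maximum fraction is kept.
#'
#' @param values Loci x samples matrix of normalized anchored IRR values.
#' @param cap Saturation cap (default 40).
#' @param max_fraction Maximum tolerated fraction of capped values
#'   (default 0.10).
#' @return Logical vector: TRUE where the locus is removed.
#' @export
cap_filter <- function(values, cap = 40, max_fraction = 0.10) {
  if (is.null(dim(values)) || nrow(values) == 0) stop("empty value matrix")
  rowMeans(values > cap) > max_fraction
}

# exact permutation distribution of the rank-sum with ties: dynamic
# programme over doubled midranks; returns P(W >= obs) ("greater")
exact_ranksum_p <- function(x, y, alternative = "greater") {
  scores <- rank(c(x, y))
  n1 <- length(x); N <- length(scores)
  s2 <- as.integer(round(2 * scores))  # midranks doubled -> integers
  obs <- sum(s2[seq_len(n1)])
  maxs <- sum(s2)
  # f[j+1, s+1] = number of j-subsets with doubled-rank sum s;
  # iterate j downward so each score is used at most once
  f <- matrix(0, n1 + 1L, maxs + 1L)
  f[1L, 1L] <- 1
  for (v in s2) {
    for (j in seq(n1, 1L)) {
      cols <- seq_len(maxs + 1L - v)
      f[j + 1L, cols + v] <- f[j + 1L, cols + v] + f[j, cols]
    }
  }
  total <- choose(N, n1)
  dist <- f[n1 + 1L, ]
  if (alternative == "greater") {
    sum(dist[seq(obs + 1L, maxs + 1L)]) / total
  } else {
    sum(dist[seq(1L, obs + 1L)]) / total
  }
}

#' One-sided rank-sum test for tumour versus normal anchored IRR values
#'
#' Wilcoxon rank-sum test of whether the tumour group's values are
#' stochastically larger than the normal group's. Uses the exact permutation
#' distribution of the tied rank-sum when both groups have at most
#' \code{exact_limit} observations, and the tie-corrected normal
#' approximation with continuity correction otherwise. When every value is
#' identical the test carries no evidence and returns p = 1.
#'
#' @param tumour_values,normal_values Numeric vectors (non-empty).
#' @param alternative \code{"greater"} (tumour larger; default) or
#'   \code{"less"}.
#' @param exact_limit Largest group size for the exact test (default 12).
#' @return One-sided p-value.
#' @export
rank_sum_test <- function(tumour_values, normal_values,
                          alternative = c("greater", "less"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(tumour_values); y <- as.numeric(normal_values)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values in rank-sum input")
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  tie <- table(r)
  tie_term <- sum(tie^3 - tie)
  varW <- length(x) * length(y) / 12 *
    ((N + 1) - tie_term / (N * (N - 1)))
  if (varW <= 0) return(1)
  if (length(x) <= exact_limit && length(y) <= exact_limit)
    return(exact_ranksum_p(x, y, alternative))
  W <- sum(r[seq_along(x)])
  mu <- length(x) * (N + 1) / 2
  z <- if (alternative == "greater") (W - mu - 0.5) / sqrt(varW)
       else (mu - W - 0.5) / sqrt(varW)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Anchored IRR quotient
#'
#' Per-pair expansion evidence:
#' \code{(tumour AIR - normal AIR) / (normal AIR + 1)}.
#'
#' @param tumour_air,normal_air Normalized anchored IRR values (>= 0).
#' @return The quotient.
#' @export
aiq <- function(tumour_air, normal_air) {
  if (any(tumour_air < 0) || any(normal_air < 0))
    stop("anchored IRR values must be non-negative")
  (tumour_air - normal_air) / (normal_air + 1)
}

# pair-matched tumour and normal value vectors for one locus
pair_values <- function(cohort, locus_id, values) {
  s <- cohort$samples
  pairs <- unique(s$pair_id)
  t_idx <- match(paste(pairs, "tumour"), paste(s$pair_id, s$role))
  n_idx <- match(paste(pairs, "normal"), paste(s$pair_id, s$role))
  if (anyNA(t_idx) || anyNA(n_idx)) stop("unpaired sample encountered")
  i <- match(locus_id, cohort$loci$locus_id)
  if (is.na(i)) stop("locus ", locus_id, " not present in matrix")
  data.frame(pair_id = pairs,
             tumour_air = values[i, s$sample_id[t_idx]],
             normal_air = values[i, s$sample_id[n_idx]],
             stringsAsFactors = FALSE)
}

#' Per-pair expansion calls at a locus
#'
#' Computes the anchored IRR quotient for every tumour-normal pair and calls
#' an expansion when the quotient strictly exceeds the threshold.
#'
#' @param cohort A \code{cohort_matrix}.
#' @param locus_id Locus identifier.
#' @param threshold Quotient call threshold (default 2.5, strict).
#' @param values Which value matrix to use: \code{"global"} (default),
#'   \code{"raw"}, or \code{"local_rescaled"} (locally normalized values
#'   rescaled by the cohort median local depth).
#' @return data.frame: \code{pair_id}, \code{locus_id}, \code{tumour_air},
#'   \code{normal_air}, \code{aiq}, \code{called}.
#' @export
call_expansions <- function(cohort, locus_id, threshold = 2.5,
                            values = c("global", "raw", "local_rescaled")) {
  values <- match.arg(values)
  v <- switch(values, global = cohort$global, raw = cohort$raw,
              local_rescaled = local_rescaled_values(cohort))
  out <- do.call(rbind, lapply(locus_id, function(l) {
    pv <- pair_values(cohort, l, v)
    pv$locus_id <- l
    pv
  }))
  out$aiq <- aiq(out$tumour_air, out$normal_air)
  out$called <- out$aiq > threshold
  out[, c("pair_id", "locus_id", "tumour_air", "normal_air", "aiq", "called")]
}

# locally normalized values rescaled by the cohort median local depth, so
# they live on the same scale as globally normalized values and the cap
# threshold keeps its meaning
local_rescaled_values <- function(cohort) {
  if (is.null(cohort$local))
    stop("local values missing: run add_local_values() first")
  med <- stats::median(cohort$local_depth[cohort$local_depth > 0],
                       na.rm = TRUE)
  cohort$local * med
}

chrom_allowed <- function(chrom, allowed) {
  sub("^chr", "", chrom) %in% sub("^chr", "", allowed)
}

locus_stats <- function(cohort, locus_ids, values, config) {
  p <- vapply(locus_ids, function(l) {
    pv <- pair_values(cohort, l, values)
    rank_sum_test(pv$tumour_air, pv$normal_air, "greater")
  }, numeric(1))
  freq <- vapply(locus_ids, function(l) {
    pv <- pair_values(cohort, l, values)
    mean(aiq(pv$tumour_air, pv$normal_air) > config$aiq_threshold)
  }, numeric(1))
  list(p = p, q = bh_fdr(p), freq = freq)
}

#' Prioritize loci in a tumour-normal cohort
#'
#' Applies the prioritization cascade on globally normalized anchored IRR
#' values, in order: chromosome filter, saturation cap filter, one-sided
#' rank-sum test per locus with Benjamini-Hochberg FDR over the surviving
#' loci, candidate/somatic FDR thresholds, and the quotient-frequency filter.
#' All threshold comparisons are strict. The local read-depth refilter
#' ([local_depth_refilter()]) is the subsequent, second-pass stage.
#'
#' @param cohort A \code{cohort_matrix}.
#' @param config A \code{tropic_config}.
#' @return data.frame with one row per locus: locus key columns, \code{p},
#'   \code{q}, \code{aiq_frequency}, \code{status} (\code{removed_chrom},
#'   \code{removed_cap}, \code{not_significant}, \code{candidate},
#'   \code{somatic_rre}) and \code{reason}.
#' @export
prioritize <- function(cohort, config = tropic_config()) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (length(unique(cohort$samples$pair_id)) < 2)
    stop("cohort must contain at least 2 tumour-normal pairs")
  loci <- cohort$loci
  res <- cbind(loci, data.frame(p = NA_real_, q = NA_real_,
                                aiq_frequency = NA_real_,
                                status = NA_character_, reason = "",
                                stringsAsFactors = FALSE))
  if (nrow(loci) == 0) return(res)

  ok_chrom <- chrom_allowed(loci$chrom, config$allowed_chromosomes)
  res$status[!ok_chrom] <- "removed_chrom"
  res$reason[!ok_chrom] <- "outside chromosomes 1-22, X, Y"

  capped <- cap_filter(cohort$global, config$air_cap,
                       config$air_cap_fraction)
  rm_cap <- ok_chrom & capped
  res$status[rm_cap] <- "removed_cap"
  res$reason[rm_cap] <- sprintf(">%.0f%% of values above cap %g",
                                100 * config$air_cap_fraction, config$air_cap)

  keep <- ok_chrom & !capped
  if (any(keep)) {
    st <- locus_stats(cohort, loci$locus_id[keep], cohort$global, config)
    res$p[keep] <- st$p
    res$q[keep] <- st$q
    res$aiq_frequency[keep] <- st$freq
    passes_freq <- st$freq > config$frequency_threshold
    status <- ifelse(st$q < config$fdr_somatic & passes_freq, "somatic_rre",
              ifelse(st$q < config$fdr_candidate & passes_freq, "candidate",
                     "not_significant"))
    reason <- ifelse(status == "not_significant",
                     ifelse(st$q >= config$fdr_candidate,
                            sprintf("q = %.3g >= %g", st$q,
                                    config$fdr_candidate),
                            sprintf("quotient frequency %.3g <= %g", st$freq,
                                    config$frequency_threshold)),
                     "")
    res$status[keep] <- status
    res$reason[keep] <- reason
  }
  rownames(res) <- NULL
  res
}

#' Local read-depth refilter of candidate loci
#'
#' Second-pass filter separating true expansions from chromosomal
#' amplification: for every candidate or somatic locus the rank-sum test and
#' quotient frequency are recomputed on locally normalized anchored IRR
#' values (rescaled by the cohort median local depth so magnitudes stay
#' comparable), with a fresh Benjamini-Hochberg adjustment across the
#' candidate set. A locus keeps expansion status (\code{rre}) only when
#' q < \code{fdr_somatic} and the quotient frequency still exceeds the
#' threshold; otherwise it becomes \code{removed_local_depth}. Candidates
#' with an undefined (zero-depth) window in any sample are flagged and
#' excluded.
#'
#' @param results Output of [prioritize()].
#' @param cohort A \code{cohort_matrix} with local values
#'   (see [add_local_values()]).
#' @param config A \code{tropic_config}.
#' @return \code{results} with columns \code{local_p}, \code{local_q},
#'   \code{local_aiq_frequency} added and statuses updated to \code{rre},
#'   \code{removed_local_depth} or \code{flagged_local_depth}.
#' @export
local_depth_refilter <- function(results, cohort, config = tropic_config()) {
  if (is.null(cohort$local))
    stop("local values missing: run add_local_values() first")
  results$local_p <- NA_real_
  results$local_q <- NA_real_
  results$local_aiq_frequency <- NA_real_
  cand <- which(results$status %in% c("candidate", "somatic_rre"))
  if (!length(cand)) return(results)
  ids <- results$locus_id[cand]
  vloc <- local_rescaled_values(cohort)
  li <- match(ids, cohort$loci$locus_id)
  undef <- apply(vloc[li, , drop = FALSE], 1, anyNA)
  if (any(undef)) {
    w <- cand[undef]
    results$status[w] <- "flagged_local_depth"
    results$reason[w] <- "zero-depth window in at least one sample"
  }
  cand <- cand[!undef]
  if (!length(cand)) return(results)
  ids <- results$locus_id[cand]
  st <- locus_stats(cohort, ids, vloc, config)
  results$local_p[cand] <- st$p
  results$local_q[cand] <- st$q
  results$local_aiq_frequency[cand] <- st$freq
  keep <- st$q < config$fdr_somatic & st$freq > config$frequency_threshold
  results$status[cand] <- ifelse(keep, "rre", "removed_local_depth")
  results$reason[cand] <- ifelse(keep, "",
    sprintf("local q = %.3g, local quotient frequency = %.3g",
            st$q, st$freq))
  results
}
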