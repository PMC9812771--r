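SAM_FLAG <- c(paired = 1L, proper = 2L, reverse = 16L, mate1 = 64L,
              mate2 = 128L, secondary = 256L, duplicate = 1024L,
              supplementary = 2048L)

#' Read a coordinate-sorted SAM/BAM file into an alignment table
#'
#' Converts the 1-based alignment records to the package's 0-based half-open
#' convention at this boundary; everything downstream is 0-based.
#'
#' @param path A SAM or BAM file (coordinate-sorted).
#' @param sample_id Sample identifier stored on the table (defaults to the
#'   file name without extension).
#' @return data.frame with columns \code{qname}, \code{mate}, \code{chrom},
#'   \code{pos} (0-based), \code{mapq}, \code{strand}, \code{seq},
#'   \code{secondary}, \code{supplementary}, \code{duplicate}; attributes
#'   \code{chrom_lengths} (named integer vector) and \code{sample_id}.
#' @export
read_alignments <- function(path,
                            sample_id = sub("\\.(sam|bam)$", "",
                                            basename(path))) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand", "seq"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- b$flag
  has <- function(bit) bitwAnd(flag, bit) > 0L
  out <- data.frame(
    qname = b$qname,
    mate = ifelse(has(SAM_FLAG["mate2"]), 2L, 1L),
    chrom = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,
    mapq = as.integer(b$mapq),
    strand = ifelse(has(SAM_FLAG["reverse"]), "-", "+"),
    seq = as.character(b$seq),
    secondary = has(SAM_FLAG["secondary"]),
    supplementary = has(SAM_FLAG["supplementary"]),
    duplicate = has(SAM_FLAG["duplicate"]),
    stringsAsFactors = FALSE)
  attr(out, "chrom_lengths") <- hdr
  attr(out, "sample_id") <- sample_id
  out
}

#' Write an alignment table as a SAM file
#'
#' Emits a coordinate-sorted SAM file (1-based positions, as the format
#' requires) from the package's 0-based alignment table. Sequences are
#' written as stored; a uniform placeholder base quality is used.
#'
#' @param alignments An alignment table with a \code{chrom_lengths}
#'   attribute (see [read_alignments()] for the columns).
#' @param path Output file path ending in \code{.sam}.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(alignments, path) {
  lens <- attr(alignments, "chrom_lengths")
  if (is.null(lens)) stop("alignment table lacks a chrom_lengths attribute")
  a <- alignments
  flag <- SAM_FLAG["paired"] + SAM_FLAG["proper"] +
    ifelse(a$mate == 2L, SAM_FLAG["mate2"], SAM_FLAG["mate1"]) +
    ifelse(a$strand == "-", SAM_FLAG["reverse"], 0L) +
    ifelse(a$secondary, SAM_FLAG["secondary"], 0L) +
    ifelse(a$supplementary, SAM_FLAG["supplementary"], 0L) +
    ifelse(a$duplicate, SAM_FLAG["duplicate"], 0L)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  a$qname, as.integer(flag), a$chrom, a$pos + 1L, a$mapq,
                  nchar(a$seq), a$seq,
                  vapply(nchar(a$seq), function(n)
                    paste(rep("I", n), collapse = ""), character(1)))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' Tab-separated table with columns \code{sample_id}, \code{path},
#' \code{role} (tumour|normal), \code{pair_id}, \code{read_length}.
#' Relative paths are resolved against the manifest's directory. All
#' validation failures are enumerated in a single error.
#'
#' @param path Manifest TSV path.
#' @return data.frame of validated samples.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  rel <- !grepl("^/", m$path)
  if (any(rel)) m$path[rel] <- file.path(dirname(path), m$path[rel])
  validate_samples(m)
  m
}

validate_samples <- function(m, check_paths = TRUE) {
  errs <- character(0)
  need <- c("sample_id", "path", "role", "pair_id", "read_length")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id))
    errs <- c(errs, paste0("duplicate sample_id: ",
                           paste(unique(m$sample_id[duplicated(m$sample_id)]),
                                 collapse = ", ")))
  bad_role <- !(m$role %in% c("tumour", "normal"))
  if (any(bad_role))
    errs <- c(errs, paste0("role must be tumour or normal: ",
                           paste(m$sample_id[bad_role], collapse = ", ")))
  tum <- m$pair_id[m$role == "tumour"]
  nor <- m$pair_id[m$role == "normal"]
  broken <- unique(c(tum[duplicated(tum)], nor[duplicated(nor)],
                     setdiff(tum, nor), setdiff(nor, tum)))
  if (length(broken))
    errs <- c(errs, paste0("tumour/normal pairing broken for pair_id: ",
                           paste(broken, collapse = ", ")))
  if (length(unique(m$pair_id)) < 2)
    errs <- c(errs, "at least 2 tumour-normal pairs required")
  if (any(m$read_length < 1))
    errs <- c(errs, "read_length must be positive")
  if (check_paths) {
    gone <- !file.exists(m$path)
    if (any(gone))
      errs <- c(errs, paste0("alignment file(s) not found: ",
                             paste(m$path[gone], collapse = ", ")))
  }
  if (length(errs))
    stop("manifest validation failed:\n  - ",
         paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}
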