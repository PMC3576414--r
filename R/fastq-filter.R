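#' Quality-filter FASTQ reads
#'
#' Retains exactly the reads with at most `max_low_qual` bases whose Phred
#' quality is strictly below `qual_threshold` (default: at most 5 bases below
#' Q20), preserving input order. Qualities are interpreted as Phred+33, the
#' encoding emitted by all modern Illumina base callers.
#'
#' @param input Path to a FASTQ file, or a
#'   [Biostrings::QualityScaledDNAStringSet] already in memory.
#' @param output Optional path; when given, the retained reads are written
#'   there as FASTQ.
#' @param max_low_qual Maximum tolerated number of low-quality bases per read.
#' @param qual_threshold Phred score below which a base counts as low-quality
#'   (the comparison is strict: a base exactly at the threshold is fine).
#'
#' @return The retained reads as a `QualityScaledDNAStringSet`, with
#'   attributes `n_input` and `n_retained`.
#' @export
filter_reads <- function(input, output = NULL, max_low_qual = 5, qual_threshold = 20) {
  stopifnot(max_low_qual >= 0, qual_threshold >= 0)
  if (is.character(input)) {
    lines <- readLines(input)
    if (length(lines) == 0) {
      out <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0)))
      if (!is.null(output)) Biostrings::writeQualityScaledXStringSet(out, output)
      attr(out, "n_input") <- 0L
      attr(out, "n_retained") <- 0L
      return(out)
    }
    if (length(lines) %% 4 != 0) {
      stop("Malformed FASTQ: record count is not a multiple of 4 lines.",
           call. = FALSE)
    }
    seq_len_ok <- nchar(lines[seq(2, length(lines), by = 4)]) ==
      nchar(lines[seq(4, length(lines), by = 4)])
    if (!all(seq_len_ok)) {
      stop("Malformed FASTQ: sequence and quality lengths differ for record(s) ",
           paste(utils::head(which(!seq_len_ok), 5), collapse = ", "),
           call. = FALSE)
    }
    reads <- withCallingHandlers(
      tryCatch(
        Biostrings::readQualityScaledDNAStringSet(input),
        error = function(e) {
          stop("Malformed FASTQ (sequence/quality mismatch or bad record): ",
               conditionMessage(e), call. = FALSE)
        }
      ),
      # parser chatter about dropped mcols carries no information here
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else if (methods::is(input, "QualityScaledDNAStringSet")) {
    reads <- input
  } else {
    stop("`input` must be a FASTQ path or a QualityScaledDNAStringSet.",
         call. = FALSE)
  }
  widths_seq <- Biostrings::width(reads)
  widths_qual <- Biostrings::width(Biostrings::quality(reads))
  if (any(widths_seq != widths_qual)) {
    stop("Malformed FASTQ: sequence and quality lengths differ for read(s) ",
         paste(utils::head(which(widths_seq != widths_qual), 5), collapse = ", "),
         call. = FALSE)
  }
  quals <- methods::as(Biostrings::quality(reads), "IntegerList")
  n_low <- vapply(quals, function(q) sum(q < qual_threshold), integer(1))
  keep <- n_low <= max_low_qual
  out <- reads[keep]
  if (!is.null(output)) {
    Biostrings::writeQualityScaledXStringSet(out, output)
  }
  attr(out, "n_input") <- length(reads)
  attr(out, "n_retained") <- sum(keep)
  out
}
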