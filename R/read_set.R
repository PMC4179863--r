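#' Construct a set of sequencing reads
#'
#' The package's read container: a data.frame with one row per read and
#' columns `read_id` (character), `bases` (upper-case nucleotide string over
#' A/C/G/T/N), `quals` (list column of integer Phred scores, or `NULL`
#' entries for quality-less reads), `pair_role` (`"single"`, `"forward"` or
#' `"reverse"`) and `sample` (sample id, `NA` until demultiplexed).
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of nucleotide sequences; uppercased.
#' @param quals optional list of integer vectors, one per read, each the
#'   same length as its sequence; `NULL` for quality-less sets.
#' @param pair_role one of `"single"`, `"forward"`, `"reverse"` (recycled).
#' @param sample optional character vector of sample ids (recycled).
#' @return a `read_set` data.frame.
#' @examples
#' rs <- read_set("r1", "ACGT", list(c(30L, 30L, 30L, 30L)))
#' n_reads(rs)
#' @export
read_set <- function(read_id, bases, quals = NULL, pair_role = "single",
                     sample = NA_character_) {
  read_id <- as.character(read_id)
  bases <- toupper(as.character(bases))
  n <- length(read_id)
  if (length(bases) != n) stop("read_id and bases must have equal length")
  if (is.null(quals)) {
    quals <- rep(list(NULL), n)
  } else {
    if (!is.list(quals) || length(quals) != n)
      stop("quals must be a list with one element per read")
    quals <- lapply(quals, function(q) if (is.null(q)) NULL else as.integer(q))
    bad <- which(vapply(seq_len(n), function(i)
      !is.null(quals[[i]]) && length(quals[[i]]) != nchar(bases[i]), logical(1)))
    if (length(bad))
      stop("quality length differs from sequence length for read '",
           read_id[bad[1]], "'")
    neg <- which(vapply(quals, function(q) !is.null(q) && any(q < 0), logical(1)))
    if (length(neg))
      stop("negative quality score for read '", read_id[neg[1]], "'")
  }
  out <- data.frame(read_id = read_id, bases = bases,
                    pair_role = rep_len(pair_role, n),
                    sample = rep_len(sample, n),
                    stringsAsFactors = FALSE)
  out$quals <- quals
  class(out) <- c("read_set", "data.frame")
  out
}

#' Number of reads in a read set
#' @param rs a [read_set()].
#' @return integer count.
#' @export
n_reads <- function(rs) nrow(rs)

#' Do all reads in a set carry qualities?
#' @param rs a [read_set()].
#' @return logical.
#' @export
has_quals <- function(rs) {
  nrow(rs) > 0 && !any(vapply(rs$quals, is.null, logical(1)))
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads",
      if (has_quals(x)) "(with qualities)" else "(no qualities)", "\n")
  if (nrow(x)) {
    show <- utils::head(x, 5)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s  %s%s  [%d bp]\n", show$read_id[i],
                  substr(show$bases[i], 1, 40),
                  if (nchar(show$bases[i]) > 40) "..." else "",
                  nchar(show$bases[i])))
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

# row subset that keeps the class and the list column intact
subset_reads <- function(rs, idx) {
  out <- rs[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

bind_reads <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(read_set(character(), character()))
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}
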