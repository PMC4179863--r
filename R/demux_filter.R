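#' Quality-filter settings
#'
#' All thresholds used by simultaneous demultiplexing and filtering. A read
#' that passes the structural filters (length, ambiguity, homopolymer) is
#' binned *high* when it meets both quality thresholds (`min_avg_qual`,
#' `max_expected_error`), *mid* when it stays within the relaxed band
#' (`min_avg_qual - mid_qual_slack`, `max_expected_error * mid_relax`), and
#' is rejected otherwise. High-bin reads drive OTU clustering (truncated to
#' `truncation_len`); mid-bin reads only add to abundance counts.
#'
#' @param min_len,max_len length bounds in bp; `max_len = 0` means unlimited.
#' @param min_avg_qual minimum mean Phred quality for the high bin.
#' @param max_expected_error maximum accumulated error
#'   (sum of per-base error probabilities) for the high bin.
#' @param window_width,window_min_qual sliding-window tail trimming: at the
#'   first window whose mean quality drops below `window_min_qual` the read
#'   is cut at the window's start.
#' @param max_ambiguous maximum number of N bases.
#' @param max_homopolymer maximum single-nucleotide run length.
#' @param barcode_mismatch_max,primer_mismatch_max mismatch budgets.
#' @param adapter optional adapter sequence, trimmed from its first exact
#'   occurrence to the 3' end.
#' @param truncation_len length of the truncated high-bin copies used as
#'   clustering input (250 bp by default, the usual choice for 454 data).
#' @param mid_relax multiplicative relaxation (>= 1) of
#'   `max_expected_error` for the mid band.
#' @param mid_qual_slack subtractive Phred slack on `min_avg_qual` for the
#'   mid band.
#' @param trim_direction `"3p"` (default) trims the low-quality tail,
#'   preserving the 5' region; `"5p"` mirrors the scan and removes a
#'   low-quality 5' head instead.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_len = 250L, max_len = 0L, min_avg_qual = 27,
                        max_expected_error = 1.0, window_width = 50L,
                        window_min_qual = 25, max_ambiguous = 0L,
                        max_homopolymer = 8L, barcode_mismatch_max = 0L,
                        primer_mismatch_max = 1L, adapter = NULL,
                        truncation_len = 250L, mid_relax = 4,
                        mid_qual_slack = 5, trim_direction = c("3p", "5p")) {
  trim_direction <- match.arg(trim_direction)
  spec <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
               min_avg_qual = as.numeric(min_avg_qual),
               max_expected_error = as.numeric(max_expected_error),
               window_width = as.integer(window_width),
               window_min_qual = as.numeric(window_min_qual),
               max_ambiguous = as.integer(max_ambiguous),
               max_homopolymer = as.integer(max_homopolymer),
               barcode_mismatch_max = as.integer(barcode_mismatch_max),
               primer_mismatch_max = as.integer(primer_mismatch_max),
               adapter = if (is.null(adapter) || is.na(adapter) ||
                             !nzchar(adapter)) NULL else toupper(adapter),
               truncation_len = as.integer(truncation_len),
               mid_relax = as.numeric(mid_relax),
               mid_qual_slack = as.numeric(mid_qual_slack),
               trim_direction = trim_direction)
  if (spec$mid_relax < 1) stop("mid_relax must be >= 1")
  if (spec$max_len > 0 &&
      !(spec$min_len <= spec$truncation_len && spec$truncation_len <= spec$max_len))
    stop("need min_len <= truncation_len <= max_len")
  class(spec) <- "filter_spec"
  spec
}

# option-file key <-> filter_spec field
OPTION_KEYS <- c(MinReadLength = "min_len", MaxReadLength = "max_len",
                 MinAvgQuality = "min_avg_qual",
                 MaxAccumulatedError = "max_expected_error",
                 QualWindowWidth = "window_width",
                 QualWindowThreshold = "window_min_qual",
                 MaxAmbiguousNT = "max_ambiguous",
                 MaxHomopolymer = "max_homopolymer",
                 BarcodeErrors = "barcode_mismatch_max",
                 PrimerErrors = "primer_mismatch_max",
                 Adapter = "adapter", TruncateLength = "truncation_len",
                 MidQualRelax = "mid_relax", MidQualSlack = "mid_qual_slack",
                 TrimDirection = "trim_direction")

#' Read an option file into a [filter_spec()]
#'
#' One `key value` pair per line; `#` starts a comment. Unknown keys are
#' kept (and re-serialized) with a warning.
#'
#' @param path option file path.
#' @return a `filter_spec`, with unknown keys in `attr(, "unknown")`.
#' @export
read_filter_options <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  args <- list()
  unknown <- character()
  for (i in seq_along(keys)) {
    fld <- OPTION_KEYS[keys[i]]
    if (is.na(fld)) {
      unknown[keys[i]] <- vals[i]
      next
    }
    args[[fld]] <- if (fld %in% c("adapter", "trim_direction")) vals[i]
                   else as.numeric(vals[i])
  }
  if (length(unknown))
    warning("unknown option keys preserved: ",
            paste(names(unknown), collapse = ", "))
  spec <- do.call(filter_spec, args)
  attr(spec, "unknown") <- unknown
  spec
}

#' Serialize a [filter_spec()] to an option file
#' @param spec a `filter_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_options <- function(spec, path) {
  lines <- character()
  for (key in names(OPTION_KEYS)) {
    val <- spec[[OPTION_KEYS[key]]]
    if (is.null(val)) next
    lines <- c(lines, paste(key, format(val, scientific = FALSE)))
  }
  unknown <- attr(spec, "unknown")
  if (length(unknown))
    lines <- c(lines, paste(names(unknown), unknown))
  writeLines(lines, path)
  invisible(path)
}

#' Accumulated expected error of a quality vector
#'
#' The sum of per-base error probabilities, `sum(10^(-Q/10))` — a
#' length-aware quality criterion: a 100 bp read at Q20 carries one
#' expected error.
#'
#' @param quals integer vector of Phred scores (>= 0).
#' @return a single number; 0 for an empty vector.
#' @examples
#' expected_error(rep(20L, 10)) # 0.1
#' @export
expected_error <- function(quals) {
  if (!length(quals)) return(0)
  if (any(quals < 0)) stop("negative quality score")
  sum(10^(-quals / 10))
}

# IUPAC degenerate match at the 5' start; returns per-read mismatch counts
iupac_mismatches <- function(bases, primer) {
  L <- nchar(primer)
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(primer, "")[[1]]], "")
  mm <- integer(length(bases))
  short <- nchar(bases) < L
  for (p in seq_len(L)) {
    ch <- substr(bases, p, p)
    mm <- mm + !(ch %in% allowed[[p]])
  }
  mm[short] <- NA_integer_
  mm
}

#' Match reads against sample barcodes
#'
#' Barcodes are anchored at the 5' read start and compared by Hamming
#' distance. A read is assigned to the unique sample within the mismatch
#' budget; ties at the minimal distance leave the read unassigned (safety
#' against cross-sample bleed). The matched barcode is removed from the
#' returned reads.
#'
#' @param rs a [read_set()].
#' @param mapping a mapping table from [read_mapping()].
#' @param max_mismatch allowed barcode mismatches.
#' @return `rs` with `sample` filled (`NA` = unassigned) and barcodes
#'   trimmed from assigned reads.
#' @export
match_barcode <- function(rs, mapping, max_mismatch = 0L) {
  n <- nrow(rs)
  if (n == 0) return(rs)
  nb <- nrow(mapping)
  d <- matrix(NA_integer_, n, nb)
  for (b in seq_len(nb)) {
    bc <- mapping$barcode[b]
    d[, b] <- cpp_hamming(substr(rs$bases, 1L, nchar(bc)), bc)
  }
  d[is.na(d)] <- .Machine$integer.max
  mind <- d[cbind(seq_len(n), max.col(-d, ties.method = "first"))]
  hits <- rowSums(d == mind)
  assigned <- mind <= max_mismatch & hits == 1L
  best <- max.col(-d, ties.method = "first")
  rs$sample <- ifelse(assigned, mapping$sample_id[best], NA_character_)
  cut <- ifelse(assigned, nchar(mapping$barcode)[best], 0L)
  rs <- trim_head(rs, cut)
  rs
}

# remove `cut` leading bases (and qualities) per read
trim_head <- function(rs, cut) {
  idx <- which(cut > 0L)
  if (!length(idx)) return(rs)
  rs$bases[idx] <- substr(rs$bases[idx], cut[idx] + 1L, nchar(rs$bases[idx]))
  rs$quals[idx] <- lapply(idx, function(i) {
    q <- rs$quals[[i]]
    if (is.null(q)) NULL else q[-seq_len(cut[i])]
  })
  rs
}

# keep the first `keep` bases per read
trim_tail_to <- function(rs, keep) {
  keep <- pmin(keep, nchar(rs$bases))
  rs$bases <- substr(rs$bases, 1L, keep)
  rs$quals <- lapply(seq_len(nrow(rs)), function(i) {
    q <- rs$quals[[i]]
    if (is.null(q)) NULL else q[seq_len(keep[i])]
  })
  rs
}

#' Match a (degenerate) primer at the read start
#'
#' IUPAC degenerate positions in the primer match any base of their set at
#' zero cost. On success the primer is removed.
#'
#' @param rs a [read_set()] (barcodes already removed).
#' @param primer primer in the IUPAC alphabet.
#' @param max_mismatch allowed mismatches.
#' @return list with `found` (logical per read) and `reads` (primer trimmed
#'   where found).
#' @export
match_primer <- function(rs, primer, max_mismatch = 0L) {
  if (nrow(rs) == 0) return(list(found = logical(), reads = rs))
  mm <- iupac_mismatches(rs$bases, toupper(primer))
  found <- !is.na(mm) & mm <= max_mismatch
  rs <- trim_head(rs, ifelse(found, nchar(primer), 0L))
  list(found = found, reads = rs)
}

# window-mean scan of one quality vector; returns the kept length
window_cut_length <- function(q, w, thr) {
  L <- length(q)
  if (w > L || w <= 0) return(L)
  cs <- cumsum(c(0, q))
  means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  bad <- which(means < thr)
  if (!length(bad)) L else bad[1] - 1L
}

#' Trim the low-quality tail of each read
#'
#' Slides a window of `window_width` bases along the read; at the first
#' window whose mean quality falls below `window_min_qual` the read is
#' truncated at that window's start. Direction `"3p"` scans 5'→3' and
#' removes the tail; `"5p"` mirrors the scan and removes the head. Reads
#' shorter than the window are returned unchanged.
#'
#' @param rs a [read_set()] with qualities.
#' @param window_width window size in bp.
#' @param window_min_qual mean-quality threshold.
#' @param direction `"3p"` or `"5p"`.
#' @return the trimmed read set.
#' @export
trim_low_quality_tail <- function(rs, window_width, window_min_qual,
                                  direction = c("3p", "5p")) {
  direction <- match.arg(direction)
  if (nrow(rs) == 0 || window_width <= 0) return(rs)
  if (direction == "3p") {
    keep <- vapply(rs$quals, window_cut_length, 0L,
                   w = window_width, thr = window_min_qual)
    trim_tail_to(rs, keep)
  } else {
    keep <- vapply(rs$quals, function(q)
      window_cut_length(rev(q), window_width, window_min_qual), 0L)
    trim_head(rs, nchar(rs$bases) - keep)
  }
}

#' Classify one or more reads into high/mid/rejected bins
#'
#' Applies, in order: adapter trimming (first exact occurrence to the 3'
#' end), window tail-trimming, structural filters (length bounds, ambiguous
#' bases, homopolymer runs), then the quality bands on the trimmed read.
#' Rejection reasons follow a fixed precedence (`too_short`, `too_long`,
#' `ambiguous`, `homopolymer`, `avg_qual`, `expected_error`) so reports are
#' deterministic.
#'
#' @param rs a [read_set()] (barcode and primer already handled).
#' @param spec a [filter_spec()].
#' @return list with `verdict` (factor high/mid/rejected per read),
#'   `reject_reason` (character, `NA` unless rejected) and `reads` (the
#'   trimmed read set; rows for rejected reads are retained but should not
#'   be used downstream).
#' @export
classify_read <- function(rs, spec) {
  n <- nrow(rs)
  quality_on <- spec$min_avg_qual > 0 || is.finite(spec$max_expected_error) ||
    spec$window_min_qual > 0
  if (n > 0 && quality_on && !has_quals(rs))
    stop("reads carry no qualities but quality criteria are enabled; ",
         "configure a quality-free filter_spec (min_avg_qual = 0, ",
         "max_expected_error = Inf, window_min_qual = 0)")

  if (!is.null(spec$adapter)) {
    pos <- regexpr(spec$adapter, rs$bases, fixed = TRUE)
    rs <- trim_tail_to(rs, ifelse(pos > 0, pos - 1L, nchar(rs$bases)))
  }
  if (quality_on && spec$window_min_qual > 0)
    rs <- trim_low_quality_tail(rs, spec$window_width, spec$window_min_qual,
                                spec$trim_direction)

  len <- nchar(rs$bases)
  n_amb <- nchar(rs$bases) - nchar(gsub("N", "", rs$bases, fixed = TRUE))
  runs <- cpp_max_run(rs$bases)
  avg <- vapply(rs$quals, function(q) if (is.null(q)) NA_real_ else mean(q),
                numeric(1))
  ee <- vapply(rs$quals, function(q) if (is.null(q)) NA_real_ else
    expected_error(q), numeric(1))

  reason <- rep(NA_character_, n)
  reason[is.na(reason) & len < spec$min_len] <- "too_short"
  if (spec$max_len > 0)
    reason[is.na(reason) & len > spec$max_len] <- "too_long"
  reason[is.na(reason) & n_amb > spec$max_ambiguous] <- "ambiguous"
  reason[is.na(reason) & runs > spec$max_homopolymer] <- "homopolymer"

  if (quality_on) {
    ok <- is.na(reason)
    high <- ok & avg >= spec$min_avg_qual & ee <= spec$max_expected_error
    mid <- ok & !high & avg >= spec$min_avg_qual - spec$mid_qual_slack &
      ee <= spec$max_expected_error * spec$mid_relax
    fail <- ok & !high & !mid
    reason[fail & avg < spec$min_avg_qual - spec$mid_qual_slack] <- "avg_qual"
    reason[fail & is.na(reason)] <- "expected_error"
  } else {
    high <- is.na(reason)
    mid <- rep(FALSE, n)
  }
  verdict <- ifelse(!is.na(reason), "rejected", ifelse(high, "high", "mid"))
  list(verdict = factor(verdict, levels = c("high", "mid", "rejected")),
       reject_reason = reason, reads = rs)
}

#' Demultiplex and quality-filter a sequencing run
#'
#' The pipeline's first stage: every read is assigned to a sample by its
#' barcode, primer-checked, trimmed, and sorted into the high-quality bin
#' (clustering input; a copy truncated to `spec$truncation_len` is emitted
#' as `high_trunc`), the mid-quality bin (abundance counting only), or
#' rejected/unassigned. Counts are conserved: every input read appears in
#' exactly one of those piles.
#'
#' @param rs a [read_set()] (multiplexed), or a file path readable by
#'   [read_sequences()].
#' @param mapping mapping table from [read_mapping()] (or `NULL` to skip
#'   demultiplexing and treat all reads as one sample `"all"`).
#' @param spec a [filter_spec()].
#' @param mates optional [read_set()] of reverse mates in matching order;
#'   mates follow their forward read's verdict and are returned untrimmed
#'   in `mates_high`.
#' @return list with read sets `high`, `high_trunc`, `mid`, a `report`
#'   data.frame (per-sample verdict counts), and `reasons` (named rejected
#'   counts incl. `no_barcode`/`no_primer`), plus `mates_high` when `mates`
#'   was given.
#' @export
demultiplex_run <- function(rs, mapping, spec = filter_spec(), mates = NULL) {
  if (is.character(rs)) rs <- read_sequences(rs)
  n_in <- nrow(rs)
  reason <- rep(NA_character_, n_in)

  if (!is.null(mapping)) {
    rs <- match_barcode(rs, mapping, spec$barcode_mismatch_max)
    reason[is.na(rs$sample)] <- "no_barcode"
    # primer check per sample (primers may differ between samples)
    primers <- setNames(mapping$fwd_primer, mapping$sample_id)
    for (s in mapping$sample_id) {
      p <- primers[[s]]
      if (is.na(p) || !nzchar(p)) next
      idx <- which(!is.na(rs$sample) & rs$sample == s)
      if (!length(idx)) next
      res <- match_primer(subset_reads(rs, idx), p, spec$primer_mismatch_max)
      rs$bases[idx] <- res$reads$bases
      rs$quals[idx] <- res$reads$quals
      reason[idx[!res$found]] <- "no_primer"
    }
  } else {
    rs$sample <- "all"
  }

  ok <- is.na(reason)
  cls <- classify_read(subset_reads(rs, which(ok)), spec)
  verdict <- rep("rejected", n_in)
  verdict[ok] <- as.character(cls$verdict)
  reason[ok] <- cls$reject_reason

  processed <- cls$reads
  keep_high <- which(as.character(cls$verdict) == "high")
  keep_mid <- which(as.character(cls$verdict) == "mid")
  high <- subset_reads(processed, keep_high)
  mid <- subset_reads(processed, keep_mid)
  high_trunc <- trim_tail_to(high, spec$truncation_len)

  samples <- if (!is.null(mapping)) mapping$sample_id else "all"
  tab <- table(factor(rs$sample[ok][c(keep_high, keep_mid)],
                      levels = samples),
               factor(rep(c("high", "mid"),
                          c(length(keep_high), length(keep_mid))),
                      levels = c("high", "mid")))
  report <- data.frame(sample_id = samples,
                       high = as.integer(tab[, "high"]),
                       mid = as.integer(tab[, "mid"]),
                       stringsAsFactors = FALSE)
  report$rejected <- as.integer(table(factor(
    rs$sample[!is.na(reason) & !is.na(rs$sample)], levels = samples)))
  reasons <- table(reason[!is.na(reason)])
  res <- list(high = high, high_trunc = high_trunc, mid = mid,
              report = report,
              reasons = setNames(as.integer(reasons), names(reasons)),
              n_input = n_in,
              n_unassigned = sum(reason %in% "no_barcode"))
  stopifnot(nrow(high) + nrow(mid) + sum(!is.na(reason)) == n_in)
  if (!is.null(mapping) && nrow(high) + nrow(mid) == 0)
    warning("no reads were assigned to any sample")

  if (!is.null(mates)) {
    if (nrow(mates) != n_in) stop("mates must match input read count")
    mates$sample <- rs$sample
    res$mates_high <- subset_reads(mates, which(ok)[keep_high])
  }
  res
}
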