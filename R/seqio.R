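#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   BStringSet reverseComplement
NULL

# gzip sniffing by magic bytes, never by extension
is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# first significant character decides fasta ('>') vs fastq ('@')
sniff_format <- function(path) {
  con <- if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) return("empty")
    line <- trimws(line)
    if (nzchar(line)) break
  }
  ch <- substr(line, 1, 1)
  if (ch == ">") "fasta" else if (ch == "@") "fastq" else
    stop("unrecognized sequence format in ", path)
}

fastq_to_read_set <- function(xs, pair_role = "single") {
  qs <- as.character(S4Vectors::mcols(xs)$qualities)
  quals <- lapply(qs, function(s) utf8ToInt(s) - 33L)
  read_set(names(xs), toupper(as.character(xs)), quals, pair_role = pair_role)
}

# 454-style .qual companion: fasta-like records of space-separated integers
parse_qual_file <- function(path) {
  con <- if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) stop("no records in quality file ", path)
  rec <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  vals <- lapply(split(lines[!is_hdr], rec[!is_hdr]), function(body)
    as.integer(unlist(strsplit(paste(body, collapse = " "), "\\s+"))))
  # records with no body lines yield no split entry; fill empties
  out <- rep(list(integer()), length(ids))
  names(out) <- ids
  present <- as.integer(names(vals))
  out[present] <- vals
  names(out) <- ids
  out
}

#' Read sequence files into a read set
#'
#' Reads FASTA, FASTA + companion quality file, or FASTQ (Phred+33), each
#' optionally gzip-compressed (detected by magic bytes, not extension).
#' Paired-end layouts are two files in matched record order.
#'
#' @param path path to the (forward) sequence file.
#' @param qual_path optional 454-style `.qual` file accompanying a FASTA.
#' @param mate_path optional reverse-mate file (same format as `path`).
#' @param chunk_size,callback if both given, the file is read in chunks of
#'   `chunk_size` records and `callback(read_set)` is invoked per chunk
#'   (single-file inputs only); the function then returns the total record
#'   count invisibly instead of a read set.
#' @return a [read_set()]; for paired input a list with elements `fwd` and
#'   `rev`.
#' @export
read_sequences <- function(path, qual_path = NULL, mate_path = NULL,
                           chunk_size = NULL, callback = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- sniff_format(path)
  if (fmt == "empty") return(read_set(character(), character()))

  if (!is.null(chunk_size) && !is.null(callback)) {
    if (!is.null(qual_path) || !is.null(mate_path))
      stop("chunked reading supports single-file input only")
    total <- 0L
    skip <- 0L
    repeat {
      xs <- readDNAStringSet(path, format = fmt, nrec = chunk_size,
                             skip = skip, with.qualities = (fmt == "fastq"))
      if (!length(xs)) break
      chunk <- if (fmt == "fastq") fastq_to_read_set(xs)
               else read_set(sub("\\s.*$", "", names(xs)),
                             toupper(as.character(xs)))
      callback(chunk)
      total <- total + length(xs)
      skip <- skip + length(xs)
      if (length(xs) < chunk_size) break
    }
    return(invisible(total))
  }

  if (!is.null(mate_path)) {
    fwd <- read_sequences(path, qual_path = qual_path)
    rev <- read_sequences(mate_path)
    if (n_reads(fwd) != n_reads(rev))
      stop("paired files have unequal record counts (", n_reads(fwd),
           " vs ", n_reads(rev), ")")
    fwd$pair_role <- "forward"
    rev$pair_role <- "reverse"
    return(list(fwd = fwd, rev = rev))
  }

  if (fmt == "fastq") {
    xs <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    return(fastq_to_read_set(xs))
  }

  xs <- readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  bases <- toupper(as.character(xs))
  if (is.null(qual_path)) return(read_set(ids, bases))

  qmap <- parse_qual_file(qual_path)
  if (!identical(names(qmap), ids))
    stop("fasta and quality file record ids do not align")
  bad <- which(lengths(qmap) != nchar(bases))
  if (length(bad))
    stop("quality length differs from sequence length for read '",
         ids[bad[1]], "'")
  read_set(ids, bases, unname(qmap))
}

#' Write reads as FASTA
#'
#' @param rs a [read_set()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(rs, path, width = 70L) {
  xs <- DNAStringSet(setNames(rs$bases, rs$read_id))
  writeXStringSet(xs, path, width = width,
                  compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(rs, path) {
  if (nrow(rs) > 0 && !has_quals(rs))
    stop("fastq output requires qualities on every read; use write_fasta()")
  xs <- DNAStringSet(setNames(rs$bases, rs$read_id))
  qs <- BStringSet(vapply(rs$quals, function(q) intToUtf8(q + 33L), ""))
  writeXStringSet(xs, path, format = "fastq", qualities = qs,
                  compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a sample mapping table
#'
#' Tab-separated with a header row: first column the sample id, a required
#' `BarcodeSequence` column and optional `LinkerPrimerSequence` /
#' `ReversePrimer` columns. The header may start with `#` (QIIME-style
#' `#SampleID`); comment lines after the header start with `#`. Extra
#' columns are kept as metadata.
#'
#' @param path path to the mapping file.
#' @return a data.frame with columns `sample_id`, `barcode`, `fwd_primer`,
#'   `rev_primer` plus any metadata columns.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty mapping file: ", path)
  header <- sub("^#", "", lines[1])
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  cols <- strsplit(header, "\t")[[1]]
  if (length(cols) < 2 || !"BarcodeSequence" %in% cols)
    stop("mapping file needs a sample-id column and a BarcodeSequence column")
  rows <- strsplit(body, "\t")
  mat <- do.call(rbind, lapply(rows, function(r) {
    length(r) <- length(cols)
    r
  }))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  out <- data.frame(sample_id = df[[1]],
                    barcode = toupper(df$BarcodeSequence),
                    fwd_primer = if ("LinkerPrimerSequence" %in% cols)
                      toupper(df$LinkerPrimerSequence) else NA_character_,
                    rev_primer = if ("ReversePrimer" %in% cols)
                      toupper(df$ReversePrimer) else NA_character_,
                    stringsAsFactors = FALSE)
  meta <- setdiff(cols, c(cols[1], "BarcodeSequence", "LinkerPrimerSequence",
                          "ReversePrimer"))
  for (m in meta) out[[m]] <- df[[m]]
  dup_s <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup_s)) stop("duplicate sample id in mapping file: ", dup_s[1])
  dup_b <- out$barcode[duplicated(out$barcode)]
  if (length(dup_b)) stop("duplicate barcode in mapping file: ", dup_b[1])
  if (any(!nzchar(out$barcode) | is.na(out$barcode)))
    stop("empty barcode for sample ",
         out$sample_id[which(!nzchar(out$barcode) | is.na(out$barcode))[1]])
  out
}
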