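#' Collect full-length seed candidates for an OTU
#'
#' Clustering runs on reads truncated to a common length, so the cluster
#' representative is short. Candidates to replace it are the full-length,
#' high-quality versions of the cluster's member reads that still align to
#' the representative at `identity_threshold` or above; each candidate is
#' tail-trimmed of low-quality bases before scoring.
#'
#' @param cluster one OTU cluster ([cluster_otus()]).
#' @param full_reads [read_set()] of full-length high-quality reads
#'   (mid-bin reads are deliberately excluded).
#' @param identity_threshold minimum identity to the representative.
#' @param window_width,window_min_qual tail-trim parameters (see
#'   [trim_low_quality_tail()]); `window_min_qual = 0` disables trimming.
#' @return data.frame of candidates: `read_id`, `bases`, `quals` (list),
#'   `identity`, `mean_error`, `length`.
#' @export
collect_candidates <- function(cluster, full_reads, identity_threshold = 0.97,
                               window_width = 50L, window_min_qual = 25) {
  idx <- which(full_reads$read_id %in% cluster$member_read_ids)
  empty <- data.frame(read_id = character(), bases = character(),
                      identity = numeric(), mean_error = numeric(),
                      length = integer(), stringsAsFactors = FALSE)
  empty$quals <- list()
  if (!length(idx)) return(empty)
  cand <- subset_reads(full_reads, idx)
  if (window_min_qual > 0 && has_quals(cand))
    cand <- trim_low_quality_tail(cand, window_width, window_min_qual)
  ident <- cpp_identity(cand$bases, cluster$seed$bases[1])
  keep <- which(ident >= identity_threshold)
  if (!length(keep)) return(empty)
  cand <- subset_reads(cand, keep)
  ee <- vapply(cand$quals, function(q) if (is.null(q)) 0 else
    expected_error(q), numeric(1))
  out <- data.frame(read_id = cand$read_id, bases = cand$bases,
                    identity = ident[keep],
                    mean_error = ee / nchar(cand$bases),
                    length = nchar(cand$bases), stringsAsFactors = FALSE)
  out$quals <- cand$quals
  out
}

#' Select the extended seed among candidates
#'
#' Lexicographic ranking: (1) identity to the representative closest to the
#' candidates' median identity (the centre of the OTU), (2) lowest per-base
#' expected error, (3) greatest length, (4) smallest read id for
#' determinism. The result is permutation-invariant in the candidate order.
#'
#' @param candidates data.frame from [collect_candidates()].
#' @return a one-row [read_set()] holding the chosen seed.
#' @export
select_seed <- function(candidates) {
  if (!nrow(candidates)) stop("no seed candidates")
  med <- median(candidates$identity)
  ord <- order(abs(candidates$identity - med), candidates$mean_error,
               -candidates$length, candidates$read_id)
  top <- candidates[ord[1], , drop = FALSE]
  read_set(top$read_id, top$bases, top$quals)
}

#' Extend all OTU seeds to full-length reads
#'
#' Replaces each cluster's truncated representative with the
#' [select_seed()] winner among its full-length high-quality members.
#' Paired runs first merge each member's mates via [merge_pair()]
#' upstream; here the reads supplied in `full_reads` are taken as the
#' full-length pool. Clusters with no surviving candidate keep their
#' representative and are flagged.
#'
#' @inheritParams collect_candidates
#' @param clusters list of OTU clusters.
#' @return the cluster list with `seed` replaced and a logical
#'   `seed_extended` element added per cluster.
#' @export
extend_seeds <- function(clusters, full_reads, identity_threshold = 0.97,
                         window_width = 50L, window_min_qual = 25) {
  lapply(clusters, function(cl) {
    cand <- collect_candidates(cl, full_reads, identity_threshold,
                               window_width, window_min_qual)
    if (nrow(cand)) {
      seed <- select_seed(cand)
      seed$read_id <- cl$otu_id
      cl$seed <- seed
      cl$seed_extended <- TRUE
    } else {
      cl$seed_extended <- FALSE
    }
    cl
  })
}

#' Merge a forward/reverse read pair by overlap
#'
#' The reverse read is reverse-complemented, then overlap lengths are
#' scanned from the longest possible down to `min_overlap`; the first
#' overlap whose mismatch fraction is at most `max_mismatch_fraction` is
#' accepted. Within the overlap, agreements keep the base with quality
#' `max(Qf, Qr)`; disagreements keep the higher-quality base with quality
#' `max(|Qf - Qr|, 2)`.
#'
#' @param fwd,rev one-row [read_set()]s (or single reads) for the forward
#'   and reverse mate; `rev` is given in sequencing orientation.
#' @param min_overlap minimum acceptable overlap, default 10 bp.
#' @param max_mismatch_fraction maximum mismatch fraction in the overlap,
#'   default 0.25.
#' @return a one-row [read_set()] with the merged read, or `NULL` when no
#'   acceptable overlap exists (callers fall back to the forward read).
#' @export
merge_pair <- function(fwd, rev, min_overlap = 10L,
                       max_mismatch_fraction = 0.25) {
  f <- fwd$bases[1]
  fq <- fwd$quals[[1]]
  r <- as.character(reverseComplement(DNAStringSet(rev$bases[1]))[[1]])
  rq <- rev(rev$quals[[1]])
  nf <- nchar(f); nr <- nchar(r)
  if (is.null(fq)) fq <- rep(30L, nf)
  if (is.null(rq)) rq <- rep(30L, nr)
  if (min(nf, nr) < min_overlap) return(NULL)
  fv <- strsplit(f, "")[[1]]
  rv <- strsplit(r, "")[[1]]
  for (ov in seq(min(nf, nr), min_overlap)) {
    ftail <- fv[(nf - ov + 1):nf]
    rhead <- rv[1:ov]
    mm <- ftail != rhead
    if (sum(mm) / ov > max_mismatch_fraction) next
    qf <- fq[(nf - ov + 1):nf]
    qr <- rq[1:ov]
    cons <- ifelse(!mm, ftail, ifelse(qf >= qr, ftail, rhead))
    consq <- ifelse(!mm, pmax(qf, qr), pmax(abs(qf - qr), 2L))
    bases <- paste0(substr(f, 1, nf - ov), paste(cons, collapse = ""),
                    substr(r, ov + 1, nr))
    quals <- c(fq[seq_len(nf - ov)], as.integer(consq),
               rq[seq_len(nr - ov) + ov])
    return(read_set(fwd$read_id[1], bases, list(quals),
                    sample = fwd$sample[1]))
  }
  NULL
}
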