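#' Pairwise sequence identity
#'
#' The single identity definition used throughout the package: matches
#' divided by alignment columns of a glocal alignment — the shorter
#' sequence aligned in full, terminal gaps free only on the longer one
#' (match +1, mismatch -1, linear gap -2; the longer sequence's overhangs
#' carry no columns). Full containment of the shorter sequence keeps the
#' ratio meaningful both for same-length reads and for a truncated
#' cluster representative against its full-length member reads.
#'
#' @param a,b nucleotide strings; `a` may be a vector (aligned against the
#'   single subject `b`).
#' @return numeric identity fraction(s) in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  cpp_identity(toupper(a), toupper(b))
}

#' Exact-string dereplication
#'
#' Collapses identical sequences, the usual precursor to centroid
#' clustering. Input reads are expected to be truncated to a common length
#' by the demultiplexer.
#'
#' @param rs a [read_set()] (or a character vector of sequences).
#' @return data.frame with `sequence`, `size` and a `member_ids` list
#'   column, sorted by size descending, ties broken lexicographically by
#'   sequence.
#' @export
dereplicate <- function(rs) {
  if (is.character(rs)) rs <- read_set(sprintf("r%d", seq_along(rs)), rs)
  if (nrow(rs) == 0)
    return(data.frame(sequence = character(), size = integer()))
  grp <- split(rs$read_id, rs$bases)
  out <- data.frame(sequence = names(grp), size = lengths(grp),
                    stringsAsFactors = FALSE)
  out$member_ids <- unname(grp)
  out <- out[order(-out$size, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_otu_id <- function(i) sprintf("OTU_%04d", i)

#' Greedy centroid OTU clustering (built-in stand-in)
#'
#' Clusters dereplicated sequences in descending-abundance order: each
#' sequence joins the first existing centroid it matches at
#' `identity_threshold` or above, otherwise it founds a new OTU. This is a
#' deliberately simple, dependency-free stand-in for heavier external
#' denoising clusterers; their output can be substituted via
#' [import_external_clusters()].
#'
#' @param derep output of [dereplicate()] (or a [read_set()], dereplicated
#'   internally).
#' @param identity_threshold identity radius, default 0.97.
#' @return list of OTU clusters, each `list(otu_id, seed, member_read_ids)`
#'   where `seed` is a one-row [read_set()] holding the representative.
#' @export
cluster_otus <- function(derep, identity_threshold = 0.97) {
  if (inherits(derep, "read_set") || is.character(derep))
    derep <- dereplicate(derep)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  centroids <- character()
  members <- list()
  for (i in seq_len(nrow(derep))) {
    s <- derep$sequence[i]
    hit <- NA_integer_
    if (length(centroids)) {
      ident <- cpp_identity(centroids, s)
      ok <- which(ident >= identity_threshold)
      if (length(ok)) hit <- ok[1]
    }
    if (is.na(hit)) {
      centroids <- c(centroids, s)
      members <- c(members, list(derep$member_ids[[i]]))
    } else {
      members[[hit]] <- c(members[[hit]], derep$member_ids[[i]])
    }
  }
  lapply(seq_along(centroids), function(k)
    list(otu_id = new_otu_id(k),
         seed = read_set(new_otu_id(k), centroids[k]),
         member_read_ids = members[[k]]))
}

#' Import clusters produced by an external clustering tool
#'
#' Adapter for the pluggable clustering backend: seeds as FASTA (headers =
#' OTU ids) plus a two-column TSV membership map (read_id, otu_id).
#'
#' @param seed_fasta path to the seed FASTA.
#' @param membership_tsv path to the membership table.
#' @return list of OTU clusters as in [cluster_otus()].
#' @export
import_external_clusters <- function(seed_fasta, membership_tsv) {
  seeds <- read_sequences(seed_fasta)
  mem <- read.delim(membership_tsv, header = FALSE,
                    col.names = c("read_id", "otu_id"),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(mem$otu_id, seeds$read_id)
  if (length(unknown))
    stop("membership references unknown OTU id: ", unknown[1])
  by_otu <- split(mem$read_id, mem$otu_id)
  lapply(seq_len(nrow(seeds)), function(k)
    list(otu_id = seeds$read_id[k],
         seed = subset_reads(seeds, k),
         member_read_ids = by_otu[[seeds$read_id[k]]] %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map reads onto OTU seeds to build the abundance matrix
#'
#' Every high- and mid-quality read is assigned to the single
#' best-identity seed at or above `identity_threshold` (ties go to the
#' lexicographically smallest OTU id); reads matching no seed are counted
#' as unmapped and omitted from the matrix. Mid-quality reads therefore add
#' to counts of established OTUs without founding spurious ones.
#'
#' @param rs a [read_set()] carrying sample labels.
#' @param clusters list of OTU clusters ([cluster_otus()]).
#' @param identity_threshold mapping identity, default 0.97.
#' @return integer matrix OTUs x samples with `attr(, "unmapped")` = count
#'   of unmapped reads and `attr(, "read_otu")` = per-read assignment
#'   (NA = unmapped).
#' @export
map_reads_to_otus <- function(rs, clusters, identity_threshold = 0.97) {
  otu_ids <- vapply(clusters, `[[`, "", "otu_id")
  ord <- order(otu_ids)
  clusters <- clusters[ord]
  otu_ids <- otu_ids[ord]
  samples <- sort(unique(rs$sample))
  if (nrow(rs) == 0 || !length(clusters)) {
    m <- matrix(0L, length(otu_ids), length(samples),
                dimnames = list(otu_ids, samples))
    attr(m, "unmapped") <- nrow(rs)
    return(m)
  }
  idmat <- vapply(clusters, function(cl)
    cpp_identity(rs$bases, cl$seed$bases[1]), numeric(nrow(rs)))
  idmat <- matrix(idmat, nrow = nrow(rs))
  best <- max.col(idmat, ties.method = "first")  # first = smallest otu_id
  best_id <- idmat[cbind(seq_len(nrow(rs)), best)]
  mapped <- best_id >= identity_threshold
  assign <- ifelse(mapped, otu_ids[best], NA_character_)
  m <- table(factor(assign[mapped], levels = otu_ids),
             factor(rs$sample[mapped], levels = samples))
  m <- matrix(as.integer(m), nrow = length(otu_ids),
              dimnames = list(otu_ids, samples))
  attr(m, "unmapped") <- sum(!mapped)
  attr(m, "read_otu") <- setNames(assign, rs$read_id)
  m
}

#' Report seed pairs exceeding the clustering identity radius
#'
#' External (and greedy) clusterers can emit OTUs whose seeds are mutually
#' within the OTU radius; such pairs are reported so they can be merged.
#'
#' @param clusters list of OTU clusters.
#' @param identity_threshold identity radius, default 0.97.
#' @return data.frame with columns `otu_a`, `otu_b`, `identity`.
#' @export
check_otu_overlap <- function(clusters, identity_threshold = 0.97) {
  out <- data.frame(otu_a = character(), otu_b = character(),
                    identity = numeric(), stringsAsFactors = FALSE)
  k <- length(clusters)
  if (k < 2) return(out)
  seqs <- vapply(clusters, function(cl) cl$seed$bases[1], "")
  ids <- vapply(clusters, `[[`, "", "otu_id")
  for (i in seq_len(k - 1)) {
    ident <- cpp_identity(seqs[(i + 1):k], seqs[i])
    hit <- which(ident >= identity_threshold)
    if (length(hit))
      out <- rbind(out, data.frame(otu_a = ids[i], otu_b = ids[i + hit],
                                   identity = ident[hit],
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Merge overlapping OTUs
#'
#' Collapses each offending pair from [check_otu_overlap()] by absorbing
#' the smaller OTU (fewer members) into the larger, repeating until no pair
#' remains within the radius.
#'
#' @inheritParams check_otu_overlap
#' @return the merged cluster list.
#' @export
merge_overlapping_otus <- function(clusters, identity_threshold = 0.97) {
  repeat {
    pairs <- check_otu_overlap(clusters, identity_threshold)
    if (!nrow(pairs)) return(clusters)
    ids <- vapply(clusters, `[[`, "", "otu_id")
    a <- match(pairs$otu_a[1], ids)
    b <- match(pairs$otu_b[1], ids)
    sz <- lengths(lapply(clusters, `[[`, "member_read_ids"))
    keep <- if (sz[a] >= sz[b]) a else b
    drop <- if (keep == a) b else a
    clusters[[keep]]$member_read_ids <-
      c(clusters[[keep]]$member_read_ids, clusters[[drop]]$member_read_ids)
    clusters <- clusters[-drop]
  }
}
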