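#' LCA classifier settings
#'
#' Parameters of the identity-windowed lowest-common-ancestor classifier.
#' Only alignment hits within `identity_window` percentage points of the
#' best hit vote (capped at `max_hits`); a rank is assigned when one name
#' wins strictly more than `consensus_fraction` of the non-discarded
#' voters; and the best hit's identity caps the assignable depth via
#' `depth_caps` (e.g. a 96% best hit can never yield a species call, only
#' genus or above).
#'
#' @param identity_window window below the best hit, in percentage points
#'   of identity (default 1.5).
#' @param max_hits cap on voting hits after the window (default 200).
#' @param consensus_fraction strict majority fraction (default 0.9: a name
#'   must exceed 90% of voters).
#' @param depth_caps named numeric vector rank -> minimum percent identity.
#'   The default is monotone in taxonomic depth (phylum 78, class 88,
#'   order 91, family 93, genus 95, species 97).
#' @param literal_printed_caps use the alternative class=91/order=88
#'   assignment of the same cap values (non-monotone in depth; kept for
#'   compatibility with configurations that list them that way).
#' @return an `lca_spec` list.
#' @export
lca_spec <- function(identity_window = 1.5, max_hits = 200L,
                     consensus_fraction = 0.9, depth_caps = NULL,
                     literal_printed_caps = FALSE) {
  if (is.null(depth_caps)) {
    depth_caps <- if (literal_printed_caps)
      c(phylum = 78, class = 91, order = 88, family = 93, genus = 95,
        species = 97)
    else
      c(phylum = 78, class = 88, order = 91, family = 93, genus = 95,
        species = 97)
  }
  stopifnot(identity_window >= 0, consensus_fraction > 0,
            consensus_fraction <= 1,
            all(names(depth_caps) %in% TAX_RANKS))
  spec <- list(identity_window = identity_window,
               max_hits = as.integer(max_hits),
               consensus_fraction = consensus_fraction,
               depth_caps = depth_caps)
  class(spec) <- "lca_spec"
  spec
}

#' Read a BLAST tabular hit file (outfmt 6)
#'
#' Standard 12 columns: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path path to the tabular file.
#' @return data.frame of hits.
#' @export
read_blast_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(cols))
    stop("expected 12 tab-separated columns, got ", ncol(df))
  names(df) <- cols
  df
}

#' Read a reference taxonomy table
#'
#' Two tab-separated columns: reference id and a semicolon-separated
#' lineage of up to 7 ranks (domain..species). Greengenes-style rank
#' prefixes (`k__`, `p__`, ...) are stripped; empty or missing ranks become
#' the unassigned marker `"?"`, and once a rank is unassigned all deeper
#' ranks are forced unassigned (truncation semantics).
#'
#' @param path path to the taxonomy TSV.
#' @return data.frame with `subject_id` plus the 7 rank columns.
#' @export
read_reference_taxonomy <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   quote = "", col.names = c("subject_id", "lineage"))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id: ", df$subject_id[duplicated(df$subject_id)][1])
  parts <- strsplit(df$lineage, ";")
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[is.na(p) | !nzchar(p)] <- UNASSIGNED
    length(p) <- 7L
    p[is.na(p)] <- UNASSIGNED
    p
  }, character(7)))
  mat <- normalize_truncation(mat)
  colnames(mat) <- TAX_RANKS
  cbind(data.frame(subject_id = df$subject_id, stringsAsFactors = FALSE),
        as.data.frame(mat, stringsAsFactors = FALSE))
}

# enforce: once unassigned, all deeper ranks unassigned
normalize_truncation <- function(mat) {
  for (r in 2:7)
    mat[mat[, r - 1] == UNASSIGNED, r] <- UNASSIGNED
  mat
}

# one reference, one vote: collapse multiple HSPs per subject to the
# best-identity one (ties: best bitscore)
dedup_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$sseqid, -hits$pident, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$sseqid), , drop = FALSE]
}

#' Retain hits within the identity window of the best hit
#'
#' Keeps hits whose percent identity is within `spec$identity_window`
#' percentage points of the best hit for this query; if more than
#' `spec$max_hits` remain, the top hits by (identity desc, bitscore desc,
#' subject id asc) are kept.
#'
#' @param hits data.frame of hits for one query.
#' @param spec an [lca_spec()].
#' @return the retained hits.
#' @export
filter_hits <- function(hits, spec = lca_spec()) {
  if (!nrow(hits)) return(hits)
  best <- max(hits$pident)
  keep <- hits[hits$pident >= best - spec$identity_window, , drop = FALSE]
  if (nrow(keep) > spec$max_hits) {
    ord <- order(-keep$pident, -keep$bitscore, keep$sseqid)
    keep <- keep[ord[seq_len(spec$max_hits)], , drop = FALSE]
  }
  keep
}

#' Deepest taxonomic rank allowed by the best hit's identity
#'
#' A best hit at, say, 96% identity may indicate that the query's species
#' is absent from the reference database, so the assignment is capped at
#' genus; below the phylum cap only the domain is assignable.
#'
#' @param best_identity best-hit percent identity.
#' @param caps named cap vector (see [lca_spec()]).
#' @return the deepest allowed rank name.
#' @export
depth_cap <- function(best_identity, caps = lca_spec()$depth_caps) {
  allowed <- "domain"
  for (r in TAX_RANKS[-1]) {
    cap <- caps[[r]]
    if (!is.null(cap) && !is.na(cap) && best_identity < cap) break
    allowed <- r
  }
  allowed
}

#' Consensus vote at one taxonomic rank
#'
#' References lacking a name at this rank are discarded from the vote (so
#' a single species-annotated reference among otherwise unannotated ones
#' can still carry a species call); among the rest, the plurality name
#' wins iff its share strictly exceeds `consensus_fraction`.
#'
#' @param subjects subject ids of the retained hits.
#' @param ref_tax reference taxonomy ([read_reference_taxonomy()]).
#' @param rank one of the 7 rank names.
#' @param consensus_fraction strict-majority fraction.
#' @return list with `name` (the assigned name or `NA`), `n_voters`
#'   (non-discarded voters) and `share` of the leading name.
#' @export
rank_vote <- function(subjects, ref_tax, rank, consensus_fraction = 0.9) {
  row <- match(subjects, ref_tax$subject_id)
  if (anyNA(row))
    stop("subject id missing from reference taxonomy: ",
         subjects[which(is.na(row))[1]])
  names <- ref_tax[[rank]][row]
  names <- names[names != UNASSIGNED]
  if (!length(names))
    return(list(name = NA_character_, n_voters = 0L, share = NA_real_))
  tab <- sort(table(names), decreasing = TRUE)
  share <- as.numeric(tab[1]) / length(names)
  list(name = if (share > consensus_fraction) names(tab)[1] else NA_character_,
       n_voters = length(names), share = share)
}

#' Windowed LCA taxonomic assignment for one query
#'
#' Collapses multi-HSP hits (one reference, one vote), retains the
#' identity window via [filter_hits()], caps the assignable depth from the
#' best hit's identity via [depth_cap()], then walks domain -> species
#' applying [rank_vote()]; the walk stops at the first rank that fails the
#' vote or exceeds the cap, and all deeper ranks stay unassigned.
#'
#' @param hits hits for one query (data.frame; may be empty).
#' @param ref_tax reference taxonomy.
#' @param spec an [lca_spec()].
#' @return named character vector over the 7 ranks (`"?"` = unassigned).
#' @export
lca_assign <- function(hits, ref_tax, spec = lca_spec()) {
  path <- setNames(rep(UNASSIGNED, 7), TAX_RANKS)
  if (is.null(hits) || !nrow(hits)) return(path)
  hits <- dedup_hits(hits)
  retained <- filter_hits(hits, spec)
  cap <- depth_cap(max(retained$pident), spec$depth_caps)
  cap_i <- match(cap, TAX_RANKS)
  for (r in seq_len(cap_i)) {
    v <- rank_vote(retained$sseqid, ref_tax, TAX_RANKS[r],
                   spec$consensus_fraction)
    if (is.na(v$name)) break
    path[TAX_RANKS[r]] <- v$name
  }
  path
}

#' Classify all OTU seeds from a hit table
#'
#' @param otu_ids character vector of seed ids (every id receives a path,
#'   possibly fully unassigned).
#' @param hits hit table over all queries ([read_blast_table()]).
#' @param ref_tax reference taxonomy.
#' @param spec an [lca_spec()].
#' @return data.frame: `otu_id` plus the 7 rank columns.
#' @export
classify_all <- function(otu_ids, hits, ref_tax, spec = lca_spec()) {
  unknown <- setdiff(unique(hits$qseqid), otu_ids)
  if (length(unknown)) {
    warning("hits for unknown query ids skipped: ",
            paste(head(unknown, 3), collapse = ", "))
    hits <- hits[!hits$qseqid %in% unknown, , drop = FALSE]
  }
  by_q <- split(hits, hits$qseqid)
  paths <- t(vapply(otu_ids, function(id)
    lca_assign(by_q[[id]], ref_tax, spec), character(7)))
  cbind(data.frame(otu_id = otu_ids, stringsAsFactors = FALSE),
        as.data.frame(paths, stringsAsFactors = FALSE))
}

#' Aggregate an OTU abundance matrix at a taxonomic rank
#'
#' OTU counts are summed by the assigned name at `rank`; OTUs unassigned
#' at that rank pool into an `"unassigned"` row. Totals are preserved.
#'
#' @param ab_matrix integer matrix OTUs x samples ([map_reads_to_otus()]).
#' @param assignments data.frame from [classify_all()].
#' @param rank one of the 7 rank names.
#' @return integer matrix taxa x samples.
#' @export
aggregate_taxa <- function(ab_matrix, assignments, rank) {
  stopifnot(rank %in% TAX_RANKS)
  names <- assignments[[rank]][match(rownames(ab_matrix), assignments$otu_id)]
  names[is.na(names) | names == UNASSIGNED] <- "unassigned"
  out <- rowsum(ab_matrix, group = names)
  storage.mode(out) <- "integer"
  out[order(rownames(out)), , drop = FALSE]
}
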