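# fixture builders and independent oracles shared across test files

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

rand_read_set <- function(n, len = 60, with_quals = TRUE) {
  read_set(sprintf("rd%03d", seq_len(n)), rand_dna(n, len),
           quals = if (with_quals)
             lapply(seq_len(n), function(i) sample(2:40, len, replace = TRUE))
           else NULL)
}

write_tmp_fastq <- function(rs, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(rs, path)
  path
}

# independent expected-error oracle: explicit per-base loop
ee_oracle <- function(q) {
  total <- 0
  for (qi in q) total <- total + 10^(-qi / 10)
  total
}

# independent identity oracle via Biostrings glocal alignment
# (pattern = shorter sequence aligned in full, same scoring scheme)
identity_oracle <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# small reference taxonomy table from lineage strings ("a;b;c" padded)
ref_tax_from <- function(ids, lineages) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(ids, lineages, sep = "\t"), path)
  read_reference_taxonomy(path)
}

# a hit data.frame in the shape align_hit_table/read_blast_table produce
make_hits <- function(qseqid, sseqid, pident, bitscore = NULL) {
  n <- length(sseqid)
  data.frame(qseqid = rep_len(qseqid, n), sseqid = sseqid,
             pident = rep_len(pident, n), length = rep_len(250L, n),
             bitscore = if (is.null(bitscore)) rep_len(pident, n)
                        else rep_len(bitscore, n),
             evalue = rep_len(0, n), stringsAsFactors = FALSE)
}

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

# random reference taxonomy: n refs, random names per rank from small pools,
# random truncation depth (deeper ranks unassigned)
rand_ref_tax <- function(n_refs, pool = 3, seed_names = "T") {
  mk <- function(rank_i, k) paste0(seed_names, rank_i, "_", k)
  rows <- lapply(seq_len(n_refs), function(i) {
    depth <- sample(0:7, 1, prob = c(1, 1, 1, 1, 2, 2, 3, 4))
    nm <- vapply(seq_len(7), function(r)
      if (r <= depth) mk(r, sample.int(pool, 1)) else "", "")
    paste(nm[nzchar(nm)], collapse = ";")
  })
  ref_tax_from(sprintf("ref%03d", seq_len(n_refs)), unlist(rows))
}

rand_hit_table <- function(ref_tax, max_hits = 20) {
  n <- sample.int(max_hits, 1)
  make_hits("q", sample(ref_tax$subject_id, n, replace = TRUE),
            pident = round(runif(n, 80, 100), 2),
            bitscore = round(runif(n, 100, 500), 1))
}

# ---- independent LCA oracle: exhaustive recount, written against the rules
# rather than the implementation (different code path: lineage-string walk)
lca_oracle <- function(hits, ref_tax, window = 1.5, max_hits = 200,
                       frac = 0.9,
                       caps = c(phylum = 78, class = 88, order = 91,
                                family = 93, genus = 95, species = 97)) {
  path <- setNames(rep("?", 7), RANKS)
  if (!nrow(hits)) return(path)
  # one vote per subject: best pident, then best bitscore
  subj <- unique(hits$sseqid)
  dd <- do.call(rbind, lapply(subj, function(s) {
    h <- hits[hits$sseqid == s, , drop = FALSE]
    h <- h[h$pident == max(h$pident), , drop = FALSE]
    h[which.max(h$bitscore), , drop = FALSE]
  }))
  best <- max(dd$pident)
  dd <- dd[dd$pident >= best - window, , drop = FALSE]
  if (nrow(dd) > max_hits) {
    ord <- order(-dd$pident, -dd$bitscore, dd$sseqid)
    dd <- dd[ord[seq_len(max_hits)], , drop = FALSE]
  }
  for (r in seq_len(7)) {
    rank <- RANKS[r]
    if (r > 1 && best < caps[[rank]]) break
    votes <- ref_tax[[rank]][match(dd$sseqid, ref_tax$subject_id)]
    votes <- votes[votes != "?"]
    if (!length(votes)) break
    counts <- table(votes)
    winner <- names(counts)[which.max(counts)]
    if (max(counts) / length(votes) <= frac) break
    path[rank] <- winner
  }
  path
}
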