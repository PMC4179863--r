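#' Simulation settings for classifier validation
#'
#' @param n_reads number of simulated reads.
#' @param read_length truncation length in bp (the 5' prefix is taken, as
#'   amplicons share the 5' primer-proximal region).
#' @param per_base_mutation_rate i.i.d. substitution probability per base
#'   (uniform over the 3 alternative bases); indels optional.
#' @param rng_seed integer seed; all randomness is drawn from it.
#' @param exclude_self drop each query's own source reference from the
#'   searchable database (the held-out evaluation design).
#' @param exclude_relatives_identity optional percent identity; database
#'   hits at or above it are additionally ignored, emulating a query whose
#'   close relatives are absent from the reference database.
#' @param indel_rate optional i.i.d. per-base indel probability (0 by
#'   default; substitution-only is the reference model).
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_reads = 200L, read_length = 250L,
                     per_base_mutation_rate = 0.01, rng_seed = 1L,
                     exclude_self = TRUE,
                     exclude_relatives_identity = NULL,
                     indel_rate = 0) {
  stopifnot(per_base_mutation_rate >= 0, per_base_mutation_rate < 1,
            read_length >= 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 per_base_mutation_rate = per_base_mutation_rate,
                 rng_seed = as.integer(rng_seed),
                 exclude_self = exclude_self,
                 exclude_relatives_identity = exclude_relatives_identity,
                 indel_rate = indel_rate),
            class = "sim_spec")
}

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES4, len, replace = TRUE),
                                  collapse = "")

mutate_seq <- function(seq, rate, indel_rate = 0) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(BASES4, v[i]), 1)
  if (indel_rate > 0) {
    keep <- runif(length(v)) >= indel_rate / 2
    v <- v[keep]
    ins <- which(runif(length(v)) < indel_rate / 2)
    if (length(ins)) {
      for (i in rev(ins)) v <- append(v, sample(BASES4, 1), after = i)
    }
  }
  paste(v, collapse = "")
}

#' Synthesize a hierarchically structured 16S-like reference database
#'
#' Builds a labeled reference set by evolving sequences down a taxonomy
#' tree: one root per phylum, then class/order/family/genus ancestors,
#' each diverging from its parent by a per-level substitution rate chosen
#' so that within-genus species pairs sit near the species identity cap
#' while higher ranks are progressively more divergent. This mimics the
#' identity structure of real 16S taxonomy (approximately, and without
#' conserved/variable region architecture).
#'
#' @param n_species number of leaf references.
#' @param seq_length reference length in bp.
#' @param rng_seed integer seed.
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family
#'   branching factors of the taxonomy tree (species fill genera round-robin).
#' @param level_rates per-level divergence (substitution rates from the
#'   parent ancestor) for phylum, class, order, family, genus, species.
#' @return list with `refs` (named character vector of sequences) and
#'   `taxonomy` (data.frame `subject_id` + 7 rank columns).
#' @export
synthesize_reference_db <- function(n_species = 200L, seq_length = 450L,
                                    rng_seed = 1L, n_phyla = 4L,
                                    classes_per_phylum = 2L,
                                    orders_per_class = 2L,
                                    families_per_order = 2L,
                                    genera_per_family = 3L,
                                    level_rates = c(phylum = 0.16,
                                                    class = 0.08,
                                                    order = 0.05,
                                                    family = 0.035,
                                                    genus = 0.02,
                                                    species = 0.008)) {
  with_seed(rng_seed, {
    root <- random_seq(seq_length)
    tree <- list()
    for (p in seq_len(n_phyla)) {
      pseq <- mutate_seq(root, level_rates[["phylum"]])
      for (cl in seq_len(classes_per_phylum)) {
        cseq <- mutate_seq(pseq, level_rates[["class"]])
        for (o in seq_len(orders_per_class)) {
          oseq <- mutate_seq(cseq, level_rates[["order"]])
          for (f in seq_len(families_per_order)) {
            fseq <- mutate_seq(oseq, level_rates[["family"]])
            for (g in seq_len(genera_per_family)) {
              gseq <- mutate_seq(fseq, level_rates[["genus"]])
              tree[[length(tree) + 1]] <- list(
                lineage = c("Bacteria",
                            paste0("Phylum", p),
                            paste0("Class", p, ".", cl),
                            paste0("Order", p, ".", cl, ".", o),
                            paste0("Family", p, ".", cl, ".", o, ".", f),
                            paste0("Genus", p, ".", cl, ".", o, ".", f,
                                   ".", g)),
                seq = gseq)
            }
          }
        }
      }
    }
    refs <- character(n_species)
    tax <- matrix("", n_species, 7)
    for (s in seq_len(n_species)) {
      node <- tree[[((s - 1) %% length(tree)) + 1]]
      refs[s] <- mutate_seq(node$seq, level_rates[["species"]])
      tax[s, ] <- c(node$lineage, paste0("Species", s))
    }
    ids <- sprintf("Ref_%04d", seq_len(n_species))
    names(refs) <- ids
    taxonomy <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
                      as.data.frame(tax, stringsAsFactors = FALSE))
    names(taxonomy)[-1] <- TAX_RANKS
    list(refs = refs, taxonomy = taxonomy)
  })
}

# run code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate truncated, mutated reads from a labeled reference set
#'
#' Each simulated read is the 5' `read_length` prefix of a sampled
#' reference with i.i.d. substitutions at `per_base_mutation_rate`
#' (uniform over the 3 alternatives), carrying its source's lineage as
#' truth. Deterministic under `spec$rng_seed`. References shorter than
#' `read_length` are skipped with a warning.
#'
#' @param refs named character vector of reference sequences.
#' @param taxonomy reference taxonomy data.frame (`subject_id` + 7 ranks).
#' @param spec a [sim_spec()].
#' @return list with `reads` (a [read_set()]) and `truth` (data.frame
#'   `read_id`, `source_id` + 7 rank columns).
#' @export
simulate_reads <- function(refs, taxonomy, spec = sim_spec()) {
  if (!length(refs)) stop("empty reference set")
  short <- nchar(refs) < spec$read_length
  if (any(short)) {
    warning(sum(short), " references shorter than read_length skipped")
    refs <- refs[!short]
  }
  if (!length(refs)) stop("no reference is at least read_length long")
  with_seed(spec$rng_seed, {
    src <- sample(names(refs), spec$n_reads,
                  replace = spec$n_reads > length(refs))
    bases <- vapply(src, function(id)
      mutate_seq(substr(refs[[id]], 1L, spec$read_length),
                 spec$per_base_mutation_rate, spec$indel_rate), "")
    ids <- sprintf("sim_%05d", seq_len(spec$n_reads))
    truth <- cbind(data.frame(read_id = ids, source_id = src,
                              stringsAsFactors = FALSE),
                   taxonomy[match(src, taxonomy$subject_id), TAX_RANKS])
    rownames(truth) <- NULL
    list(reads = read_set(ids, unname(bases)), truth = truth)
  })
}

#' Build an alignment hit table by all-vs-all pairwise alignment
#'
#' The in-package stand-in for an external aligner at test scale: every
#' query is aligned against every reference with the package's end-gap-free
#' aligner, emitting BLAST-tabular-like hit records (bitscore = match
#' count; evalue 0). Hits below `min_identity` are dropped to keep tables
#' small; the LCA window only ever consults near-best hits.
#'
#' @param rs query [read_set()].
#' @param refs named character vector of reference sequences.
#' @param min_identity report floor, fraction (default 0.6).
#' @return data.frame of hits (qseqid, sseqid, pident, length, bitscore,
#'   evalue).
#' @export
align_hit_table <- function(rs, refs, min_identity = 0.6) {
  out <- vector("list", length(refs))
  for (k in seq_along(refs)) {
    st <- cpp_align_many(rs$bases, refs[[k]])
    ident <- ifelse(st$columns > 0, st$matches / st$columns, 0)
    keep <- which(ident >= min_identity)
    if (length(keep))
      out[[k]] <- data.frame(qseqid = rs$read_id[keep],
                             sseqid = names(refs)[k],
                             pident = 100 * ident[keep],
                             length = st$columns[keep],
                             bitscore = st$matches[keep],
                             evalue = 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify simulated reads against their reference database
#'
#' Runs the windowed LCA classifier on an all-vs-all hit table, honouring
#' the simulation's exclusion switches: `exclude_self` removes each
#' query's own source reference from its hits, and
#' `exclude_relatives_identity` drops all hits at or above that percent
#' identity (no close relative in the database).
#'
#' @param sim output of [simulate_reads()].
#' @param refs named character vector of references.
#' @param taxonomy reference taxonomy data.frame.
#' @param spec the [sim_spec()] used for simulation.
#' @param lspec an [lca_spec()].
#' @param hits optional precomputed hit table (e.g. from a real aligner);
#'   computed via [align_hit_table()] when missing.
#' @return data.frame of predicted paths (`read_id` + 7 rank columns).
#' @export
classify_simulated <- function(sim, refs, taxonomy, spec = sim_spec(),
                               lspec = lca_spec(), hits = NULL) {
  if (is.null(hits)) hits <- align_hit_table(sim$reads, refs)
  if (spec$exclude_self && nrow(hits)) {
    src <- sim$truth$source_id[match(hits$qseqid, sim$truth$read_id)]
    hits <- hits[hits$sseqid != src, , drop = FALSE]
  }
  if (!is.null(spec$exclude_relatives_identity) && nrow(hits))
    hits <- hits[hits$pident < spec$exclude_relatives_identity, , drop = FALSE]
  res <- classify_all(sim$reads$read_id, hits, taxonomy, lspec)
  names(res)[1] <- "read_id"
  res
}

#' Score predicted against true lineages per rank
#'
#' Per rank: TP = assigned and equal to truth; FP = assigned and
#' different; among unassigned predictions, TN when the truth itself lacks
#' the rank, FN otherwise. Precision = TP/(TP+FP), specificity =
#' TN/(TN+FP); either is reported as `NA` when its denominator is zero.
#' `unassigned_fraction` is the fraction of reads without an assignment at
#' the rank.
#'
#' @param predicted data.frame `read_id` + 7 rank columns.
#' @param truth data.frame `read_id` + 7 rank columns.
#' @return data.frame, one row per rank: TP, FP, TN, FN, precision,
#'   specificity, unassigned_fraction.
#' @export
evaluate_assignments <- function(predicted, truth) {
  if (!setequal(predicted$read_id, truth$read_id))
    stop("predicted and truth read ids do not match")
  truth <- truth[match(predicted$read_id, truth$read_id), , drop = FALSE]
  n <- nrow(predicted)
  rows <- lapply(TAX_RANKS, function(r) {
    p <- predicted[[r]]
    t <- truth[[r]]
    assigned <- p != UNASSIGNED
    tp <- sum(assigned & p == t)
    fp <- sum(assigned & p != t)
    tn <- sum(!assigned & t == UNASSIGNED)
    fn <- sum(!assigned & t != UNASSIGNED)
    data.frame(rank = r, TP = tp, FP = fp, TN = tn, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               unassigned_fraction = (tn + fn) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classification performance as a function of read length
#'
#' Runs simulate -> classify -> evaluate for each read length, holding the
#' reference set and all other settings fixed. The expected behaviour on a
#' structured database is that longer reads resolve identity better and
#' leave a smaller fraction of reads unassigned.
#'
#' @param refs,taxonomy the reference database.
#' @param lengths integer vector of read lengths (>= 2 values).
#' @param spec a [sim_spec()] (its `read_length` is overridden).
#' @param lspec an [lca_spec()].
#' @param out_tsv optional path; when given, the table is written as TSV.
#' @return data.frame: rank x length evaluation rows with a `read_length`
#'   column.
#' @export
length_sweep <- function(refs, taxonomy, lengths, spec = sim_spec(),
                         lspec = lca_spec(), out_tsv = NULL) {
  stopifnot(length(lengths) >= 2)
  rows <- lapply(lengths, function(L) {
    sp <- spec
    sp$read_length <- as.integer(L)
    sim <- simulate_reads(refs, taxonomy, sp)
    pred <- classify_simulated(sim, refs, taxonomy, sp, lspec)
    ev <- evaluate_assignments(pred, sim$truth)
    cbind(read_length = L, ev)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_tsv))
    write.table(out, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Synthesize a multiplexed sequencing run
#'
#' The end-to-end fixture generator: reads are drawn from a few template
#' sequences (mutated lightly), prefixed with per-sample barcodes and an
#' optional primer, and given plateau-then-decaying quality profiles so
#' that high-, mid- and rejected bins are all populated. Returns the
#' multiplexed reads, the mapping table and the per-read truth template.
#'
#' @param n_reads total reads.
#' @param n_samples number of samples/barcodes.
#' @param templates optional character vector of template sequences;
#'   by default 3 random 420 bp templates mutually < 90% identical.
#' @param rng_seed integer seed.
#' @param template_length template length when templates are generated.
#' @param mutation_rate per-base substitution rate applied per read.
#' @param frac_mid_quality fraction of reads given a uniformly mediocre
#'   quality profile (passes the relaxed band only: mid bin).
#' @param frac_reject fraction of reads given a steeply decaying profile
#'   (window-trimmed below the length floor: rejected).
#' @param frac_bad_barcode fraction of reads given a non-mapping barcode.
#' @param primer forward primer placed between barcode and insert
#'   (`NULL` for none).
#' @return list with `reads` (multiplexed [read_set()]), `mapping`
#'   (data.frame as from [read_mapping()]), `truth` (read_id -> template
#'   index) and `templates`.
#' @export
synthesize_run <- function(n_reads = 1000L, n_samples = 4L,
                           templates = NULL, rng_seed = 1L,
                           template_length = 420L, mutation_rate = 0.005,
                           frac_mid_quality = 0.1, frac_reject = 0.05,
                           frac_bad_barcode = 0,
                           primer = "GTGCCAGCMGCCGCGGTAA") {
  with_seed(rng_seed, {
    if (is.null(templates)) {
      repeat {
        templates <- vapply(1:3, function(i) random_seq(template_length), "")
        ok <- TRUE
        for (i in 1:2) for (j in (i + 1):3)
          if (seq_identity(templates[i], templates[j]) >= 0.9) ok <- FALSE
        if (ok) break
      }
    }
    barcodes <- c("ACGTACGT", "TGCATGCA", "GATCGATC", "CTAGCTAG",
                  "AAGGTTCC", "GGCCAATT", "TTAACCGG", "CCGGTTAA")
    if (n_samples > length(barcodes)) stop("at most 8 samples supported")
    barcodes <- barcodes[seq_len(n_samples)]
    mapping <- data.frame(sample_id = paste0("S", seq_len(n_samples)),
                          barcode = barcodes,
                          fwd_primer = if (is.null(primer)) NA_character_
                                       else primer,
                          rev_primer = NA_character_,
                          stringsAsFactors = FALSE)
    tmpl_idx <- sample(seq_along(templates), n_reads, replace = TRUE)
    samp_idx <- sample(seq_len(n_samples), n_reads, replace = TRUE)
    u <- runif(n_reads)
    profile <- ifelse(u < frac_reject, "reject",
                      ifelse(u < frac_reject + frac_mid_quality, "mid",
                             "high"))
    bad_bc <- runif(n_reads) < frac_bad_barcode
    bases <- character(n_reads)
    quals <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      insert <- mutate_seq(templates[tmpl_idx[i]], mutation_rate)
      bc <- if (bad_bc[i]) random_seq(8L) else barcodes[samp_idx[i]]
      pr <- if (is.null(primer)) "" else
        paste(vapply(strsplit(primer, "")[[1]], function(ch)
          sample(strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]], 1),
          ""), collapse = "")
      bases[i] <- paste0(bc, pr, insert)
      L <- nchar(bases[i])
      quals[[i]] <- switch(profile[i],
        # steadily high: passes avg-qual and accumulated-error thresholds
        high = pmin(40L, as.integer(38 + rbinom(L, 2, 0.3) -
                                      as.integer(seq_len(L) > 0.9 * L))),
        # uniformly mediocre: survives window trimming but fails the
        # high band on both mean quality and accumulated error
        mid = rep(26L, L),
        # steep 3' decay: window trimming cuts below the length floor
        reject = pmax(2L, as.integer(38 - 36 * (seq_len(L) / L)^1.2)))
    }
    list(reads = read_set(sprintf("run_%05d", seq_len(n_reads)), bases,
                          quals),
         mapping = mapping,
         truth = setNames(tmpl_idx, sprintf("run_%05d", seq_len(n_reads))),
         templates = templates)
  })
}
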