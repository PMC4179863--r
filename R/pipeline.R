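#' Pipeline run configuration
#'
#' @param input path to the multiplexed reads (or a [read_set()]).
#' @param mate optional reverse-mate path/read set.
#' @param mapping path to the mapping file (or a mapping data.frame), or
#'   `NULL` to skip demultiplexing.
#' @param options path to a filter option file, or a [filter_spec()].
#' @param outdir output directory; must not exist or be empty unless
#'   `overwrite`.
#' @param identity_threshold OTU radius and mapping identity (default 0.97).
#' @param lca an [lca_spec()].
#' @param blast_table optional precomputed BLAST tabular hit file (queries
#'   = OTU ids); `NULL` disables taxonomy (all ranks `"?"`).
#' @param ref_taxonomy path to the reference taxonomy TSV (required with
#'   `blast_table`).
#' @param cluster_seeds,cluster_membership optional external-clusterer
#'   output (seed FASTA + membership TSV) replacing the built-in clusterer.
#' @param tree_cmd optional external command template (with placeholders
#'   `{fasta}` and `{out}`) that builds a phylogenetic tree from the
#'   extended seeds; its output file is copied into the run folder
#'   unchanged.
#' @param overwrite allow writing into a non-empty directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input, mapping, options = filter_spec(),
                       outdir, mate = NULL, identity_threshold = 0.97,
                       lca = lca_spec(), blast_table = NULL,
                       ref_taxonomy = NULL, cluster_seeds = NULL,
                       cluster_membership = NULL, tree_cmd = NULL,
                       overwrite = FALSE) {
  structure(list(input = input, mate = mate, mapping = mapping,
                 options = options, outdir = outdir,
                 identity_threshold = identity_threshold, lca = lca,
                 blast_table = blast_table, ref_taxonomy = ref_taxonomy,
                 cluster_seeds = cluster_seeds,
                 cluster_membership = cluster_membership,
                 tree_cmd = tree_cmd, overwrite = overwrite),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages, in order: demultiplex + filter, OTU clustering on the truncated
#' high bin, read-to-OTU abundance mapping (high + mid), seed extension,
#' taxonomy (when a hit table is configured), per-rank aggregation, and
#' writers. The output folder receives `OTU_table.tsv`,
#' `OTU_taxonomy.tsv`, `seeds.fasta`, `table.biom` and the subfolders
#' `logs/`, `config/` and `higher_taxa/` (one TSV per rank). A stage
#' failure aborts with the stage name; partial outputs are retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory artifacts
#'   (`demux`, `clusters`, `abundance`, `taxonomy`, `log`).
#' @export
run_pipeline <- function(config) {
  out <- config$outdir
  if (dir.exists(out) && length(dir(out, all.files = TRUE, no.. = TRUE)) &&
      !config$overwrite)
    stop("output directory exists and is not empty: ", out)
  for (d in c(out, file.path(out, c("logs", "config", "higher_taxa"))))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)

  log <- list()
  stamp <- function(stage, ...) {
    log[[stage]] <<- list(stage = stage, time = format(Sys.time()),
                          counts = list(...))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed (see ",
           file.path(out, "logs"), "): ", conditionMessage(e),
           call. = FALSE))
  }

  spec <- if (inherits(config$options, "filter_spec")) config$options
          else read_filter_options(config$options)
  mapping <- if (is.null(config$mapping)) NULL
             else if (is.data.frame(config$mapping)) config$mapping
             else read_mapping(config$mapping)
  write_filter_options(spec, file.path(out, "config", "filter_options.txt"))
  if (!is.null(mapping))
    write.table(mapping, file.path(out, "config", "mapping.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # -- demultiplex + filter
  demux <- run_stage("demultiplex", {
    rs <- config$input
    if (is.character(rs)) rs <- read_sequences(rs)
    mates <- config$mate
    if (is.character(mates)) mates <- read_sequences(mates)
    demultiplex_run(rs, mapping, spec, mates = mates)
  })
  stamp("demultiplex", input = demux$n_input, high = nrow(demux$high),
        mid = nrow(demux$mid), unassigned = demux$n_unassigned)

  # -- clustering (built-in greedy, or external import)
  clusters <- run_stage("cluster", {
    if (!is.null(config$cluster_seeds))
      import_external_clusters(config$cluster_seeds,
                               config$cluster_membership)
    else cluster_otus(dereplicate(demux$high_trunc),
                      config$identity_threshold)
  })
  clusters <- merge_overlapping_otus(clusters, config$identity_threshold)
  stamp("cluster", otus = length(clusters))

  # -- abundance mapping on full-length high + mid reads
  abundance <- run_stage("map", {
    map_reads_to_otus(bind_reads(demux$high, demux$mid), clusters,
                      config$identity_threshold)
  })
  stamp("map", mapped = sum(abundance),
        unmapped = attr(abundance, "unmapped"))

  # -- seed extension on full-length high reads
  clusters <- run_stage("seed_extension", {
    extend_seeds(clusters, demux$high, config$identity_threshold,
                 spec$window_width, spec$window_min_qual)
  })
  stamp("seed_extension",
        extended = sum(vapply(clusters, `[[`, TRUE, "seed_extended")))
  seeds <- bind_reads(do.call(bind_reads, lapply(clusters, `[[`, "seed")))
  write_fasta(seeds, file.path(out, "seeds.fasta"))

  # -- taxonomy
  otu_ids <- vapply(clusters, `[[`, "", "otu_id")
  taxonomy <- run_stage("taxonomy", {
    if (!is.null(config$blast_table)) {
      hits <- if (is.data.frame(config$blast_table)) config$blast_table
              else read_blast_table(config$blast_table)
      ref_tax <- if (is.data.frame(config$ref_taxonomy)) config$ref_taxonomy
                 else read_reference_taxonomy(config$ref_taxonomy)
      classify_all(otu_ids, hits, ref_tax, config$lca)
    } else {
      empty <- matrix(UNASSIGNED, length(otu_ids), 7,
                      dimnames = list(NULL, TAX_RANKS))
      cbind(data.frame(otu_id = otu_ids, stringsAsFactors = FALSE),
            as.data.frame(empty, stringsAsFactors = FALSE))
    }
  })
  stamp("taxonomy",
        assigned_genus = sum(taxonomy$genus != UNASSIGNED))

  # -- writers
  run_stage("write", {
    write.table(cbind(otu_id = rownames(abundance), as.data.frame(abundance)),
                file.path(out, "OTU_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(taxonomy, file.path(out, "OTU_taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_biom(abundance, taxonomy, file.path(out, "table.biom"))
    for (r in TAX_RANKS) {
      agg <- aggregate_taxa(abundance, taxonomy, r)
      write.table(cbind(taxon = rownames(agg), as.data.frame(agg)),
                  file.path(out, "higher_taxa", paste0(r, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  stamp("write", files = length(dir(out, recursive = TRUE)))

  # -- optional external tree hook (pass-through of the tool's output)
  if (!is.null(config$tree_cmd)) run_stage("tree", {
    treefile <- file.path(out, "tree.nwk")
    cmd <- gsub("{fasta}", file.path(out, "seeds.fasta"),
                gsub("{out}", treefile, config$tree_cmd, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop("tree command exited with status ", status)
    stamp("tree", written = file.exists(treefile))
  })

  write_reports(log, demux, out)
  invisible(list(demux = demux, clusters = clusters, abundance = abundance,
                 taxonomy = taxonomy, log = log))
}

#' Write an abundance matrix as BIOM 1.0 (JSON, sparse)
#'
#' Emits the Biological Observation Matrix 1.0 interchange format with
#' sparse integer data and the 7-rank taxonomy as per-observation
#' metadata, readable by standard BIOM readers.
#'
#' @param ab_matrix integer matrix OTUs x samples.
#' @param assignments data.frame from [classify_all()] (must cover the
#'   matrix's OTU ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom <- function(ab_matrix, assignments, path) {
  otus <- rownames(ab_matrix)
  hit <- match(otus, assignments$otu_id)
  if (anyNA(hit))
    stop("assignments missing for OTU id: ", otus[which(is.na(hit))[1]])
  rows <- lapply(seq_along(otus), function(i)
    list(id = otus[i],
         metadata = list(taxonomy = as.list(
           unname(unlist(assignments[hit[i], TAX_RANKS]))))))
  cols <- lapply(colnames(ab_matrix), function(s)
    list(id = s, metadata = NULL))
  nz <- which(ab_matrix != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(k)
    c(nz[k, 1] - 1L, nz[k, 2] - 1L, ab_matrix[nz[k, 1], nz[k, 2]]))
  doc <- list(
    id = "otuflow OTU table",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("otuflow ", utils::packageVersion("otuflow")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = rows, columns = cols,
    matrix_type = "sparse", matrix_element_type = "int",
    shape = c(nrow(ab_matrix), ncol(ab_matrix)),
    data = data)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Write run reports
#'
#' A human-readable run log plus a machine-readable TSV of per-stage
#' counts into `outdir/logs/`.
#'
#' @param log stage log list (from [run_pipeline()]).
#' @param demux demultiplexing result (its `report` is written alongside).
#' @param outdir the run output directory.
#' @return invisibly, the logs directory.
#' @export
write_reports <- function(log, demux, outdir) {
  logdir <- file.path(outdir, "logs")
  dir.create(logdir, showWarnings = FALSE, recursive = TRUE)
  lines <- c(paste0("otuflow ", utils::packageVersion("otuflow"), " run"),
             "")
  rows <- list()
  for (st in log) {
    cts <- vapply(st$counts, function(x) paste(x, collapse = ","), "")
    lines <- c(lines, sprintf("[%s] %s: %s", st$time, st$stage,
                              paste(names(cts), cts, sep = "=",
                                    collapse = "  ")))
    rows[[st$stage]] <- data.frame(stage = st$stage,
                                   key = names(st$counts),
                                   value = unlist(lapply(st$counts, `[`, 1)),
                                   stringsAsFactors = FALSE)
  }
  writeLines(lines, file.path(logdir, "run_log.txt"))
  write.table(do.call(rbind, rows), file.path(logdir, "stage_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(demux$report))
    write.table(demux$report, file.path(logdir, "demux_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(logdir)
}
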