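test_that("dereplication counts exact duplicates and orders by size", {
  d <- dereplicate(c("AA", "AC", "AA"))
  expect_equal(d$sequence, c("AA", "AC"))
  expect_equal(d$size, c(2L, 1L))
  expect_equal(sum(d$size), 3L)

  distinct <- dereplicate(c("AC", "GT", "CA"))
  expect_equal(distinct$size, rep(1L, 3))
  expect_equal(distinct$sequence, sort(distinct$sequence))  # size ties: lexicographic

  expect_equal(nrow(dereplicate(character())), 0)
})

test_that("identity is glocal-alignment matches over columns", {
  set.seed(3)
  mutate_chr <- function(x, k) {
    v <- strsplit(x, "")[[1]]
    at <- sample(length(v), k)
    for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  for (i in 1:10) {
    a <- rand_dna(1, sample(80:150, 1))
    b <- mutate_chr(a, sample(2:8, 1))            # same-length variant
    expect_equal(seq_identity(a, b), identity_oracle(a, b), tolerance = 1e-9)
    p <- substr(a, sample(1:20, 1), nchar(a))      # contained fragment
    expect_equal(seq_identity(p, a), identity_oracle(p, a), tolerance = 1e-9)
  }
  expect_equal(seq_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(seq_identity(strrep("A", 10), strrep("T", 10)), 0)
  # unrelated same-length sequences must not look similar: a short perfect
  # terminal overlap is no longer enough to inflate identity
  for (i in 1:10)
    expect_lt(seq_identity(rand_dna(1, 120), rand_dna(1, 120)), 0.6)
})

test_that("greedy clustering separates templates and merges near-identical reads", {
  expect_length(cluster_otus(c("ACGTACGTACGT", "ACGTACGTACGT")), 1)
  expect_length(cluster_otus(c(strrep("A", 10), strrep("T", 10))), 2)

  # 100 reads off 3 mutually distant templates at ~1% divergence
  set.seed(21)
  run <- synthesize_run(n_reads = 100, rng_seed = 21, mutation_rate = 0.01,
                        frac_mid_quality = 0, frac_reject = 0)
  dm <- demultiplex_run(run$reads, run$mapping)
  cl <- cluster_otus(dereplicate(dm$high_trunc))
  expect_length(cl, 3)
  # within-template identity above, between-template below the radius
  # (verified against the independent alignment oracle on a sample)
  t1 <- substr(run$templates[1], 1, 250)
  t2 <- substr(run$templates[2], 1, 250)
  expect_lt(identity_oracle(t1, t2), 0.9)
})

test_that("every clustering-input read lands in exactly one cluster", {
  run <- synthesize_run(n_reads = 150, rng_seed = 4)
  dm <- demultiplex_run(run$reads, run$mapping)
  cl <- cluster_otus(dereplicate(dm$high_trunc))
  ids <- unlist(lapply(cl, `[[`, "member_read_ids"))
  expect_equal(sort(ids), sort(dm$high_trunc$read_id))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("greedy memberships agree with best-centroid assignment on separated input", {
  run <- synthesize_run(n_reads = 50, rng_seed = 13, mutation_rate = 0.005)
  dm <- demultiplex_run(run$reads, run$mapping)
  cl <- cluster_otus(dereplicate(dm$high_trunc))
  seeds <- vapply(cl, function(x) x$seed$bases[1], "")
  for (k in seq_along(cl)) {
    for (id in cl[[k]]$member_read_ids) {
      b <- dm$high_trunc$bases[dm$high_trunc$read_id == id]
      best <- which.max(vapply(seeds, function(s) identity_oracle(b, s), 0))
      expect_equal(best, k, ignore_attr = TRUE)
    }
  }
})

test_that("read mapping is best-hit with deterministic tie-breaking", {
  seeds <- list(
    list(otu_id = "OTU_0001", seed = read_set("OTU_0001", strrep("ACGT", 10)),
         member_read_ids = "a"),
    list(otu_id = "OTU_0002", seed = read_set("OTU_0002", strrep("TGCA", 10)),
         member_read_ids = "b"))
  rs <- read_set(c("x", "y", "z"),
                 c(strrep("ACGT", 10), strrep("TGCA", 10), strrep("GGCC", 10)),
                 sample = c("s1", "s2", "s1"))
  m <- map_reads_to_otus(rs, seeds, 0.97)
  expect_equal(m["OTU_0001", "s1"], 1L)
  expect_equal(m["OTU_0002", "s2"], 1L)
  expect_equal(attr(m, "unmapped"), 1L)  # "z" matches neither
  expect_equal(sum(m), 2L)

  # a read identical to both seeds goes to the smaller otu_id
  both <- list(seeds[[1]],
               list(otu_id = "OTU_0002",
                    seed = read_set("OTU_0002", strrep("ACGT", 10)),
                    member_read_ids = "b"))
  tie <- map_reads_to_otus(read_set("t", strrep("ACGT", 10), sample = "s"),
                           both, 0.97)
  expect_equal(tie["OTU_0001", "s"], 1L)
  expect_equal(tie["OTU_0002", "s"], 0L)
})

test_that("mapped plus unmapped reads account for every input read", {
  run <- synthesize_run(n_reads = 250, rng_seed = 6, frac_mid_quality = 0.2)
  dm <- demultiplex_run(run$reads, run$mapping)
  cl <- cluster_otus(dereplicate(dm$high_trunc))
  pool <- otuflow:::bind_reads(dm$high, dm$mid)
  m <- map_reads_to_otus(pool, cl)
  expect_equal(sum(m) + attr(m, "unmapped"), n_reads(pool))
  # per-sample column sums never exceed the high+mid pool of that sample
  pool_per_sample <- table(pool$sample)
  expect_true(all(colSums(m) <= as.integer(pool_per_sample[colnames(m)])))
})

test_that("overlapping seeds are reported and merging is idempotent", {
  base <- strrep("ACGTTGCA", 25)
  variant <- sub("^AC", "AA", base)   # 99% identical variant
  clusters <- list(
    list(otu_id = "OTU_0001", seed = read_set("OTU_0001", base),
         member_read_ids = c("a", "b", "c")),
    list(otu_id = "OTU_0002", seed = read_set("OTU_0002", variant),
         member_read_ids = "d"),
    list(otu_id = "OTU_0003", seed = read_set("OTU_0003", strrep("GATC", 50)),
         member_read_ids = "e"))
  ov <- check_otu_overlap(clusters, 0.97)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$otu_a, "OTU_0001")
  expect_equal(ov$otu_b, "OTU_0002")
  expect_gte(ov$identity, identity_oracle(base, variant) - 1e-9)

  merged <- merge_overlapping_otus(clusters, 0.97)
  expect_length(merged, 2)
  # the larger OTU absorbed the smaller's members
  expect_setequal(merged[[1]]$member_read_ids, c("a", "b", "c", "d"))
  expect_equal(nrow(check_otu_overlap(merged, 0.97)), 0)

  expect_equal(nrow(check_otu_overlap(clusters[3], 0.97)), 0)  # single seed
})

test_that("external clusterer output imports as clusters", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">OTU_A", strrep("ACGT", 20), ">OTU_B", strrep("GGCA", 20)), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tOTU_A", "r2\tOTU_A", "r3\tOTU_B"), tsv)
  cl <- import_external_clusters(fa, tsv)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$member_read_ids, c("r1", "r2"))
  writeLines(c("r1\tOTU_MISSING"), tsv)
  expect_error(import_external_clusters(fa, tsv), "OTU_MISSING")
})
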