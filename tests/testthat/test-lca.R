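# a fully annotated mini-reference shared by several blocks
FULL_TAX <- ref_tax_from(
  c("g1", "g2", "g3", "p1", "p2"),
  c("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;B.fragilis",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;B.fragilis",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;B.fragilis",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia;B.producta",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia;B.producta"))

test_that("taxonomy tables parse prefixes and enforce truncation semantics", {
  tax <- ref_tax_from(
    c("a", "b", "c"),
    c("k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__;g__;s__",
      "Bacteria;Proteobacteria",
      "Bacteria;;Gammaproteobacteria"))  # gap forces deeper ranks unassigned
  expect_equal(tax$phylum, c("Firmicutes", "Proteobacteria", "?"))
  expect_equal(tax$family[1], "?")
  expect_equal(tax$class[3], "?")        # truncation propagates past the gap
  expect_error(ref_tax_from(c("x", "x"), c("Bacteria", "Bacteria")),
               "duplicate")
})

test_that("the identity window retains hits near the best and caps the count", {
  hits <- make_hits("q", c("g1", "g2", "g3"), c(99.0, 97.6, 97.4))
  kept <- filter_hits(hits, lca_spec())
  expect_setequal(kept$sseqid, c("g1", "g2"))   # 97.6 in, 97.4 out

  many <- make_hits("q", sprintf("r%03d", 1:250), rep(98, 250))
  expect_equal(nrow(filter_hits(many, lca_spec())), 200)

  one <- make_hits("q", "g1", 91.2)
  expect_equal(nrow(filter_hits(one, lca_spec())), 1)
  expect_equal(nrow(filter_hits(one[0, ], lca_spec())), 0)
})

test_that("best-hit identity caps the assignable depth", {
  caps <- lca_spec()$depth_caps
  expect_equal(depth_cap(96.0, caps), "genus")
  expect_equal(depth_cap(97.0, caps), "species")
  expect_equal(depth_cap(70.0, caps), "domain")
  expect_equal(depth_cap(94.0, caps), "family")
  expect_equal(depth_cap(100, caps), "species")
  # the literal printed cap arrangement remains available
  lit <- lca_spec(literal_printed_caps = TRUE)$depth_caps
  expect_equal(lit[["class"]], 91)
  expect_equal(lit[["order"]], 88)
})

test_that("rank votes need a strict majority among annotated references", {
  tax <- ref_tax_from(
    sprintf("r%02d", 1:10),
    c(rep("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides", 9),
      "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella"))
  # 9/10 = 0.9 is NOT > 0.9: no call
  v <- rank_vote(sprintf("r%02d", 1:10), tax, "genus", 0.9)
  expect_true(is.na(v$name))
  # unanimity passes
  v2 <- rank_vote(sprintf("r%02d", 1:9), tax, "genus", 0.9)
  expect_equal(v2$name, "Bacteroides")
  expect_error(rank_vote("missing", tax, "genus"), "missing")
})

test_that("a single annotated reference outvotes unannotated ones", {
  tax <- ref_tax_from(
    c("s1", "u1", "u2", "u3", "u4"),
    c("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;B.fragilis",
      rep("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides", 4)))
  hits <- make_hits("q", c("s1", "u1", "u2", "u3", "u4"), rep(99, 5))
  path <- lca_assign(hits, tax)
  expect_equal(path[["species"]], "B.fragilis")
})

test_that("assignment walks down ranks and stops at the cap or a failed vote", {
  # unanimous full lineage at high identity: complete 7-rank path
  h99 <- make_hits("q", c("g1", "g2", "g3"), c(99, 98.5, 98.2))
  p99 <- lca_assign(h99, FULL_TAX)
  expect_equal(unname(p99),
               c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
                 "Bacteroidaceae", "Bacteroides", "B.fragilis"))

  # same hits at 96% best identity: truncated after genus
  h96 <- make_hits("q", c("g1", "g2", "g3"), c(96, 95.6, 95.2))
  p96 <- lca_assign(h96, FULL_TAX)
  expect_equal(p96[["genus"]], "Bacteroides")
  expect_equal(p96[["species"]], "?")

  # a 50/50 split at phylum leaves only the domain assigned
  hsplit <- make_hits("q", c("g1", "g2", "p1", "p2"), rep(99, 4))
  psplit <- lca_assign(hsplit, FULL_TAX)
  expect_equal(psplit[["domain"]], "Bacteria")
  expect_equal(psplit[["phylum"]], "?")

  expect_equal(unname(lca_assign(make_hits("q", character(0), numeric(0)),
                                 FULL_TAX)), rep("?", 7))
})

test_that("multiple HSPs to one subject count as one vote", {
  tax <- ref_tax_from(
    c("dup", "other1", "other2"),
    c("Bacteria;Firmicutes", "Bacteria;Bacteroidetes", "Bacteria;Bacteroidetes"))
  # 8 HSPs to 'dup' would dominate a raw vote; deduplicated it is 1 of 3
  hits <- make_hits("q", c(rep("dup", 8), "other1", "other2"),
                    c(rep(99, 8), 98.8, 98.6))
  path <- lca_assign(hits, tax)
  expect_equal(path[["phylum"]], "?")   # 2/3 Bacteroidetes is not > 0.9
  expect_equal(path[["domain"]], "Bacteria")
})

test_that("hit order never changes the assignment", {
  set.seed(23)
  tax <- rand_ref_tax(12)
  for (i in 1:20) {
    hits <- rand_hit_table(tax)
    p <- lca_assign(hits, tax)
    perm <- hits[sample(nrow(hits)), , drop = FALSE]
    expect_identical(lca_assign(perm, tax), p)
  }
})

test_that("scaling identities down never deepens the assignment", {
  # with consensus held fixed (unanimous lineage), the depth cap is the
  # only binding constraint and must be monotone in the best-hit identity
  set.seed(29)
  lineage <- "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;L.reuteri"
  tax <- ref_tax_from(sprintf("m%02d", 1:10), rep(lineage, 10))
  depth_of <- function(p) sum(p != "?")
  for (i in 1:20) {
    hits <- rand_hit_table(tax)
    d_full <- depth_of(lca_assign(hits, tax))
    for (f in c(0.99, 0.97, 0.92, 0.8)) {
      scaled <- hits
      scaled$pident <- hits$pident * f
      expect_lte(depth_of(lca_assign(scaled, tax)), d_full)
    }
  }
})

test_that("assignment equals the exhaustive-recount oracle on random tables", {
  set.seed(31)
  tax <- rand_ref_tax(15)
  for (i in 1:300) {
    hits <- rand_hit_table(tax)
    expect_identical(unname(lca_assign(hits, tax, lca_spec())),
                     unname(lca_oracle(hits, tax)))
  }
})

test_that("classify_all covers every seed and tolerates noise in the table", {
  hits <- rbind(make_hits("OTU_1", c("g1", "g2"), c(99, 98.5)),
                make_hits("OTU_2", c("g1", "g2", "g3"), c(96, 95.8, 95.1)),
                make_hits("ghost", "g1", 99))
  expect_warning(res <- classify_all(c("OTU_1", "OTU_2", "OTU_3"), hits,
                                     FULL_TAX), "ghost")
  expect_equal(res$otu_id, c("OTU_1", "OTU_2", "OTU_3"))
  expect_equal(res$species[1], "B.fragilis")
  expect_equal(res$species[2], "?")          # capped at genus
  expect_equal(res$genus[2], "Bacteroides")
  expect_equal(unname(unlist(res[3, -1])), rep("?", 7))  # no hits at all

  # duplicated hit lines change nothing
  res2 <- suppressWarnings(classify_all(c("OTU_1", "OTU_2", "OTU_3"),
                                        rbind(hits, hits), FULL_TAX))
  expect_identical(res2, res)
})

test_that("aggregation preserves totals and pools unassigned OTUs", {
  m <- matrix(c(5L, 3L, 2L, 0L, 1L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("sA", "sB")))
  assign <- data.frame(otu_id = c("OTU_1", "OTU_2", "OTU_3"),
                       stringsAsFactors = FALSE)
  for (r in RANKS) assign[[r]] <- c("X", "X", "?")
  g <- aggregate_taxa(m, assign, "genus")
  expect_equal(g["X", ], c(sA = 7L, sB = 3L))
  expect_equal(g["unassigned", ], c(sA = 1L, sB = 4L))
  expect_equal(sum(g), sum(m))
  for (r in RANKS) expect_equal(sum(aggregate_taxa(m, assign, r)), sum(m))
})

test_that("unanimous full-lineage hits above the species cap recover the lineage", {
  set.seed(37)
  lineage <- "Bacteria;Actinobacteria;Actinomycetia;Micrococcales;Micrococcaceae;Rothia;R.aeria"
  tax <- ref_tax_from(sprintf("n%02d", 1:6), rep(lineage, 6))
  for (i in 1:10) {
    k <- sample(2:6, 1)
    hits <- make_hits("q", sample(tax$subject_id, k),
                      round(runif(k, 97.2, 100), 2))
    p <- lca_assign(hits, tax)
    expect_equal(unname(p), strsplit(lineage, ";")[[1]])
  }
})
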