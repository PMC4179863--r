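test_that("expected error follows the per-base error-probability sum", {
  expect_equal(expected_error(rep(20L, 10)), 0.1)
  expect_equal(expected_error(integer()), 0)
  expect_equal(expected_error(c(10L, 20L, 30L)), 0.111)
  expect_error(expected_error(c(10L, -1L)), "negative")
})

test_that("expected error agrees with a direct summation oracle", {
  set.seed(11)
  for (i in 1:200) {
    q <- sample(0:41, sample(1:300, 1), replace = TRUE)
    expect_equal(expected_error(q), ee_oracle(q), tolerance = 1e-12)
  }
})

test_that("barcode matching assigns unique minima and trims; ties stay unassigned", {
  mapping <- data.frame(sample_id = c("S1", "S2"),
                        barcode = c("ACGT", "ACGA"),
                        fwd_primer = NA, rev_primer = NA,
                        stringsAsFactors = FALSE)
  rs <- read_set(c("exact", "onemm", "tie", "none"),
                 c("ACGTTTTTTTTT", "ACCTTTTTTTTT", "ACGCTTTTTTTT",
                   "GGGGTTTTTTTT"),
                 lapply(1:4, function(i) rep(35L, 12)))
  r0 <- match_barcode(rs, mapping, max_mismatch = 0)
  expect_equal(r0$sample, c("S1", NA, NA, NA))
  expect_equal(r0$bases[1], "TTTTTTTT")
  expect_equal(length(r0$quals[[1]]), 8)

  r1 <- match_barcode(rs, mapping, max_mismatch = 1)
  # brute-force Hamming over both barcodes confirms: "ACCT" is uniquely
  # closest to ACGT (d=1 vs d=2); "ACGC" ties both at d=1
  expect_equal(r1$sample, c("S1", "S1", NA, NA))
  expect_equal(r1$bases[3], rs$bases[3])  # unassigned reads keep the barcode
})

test_that("degenerate primer positions match their IUPAC set at zero cost", {
  rs <- read_set("r", "GTGACAGAAAA", list(rep(30L, 11)))
  m <- match_primer(rs, "GTGNCAG", 0)
  expect_true(m$found)
  expect_equal(m$reads$bases, "AAAA")

  m2 <- match_primer(rs, "GTGYCAG", 0)   # Y = C/T, read has A
  expect_false(m2$found)
  m3 <- match_primer(rs, "GTGYCAG", 1)
  expect_true(m3$found)
})

test_that("window trimming cuts at the first failing window", {
  good <- read_set("g", strrep("ACGT", 25), list(rep(40L, 100)))
  expect_equal(trim_low_quality_tail(good, 10, 20), good)

  q <- c(rep(40L, 80), rep(2L, 20))
  rs <- read_set("r", strrep("ACGT", 25), list(q))
  # direct window-mean scan: the first window with mean < 20 is the one
  # starting at base 77 (4xQ40 + 6xQ2 = 17.2), so 76 bases survive
  cut <- trim_low_quality_tail(rs, 10, 20)
  expect_equal(nchar(cut$bases), 76)
  expect_equal(length(cut$quals[[1]]), 76)

  short <- read_set("s", "ACGTA", list(rep(2L, 5)))
  expect_equal(trim_low_quality_tail(short, 10, 20), short)

  # 5' mode removes the head instead
  q5 <- c(rep(2L, 20), rep(40L, 80))
  rs5 <- read_set("r5", strrep("ACGT", 25), list(q5))
  cut5 <- trim_low_quality_tail(rs5, 10, 20, direction = "5p")
  expect_equal(nchar(cut5$bases), 76)
})

test_that("reads are binned high/mid/rejected per the quality bands", {
  spec <- filter_spec(min_len = 250, max_expected_error = 1.0,
                      min_avg_qual = 27, window_min_qual = 0)
  r38 <- read_set("a", strrep("ACGT", 75), list(rep(38L, 300)))
  # accumulated error 300 * 10^-3.8 = 0.0475 < 1 and mean 38 >= 27
  expect_equal(as.character(classify_read(r38, spec)$verdict), "high")

  r20 <- read_set("b", strrep("ACGT", 75), list(rep(20L, 300)))
  # accumulated error 3.0: fails high, within 4x relaxation; mean 20
  spec7 <- spec; spec7$mid_qual_slack <- 7
  expect_equal(as.character(classify_read(r20, spec7)$verdict), "mid")
  spec5 <- spec; spec5$mid_qual_slack <- 5
  out5 <- classify_read(r20, spec5)
  expect_equal(as.character(out5$verdict), "rejected")
  expect_equal(out5$reject_reason, "avg_qual")

  short <- read_set("c", strrep("ACGT", 25), list(rep(38L, 100)))
  out <- classify_read(short, spec)
  expect_equal(out$reject_reason, "too_short")
})

test_that("structural filters and adapter trimming apply in order", {
  spec <- filter_spec(min_len = 10, max_len = 40, max_ambiguous = 1,
                      max_homopolymer = 5, window_min_qual = 0,
                      truncation_len = 20, adapter = "CTGTCT")
  mk <- function(id, seq) read_set(id, seq, list(rep(35L, nchar(seq))))
  expect_equal(classify_read(mk("l", strrep("ACGT", 15)), spec)$reject_reason,
               "too_long")
  expect_equal(classify_read(mk("n", paste0("NNA", strrep("ACGT", 4))),
                             spec)$reject_reason, "ambiguous")
  expect_equal(classify_read(mk("h", paste0("AAAAAA", strrep("GTC", 5))),
                             spec)$reject_reason, "homopolymer")
  # adapter removal shortens the read before the length check
  ad <- classify_read(mk("a", paste0(strrep("ACGT", 5), "CTGTCTAAAAAAAA")),
                      spec)
  expect_equal(as.character(ad$verdict), "high")
  expect_equal(ad$reads$bases, strrep("ACGT", 5))
})

test_that("quality-less reads with quality criteria enabled are refused", {
  rs <- read_set("x", strrep("ACGT", 75))
  expect_error(classify_read(rs, filter_spec()), "quality-free")
  qfree <- filter_spec(min_avg_qual = 0, max_expected_error = Inf,
                       window_min_qual = 0)
  expect_equal(as.character(classify_read(rs, qfree)$verdict), "high")
})

test_that("demultiplexing conserves read counts under arbitrary inputs", {
  for (seed in 1:3) {
    run <- synthesize_run(n_reads = 400, rng_seed = seed,
                          frac_bad_barcode = 0.1, frac_mid_quality = 0.15,
                          frac_reject = 0.1)
    dm <- demultiplex_run(run$reads, run$mapping)
    expect_equal(nrow(dm$high) + nrow(dm$mid) + sum(dm$reasons), dm$n_input)
    expect_equal(sum(dm$report$high), nrow(dm$high))
    expect_equal(sum(dm$report$mid), nrow(dm$mid))
    expect_gt(dm$n_unassigned, 0)
    expect_gt(nrow(dm$mid), 0)
  }
})

test_that("tightening any single threshold never promotes a read", {
  run <- synthesize_run(n_reads = 300, rng_seed = 5, frac_mid_quality = 0.2,
                        frac_reject = 0.1)
  dm <- demultiplex_run(run$reads, run$mapping, filter_spec())
  high_ids <- dm$high$read_id
  tighter <- list(filter_spec(min_avg_qual = 30),
                  filter_spec(max_expected_error = 0.5),
                  filter_spec(min_len = 300))
  for (spec in tighter) {
    dm2 <- demultiplex_run(run$reads, run$mapping, spec)
    expect_true(all(dm2$high$read_id %in% high_ids))
  }
})

test_that("identical inputs give identical bins and report", {
  run <- synthesize_run(n_reads = 200, rng_seed = 8)
  a <- demultiplex_run(run$reads, run$mapping)
  b <- demultiplex_run(run$reads, run$mapping)
  expect_identical(a$high, b$high)
  expect_identical(a$report, b$report)
})

test_that("a length floor above every read rejects everything as too short", {
  run <- synthesize_run(n_reads = 50, rng_seed = 2)
  expect_warning(
    dm <- demultiplex_run(run$reads, run$mapping,
                          filter_spec(min_len = 5000, max_len = 0)),
    "no reads")
  expect_equal(nrow(dm$high) + nrow(dm$mid), 0)
  expect_true(dm$reasons[["too_short"]] > 0)
})
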