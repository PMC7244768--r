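test_that("match_read assigns exact reads and extracts the UMI", {
  panel <- tiny_panel()
  res <- match_read(make_read(panel, "CD10_1", "ACGTACG"), panel)
  expect_equal(res$status, "assigned")
  expect_equal(res$marker, "CD10_1")
  expect_equal(res$umi, "ACGTACG")
})

test_that("mismatch budget is respected per half-probe", {
  panel <- tiny_panel()
  layout <- read_layout(max_mismatches = 2)
  read <- make_read(panel, "CD10_1")
  flip <- function(r, pos) {
    s <- strsplit(r, "")[[1]]
    s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
    paste(s, collapse = "")
  }
  # 2 mismatches in the left half (positions 8..19) still assign
  r2 <- flip(flip(read, 8), 10)
  expect_equal(match_read(r2, panel, layout)$marker, "CD10_1")
  # 3 mismatches in the same half exceed the budget
  r3 <- flip(r2, 12)
  expect_equal(match_read(r3, panel, layout)$status, "no_match")
})

test_that("chimeric reads (halves from different pairs) are flagged", {
  panel <- tiny_panel()
  read <- paste0("ACGTACG",
                 panel$probes$left_seq[panel$probes$marker_id == "CD10_1"],
                 panel$probes$right_seq[panel$probes$marker_id == "CD5_1"])
  expect_equal(match_read(read, panel)$status, "chimera")
})

test_that("reads too short for the layout are below_quality, not errors", {
  panel <- tiny_panel()
  res <- match_read("ACGTACGACGT", panel)
  expect_equal(res$status, "below_quality")
})

test_that("noisy read assignment agrees with a brute-force Hamming oracle", {
  panel <- default_panel()
  layout <- read_layout()
  cfg <- sim_config(seq_error_rate = 0.01, chimera_rate = 0, seed = 5)
  counts <- stats::setNames(rep(5L, 120),
                            sample(panel$probes$marker_id, 120))
  path <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(counts, panel, layout, cfg, path, seed = 5)
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  res <- match_reads(reads, panel, layout)
  oracle <- hamming_oracle(reads, panel, layout)
  assigned <- res$status == "assigned"
  expect_gt(mean(assigned), 0.9)
  expect_equal(res$marker[assigned], oracle[assigned])
})

test_that("match_reads statuses account for every read", {
  panel <- tiny_panel()
  reads <- c(make_read(panel, "CD10_1"), make_read(panel, "MYC_1"),
             "ACGTACGACGT", strrep("A", 40),
             paste0("ACGTACG", panel$probes$left_seq[1],
                    panel$probes$right_seq[2]))
  res <- match_reads(reads, panel)
  expect_equal(sum(table(res$status)), length(reads))
  expect_setequal(unique(res$status),
                  c("assigned", "below_quality", "no_match", "chimera"))
})

test_that("PCR duplicates with the same UMI collapse to one molecule", {
  panel <- tiny_panel()
  events <- data.frame(sample = "S1", marker = "MYC_1",
                       umi = rep("AAAAAAA", 5), status = "assigned")
  ucm <- collapse_umis(events, panel)
  expect_equal(unname(ucm$counts["S1", "MYC_1"]), 1L)
})

test_that("interpretability flips exactly at 5000 distinct UMIs", {
  panel <- tiny_panel()
  make_events <- function(n) {
    data.frame(sample = "S1", marker = "CD10_1",
               umi = rtmis:::int_to_umi(seq_len(n)), status = "assigned")
  }
  low <- collapse_umis(make_events(4999), panel)
  high <- collapse_umis(make_events(5000), panel)
  expect_false(unname(low$interpretable["S1"]))
  expect_true(unname(high$interpretable["S1"]))
  expect_equal(unname(low$total_umis["S1"]), 4999L)
})

test_that("exact collapse equals a hash-set oracle on random events", {
  panel <- tiny_panel()
  set.seed(42)
  markers <- panel$probes$marker_id
  events <- data.frame(
    sample = sample(c("S1", "S2"), 10000, replace = TRUE),
    marker = sample(markers, 10000, replace = TRUE),
    umi = rtmis:::int_to_umi(sample.int(4^7, 10000, replace = TRUE)),
    status = "assigned", stringsAsFactors = FALSE)
  ucm <- collapse_umis(events, panel, samples = c("S1", "S2"))
  oracle <- hashset_oracle(events, c("S1", "S2"), markers)
  expect_equal(ucm$counts, oracle)
})

test_that("UMIs with non-ACGT characters are dropped as below_quality", {
  panel <- tiny_panel()
  events <- data.frame(sample = "S1", marker = "CD10_1",
                       umi = c("AAAAAAA", "AANAAAA"), status = "assigned")
  ucm <- collapse_umis(events, panel)
  expect_equal(unname(ucm$counts["S1", "CD10_1"]), 1L)
  expect_equal(ucm$discard_stats$below_quality, 1L)
})

test_that("directional Hamming-1 collapse merges error UMIs into abundant ones", {
  panel <- tiny_panel()
  ev <- function(umis) data.frame(sample = "S1", marker = "CD10_1",
                                  umi = umis, status = "assigned")
  # 1-off singleton absorbed by an abundant parent (5 >= 2*1 - 1)
  merged <- collapse_umis(ev(c(rep("AAAAAAA", 5), "AAAAAAT")), panel,
                          umi_collapse = "hamming1")
  expect_equal(unname(merged$counts["S1", "CD10_1"]), 1L)
  # near-equal abundances stay separate (2 < 2*2 - 1)
  kept <- collapse_umis(ev(c(rep("AAAAAAA", 2), rep("AAAAAAT", 2))), panel,
                        umi_collapse = "hamming1")
  expect_equal(unname(kept$counts["S1", "CD10_1"]), 2L)
  # distant UMIs are never merged
  far <- collapse_umis(ev(c(rep("AAAAAAA", 5), "TTTTTTT")), panel,
                       umi_collapse = "hamming1")
  expect_equal(unname(far$counts["S1", "CD10_1"]), 2L)
})

test_that("counts are invariant to read order and read duplication", {
  panel <- tiny_panel()
  layout <- read_layout()
  reads <- c(make_read(panel, "CD10_1", "AAAAAAA"),
             make_read(panel, "CD10_1", "CCCCCCC"),
             make_read(panel, "MYC_1", "GGGGGGG"))
  write_fq <- function(rds, path) {
    writeLines(paste0("@r", seq_along(rds), "\n", rds, "\n+\n",
                      strrep("I", nchar(rds))), path)
  }
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fq(reads, f1)
  write_fq(c(rev(reads), reads[1]), f2)  # permuted + duplicated read
  c1 <- count_fastq(c(S = f1), panel, layout)
  c2 <- count_fastq(c(S = f2), panel, layout)
  expect_equal(c1$counts, c2$counts)
})

test_that("empty FASTQ yields an all-zero non-interpretable row", {
  panel <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".fastq")
  file.create(f)
  ucm <- count_fastq(c(S1 = f), panel)
  expect_equal(sum(ucm$counts), 0L)
  expect_false(unname(ucm$interpretable["S1"]))
})

test_that("malformed FASTQ reports the offending file", {
  panel <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), f)
  expect_error(count_fastq(c(S1 = f), panel), "malformed FASTQ")
})

test_that("counts TSV and QC round-trip through write_counts/read_counts", {
  panel <- tiny_panel()
  m <- matrix(c(10L, 0L, 3L, 7L), 2, 2,
              dimnames = list(c("S1", "S2"), c("CD10_1", "MYC_1")))
  ucm <- umi_count_matrix(m)
  cf <- withr::local_tempfile(fileext = ".tsv")
  qf <- withr::local_tempfile(fileext = ".tsv")
  write_counts(ucm, cf, qf)
  back <- read_counts(cf)
  expect_equal(back$counts, ucm$counts)
  qc <- read.delim(qf)
  expect_equal(qc$total_umis, c(13L, 7L))
})
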