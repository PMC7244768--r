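# Shared fixtures, built in code.

# Small hand-checkable panel: 4 expression genes (MYC dual-pair) and one
# mutation locus, 12-nt halves, all ligation products mutually distant.
tiny_panel <- function() {
  probes <- data.frame(
    marker_id = c("CD10_1", "CD5_1", "MYC_1", "MYC_2", "BCL2_1",
                  "MYD88.L265P_1", "MYD88.L265P_2"),
    gene = c("CD10", "CD5", "MYC", "MYC", "BCL2",
             "MYD88.L265P", "MYD88.L265P"),
    group = c("GCB_SIG", "T_CELL", "DOUBLE_EXPRESSOR", "DOUBLE_EXPRESSOR",
              "DOUBLE_EXPRESSOR", "MUTATION", "MUTATION"),
    pair_index = c(1L, 1L, 1L, 2L, 1L, 1L, 2L),
    left_seq = c("ACGTACGTACGT", "TTTTCCCCAAAA", "GGGGAAAATTTT",
                 "CACACACACACA", "GTGTGTGTGTGT", "AACCGGTTAACC",
                 "CCAATTGGCCAA"),
    right_seq = c("TTGCTTGCTTGC", "GGGGTTTTCCCC", "AAAACCCCGGGG",
                  "AGAGAGAGAGAG", "TCTCTCTCTCTC", "GGTTAACCGGTT",
                  "TTGGCCAATTGG"),
    stringsAsFactors = FALSE)
  rtmis:::new_panel(probes, umi_length = 7L)
}

# Panel TSV text for parser tests.
panel_tsv_lines <- function(probes) {
  c(paste(c("marker_id", "gene", "group", "pair_index", "left_seq",
            "right_seq"), collapse = "\t"),
    do.call(paste, c(probes[c("marker_id", "gene", "group", "pair_index",
                              "left_seq", "right_seq")], sep = "\t")))
}

write_tmp_panel <- function(probes) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(panel_tsv_lines(probes), path)
  path
}

# A read carrying `umi` + the ligation product of `marker` in `panel`.
make_read <- function(panel, marker, umi = "ACGTACG") {
  paste0(umi, ligation_products(panel)[[marker]])
}

# Brute-force full-product minimum-Hamming oracle for read assignment.
hamming_oracle <- function(reads, panel, layout) {
  products <- ligation_products(panel)
  ins <- layout$insert_offset
  vapply(reads, function(r) {
    d <- vapply(products, function(p) {
      frag <- substr(r, ins + 1L, ins + nchar(p))
      if (nchar(frag) < nchar(p)) return(Inf)
      sum(strsplit(frag, "")[[1]] != strsplit(p, "")[[1]])
    }, numeric(1))
    best <- which(d == min(d))
    if (length(best) > 1) NA_character_ else names(products)[best]
  }, character(1), USE.NAMES = FALSE)
}

# Independent distinct-UMI oracle per (sample, marker).
hashset_oracle <- function(events, samples, markers) {
  out <- matrix(0L, length(samples), length(markers),
                dimnames = list(samples, markers))
  ev <- events[events$status == "assigned" & grepl("^[ACGT]+$", events$umi), ]
  if (!nrow(ev)) return(out)
  agg <- aggregate(umi ~ sample + marker, data = ev,
                   FUN = function(u) length(unique(u)))
  for (i in seq_len(nrow(agg)))
    out[agg$sample[i], agg$marker[i]] <- agg$umi[i]
  out
}

# Gene-level expression for a simulated cohort at given size/noise.
# (Non-interpretable samples in extreme-noise settings are expected to be
# dropped; the warning is part of normal operation.)
sim_gene_cohort <- function(n_per_class, noise_scale = 0.6, seed = 1) {
  sim <- simulate_cohort(sim_config(n_per_class = n_per_class,
                                    noise_scale = noise_scale, seed = seed))
  suppressWarnings(cohort_from_sim(sim))
}

expr_subset <- function(expr, rows) {
  expression_matrix(expr$values[rows, , drop = FALSE],
                    normalization = expr$normalization, level = expr$level)
}
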