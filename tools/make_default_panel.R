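# Regenerates inst/extdata/panel_default.tsv.
# Marker names and groups follow the published assay description; half-probe
# sequences are synthetic placeholders drawn at a fixed seed and checked so
# that any two ligation products differ at >= 8 positions.
# Run from the repository root: Rscript tools/make_default_panel.R

set.seed(20200522)

b_cell <- c("CD19", "CD20", "CD79A", "CD79B", "PAX5", "AICDA", "CD24", "CD27",
            "CD38", "CD44", "SOX11", "CCND1", "CCND3", "CD138", "PRDM1",
            "XBP1", "BACH2", "SPIB", "IRF8", "TCF3", "ID3", "EBF1", "CD40",
            "FAS", "TRAF3", "REL", "BTK", "SYK", "LYN", "BLNK", "PLCG2",
            "PIK3CD", "STAT3", "STAT6", "CREB3L2", "BCL2L1", "MCL1", "BIRC3",
            "TNFAIP3", "BCL10", "MALT1", "CD58", "B2M", "EZH2", "WHSC1",
            "CREBBP", "EP300", "KMT2D", "MEF2B", "FOXO1", "GNA13", "SGK1",
            "PTEN", "TP53", "CDKN2A", "TCL1A", "FCRL5", "SLAMF1", "BANK1",
            "CXCR4")
abc_sig <- c("IRF4", "FOXP1", "LIMD1", "TACI", "SH3BP5", "CCDC50", "CARD11",
             "PIM1", "CCND2", "BATF")
gcb_sig <- c("CD10", "BCL6", "MYBL1", "NEK6", "LMO2", "SERPINA9", "ASB13",
             "MAML3", "ITPKB", "S1PR2")
pmbl_sig <- c("PDL1", "PDL2", "JAK2", "CD30", "CD23", "CIITA", "NFKBIA",
              "MAL", "SNX22", "RHOF")
t_cell <- c("CD2", "CD3", "CD4", "CD5", "CD8", "CD28", "CTLA4", "GATA3",
            "CCR4", "ICOS", "CD40L", "CXCL13", "PD1", "IL21")
other <- c("KI67", "CD68", "CD163", "CSF1R", "GRB", "PRF", "CD56", "IL10",
           "TGFB1", "VEGFA", "CXCR5", "CCL17", "CCL22", "IDO1", "LAG3",
           "TIM3", "TIGIT", "BAFF", "BCMA", "IL6", "IL4", "IFNG", "TNF")
double_exp <- c("MYC", "BCL2")
ig <- c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE",
        "IMU_CMU", "IGAMMA_CGAMMA", "IEPSILON_CEPSILON")
mutation_loci <- c("MYD88_L265P", "EZH2_Y646", "BRAF_V600E", "XPO1_E571K",
                   "CD79B_Y196", "NOTCH2_R2400", "EBV_EBER1", "HHV8_LANA")

genes <- data.frame(
  gene = c(b_cell, ig, t_cell, double_exp, abc_sig, gcb_sig, pmbl_sig, other),
  group = rep(c("B_CELL", "IG_TRANSCRIPT", "T_CELL", "DOUBLE_EXPRESSOR",
                "ABC_SIG", "GCB_SIG", "PMBL_SIG", "OTHER"),
              c(length(b_cell), length(ig), length(t_cell), length(double_exp),
                length(abc_sig), length(gcb_sig), length(pmbl_sig),
                length(other))),
  stringsAsFactors = FALSE)
stopifnot(nrow(genes) == 137, !anyDuplicated(genes$gene))

dual <- c("AICDA", "BCL6", "MYC", "BCL2")
rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
  n_pairs <- if (genes$gene[i] %in% dual) 2L else 1L
  data.frame(gene = genes$gene[i], group = genes$group[i],
             pair_index = seq_len(n_pairs), stringsAsFactors = FALSE)
}))
mut_rows <- do.call(rbind, lapply(mutation_loci, function(g)
  data.frame(gene = g, group = "MUTATION", pair_index = 1:2,
             stringsAsFactors = FALSE)))
rows <- rbind(rows, mut_rows)
rows$marker_id <- paste0(rows$gene, "_", rows$pair_index)

half_len <- 28L
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
repeat {
  rows$left_seq <- vapply(seq_len(nrow(rows)), function(i) rand_seq(half_len), "")
  rows$right_seq <- vapply(seq_len(nrow(rows)), function(i) rand_seq(half_len), "")
  prod <- paste0(rows$left_seq, rows$right_seq)
  m <- do.call(rbind, strsplit(prod, ""))
  dmin <- Inf
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(m[(i + 1):nrow(m), , drop = FALSE] !=
                 matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    dmin <- min(dmin, d)
  }
  if (dmin >= 8) break
}
cat("min pairwise Hamming distance between products:", dmin, "\n")

out <- file.path("inst", "extdata", "panel_default.tsv")
con <- file(out, "w")
writeLines(c(
  "# RT-MLPA probe panel: 137 expression markers plus paired variant/reference",
  "# probes for recurrent somatic mutations and virus status.",
  "# Half-probe sequences are SYNTHETIC placeholders (min pairwise Hamming",
  "# distance between ligation products >= 8); marker names and groups follow",
  "# the published assay.",
  "#umi_length=7",
  "#adapter5=ACACTCTTTCCCTACACGACGCTC",
  "#adapter3=AGATCGGAAGAGCACACGTCTGAA",
  paste(c("marker_id", "gene", "group", "pair_index", "left_seq", "right_seq"),
        collapse = "\t")), con)
writeLines(paste(rows$marker_id, rows$gene, rows$group, rows$pair_index,
                 rows$left_seq, rows$right_seq, sep = "\t"), con)
close(con)
cat("wrote", out, ":", nrow(rows), "probe rows\n")
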