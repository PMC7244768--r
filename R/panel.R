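# Probe-panel definition: loading, validation, ligation products.

#' Functional groups recognised in a probe panel
#'
#' Panel probes are annotated with the functional group of the marker they
#' report: general B-cell differentiation markers, immunoglobulin (including
#' sterile switch) transcripts, T-cell / microenvironment markers, paired
#' variant/reference probes for somatic mutation and virus status detection,
#' the MYC/BCL2 double-expressor pair, the ABC/GCB/PMBL discriminating
#' signatures, and other (macrophage, cytotoxic, cytokine) markers.
#'
#' @export
MARKER_GROUPS <- c("B_CELL", "IG_TRANSCRIPT", "T_CELL", "MUTATION",
                   "DOUBLE_EXPRESSOR", "ABC_SIG", "GCB_SIG", "PMBL_SIG",
                   "OTHER")

#' Genes assayed by two independent probe pairs
#'
#' AICDA, BCL6, MYC and BCL2 are each measured by two probe pairs spanning
#' different exon junctions; their expression is averaged at the gene level.
#'
#' @export
DUAL_PAIR_GENES <- c("AICDA", "BCL6", "MYC", "BCL2")

PANEL_COLUMNS <- c("marker_id", "gene", "group", "pair_index",
                   "left_seq", "right_seq")

new_panel <- function(probes, umi_length = 7L, adapters = c("", "")) {
  structure(list(probes = probes,
                 umi_length = as.integer(umi_length),
                 adapters = adapters),
            class = "PanelDefinition")
}

#' Load a probe-panel definition
#'
#' Reads a tab-separated panel file with columns \code{marker_id}, \code{gene},
#' \code{group}, \code{pair_index}, \code{left_seq}, \code{right_seq}.
#' Lines starting with \code{#} are comments; \code{#umi_length=},
#' \code{#adapter5=} and \code{#adapter3=} comment lines set panel metadata.
#' The file is validated on load: probe sequences must be plain A/C/G/T,
#' \code{(gene, pair_index)} must be unique, expression genes carry at most
#' two pairs, and every MUTATION-group locus must provide both a reference
#' (\code{pair_index} 1) and a variant (\code{pair_index} 2) probe.
#'
#' @param path path to a panel TSV.
#' @return a \code{PanelDefinition}: list with \code{probes} (data.frame in
#'   file order), \code{umi_length} and \code{adapters}.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("panel validation: no probes in ", path)
  is_comment <- startsWith(lines, "#")
  meta <- lines[is_comment]
  umi_length <- 7L
  adapters <- c("", "")
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1]) else NULL
  }
  if (!is.null(v <- get_meta("umi_length"))) umi_length <- as.integer(v)
  if (!is.null(v <- get_meta("adapter5"))) adapters[1] <- v
  if (!is.null(v <- get_meta("adapter3"))) adapters[2] <- v

  body <- lines[!is_comment]
  body_line_no <- which(!is_comment)
  if (length(body) < 1L) stop("panel validation: no probes in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(PANEL_COLUMNS %in% header))
    stop("panel validation: missing columns: ",
         paste(setdiff(PANEL_COLUMNS, header), collapse = ", "))
  if (length(body) == 1L) stop("panel validation: no probes in ", path)

  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  n_col <- length(header)
  bad <- which(vapply(fields, length, 0L) != n_col)
  if (length(bad))
    stop("panel validation: wrong field count at line ",
         body_line_no[bad[1] + 1L])
  probes <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(probes) <- header
  probes <- probes[PANEL_COLUMNS]
  probes$pair_index <- as.integer(probes$pair_index)
  validate_panel_probes(probes, line_no = body_line_no[-1])
  new_panel(probes, umi_length = umi_length, adapters = adapters)
}

validate_panel_probes <- function(probes, line_no = seq_len(nrow(probes)) + 1L) {
  for (col in c("left_seq", "right_seq")) {
    ok <- grepl("^[ACGT]+$", probes[[col]])
    if (!all(ok))
      stop("panel validation: non-ACGT character in ", col,
           " at line ", line_no[which(!ok)[1]])
  }
  key <- paste(probes$gene, probes$pair_index)
  if (anyDuplicated(key))
    stop("panel validation: duplicate (gene, pair_index): ",
         key[duplicated(key)][1])
  if (anyDuplicated(probes$marker_id))
    stop("panel validation: duplicate marker_id: ",
         probes$marker_id[duplicated(probes$marker_id)][1])
  if (!all(probes$group %in% MARKER_GROUPS))
    stop("panel validation: unknown group: ",
         setdiff(probes$group, MARKER_GROUPS)[1])
  if (!all(probes$pair_index %in% 1:2))
    stop("panel validation: pair_index must be 1 or 2")
  expr <- probes[probes$group != "MUTATION", , drop = FALSE]
  pairs_per_gene <- table(expr$gene)
  over <- names(pairs_per_gene)[pairs_per_gene > 2]
  if (length(over))
    stop("panel validation: more than two pairs for gene ", over[1])
  dual <- names(pairs_per_gene)[pairs_per_gene == 2]
  rogue <- setdiff(dual, DUAL_PAIR_GENES)
  if (length(rogue))
    stop("panel validation: unexpected dual-pair gene ", rogue[1])
  mut <- probes[probes$group == "MUTATION", , drop = FALSE]
  if (nrow(mut)) {
    for (locus in unique(mut$gene)) {
      idx <- sort(mut$pair_index[mut$gene == locus])
      if (!identical(idx, 1:2))
        stop("panel validation: mutation locus ", locus,
             " needs reference (pair 1) and variant (pair 2) probes")
    }
  }
  invisible(TRUE)
}

#' Write a panel back to TSV
#'
#' Inverse of \code{\link{load_panel}}: the written file reloads
#' field-for-field identical.
#'
#' @param panel a \code{PanelDefinition}.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "PanelDefinition"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#umi_length=", panel$umi_length),
               paste0("#adapter5=", panel$adapters[1]),
               paste0("#adapter3=", panel$adapters[2]),
               paste(PANEL_COLUMNS, collapse = "\t")), con)
  writeLines(do.call(paste, c(panel$probes[PANEL_COLUMNS], sep = "\t")), con)
  invisible(path)
}

#' The packaged default panel
#'
#' Loads the 137-marker panel shipped with the package. Marker names and
#' groups follow the published assay; the half-probe sequences are synthetic
#' placeholders (the assay's oligonucleotides are not public) generated so
#' that any two ligation products differ at 8 or more positions, which makes
#' read-level simulation and matching well defined.
#'
#' @return a \code{PanelDefinition} with 137 expression markers plus paired
#'   variant/reference probes for mutation and virus status detection.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_default.tsv", package = "rtmis",
                         mustWork = TRUE))
}

#' Expected ligation products of a panel
#'
#' For every probe pair, the sequence observed in a correctly ligated read is
#' the concatenation left half + right half. Products must be unique across
#' the panel, otherwise read assignment would be ambiguous.
#'
#' @param panel a \code{PanelDefinition}.
#' @return named character vector, one product per \code{marker_id}.
#' @export
ligation_products <- function(panel) {
  stopifnot(inherits(panel, "PanelDefinition"))
  prod <- paste0(panel$probes$left_seq, panel$probes$right_seq)
  names(prod) <- panel$probes$marker_id
  if (anyDuplicated(prod))
    stop("ambiguous panel: identical ligation products for ",
         paste(names(prod)[prod == prod[duplicated(prod)][1]], collapse = ", "))
  prod
}

#' Export ligation products as FASTA
#'
#' @param panel a \code{PanelDefinition}.
#' @param path output FASTA path.
#' @export
export_products_fasta <- function(panel, path) {
  prod <- ligation_products(panel)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(prod), path)
  invisible(path)
}

#' Number of distinct expression markers in a panel
#'
#' Counts distinct genes outside the MUTATION group (mutation and
#' virus-status probes are genotyping, not expression, markers). Dual-pair
#' genes count once. The packaged default panel reports 137.
#'
#' @param panel a \code{PanelDefinition}.
#' @export
n_markers <- function(panel) {
  stopifnot(inherits(panel, "PanelDefinition"))
  length(unique(panel$probes$gene[panel$probes$group != "MUTATION"]))
}

#' Expression-probe subset of a panel (excludes MUTATION-group probes)
#' @param panel a \code{PanelDefinition}.
#' @keywords internal
expression_probes <- function(panel) {
  panel$probes[panel$probes$group != "MUTATION", , drop = FALSE]
}

#' @export
print.PanelDefinition <- function(x, ...) {
  cat("PanelDefinition:", nrow(x$probes), "probe pairs,",
      n_markers(x), "expression markers\n")
  cat("  dual-pair genes:",
      paste(intersect(DUAL_PAIR_GENES, x$probes$gene), collapse = ", "), "\n")
  cat("  mutation/virus loci:",
      length(unique(x$probes$gene[x$probes$group == "MUTATION"])), "\n")
  cat("  UMI length:", x$umi_length, "nt\n")
  invisible(x)
}
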