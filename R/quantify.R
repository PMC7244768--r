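# Normalized expression values, dual-probe aggregation, mutation calls.

#' Construct an ExpressionMatrix from a plain value matrix
#'
#' @param values numeric matrix, samples x markers.
#' @param normalization \code{"RELATIVE_LOG"} or \code{"RAW"}.
#' @param level \code{"probe"} or \code{"gene"}.
#' @return an \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, normalization = "RELATIVE_LOG",
                              level = "probe") {
  new_expression_matrix(values, normalization, level)
}

new_expression_matrix <- function(values, normalization = "RELATIVE_LOG",
                                  level = "probe") {
  structure(list(values = as.matrix(values),
                 samples = rownames(values),
                 markers = colnames(values),
                 normalization = normalization,
                 level = level),
            class = "ExpressionMatrix")
}

#' Depth-invariant expression normalization
#'
#' Converts deduplicated molecule counts into expression values that do not
#' depend on sequencing depth: per sample,
#' \code{value = log2(1 + scale * count / total)}, where \code{total} is the
#' sample's summed count over expression markers (MUTATION-group probes are
#' genotyping probes and are excluded from both the matrix and the
#' denominator). Pre-log relative abundances therefore sum to 1 per sample.
#' Depth invariance matters because the interpretability floor (5000 UMIs)
#' still admits an order-of-magnitude depth spread between samples.
#' Non-interpretable samples are excluded with a warning.
#'
#' @param counts a \code{UmiCountMatrix}.
#' @param panel a \code{PanelDefinition}.
#' @param scale abundance scale factor before the log (default 1e4).
#' @return an \code{ExpressionMatrix} at probe-pair resolution
#'   (\code{normalization = "RELATIVE_LOG"}).
#' @export
normalize_counts <- function(counts, panel, scale = 1e4) {
  stopifnot(inherits(counts, "UmiCountMatrix"),
            inherits(panel, "PanelDefinition"))
  expr_ids <- expression_probes(panel)$marker_id
  missing <- setdiff(expr_ids, counts$markers)
  if (length(missing))
    stop("counts matrix lacks panel markers: ", missing[1])
  keep <- counts$interpretable
  if (!any(keep))
    stop("no interpretable samples (all below ", INTERPRETABLE_MIN_UMIS,
         " total UMIs)")
  if (!all(keep))
    warning("excluding ", sum(!keep), " non-interpretable sample(s): ",
            paste(counts$samples[!keep], collapse = ", "))
  m <- counts$counts[keep, expr_ids, drop = FALSE]
  tot <- rowSums(m)
  rel <- m / tot
  new_expression_matrix(log2(1 + scale * rel))
}

#' Aggregate dual probe pairs to gene level
#'
#' Genes measured by two probe pairs (AICDA, BCL6, MYC, BCL2) get the
#' arithmetic mean of their two pair values; single-pair genes pass through.
#' The output marker axis is gene-level, ordered by first appearance in the
#' panel.
#'
#' @param expr an \code{ExpressionMatrix} at probe-pair resolution.
#' @param panel a \code{PanelDefinition}.
#' @return an \code{ExpressionMatrix} with one column per gene.
#' @export
aggregate_dual_probes <- function(expr, panel) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(panel, "PanelDefinition"))
  if (expr$level == "gene") return(expr)
  probes <- expression_probes(panel)
  probes <- probes[probes$marker_id %in% expr$markers, , drop = FALSE]
  genes <- unique(probes$gene)
  vals <- vapply(genes, function(g) {
    ids <- probes$marker_id[probes$gene == g]
    rowMeans(expr$values[, ids, drop = FALSE])
  }, numeric(nrow(expr$values)))
  vals <- matrix(vals, nrow = nrow(expr$values),
                 dimnames = list(expr$samples, genes))
  new_expression_matrix(vals, normalization = expr$normalization,
                        level = "gene")
}

#' Call somatic mutations / virus status from paired probes
#'
#' Each MUTATION-group locus carries a reference probe (\code{pair_index} 1)
#' and a variant probe (\code{pair_index} 2). The variant fraction is
#' variant / (variant + reference) molecules; a locus is called positive when
#' the fraction reaches \code{min_fraction} at a depth of at least
#' \code{min_depth} molecules. Zero-depth loci are reported with \code{NA}
#' fraction and a negative call.
#'
#' @param counts a \code{UmiCountMatrix}.
#' @param panel a \code{PanelDefinition}.
#' @param min_fraction variant-fraction threshold (default 0.1).
#' @param min_depth minimum molecule depth (default 20).
#' @return data.frame: \code{sample}, \code{locus}, \code{variant_umis},
#'   \code{reference_umis}, \code{depth}, \code{fraction}, \code{call}.
#' @export
call_mutations <- function(counts, panel, min_fraction = 0.1, min_depth = 20) {
  stopifnot(inherits(counts, "UmiCountMatrix"),
            inherits(panel, "PanelDefinition"))
  mut <- panel$probes[panel$probes$group == "MUTATION", , drop = FALSE]
  if (!nrow(mut)) stop("panel has no MUTATION-group probes")
  loci <- unique(mut$gene)
  out <- do.call(rbind, lapply(loci, function(locus) {
    ref_id <- mut$marker_id[mut$gene == locus & mut$pair_index == 1L]
    var_id <- mut$marker_id[mut$gene == locus & mut$pair_index == 2L]
    if (!length(ref_id))
      stop("panel validation: missing reference probe for locus ", locus)
    v <- counts$counts[, var_id]
    r <- counts$counts[, ref_id]
    depth <- v + r
    frac <- ifelse(depth > 0, v / depth, NA_real_)
    data.frame(sample = counts$samples, locus = locus,
               variant_umis = as.integer(v), reference_umis = as.integer(r),
               depth = as.integer(depth), fraction = frac,
               call = !is.na(frac) & frac >= min_fraction & depth >= min_depth,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix (", x$normalization, ", ", x$level, "-level): ",
      length(x$samples), " samples x ", length(x$markers), " markers\n",
      sep = "")
  invisible(x)
}
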