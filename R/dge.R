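# Exploratory statistics: Welch volcano, PCA maps, Wilcoxon comparisons.

#' Welch volcano analysis of a two-group comparison
#'
#' Per gene: a two-sided Welch unequal-variances t-test on the (log-scale)
#' expression values, and a log2 fold change computed on the de-logged
#' relative abundances with a 0.5 pseudo-molecule so zero-count genes stay
#' finite. P-values are Benjamini-Hochberg adjusted across all tested genes;
#' a gene is flagged significant when |log2 FC| > 1 and FDR < 0.05. Genes
#' with zero variance in both groups cannot be tested and are flagged
#' \code{tested = FALSE}.
#'
#' @param expr an \code{ExpressionMatrix} (RELATIVE_LOG values).
#' @param groups two-level factor (or coercible) over the samples; the fold
#'   change is level1 over level2.
#' @param pseudo pseudo-molecule added before the fold-change log
#'   (default 0.5).
#' @return data.frame: \code{gene}, \code{log2_fc}, \code{p_value},
#'   \code{fdr}, \code{significant}, \code{tested}.
#' @export
volcano <- function(expr, groups, pseudo = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  groups <- as.factor(groups)
  if (length(groups) != length(expr$samples))
    stop("groups length != number of samples")
  keep <- !is.na(groups)
  groups <- droplevels(groups[keep])
  vals <- expr$values[keep, , drop = FALSE]
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (min(table(groups)) < 2) stop("both groups need at least 2 samples")
  a <- vals[groups == levels(groups)[1], , drop = FALSE]
  b <- vals[groups == levels(groups)[2], , drop = FALSE]
  delog <- function(v) 2^v - 1  # inverse of log2(1 + x)
  res <- vapply(seq_along(expr$markers), function(j) {
    p <- tryCatch(stats::t.test(a[, j], b[, j])$p.value,
                  error = function(e) NA_real_)
    fc <- log2(mean(delog(a[, j])) + pseudo) -
          log2(mean(delog(b[, j])) + pseudo)
    c(fc, p)
  }, numeric(2))
  out <- data.frame(gene = expr$markers,
                    log2_fc = res[1, ], p_value = res[2, ],
                    stringsAsFactors = FALSE)
  out$tested <- !is.na(out$p_value)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                         method = "BH")
  out$significant <- out$tested & abs(out$log2_fc) > 1 & out$fdr < 0.05
  out
}

#' Two-dimensional PCA map with most-discriminatory markers
#'
#' Genes are centered and scaled to unit variance, then decomposed; the map
#' reports sample coordinates and gene loadings on the first two components,
#' the explained variance fractions, and the \code{n_top} genes with the
#' largest Euclidean loading norm over components 1-2 (the map's "most
#' discriminatory" markers). Component signs are fixed so the gene with the
#' largest |loading| on each component loads positively. Constant genes
#' carry no information on a correlation-scaled map and are dropped with a
#' warning; fully degenerate input (all rows identical) yields zero
#' coordinates and zero explained variance.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param subset optional sample selector (names or logical/integer index).
#' @param n_top number of top markers to report (default 40).
#' @return a \code{PcaMap}: \code{coordinates}, \code{loadings},
#'   \code{explained_variance}, \code{top_markers}.
#' @export
pca_map <- function(expr, subset = NULL, n_top = 40L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (!is.null(subset)) v <- v[subset, , drop = FALSE]
  if (nrow(v) < 3) stop("PCA needs at least 3 samples")
  if (ncol(v) < 2) stop("PCA needs at least 2 genes")
  sds <- apply(v, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) {
    coords <- matrix(0, nrow(v), 2,
                     dimnames = list(rownames(v), c("PC1", "PC2")))
    loads <- matrix(0, ncol(v), 2,
                    dimnames = list(colnames(v), c("PC1", "PC2")))
    return(structure(list(coordinates = coords, loadings = loads,
                          explained_variance = c(0, 0),
                          top_markers = character(0)),
                     class = "PcaMap"))
  }
  if (any(!keep))
    warning("dropping ", sum(!keep), " constant gene(s) before PCA")
  pc <- stats::prcomp(v[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(2L, ncol(pc$rotation))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  loads <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loads[, j]))
    if (loads[top, j] < 0) {
      loads[, j] <- -loads[, j]
      coords[, j] <- -coords[, j]
    }
  }
  if (k < 2) {
    coords <- cbind(coords, 0)
    loads <- cbind(loads, 0)
  }
  colnames(coords) <- colnames(loads) <- c("PC1", "PC2")
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  ev[is.na(ev)] <- 0
  norm2 <- sqrt(loads[, 1]^2 + loads[, 2]^2)
  top_markers <- names(sort(norm2, decreasing = TRUE))
  top_markers <- utils::head(top_markers, n_top)
  structure(list(coordinates = coords, loadings = loads,
                 explained_variance = ev, top_markers = top_markers),
            class = "PcaMap")
}

#' @export
print.PcaMap <- function(x, ...) {
  cat("PcaMap:", nrow(x$coordinates), "samples;",
      sprintf("PC1 %.1f%%, PC2 %.1f%% variance",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]),
      "\n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of one gene between two groups
#'
#' Two-sided rank-sum test: exact when both groups have at most 25 samples
#' and the values carry no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param gene gene/marker name.
#' @param groups two-level factor over the samples.
#' @return list: \code{p_value}, \code{medians} (named per group),
#'   \code{exact}.
#' @export
compare_groups <- function(expr, gene, groups) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!gene %in% expr$markers) stop("unknown gene: ", gene)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  x <- expr$values[groups == levels(groups)[1], gene]
  y <- expr$values[groups == levels(groups)[2], gene]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact)$p.value)
  list(p_value = p,
       medians = stats::setNames(c(stats::median(x), stats::median(y)),
                                 levels(groups)),
       exact = exact)
}
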