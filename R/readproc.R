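# Read-to-probe matching and UMI-based molecular counting.

#' Minimum deduplicated molecules for an interpretable sample
#'
#' A sample's run is reportable only when at least 5000 deduplicated UMIs
#' (summed over all markers) are detected; below that, per-marker counts are
#' too shallow to interpret.
#'
#' @export
INTERPRETABLE_MIN_UMIS <- 5000L

#' Describe the layout of a sequencing read
#'
#' Default layout: the 7-nt UMI at the start of the read, immediately
#' followed by the ligated probe insert (left half + right half). Universal
#' adapters are assumed trimmed upstream. Offsets are 0-based.
#'
#' @param umi_offset 0-based position of the UMI.
#' @param umi_length UMI length in nucleotides (7 for the standard assay).
#' @param insert_offset 0-based start of the ligated insert.
#' @param max_mismatches mismatches tolerated per half-probe (no indels).
#' @return a \code{ReadLayout}.
#' @export
read_layout <- function(umi_offset = 0L, umi_length = 7L,
                        insert_offset = umi_offset + umi_length,
                        max_mismatches = 2L) {
  stopifnot(umi_offset >= 0, umi_length > 0, insert_offset >= 0,
            max_mismatches >= 0)
  if (insert_offset < umi_offset + umi_length)
    stop("UMI and insert intervals overlap: insert must start at or after ",
         umi_offset + umi_length)
  structure(list(umi_offset = as.integer(umi_offset),
                 umi_length = as.integer(umi_length),
                 insert_offset = as.integer(insert_offset),
                 max_mismatches = as.integer(max_mismatches)),
            class = "ReadLayout")
}

# Hamming mismatch counts of one probe half against fixed-position slices of
# a padded read character matrix. `mat` is reads x positions.
half_mismatches <- function(mat, seq, start) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  if (start + len - 1L > ncol(mat))
    return(rep(Inf, nrow(mat)))
  slice <- mat[, start:(start + len - 1L), drop = FALSE]
  rowSums(slice != matrix(chars, nrow(mat), len, byrow = TRUE))
}

#' Match reads to panel probes
#'
#' Extracts the UMI at its layout position, then assigns each read to the
#' probe pair whose left half matches at the insert start within
#' \code{max_mismatches} and whose right half matches immediately after the
#' matched left half. Reads whose best left and right halves come from
#' different probe pairs are flagged \code{chimera} (a ligation artifact);
#' reads where either half exceeds the mismatch budget, or where two probes
#' tie for best match, are \code{no_match}; reads too short for the layout
#' are \code{below_quality}.
#'
#' @param reads character vector of read sequences.
#' @param panel a \code{PanelDefinition}.
#' @param layout a \code{ReadLayout}.
#' @return data.frame with columns \code{marker} (marker_id or NA),
#'   \code{status} (\code{assigned}/\code{no_match}/\code{chimera}/
#'   \code{below_quality}) and \code{umi}.
#' @export
match_reads <- function(reads, panel, layout = read_layout()) {
  stopifnot(inherits(panel, "PanelDefinition"), inherits(layout, "ReadLayout"))
  probes <- panel$probes
  n <- length(reads)
  marker <- rep(NA_character_, n)
  status <- rep("no_match", n)
  umi <- rep(NA_character_, n)
  if (n == 0L)
    return(data.frame(marker = character(), status = character(),
                      umi = character(), stringsAsFactors = FALSE))

  left_len <- nchar(probes$left_seq)
  right_len <- nchar(probes$right_seq)
  min_insert <- min(left_len + right_len)
  need <- layout$insert_offset + min_insert
  need <- max(need, layout$umi_offset + layout$umi_length)
  short <- nchar(reads) < need
  status[short] <- "below_quality"

  idx <- which(!short)
  if (length(idx)) {
    umi[idx] <- substr(reads[idx], layout$umi_offset + 1L,
                       layout$umi_offset + layout$umi_length)

    # exact-match fast path: with unique fixed-length halves, an exact
    # left+right hit is provably the unique best match of the general rule
    fast_ok <- length(unique(left_len)) == 1L &&
      length(unique(right_len)) == 1L &&
      !anyDuplicated(probes$left_seq) && !anyDuplicated(probes$right_seq)
    if (fast_ok) {
      ins0 <- layout$insert_offset
      L <- left_len[1]
      li <- match(substr(reads[idx], ins0 + 1L, ins0 + L), probes$left_seq)
      ri <- match(substr(reads[idx], ins0 + L + 1L, ins0 + L + right_len[1]),
                  probes$right_seq)
      hit <- !is.na(li) & !is.na(ri)
      same <- hit & li == ri
      status[idx[same]] <- "assigned"
      marker[idx[same]] <- probes$marker_id[li[same]]
      status[idx[hit & !same]] <- "chimera"
      idx <- idx[!hit]
    }
  }
  if (length(idx)) {
    maxw <- max(nchar(reads[idx]))
    padded <- formatC(reads[idx], width = -maxw, flag = "-")
    mat <- matrix(unlist(strsplit(padded, ""), use.names = FALSE),
                  nrow = length(idx), byrow = TRUE)
    mat[mat == " "] <- "N"

    ins <- layout$insert_offset + 1L
    mm <- layout$max_mismatches
    # left-half distances, reads x probes
    ldist <- vapply(seq_len(nrow(probes)),
                    function(p) half_mismatches(mat, probes$left_seq[p], ins),
                    numeric(length(idx)))
    ldist <- matrix(ldist, nrow = length(idx))
    lbest <- max.col(-ldist, ties.method = "first")
    lmin <- ldist[cbind(seq_along(idx), lbest)]
    ltied <- rowSums(ldist == lmin) > 1L
    lok <- lmin <= mm & !ltied

    # right halves evaluated just after the best left; group by left length
    for (L in unique(left_len[lbest[lok]])) {
      sel <- which(lok & left_len[lbest] == L)
      if (!length(sel)) next
      rstart <- ins + L
      rdist <- vapply(seq_len(nrow(probes)),
                      function(p) half_mismatches(mat[sel, , drop = FALSE],
                                                  probes$right_seq[p], rstart),
                      numeric(length(sel)))
      rdist <- matrix(rdist, nrow = length(sel))
      rbest <- max.col(-rdist, ties.method = "first")
      rmin <- rdist[cbind(seq_along(sel), rbest)]
      rtied <- rowSums(rdist == rmin) > 1L
      rok <- rmin <= mm & !rtied
      same <- rbest == lbest[sel]
      g <- idx[sel]
      status[g[rok & same]] <- "assigned"
      marker[g[rok & same]] <- probes$marker_id[rbest[rok & same]]
      status[g[rok & !same]] <- "chimera"
    }
  }
  data.frame(marker = marker, status = status, umi = umi,
             stringsAsFactors = FALSE)
}

#' Match a single read
#'
#' Scalar convenience wrapper around \code{\link{match_reads}}.
#'
#' @inheritParams match_reads
#' @param read a single read sequence.
#' @return list with \code{marker}, \code{status}, \code{umi}.
#' @export
match_read <- function(read, panel, layout = read_layout()) {
  res <- match_reads(read, panel, layout)
  list(marker = res$marker[1], status = res$status[1], umi = res$umi[1])
}

# Directional single-linkage UMI collapse: visiting UMIs by decreasing read
# count, a UMI at Hamming distance 1 from an already-kept UMI with count
# >= 2*count - 1 is absorbed into it (the standard directional network rule).
collapse_directional <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  u <- names(tab)
  k <- length(u)
  if (k <= 1L) return(k)
  cnt <- as.integer(tab)
  len <- nchar(u[1])
  m <- matrix(unlist(strsplit(u, ""), use.names = FALSE), nrow = k, byrow = TRUE)
  kept <- logical(k)
  assigned <- logical(k)
  for (i in seq_len(k)) {
    if (assigned[i]) next
    kept[i] <- TRUE
    assigned[i] <- TRUE
    if (i < k) {
      cand <- which(!assigned)
      if (length(cand)) {
        d <- rowSums(m[cand, , drop = FALSE] !=
                     matrix(m[i, ], length(cand), len, byrow = TRUE))
        absorb <- cand[d == 1L & cnt[i] >= 2L * cnt[cand] - 1L]
        assigned[absorb] <- TRUE
      }
    }
  }
  sum(kept)
}

#' Construct a UmiCountMatrix from a plain count matrix
#'
#' For counts obtained outside \code{\link{count_fastq}} (external runs,
#' simulations). Rows are samples, columns marker_ids; total UMIs and the
#' interpretability flag are derived.
#'
#' @param counts integer matrix with sample rownames and marker colnames.
#' @param discard_stats optional per-sample discard statistics data.frame.
#' @return a \code{UmiCountMatrix}.
#' @export
umi_count_matrix <- function(counts, discard_stats = NULL) {
  new_umi_count_matrix(counts, discard_stats)
}

new_umi_count_matrix <- function(counts, discard_stats = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts matrix needs sample rownames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(discard_stats))
    discard_stats <- data.frame(sample_id = rownames(counts),
                                no_match = rep(0L, nrow(counts)),
                                chimeric = rep(0L, nrow(counts)),
                                below_quality = rep(0L, nrow(counts)),
                                stringsAsFactors = FALSE)
  total <- as.integer(rowSums(counts))
  structure(list(counts = counts,
                 samples = rownames(counts),
                 markers = colnames(counts),
                 total_umis = stats::setNames(total, rownames(counts)),
                 interpretable = stats::setNames(
                   total >= INTERPRETABLE_MIN_UMIS, rownames(counts)),
                 discard_stats = discard_stats),
            class = "UmiCountMatrix")
}

#' Collapse matched read events into a deduplicated count matrix
#'
#' Counts, for each (sample, marker), the number of distinct UMIs observed:
#' PCR duplicates of the same captured molecule share a UMI and collapse to
#' one count. With \code{umi_collapse = "hamming1"} UMIs one substitution
#' away from a more abundant UMI are additionally merged into it
#' (directional rule), absorbing sequencing errors in the UMI itself.
#' Events whose UMI contains a non-ACGT character are dropped and counted
#' under \code{below_quality}.
#'
#' @param events data.frame with columns \code{sample}, \code{marker},
#'   \code{umi} and optionally \code{status} (non-\code{assigned} rows are
#'   tallied into the discard statistics).
#' @param panel a \code{PanelDefinition} (fixes the marker axis).
#' @param umi_collapse \code{"exact"} (default) or \code{"hamming1"}.
#' @param samples optional character vector fixing the sample axis (so
#'   all-discarded samples still get a row).
#' @return a \code{UmiCountMatrix}: integer matrix samples x markers plus
#'   \code{total_umis}, \code{interpretable} (total >= 5000) and per-sample
#'   \code{discard_stats}.
#' @export
collapse_umis <- function(events, panel, umi_collapse = c("exact", "hamming1"),
                          samples = NULL) {
  umi_collapse <- match.arg(umi_collapse)
  stopifnot(inherits(panel, "PanelDefinition"))
  if (is.null(events$status)) events$status <- "assigned"
  if (is.null(samples)) samples <- unique(events$sample)
  markers <- panel$probes$marker_id

  bad_umi <- events$status == "assigned" & !grepl("^[ACGT]+$", events$umi)
  events$status[bad_umi] <- "below_quality"

  ds <- data.frame(sample_id = samples, no_match = 0L, chimeric = 0L,
                   below_quality = 0L, stringsAsFactors = FALSE)
  tally <- function(st) {
    t <- table(factor(events$sample[events$status == st], levels = samples))
    as.integer(t)
  }
  ds$no_match <- tally("no_match")
  ds$chimeric <- tally("chimera")
  ds$below_quality <- tally("below_quality")

  keep <- events$status == "assigned"
  counts <- matrix(0L, length(samples), length(markers),
                   dimnames = list(samples, markers))
  if (any(keep)) {
    ev <- events[keep, , drop = FALSE]
    if (!all(ev$marker %in% markers))
      stop("event marker not in panel: ",
           setdiff(ev$marker, markers)[1])
    key <- split(ev$umi, list(factor(ev$sample, levels = samples),
                              factor(ev$marker, levels = markers)),
                 drop = FALSE)
    nfun <- if (umi_collapse == "exact")
      function(u) length(unique(u)) else collapse_directional
    vals <- vapply(key, function(u) if (length(u)) nfun(u) else 0L, 0L)
    counts[] <- as.integer(vals)  # split() order: sample varies fastest
  }
  new_umi_count_matrix(counts, ds)
}

read_fastq_seqs <- function(path) {
  lines <- readLines(path, warn = FALSE)  # gzip handled transparently
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad))
    stop("malformed FASTQ in ", path, ": record ", bad[1], call. = FALSE)
  lines[seq(2L, length(lines), by = 4L)]
}

#' Count a set of per-sample FASTQ files
#'
#' Composition of \code{\link{match_reads}} and \code{\link{collapse_umis}}
#' over all reads of each sample. One FASTQ (optionally gzipped) per sample;
#' demultiplexing by index is assumed done by the sequencer.
#'
#' @param fastq_paths named character vector, \code{sample_id -> path}.
#' @param panel a \code{PanelDefinition}.
#' @param layout a \code{ReadLayout}.
#' @param umi_collapse passed to \code{\link{collapse_umis}}.
#' @return a \code{UmiCountMatrix}.
#' @export
count_fastq <- function(fastq_paths, panel, layout = read_layout(),
                        umi_collapse = "exact") {
  if (is.null(names(fastq_paths)) || any(names(fastq_paths) == ""))
    stop("fastq_paths must be named by sample_id")
  events <- lapply(names(fastq_paths), function(s) {
    reads <- read_fastq_seqs(fastq_paths[[s]])
    res <- match_reads(reads, panel, layout)
    if (nrow(res)) res$sample <- s
    res
  })
  events <- do.call(rbind, events[vapply(events, nrow, 0L) > 0])
  if (is.null(events))
    events <- data.frame(sample = character(), marker = character(),
                         status = character(), umi = character())
  collapse_umis(events, panel, umi_collapse = umi_collapse,
                samples = names(fastq_paths))
}

#' Write counts and QC tables
#'
#' Counts TSV: first column \code{sample_id}, one column per marker.
#' QC TSV: \code{sample_id}, \code{total_umis}, \code{interpretable},
#' \code{no_match}, \code{chimeric}, \code{below_quality}.
#'
#' @param ucm a \code{UmiCountMatrix}.
#' @param counts_path,qc_path output paths (\code{qc_path} optional).
#' @export
write_counts <- function(ucm, counts_path, qc_path = NULL) {
  stopifnot(inherits(ucm, "UmiCountMatrix"))
  df <- data.frame(sample_id = ucm$samples, ucm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(qc_path)) {
    qc <- data.frame(sample_id = ucm$samples,
                     total_umis = ucm$total_umis,
                     interpretable = ucm$interpretable,
                     ucm$discard_stats[match(ucm$samples,
                                             ucm$discard_stats$sample_id),
                                       c("no_match", "chimeric",
                                         "below_quality")],
                     stringsAsFactors = FALSE)
    utils::write.table(qc, qc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(counts_path)
}

#' Read a counts TSV written by \code{\link{write_counts}}
#' @param path counts TSV path.
#' @return a \code{UmiCountMatrix} (discard statistics zeroed).
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  new_umi_count_matrix(m)
}

#' @export
print.UmiCountMatrix <- function(x, ...) {
  cat("UmiCountMatrix:", length(x$samples), "samples x",
      length(x$markers), "markers\n")
  cat("  interpretable (>=", INTERPRETABLE_MIN_UMIS, "UMIs):",
      sum(x$interpretable), "/", length(x$samples), "\n")
  invisible(x)
}
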