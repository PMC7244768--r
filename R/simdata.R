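# Synthetic data with the statistical structure the assay assumes:
# subtype-structured marker abundances mixed with microenvironment
# components, multinomial molecular sampling at lognormal depth, read-level
# UMI/PCR-duplicate/error structure, and exponential survival outcomes.

#' Simulation configuration
#'
#' @param n_per_class samples simulated per subtype (default 40).
#' @param depth_median median total molecules per sample (lognormal depth,
#'   default 20000 — a comfortable multiple of the 5000-UMI
#'   interpretability floor).
#' @param depth_sdlog lognormal sigma of the per-sample depth (default 0.4).
#' @param noise_scale per-marker lognormal sigma of biological noise
#'   (default 0.6, i.e. marker abundances typically vary ~2x around the
#'   subtype template).
#' @param seq_error_rate per-base substitution error rate in reads
#'   (default 0.005; must be <= 0.05).
#' @param chimera_rate fraction of reads that are ligation chimeras
#'   (default 0.01).
#' @param pcr_dup_mean mean PCR duplicate multiplicity per molecule,
#'   geometric with minimum 1 (default 4).
#' @param seed RNG seed; every generator draw is reproducible under it.
#' @return a \code{SimConfig}.
#' @export
sim_config <- function(n_per_class = 40L, depth_median = 20000,
                       depth_sdlog = 0.4, noise_scale = 0.6,
                       seq_error_rate = 0.005, chimera_rate = 0.01,
                       pcr_dup_mean = 4, seed = 1L) {
  stopifnot(n_per_class >= 0, depth_median > 0, depth_sdlog >= 0,
            noise_scale >= 0,
            seq_error_rate >= 0, seq_error_rate <= 0.05,
            chimera_rate >= 0, chimera_rate < 1, pcr_dup_mean >= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 noise_scale = noise_scale, seq_error_rate = seq_error_rate,
                 chimera_rate = chimera_rate, pcr_dup_mean = pcr_dup_mean,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Multiply the mean of every probe of the given genes by `fold`.
bump <- function(means, probes, genes, fold) {
  hit <- probes$gene %in% genes
  means[hit] <- means[hit] * fold
  means
}

microenv_components <- function(panel) {
  probes <- panel$probes
  comp_genes <- list(
    T_CELL = c("CD2", "CD3", "CD4", "CD5", "CD28", "CTLA4", "GATA3", "CCR4"),
    TFH = c("ICOS", "CD40L", "CXCL13", "PD1", "IL21", "CXCR5", "CD23"),
    MACROPHAGE = c("CD68", "CD163", "CSF1R"),
    CYTOTOXIC = c("CD8", "GRB", "PRF", "CD56", "IFNG"))
  lapply(comp_genes, function(g) {
    v <- rep(0.05, nrow(probes))
    v[probes$group == "MUTATION"] <- 0.001
    v <- bump(v, probes, g, 200)
    v / sum(v)
  })
}

#' Subtype expression templates
#'
#' Hand-authored mean abundance profiles encoding the qualitative marker
#' signatures of the seven subtypes: ABC tumors are IGHM/AICDA-high with the
#' ABC discriminating signature up and the sterile I-mu/C-mu transcript low;
#' GCB tumors carry the GCB signature with high proliferation; PMBL is
#' PDL1/PDL2/JAK2/CD30/CD23-high; FL combines a GCB profile with a large
#' Tfh-rich microenvironment and near-exclusive I-epsilon/C-epsilon
#' expression; MCL is CCND1/SOX11/CD5-high and CD10/CD23-low; SLL is
#' CD5/CD23-high; MZL shows an activated/marginal-zone profile
#' (MALT1/BIRC3/IGHA). Each template also fixes a tumor-purity range and
#' microenvironment composition (T, Tfh, macrophage, cytotoxic weights).
#'
#' @param panel a \code{PanelDefinition}.
#' @return named list of \code{SubtypeTemplate}s (one per class, canonical
#'   order), with the microenvironment component vectors attached as
#'   attribute \code{"components"}.
#' @export
subtype_templates <- function(panel = default_panel()) {
  probes <- panel$probes
  base <- function() {
    v <- rep(1, nrow(probes))
    v[probes$group == "MUTATION" & probes$pair_index == 1] <- 0.3
    v[probes$group == "MUTATION" & probes$pair_index == 2] <- 0.01
    v
  }
  spec <- list(
    ABC = list(mods = list(list(c("IRF4", "FOXP1", "LIMD1", "TACI", "SH3BP5",
                                  "CCDC50", "CARD11", "PIM1", "CCND2",
                                  "BATF"), 8),
                           list("IGHM", 8), list("AICDA", 4),
                           list("IMU_CMU", 0.2), list(c("MYC", "BCL2"), 3),
                           list(c("CD10", "MYBL1", "NEK6", "LMO2"), 0.3)),
               frac = c(0.6, 0.9),
               micro = c(T_CELL = 0.40, TFH = 0.10, MACROPHAGE = 0.30,
                         CYTOTOXIC = 0.20)),
    GCB = list(mods = list(list(c("CD10", "BCL6", "MYBL1", "NEK6", "LMO2",
                                  "SERPINA9", "ASB13", "MAML3", "ITPKB",
                                  "S1PR2"), 8),
                           list("KI67", 4), list("IGHG", 3),
                           list(c("MYC", "BCL2"), 2)),
               frac = c(0.6, 0.9),
               micro = c(T_CELL = 0.30, TFH = 0.10, MACROPHAGE = 0.35,
                         CYTOTOXIC = 0.25)),
    PMBL = list(mods = list(list(c("PDL1", "PDL2", "JAK2", "CD30", "CD23",
                                   "CIITA", "NFKBIA", "MAL", "SNX22",
                                   "RHOF"), 10)),
                frac = c(0.6, 0.9),
                micro = c(T_CELL = 0.40, TFH = 0.05, MACROPHAGE = 0.30,
                          CYTOTOXIC = 0.25)),
    FL = list(mods = list(list(c("CD10", "BCL6", "MYBL1", "LMO2"), 5),
                          list("IEPSILON_CEPSILON", 12), list("BCL2", 5),
                          list("CD23", 3)),
              frac = c(0.3, 0.6),
              micro = c(T_CELL = 0.35, TFH = 0.50, MACROPHAGE = 0.10,
                        CYTOTOXIC = 0.05)),
    MCL = list(mods = list(list("CCND1", 12), list("SOX11", 8),
                           list("CD5", 5), list("IGHD", 5), list("BCL2", 3),
                           list(c("CD10", "CD23"), 0.2)),
               frac = c(0.5, 0.9),
               micro = c(T_CELL = 0.50, TFH = 0.05, MACROPHAGE = 0.25,
                         CYTOTOXIC = 0.20)),
    SLL = list(mods = list(list("CD5", 5), list("CD23", 6), list("CD27", 3),
                           list("CCND2", 2), list("IGHD", 4),
                           list("TCL1A", 4), list("CD10", 0.2)),
               frac = c(0.5, 0.9),
               micro = c(T_CELL = 0.50, TFH = 0.05, MACROPHAGE = 0.25,
                         CYTOTOXIC = 0.20)),
    MZL = list(mods = list(list("MALT1", 4), list("BIRC3", 4),
                           list("IGHA", 4), list("TNFAIP3", 3),
                           list("BANK1", 3), list("IGHM", 3),
                           list("CD10", 0.3)),
               frac = c(0.4, 0.8),
               micro = c(T_CELL = 0.45, TFH = 0.15, MACROPHAGE = 0.25,
                         CYTOTOXIC = 0.15)))
  templates <- lapply(names(spec), function(lab) {
    s <- spec[[lab]]
    m <- base()
    for (mod in s$mods) m <- bump(m, probes, mod[[1]], mod[[2]])
    structure(list(label = lab,
                   marker_means = stats::setNames(m / sum(m),
                                                  probes$marker_id),
                   tumor_fraction_range = s$frac,
                   microenvironment_components = s$micro),
              class = "SubtypeTemplate")
  })
  names(templates) <- names(spec)
  attr(templates, "components") <- microenv_components(panel)
  templates
}

#' Simulate a subtype-labeled cohort of molecule counts
#'
#' Per sample: draw a tumor fraction from the template's range, mix the
#' tumor profile with the template's microenvironment composition, perturb
#' every marker by lognormal noise of sigma \code{noise_scale}, draw the
#' sample's depth from a lognormal, and sample molecule counts
#' multinomially. Fully deterministic under \code{config$seed}.
#'
#' @param config a \code{SimConfig}.
#' @param templates output of \code{\link{subtype_templates}}.
#' @param panel a \code{PanelDefinition}.
#' @param classes subtype labels to simulate (default all seven).
#' @return list: \code{counts} (a \code{UmiCountMatrix}), \code{labels}
#'   (named character), \code{truth} (data.frame of per-sample tumor
#'   fraction and depth).
#' @export
simulate_cohort <- function(config = sim_config(),
                            templates = subtype_templates(panel),
                            panel = default_panel(),
                            classes = names(templates)) {
  stopifnot(inherits(config, "SimConfig"))
  comps <- attr(templates, "components")
  markers <- panel$probes$marker_id
  set.seed(config$seed)
  rows <- list(); labels <- character(); truth <- list()
  for (lab in classes) {
    tpl <- templates[[lab]]
    if (config$n_per_class == 0L) next
    for (i in seq_len(config$n_per_class)) {
      f <- stats::runif(1, tpl$tumor_fraction_range[1],
                        tpl$tumor_fraction_range[2])
      w <- tpl$microenvironment_components
      micro <- Reduce(`+`, Map(function(wk, ck) wk * ck, w, comps[names(w)]))
      mu <- f * tpl$marker_means + (1 - f) * micro
      mu <- mu * exp(stats::rnorm(length(mu), 0, config$noise_scale))
      mu <- mu / sum(mu)
      depth <- max(1L, round(stats::rlnorm(1, log(config$depth_median),
                                           config$depth_sdlog)))
      cnt <- stats::rmultinom(1, depth, mu)[, 1]
      id <- sprintf("%s_%03d", lab, i)
      rows[[id]] <- cnt
      labels[id] <- lab
      truth[[id]] <- data.frame(sample = id, label = lab,
                                tumor_fraction = f, depth = depth)
    }
  }
  counts <- if (length(rows))
    do.call(rbind, rows)
  else matrix(0L, 0, length(markers))
  colnames(counts) <- markers
  list(counts = new_umi_count_matrix(counts),
       labels = labels,
       truth = if (length(truth)) do.call(rbind, c(truth,
                                                   make.row.names = FALSE))
               else data.frame())
}

#' Normalize and label a simulated cohort
#'
#' Convenience composition: depth-invariant normalization, dual-probe
#' aggregation to gene level, and label attachment.
#'
#' @param sim output of \code{\link{simulate_cohort}}.
#' @param panel a \code{PanelDefinition}.
#' @return a \code{LabeledCohort} at gene level.
#' @export
cohort_from_sim <- function(sim, panel = default_panel()) {
  expr <- aggregate_dual_probes(normalize_counts(sim$counts, panel), panel)
  labeled_cohort(expr, sim$labels[expr$samples])
}

int_to_umi <- function(i, len = 7L) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(i))
  v <- i - 1L
  cols <- vector("list", len)
  for (p in seq_len(len)) {
    cols[[p]] <- bases[v %% 4L + 1L]
    v <- v %/% 4L
  }
  do.call(paste0, cols)
}

mutate_bases <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads[1])
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
              nrow = length(reads), byrow = TRUE)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- bases[(match(m[hit], bases) - 1L +
                   sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
    m[hit] <- repl
  }
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Simulate a FASTQ file from a molecule count vector
#'
#' The inverse of \code{\link{count_fastq}}: for every marker with count
#' \code{k}, emits \code{k} distinct UMIs, duplicates each molecule a
#' geometric number of times (PCR duplicates, mean \code{pcr_dup_mean},
#' minimum 1), mutates bases uniformly at \code{seq_error_rate}, injects
#' chimeric reads (left half of one probe, right half of another, fresh
#' UMI) at \code{chimera_rate} of the read stream, and shuffles read order.
#' At zero error and zero chimera rate, \code{count_fastq} recovers the
#' input counts exactly.
#'
#' @param counts_row named integer vector (marker_id -> molecule count).
#' @param panel a \code{PanelDefinition}.
#' @param layout a \code{ReadLayout}.
#' @param config a \code{SimConfig}.
#' @param path output FASTQ path (gzipped when it ends in \code{.gz}).
#' @param seed RNG seed (default \code{config$seed}).
#' @return \code{path}, invisibly.
#' @export
simulate_fastq <- function(counts_row, panel, layout = read_layout(),
                           config = sim_config(), path, seed = config$seed) {
  stopifnot(inherits(panel, "PanelDefinition"), inherits(config, "SimConfig"))
  products <- ligation_products(panel)
  counts_row <- counts_row[counts_row > 0]
  unknown <- setdiff(names(counts_row), names(products))
  if (length(unknown)) stop("count for marker not in panel: ", unknown[1])
  set.seed(seed)
  umi_space <- 4L^layout$umi_length
  read_parts <- vector("list", length(counts_row))
  names(read_parts) <- names(counts_row)
  for (m in names(counts_row)) {
    k <- counts_row[[m]]
    if (k > umi_space)
      stop("count ", k, " exceeds UMI diversity 4^", layout$umi_length)
    umis <- int_to_umi(sample.int(umi_space, k), layout$umi_length)
    dups <- stats::rgeom(k, prob = 1 / config$pcr_dup_mean) + 1L
    read_parts[[m]] <- paste0(rep(umis, dups), products[m])
  }
  reads <- unlist(read_parts, use.names = FALSE)
  # additional chimeric reads so they form ~chimera_rate of the stream
  if (config$chimera_rate > 0 && length(reads)) {
    n_chim <- stats::rbinom(1, length(reads),
                            config$chimera_rate / (1 - config$chimera_rate))
    if (n_chim > 0) {
      li <- sample.int(nrow(panel$probes), n_chim, replace = TRUE)
      ri <- (li + sample.int(nrow(panel$probes) - 1L, n_chim,
                             replace = TRUE) - 1L) %% nrow(panel$probes) + 1L
      chim <- paste0(int_to_umi(sample.int(umi_space, n_chim, replace = TRUE),
                                layout$umi_length),
                     panel$probes$left_seq[li], panel$probes$right_seq[ri])
      reads <- c(reads, chim)
    }
  }
  reads <- mutate_bases(reads, config$seq_error_rate)
  if (length(reads) > 1) reads <- reads[sample.int(length(reads))]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- strrep("I", nchar(reads))
    writeLines(paste0("@sim_read_", seq_along(reads), "\n", reads, "\n+\n",
                      qual), con)
  }
  invisible(path)
}

#' Simulate survival outcomes with covariate-dependent hazards
#'
#' Exponential event times with the baseline hazard multiplied by the given
#' hazard ratio for every TRUE covariate flag; independent exponential
#' censoring; administrative cap at \code{cap} months. The default effect
#' size (hazard ratio 2.0 for the double-expressor flag) mirrors the
#' magnitude reported for MYC/BCL2 dual expression in DLBCL.
#'
#' @param covariates data.frame of logical covariate columns, rownames =
#'   sample ids.
#' @param hazard_ratios named numeric, one entry per covariate column
#'   (default \code{c(double_expressor = 2.0)}).
#' @param baseline_hazard events per month for flag-free samples
#'   (default 0.025, i.e. ~78% event rate within the 60-month horizon).
#' @param censor_rate exponential censoring rate per month (default 0.005).
#' @param cap administrative censoring horizon (default 60 months).
#' @param seed RNG seed.
#' @return a \code{SurvivalRecords} data.frame carrying the covariates.
#' @export
simulate_survival <- function(covariates,
                              hazard_ratios = c(double_expressor = 2.0),
                              baseline_hazard = 0.025, censor_rate = 0.005,
                              cap = SURVIVAL_CAP_MONTHS, seed = 1L) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  if (is.null(rownames(covariates)) ||
      identical(rownames(covariates), as.character(seq_len(n))))
    rownames(covariates) <- sprintf("S%04d", seq_len(n))
  missing <- setdiff(names(hazard_ratios), names(covariates))
  if (length(missing)) stop("covariates lack column: ", missing[1])
  set.seed(seed)
  loghr <- rep(0, n)
  for (cv in names(hazard_ratios))
    loghr <- loghr + log(hazard_ratios[[cv]]) * as.numeric(covariates[[cv]])
  rate <- baseline_hazard * exp(loghr)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  survival_records(rownames(covariates), time, event,
                   covariates = covariates, cap = cap)
}
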