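# Outcome analyses: Kaplan-Meier, log-rank, threshold scanning,
# double-expressor calling, multivariate Cox.

#' Administrative censoring horizon (months)
#'
#' Follow-up is right-censored at 5 years: stored times never exceed 60
#' months and events past the cap are recoded as censored.
#'
#' @export
SURVIVAL_CAP_MONTHS <- 60

#' Build survival records with administrative censoring
#'
#' @param sample sample ids.
#' @param time follow-up in months (>= 0).
#' @param event event indicator (death for OS; progression/relapse/death for
#'   PFS).
#' @param ipi_high optional logical, IPI score 3-5 vs 0-2.
#' @param covariates optional data.frame of named logical covariates
#'   (e.g. \code{double_expressor}, \code{abc_subtype}).
#' @param cap censoring horizon in months (default 60).
#' @return data.frame of class \code{SurvivalRecords}.
#' @export
survival_records <- function(sample, time, event, ipi_high = NULL,
                             covariates = NULL, cap = SURVIVAL_CAP_MONTHS) {
  stopifnot(length(time) == length(sample), length(event) == length(sample))
  if (any(time < 0)) stop("negative follow-up time")
  event <- as.logical(event)
  over <- time > cap
  event[over] <- FALSE
  time[over] <- cap
  df <- data.frame(sample = as.character(sample), time = as.numeric(time),
                   event = event, stringsAsFactors = FALSE)
  if (!is.null(ipi_high)) df$ipi_high <- as.logical(ipi_high)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  class(df) <- c("SurvivalRecords", "data.frame")
  df
}

#' Read a clinical CSV (sample_id, time_months, event[, ipi_score])
#'
#' IPI scores 3-5 map to \code{ipi_high = TRUE}, 0-2 to \code{FALSE}.
#'
#' @param path CSV path.
#' @param cap censoring horizon in months.
#' @return a \code{SurvivalRecords} data.frame.
#' @export
read_clinical <- function(path, cap = SURVIVAL_CAP_MONTHS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("clinical CSV needs columns ", paste(need, collapse = ", "))
  ipi <- if ("ipi_score" %in% names(df)) df$ipi_score >= 3 else NULL
  survival_records(df$sample_id, df$time_months, df$event,
                   ipi_high = ipi, cap = cap)
}

#' Kaplan-Meier estimate with 95% confidence band
#'
#' Product-limit estimate with Greenwood variance; the confidence interval
#' is computed on the log(-log) scale and therefore stays inside [0, 1].
#'
#' @param records a \code{SurvivalRecords} data.frame.
#' @return data.frame: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}, \code{lower}, \code{upper} (rows at event/censoring
#'   times).
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1,
    conf.type = "log-log", conf.int = 0.95)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv,
             lower = ifelse(is.na(fit$lower), 0, fit$lower),
             upper = ifelse(is.na(fit$upper), 1, fit$upper))
}

#' Two-group log-rank test
#'
#' @param records a \code{SurvivalRecords} data.frame.
#' @param group binary grouping over the records (logical or two-level).
#' @return list: \code{statistic} (1-df chi-squared), \code{p_value}.
#' @export
logrank_test <- function(records, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ group)
  stat <- sd$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Scan expression thresholds for the most significant split
#'
#' Dichotomizes the cohort at each expression quantile of the grid, log-rank
#' tests each split, and reports the threshold attaining the smallest
#' p-value. The scan is exploratory: the minimum over the grid is not
#' corrected for the multiplicity of thresholds tried, so the chosen p-value
#' is optimistic; the full p-vector is returned so users can correct.
#'
#' @param expr an \code{ExpressionMatrix}.
#' @param gene gene to scan (e.g. \code{"MYC"}, \code{"BCL2"}).
#' @param records a \code{SurvivalRecords} data.frame (samples matched by
#'   name against the expression matrix).
#' @param probs quantile grid (default 0.10 to 0.90 in steps of 0.05).
#' @return a \code{ThresholdScanResult}: \code{grid} data.frame
#'   (\code{quantile}, \code{threshold}, \code{n_high}, \code{p_value}),
#'   \code{chosen} threshold, \code{chosen_quantile}, \code{chosen_p}.
#' @export
threshold_scan <- function(expr, gene, records,
                           probs = seq(0.10, 0.90, by = 0.05)) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!gene %in% expr$markers) stop("unknown gene: ", gene)
  x <- expr$values[, gene]
  names(x) <- expr$samples
  missing <- setdiff(records$sample, expr$samples)
  if (length(missing)) stop("no expression for sample ", missing[1])
  x <- x[records$sample]
  if (length(unique(x)) < 2) stop("degenerate grid: constant expression")
  thr <- stats::quantile(x, probs = probs, names = FALSE)
  grid <- data.frame(quantile = probs, threshold = thr,
                     n_high = NA_integer_, p_value = NA_real_)
  for (i in seq_along(thr)) {
    high <- x > thr[i]
    grid$n_high[i] <- sum(high)
    if (length(unique(high)) < 2) next
    grid$p_value[i] <- tryCatch(logrank_test(records, high)$p_value,
                                error = function(e) NA_real_)
  }
  if (all(is.na(grid$p_value))) stop("degenerate grid: no testable split")
  best <- which.min(grid$p_value)
  structure(list(gene = gene, grid = grid,
                 chosen = grid$threshold[best],
                 chosen_quantile = grid$quantile[best],
                 chosen_p = grid$p_value[best]),
            class = "ThresholdScanResult")
}

#' @export
print.ThresholdScanResult <- function(x, ...) {
  cat("ThresholdScanResult for ", x$gene, ": threshold ",
      signif(x$chosen, 4), " (quantile ", x$chosen_quantile,
      "), log-rank p = ", signif(x$chosen_p, 3),
      " (exploratory: uncorrected minimum over ", nrow(x$grid),
      " thresholds)\n", sep = "")
  invisible(x)
}

#' MYC/BCL2 double-expressor call
#'
#' A sample is double-positive when its MYC expression exceeds the MYC
#' threshold AND its BCL2 expression exceeds the BCL2 threshold (thresholds
#' typically chosen by \code{\link{threshold_scan}}).
#'
#' @param expr an \code{ExpressionMatrix} containing MYC and BCL2.
#' @param myc_threshold,bcl2_threshold expression cutoffs.
#' @param genes the two gene names (default \code{c("MYC", "BCL2")}).
#' @return list: \code{flag} (named logical), \code{n_positive}, \code{n},
#'   \code{prevalence_pct}.
#' @export
double_expressor <- function(expr, myc_threshold, bcl2_threshold,
                             genes = c("MYC", "BCL2")) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(genes) == 2)
  if (!all(genes %in% expr$markers))
    stop("expression matrix lacks gene: ", setdiff(genes, expr$markers)[1])
  flag <- expr$values[, genes[1]] > myc_threshold &
          expr$values[, genes[2]] > bcl2_threshold
  names(flag) <- expr$samples
  list(flag = flag, n_positive = sum(flag), n = length(flag),
       prevalence_pct = round(100 * mean(flag)))
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron tie approximation; per covariate a
#' hazard ratio with Wald 95% CI and p-value. Warns when events are fewer
#' than 10 per covariate (unstable fit).
#'
#' @param records a \code{SurvivalRecords} data.frame carrying the covariate
#'   columns.
#' @param covariates covariate column names (default the published model:
#'   double-expressor status, ABC vs GCB cell of origin, IPI group).
#' @return data.frame: \code{covariate}, \code{hr}, \code{lower},
#'   \code{upper}, \code{p_value}.
#' @export
cox_multivariate <- function(records,
                             covariates = c("double_expressor",
                                            "abc_subtype", "ipi_high")) {
  missing <- setdiff(covariates, names(records))
  if (length(missing)) stop("records lack covariate: ", missing[1])
  for (cv in covariates)
    if (length(unique(records[[cv]])) < 2)
      stop("non-identifiable covariate (constant across cohort): ", cv)
  n_events <- sum(records$event)
  if (n_events < 10 * length(covariates))
    warning("only ", n_events, " events for ", length(covariates),
            " covariates; estimates may be unstable")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  s <- summary(fit)
  data.frame(covariate = covariates,
             hr = unname(s$conf.int[, "exp(coef)"]),
             lower = unname(s$conf.int[, "lower .95"]),
             upper = unname(s$conf.int[, "upper .95"]),
             p_value = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}
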