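#' Packaged normal-eye cohort table
#'
#' Path to (or the contents of) the packaged per-eye cohort table: 61
#' eyes of 45 normal individuals with case id, eye index, laterality,
#' sex, age, subfoveal choroidal thickness (um), swept-source flow-area
#' ratio (%), and whether the eye was also examined by spectral-domain
#' OCTA.
#'
#' @param as_records If `TRUE` (default) read and return the validated
#'   records; if `FALSE` return the file path.
#' @return A data frame of eye records, or a path.
#' @export
cohort_table1 <- function(as_records = TRUE) {
  path <- system.file("extdata", "table1.csv", package = "choroidflow",
                      mustWork = TRUE)
  if (as_records) read_cohort_csv(path) else path
}

#' Filter eligible eyes
#'
#' Drops eyes with subfoveal choroidal thinning below the cutoff
#' (default 150 um — thinner choroids suggest pathologic myopia and the
#' half-choroid slab geometry degenerates).
#'
#' @param records Eye-record data frame (see [read_cohort_csv()]).
#' @param min_sct_um Eligibility cutoff in micrometres.
#' @return The retained records; removals are reported via `message()`,
#'   and an empty result triggers a warning.
#' @export
filter_eligible <- function(records, min_sct_um = 150) {
  keep <- records$sct_um >= min_sct_um
  if (any(!keep))
    message(sprintf("excluding %d eye(s) with SCT < %g um (case %s)",
                    sum(!keep), min_sct_um,
                    paste(records$case_id[!keep], collapse = ", ")))
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no eligible eyes remain after the SCT filter", call. = FALSE)
  out
}

#' Spearman rank correlation with t-approximated p-value
#'
#' Rho is the Pearson correlation of average ranks (ties get their mean
#' rank); the two-sided p-value uses the t approximation with `n - 2`
#' degrees of freedom. Monotone transforms of either variable leave rho
#' unchanged.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p_value`, `n`.
#' @examples
#' spearman_correlation(1:10, (1:10)^3)$rho  # 1
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("rho is undefined for a constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Summarize a cohort of eye records
#'
#' Descriptive statistics and the SCT-flow association. Age is
#' summarized per case (one age per individual); subfoveal choroidal
#' thickness and flow-area ratio are summarized per eye, both eyes of an
#' individual counting as independent observations (a per-case
#' sensitivity analysis using each case's first eye is available).
#' Spread is the sample standard deviation (n - 1).
#'
#' @param records Eye-record data frame (see [read_cohort_csv()]).
#' @param one_eye_per_case If `TRUE`, restrict SCT/flow statistics and
#'   the correlation to each case's lowest-numbered eye.
#' @return A `cohort_summary` list: counts, per-variable
#'   mean/sd/min/max, and `spearman_rho` / `spearman_p` for flow vs SCT.
#' @export
summarize_cohort <- function(records, one_eye_per_case = FALSE) {
  if (nrow(records) < 2L) stopf("need at least 2 records to summarize")
  per_case <- records[!duplicated(records$case_id), , drop = FALSE]
  eyes <- if (one_eye_per_case) {
    ord <- records[order(records$case_id, records$eye_index), , drop = FALSE]
    ord[!duplicated(ord$case_id), , drop = FALSE]
  } else records
  desc <- function(v) list(mean = mean(v), sd = stats::sd(v),
                           min = min(v), max = max(v))
  # correlation is NA when degenerate (< 3 eyes or a constant variable)
  sp <- tryCatch(spearman_correlation(eyes$sct_um, eyes$flow_pct),
                 error = function(e) list(rho = NA_real_,
                                          p_value = NA_real_))
  structure(list(
    n_eyes = nrow(eyes), n_cases = nrow(per_case),
    n_sd_octa_eyes = sum(records$sd_octa),
    age = desc(per_case$age),
    sct_um = desc(eyes$sct_um),
    flow_pct = desc(eyes$flow_pct),
    spearman_rho = sp$rho, spearman_p = sp$p_value,
    one_eye_per_case = one_eye_per_case),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(d) sprintf("%.1f +/- %.1f (range %g-%g)",
                             d$mean, d$sd, d$min, d$max)
  cat(sprintf("<cohort_summary> %d eyes of %d cases\n", x$n_eyes, x$n_cases))
  cat("  age (per case, years): ", fmt(x$age), "\n", sep = "")
  cat("  SCT (um):              ", fmt(x$sct_um), "\n", sep = "")
  cat("  flow area (%):         ", fmt(x$flow_pct), "\n", sep = "")
  cat(sprintf("  Spearman rho(SCT, flow) = %.3f, p = %.2g\n",
              x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Scatter plot of flow-area ratio against choroidal thickness
#'
#' @param records Eye-record data frame.
#' @param ... Passed to [graphics::plot()].
#' @return The [spearman_correlation()] result, invisibly.
#' @export
plot_flow_vs_sct <- function(records, ...) {
  sp <- spearman_correlation(records$sct_um, records$flow_pct)
  graphics::plot(records$sct_um, records$flow_pct,
                 xlab = "Subfoveal choroidal thickness (um)",
                 ylab = "Choroidal blood flow area (%)",
                 main = sprintf("Spearman rho = %.3f", sp$rho),
                 pch = 19, ...)
  invisible(sp)
}
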