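#' Group-level comparison of RT- and confidence-based fits
#'
#' Aligns the per-subject results from two rating dimensions (response time
#' and confidence), keeps subjects whose fits converged under both, and
#' computes the group-level quantities: means and SDs per parameter and
#' source; paired t-tests between sources for `mu`, `sigma` and `d_a` and
#' between `d_prime` and `d_a` within each source; Pearson correlations
#' between sources per parameter; and the correlation between the criterion
#' `c` and the misevaluation index `d' - d_a` per source. Percent
#' differences between sources use the confidence-based mean as denominator,
#' `100 * (mean_conf - mean_rt) / mean_conf`.
#'
#' @param results_rt,results_conf Per-subject data frames from
#'   [fit_subjects()] (columns `subject`, `mu`, `sigma`, `d_a`, `d_prime`,
#'   `c`, `converged`).
#' @return An object of class `"cohort_summary"`: `subjects` (merged wide
#'   data frame), `means`, `paired`, `correlations`, `bias`, `n`.
#' @export
summarize_cohort <- function(results_rt, results_conf) {
  need <- c("subject", "mu", "sigma", "d_a", "d_prime", "c", "converged")
  stopifnot(all(need %in% names(results_rt)),
            all(need %in% names(results_conf)))
  rt <- results_rt[results_rt$converged, need]
  cf <- results_conf[results_conf$converged, need]
  m <- merge(rt, cf, by = "subject", suffixes = c("_rt", "_conf"))
  n <- nrow(m)

  params <- c("mu", "sigma", "d_a", "d_prime", "c")
  means <- do.call(rbind, lapply(params, function(p) {
    v_rt <- m[[paste0(p, "_rt")]]
    v_cf <- m[[paste0(p, "_conf")]]
    data.frame(parameter = p,
               mean_rt = mean(v_rt), sd_rt = stats::sd(v_rt),
               mean_conf = mean(v_cf), sd_conf = stats::sd(v_cf),
               pct_diff = 100 * (mean(v_cf) - mean(v_rt)) / mean(v_cf),
               stringsAsFactors = FALSE)
  }))

  paired_row <- function(label, a, b) {
    if (length(a) < 2L || stats::sd(a - b) == 0) {
      return(data.frame(comparison = label, t = NA_real_, df = NA_real_,
                        p = NA_real_, mean_diff = mean(a - b),
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(comparison = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = unname(tt$estimate), stringsAsFactors = FALSE)
  }
  paired <- rbind(
    paired_row("mu: conf vs rt", m$mu_conf, m$mu_rt),
    paired_row("sigma: conf vs rt", m$sigma_conf, m$sigma_rt),
    paired_row("d_a: conf vs rt", m$d_a_conf, m$d_a_rt),
    paired_row("d_prime vs d_a (rt)", m$d_prime_rt, m$d_a_rt),
    paired_row("d_prime vs d_a (conf)", m$d_prime_conf, m$d_a_conf)
  )

  cor_row <- function(p) {
    a <- m[[paste0(p, "_rt")]]
    b <- m[[paste0(p, "_conf")]]
    if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(parameter = p, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(a, b)
    data.frame(parameter = p, r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }
  if (n < 3L) {
    warning("fewer than 3 matched converged subjects; ",
            "correlations left unset", call. = FALSE)
  }
  correlations <- do.call(rbind, lapply(c("mu", "sigma", "d_a"), cor_row))

  out <- structure(
    list(subjects = m, means = means, paired = paired,
         correlations = correlations, bias = NULL, n = n),
    class = "cohort_summary"
  )
  out$bias <- list(
    rt = tryCatch(suppressWarnings(bias_correlation(out, "rt")),
                  error = function(e) list(r = NA_real_, p = NA_real_)),
    conf = tryCatch(suppressWarnings(bias_correlation(out, "conf")),
                    error = function(e) list(r = NA_real_, p = NA_real_))
  )
  out
}

#' Criterion vs misevaluation correlation
#'
#' Pearson correlation, across subjects, between the response criterion `c`
#' and the performance misevaluation index `d' - d_a`. Under an
#' unequal-variance observer (`sigma > 1`) this correlation is positive:
#' conservative subjects have their sensitivity overestimated by d'.
#'
#' @param summary A `"cohort_summary"` from [summarize_cohort()].
#' @param source Which rating dimension's `d_a` to use, `"rt"` or `"conf"`.
#' @return A list `(r, p)`; both `NA` (with a warning) when fewer than 3
#'   subjects or either variable has zero variance.
#' @export
bias_correlation <- function(summary, source = c("rt", "conf")) {
  source <- match.arg(source)
  stopifnot(inherits(summary, "cohort_summary"))
  m <- summary$subjects
  cc <- m[[paste0("c_", source)]]
  mis <- m[[paste0("d_prime_", source)]] - m[[paste0("d_a_", source)]]
  if (length(cc) < 3L || stats::sd(cc) == 0 || stats::sd(mis) == 0) {
    warning("criterion/misevaluation correlation undefined ",
            "(fewer than 3 subjects or zero variance)", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(cc, mis)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d matched converged subjects\n", x$n))
  cat("\nGroup means (rt vs confidence):\n")
  print(x$means, digits = 3, row.names = FALSE)
  cat("\nPaired comparisons:\n")
  print(x$paired, digits = 3, row.names = FALSE)
  cat("\nBetween-source correlations:\n")
  print(x$correlations, digits = 3, row.names = FALSE)
  if (!is.null(x$bias)) {
    cat(sprintf("\nCriterion vs misevaluation (d' - d_a): r = %.3f (rt), %.3f (conf)\n",
                x$bias$rt$r, x$bias$conf$r))
  }
  invisible(x)
}
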