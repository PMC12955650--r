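#' Starting values for the maximum-likelihood fit
#'
#' Derives initial parameters from the empirical zROC line: `sigma0` is the
#' reciprocal of the least-squares slope (clipped to \[0.2, 5\]) and `mu0`
#' the intercept times `sigma0`. Initial criteria are the normal quantiles
#' implied by the cumulative false-alarm rates, nudged where necessary to
#' strict monotonicity with a minimum gap of 1e-3. A degenerate zROC (fewer
#' than two distinct points, or a non-positive slope) falls back to
#' `mu0 = 1`, `sigma0 = 1` and equally spaced criteria.
#'
#' @param table A padded [rating_table()] with interior cumulative rates.
#' @return An [uvsdt_params()] object.
#' @export
initialize_params <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  n <- table$n_levels
  curve <- empirical_roc(table)
  z <- tryCatch(zroc(curve), error = function(e) NULL)
  ok <- !is.null(z) && is.finite(z$slope) && z$slope > 0
  if (ok) {
    sigma0 <- min(max(1 / z$slope, 0.2), 5)
    mu0 <- z$intercept * sigma0
    # FA_k = 1 - pnorm(c_{2n-k}); invert, then reverse into increasing order
    crit0 <- rev(-stats::qnorm(curve$points$fa))
  } else {
    sigma0 <- 1
    mu0 <- 1
    crit0 <- seq(-0.5 * (n - 1), 0.5 * (n - 1), length.out = 2L * n - 1L) +
      mu0 / 2
  }
  crit0[!is.finite(crit0)] <- 0
  for (j in seq_along(crit0)[-1L]) {
    if (crit0[j] <= crit0[j - 1L] + 1e-3) crit0[j] <- crit0[j - 1L] + 1e-3
  }
  uvsdt_params(mu0, sigma0, crit0)
}

# Unconstrained working parameterization: theta = (mu, log sigma, c1,
# log-gaps between consecutive criteria). Gaps are floored at 1e-4 so the
# criteria stay strictly ordered for any real-valued theta.
theta_from_params <- function(params) {
  c(params$mu, log(params$sigma), params$criteria[1L],
    log(pmax(diff(params$criteria), 1e-4)))
}

params_from_theta <- function(theta) {
  n_crit <- length(theta) - 2L
  gaps <- pmax(exp(theta[seq.int(4L, length.out = n_crit - 1L)]), 1e-4)
  uvsdt_params(theta[1L], exp(theta[2L]),
               theta[3L] + cumsum(c(0, gaps)))
}

#' Fit the unequal-variance SDT model by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of a padded rating table over
#' `mu`, `sigma` and the `2n - 1` ordered criteria, using an unconstrained
#' reparameterization (`log sigma`; first criterion plus log-gaps) that
#' guarantees `sigma > 0` and strict criterion ordering. The optimizer is
#' [stats::optim()] (Nelder-Mead simplex by default, BFGS optionally),
#' started at [initialize_params()] plus `n_restarts` jittered restarts; the
#' best optimum is kept. A fit counts as converged when the optimizer
#' reports success and the fitted `sigma` lies in `sigma_bounds` (estimates
#' outside it indicate a degenerate table, not a usable fit).
#'
#' @param table A padded [rating_table()].
#' @param init Optional [uvsdt_params()] starting values; defaults to
#'   [initialize_params()].
#' @param method Optimizer, `"Nelder-Mead"` (default) or `"BFGS"`.
#' @param n_restarts Number of jittered restarts (default 3); jitter is
#'   N(0, 0.1) on the working scale.
#' @param reltol Relative convergence tolerance on the log-likelihood
#'   (default 1e-8).
#' @param maxit Maximum function evaluations per start (default 5000).
#' @param sigma_bounds Admissible range for the fitted sigma (default
#'   `c(0.05, 20)`).
#' @param evidence_source Label stored in the result (`"confidence"`,
#'   `"rt"`, or `NA`).
#' @param seed Optional integer seed for the restart jitter, recorded in
#'   the result; the caller's RNG state is left untouched.
#' @return An object of class `"uvsdt_fit"`: `params`, `loglik`,
#'   `converged`, `n_evals`, `report` (a list with `d_prime` and
#'   `criterion_c` from the table's padded midpoint rates, and `d_a` and
#'   `auc` from the fitted model), `evidence_source`, `seed`.
#' @examples
#' tab <- pad_table(rating_table(rbind(c(4, 10, 26, 60), c(42, 28, 20, 10))))
#' fit_uvsdt(tab, seed = 1)
#' @export
fit_uvsdt <- function(table, init = NULL, method = c("Nelder-Mead", "BFGS"),
                      n_restarts = 3L, reltol = 1e-8, maxit = 5000L,
                      sigma_bounds = c(0.05, 20),
                      evidence_source = NA_character_, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "rating_table"))
  if (!table$padded) {
    warning("fitting an unpadded table; boundary rates may destabilize ",
            "the likelihood", call. = FALSE)
  }
  if (any(rowSums(table$freq) == 0)) {
    stop("a stimulus row is all zeros; cannot fit", call. = FALSE)
  }
  if (is.null(init)) init <- initialize_params(table)
  stopifnot(inherits(init, "uvsdt_params"),
            n_levels(init) == n_levels(table))

  nll <- function(theta) {
    p <- params_from_theta(theta)
    ll <- suppressWarnings(uvsdt_loglik(table, p))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  theta0 <- theta_from_params(init)

  jitters <- local_rng(seed, {
    lapply(seq_len(n_restarts), function(i) {
      stats::rnorm(length(theta0), 0, 0.1)
    })
  })
  starts <- c(list(rep(0, length(theta0))), jitters)

  best <- NULL
  n_evals <- 0L
  for (jit in starts) {
    res <- tryCatch(
      stats::optim(theta0 + jit, nll, method = method,
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_evals <- n_evals + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }

  params <- params_from_theta(best$par)
  loglik <- -best$value
  converged <- best$convergence == 0L && is.finite(loglik) &&
    params$sigma >= sigma_bounds[1L] && params$sigma <= sigma_bounds[2L]

  ev <- fit_evsdt_midpoint(table)
  report <- list(
    d_prime = ev$d_prime,
    d_a = d_a(params$mu, params$sigma),
    criterion_c = ev$criterion_c,
    auc = model_auc(params)
  )
  structure(
    list(params = params, loglik = loglik, converged = converged,
         n_evals = n_evals, report = report,
         evidence_source = evidence_source, seed = seed),
    class = "uvsdt_fit"
  )
}

#' @export
print.uvsdt_fit <- function(x, ...) {
  cat(sprintf(
    "Unequal-variance SDT fit (%s): logLik %.3f, %sconverged\n",
    if (is.na(x$evidence_source)) "unlabeled" else x$evidence_source,
    x$loglik, if (x$converged) "" else "NOT "))
  cat(sprintf("  mu = %.3f, sigma = %.3f -> d_a = %.3f (AUC %.3f)\n",
              x$params$mu, x$params$sigma, x$report$d_a, x$report$auc))
  cat(sprintf("  midpoint d' = %.3f, c = %.3f\n",
              x$report$d_prime, x$report$criterion_c))
  invisible(x)
}

#' Conventional equal-variance indices from the ROC midpoint
#'
#' Collapses the rating levels to plain yes/no, and returns the conventional
#' d' and criterion c computed from the resulting single (FA, hit) pair —
#' the quantities the equal-variance model reads off the ROC midpoint.
#'
#' @param table A padded [rating_table()].
#' @return A list of class `"evsdt_report"`: `d_prime`, `criterion_c`,
#'   `hit_rate`, `fa_rate`.
#' @export
fit_evsdt_midpoint <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  n <- table$n_levels
  yes <- rowSums(table$freq[, seq_len(n), drop = FALSE]) / rowSums(table$freq)
  hit <- yes[["present"]]
  fa <- yes[["absent"]]
  structure(
    list(d_prime = d_prime(hit, fa), criterion_c = criterion_c(hit, fa),
         hit_rate = hit, fa_rate = fa),
    class = "evsdt_report"
  )
}

#' @export
print.evsdt_report <- function(x, ...) {
  cat(sprintf("Equal-variance midpoint: hit %.3f, FA %.3f, d' = %.3f, c = %.3f\n",
              x$hit_rate, x$fa_rate, x$d_prime, x$criterion_c))
  invisible(x)
}

#' Performance misevaluation index
#'
#' The difference `d' - d_a` between the conventional equal-variance index
#' and the unequal-variance fit for the same subject. Positive values mean
#' d' overestimates sensitivity (typical for conservative criteria under
#' sigma > 1), negative values underestimation (lenient criteria).
#'
#' @param fit An `"uvsdt_fit"`.
#' @param ev An `"evsdt_report"` computed on the same table; defaults to the
#'   midpoint report embedded in `fit`.
#' @return A single numeric index.
#' @export
misevaluation_index <- function(fit, ev = NULL) {
  stopifnot(inherits(fit, "uvsdt_fit"))
  dp <- if (is.null(ev)) fit$report$d_prime else ev$d_prime
  dp - fit$report$d_a
}

#' Fit every subject in a set of rating tables
#'
#' Runs [fit_uvsdt()] on each table and collects a tidy per-subject data
#' frame suitable for [summarize_cohort()].
#'
#' @param tables Named list of padded per-subject [rating_table()]s.
#' @param evidence_source Label for the rating dimension used.
#' @param seed Optional base seed; subject `i` uses `seed + i` for its
#'   restart jitter.
#' @param ... Passed on to [fit_uvsdt()].
#' @return Data frame with columns `subject`, `evidence_source`, `mu`,
#'   `sigma`, `d_a`, `d_prime`, `c`, `auc`, `loglik`, `converged`.
#' @export
fit_subjects <- function(tables, evidence_source = NA_character_,
                         seed = NULL, ...) {
  stopifnot(is.list(tables), length(tables) > 0L)
  rows <- lapply(seq_along(tables), function(i) {
    fit <- fit_uvsdt(tables[[i]],
                     evidence_source = evidence_source,
                     seed = if (is.null(seed)) NULL else seed + i, ...)
    data.frame(subject = names(tables)[i],
               evidence_source = evidence_source,
               mu = fit$params$mu, sigma = fit$params$sigma,
               d_a = fit$report$d_a, d_prime = fit$report$d_prime,
               c = fit$report$criterion_c, auc = fit$report$auc,
               loglik = fit$loglik, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (if not
# NULL), restoring the caller's state afterwards.
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
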