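#' Configuration of a synthetic unequal-variance observer
#'
#' Describes a generative signal-detection observer: on each trial a
#' stimulus is present with probability `p_present`; internal evidence is
#' drawn from N(0, 1) on absent trials and N(`mu`, `sigma`) on present
#' trials; the observer says "yes" when evidence exceeds the decision
#' criterion (the middle element of `criteria`) and reports a confidence
#' level given by which inter-criterion interval the evidence falls in,
#' folded around the decision criterion so that level `n` marks the
#' strongest evidence for the chosen response.
#'
#' Response times follow a log-linear speed-up with evidence strength:
#' `rt = exp(rt_a - rt_b * |x - c0| + eps)`, `eps ~ N(0, rt_tau^2)`, so a
#' faster RT is a stronger indication of the choice made; `rt_tau` controls
#' how noisily RT reflects evidence (0 = perfectly monotone).
#'
#' @param mu,sigma Target-present evidence mean and SD (`sigma > 0`).
#' @param criteria Strictly increasing vector of `2n - 1` confidence/decision
#'   criteria whose middle element is the yes/no criterion; defaults to
#'   `n_levels`-level criteria spaced 0.5 apart, symmetric about
#'   `decision_criterion`.
#' @param n_levels Rating levels used when `criteria` is NULL (default 3).
#' @param decision_criterion The yes/no cutpoint `c0` (default 0); must equal
#'   the middle element of `criteria` when both are given.
#' @param n_trials Trials per subject.
#' @param p_present Probability of a target-present trial (default 0.5).
#' @param rt_a Baseline log-RT at the decision criterion (default
#'   `log(0.7)`, i.e. 0.7 s).
#' @param rt_b Evidence-to-speed slope, > 0 (default 0.35 per evidence unit).
#' @param rt_tau SD of log-normal RT noise, >= 0 (default 0.25).
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(mu = 1.5, sigma = 1.5, n_trials = 500)
#' @export
sim_config <- function(mu = 1, sigma = 1, criteria = NULL, n_levels = 3L,
                       decision_criterion = 0, n_trials = 1000L,
                       p_present = 0.5, rt_a = log(0.7), rt_b = 0.35,
                       rt_tau = 0.25) {
  n_levels <- as.integer(n_levels)
  if (is.null(criteria)) {
    criteria <- decision_criterion +
      0.5 * seq.int(-(n_levels - 1L), n_levels - 1L)
  }
  criteria <- as.numeric(criteria)
  n <- (length(criteria) + 1L) %/% 2L
  if (length(criteria) %% 2L == 0L || n < 2L ||
      any(diff(criteria) <= 0)) {
    stop("`criteria` must be strictly increasing with odd length 2n - 1, n >= 2",
         call. = FALSE)
  }
  if (abs(criteria[n] - decision_criterion) > 1e-12) {
    stop("the middle criterion must equal `decision_criterion`",
         call. = FALSE)
  }
  if (sigma <= 0 || rt_b <= 0 || rt_tau < 0 ||
      p_present <= 0 || p_present >= 1 || n_trials < 1) {
    stop("invalid simulation configuration", call. = FALSE)
  }
  structure(
    list(mu = mu, sigma = sigma, criteria = criteria, n_levels = n,
         decision_criterion = decision_criterion,
         n_trials = as.integer(n_trials), p_present = p_present,
         rt_a = rt_a, rt_b = rt_b, rt_tau = rt_tau),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulated observer: mu %.3f, sigma %.3f, c0 %.3f, %d levels, %d trials\n",
    x$mu, x$sigma, x$decision_criterion, x$n_levels, x$n_trials))
  cat(sprintf("  RT model: log RT = %.3f - %.3f |x - c0| + N(0, %.3f^2)\n",
              x$rt_a, x$rt_b, x$rt_tau))
  invisible(x)
}

#' Simulate trials from an unequal-variance observer
#'
#' Draws `n_trials` trials under the generative model described in
#' [sim_config()]. Output is deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @param subject Subject identifier stored in the `subject` column.
#' @return A data frame of trials: `subject`, `stimulus` (0/1), `response`
#'   (0/1), `rt` (seconds), `confidence` (ordinal 1..n), and the latent
#'   `evidence` value (useful for oracle checks; ignored by the analysis).
#' @export
simulate_observer <- function(config, seed = NULL, subject = "s01") {
  stopifnot(inherits(config, "sim_config"))
  local_rng(seed, {
    n <- config$n_trials
    stimulus <- stats::rbinom(n, 1L, config$p_present)
    x <- stats::rnorm(n,
                      mean = ifelse(stimulus == 1L, config$mu, 0),
                      sd = ifelse(stimulus == 1L, config$sigma, 1))
    c0 <- config$decision_criterion
    nl <- config$n_levels
    response <- as.integer(x > c0)
    # interval index: number of criteria below x, in 0 .. 2n-1
    idx <- rowSums(outer(x, config$criteria, ">"))
    confidence <- ifelse(response == 1L, idx - nl + 1L, nl - idx)
    rt <- exp(config$rt_a - config$rt_b * abs(x - c0) +
                stats::rnorm(n, 0, config$rt_tau))
    data.frame(subject = subject, stimulus = stimulus, response = response,
               rt = rt, confidence = as.integer(confidence), evidence = x,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a cohort of heterogeneous observers
#'
#' Draws per-subject parameters around the base configuration — `mu`
#' normally, `sigma` and `rt_b` log-normally, and the criterion placement by
#' a normal shift applied to the whole criterion vector (preserving the
#' inter-criterion gaps) — then simulates each subject with
#' [simulate_observer()]. Reproducible given `seed`.
#'
#' @param base A [sim_config()] holding the population-level parameters.
#' @param n_subjects Number of subjects.
#' @param sd_mu,sd_log_sigma,sd_c0,sd_log_rt_b Between-subject SDs (>= 0;
#'   all default 0, i.e. identical subjects).
#' @param seed Optional integer seed.
#' @return A data frame of all subjects' trials (as [simulate_observer()]),
#'   with the per-subject true parameters attached as
#'   `attr(, "true_params")`.
#' @export
simulate_cohort <- function(base, n_subjects, sd_mu = 0, sd_log_sigma = 0,
                            sd_c0 = 0, sd_log_rt_b = 0, seed = NULL) {
  stopifnot(inherits(base, "sim_config"), n_subjects >= 1L,
            sd_mu >= 0, sd_log_sigma >= 0, sd_c0 >= 0, sd_log_rt_b >= 0)
  local_rng(seed, {
    ids <- sprintf("s%03d", seq_len(n_subjects))
    mu_i <- stats::rnorm(n_subjects, base$mu, sd_mu)
    sigma_i <- exp(stats::rnorm(n_subjects, log(base$sigma), sd_log_sigma))
    shift_i <- stats::rnorm(n_subjects, 0, sd_c0)
    rt_b_i <- exp(stats::rnorm(n_subjects, log(base$rt_b), sd_log_rt_b))
    pieces <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      cfg <- sim_config(
        mu = mu_i[i], sigma = sigma_i[i],
        criteria = base$criteria + shift_i[i],
        decision_criterion = base$decision_criterion + shift_i[i],
        n_trials = base$n_trials, p_present = base$p_present,
        rt_a = base$rt_a, rt_b = rt_b_i[i], rt_tau = base$rt_tau
      )
      pieces[[i]] <- simulate_observer(cfg, subject = ids[i])
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "true_params") <- data.frame(
      subject = ids, mu = mu_i, sigma = sigma_i,
      c0 = base$decision_criterion + shift_i, rt_b = rt_b_i,
      stringsAsFactors = FALSE
    )
    out
  })
}
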