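#' Synthetic thermal-degradation fixture
#'
#' Generates a synthetic dataset emulating an accelerated thermal-stress
#' experiment on a heat-sensitive compound: specimens held at a set of oven
#' temperatures for exposure times on a 10--120 minute grid, with a positive,
#' heavy-tailed "degradation index" (an absorbance-derived measure of
#' breakdown-product accumulation) recorded per specimen. Indices are drawn
#' from the Inverse Weibull with per-temperature parameters; the defaults are
#' illustrative (not calibrated to any real dataset) and are chosen so the
#' index distribution shifts right as temperature rises. Exposure times are
#' assigned cyclically over the grid and do not enter the index distribution;
#' the record analysis treats the per-temperature index sequences as
#' exchangeable.
#'
#' @param seed optional integer seed (same seed, same dataset).
#' @param temps temperatures in degrees Celsius.
#' @param times exposure-time grid in minutes.
#' @param n_per_temp specimens per temperature.
#' @param params named list mapping each temperature (as character) to
#'   `c(phi, gamma)`.
#' @return A data frame with columns `temperature`, `time`, `replicate`,
#'   `degradation_index`.
#' @examples
#' d <- sim_degradation(seed = 1)
#' table(d$temperature)
#' @export
sim_degradation <- function(seed = NULL, temps = c(70, 85, 100),
                            times = seq(10, 120, by = 10), n_per_temp = 100L,
                            params = list(`70` = c(phi = 2.2e10, gamma = 6),
                                          `85` = c(phi = 6.5e10, gamma = 6),
                                          `100` = c(phi = 2.5e11, gamma = 6))) {
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(as.character(temps), names(params))
  if (length(miss))
    stop("no parameters supplied for temperature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  blocks <- lapply(temps, function(tp) {
    p <- params[[as.character(tp)]]
    data.frame(temperature = tp,
               time = rep_len(times, n_per_temp),
               replicate = seq_len(n_per_temp),
               degradation_index = rinvweibull(n_per_temp, p[[1L]], p[[2L]]))
  })
  do.call(rbind, blocks)
}

#' Monte-Carlo study of the record-sample MLE
#'
#' For each record-sample size in `n`, simulates `reps` independent upper
#' record samples at the true parameters, fits the record-likelihood MLE to
#' each, and reports the Monte-Carlo mean of each estimate with its standard
#' error (standard deviation of the estimates divided by the square root of
#' the number of converged fits). Non-converged fits are excluded and their
#' rate reported — never silently imputed.
#'
#' @param n vector of record-sample sizes (each >= 2).
#' @param phi,gamma true parameter values.
#' @param reps replicates per sample size (>= 100).
#' @param seed optional integer seed.
#' @param method record generator passed to [sim_records()].
#' @return A data frame with one row per `n`: `n`, `mean_phi`, `se_phi`,
#'   `sd_phi`, `mean_gamma`, `se_gamma`, `sd_gamma`, `failed` (fraction of
#'   non-converged fits), plus attributes `seed`, `reps`, `true`.
#' @examples
#' sim_study_mle(n = c(10, 20), reps = 100, seed = 1)
#' @export
sim_study_mle <- function(n = c(10, 20, 30, 40, 50), phi = 1, gamma = 1,
                          reps = 2000L, seed = NULL,
                          method = c("quantile", "truncation")) {
  method <- match.arg(method)
  if (reps < 100L) stop("'reps' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(n, function(ni) {
    est <- matrix(NA_real_, reps, 2L)
    ok <- logical(reps)
    for (r in seq_len(reps)) {
      smp <- sim_records(ni, phi, gamma, method = method)
      f <- tryCatch(.fit_record_mle(smp, restarts = 2L),
                    error = function(e) NULL)
      if (!is.null(f) && f$converged) {
        est[r, ] <- f$par
        ok[r] <- TRUE
      }
    }
    e <- est[ok, , drop = FALSE]
    m <- nrow(e)
    data.frame(n = ni,
               mean_phi = mean(e[, 1L]), se_phi = stats::sd(e[, 1L]) / sqrt(m),
               sd_phi = stats::sd(e[, 1L]),
               mean_gamma = mean(e[, 2L]),
               se_gamma = stats::sd(e[, 2L]) / sqrt(m),
               sd_gamma = stats::sd(e[, 2L]),
               failed = 1 - m / reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  attr(out, "true") <- c(phi = phi, gamma = gamma)
  out
}

#' Monte-Carlo study of the Bayesian estimator
#'
#' For each record-sample size, simulates `reps` record samples at the true
#' parameters, runs the Metropolis--Hastings sampler under the given prior on
#' each, and averages the posterior summaries over replicates (the averaging
#' convention — summaries first, then the mean across datasets — is reported
#' because alternatives exist).
#'
#' @param n vector of record-sample sizes; 0 is allowed and runs the sampler
#'   with no data (prior recovery).
#' @param phi,gamma true parameter values.
#' @param prior an [iw_prior].
#' @param control an [mcmc_control]; per-replicate chains are seeded from the
#'   study seed.
#' @param reps replicates per sample size (>= 50).
#' @param seed optional integer seed.
#' @return A data frame with one row per `n` and parameter: columns `n`,
#'   `parameter`, `estimate` (average posterior mean), `se` (average
#'   posterior sd), `mc_error`, `q2.5`, `median`, `q97.5`, each averaged over
#'   replicates; attributes `seed`, `reps`, `true`, `prior`.
#' @examples
#' sim_study_bayes(n = 10, reps = 50, seed = 1,
#'                 control = mcmc_control(1000, seed = 1))
#' @export
sim_study_bayes <- function(n = c(10, 20, 30, 40, 50), phi = 1, gamma = 1,
                            prior = iw_prior(3, 3, 3, 3),
                            control = mcmc_control(), reps = 200L,
                            seed = NULL) {
  if (reps < 50L) stop("'reps' must be at least 50", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(n, function(ni) {
    acc <- vector("list", reps)
    for (r in seq_len(reps)) {
      # ni = 0 runs the sampler with no data: prior recovery
      smp <- if (ni == 0L) numeric(0) else sim_records(ni, phi, gamma)
      ctl <- control
      ctl$seed <- NULL           # stay on the study RNG stream
      d <- mh_records(smp, prior, ctl)
      acc[[r]] <- posterior_summary(d)
    }
    avg <- Reduce(`+`, lapply(acc, as.matrix)) / reps
    cbind(data.frame(n = ni, parameter = c("phi", "gamma")),
          as.data.frame(avg), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  attr(out, "true") <- c(phi = phi, gamma = gamma)
  attr(out, "prior") <- prior
  out
}
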