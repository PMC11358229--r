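# MCMC housekeeping shared by the ex-Gaussian and SDT fitters.

#' MCMC run-length presets
#'
#' `"desk"` (4 chains x 2,000 iterations, 500 warm-up) is sized for
#' simulation studies and parameter-recovery checks; `"paper"` (2 chains x
#' 50,000 iterations, 5,000 warm-up) mirrors the long-run configuration
#' typical of published analyses of this design.
#'
#' @param preset `"desk"` or `"paper"`, or leave both-length overrides.
#' @param n_chains,n_iter,n_warmup optional overrides of the preset.
#' @param n_thin internal update sweeps per recorded iteration (thinning at
#'   the sweep level reduces autocorrelation without inflating memory).
#'   `NULL` uses each model's default: 2 sweeps for the ex-Gaussian model,
#'   5 for the cheaper SDT model.
#' @return list with `n_chains`, `n_iter`, `n_warmup`, `n_thin`,
#'   `rhat_threshold`.
#' @export
mcmc_config <- function(preset = c("desk", "paper"), n_chains = NULL,
                        n_iter = NULL, n_warmup = NULL, n_thin = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(n_chains = 4L, n_iter = 2000L, n_warmup = 500L)
  } else {
    list(n_chains = 2L, n_iter = 50000L, n_warmup = 5000L)
  }
  if (!is.null(n_chains)) cfg$n_chains <- as.integer(n_chains)
  if (!is.null(n_iter)) cfg$n_iter <- as.integer(n_iter)
  if (!is.null(n_warmup)) cfg$n_warmup <- as.integer(n_warmup)
  cfg$n_thin <- if (is.null(n_thin)) NULL else as.integer(n_thin)
  stopifnot(cfg$n_warmup < cfg$n_iter, cfg$n_chains >= 1)
  cfg$preset <- preset
  cfg$rhat_threshold <- 1.01
  cfg
}

#' Split-chain potential scale reduction factor
#'
#' The Gelman--Rubin convergence diagnostic computed after splitting each
#' chain in half, so that within-chain drift also registers as
#' non-convergence.  Values near 1 indicate that the chains have mixed.
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return scalar R-hat.
#' @export
rhat_split <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  half <- floor(min(lengths(chains)) / 2)
  if (half < 2) return(NA_real_)
  split_chains <- unlist(lapply(chains, function(x) {
    x <- x[seq_len(2 * half)]
    list(x[seq_len(half)], x[half + seq_len(half)])
  }), recursive = FALSE)
  m <- length(split_chains)
  n <- half
  means <- vapply(split_chains, mean, 0)
  vars <- vapply(split_chains, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# central credible interval + median summary of a draws vector
summarize_draws <- function(x, prob = 0.95) {
  a <- (1 - prob) / 2
  q <- unname(quantile(x, c(a, 0.5, 1 - a), names = FALSE))
  c(median = q[2], ci_low = q[1], ci_high = q[3])
}

# effective sample size across chains (coda, on the pooled mcmc.list)
ess_chains <- function(chains) {
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  unname(coda::effectiveSize(ml))
}

# deterministic per-chain seed derived from a user seed (kept < 2^31)
chain_seed <- function(seed, chain, offset = 0L) {
  (as.integer(seed) %% 1000000L) * 1000L + offset * 10L + chain
}
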