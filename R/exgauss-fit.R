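#' Hierarchical Bayesian ex-Gaussian model of reaction times
#'
#' Fits, separately for each age group, a hierarchical ex-Gaussian model in
#' which every participant has condition-specific parameters
#' `(mu_ik, sigma_ik, tau_ik)` partially pooled toward group-level means:
#' participant `mu` is Normal around the group mean, `sigma` and `tau` are
#' truncated-Normal (positive) around theirs, and the group-level means and
#' between-participant SDs get weakly informative, scale-adaptive priors
#' (group `mu` Normal centred on the grand mean RT with SD twice the RT
#' SD, truncated positive; group `sigma`/`tau` half-Normal at twice the RT
#' SD; between-participant SDs half-Normal at the RT SD).  Hierarchical
#' pooling is what makes the parameters estimable from the limited number
#' of trials a child can perform.
#'
#' Posterior sampling uses an adaptive Metropolis-within-Gibbs scheme
#' (random-walk moves on participant parameters including a correlated
#' `mu`/`tau` move, conjugate and adaptive-MH updates for group-level
#' quantities), with proposal scales tuned during warm-up only.
#' Convergence is summarized by the split-chain R-hat for every group-level
#' quantity; a warning is raised if any exceeds the threshold.
#'
#' @param trials trial data.frame (typically the `$trials` element of
#'   [filter_trials()]); columns `participant_id`, `group`, `condition`,
#'   `rt`.
#' @param config an [mcmc_config()].
#' @param seed integer seed controlling all chains.
#' @param min_trials minimum trials required per participant x condition.
#' @return object of class `"exg_posterior"`: list with `summary` (data.frame
#'   `group, condition, parameter, median, ci_low, ci_high, rhat, ess`, where
#'   `parameter` is one of `mu, sigma, tau` for group means and
#'   `sd_mu, sd_sigma, sd_tau` for between-participant SDs), `draws` (per
#'   group, per chain, matrix of group-level draws) and `config`.
#' @export
fit_hierarchical_exgauss <- function(trials, config = mcmc_config(),
                                     seed = 1L, min_trials = 10L) {
  stopifnot(all(c("participant_id", "group", "condition", "rt") %in% names(trials)))
  groups <- unique(trials$group)
  summaries <- list()
  draws_all <- list()
  for (g in groups) {
    tg <- trials[trials$group == g, , drop = FALSE]
    ids <- unique(tg$participant_id)
    conds <- sort(unique(tg$condition))
    if (length(ids) < 2)
      stop("group ", g, " has fewer than 2 participants")
    tab <- table(tg$participant_id, tg$condition)
    if (any(tab < min_trials))
      stop("group ", g, ": some participant x condition cells have fewer than ",
           min_trials, " trials")

    part <- match(tg$participant_id, ids) - 1L
    cond <- match(tg$condition, conds) - 1L
    rt <- as.numeric(tg$rt)
    n_part <- length(ids); n_cond <- length(conds)

    # scale-adaptive priors
    m0 <- mean(rt); s0 <- sd(rt)
    prior <- list(mu_mean = m0, mu_sd = 2 * s0,
                  group_scale = 2 * s0, sd_scale = s0)

    # moment-based initial values per cell
    init0 <- exgauss_inits(rt, part, cond, n_part, n_cond)

    chains <- vector("list", config$n_chains)
    for (ch in seq_len(config$n_chains)) {
      set.seed(chain_seed(seed, ch, offset = match(g, groups)))
      init <- jitter_inits(init0)
      fit <- exgauss_hier_chain(rt, part, cond, n_part, n_cond,
                                config$n_iter, config$n_warmup, prior, init,
                                if (is.null(config$n_thin)) 2L else config$n_thin)
      colnames(fit$draws) <- as.vector(t(outer(
        conds, c("mu", "sigma", "tau", "sd_mu", "sd_sigma", "sd_tau"),
        function(k, p) paste(k, p, sep = "."))))
      chains[[ch]] <- fit$draws
    }
    draws_all[[g]] <- chains

    cols <- colnames(chains[[1]])
    for (cn in cols) {
      per_chain <- lapply(chains, function(m) m[, cn])
      pooled <- unlist(per_chain)
      s <- summarize_draws(pooled)
      parts <- strsplit(cn, ".", fixed = TRUE)[[1]]
      summaries[[paste(g, cn)]] <- data.frame(
        group = g, condition = parts[1], parameter = parts[2],
        median = s[["median"]], ci_low = s[["ci_low"]], ci_high = s[["ci_high"]],
        rhat = rhat_split(per_chain), ess = ess_chains(per_chain),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  bad <- summary$rhat > config$rhat_threshold
  if (any(bad, na.rm = TRUE))
    warning("R-hat above ", config$rhat_threshold, " for: ",
            paste(head(paste(summary$group, summary$condition,
                             summary$parameter)[which(bad)], 10), collapse = "; "))
  structure(list(summary = summary, draws = draws_all, config = config),
            class = "exg_posterior")
}

# moment-based starting values: tau from the sample skew share of the SD
exgauss_inits <- function(rt, part, cond, n_part, n_cond) {
  mu <- matrix(0, n_part, n_cond); sg <- matrix(0, n_part, n_cond)
  ta <- matrix(0, n_part, n_cond)
  for (i in seq_len(n_part)) for (k in seq_len(n_cond)) {
    x <- rt[part == (i - 1L) & cond == (k - 1L)]
    m <- mean(x); s <- max(sd(x), 0.05)
    ta[i, k] <- max(0.8 * s, 0.05)
    sg[i, k] <- max(0.6 * s, 0.05)
    mu[i, k] <- max(m - ta[i, k], 0.05)
  }
  list(mu = mu, sig = sg, tau = ta,
       Mmu = pmax(colMeans(mu), 0.05), Msig = pmax(colMeans(sg), 0.05),
       Mtau = pmax(colMeans(ta), 0.05),
       Smu = pmax(apply(mu, 2, sd), 0.05),
       Ssig = pmax(apply(sg, 2, sd), 0.02),
       Stau = pmax(apply(ta, 2, sd), 0.02))
}

# overdispersed chain starts
jitter_inits <- function(init) {
  j <- function(x) x * exp(runif(length(x), -0.15, 0.15))
  init$mu <- init$mu * matrix(exp(runif(length(init$mu), -0.1, 0.1)),
                              nrow(init$mu))
  init$sig <- matrix(j(init$sig), nrow(init$sig))
  init$tau <- matrix(j(init$tau), nrow(init$tau))
  for (nm in c("Mmu", "Msig", "Mtau", "Smu", "Ssig", "Stau"))
    init[[nm]] <- j(init[[nm]])
  init
}

#' @export
print.exg_posterior <- function(x, ...) {
  cat("Hierarchical ex-Gaussian posterior (",
      x$config$n_chains, " chains x ", x$config$n_iter, " iterations)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Pooled posterior draws of one group-level quantity
#'
#' @param fit an `"exg_posterior"` or `"sdt_posterior"` object.
#' @param group group label.
#' @param quantity column name of the draws matrix (e.g.
#'   `"angry_target.mu"` for the ex-Gaussian fit, `"d.angry"` for SDT).
#' @return numeric vector of draws pooled across chains.
#' @export
posterior_draws <- function(fit, group, quantity) {
  ch <- fit$draws[[group]]
  if (is.null(ch)) stop("unknown group: ", group)
  if (!quantity %in% colnames(ch[[1]]))
    stop("unknown quantity: ", quantity, "; available: ",
         paste(colnames(ch[[1]]), collapse = ", "))
  unlist(lapply(ch, function(m) m[, quantity]))
}
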