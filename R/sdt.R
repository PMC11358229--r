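#' Point estimate of sensitivity (d-prime)
#'
#' The classic equal-variance signal-detection estimate
#' `d' = z(hit rate) - z(false-alarm rate)`.  Rates of exactly 0 or 1 make
#' the quantile infinite; when the trial counts are supplied, such edge
#' rates are replaced by `1/(2N)` and `1 - 1/(2N)` respectively (the
#' standard log-linear-style correction for point estimates; the
#' hierarchical model needs no correction because it works on the binomial
#' counts directly).
#'
#' @param hit_rate,fa_rate proportions in `[0, 1]`.
#' @param n_signal,n_noise trial counts behind the rates; required only
#'   when a rate sits on the boundary.
#' @return sensitivity in d' units.
#' @examples
#' dprime_point(0.97725, 0.5)   # 2
#' @export
dprime_point <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL) {
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1))
    stop("rates must lie in [0, 1]")
  fix <- function(r, n) {
    edge <- which(r %in% c(0, 1))
    if (length(edge) > 0) {
      if (is.null(n)) stop("edge rate needs the trial count for the 1/(2N) correction")
      nn <- rep_len(n, length(r))[edge]
      r[edge] <- pmin(pmax(r[edge], 1 / (2 * nn)), 1 - 1 / (2 * nn))
    }
    r
  }
  qnorm(fix(hit_rate, n_signal)) - qnorm(fix(fa_rate, n_noise))
}

#' Hierarchical Bayesian signal-detection model
#'
#' Fits, separately per age group, an equal-variance SDT model on hit and
#' false-alarm counts: participant sensitivity `d_ie` for each target
#' emotion is Normal around a group-level mean `mu_d[e]`, the participant
#' criterion `c_i` is Normal around `mu_c` and shared across emotions
#' (the target-absent trials that produce false alarms are common to both
#' emotions in the search design; their response probability uses the
#' participant's mean sensitivity).  Hit counts are Binomial with success
#' probability `Phi(d/2 - c)` and false-alarm counts Binomial with
#' `Phi(-dbar/2 - c)`.  Priors are weakly informative on the probit scale:
#' `mu_d, mu_c ~ Normal(0, 2)`, between-participant SDs half-Normal(1).
#'
#' @param counts SDT count data.frame from [to_sdt_counts()].
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @return object of class `"sdt_posterior"`: `summary` (data.frame
#'   `group, emotion, parameter, median, ci_low, ci_high, rhat, ess`, with
#'   `parameter` one of `mu_d, sd_d` per emotion and `mu_c, sd_c` with
#'   `emotion = NA`), `draws` (per group, per chain), `participant_d`
#'   (posterior means of participant-level sensitivities, for shrinkage
#'   diagnostics) and `config`.
#' @export
fit_hierarchical_sdt <- function(counts, config = mcmc_config(), seed = 1L) {
  need <- c("participant_id", "group", "emotion", "n_signal", "n_hits",
            "n_noise", "n_false_alarms")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_noise <= 0) || any(counts$n_signal <= 0))
    stop("every participant needs n_signal > 0 and n_noise > 0")
  if (all(counts$n_hits == 0) && all(counts$n_false_alarms == 0))
    stop("degenerate all-zero counts")
  groups <- unique(counts$group)
  summaries <- list(); draws_all <- list(); pd_all <- list()
  for (g in groups) {
    cg <- counts[counts$group == g, , drop = FALSE]
    ids <- unique(cg$participant_id)
    emotions <- unique(cg$emotion)
    E <- length(emotions)
    hits <- nsig <- matrix(0L, length(ids), E)
    fa <- nnoise <- integer(length(ids))
    for (i in seq_along(ids)) {
      ci <- cg[cg$participant_id == ids[i], , drop = FALSE]
      for (e in seq_len(E)) {
        r <- ci[ci$emotion == emotions[e], , drop = FALSE]
        if (nrow(r) != 1) stop("participant ", ids[i], " lacks emotion ", emotions[e])
        hits[i, e] <- r$n_hits; nsig[i, e] <- r$n_signal
      }
      fa[i] <- ci$n_false_alarms[1]; nnoise[i] <- ci$n_noise[1]
    }
    prior <- list(m_sd = 2, s_scale = 1)
    # empirical d' starting values, corrected at the edges
    emp_d <- matrix(0, length(ids), E)
    for (e in seq_len(E))
      emp_d[, e] <- dprime_point(hits[, e] / nsig[, e], fa / nnoise,
                                 n_signal = nsig[, e], n_noise = nnoise)
    emp_c <- -qnorm(pmin(pmax(fa / nnoise, 1 / (2 * nnoise)),
                         1 - 1 / (2 * nnoise))) - rowMeans(emp_d) / 2
    init0 <- list(d = emp_d, c = emp_c,
                  Md = colMeans(emp_d), Sd = pmax(apply(emp_d, 2, sd), 0.1),
                  Mc = mean(emp_c), Sc = max(sd(emp_c), 0.1))
    chains <- vector("list", config$n_chains)
    pd <- 0
    for (ch in seq_len(config$n_chains)) {
      set.seed(chain_seed(seed, ch, offset = match(g, groups)))
      init <- init0
      init$d <- init$d + rnorm(length(init$d), 0, 0.1)
      init$c <- init$c + rnorm(length(init$c), 0, 0.1)
      init$Md <- init$Md + rnorm(E, 0, 0.1)
      init$Mc <- init$Mc + rnorm(1, 0, 0.1)
      fit <- sdt_hier_chain(hits, nsig, fa, nnoise, config$n_iter,
                            config$n_warmup, prior, init,
                            if (is.null(config$n_thin)) 5L else config$n_thin)
      colnames(fit$draws) <- c(paste0("d.", emotions), paste0("sd_d.", emotions),
                               "c", "sd_c")
      chains[[ch]] <- fit$draws
      pd <- pd + fit$d_postmean / config$n_chains
    }
    draws_all[[g]] <- chains
    dimnames(pd) <- list(ids, emotions)
    pd_all[[g]] <- pd

    cols <- colnames(chains[[1]])
    meta <- rbind(
      data.frame(parameter = "mu_d", emotion = emotions, col = paste0("d.", emotions)),
      data.frame(parameter = "sd_d", emotion = emotions, col = paste0("sd_d.", emotions)),
      data.frame(parameter = "mu_c", emotion = NA_character_, col = "c"),
      data.frame(parameter = "sd_c", emotion = NA_character_, col = "sd_c"))
    for (r in seq_len(nrow(meta))) {
      per_chain <- lapply(chains, function(m) m[, meta$col[r]])
      s <- summarize_draws(unlist(per_chain))
      summaries[[paste(g, meta$col[r])]] <- data.frame(
        group = g, emotion = meta$emotion[r], parameter = meta$parameter[r],
        median = s[["median"]], ci_low = s[["ci_low"]], ci_high = s[["ci_high"]],
        rhat = rhat_split(per_chain), ess = ess_chains(per_chain),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  bad <- summary$rhat > config$rhat_threshold
  if (any(bad, na.rm = TRUE))
    warning("R-hat above ", config$rhat_threshold, " for: ",
            paste(head(paste(summary$group, summary$parameter,
                             summary$emotion)[which(bad)], 10), collapse = "; "))
  structure(list(summary = summary, draws = draws_all,
                 participant_d = pd_all, config = config),
            class = "sdt_posterior")
}

#' @export
print.sdt_posterior <- function(x, ...) {
  cat("Hierarchical SDT posterior (",
      x$config$n_chains, " chains x ", x$config$n_iter, " iterations)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Collapse groups and refit the SDT model
#'
#' Relabels the participants of the named groups to a single merged group
#' and refits the same hierarchical model, pooling them into one
#' group-level posterior per emotion.  Collapsing trades group resolution
#' for a larger sample and hence a more precise posterior.
#'
#' @param counts SDT count data.frame.
#' @param groups_to_merge character vector of at least two distinct
#'   existing group labels.
#' @param merged_label label of the merged group.
#' @inheritParams fit_hierarchical_sdt
#' @return an `"sdt_posterior"` for the relabelled data.
#' @export
collapse_and_refit <- function(counts, groups_to_merge,
                               merged_label = paste(sort(unique(groups_to_merge)),
                                                    collapse = "+"),
                               config = mcmc_config(), seed = 1L) {
  groups_to_merge <- unique(groups_to_merge)
  if (length(groups_to_merge) < 2)
    stop("need at least two distinct groups to merge")
  unknown <- setdiff(groups_to_merge, unique(counts$group))
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  counts$group[counts$group %in% groups_to_merge] <- merged_label
  fit_hierarchical_sdt(counts, config = config, seed = seed)
}
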