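#' Default generating parameters for the behavioral simulator
#'
#' Group-level ex-Gaussian reaction-time parameters (seconds) and
#' equal-variance SDT sensitivities for a three-group developmental
#' visual-search design (first-, fifth- and ninth-grade children; groups
#' "I", "V", "IX") with three display conditions: an angry target among
#' neutral faces, a happy target among neutral faces, or no target.
#' The values are posterior medians typical of this paradigm and serve as
#' the simulator's ground truth.
#'
#' @return `default_exgauss_truth()`: data.frame with columns `group`,
#'   `condition`, `mu`, `sigma`, `tau`.  `default_sdt_truth()`: data.frame
#'   with columns `group`, `emotion`, `d`, `c`.
#' @export
default_exgauss_truth <- function() {
  data.frame(
    group = rep(c("I", "V", "IX"), each = 3),
    condition = rep(c("angry_target", "happy_target", "target_absent"), 3),
    mu    = c(3.21, 3.35, 3.33, 2.65, 2.71, 2.72, 1.58, 1.81, 2.80),
    sigma = c(0.98, 1.05, 0.93, 0.86, 0.89, 0.90, 0.51, 0.57, 0.42),
    tau   = c(1.52, 1.41, 1.55, 1.26, 1.21, 1.25, 0.57, 0.50, 0.41),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_exgauss_truth
#' @export
default_sdt_truth <- function() {
  data.frame(
    group = rep(c("I", "V", "IX"), each = 2),
    emotion = rep(c("angry", "happy"), 3),
    d = c(2.87, 2.32, 3.10, 2.74, 2.91, 2.51),
    c = 0,
    stringsAsFactors = FALSE
  )
}

#' Configuration of the behavioral-data simulator
#'
#' Bundles and validates everything the trial generator needs: the design
#' (groups, trials per participant, with exactly half of each participant's
#' trials target-absent and the present half split between angry and happy
#' targets), the group-level ex-Gaussian truth per condition, the group-level
#' SDT truth per target emotion, and the between-participant spreads.
#'
#' @param n_participants_per_group participants simulated in each group.
#' @param n_trials_per_participant trials per participant; must be even so
#'   that exactly half can be target-absent.  Default 96 (48 absent, 24
#'   angry-target, 24 happy-target).
#' @param group_labels ordered group labels.
#' @param exgauss_truth data.frame `(group, condition, mu, sigma, tau)`;
#'   every group x condition cell must be present with positive parameters.
#' @param sdt_truth data.frame `(group, emotion, d, c)`.
#' @param participant_sd named list of between-participant spreads:
#'   `mu` and `d` are relative SDs on the natural scale, `sigma` and `tau`
#'   are SDs on the log scale (guaranteeing positivity), `c` is an absolute
#'   SD (the criterion may be 0).
#' @param rng_seed integer seed; the generated dataset is a deterministic
#'   function of the configuration including this seed.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants_per_group = 30L,
                              n_trials_per_participant = 96L,
                              group_labels = c("I", "V", "IX"),
                              exgauss_truth = default_exgauss_truth(),
                              sdt_truth = default_sdt_truth(),
                              participant_sd = list(mu = 0.10, sigma = 0.10,
                                                    tau = 0.10, d = 0.10,
                                                    c = 0.10),
                              rng_seed = 1L) {
  n_trials_per_participant <- as.integer(n_trials_per_participant)
  if (n_trials_per_participant %% 2L != 0L)
    stop("n_trials_per_participant must be even: half the trials are target-absent")
  if (n_participants_per_group < 1)
    stop("n_participants_per_group must be positive")
  conditions <- c("angry_target", "happy_target", "target_absent")
  for (g in group_labels) for (cnd in conditions) {
    row <- exgauss_truth[exgauss_truth$group == g & exgauss_truth$condition == cnd, ]
    if (nrow(row) != 1)
      stop("exgauss_truth is missing cell (", g, ", ", cnd, ")")
    if (any(!is.finite(c(row$mu, row$sigma, row$tau))) ||
        any(c(row$mu, row$sigma, row$tau) <= 0))
      stop("exgauss_truth parameters must be positive in cell (", g, ", ", cnd, ")")
  }
  for (g in group_labels) for (em in c("angry", "happy")) {
    if (sum(sdt_truth$group == g & sdt_truth$emotion == em) != 1)
      stop("sdt_truth is missing cell (", g, ", ", em, ")")
  }
  structure(list(
    n_participants_per_group = as.integer(n_participants_per_group),
    n_trials_per_participant = n_trials_per_participant,
    group_labels = group_labels,
    exgauss_truth = exgauss_truth,
    sdt_truth = sdt_truth,
    participant_sd = participant_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Generate a trial-level visual-search dataset
#'
#' Simulates every trial of the design described by a [simulation_config()]:
#' per participant, exactly half the trials are target-absent and the
#' present half is split between angry and happy targets (when the present
#' half is odd, the extra trial goes to the angry target for
#' even-numbered participants and to the happy target for odd-numbered
#' ones, keeping the design deterministic).  Participant-level ex-Gaussian
#' parameters are drawn around the group truth (natural scale for mu, log
#' scale for sigma and tau); reaction times are ex-Gaussian draws from the
#' participant's condition parameters.  Responses come from an
#' equal-variance SDT observer: "different" with probability
#' Phi(d/2 - c) on target-present trials and Phi(-dbar/2 - c) on
#' target-absent trials, where dbar is the participant's mean sensitivity
#' (target-absent trials are shared between the two target emotions, so a
#' single criterion governs them).  RTs and responses are generated
#' independently given the design.
#'
#' @param config a [simulation_config()].
#' @return data.frame of trials with columns `participant_id`, `group`,
#'   `condition`, `target_present`, `response` ("different"/"same"), `rt`
#'   (seconds), `correct`.
#' @export
generate_behavioral_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  psd <- config$participant_sd
  n <- config$n_trials_per_participant
  n_absent <- n %/% 2L
  n_present <- n - n_absent
  out <- vector("list", length(config$group_labels) * config$n_participants_per_group)
  slot <- 1L
  for (g in config$group_labels) {
    exg <- config$exgauss_truth[config$exgauss_truth$group == g, ]
    sdt <- config$sdt_truth[config$sdt_truth$group == g, ]
    d_g <- setNames(sdt$d, sdt$emotion)
    c_g <- mean(sdt$c)
    for (i in seq_len(config$n_participants_per_group)) {
      # deterministic split of the present half between the two emotions
      n_angry <- n_present %/% 2L
      if (n_present %% 2L == 1L && i %% 2L == 0L) n_angry <- n_angry + 1L
      n_happy <- n_present - n_angry
      counts <- c(angry_target = n_angry, happy_target = n_happy,
                  target_absent = n_absent)

      # participant-level latent parameters
      pars <- lapply(seq_len(nrow(exg)), function(r) {
        mu_i <- -1
        while (mu_i <= 0) mu_i <- rnorm(1, exg$mu[r], psd$mu * exg$mu[r])
        list(mu = mu_i,
             sigma = rlnorm(1, log(exg$sigma[r]), psd$sigma),
             tau = rlnorm(1, log(exg$tau[r]), psd$tau))
      })
      names(pars) <- exg$condition
      d_i <- c(angry = rnorm(1, d_g[["angry"]], psd$d * abs(d_g[["angry"]])),
               happy = rnorm(1, d_g[["happy"]], psd$d * abs(d_g[["happy"]])))
      c_i <- rnorm(1, c_g, psd$c)

      trials <- lapply(names(counts), function(cnd) {
        m <- counts[[cnd]]
        if (m == 0L) return(NULL)
        p <- pars[[cnd]]
        rt <- rexgauss(m, p$mu, p$sigma, p$tau, positive_only = TRUE)
        p_diff <- switch(cnd,
          angry_target = pnorm(d_i[["angry"]] / 2 - c_i),
          happy_target = pnorm(d_i[["happy"]] / 2 - c_i),
          target_absent = pnorm(-mean(d_i) / 2 - c_i))
        resp <- ifelse(rbinom(m, 1L, p_diff) == 1L, "different", "same")
        data.frame(condition = cnd, rt = rt, response = resp,
                   stringsAsFactors = FALSE)
      })
      trials <- do.call(rbind, trials)
      trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
      trials$participant_id <- sprintf("%s_%03d", g, i)
      trials$group <- g
      trials$target_present <- trials$condition != "target_absent"
      trials$correct <- (trials$response == "different") == trials$target_present
      rownames(trials) <- NULL
      out[[slot]] <- trials[, c("participant_id", "group", "condition",
                                "target_present", "response", "rt", "correct")]
      slot <- slot + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read or write a trial table as CSV
#'
#' The on-disk format has header
#' `participant_id,group,condition,target_present,response,rt,correct`,
#' RTs in decimal seconds and booleans as `true`/`false`.
#'
#' @param trials trial data.frame as returned by
#'   [generate_behavioral_dataset()].
#' @param path file path.
#' @return `read_trial_table` returns the trial data.frame.
#' @export
write_trial_table <- function(trials, path) {
  df <- trials
  df$target_present <- ifelse(df$target_present, "true", "false")
  df$correct <- ifelse(df$correct, "true", "false")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "condition", "target_present",
            "response", "rt", "correct")
  if (!all(need %in% names(df)))
    stop("trial table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$target_present <- df$target_present %in% c("true", "TRUE", TRUE)
  df$correct <- df$correct %in% c("true", "TRUE", TRUE)
  df$group <- as.character(df$group)
  df
}
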