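#' Credible-interval overlap decision
#'
#' Two conditions are deemed credibly different when their 95% credible
#' intervals do not overlap.  A shared endpoint counts as overlap
#' (the conservative reading of the rule).  The decision is symmetric in
#' its arguments.
#'
#' @param ci_a,ci_b numeric length-2 intervals `(low, high)`.
#' @param label optional label describing the compared quantity.
#' @return list of class `"comparison_result"`: `label`, `ci_a`, `ci_b`,
#'   `overlap` (logical) and `decision` (`"credibly_different"` or
#'   `"not_distinguished"`).
#' @examples
#' ci_overlap_decision(c(1, 2), c(3, 4))$decision   # credibly_different
#' @export
ci_overlap_decision <- function(ci_a, ci_b, label = NULL) {
  stopifnot(length(ci_a) == 2, length(ci_b) == 2)
  if (ci_a[1] > ci_a[2] || ci_b[1] > ci_b[2])
    stop("intervals must be ordered (low <= high)")
  overlap <- max(ci_a[1], ci_b[1]) <= min(ci_a[2], ci_b[2])
  structure(list(label = label, ci_a = unname(ci_a), ci_b = unname(ci_b),
                 overlap = overlap,
                 decision = if (overlap) "not_distinguished" else "credibly_different"),
            class = "comparison_result")
}

#' Standardized effect size for multilevel posteriors (delta_t)
#'
#' Computes, draw by draw, the difference of two group-level means divided
#' by the square root of the summed variance components, and summarizes
#' the resulting effect-size posterior.  The caller chooses the variance
#' components (for RT contrasts the between-participant variance plus the
#' within-participant ex-Gaussian variance `sigma^2 + tau^2`; for
#' sensitivity contrasts the between-participant variance of d').  The
#' index is scale-invariant: rescaling means and SD components by a common
#' factor leaves it unchanged.
#'
#' @param draws_a,draws_b aligned numeric vectors of posterior draws of the
#'   two group-level means.
#' @param sd_component_draws list (or matrix columns) of aligned draws of
#'   the standard-deviation components; their squares are summed per draw.
#' @return list with `median`, `ci_low`, `ci_high` of the delta_t posterior
#'   and the raw `draws`.
#' @export
delta_t <- function(draws_a, draws_b, sd_component_draws) {
  if (is.matrix(sd_component_draws))
    sd_component_draws <- lapply(seq_len(ncol(sd_component_draws)),
                                 function(j) sd_component_draws[, j])
  if (!is.list(sd_component_draws)) sd_component_draws <- list(sd_component_draws)
  n <- length(draws_a)
  stopifnot(length(draws_b) == n, all(lengths(sd_component_draws) == n))
  total_var <- Reduce(`+`, lapply(sd_component_draws, function(s) s^2))
  if (any(total_var <= 0)) stop("total variance must be positive in every draw")
  d <- (draws_a - draws_b) / sqrt(total_var)
  s <- summarize_draws(d)
  list(median = s[["median"]], ci_low = s[["ci_low"]], ci_high = s[["ci_high"]],
       draws = d)
}

#' Assemble an inference report from fitted posteriors
#'
#' Collects every group x condition x parameter cell of the ex-Gaussian
#' posterior and every group x emotion sensitivity cell of the SDT
#' posterior into one machine-readable report, together with a list of
#' credible-interval comparisons and their effect sizes.  Errors if any
#' expected cell is missing or (unless overridden) if any R-hat exceeds
#' the convergence threshold.
#'
#' @param exg an `"exg_posterior"` (or NULL).
#' @param sdt an `"sdt_posterior"` (or NULL).
#' @param comparisons optional data.frame describing contrasts with columns
#'   `model` ("exgauss" or "sdt"), `group_a`, `cell_a`, `group_b`, `cell_b`
#'   where `cell` is a draws-column name (see [posterior_draws()]), plus
#'   optional `label`.  Effect sizes use the model's between-participant SD
#'   (plus, for ex-Gaussian `mu` contrasts, the within-participant
#'   ex-Gaussian SD components) as variance components.
#' @param ignore_convergence proceed despite R-hat warnings?
#' @return list of class `"inference_report"` with elements `rt_cells`,
#'   `sdt_cells`, `comparisons` (each a data.frame) and `diagnostics`.
#' @export
build_report <- function(exg = NULL, sdt = NULL, comparisons = NULL,
                         ignore_convergence = FALSE) {
  rt_cells <- sdt_cells <- NULL
  max_rhat <- 0
  if (!is.null(exg)) {
    stopifnot(inherits(exg, "exg_posterior"))
    rt_cells <- exg$summary[exg$summary$parameter %in% c("mu", "sigma", "tau"), ]
    miss <- with(rt_cells, table(group, condition))
    if (any(miss != 3))
      stop("incomplete ex-Gaussian cells: ",
           paste(names(which(apply(miss != 3, 1, any))), collapse = ", "))
    max_rhat <- max(max_rhat, exg$summary$rhat, na.rm = TRUE)
  }
  if (!is.null(sdt)) {
    stopifnot(inherits(sdt, "sdt_posterior"))
    sdt_cells <- sdt$summary[sdt$summary$parameter == "mu_d", ]
    max_rhat <- max(max_rhat, sdt$summary$rhat, na.rm = TRUE)
  }
  threshold <- (if (!is.null(exg)) exg$config$rhat_threshold
                else if (!is.null(sdt)) sdt$config$rhat_threshold else 1.01)
  if (!ignore_convergence && max_rhat > threshold)
    stop("max R-hat ", round(max_rhat, 4), " exceeds ", threshold,
         "; pass ignore_convergence = TRUE to override")

  comp_rows <- NULL
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    comp_rows <- do.call(rbind, lapply(seq_len(nrow(comparisons)), function(r) {
      cmp <- comparisons[r, ]
      fit <- if (cmp$model == "exgauss") exg else sdt
      if (is.null(fit)) stop("comparison ", r, " needs a fitted ", cmp$model, " model")
      da <- posterior_draws(fit, cmp$group_a, cmp$cell_a)
      db <- posterior_draws(fit, cmp$group_b, cmp$cell_b)
      sdc <- comparison_sd_components(fit, cmp)
      ci_a <- unname(quantile(da, c(0.025, 0.975)))
      ci_b <- unname(quantile(db, c(0.025, 0.975)))
      dec <- ci_overlap_decision(ci_a, ci_b)
      dt <- delta_t(da, db, sdc)
      data.frame(label = if (!is.null(cmp$label)) cmp$label else
                   paste(cmp$group_a, cmp$cell_a, "vs", cmp$group_b, cmp$cell_b),
                 model = cmp$model,
                 group_a = cmp$group_a, cell_a = cmp$cell_a,
                 group_b = cmp$group_b, cell_b = cmp$cell_b,
                 ci_a_low = ci_a[1], ci_a_high = ci_a[2],
                 ci_b_low = ci_b[1], ci_b_high = ci_b[2],
                 overlap = dec$overlap, decision = dec$decision,
                 delta_t_median = dt$median, delta_t_ci_low = dt$ci_low,
                 delta_t_ci_high = dt$ci_high, stringsAsFactors = FALSE)
    }))
  }
  structure(list(rt_cells = rt_cells, sdt_cells = sdt_cells,
                 comparisons = comp_rows,
                 diagnostics = list(max_rhat = max_rhat, threshold = threshold)),
            class = "inference_report")
}

# variance components for the delta_t denominator: between-participant SD
# draws of both cells; for ex-Gaussian mu contrasts also the group-level
# within-participant SD components (sigma, tau) averaged across the two cells
comparison_sd_components <- function(fit, cmp) {
  if (cmp$model == "sdt") {
    sa <- posterior_draws(fit, cmp$group_a, sub("^d\\.", "sd_d.", cmp$cell_a))
    sb <- posterior_draws(fit, cmp$group_b, sub("^d\\.", "sd_d.", cmp$cell_b))
    return(list(sqrt((sa^2 + sb^2) / 2)))
  }
  cond_a <- sub("\\.[^.]+$", "", cmp$cell_a)
  cond_b <- sub("\\.[^.]+$", "", cmp$cell_b)
  par <- sub("^.*\\.", "", cmp$cell_a)
  between_a <- posterior_draws(fit, cmp$group_a, paste0(cond_a, ".sd_", par))
  between_b <- posterior_draws(fit, cmp$group_b, paste0(cond_b, ".sd_", par))
  comps <- list(sqrt((between_a^2 + between_b^2) / 2))
  if (par == "mu") {
    sig_a <- posterior_draws(fit, cmp$group_a, paste0(cond_a, ".sigma"))
    sig_b <- posterior_draws(fit, cmp$group_b, paste0(cond_b, ".sigma"))
    tau_a <- posterior_draws(fit, cmp$group_a, paste0(cond_a, ".tau"))
    tau_b <- posterior_draws(fit, cmp$group_b, paste0(cond_b, ".tau"))
    comps <- c(comps, list(sqrt((sig_a^2 + sig_b^2) / 2),
                           sqrt((tau_a^2 + tau_b^2) / 2)))
  }
  comps
}

#' Write / read an inference report as JSON
#'
#' @param report an `"inference_report"`.
#' @param path file path (`.json`).
#' @return `read_report` returns the report (class restored).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  if (!is.null(x$rt_cells)) {
    cat("Reaction-time cells (ex-Gaussian group-level posteriors):\n")
    print(x$rt_cells, digits = 3)
  }
  if (!is.null(x$sdt_cells)) {
    cat("\nSensitivity cells (SDT group-level posteriors):\n")
    print(x$sdt_cells, digits = 3)
  }
  if (!is.null(x$comparisons)) {
    cat("\nComparisons:\n")
    print(x$comparisons[, c("label", "decision", "delta_t_median")], digits = 3)
  }
  invisible(x)
}
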