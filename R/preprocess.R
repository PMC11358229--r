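#' Tukey fence outlier filter for reaction times
#'
#' Flags values strictly above `Q3 + 1.5 IQR` or strictly below
#' `Q1 - 1.5 IQR`.  Quartiles are computed by linear interpolation between
#' order statistics (`stats::quantile` type 7), the default convention in
#' R; Tukey's hinges can differ on small samples, so the convention is
#' fixed here rather than left to chance.
#'
#' @param rts numeric vector of at least 4 finite reaction times (seconds).
#' @param k fence multiplier (1.5, the conventional value).
#' @return list with `keep` (logical mask, `TRUE` = retained), and `report`:
#'   `n_total`, `n_removed`, `fraction_removed`, `fences = c(lower, upper)`.
#' @examples
#' tukey_filter(c(1, 2, 3, 4, 100))$keep   # only 100 removed
#' @export
tukey_filter <- function(rts, k = 1.5) {
  rts <- as.numeric(rts)
  if (sum(is.finite(rts)) < 4)
    stop("tukey_filter needs at least 4 finite values")
  q <- quantile(rts, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  keep <- rts >= fences[1] & rts <= fences[2]
  keep[!is.finite(rts)] <- FALSE
  list(keep = keep,
       report = list(n_total = length(rts),
                     n_removed = sum(!keep),
                     fraction_removed = mean(!keep),
                     fences = fences))
}

#' Filter a trial table for RT outliers
#'
#' Applies [tukey_filter()] within each participant x condition cell (fences
#' computed per cell, respecting the large group and condition differences
#' in RT location), and reports the pooled fraction of removed trials.
#' Optionally restricts the RT analysis set to correct trials first
#' (the default), since RT models of search performance are conventionally
#' fit to correct responses.
#'
#' @param trials trial data.frame (see [generate_behavioral_dataset()]).
#' @param scope `"participant_condition"` (default), `"participant"`, or
#'   `"global"`: the grouping within which fences are computed.
#' @param correct_only drop incorrect trials before filtering?
#' @param k fence multiplier.
#' @return list with `trials` (the retained rows), `report` (pooled
#'   `n_total`, `n_removed`, `fraction_removed`) and `fences` (data.frame of
#'   per-scope fences).
#' @export
filter_trials <- function(trials, scope = c("participant_condition",
                                            "participant", "global"),
                          correct_only = TRUE, k = 1.5) {
  scope <- match.arg(scope)
  df <- trials
  if (correct_only) df <- df[df$correct, , drop = FALSE]
  key <- switch(scope,
    participant_condition = paste(df$participant_id, df$condition, sep = "|"),
    participant = df$participant_id,
    global = rep("all", nrow(df)))
  keep <- logical(nrow(df))
  fences <- list()
  for (kv in unique(key)) {
    idx <- which(key == kv)
    f <- tukey_filter(df$rt[idx], k = k)
    keep[idx] <- f$keep
    fences[[kv]] <- data.frame(scope = kv,
                               lower = f$report$fences[["lower"]],
                               upper = f$report$fences[["upper"]])
  }
  list(trials = df[keep, , drop = FALSE],
       report = list(n_total = nrow(df),
                     n_removed = sum(!keep),
                     fraction_removed = mean(!keep)),
       fences = do.call(rbind, c(fences, list(make.row.names = FALSE))))
}

#' Reduce trials to signal-detection count data
#'
#' For each participant and target emotion: hits are target-present trials
#' of that emotion answered "different"; false alarms are target-absent
#' trials answered "different".  Target-absent trials are common to both
#' emotions, so the same noise counts appear in both emotion rows of a
#' participant.
#'
#' @param trials trial data.frame.
#' @return data.frame with columns `participant_id`, `group`, `emotion`,
#'   `n_signal`, `n_hits`, `n_noise`, `n_false_alarms`.
#' @export
to_sdt_counts <- function(trials) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(pid) {
    tp <- trials[trials$participant_id == pid, , drop = FALSE]
    absent <- tp[tp$condition == "target_absent", , drop = FALSE]
    if (nrow(absent) == 0)
      stop("participant ", pid, " has no target-absent trials")
    n_noise <- nrow(absent)
    n_fa <- sum(absent$response == "different")
    do.call(rbind, lapply(c("angry", "happy"), function(em) {
      sig <- tp[tp$condition == paste0(em, "_target"), , drop = FALSE]
      data.frame(participant_id = pid, group = tp$group[1], emotion = em,
                 n_signal = nrow(sig),
                 n_hits = sum(sig$response == "different"),
                 n_noise = n_noise, n_false_alarms = n_fa,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
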