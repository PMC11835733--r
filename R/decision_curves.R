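# Decision-curve analysis ------------------------------------------------
#
# Net benefit at threshold t weighs false positives against true
# positives at the exchange rate t/(1-t): at a 10% threshold, nine
# needless interventions are accepted to catch one event. The companion
# quantity counts net interventions avoided in true-negative units.

#' Net benefit at a single threshold
#'
#' `NB = TP/N - (FP/N) * t/(1-t)` with `treated = risk >= t`; the
#' companion `NB_avoided = TN/N - (FN/N) * (1-t)/t`.
#'
#' @param risk Predicted event probabilities.
#' @param outcome 0/1 vector.
#' @param p_t Threshold probability in (0, 1).
#' @return List with `nb` and `nb_avoided`.
#' @export
net_benefit <- function(risk, outcome, p_t) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must be in (0, 1)")
  stopifnot(all(risk >= 0 & risk <= 1), all(outcome %in% 0:1))
  n <- length(outcome)
  treated <- risk >= p_t
  tp <- sum(treated & outcome == 1)
  fp <- sum(treated & outcome == 0)
  tn <- sum(!treated & outcome == 0)
  fn <- sum(!treated & outcome == 1)
  list(nb = tp / n - (fp / n) * p_t / (1 - p_t),
       nb_avoided = tn / n - (fn / n) * (1 - p_t) / p_t)
}

.curve_one_cohort <- function(risks, outcome, thresholds) {
  strategies <- c(names(risks), "treat_all", "treat_none")
  out <- expand.grid(strategy = strategies, threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$net_benefit <- NA_real_
  out$nb_avoided <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- out$strategy[i]
    t <- out$threshold[i]
    r <- switch(s,
                treat_all = rep(1, length(outcome)),
                treat_none = rep(0, length(outcome)),
                risks[[s]])
    nb <- net_benefit(r, outcome, t)
    out$net_benefit[i] <- nb$nb
    out$nb_avoided[i] <- nb$nb_avoided
  }
  out
}

#' Decision curves across thresholds and cohorts
#'
#' Net benefit per strategy per threshold within each cohort, then the
#' unweighted mean across cohorts; treat-all and treat-none reference
#' strategies are always included. Cohorts without events are skipped
#' with a warning.
#'
#' @param risks Named list of risk vectors (one per model), or — for
#'   multiple cohorts — a list of such named lists.
#' @param outcome 0/1 vector, or list of vectors (one per cohort).
#' @param thresholds Threshold grid (default 0.001 to 0.15 by 0.001).
#' @return Tidy data.frame: `strategy`, `threshold`, `net_benefit`,
#'   `nb_avoided`, `cohort` (cohort id or `"pooled"`).
#' @export
decision_curve <- function(risks, outcome,
                           thresholds = seq(0.001, 0.15, by = 0.001)) {
  multi <- is.list(outcome)
  if (!multi) {
    risks <- list(risks)
    outcome <- list(outcome)
  }
  per <- NULL
  for (cid in seq_along(outcome)) {
    if (sum(outcome[[cid]]) == 0) {
      warning(sprintf("cohort %d has no events; skipped", cid))
      next
    }
    cc <- .curve_one_cohort(risks[[cid]], outcome[[cid]], thresholds)
    cc$cohort <- as.character(cid)
    per <- rbind(per, cc)
  }
  if (is.null(per)) stop("no cohort with events")
  pooled <- stats::aggregate(cbind(net_benefit, nb_avoided) ~ strategy + threshold,
                             data = per, FUN = mean)
  pooled$cohort <- "pooled"
  rbind(per, pooled[names(per)])
}

#' True positives / negatives gained per 10,000 individuals
#'
#' Converts the net-benefit difference between a full and a base model at
#' a focal threshold into counts per 10,000: `1e4 * (NB_full - NB_base)`
#' for true positives and the analogue on the interventions-avoided scale
#' for true negatives.
#'
#' @param curve Tidy curve from [decision_curve()] (pooled rows are used
#'   when present).
#' @param base,full Strategy names to compare.
#' @param p_t Focal threshold (default 0.10).
#' @return List with `delta_tp_per_10000`, `delta_tn_per_10000`.
#' @export
delta_per_10000 <- function(curve, base, full, p_t = 0.10) {
  rows <- curve[curve$cohort == (if ("pooled" %in% curve$cohort) "pooled" else curve$cohort[1]), ]
  at <- function(s) {
    r <- rows[rows$strategy == s & abs(rows$threshold - p_t) < 1e-9, ]
    if (!nrow(r)) stop(sprintf("threshold %.3f not on the curve grid", p_t))
    r
  }
  b <- at(base)
  f <- at(full)
  list(delta_tp_per_10000 = 1e4 * (f$net_benefit - b$net_benefit),
       delta_tn_per_10000 = 1e4 * (f$nb_avoided - b$nb_avoided))
}

#' Profile-specific decision curves
#'
#' Recomputes every count with each profile's allocation probabilities as
#' weights: `TP_k = sum(p_ik * treated * event)` and so on, with the
#' profile's total weight as denominator. Weighted per-profile net
#' benefits, averaged with the profile weights, reproduce the overall
#' curve exactly. Profiles with near-zero total weight are suppressed
#' with a warning.
#'
#' @param risks Named list of risk vectors.
#' @param outcome 0/1 vector.
#' @param alloc Allocation matrix (rows sum to 1).
#' @param thresholds Threshold grid.
#' @return Tidy data.frame with a `profile` column.
#' @export
profile_specific_curves <- function(risks, outcome, alloc,
                                    thresholds = seq(0.001, 0.15, by = 0.001)) {
  stopifnot(nrow(alloc) == length(outcome))
  out <- NULL
  for (lab in colnames(alloc)) {
    w <- alloc[, lab]
    if (sum(w) < 1e-8) {
      warning(sprintf("profile '%s' has near-zero weight; curve suppressed", lab))
      next
    }
    for (s in names(risks)) {
      for (t in thresholds) {
        treated <- risks[[s]] >= t
        sw <- sum(w)
        tp <- sum(w[treated & outcome == 1])
        fp <- sum(w[treated & outcome == 0])
        tn <- sum(w[!treated & outcome == 0])
        fn <- sum(w[!treated & outcome == 1])
        out <- rbind(out, data.frame(
          profile = lab, strategy = s, threshold = t,
          net_benefit = tp / sw - (fp / sw) * t / (1 - t),
          nb_avoided = tn / sw - (fn / sw) * (1 - t) / t,
          weight = sw, stringsAsFactors = FALSE))
      }
    }
  }
  out
}
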