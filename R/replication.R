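# Cross-cohort profile replication ---------------------------------------

#' Match discordant profiles between two mixtures
#'
#' Greedy one-to-one matching of discordant components by descending
#' cosine similarity of their mean residual vectors; pairs below
#' `min_similarity` are never matched. The concordant components are
#' matched to each other by definition.
#'
#' @param discovery,validation `mixture_model` objects sharing the
#'   biomarker order.
#' @param min_similarity Similarity below which a pair is left unmatched
#'   (default 0.5).
#' @return data.frame with `discovery_label`, `validation_label` (NA when
#'   unmatched) and `similarity`.
#' @export
match_profiles <- function(discovery, validation, min_similarity = 0.5) {
  d_lab <- setdiff(discovery$labels, discovery$concordant)
  v_lab <- setdiff(validation$labels, validation$concordant)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  out <- data.frame(discovery_label = d_lab,
                    validation_label = NA_character_,
                    similarity = NA_real_, stringsAsFactors = FALSE)
  if (!length(d_lab) || !length(v_lab)) return(out)
  sim <- outer(seq_along(d_lab), seq_along(v_lab), Vectorize(function(i, j) {
    cosine(discovery$means[d_lab[i], ], validation$means[v_lab[j], ])
  }))
  repeat {
    best <- which(sim == max(sim), arr.ind = TRUE)[1, , drop = TRUE]
    if (!is.finite(sim[best[1], best[2]]) ||
        sim[best[1], best[2]] < min_similarity) break
    out$validation_label[best[1]] <- v_lab[best[2]]
    out$similarity[best[1]] <- sim[best[1], best[2]]
    sim[best[1], ] <- -Inf
    sim[, best[2]] <- -Inf
    if (all(!is.finite(sim))) break
  }
  out
}

#' Test which discovery profiles replicate in validation cohorts
#'
#' For each discordant discovery profile, the discovery individuals
#' allocated to it with probability above `threshold` are re-scored under
#' each validation mixture; the profile replicates if the median
#' probability of the matched validation profile exceeds `threshold` in
#' every validation cohort.
#'
#' @param discovery_alloc Allocation matrix of the discovery cohort under
#'   the discovery mixture.
#' @param discovery Discovery `mixture_model`.
#' @param validations List of validation `mixture_model`s.
#' @param discovery_residuals Residual matrix of the discovery cohort
#'   (needed to score its individuals under the validation mixtures).
#' @param threshold Allocation probability defining confident membership
#'   (default 0.8).
#' @return List with `replicated` (character vector of labels) and
#'   `report` (one row per profile x validation cohort).
#' @export
replication_test <- function(discovery_alloc, discovery, validations,
                             discovery_residuals, threshold = 0.8) {
  stopifnot(length(validations) >= 1L)
  x <- if (inherits(discovery_residuals, "residual_matrix"))
    discovery_residuals$values else discovery_residuals
  d_lab <- setdiff(discovery$labels, discovery$concordant)
  report <- NULL
  replicated <- character(0)
  for (lab in d_lab) {
    members <- which(discovery_alloc[, lab] > threshold)
    if (!length(members)) {
      warning(sprintf("no individuals allocated to '%s' above %.2f", lab,
                      threshold))
      report <- rbind(report, data.frame(
        profile = lab, cohort = seq_along(validations),
        matched = NA_character_, median_prob = NA_real_, pass = FALSE))
      next
    }
    pass_all <- TRUE
    for (v in seq_along(validations)) {
      match <- match_profiles(discovery, validations[[v]])
      vlab <- match$validation_label[match$discovery_label == lab]
      if (is.na(vlab)) {
        med <- NA_real_
        ok <- FALSE
      } else {
        va <- allocate(validations[[v]], x[members, , drop = FALSE])
        med <- stats::median(va[, vlab])
        ok <- med > threshold
      }
      pass_all <- pass_all && ok
      report <- rbind(report, data.frame(
        profile = lab, cohort = v, matched = vlab, median_prob = med,
        pass = ok, stringsAsFactors = FALSE))
    }
    if (pass_all) replicated <- c(replicated, lab)
  }
  list(replicated = replicated, report = report)
}

#' Finalize the mixture after replication
#'
#' Drops discordant components that failed replication, refits the weights
#' with fixed moments and returns fresh allocations. The concordant
#' component is always retained.
#'
#' @param discovery Discovery `mixture_model`.
#' @param replicated Character vector of replicated discordant labels.
#' @param residuals Residual matrix of the discovery cohort.
#' @return List with `mixture` and `alloc`.
#' @export
finalize_model <- function(discovery, replicated, residuals) {
  keep <- c(replicated, discovery$concordant)
  idx <- which(discovery$labels %in% keep)
  if (!length(replicated)) warning("no discordant profile replicated")
  mix <- discovery
  mix$labels <- discovery$labels[idx]
  mix$means <- discovery$means[idx, , drop = FALSE]
  mix$covs <- discovery$covs[idx]
  mix$weights <- discovery$weights[idx] / sum(discovery$weights[idx])
  mix <- fit_mixture_weights(mix, residuals)
  list(mixture = mix, alloc = allocate(mix, residuals))
}
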