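#' Posterior error probability at a score
#'
#' The PEP (also called the local false discovery rate) of a score under a
#' fitted mixture model; delegates to [e_step()].
#'
#' @param model A [mixture_model()].
#' @param s Numeric vector of scores.
#' @param levels Optional discrete levels (see [e_step()]).
#' @return Numeric vector of PEPs.
#' @export
pep_at <- function(model, s, levels = NULL) {
  e_step(model, s, levels)
}

#' P-value of a score under the incorrect-match distribution
#'
#' `P(S > s | T = 0)`: the upper tail of the negative component past the
#' observed score (closed form for the Gamma and Gumbel; per-kernel Normal
#' tails for kernel components). [fpr_at()] is the set-level reading of the
#' same tail — the probability that an incorrect match exceeds the cutoff —
#' and is identical by definition.
#'
#' @param model A [mixture_model()].
#' @param s,t Numeric vector of scores / cutoffs.
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @export
p_value_at <- function(model, s) {
  component_tail(model$negative, s)
}

#' @rdname p_value_at
#' @export
fpr_at <- function(model, t) {
  p_value_at(model, t)
}

#' Model-based false discovery rate at a cutoff
#'
#' `FDR(t) = pi0 A0 / (pi0 A0 + (1 - pi0) A1)` with
#' `A_c = P(S > t | T = c)` the component upper tails — the ratio of the
#' incorrect-component mass above the cutoff to the total mass above it.
#' Supplying `condition` (e.g. `list(nmc = 0)`) multiplies each component's
#' tail by that component's probability of the conditioned level, giving the
#' FDR restricted to matches with that feature value; because correct
#' matches usually concentrate on the "good" levels (say, 0 missed
#' cleavages), the conditional FDR at the same cutoff is typically lower.
#'
#' @param model A [mixture_model()] (discrete tables required for
#'   `condition`).
#' @param t Numeric vector of score cutoffs.
#' @param condition Optional named list/vector mapping fitted discrete
#'   features to a level, e.g. `list(nmc = 0)`.
#' @return Numeric vector of FDR estimates in `[0, 1]`.
#' @export
fdr_model <- function(model, t, condition = NULL) {
  a0 <- component_tail(model$negative, t)
  a1 <- component_tail(model$positive, t)
  if (!is.null(condition)) {
    for (feat in names(condition)) {
      tab <- model$discrete[[feat]]
      if (is.null(tab))
        stop("no fitted discrete table for feature `", feat, "`",
             call. = FALSE)
      i <- match(condition[[feat]], tab$levels)
      if (is.na(i))
        stop("level ", condition[[feat]], " not in the fitted table for `",
             feat, "`", call. = FALSE)
      a0 <- a0 * tab$p_incorrect[i]
      a1 <- a1 * tab$p_correct[i]
    }
  }
  num <- model$pi0 * a0
  den <- num + (1 - model$pi0) * a1
  if (any(den == 0))
    stop("empty rejection region: no mixture mass above cutoff ",
         signif(t[which(den == 0)[1]], 6), call. = FALSE)
  num / den
}

#' Mean-PEP false discovery rate at a cutoff
#'
#' Interprets each PEP as a local false discovery rate and averages over the
#' accepted set: `FDR(t) = sum_{s_i >= t} PEP_i / #\{s_i >= t\}`. Note the
#' `>=` convention for the accepted set, versus the strict `>` of the tail
#' formulas.
#'
#' @param peps Numeric vector of per-record PEPs.
#' @param scores Numeric score vector, same length.
#' @param t Score cutoff (scalar).
#' @return The estimated FDR of the set `{s_i >= t}`.
#' @export
fdr_mean_pep <- function(peps, scores, t) {
  stopifnot(length(peps) == length(scores), length(t) == 1)
  keep <- scores >= t
  if (!any(keep))
    stop("no scores at or above cutoff ", signif(t, 6), call. = FALSE)
  mean(peps[keep])
}

#' Target-decoy ratio estimate of the FDR
#'
#' The ratio of decoy to target matches above the cutoff,
#' `#\{decoys > t\} / #\{targets > t\}`. Under a search with as many decoy
#' as incorrect-target opportunities, this estimates the fraction of
#' accepted targets that are incorrect.
#'
#' @param table A PSM table with `discriminant_score` and `is_decoy`.
#' @param t Score cutoff (scalar).
#' @return Non-negative ratio (0 when no decoy exceeds `t`).
#' @export
fdr_decoy_ratio <- function(table, t) {
  stopifnot(length(t) == 1)
  if (!"is_decoy" %in% names(table) || !any(table$is_decoy))
    stop("table has no decoy records", call. = FALSE)
  if (!any(!table$is_decoy))
    stop("table has no target records", call. = FALSE)
  s <- table$discriminant_score
  n_target <- sum(!table$is_decoy & s > t)
  if (n_target == 0)
    stop("no target scores above cutoff ", signif(t, 6), call. = FALSE)
  sum(table$is_decoy & s > t) / n_target
}

#' Q-values from cutoff-indexed FDR estimates
#'
#' The q-value of a score is the minimum estimated FDR over all cutoffs at
#' or below that score: `q(s) = min_{c <= s} FDR(c)` over the observed
#' cutoffs. Unlike the raw FDR curve, the q-value is monotone
#' (non-increasing in the score), so relaxing a threshold never appears to
#' *reduce* the error rate.
#'
#' @param scores Numeric vector of observed scores (used as the cutoffs).
#' @param fdr Either a numeric vector of FDR estimates aligned with
#'   `scores`, or a function `fdr(t)` evaluated at each observed score.
#' @return Numeric vector of q-values aligned with the input order.
#' @examples
#' q_values(c(1, 2, 3), c(0.05, 0.03, 0.04))  # 0.05, 0.03, 0.03
#' @export
q_values <- function(scores, fdr) {
  stopifnot(length(scores) >= 1)
  if (is.function(fdr)) fdr <- vapply(scores, fdr, numeric(1))
  stopifnot(length(fdr) == length(scores))
  ord <- order(scores)
  q_sorted <- cummin(fdr[ord])
  out <- numeric(length(scores))
  out[ord] <- q_sorted
  out
}

#' Assemble a per-record confidence table
#'
#' Combines a fitted mixture with its PSM table into one tibble holding, per
#' record: the score, PEP, p-value, the FDR of the set accepted at that
#' record's score, and the q-value. FDR estimates use either the
#' model-based tail formula ([fdr_model()]) or the mean-PEP average
#' ([fdr_mean_pep()]); q-values are cumulative minima over the observed
#' scores within each charge. The accepted sets behind the mean-PEP FDR and
#' the q-values contain target records only (decoys, pinned to PEP 1 under
#' the semisupervised fit, would mechanically inflate them); decoy rows
#' inherit the q-value at their score.
#'
#' @param fit A `psmix_fit` covering every charge in `table`.
#' @param table The PSM table the fit was run on.
#' @param fdr_method `"model"` or `"mean_pep"`.
#' @return A tibble of class `psmix_confidence` with columns `spectrum_id`,
#'   `charge`, `rank`, `is_decoy`, `score`, `pep`, `p_value`, `fdr`,
#'   `q_value`.
#' @export
build_confidence_table <- function(fit, table,
                                   fdr_method = c("model", "mean_pep")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(fit, "psmix_fit"))
  table <- validate_psm_table(table)
  if (!"is_decoy" %in% names(table)) table$is_decoy <- FALSE
  missing_ch <- setdiff(unique(table$charge), as.integer(names(fit$models)))
  missing_ch <- setdiff(missing_ch, fit$skipped)
  if (length(missing_ch) > 0)
    stop("no fitted model for charge ", missing_ch[1], call. = FALSE)

  out <- vector("list", length(fit$models))
  for (k in seq_along(fit$models)) {
    ch <- as.integer(names(fit$models)[k])
    model <- fit$models[[k]]
    idx <- which(table$charge == ch)
    s <- table$discriminant_score[idx]
    pep <- fit$pep[idx]
    tgt <- !table$is_decoy[idx]
    fdr_t <- if (fdr_method == "model") {
      fdr_model(model, s)
    } else {
      st_sorted <- sort(s[tgt])
      pt_desc <- pep[tgt][order(s[tgt], decreasing = TRUE)]
      cm <- cumsum(pt_desc) / seq_along(pt_desc)  # mean PEP of the top-k set
      n_acc <- length(st_sorted) - findInterval(s, st_sorted, left.open = TRUE)
      ifelse(n_acc > 0, cm[pmax(n_acc, 1)], NA_real_)
    }
    # q-values over target cutoffs; non-target rows interpolate by score
    q_t <- q_values(s[tgt], fdr_t[tgt])
    q_all <- numeric(length(s))
    q_all[tgt] <- q_t
    if (any(!tgt)) {
      st_ord <- sort(s[tgt])
      q_ord <- q_t[order(s[tgt])]
      pos <- findInterval(s[!tgt], st_ord)
      q_all[!tgt] <- ifelse(pos == 0, q_ord[1], q_ord[pmax(pos, 1)])
    }
    out[[k]] <- tibble::tibble(
      spectrum_id = table$spectrum_id[idx],
      charge = ch,
      rank = table$rank[idx] %||% 1L,
      is_decoy = table$is_decoy[idx],
      score = s,
      pep = pep,
      p_value = p_value_at(model, s),
      fdr = fdr_t,
      q_value = q_all
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "fdr_method") <- fdr_method
  class(res) <- c("psmix_confidence", class(res))
  res
}
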