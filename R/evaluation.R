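#' ROC and precision-recall analysis
#'
#' Computes the ROC curve (AUROC by the trapezoidal rule over the unique
#' score thresholds) and the precision-recall curve (AUPRC by step-wise
#' integration, no interpolation; the curve starts at the first achievable
#' operating point rather than an extrapolated recall-0 precision).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return An object of class `ecg_eval`: list with `roc` (data frame fpr,
#'   tpr, threshold), `pr` (data frame recall, precision, threshold),
#'   `auroc`, `auprc` and `counts` (per-threshold confusion counts).
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute ROC/PR curves")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative counts at the last index of each run
  n <- length(s)
  is_last <- c(s[-n] != s[-1], TRUE)
  tp <- cumsum(y)[is_last]
  fp <- cumsum(1 - y)[is_last]
  thr <- s[is_last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(
    roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
    pr = data.frame(recall = recall, precision = precision, threshold = thr),
    auroc = auroc,
    auprc = auprc,
    counts = data.frame(threshold = thr, tp = tp, fp = fp,
                        fn = P - tp, tn = N - fp)
  ), class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat(sprintf("<ecg_eval> AUROC %.4f, AUPRC %.4f (%d thresholds)\n",
              x$auroc, x$auprc, nrow(x$counts)))
  invisible(x)
}

#' Operating point at a matched specificity
#'
#' Selects the smallest decision threshold whose specificity is at least
#' `target_specificity` (prediction positive when score >= threshold).
#' Because sensitivity is non-increasing in the threshold, this is the
#' operating point with the highest sensitivity subject to the specificity
#' constraint; on a discrete ROC curve the achieved specificity may exceed
#' the target.
#'
#' @param scores,labels As in [roc_pr()].
#' @param target_specificity Target specificity in (0, 1).
#' @return List with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
sensitivity_at_specificity <- function(scores, labels, target_specificity) {
  if (length(target_specificity) != 1L || target_specificity <= 0 ||
      target_specificity >= 1) {
    stop("`target_specificity` must be in (0, 1)")
  }
  ev <- roc_pr(scores, labels)
  ct <- ev$counts
  spec <- ct$tn / (ct$tn + ct$fp)
  ok <- which(spec >= target_specificity)
  if (!length(ok)) {
    # predicting all-negative (threshold above every score) has
    # specificity 1, so this is unreachable for valid targets
    stop("target specificity ", target_specificity, " is unattainable")
  }
  i <- max(ok)   # counts are ordered by decreasing threshold
  tp <- ct$tp[i]; fp <- ct$fp[i]; fn <- ct$fn[i]; tn <- ct$tn[i]
  list(
    threshold = ct$threshold[i],
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# Placement values (structural components) of paired AUC estimation, via
# midranks: V10[i] = mean_j psi(X_i, Y_j), V01[j] = mean_i psi(X_i, Y_j),
# psi = 1 if X > Y, 1/2 if tie, 0 otherwise.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors computed on the same labeled
#' cases, using the placement-value (structural-component) variance
#' estimate of the AUC difference and a two-sided normal p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary labels.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present for the DeLong test")
  }
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  z <- if (var_diff > 0) d / sqrt(var_diff) else 0
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff, z = z,
       p_value = if (var_diff > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

#' Categorize an automatic interpretation text
#'
#' Phrase-based categorization of commercial 12-lead interpretation
#' statements as suggestive of myocardial infarction.  Criterion 1 matches
#' "ACUTE MI", "ST elevation" or "infarct"; criterion 2 additionally
#' matches "T wave abnormality", "ST abnormality" and "ST depression", so
#' its positives are a superset of criterion 1's.  Matching is
#' case-insensitive substring matching after whitespace normalization.
#'
#' @param text Character vector of interpretation strings (may be empty or
#'   `NA`; both yield `FALSE`).
#' @param criterion 1 or 2.
#' @return Logical vector.
#' @export
categorize_interpretation <- function(text, criterion = 1L) {
  if (length(criterion) != 1L || !criterion %in% c(1L, 2L)) {
    stop("`criterion` must be 1 or 2")
  }
  phrases <- c("acute mi", "st elevation", "infarct")
  if (criterion == 2L) {
    phrases <- c(phrases, "t wave abnormality", "st abnormality",
                 "st depression")
  }
  norm <- tolower(gsub("\\s+", " ", trimws(as.character(text))))
  out <- rep(FALSE, length(norm))
  for (ph in phrases) {
    out <- out | grepl(ph, norm, fixed = TRUE)
  }
  out[is.na(text)] <- FALSE
  out
}

#' Evaluate a trained model on records for a target lead set
#'
#' Convenience wrapper: slices the records, masks every lead outside the
#' target set, scores, and computes ROC/PR plus (optionally) the operating
#' point matched to a target specificity.
#'
#' @param model An [init_model()] model (typically trained).
#' @param data List from [as_model_input()].
#' @param set A [lead_set()].
#' @param match_specificity Optional specificity to match.
#' @return List with `scores`, `eval` (an `ecg_eval`) and, when requested,
#'   `operating_point`.
#' @export
evaluate_lead_set <- function(model, data, set, match_specificity = NULL) {
  res <- evaluate_model(model, data, as_lead_mask(set))
  ev <- roc_pr(res$prob, data$labels)
  out <- list(scores = res$prob, eval = ev)
  if (!is.null(match_specificity)) {
    out$operating_point <- sensitivity_at_specificity(
      res$prob, data$labels, match_specificity)
  }
  out
}
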