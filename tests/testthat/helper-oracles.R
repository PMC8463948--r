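# Independent oracles used across the suite.  Each is a deliberately
# naive/brute-force implementation, kept separate from the package code
# paths it checks.

# All limb-lead coefficient rows in the (I, II) basis -- restated here
# independently from the hexaxial definitions.
oracle_limb_coef <- rbind(
  I   = c(1, 0),
  II  = c(0, 1),
  III = c(-1, 1),           # Einthoven: III = II - I
  aVR = c(-0.5, -0.5),      # aVR = -(I + II)/2
  aVL = c(1, -0.5),         # aVL = I - II/2
  aVF = c(-0.5, 1)          # aVF = II - I/2
)

# Brute-force enumeration of lead sets satisfying the textual constraints:
# members are lead I, the slot-2 derived lead II, or precordial leads;
# multi-lead sets contain I; sets of 3+ leads contain II; members of 2-4
# lead sets come from pairwise distinct slots.
oracle_lead_sets <- function(n_leads) {
  if (n_leads == 12) return(list(asyncecg::lead_order()))
  if (n_leads == 1) return(list("I", "II"))
  universe <- c("I", "II", paste0("V", 1:6))
  slot <- c(I = 1, II = 2, V1 = 3, V2 = 3, V3 = 3, V4 = 4, V5 = 4, V6 = 4)
  combs <- utils::combn(universe, n_leads, simplify = FALSE)
  keep <- Filter(function(s) {
    if (!"I" %in% s) return(FALSE)
    if (n_leads >= 3 && !"II" %in% s) return(FALSE)
    !anyDuplicated(slot[s])
  }, combs)
  keep
}

# Pairwise Mann-Whitney AUROC with ties counted 1/2.
oracle_auroc_mw <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(x) * length(y))
}

# Exhaustive threshold scan for the matched-specificity operating point:
# over every candidate threshold (predict positive when score >= t), keep
# those with specificity >= target, and among them the highest sensitivity.
oracle_operating_point <- function(scores, labels, target) {
  cand <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    spec <- tn / (tn + fp)
    if (spec >= target) {
      sens <- tp / (tp + fn)
      # >= : among equal sensitivities keep the smallest threshold,
      # matching the documented tie-break
      if (is.null(best) || sens >= best$sensitivity) {
        best <- list(threshold = t, sensitivity = sens, specificity = spec,
                     ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                     npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
      }
    }
  }
  best
}

# Direct double-loop computation of the DeLong structural components.
oracle_delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(x, function(xi) mean(vapply(y, function(yj) psi(xi, yj),
                                            numeric(1))), numeric(1))
  v01 <- vapply(y, function(yj) mean(vapply(x, function(xi) psi(xi, yj),
                                            numeric(1))), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

# Reference dense 1-D convolution (direct summation, "same" padding).
oracle_conv1d <- function(X, W, bias, L, nseg, k, stride) {
  C_in <- nrow(X); C_out <- nrow(W)
  Lout <- ceiling(L / stride)
  pad_left <- ((Lout - 1) * stride + k - L) %/% 2
  Y <- matrix(0, C_out, Lout * nseg)
  Warr <- array(W, c(C_out, C_in, k))
  for (s in seq_len(nseg)) for (t in seq_len(Lout)) {
    acc <- bias
    for (j in seq_len(k)) {
      src <- (t - 1) * stride + (j - 1) - pad_left + 1
      if (src >= 1 && src <= L) {
        acc <- acc + Warr[, , j] %*% X[, (s - 1) * L + src, drop = FALSE]
      }
    }
    Y[, (s - 1) * Lout + t] <- acc
  }
  Y
}
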