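#' Training configuration
#'
#' Optimizer, masking and augmentation settings.  The optimizer is Adam
#' with batch size 32 and learning rate 0.001; weight decay and the
#' augmentation magnitudes are documented package defaults.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 coefficient added to weight gradients (batch-norm
#'   scale/shift excluded).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation AUROC.
#' @param mask_prob Per-lead probability of masking during training; a
#'   fresh mask is drawn per sample per step (all-masked draws rejected).
#' @param aug_prob Probability that each augmentation is applied to a
#'   segment.
#' @param noise_sd SD (mV) of additive Gaussian noise augmentation.
#' @param time_scale_range Range of the random time-scaling factor
#'   (resampled back to the original length).
#' @param signal_mask_max_frac Max fraction of the segment zeroed by the
#'   signal-masking augmentation.
#' @param seed Integer seed; all training randomness flows from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L,
                         learning_rate = 1e-3,
                         weight_decay = 1e-4,
                         max_epochs = 20L,
                         patience = 10L,
                         mask_prob = 0.5,
                         aug_prob = 0.5,
                         noise_sd = 0.05,
                         time_scale_range = c(0.9, 1.1),
                         signal_mask_max_frac = 0.1,
                         seed = 1L) {
  stopifnot(batch_size >= 1L, mask_prob >= 0, mask_prob < 1,
            learning_rate > 0, length(time_scale_range) == 2L)
  structure(list(
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), mask_prob = mask_prob,
    aug_prob = aug_prob, noise_sd = noise_sd,
    time_scale_range = time_scale_range,
    signal_mask_max_frac = signal_mask_max_frac,
    seed = as.integer(seed)
  ), class = "train_config")
}

#' Draw random lead masks for training
#'
#' Each of the 12 leads is masked independently with probability
#' `mask_prob`; draws where every lead would be masked are rejected and
#' redrawn, so every returned mask has at least one available lead.
#'
#' @param n Number of masks to draw.
#' @param mask_prob Per-lead masking probability.
#' @return If `n == 1`, a [lead_mask()]; otherwise an `n x 12` logical
#'   availability matrix.
#' @export
sample_lead_mask <- function(n = 1L, mask_prob = 0.5) {
  avail <- matrix(stats::runif(n * 12L) >= mask_prob, n, 12L)
  bad <- which(rowSums(avail) == 0L)
  while (length(bad)) {
    avail[bad, ] <- stats::runif(length(bad) * 12L) >= mask_prob
    bad <- bad[rowSums(avail[bad, , drop = FALSE]) == 0L]
  }
  if (n == 1L) lead_mask(avail[1L, ]) else avail
}

# Zero a contiguous window covering floor(frac * length(x)) samples,
# starting at `start` (1-based).
mask_signal_window <- function(x, frac, start = 1L) {
  n0 <- floor(frac * length(x))
  if (n0 >= 1L) {
    start <- min(start, length(x) - n0 + 1L)
    x[start:(start + n0 - 1L)] <- 0
  }
  x
}

# Time-scale by factor `f` then resample back to the original length
# (linear interpolation).
time_scale_segment <- function(x, f) {
  n <- length(x)
  m <- max(2L, round(n * f))
  xs <- stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
  stats::approx(seq_len(m), xs, xout = seq(1, m, length.out = n))$y
}

#' Augment a lead segment
#'
#' Applies, each with independent probability `config$aug_prob`: additive
#' Gaussian noise (`noise_sd` mV), random time scaling (factor drawn from
#' `time_scale_range`, resampled back to the original length) and signal
#' masking (a random contiguous window of up to `signal_mask_max_frac` of
#' the segment zeroed).  Output length always equals input length.
#'
#' @param x Numeric segment.
#' @param config A [train_config()].
#' @return Augmented segment.
#' @export
augment_segment <- function(x, config) {
  p <- config$aug_prob
  if (stats::runif(1) < p && config$noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = config$noise_sd)
  }
  if (stats::runif(1) < p) {
    f <- stats::runif(1, config$time_scale_range[1], config$time_scale_range[2])
    x <- time_scale_segment(x, f)
  }
  if (stats::runif(1) < p && config$signal_mask_max_frac > 0) {
    frac <- stats::runif(1, 0, config$signal_mask_max_frac)
    start <- sample.int(length(x), 1L)
    x <- mask_signal_window(x, frac, start)
  }
  x
}

#' Patient-grouped train/validation/test split
#'
#' Splits records into training/validation (80%) and held-out test (20%)
#' sets by patient, then splits training/validation into training (85%)
#' and validation (15%), again by patient.  No patient appears in more
#' than one partition; the split is deterministic for a given RNG state.
#'
#' @param records List of [ecg_record()]s (or any objects with a
#'   `subject_id` field).
#' @param trainval_fraction Fraction of patients in training+validation.
#' @param train_fraction Fraction of training+validation patients used for
#'   training.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   into `records`.
#' @export
split_by_patient <- function(records, trainval_fraction = 0.80,
                             train_fraction = 0.85) {
  if (!length(records)) stop("no records to split")
  stopifnot(trainval_fraction > 0, trainval_fraction < 1,
            train_fraction > 0, train_fraction < 1)
  subjects <- vapply(records, function(r) r$subject_id, character(1))
  uniq <- unique(subjects)
  perm <- sample(uniq)
  n_tv <- round(trainval_fraction * length(uniq))
  tv <- perm[seq_len(n_tv)]
  test <- perm[-seq_len(n_tv)]
  n_tr <- round(train_fraction * length(tv))
  train <- tv[seq_len(n_tr)]
  val <- tv[-seq_len(n_tr)]
  list(train = which(subjects %in% train),
       validation = which(subjects %in% val),
       test = which(subjects %in% test))
}

#' Convert records to the model input tensor
#'
#' Slices the 12 asynchronous 2.5 s segments of every record (deriving
#' missing limb leads where possible) into an
#' `input_samples x 12 x n` array in canonical lead order.
#'
#' @param records List of [ecg_record()]s.
#' @param input_samples Samples per segment.
#' @return List with `segments` (array), `labels` (integer vector) and
#'   `subjects` (character vector).
#' @export
as_model_input <- function(records, input_samples = 625L) {
  n <- length(records)
  segs <- array(0, c(input_samples, 12L, n))
  full_set <- enumerate_lead_sets(12L)[[1]]
  for (i in seq_len(n)) {
    sl <- slice_asynchronous(records[[i]], full_set)
    for (l in seq_len(12L)) {
      segs[, l, i] <- sl$segments[[lead_order()[l]]]
    }
  }
  list(
    segments = segs,
    labels = vapply(records, function(r) r$label, integer(1)),
    subjects = vapply(records, function(r) r$subject_id, character(1))
  )
}

#' Train the classifier with random lead masking
#'
#' Minimizes binary cross-entropy with Adam.  A fresh lead mask is drawn
#' for every sample at every step (masked leads are fed zeros and carry no
#' gradient); segments are augmented on the fly.  After each epoch the
#' model is evaluated on the validation set with all 12 leads available,
#' and the parameters with the best validation AUROC are kept; training
#' stops early when the AUROC has not improved for `patience` epochs.
#'
#' @param model An [init_model()] model.
#' @param data A list as returned by [as_model_input()] (fields `segments`,
#'   `labels`).
#' @param config A [train_config()].
#' @param val_data Optional validation list of the same shape; when absent,
#'   validation metrics are reported on the training data.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint) and `history` (data frame
#'   of epoch, train_loss, val_loss, val_auroc).
#' @export
fit_ecg_classifier <- function(model, data, config = train_config(),
                               val_data = NULL, verbose = FALSE) {
  y <- data$labels
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  set.seed(config$seed)
  n <- length(y)
  opt <- adam_init(model$params)
  decay_skip <- grep("bn|_b$|_bq$|_bk$|_bv$|_bo$|clf_b", names(model$params),
                     value = TRUE)
  if (is.null(val_data)) val_data <- data
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auroc = numeric(0))
  best <- list(score = -Inf, params = model$params, state = model$state)
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      segs <- data$segments[, , idx, drop = FALSE]
      avail <- if (config$mask_prob > 0) {
        m <- sample_lead_mask(B, config$mask_prob)
        if (B == 1L) matrix(m$available, 1L) else m
      } else {
        matrix(TRUE, B, 12L)
      }
      for (b in seq_len(B)) {
        for (l in seq_len(12L)) {
          if (!avail[b, l]) {
            segs[, l, b] <- 0        # masked leads carry zeros
          } else {
            segs[, l, b] <- augment_segment(segs[, l, b], config)
          }
        }
      }
      fwd <- model_fwd(model, segs, avail, training = TRUE,
                       keep_cache = TRUE)
      model <- fwd$model               # batch-norm running stats
      yb <- y[idx]
      losses <- c(losses, bce_from_logits(fwd$logits, yb))
      dlogits <- (sigmoid(fwd$logits) - yb) / B
      grads <- model_bwd(model, fwd$cache, dlogits)
      upd <- adam_step(model$params, grads, opt,
                       lr = config$learning_rate,
                       weight_decay = config$weight_decay,
                       decay_skip = decay_skip)
      model$params <- upd$params
      opt <- upd$opt
    }
    val <- evaluate_model(model, val_data, mask = lead_mask(rep(TRUE, 12L)))
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_loss = val$loss, val_auroc = val$auroc
    ))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val AUROC %.4f",
                      epoch, mean(losses), val$loss, val$auroc))
    }
    # selection score: validation AUROC, or negative validation loss when
    # the validation split is single-class (AUROC undefined)
    score <- if (is.na(val$auroc)) -val$loss else val$auroc
    if (score > best$score) {
      best <- list(score = score, params = model$params,
                   state = model$state)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = history)
}

#' Score a dataset under a lead mask
#'
#' Inference-mode forward passes in chunks; returns probabilities plus loss
#' and AUROC against the labels.
#'
#' @param model An [init_model()] model.
#' @param data List with `segments` and `labels` (see [as_model_input()]).
#' @param mask A [lead_mask()] (e.g. from [as_lead_mask()]).
#' @param chunk Number of records per forward pass.
#' @return List with `prob`, `loss`, `auroc`.
#' @export
evaluate_model <- function(model, data, mask, chunk = 64L) {
  n <- dim(data$segments)[3]
  prob <- numeric(n)
  logits <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    avail <- matrix(mask$available, length(idx), 12L, byrow = TRUE)
    fwd <- model_fwd(model, data$segments[, , idx, drop = FALSE], avail,
                     training = FALSE)
    prob[idx] <- fwd$prob
    logits[idx] <- fwd$logits
  }
  auroc <- if (length(unique(data$labels)) == 2L) {
    roc_pr(prob, data$labels)$auroc
  } else {
    NA_real_
  }
  list(prob = prob, loss = bce_from_logits(logits, data$labels),
       auroc = auroc)
}
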