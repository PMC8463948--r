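# Neural-network primitives with hand-written backward passes.
#
# Everything operates on the batched-segment layout used by the conv
# kernel: a matrix of C channels x (L * nseg) columns, segments
# concatenated along the column axis.

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, y) {
  dy * (y > 0)
}

# Batch normalization (+ fused ReLU) lives in C++ (bn_fwd_cpp /
# bn_bwd_cpp): single-pass kernels over the channel rows.

# Ceil-mode average pooling with kernel 2, stride 2 (pairs a trailing odd
# sample with itself), matching the output length of a same-padded stride-2
# convolution: ceil(L/2).
pool_cols <- function(L, nseg) {
  idx1 <- seq(1L, L, by = 2L)
  idx2 <- pmin(idx1 + 1L, L)
  offs <- rep((seq_len(nseg) - 1L) * L, each = length(idx1))
  list(col1 = offs + idx1, col2 = offs + idx2,
       Lout = length(idx1))
}

avgpool2_fwd <- function(x, L, nseg) {
  pc <- pool_cols(L, nseg)
  list(y = (x[, pc$col1, drop = FALSE] + x[, pc$col2, drop = FALSE]) / 2,
       Lout = pc$Lout)
}

avgpool2_bwd <- function(dy, L, nseg, C) {
  pc <- pool_cols(L, nseg)
  dx <- matrix(0, C, L * nseg)
  dx[, pc$col1] <- dx[, pc$col1] + dy / 2
  dx[, pc$col2] <- dx[, pc$col2] + dy / 2
  dx
}

# Global average pooling over the time axis of each segment:
# C x (Lf * nseg)  ->  C x nseg.
gap_fwd <- function(x, Lf, nseg) {
  grp <- rep(seq_len(nseg), each = Lf)
  t(rowsum(t(x), grp, reorder = FALSE)) / Lf
}

gap_bwd <- function(dE, Lf, nseg) {
  dE[, rep(seq_len(nseg), each = Lf), drop = FALSE] / Lf
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean binary cross-entropy computed from logits (numerically stable form).
bce_from_logits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decay_skip = character(0)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !(nm %in% decay_skip)) {
      g <- g + weight_decay * params[[nm]]
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
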