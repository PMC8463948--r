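#' Model configuration
#'
#' Hyperparameters of the asynchronous-lead classifier.  The encoder is a
#' weight-shared stack of `n_blocks` residual 1-D conv blocks; feature depth
#' starts at `initial_depth` and doubles every `blocks_per_stage` blocks, so
#' the final depth — which is also the per-lead embedding dimension fed to
#' the self-attention module — is
#' `initial_depth * 2^(n_blocks / blocks_per_stage - 1)`.
#' Odd-numbered blocks have three convolutions with strides (2,1,1)
#' (block 1: (1,1,2), its shortcut being a stride-2 average pooling of the
#' first ReLU output); even-numbered blocks have two stride-1 convolutions
#' and an identity skip.  The default geometry (16 blocks, depth 64, kernel
#' 7, same padding) downsamples a 625-sample segment by 2^8 to length 3
#' before global average pooling, yields 512-dimensional embeddings, and a
#' classifier input of 12 x 512 = 6144.
#'
#' @param n_leads Number of lead channels (12).
#' @param input_samples Samples per lead segment (625 = 2.5 s at 250 Hz).
#' @param n_blocks Number of residual blocks (multiple of
#'   `blocks_per_stage`).
#' @param blocks_per_stage Blocks between depth doublings (4).
#' @param kernel_size Convolution kernel size (7, "same" padding).
#' @param initial_depth Feature count of the first stage.
#' @param n_heads Attention head count; must divide the embedding dim.
#' @param classifier_hidden Hidden width of the 2-layer dense classifier.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_leads = 12L,
                         input_samples = 625L,
                         n_blocks = 16L,
                         blocks_per_stage = 4L,
                         kernel_size = 7L,
                         initial_depth = 64L,
                         n_heads = 8L,
                         classifier_hidden = 512L) {
  stopifnot(n_blocks >= 2L, n_blocks %% blocks_per_stage == 0L,
            input_samples >= kernel_size, n_leads >= 1L)
  n_stages <- n_blocks %/% blocks_per_stage
  embed_dim <- as.integer(initial_depth * 2^(n_stages - 1L))
  if (embed_dim %% n_heads != 0L) {
    stop("embedding dimension ", embed_dim,
         " is not divisible by n_heads = ", n_heads)
  }
  structure(list(
    n_leads = as.integer(n_leads),
    input_samples = as.integer(input_samples),
    n_blocks = as.integer(n_blocks),
    blocks_per_stage = as.integer(blocks_per_stage),
    kernel_size = as.integer(kernel_size),
    initial_depth = as.integer(initial_depth),
    n_heads = as.integer(n_heads),
    head_dim = embed_dim %/% as.integer(n_heads),
    embed_dim = embed_dim,
    classifier_input = as.integer(n_leads) * embed_dim,
    classifier_hidden = as.integer(classifier_hidden),
    stage_depths = as.integer(initial_depth * 2^(seq_len(n_stages) - 1L))
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$n_blocks, " residual blocks, depths ",
      paste(x$stage_depths, collapse = "/"), ", kernel ", x$kernel_size,
      ", embed ", x$embed_dim, " (", x$n_heads, " heads), classifier ",
      x$classifier_input, " -> ", x$classifier_hidden, " -> 1\n", sep = "")
  invisible(x)
}

# Per-block structural description derived from the config.
encoder_spec <- function(config) {
  lapply(seq_len(config$n_blocks), function(b) {
    stage <- (b - 1L) %/% config$blocks_per_stage + 1L
    depth <- config$stage_depths[stage]
    in_depth <- if (b == 1L) 1L else {
      prev_stage <- (b - 2L) %/% config$blocks_per_stage + 1L
      config$stage_depths[prev_stage]
    }
    odd <- b %% 2L == 1L
    strides <- if (b == 1L) c(1L, 1L, 2L) else if (odd) c(2L, 1L, 1L)
               else c(1L, 1L)
    list(block = b, in_depth = in_depth, out_depth = depth,
         strides = strides, n_convs = length(strides), is_first = b == 1L,
         total_stride = prod(strides))
  })
}

#' Lead availability mask
#'
#' A boolean availability vector over the 12 canonical leads.  Masked leads
#' are removed as attention keys/values and their fused output rows are
#' zeroed, so the classifier output provably does not depend on their
#' signals.
#'
#' @param available Logical vector of length 12 (canonical lead order), or
#'   a character vector of available lead names.
#' @return An object of class `lead_mask`.
#' @export
lead_mask <- function(available) {
  if (is.character(available)) {
    available <- lead_order() %in% available
  }
  available <- as.logical(available)
  if (length(available) != 12L || anyNA(available)) {
    stop("`available` must be a logical vector of length 12")
  }
  if (!any(available)) stop("at least one lead must be available")
  structure(list(available = available), class = "lead_mask")
}

#' @export
print.lead_mask <- function(x, ...) {
  cat("<lead_mask> available: ",
      paste(lead_order()[x$available], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- initialization ---------------------------------------------------

he_mat <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

xavier_mat <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize a classifier model
#'
#' Builds the parameter set for a given configuration: one weight-shared
#' encoder (its parameter count is independent of the number of leads), the
#' multi-head self-attention projections and the dense classifier.  All
#' randomness is drawn from R's RNG; call inside `set.seed()` or pass
#' `seed` for reproducible initialization.
#'
#' @param config A [model_config()].
#' @param seed Optional integer seed.
#' @return An object of class `ecg_model`: list of `config`, `params`
#'   (trainable arrays) and `state` (batch-norm running statistics).
#' @export
init_model <- function(config = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$kernel_size
  params <- list()
  state <- list()
  for (bs in encoder_spec(config)) {
    cin <- bs$in_depth
    for (j in seq_len(bs$n_convs)) {
      cj <- if (j == 1L) cin else bs$out_depth
      nm <- sprintf("enc_b%02d_conv%d", bs$block, j)
      params[[paste0(nm, "_W")]] <- he_mat(bs$out_depth, cj * k, cj * k)
      params[[paste0(nm, "_b")]] <- numeric(bs$out_depth)
      bn <- sprintf("enc_b%02d_bn%d", bs$block, j)
      params[[paste0(bn, "_gamma")]] <- rep(1, bs$out_depth)
      params[[paste0(bn, "_beta")]] <- numeric(bs$out_depth)
      state[[paste0(bn, "_mean")]] <- numeric(bs$out_depth)
      state[[paste0(bn, "_var")]] <- rep(1, bs$out_depth)
    }
  }
  D <- config$embed_dim
  for (nm in c("att_Wq", "att_Wk", "att_Wv", "att_Wo")) {
    params[[nm]] <- xavier_mat(D, D)
  }
  for (nm in c("att_bq", "att_bk", "att_bv", "att_bo")) {
    params[[nm]] <- numeric(D)
  }
  fin <- config$classifier_input
  params$clf_W1 <- he_mat(fin, config$classifier_hidden, fin)
  params$clf_b1 <- numeric(config$classifier_hidden)
  params$clf_W2 <- he_mat(config$classifier_hidden, 1L,
                          config$classifier_hidden)
  params$clf_b2 <- numeric(1L)
  structure(list(config = config, params = params, state = state,
                 lead_order = lead_order()),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<ecg_model> ", format(np, big.mark = ","), " parameters\n", sep = "")
  print(x$config)
  invisible(x)
}

# ---- encoder ----------------------------------------------------------

# X: 1 x (L * nseg) matrix of segments. Returns embeddings (D x nseg) and,
# when `keep_cache`, everything needed for the backward pass.
encoder_fwd <- function(model, X, nseg, training = FALSE,
                        keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  k <- cfg$kernel_size
  blocks <- encoder_spec(cfg)
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  x <- X
  L <- cfg$input_samples
  for (bs in blocks) {
    bc <- list(bs = bs, L_in = L)
    h <- x
    Lh <- L
    for (j in seq_len(bs$n_convs)) {
      nm <- sprintf("enc_b%02d_conv%d", bs$block, j)
      bn <- sprintf("enc_b%02d_bn%d", bs$block, j)
      if (keep_cache) bc[[paste0("x", j)]] <- h
      z <- conv1d_fwd(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                      Lh, nseg, k, bs$strides[j])
      Lh <- conv1d_out_len(Lh, bs$strides[j])
      is_last <- j == bs$n_convs
      bnr <- bn_fwd_cpp(z, p[[paste0(bn, "_gamma")]],
                        p[[paste0(bn, "_beta")]],
                        st[[paste0(bn, "_mean")]], st[[paste0(bn, "_var")]],
                        training, 0.9, 1e-5, relu = !is_last)
      if (training) {
        st[[paste0(bn, "_mean")]] <- bnr$rmean
        st[[paste0(bn, "_var")]] <- bnr$rvar
      }
      if (keep_cache) {
        bc[[paste0("z", j)]] <- z
        bc[[paste0("mu", j)]] <- bnr$mu
        bc[[paste0("istd", j)]] <- bnr$istd
      }
      if (!is_last) {
        h <- bnr$y
        if (keep_cache) bc[[paste0("h", j)]] <- h
        if (bs$is_first && j == 1L) h1 <- h
      } else {
        pre <- bnr$y
      }
    }
    # shortcut
    if (bs$is_first) {
      sc <- avgpool2_fwd(h1, L, nseg)$y
      if (keep_cache) bc$h1_len <- L
    } else if (bs$total_stride == 2L) {
      sc <- avgpool2_fwd(x, L, nseg)$y
      if (bs$out_depth > bs$in_depth) {
        sc <- rbind(sc, matrix(0, bs$out_depth - bs$in_depth, ncol(sc)))
      }
    } else {
      sc <- x
    }
    out <- relu_fwd(pre + sc)
    if (keep_cache) {
      bc$out <- out
      caches[[bs$block]] <- bc
    }
    x <- out
    L <- Lh
  }
  E <- gap_fwd(x, L, nseg)   # embed_dim x nseg
  list(E = E, state = st, final_len = L,
       cache = if (keep_cache) list(blocks = caches, final_len = L,
                                    training = training) else NULL)
}

encoder_bwd <- function(model, cache, dE, nseg) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  training <- cache$training
  grads <- list()
  none <- matrix(0, 0L, 0L)
  dx <- gap_bwd(dE, cache$final_len, nseg)
  for (bs in rev(encoder_spec(cfg))) {
    bc <- cache$blocks[[bs$block]]
    dout <- relu_bwd(dx, bc$out)
    dpre <- dout
    # shortcut gradient
    if (bs$is_first) {
      dh1_sc <- avgpool2_bwd(dout, bc$L_in, nseg, bs$out_depth)
      dsc_in <- NULL
    } else if (bs$total_stride == 2L) {
      dsc <- dout[seq_len(bs$in_depth), , drop = FALSE]
      dsc_in <- avgpool2_bwd(dsc, bc$L_in, nseg, bs$in_depth)
    } else {
      dsc_in <- dout
    }
    dh <- NULL
    for (j in rev(seq_len(bs$n_convs))) {
      nm <- sprintf("enc_b%02d_conv%d", bs$block, j)
      bn <- sprintf("enc_b%02d_bn%d", bs$block, j)
      is_last <- j == bs$n_convs
      d_in <- if (is_last) dpre else {
        # the first block's shortcut taps the ReLU-1 output, so its
        # gradient joins before the fused ReLU/batch-norm backward
        if (bs$is_first && j == 1L) dh + dh1_sc else dh
      }
      bnb <- bn_bwd_cpp(d_in,
                        if (is_last) none else bc[[paste0("h", j)]],
                        bc[[paste0("z", j)]],
                        bc[[paste0("mu", j)]], bc[[paste0("istd", j)]],
                        p[[paste0(bn, "_gamma")]],
                        training, relu = !is_last)
      grads[[paste0(bn, "_gamma")]] <- as.numeric(bnb$dgamma)
      grads[[paste0(bn, "_beta")]] <- as.numeric(bnb$dbeta)
      xj <- bc[[paste0("x", j)]]
      Lj <- ncol(xj) / nseg
      cb <- conv1d_bwd(xj, p[[paste0(nm, "_W")]], bnb$dx,
                       Lj, nseg, k, bs$strides[j])
      grads[[paste0(nm, "_W")]] <- cb$dW
      grads[[paste0(nm, "_b")]] <- as.numeric(cb$db)
      dh <- cb$dX
    }
    dx <- dh
    if (!is.null(dsc_in)) dx <- dx + dsc_in
  }
  list(grads = grads, dX = dx)
}

# ---- attention --------------------------------------------------------

# E_all: (B * n_leads) x D, rows grouped per sample in canonical lead
# order.  avail: B x n_leads logical matrix.
attention_fwd <- function(model, E_all, avail, keep_cache = FALSE,
                          return_weights = FALSE) {
  cfg <- model$config
  p <- model$params
  N <- cfg$n_leads
  D <- cfg$embed_dim
  H <- cfg$n_heads
  dh <- cfg$head_dim
  B <- nrow(E_all) %/% N
  if (any(rowSums(avail) == 0L)) stop("all leads masked for some sample")

  Q <- E_all %*% p$att_Wq + rep(p$att_bq, each = nrow(E_all))
  K <- E_all %*% p$att_Wk + rep(p$att_bk, each = nrow(E_all))
  V <- E_all %*% p$att_Wv + rep(p$att_bv, each = nrow(E_all))
  AV <- matrix(0, nrow(E_all), D)
  A_list <- if (keep_cache || return_weights) {
    vector("list", B)
  } else NULL
  hcols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    masked <- !avail[b, ]
    Ab <- if (!is.null(A_list)) vector("list", H) else NULL
    for (h in seq_len(H)) {
      hc <- hcols[[h]]
      S <- (Q[rows, hc, drop = FALSE] %*%
              t(K[rows, hc, drop = FALSE])) * scale
      if (any(masked)) S[, masked] <- -Inf
      S <- S - apply(S, 1L, max)
      Ew <- exp(S)
      A <- Ew / rowSums(Ew)
      AV[rows, hc] <- A %*% V[rows, hc, drop = FALSE]
      if (!is.null(Ab)) Ab[[h]] <- A
    }
    if (!is.null(A_list)) A_list[[b]] <- Ab
  }
  O <- AV %*% p$att_Wo + rep(p$att_bo, each = nrow(E_all))
  # zero the fused rows of masked leads so nothing downstream can see them
  mask_rows <- as.vector(t(!avail))
  O[mask_rows, ] <- 0
  list(O = O,
       weights = if (return_weights) A_list else NULL,
       cache = if (keep_cache) list(E = E_all, Q = Q, K = K, V = V, AV = AV,
                                    A = A_list, avail = avail,
                                    mask_rows = mask_rows) else NULL)
}

attention_bwd <- function(model, cache, dO) {
  cfg <- model$config
  p <- model$params
  N <- cfg$n_leads
  H <- cfg$n_heads
  dh <- cfg$head_dim
  B <- nrow(dO) %/% N
  dO[cache$mask_rows, ] <- 0
  grads <- list(
    att_Wo = t(cache$AV) %*% dO,
    att_bo = colSums(dO)
  )
  dAV <- dO %*% t(p$att_Wo)
  dQ <- matrix(0, nrow(dO), cfg$embed_dim)
  dK <- matrix(0, nrow(dO), cfg$embed_dim)
  dV <- matrix(0, nrow(dO), cfg$embed_dim)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (h in seq_len(H)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      dAVh <- dAV[rows, hc, drop = FALSE]
      Vh <- cache$V[rows, hc, drop = FALSE]
      dA <- dAVh %*% t(Vh)
      dV[rows, hc] <- t(A) %*% dAVh
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, hc] <- (dS %*% cache$K[rows, hc, drop = FALSE]) * scale
      dK[rows, hc] <- (t(dS) %*% cache$Q[rows, hc, drop = FALSE]) * scale
    }
  }
  E <- cache$E
  grads$att_Wq <- t(E) %*% dQ
  grads$att_Wk <- t(E) %*% dK
  grads$att_Wv <- t(E) %*% dV
  grads$att_bq <- colSums(dQ)
  grads$att_bk <- colSums(dK)
  grads$att_bv <- colSums(dV)
  dE <- dQ %*% t(p$att_Wq) + dK %*% t(p$att_Wk) + dV %*% t(p$att_Wv)
  list(grads = grads, dE = dE)
}

# ---- classifier -------------------------------------------------------

classifier_fwd <- function(model, Fin, keep_cache = FALSE) {
  p <- model$params
  Z1 <- Fin %*% p$clf_W1 + rep(p$clf_b1, each = nrow(Fin))
  H1 <- relu_fwd(Z1)
  logits <- as.numeric(H1 %*% p$clf_W2 + p$clf_b2)
  list(logits = logits, prob = sigmoid(logits),
       cache = if (keep_cache) list(Fin = Fin, H1 = H1) else NULL)
}

classifier_bwd <- function(model, cache, dlogits) {
  p <- model$params
  dlog <- matrix(dlogits, ncol = 1L)
  grads <- list(
    clf_W2 = t(cache$H1) %*% dlog,
    clf_b2 = sum(dlogits)
  )
  dH1 <- dlog %*% t(p$clf_W2)
  dZ1 <- relu_bwd(dH1, cache$H1)
  grads$clf_W1 <- t(cache$Fin) %*% dZ1
  grads$clf_b1 <- colSums(dZ1)
  dF <- dZ1 %*% t(p$clf_W1)
  list(grads = grads, dF = dF)
}

# ---- full model -------------------------------------------------------

# segments: array (input_samples x n_leads x B); avail: B x 12 logical.
# Only available segments are run through the encoder: masked leads are
# dropped as attention keys/values and their fused rows zeroed, so their
# embeddings can never reach the output (and carry no gradient); skipping
# them also keeps batch-norm statistics free of placeholder segments.
model_fwd <- function(model, segments, avail, training = FALSE,
                      keep_cache = FALSE) {
  cfg <- model$config
  d <- dim(segments)
  stopifnot(d[1] == cfg$input_samples, d[2] == cfg$n_leads)
  B <- d[3]
  nseg <- B * cfg$n_leads
  active <- which(as.vector(t(avail)))     # segment index, lead-major
  Xm <- matrix(as.vector(segments), nrow = cfg$input_samples)
  X <- matrix(Xm[, active, drop = FALSE], nrow = 1L)
  enc <- encoder_fwd(model, X, length(active), training = training,
                     keep_cache = keep_cache)
  if (training) model$state <- enc$state
  E_all <- matrix(0, nseg, cfg$embed_dim)  # nseg x D, lead-major per sample
  E_all[active, ] <- t(enc$E)
  att <- attention_fwd(model, E_all, avail, keep_cache = keep_cache)
  Fin <- t(matrix(as.vector(t(att$O)), nrow = cfg$classifier_input))
  clf <- classifier_fwd(model, Fin, keep_cache = keep_cache)
  list(prob = clf$prob, logits = clf$logits, model = model,
       cache = if (keep_cache) list(enc = enc$cache, att = att$cache,
                                    clf = clf$cache, active = active,
                                    B = B) else NULL)
}

model_bwd <- function(model, cache, dlogits) {
  cfg <- model$config
  cb <- classifier_bwd(model, cache$clf, dlogits)
  dO <- t(matrix(as.vector(t(cb$dF)), nrow = cfg$embed_dim))
  ab <- attention_bwd(model, cache$att, dO)
  dE_act <- ab$dE[cache$active, , drop = FALSE]
  eb <- encoder_bwd(model, cache$enc, t(dE_act), length(cache$active))
  c(cb$grads, ab$grads, eb$grads)
}

#' Encode one lead segment into an embedding
#'
#' Runs a single 2.5 s lead segment through the weight-shared residual
#' encoder (inference mode) and global average pooling.
#'
#' @param segment Numeric vector of `config$input_samples` samples (mV).
#' @param model An [init_model()] model.
#' @return Numeric embedding of length `embed_dim`.
#' @export
encode_lead <- function(segment, model) {
  cfg <- model$config
  if (length(segment) != cfg$input_samples) {
    stop("segment must have ", cfg$input_samples, " samples, got ",
         length(segment))
  }
  enc <- encoder_fwd(model, matrix(segment, nrow = 1L), 1L,
                     training = FALSE)
  as.numeric(enc$E[, 1L])
}

#' Lead-masked multi-head self-attention
#'
#' Fuses the 12 per-lead embeddings.  Masked leads are removed as attention
#' keys/values (score set to -Inf before the softmax, so their attention
#' weight is exactly zero) and their fused output rows are zeroed; each
#' remaining attention row is a probability distribution over the available
#' leads.
#'
#' @param embeddings `n_leads x embed_dim` matrix (one row per lead, in
#'   canonical order).
#' @param mask A [lead_mask()].
#' @param model An [init_model()] model.
#' @param return_weights If `TRUE`, also return the per-head attention
#'   matrices.
#' @return `n_leads x embed_dim` fused matrix, with attribute `weights`
#'   (list of per-head `n_leads x n_leads` matrices) when requested.
#' @export
masked_attention <- function(embeddings, mask, model,
                             return_weights = FALSE) {
  cfg <- model$config
  stopifnot(inherits(mask, "lead_mask"),
            nrow(embeddings) == cfg$n_leads,
            ncol(embeddings) == cfg$embed_dim)
  att <- attention_fwd(model, embeddings,
                       matrix(mask$available, nrow = 1L),
                       return_weights = return_weights)
  out <- att$O
  if (return_weights) attr(out, "weights") <- att$weights[[1]]
  out
}

#' Predict AMI probability for lead segments under a mask
#'
#' Full inference pass: weight-shared encoding of each lead, lead-masked
#' self-attention, flattening to `n_leads * embed_dim` features, the
#' two-layer dense classifier and a sigmoid.  The output is provably
#' invariant to the signals of masked leads.
#'
#' @param model An [init_model()] model.
#' @param segments `input_samples x n_leads` matrix or
#'   `input_samples x n_leads x B` array; masked leads may carry zeros (or
#'   anything else -- they cannot influence the output).
#' @param mask A [lead_mask()], or a `B x 12` logical matrix for per-sample
#'   masks.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, segments, mask) {
  cfg <- model$config
  if (length(dim(segments)) == 2L) {
    segments <- array(segments, c(dim(segments), 1L))
  }
  B <- dim(segments)[3]
  avail <- if (inherits(mask, "lead_mask")) {
    matrix(mask$available, nrow = B, ncol = 12L, byrow = TRUE)
  } else {
    mask
  }
  model_fwd(model, segments, avail, training = FALSE)$prob
}

# ---- checkpoint io ----------------------------------------------------

#' Save / load a model checkpoint
#'
#' Serializes the full configuration, all parameters, batch-norm running
#' statistics and the canonical lead order to a JSON file; numbers are
#' written at full precision so the round trip is lossless for practical
#' purposes.
#'
#' @param model An [init_model()] model.
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  enc <- function(x) list(dim = if (is.matrix(x)) dim(x) else length(x),
                          data = as.numeric(x))
  obj <- list(
    format = "asyncecg-checkpoint-1",
    config = unclass(model$config),
    lead_order = model$lead_order,
    params = lapply(model$params, enc),
    state = lapply(model$state, enc)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) {
    if (length(e$dim) == 2L) matrix(e$data, e$dim[1], e$dim[2])
    else as.numeric(e$data)
  }
  cfg <- obj$config
  config <- model_config(
    n_leads = cfg$n_leads, input_samples = cfg$input_samples,
    n_blocks = cfg$n_blocks, blocks_per_stage = cfg$blocks_per_stage,
    kernel_size = cfg$kernel_size, initial_depth = cfg$initial_depth,
    n_heads = cfg$n_heads, classifier_hidden = cfg$classifier_hidden
  )
  structure(list(config = config,
                 params = lapply(obj$params, dec),
                 state = lapply(obj$state, dec),
                 lead_order = obj$lead_order),
            class = "ecg_model")
}
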