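#' @include AllClasses.R utils.R
NULL

#' Configuration for the DPPE sequence autoencoder
#'
#' @param input_dim number of clinical variables V.
#' @param embedding_dim embedding length (>= 2), default 16.
#' @param n_layers LSTM layers (this implementation supports 1).
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size; 1 reproduces the per-patient
#'   update scheme, larger values are a supported speed option.
#' @param val_fraction held-out fraction for early stopping.
#' @param patience epochs without validation improvement before stop.
#' @param seed integer seed controlling init and batching.
#' @return named list of class `dppeConfig`.
#' @export
dppeConfig <- function(input_dim, embedding_dim = 16, n_layers = 1,
                       learning_rate = 0.01, epochs = 100,
                       batch_size = 1, val_fraction = 0.1,
                       patience = 10, seed = 1L) {
  if (input_dim < 1 || embedding_dim < 2)
    stop("input_dim must be >= 1 and embedding_dim >= 2")
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (n_layers != 1) stop("only single-layer LSTMs are implemented")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 embedding_dim = as.integer(embedding_dim),
                 n_layers = as.integer(n_layers),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = c("dppeConfig", "list"))
}

sigm <- function(x) 1 / (1 + exp(-x))

# one LSTM forward pass over a batch; X is n x T x Vin.
# Returns per-step caches needed for BPTT.
lstmForward <- function(X, Wx, Wh, b) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  H <- nrow(Wh)
  nG <- ncol(Wx)            # 4H
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", Tn)
  iH <- seq_len(H)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], n)
    Z <- xt %*% Wx + h %*% Wh + matrix(b, n, nG, byrow = TRUE)
    ig <- sigm(Z[, iH, drop = FALSE])
    fg <- sigm(Z[, H + iH, drop = FALSE])
    og <- sigm(Z[, 2 * H + iH, drop = FALSE])
    gg <- tanh(Z[, 3 * H + iH, drop = FALSE])
    cPrev <- cc
    cc <- fg * cPrev + ig * gg
    tc <- tanh(cc)
    hPrev <- h
    h <- og * tc
    cache[[t]] <- list(x = xt, i = ig, f = fg, o = og, g = gg,
                       c = cc, tc = tc, cPrev = cPrev, hPrev = hPrev)
  }
  list(h = h, cache = cache)
}

# backward through one LSTM; dhT is gradient on the final hidden state,
# dhStep (n x T x H or NULL) per-step gradients flowing into h_t.
lstmBackward <- function(cache, Wx, Wh, dhT = NULL, dhStep = NULL) {
  Tn <- length(cache)
  H <- nrow(Wh); n <- nrow(cache[[1]]$i)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, ncol(Wh))
  db <- numeric(ncol(Wh))
  dX <- array(0, dim = c(n, Tn, nrow(Wx)))
  dh <- if (is.null(dhT)) matrix(0, n, H) else dhT
  dc <- matrix(0, n, H)
  iH <- seq_len(H)
  for (t in rev(seq_len(Tn))) {
    cs <- cache[[t]]
    if (!is.null(dhStep)) dh <- dh + matrix(dhStep[, t, ], n)
    do <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$cPrev
    dcPrev <- dc * cs$f
    dZ <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                do * cs$o * (1 - cs$o),
                dg * (1 - cs$g^2))
    dWx <- dWx + crossprod(cs$x, dZ)
    dWh <- dWh + crossprod(cs$hPrev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dh <- dZ %*% t(Wh)
    dc <- dcPrev
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

initLstm <- function(Vin, H, scale = 0.08) {
  Wx <- matrix(runif(Vin * 4 * H, -scale, scale), Vin)
  Wh <- matrix(runif(H * 4 * H, -scale, scale), H)
  b <- rep(0, 4 * H)
  b[H + seq_len(H)] <- 1          # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

#' Build an untrained DPPE model
#'
#' Encoder: an LSTM over the T x V input whose final hidden state (of
#' length `embedding_dim`) is the progression embedding. Decoder: a
#' mirror LSTM that receives the embedding repeated at every time step
#' and reconstructs the T x V sequence through a linear output layer.
#' All weights are initialized from the seeded generator.
#'
#' @param config a [dppeConfig()].
#' @return An untrained [DppeModel-class].
#' @export
buildDppe <- function(config) {
  stopifnot(inherits(config, "dppeConfig"))
  set.seed(config$seed)
  V <- config$input_dim; H <- config$embedding_dim
  enc <- initLstm(V, H)
  dec <- initLstm(H, H)
  params <- list(encWx = enc$Wx, encWh = enc$Wh, encB = enc$b,
                 decWx = dec$Wx, decWh = dec$Wh, decB = dec$b,
                 outW = matrix(runif(H * V, -0.08, 0.08), H),
                 outB = rep(0, V))
  new("DppeModel", params = params, config = config,
      lossHistory = numeric(0), trained = FALSE)
}

#' Number of trainable parameters of a DPPE model
#' @param model a [DppeModel-class].
#' @return integer parameter count.
#' @export
dppeParameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

# forward pass: returns reconstruction and caches
dppeForward <- function(params, X) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  H <- ncol(params$encWh) / 4
  enc <- lstmForward(X, params$encWx, params$encWh, params$encB)
  emb <- enc$h
  Xdec <- array(0, dim = c(n, Tn, H))
  for (t in seq_len(Tn)) Xdec[, t, ] <- emb
  dec <- lstmForward(Xdec, params$decWx, params$decWh, params$decB)
  Y <- array(0, dim = dim(X))
  for (t in seq_len(Tn))
    Y[, t, ] <- (dec$cache[[t]]$o * dec$cache[[t]]$tc) %*% params$outW +
      matrix(params$outB, n, dim(X)[3], byrow = TRUE)
  list(Y = Y, enc = enc, dec = dec, emb = emb)
}

# full backward pass; returns gradient list matching params
dppeBackward <- function(params, X, fwd) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; V <- dim(X)[3]
  H <- ncol(params$encWh) / 4
  dY <- 2 * (fwd$Y - X) / length(X)
  dOutW <- matrix(0, H, V); dOutB <- numeric(V)
  dhStep <- array(0, dim = c(n, Tn, H))
  for (t in seq_len(Tn)) {
    ht <- fwd$dec$cache[[t]]$o * fwd$dec$cache[[t]]$tc
    dyt <- matrix(dY[, t, ], n)
    dOutW <- dOutW + crossprod(ht, dyt)
    dOutB <- dOutB + colSums(dyt)
    dhStep[, t, ] <- dyt %*% t(params$outW)
  }
  decB <- lstmBackward(fwd$dec$cache, params$decWx, params$decWh,
                       dhT = NULL, dhStep = dhStep)
  # embedding gradient: decoder input at every step plus nothing else
  dEmb <- apply(decB$dX, c(1, 3), sum)
  encB <- lstmBackward(fwd$enc$cache, params$encWx, params$encWh,
                       dhT = dEmb)
  list(encWx = encB$dWx, encWh = encB$dWh, encB = encB$db,
       decWx = decB$dWx, decWh = decB$dWh, decB = decB$db,
       outW = dOutW, outB = dOutB)
}

#' Train a DPPE model
#'
#' Minimizes mean squared reconstruction error with the Adam optimizer.
#' A `val_fraction` split (seeded) is held out; training stops early
#' when validation loss has not improved for `patience` epochs and the
#' best-validation parameters are kept. Sequences from all participant
#' groups (cases, controls, and any additional groups) may be pooled
#' for training.
#'
#' @param model a [DppeModel-class] from [buildDppe()].
#' @param sequences a [SequenceSet-class] or n x T x V array.
#' @param epochs,batch_size,learning_rate optional overrides of the
#'   model config.
#' @return The trained model; per-epoch mean training loss in
#'   `lossHistory`.
#' @export
trainDppe <- function(model, sequences, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL) {
  X <- if (is(sequences, "SequenceSet")) sequences@data else sequences
  stopifnot(length(dim(X)) == 3, dim(X)[1] >= 1)
  cfg <- model@config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  if (is.null(learning_rate)) learning_rate <- cfg$learning_rate
  if (dim(X)[3] != cfg$input_dim)
    stop("sequence variable count does not match the model input_dim")
  n <- dim(X)[1]
  set.seed(childSeed(cfg$seed, 1L))
  nVal <- max(0L, min(n - 1L, round(cfg$val_fraction * n)))
  valIdx <- if (nVal > 0) sample.int(n, nVal) else integer(0)
  trIdx <- setdiff(seq_len(n), valIdx)
  Xval <- X[valIdx, , , drop = FALSE]

  params <- model@params
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; step <- 0
  lossHist <- numeric(0)
  bestVal <- Inf; bestParams <- params; wait <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    epLoss <- 0; nCells <- 0
    for (bidx in batches) {
      Xb <- X[bidx, , , drop = FALSE]
      fwd <- dppeForward(params, Xb)
      l <- mean((fwd$Y - Xb)^2)
      if (!is.finite(l))
        stop("non-finite training loss at epoch ", ep,
             "; reduce the learning rate")
      epLoss <- epLoss + l * length(Xb); nCells <- nCells + length(Xb)
      grads <- dppeBackward(params, Xb, fwd)
      step <- step + 1
      for (nm in names(params)) {
        mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * grads[[nm]]
        vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * grads[[nm]]^2
        mh <- mAdam[[nm]] / (1 - b1^step)
        vh <- vAdam[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - learning_rate * mh / (sqrt(vh) + epsA)
      }
    }
    lossHist <- c(lossHist, epLoss / nCells)
    if (nVal > 0) {
      vl <- mean((dppeForward(params, Xval)$Y - Xval)^2)
      if (vl < bestVal - 1e-9) {
        bestVal <- vl; bestParams <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  model@params <- if (nVal > 0) bestParams else params
  model@lossHistory <- lossHist
  model@trained <- TRUE
  model
}

#' Embed participants with a trained DPPE model
#'
#' Deterministic encoder forward pass; identical inputs give identical
#' vectors.
#'
#' @param model trained [DppeModel-class].
#' @param sequences a [SequenceSet-class] or n x T x V array.
#' @return numeric matrix, participants x embedding_dim, rownames =
#'   participant ids when available.
#' @export
embedParticipants <- function(model, sequences) {
  X <- if (is(sequences, "SequenceSet")) sequences@data else sequences
  if (dim(X)[3] != model@config$input_dim)
    stop("sequence variable count does not match the model input_dim")
  enc <- lstmForward(X, model@params$encWx, model@params$encWh,
                     model@params$encB)
  emb <- enc$h
  rownames(emb) <- dimnames(X)[[1]]
  colnames(emb) <- sprintf("e%d", seq_len(ncol(emb)))
  emb
}

#' Reconstruction loss of a model on a sequence set
#' @param model trained [DppeModel-class].
#' @param sequences [SequenceSet-class] or array.
#' @return mean squared reconstruction error.
#' @export
dppeReconstructionLoss <- function(model, sequences) {
  X <- if (is(sequences, "SequenceSet")) sequences@data else sequences
  mean((dppeForward(model@params, X)$Y - X)^2)
}
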