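## Fully connected classifier over NDS descriptors, and the Feature
## Prominence (FP) score: the pre-softmax output of a class, read as a
## severity proxy relative to the training distribution.

#' Random dataset split
#'
#' Unstratified random partition into train/validation/test at the given
#' fractions (train gets floor(f1*n), validation floor(f2*n), test the
#' remainder), seeded and reproducible. Stratification is deliberately off:
#' per-class counts drift the way they do in a plain random split.
#'
#' @param x an [NDSSet-class]
#' @param fractions length-3 positive fractions summing to 1
#' @param seed integer RNG seed
#' @return named list of [NDSSet-class]s: train, validation, test
#' @export
splitDataset <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is(x, "NDSSet"), length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  cnt <- table(SummarizedExperiment::colData(x)$label)
  if (any(cnt < 10L))
    stop("every class needs at least 10 samples; smallest has ", min(cnt))
  n <- ncol(x)
  set.seed(seed)
  perm <- sample.int(n)
  nTrain <- floor(fractions[1L] * n)
  nVal <- floor(fractions[2L] * n)
  list(train = x[, sort(perm[seq_len(nTrain)])],
       validation = x[, sort(perm[nTrain + seq_len(nVal)])],
       test = x[, sort(perm[(nTrain + nVal + 1L):n])])
}

#' Training configuration
#'
#' Standard small-MLP recipe: ReLU hidden activations, softmax cross-entropy,
#' Adam, mini-batches, early stopping on validation accuracy with the best
#' validation weights retained.
#'
#' @param learningRate Adam step size
#' @param batchSize mini-batch size
#' @param maxEpochs epoch cap
#' @param patience early-stopping patience (epochs without validation
#'   improvement); ignored when no validation set is supplied
#' @param standardize z-score features using training statistics (off by
#'   default: FP values are only meaningful relative to a fixed input scale)
#' @return a configuration list
#' @export
trainConfig <- function(learningRate = 1e-3, batchSize = 16L,
                        maxEpochs = 200L, patience = 20L,
                        standardize = FALSE) {
  stopifnot(learningRate > 0, batchSize >= 1L, maxEpochs >= 1L, patience >= 1L)
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       standardize = isTRUE(standardize))
}

## ---- MLP internals ----

.mlp_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass on a batch (rows = samples); returns hidden activations and
# pre-softmax logits
.mlp_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(X))
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

.mlp_logits <- function(W, b, X) {
  A <- .mlp_forward(W, b, X)
  A[[length(A)]]
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# gradients of mean cross-entropy w.r.t. parameters; Y is a one-hot matrix
.mlp_grad <- function(W, b, X, Y) {
  L <- length(W)
  A <- .mlp_forward(W, b, X)
  P <- .softmax_rows(A[[L + 1L]])
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-300))))
  G <- (P - Y) / nrow(X)               # d loss / d logits
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], G)
    gb[[l]] <- colSums(G)
    if (l > 1L) G <- (G %*% t(W[[l]])) * (A[[l]] > 0)
  }
  list(gW = gW, gb = gb, loss = loss)
}

# gradient of the pre-softmax output of one class w.r.t. the inputs,
# vectorized over the rows of X
.mlp_input_grad <- function(W, b, X, classIdx) {
  L <- length(W)
  A <- .mlp_forward(W, b, X)
  G <- matrix(0, nrow(X), ncol(W[[L]]))
  G[, classIdx] <- 1
  for (l in L:1) {
    G <- G %*% t(W[[l]])
    if (l > 1L) G <- G * (A[[l]] > 0)
  }
  G
}

.adam_new <- function(W, b) {
  list(mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
       mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(state, W, b, g, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * g$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * g$gW[[l]]^2
    W[[l]] <- W[[l]] - lr * (state$mW[[l]] / c1) /
      (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * g$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * g$gb[[l]]^2
    b[[l]] <- b[[l]] - lr * (state$mb[[l]] / c1) /
      (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(state = state, W = W, b = b)
}

.nds_matrix <- function(x) t(SummarizedExperiment::assay(x, "nds"))

.apply_scaling <- function(X, scaling) {
  if (!length(scaling)) return(X)
  sweep(sweep(X, 2L, scaling$center), 2L, scaling$scale, "/")
}

## ---- training ----

#' Train the fully connected NDS classifier
#'
#' Fits the network (default architecture input-256-128-64-32-classes) by
#' mini-batch Adam on softmax cross-entropy. When a validation set is given,
#' training stops early once validation accuracy has not improved for
#' `config$patience` epochs, and the best-validation weights are retained.
#' After training, the per-class Feature Prominence distributions (sorted
#' pre-softmax outputs of each class's own training samples) are stored for
#' percentile normalization.
#'
#' @param train an [NDSSet-class] of training samples
#' @param validation optional [NDSSet-class] for early stopping
#' @param hidden integer vector of hidden-layer widths
#' @param config see [trainConfig()]
#' @param seed integer seed controlling initialization and batching
#' @return an [NDSModel-class]
#' @export
trainNDSModel <- function(train, validation = NULL,
                          hidden = c(256L, 128L, 64L, 32L),
                          config = trainConfig(), seed = 1L) {
  stopifnot(is(train, "NDSSet"))
  if (!is.null(validation)) {
    stopifnot(is(validation, "NDSSet"))
    if (!identical(gridHash(train), gridHash(validation)))
      stop("training and validation descriptors come from different grids")
  }
  X <- .nds_matrix(train)
  labels <- SummarizedExperiment::colData(train)$label
  classLabels <- levels(labels)
  y <- as.integer(labels)
  dims <- as.integer(c(ncol(X), hidden, length(classLabels)))

  scaling <- list()
  if (config$standardize) {
    scaling <- list(center = colMeans(X),
                    scale = pmax(apply(X, 2L, sd), 1e-12))
    X <- .apply_scaling(X, scaling)
  }
  Y <- matrix(0, nrow(X), length(classLabels))
  Y[cbind(seq_len(nrow(X)), y)] <- 1

  if (!is.null(validation)) {
    Xv <- .apply_scaling(.nds_matrix(validation), scaling)
    yv <- as.integer(factor(SummarizedExperiment::colData(validation)$label,
                            levels = classLabels))
  }

  set.seed(seed)
  par <- .mlp_init(dims)
  W <- par$W; b <- par$b
  opt <- .adam_new(W, b)
  best <- list(W = W, b = b, acc = -Inf, loss = Inf, epoch = 0L)
  sinceBest <- 0L
  history <- list(loss = numeric(0), valAccuracy = numeric(0))
  n <- nrow(X)
  for (epoch in seq_len(config$maxEpochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    epochLoss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batchSize - 1L, n)]
      g <- .mlp_grad(W, b, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      st <- .adam_step(opt, W, b, g, config$learningRate)
      opt <- st$state; W <- st$W; b <- st$b
      epochLoss <- epochLoss + g$loss * length(idx)
    }
    history$loss <- c(history$loss, epochLoss / n)
    if (!is.null(validation)) {
      lv <- .mlp_logits(W, b, Xv)
      pv <- max.col(lv, ties.method = "first")
      acc <- mean(pv == yv)
      Pv <- .softmax_rows(lv)
      valLoss <- -mean(log(pmax(Pv[cbind(seq_along(yv), yv)], 1e-300)))
      history$valAccuracy <- c(history$valAccuracy, acc)
      # a small validation set saturates accuracy quickly; break ties on
      # validation loss so the model keeps sharpening the boundary
      if (acc > best$acc || (acc == best$acc && valLoss < best$loss)) {
        best <- list(W = W, b = b, acc = acc, loss = valLoss, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  }
  if (!is.null(validation)) { W <- best$W; b <- best$b }

  # per-class FP distributions on the training set with the final weights
  logits <- .mlp_logits(W, b, X)
  trainingFP <- lapply(seq_along(classLabels), function(ci)
    sort(logits[y == ci, ci]))
  names(trainingFP) <- classLabels

  new("NDSModel", layerDims = dims, weights = W, biases = b,
      classLabels = classLabels, gridHash = gridHash(train),
      trainingFP = trainingFP, scaling = scaling, seed = as.integer(seed),
      history = list(
        epochs = length(history$loss),
        loss = history$loss,
        valAccuracy = history$valAccuracy,
        bestValAccuracy = if (is.null(validation)) NA_real_ else best$acc,
        bestEpoch = if (is.null(validation)) NA_integer_ else best$epoch))
}

#' Classify a descriptor and read its Feature Prominence score
#'
#' Runs the forward pass, converts the final-layer pre-activations to softmax
#' probabilities, and reports the raw FP score: the pre-softmax output of the
#' scored class (the argmax class by default, ties broken by class order; or
#' a caller-chosen class, e.g. to track the scaphocephalic node across a
#' treatment). When `normalize = TRUE` the FP percentile within the scored
#' class's training distribution is attached.
#'
#' @param model an [NDSModel-class]
#' @param nds an [NDSVector-class] (or numeric vector of matching length)
#' @param scoreClass optional class label whose output node to score
#' @param normalize attach the per-class FP percentile
#' @return an [FPResult-class]
#' @export
predictNDS <- function(model, nds, scoreClass = NULL, normalize = FALSE) {
  stopifnot(is(model, "NDSModel"))
  if (is(nds, "NDSVector")) {
    if (!identical(nds@gridHash, model@gridHash))
      stop("descriptor grid (", nds@gridHash, ") does not match the grid the ",
           "model was trained on (", model@gridHash, ")")
    xv <- nds@densities
  } else xv <- as.numeric(nds)
  if (length(xv) != model@layerDims[1L])
    stop("descriptor length ", length(xv), " does not match the model input ",
         "width ", model@layerDims[1L])
  X <- .apply_scaling(matrix(xv, 1L), model@scaling)
  logits <- .mlp_logits(model@weights, model@biases, X)[1L, ]
  probs <- as.numeric(.softmax_rows(matrix(logits, 1L)))
  names(probs) <- model@classLabels
  cls <- if (is.null(scoreClass)) {
    model@classLabels[which.max(logits)]   # first max wins: class-order ties
  } else {
    if (!scoreClass %in% model@classLabels)
      stop("unknown class: ", scoreClass)
    scoreClass
  }
  fp <- logits[match(cls, model@classLabels)]
  pct <- if (normalize) normalizeFP(fp, model, cls) else NA_real_
  new("FPResult", rawFP = as.numeric(fp), scoredClass = cls,
      probabilities = probs, percentile = pct)
}

#' Classify every sample of an NDSSet
#'
#' @param model an [NDSModel-class]
#' @param x an [NDSSet-class]
#' @param scoreClass optional class label whose FP node to read for every
#'   sample (defaults to each sample's predicted class)
#' @return a data.frame with predicted class, per-class probabilities, rawFP
#'   and fpPercentile per sample
#' @export
predictNDSSet <- function(model, x, scoreClass = NULL) {
  stopifnot(is(model, "NDSModel"), is(x, "NDSSet"))
  if (!identical(gridHash(x), model@gridHash))
    stop("descriptor grid does not match the grid the model was trained on")
  X <- .apply_scaling(.nds_matrix(x), model@scaling)
  logits <- .mlp_logits(model@weights, model@biases, X)
  probs <- .softmax_rows(logits)
  predIdx <- max.col(logits, ties.method = "first")
  scoreIdx <- if (is.null(scoreClass)) predIdx else
    rep(match(scoreClass, model@classLabels), nrow(X))
  fp <- logits[cbind(seq_len(nrow(X)), scoreIdx)]
  pct <- vapply(seq_len(nrow(X)), function(i)
    normalizeFP(fp[i], model, model@classLabels[scoreIdx[i]]), numeric(1))
  out <- data.frame(sample = colnames(x),
                    predicted = model@classLabels[predIdx],
                    rawFP = fp, fpPercentile = pct,
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p_", model@classLabels)
  cbind(out, probs)
}

#' Percentile normalization of a Feature Prominence score
#'
#' The absolute FP value depends on the training set and architecture; the
#' percentile of a score within the scored class's training FP distribution
#' (linear interpolation between order statistics, clamped to [0, 100]) is
#' the comparable scale.
#'
#' @param rawFP pre-softmax class output
#' @param model a trained [NDSModel-class]
#' @param class class label whose training distribution to use
#' @return percentile in [0, 100]
#' @export
normalizeFP <- function(rawFP, model, class) {
  stopifnot(is(model, "NDSModel"))
  if (!length(model@trainingFP))
    stop("model carries no training FP distributions; train it first")
  if (!class %in% names(model@trainingFP)) stop("unknown class: ", class)
  v <- model@trainingFP[[class]]
  if (length(v) < 2L)
    stop("class ", class, " has fewer than 2 training FP values")
  approx(v, seq(0, 100, length.out = length(v)), xout = rawFP,
         rule = 2, ties = "ordered")$y
}

#' Save / load an NDS classifier
#'
#' The archive bundles architecture, weights, class labels, grid fingerprint,
#' feature-scaling statistics and the training FP distributions, so a loaded
#' model refuses descriptors of different provenance.
#'
#' @param model an [NDSModel-class]
#' @param path file path (.rds archive)
#' @return `readNDSModel()`: the [NDSModel-class]
#' @export
saveNDSModel <- function(model, path) {
  stopifnot(is(model, "NDSModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveNDSModel
#' @export
readNDSModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "NDSModel")) stop("file does not contain an NDSModel")
  validObject(model)
  model
}
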