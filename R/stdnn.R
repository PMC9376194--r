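## The spatiotemporal classifier (stDNN): two 1D-convolutional blocks over
## time with brain regions as input channels (each block = valid
## convolution + ReLU), temporal averaging of the second block's feature
## maps, concatenation of a one-hot site vector, and an affine head
## producing two class logits. Class-1 probability is the softmax of the
## logits, which equals the sigmoid of the logit difference. Training
## minimises the label-distribution-aware margin (LDAM) loss with Adam.
##
## Convolutions are computed as matrix products against an im2col
## expansion, so both the forward pass and backpropagation run on BLAS.

#' Classifier configuration
#'
#' @param nRegions input channels Nc (must match the cohort).
#' @param convChannels c(F1, F2) filter counts of the two blocks.
#' @param kernelSizes c(k1, k2) temporal kernel widths (odd).
#' @param strides c(S1, S2) temporal strides.
#' @param siteVocabSize length of the site one-hot input; 0 means "take it
#'   from the cohort at training time".
#' @param ldamC LDAM margin scale C (margins are C * n_j^(-1/4)); 0
#'   disables margins.
#' @param ldamMaxMargin margins are rescaled by a single constant so the
#'   largest equals this cap; NA disables rescaling, leaving margins
#'   linear in C.
#' @param logitScale logit multiplier s of the LDAM loss. With
#'   \code{ldamC = 0, logitScale = 1} training uses plain softmax
#'   cross-entropy.
#' @param learningRate,epochs,batchSize Adam hyperparameters.
#' @param weightDecay decoupled L2 penalty on the weight matrices
#'   (AdamW style; biases are exempt).
#' @param augmentNoiseSd train-time Gaussian noise injection: fresh
#'   N(0, sd) noise is added to every input presentation, so the
#'   network cannot fit subject-specific noise patterns and must rely
#'   on features that survive perturbation (0 disables).
#' @param seed seed for weight initialization and batch shuffling.
#' @return An \code{\linkS4class{StDNNConfig}}.
#' @export
stdnnConfig <- function(nRegions, convChannels = c(64L, 32L),
                        kernelSizes = c(21L, 9L), strides = c(1L, 1L),
                        siteVocabSize = 0L, ldamC = 1.0,
                        ldamMaxMargin = 0.5, logitScale = 30,
                        learningRate = 1e-3, weightDecay = 1e-4,
                        augmentNoiseSd = 1.0, epochs = 60L, batchSize = 16L,
                        seed = 1L) {
  new("StDNNConfig",
      nRegions = as.integer(nRegions),
      convChannels = as.integer(convChannels),
      kernelSizes = as.integer(kernelSizes),
      strides = as.integer(strides),
      siteVocabSize = as.integer(siteVocabSize),
      ldamC = as.numeric(ldamC), ldamMaxMargin = as.numeric(ldamMaxMargin),
      logitScale = as.numeric(logitScale),
      learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay),
      augmentNoiseSd = as.numeric(augmentNoiseSd),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed))
}

#' Per-class LDAM margins
#'
#' Margins are inversely proportional to the fourth root of the class
#' counts, so the rare class receives the larger margin:
#' \eqn{\Delta_j = C \, n_j^{-1/4}}, then all margins are multiplied by
#' one constant so that the largest equals \code{maxMargin}.
#'
#' @param classCounts per-class training counts, all >= 1
#' @param C margin scale, > 0
#' @param maxMargin cap on the largest margin (NA = no rescaling)
#' @return numeric vector of margins, one per class.
#' @export
ldamMargins <- function(classCounts, C = 1, maxMargin = 0.5) {
  if (any(classCounts < 1)) .stopf("class counts must all be >= 1")
  if (C <= 0) .stopf("LDAM margin scale C must be > 0")
  delta <- C * classCounts^(-0.25)
  if (!is.na(maxMargin)) delta <- delta * (maxMargin / max(delta))
  delta
}

## loss and d(loss)/d(logits) in one pass; y in {0,1}
.ldamTerms <- function(logits, y, margins, s) {
  zadj <- logits
  zadj[y + 1L] <- zadj[y + 1L] - margins[y + 1L]
  zs <- s * zadj
  mx <- max(zs)
  lse <- mx + log(sum(exp(zs - mx)))
  p <- exp(zs - lse)
  grad <- s * p
  grad[y + 1L] <- grad[y + 1L] - s
  list(loss = lse - zs[y + 1L], grad = grad)
}

#' LDAM loss for one example
#'
#' \deqn{\ell = -\log\frac{e^{s(z_y-\Delta_y)}}{e^{s(z_y-\Delta_y)} +
#' e^{s z_{1-y}}}}
#' With \eqn{\Delta = 0} and \eqn{s = 1} this is exactly the two-class
#' softmax cross-entropy.
#'
#' @param logits numeric length-2 vector (class-0, class-1 logit)
#' @param label true class, 0 or 1
#' @param margins per-class margins (see \code{\link{ldamMargins}})
#' @param scale logit scale s
#' @return scalar loss.
#' @export
ldamLoss <- function(logits, label, margins = c(0, 0), scale = 1) {
  .assertFinite(logits, "logits")
  .ldamTerms(logits, as.integer(label), margins, scale)$loss
}

## -- convolution plumbing -------------------------------------------------

## unfold X (C x Nt) into (C*k) x L, column j = window starting at (j-1)*S+1;
## row index = channel + C*(tap-1)
.im2col <- function(X, k, S) {
  nt <- ncol(X)
  L <- (nt - k) %/% S + 1L
  tidx <- outer(seq_len(k), (seq_len(L) - 1L) * S, "+")
  matrix(array(X[, as.vector(tidx)], c(nrow(X), k, L)), nrow(X) * k, L)
}

## adjoint of .im2col: fold (C*k) x L back onto C x Nt, accumulating overlaps
.col2im <- function(M, k, S, C, nt) {
  L <- ncol(M)
  out <- matrix(0, C, nt)
  for (tap in seq_len(k)) {
    cols <- (seq_len(L) - 1L) * S + tap
    out[, cols] <- out[, cols] + M[((tap - 1L) * C + 1L):(tap * C), , drop = FALSE]
  }
  out
}

.minNt <- function(cfg) {
  cfg@kernelSizes[1] + cfg@strides[1] * (cfg@kernelSizes[2] - 1L)
}

.initParams <- function(cfg) {
  F1 <- cfg@convChannels[1]; F2 <- cfg@convChannels[2]
  k1 <- cfg@kernelSizes[1]; k2 <- cfg@kernelSizes[2]
  nc <- cfg@nRegions; v <- cfg@siteVocabSize
  list(
    W1 = matrix(rnorm(F1 * nc * k1, sd = sqrt(2 / (nc * k1))), F1, nc * k1),
    b1 = numeric(F1),
    W2 = matrix(rnorm(F2 * F1 * k2, sd = sqrt(2 / (F1 * k2))), F2, F1 * k2),
    b2 = numeric(F2),
    W3 = matrix(rnorm(2 * (F2 + v), sd = sqrt(1 / (F2 + v))), 2, F2 + v),
    b3 = numeric(2)
  )
}

.forwardCore <- function(par, X, siteVec, cfg, keepCache = FALSE) {
  k1 <- cfg@kernelSizes[1]; k2 <- cfg@kernelSizes[2]
  S1 <- cfg@strides[1]; S2 <- cfg@strides[2]
  X1 <- .im2col(X, k1, S1)
  Z1 <- par$W1 %*% X1 + par$b1
  A1 <- Z1 * (Z1 > 0)
  X2 <- .im2col(A1, k2, S2)
  Z2 <- par$W2 %*% X2 + par$b2
  A2 <- Z2 * (Z2 > 0)
  h <- rowMeans(A2)
  u <- c(h, siteVec)
  logits <- drop(par$W3 %*% u) + par$b3
  if (!keepCache) return(list(logits = logits))
  list(logits = logits, X1 = X1, Z1 = Z1, A1 = A1, X2 = X2, Z2 = Z2,
       A2 = A2, u = u, X = X)
}

## gradients of a scalar loss wrt parameters (and optionally the input),
## given dlogits = d(loss)/d(logits)
.backwardCore <- function(par, cache, dlogits, cfg, wantInputGrad = FALSE) {
  F1 <- cfg@convChannels[1]; F2 <- cfg@convChannels[2]
  k1 <- cfg@kernelSizes[1]; k2 <- cfg@kernelSizes[2]
  S1 <- cfg@strides[1]; S2 <- cfg@strides[2]
  L2 <- ncol(cache$A2); L1 <- ncol(cache$A1)
  gW3 <- outer(dlogits, cache$u)
  gb3 <- dlogits
  du <- drop(crossprod(par$W3, dlogits))
  dA2 <- matrix(du[seq_len(F2)] / L2, F2, L2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  gW2 <- tcrossprod(dZ2, cache$X2)
  gb2 <- rowSums(dZ2)
  dA1 <- .col2im(crossprod(par$W2, dZ2), k2, S2, F1, L1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- tcrossprod(dZ1, cache$X1)
  gb1 <- rowSums(dZ1)
  out <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
  if (wantInputGrad)
    out$X <- .col2im(crossprod(par$W1, dZ1), k1, S1, cfg@nRegions,
                     ncol(cache$X))
  out
}

#' Forward pass of a trained model on one subject
#'
#' Timepoints beyond \code{ntValid} (right padding added for batching) are
#' dropped before the convolution, so padded and unpadded inputs yield
#' identical logits.
#'
#' @param model a \code{\linkS4class{TrainedModel}}
#' @param timeseries numeric Nc x Nt matrix
#' @param siteOnehot one-hot site vector of the model's vocabulary length
#'   (all zeros for an unseen site)
#' @param ntValid number of valid (non-padded) timepoints; default all
#' @return list with \code{logits} (length 2) and \code{prob1}, the
#'   softmax probability of class 1.
#' @export
forwardPass <- function(model, timeseries, siteOnehot = NULL, ntValid = NULL) {
  cfg <- model@config
  if (nrow(timeseries) != cfg@nRegions)
    .stopf("input has %d regions but the model expects %d",
           nrow(timeseries), cfg@nRegions)
  if (is.null(siteOnehot)) siteOnehot <- numeric(cfg@siteVocabSize)
  if (length(siteOnehot) != cfg@siteVocabSize)
    .stopf("site one-hot has length %d; model expects %d",
           length(siteOnehot), cfg@siteVocabSize)
  if (!is.null(ntValid))
    timeseries <- timeseries[, seq_len(ntValid), drop = FALSE]
  if (ncol(timeseries) < .minNt(cfg))
    .stopf("input has %d timepoints; the receptive field requires at least %d",
           ncol(timeseries), .minNt(cfg))
  logits <- .forwardCore(model@parameters, timeseries, siteOnehot, cfg)$logits
  z <- logits - max(logits)
  list(logits = logits, prob1 = exp(z[2]) / sum(exp(z)))
}

## -- training -------------------------------------------------------------

.zeroLike <- function(par) lapply(par, function(p) p * 0)

#' Train the stDNN classifier with the LDAM loss
#'
#' Minibatch Adam on the mean LDAM loss over the training subjects.
#' Margins are computed once from the training-set class counts. Fully
#' deterministic given \code{config@seed}. The cohort is expected to be
#' normalized already (see \code{\link{zscoreNormalize}}); training does
#' not rescale inputs.
#'
#' @param cohort a \code{\linkS4class{Cohort}}
#' @param trainIdx indices of the training subjects
#' @param config an \code{\linkS4class{StDNNConfig}}; its
#'   \code{nRegions} must match the cohort and \code{siteVocabSize} must
#'   be 0 (auto) or the cohort's vocabulary length
#' @return A \code{\linkS4class{TrainedModel}}.
#' @export
trainStDNN <- function(cohort, trainIdx = seq_len(nSubjects(cohort)),
                       config = stdnnConfig(nRegions(cohort))) {
  validObject(config)
  if (length(trainIdx) == 0L) .stopf("training index set is empty")
  if (config@nRegions != nRegions(cohort))
    .stopf("config nRegions (%d) does not match cohort (%d)",
           config@nRegions, nRegions(cohort))
  labels <- classLabels(cohort)[trainIdx]
  counts <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(counts == 0L))
    .stopf("training set must contain both classes (counts %d/%d)",
           counts[1], counts[2])
  vocab <- siteVocabulary(cohort)
  if (config@siteVocabSize == 0L) config@siteVocabSize <- length(vocab)
  if (config@siteVocabSize != length(vocab))
    .stopf("config siteVocabSize (%d) does not match cohort (%d sites)",
           config@siteVocabSize, length(vocab))
  margins <- if (config@ldamC > 0)
    ldamMargins(counts, config@ldamC, config@ldamMaxMargin) else c(0, 0)
  s <- config@logitScale
  siteM <- encodeSites(cohort)$matrix[trainIdx, , drop = FALSE]
  ts <- cohort@timeseries[trainIdx]
  minNt <- .minNt(config)
  short <- which(vapply(ts, ncol, integer(1)) < minNt)
  if (length(short))
    .stopf("subjects with Nt below the receptive field (%d): %s", minNt,
           paste(subjectIds(cohort)[trainIdx][short], collapse = ", "))

  .withSeed(config@seed, {
    par <- .initParams(config)
    mAdam <- .zeroLike(par); vAdam <- .zeroLike(par)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    n <- length(trainIdx)
    lossLog <- numeric(config@epochs)
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      starts <- seq(1L, n, by = config@batchSize)
      for (st in starts) {
        batch <- ord[st:min(st + config@batchSize - 1L, n)]
        grad <- .zeroLike(par)
        bl <- 0
        for (i in batch) {
          Xi <- ts[[i]]
          if (config@augmentNoiseSd > 0)
            Xi <- Xi + rnorm(length(Xi), sd = config@augmentNoiseSd)
          fc <- .forwardCore(par, Xi, siteM[i, ], config, keepCache = TRUE)
          lt <- .ldamTerms(fc$logits, labels[i], margins, s)
          bl <- bl + lt$loss
          g <- .backwardCore(par, fc, lt$grad / length(batch), config)
          for (nm in names(grad)) grad[[nm]] <- grad[[nm]] + g[[nm]]
        }
        epochLoss <- epochLoss + bl
        t <- t + 1L
        for (nm in names(par)) {
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * grad[[nm]]
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * grad[[nm]]^2
          mhat <- mAdam[[nm]] / (1 - b1^t)
          vhat <- vAdam[[nm]] / (1 - b2^t)
          step <- mhat / (sqrt(vhat) + eps)
          if (config@weightDecay > 0 && substr(nm, 1L, 1L) == "W")
            step <- step + config@weightDecay * par[[nm]]
          par[[nm]] <- par[[nm]] - config@learningRate * step
        }
      }
      lossLog[epoch] <- epochLoss / n
    }
    new("TrainedModel", config = config, parameters = par,
        siteVocabulary = vocab, classCounts = counts,
        margins = margins, trainingLog = lossLog)
  })
}

#' Predict classes for a cohort
#'
#' Decision rule is the argmax of the logits; margins are a train-time
#' device only. Sites outside the model's vocabulary are encoded as
#' all-zero vectors, so models transfer to cohorts with unseen sites
#' without retraining.
#'
#' @param object a \code{\linkS4class{TrainedModel}}
#' @param cohort a \code{\linkS4class{Cohort}} with matching region count
#' @return list with \code{class} (integer 0/1 per subject) and
#'   \code{prob1} (class-1 softmax probability per subject).
#' @export
setMethod("predict", "TrainedModel", function(object, cohort) {
  if (nRegions(cohort) != object@config@nRegions)
    .stopf("cohort has %d regions but the model expects %d",
           nRegions(cohort), object@config@nRegions)
  siteM <- encodeSites(siteLabels(cohort), object@siteVocabulary)$matrix
  n <- nSubjects(cohort)
  prob1 <- numeric(n)
  for (i in seq_len(n))
    prob1[i] <- forwardPass(object, cohort@timeseries[[i]], siteM[i, ])$prob1
  list(class = as.integer(prob1 > 0.5), prob1 = prob1)
})

setMethod("show", "TrainedModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "TrainedModel (stDNN): Nc=%d, conv %d>%d (k=%d/%d), %d sites\n",
    "  class counts %d/%d, margins %.3f/%.3f, final loss %.4f\n"),
    cfg@nRegions, cfg@convChannels[1], cfg@convChannels[2],
    cfg@kernelSizes[1], cfg@kernelSizes[2], cfg@siteVocabSize,
    object@classCounts[1], object@classCounts[2],
    object@margins[1], object@margins[2],
    if (length(object@trainingLog)) object@trainingLog[length(object@trainingLog)]
    else NA_real_))
})

#' Save / load a trained model container
#'
#' A single-file binary container (RDS) holding the weights together with
#' the configuration and site vocabulary.
#'
#' @param model a \code{\linkS4class{TrainedModel}}
#' @param path file path
#' @return \code{loadModel} returns the \code{TrainedModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(list(container = "stFingerprint.TrainedModel", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "stFingerprint.TrainedModel"))
    .stopf("%s is not a stFingerprint model container", path)
  validObject(obj$model)
  obj$model
}
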