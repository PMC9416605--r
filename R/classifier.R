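## Two-layer feedforward pattern-recognition network: logistic-sigmoid
## hidden layer, softmax output over the six movement classes, trained by
## full-batch Adam on the cross-entropy of a stratified train partition
## with patience-based early stopping on validation loss.

#' Network and experiment configuration
#'
#' @param hiddenSize hidden-layer width; the experiment grid of the
#'   reference study uses 34, 49 and 63.
#' @param splitFractions train/validation/test fractions (positive,
#'   summing to 1).
#' @param maxEpochs training-epoch cap (default 1000, comfortably above
#'   the 91-134 epochs typical of the reference runs).
#' @param patience consecutive epochs without validation-loss improvement
#'   tolerated before stopping; `Inf` disables early stopping.
#' @param minDelta smallest validation-loss decrease counted as an
#'   improvement by the stopping rule.
#' @param learningRate Adam step size.
#' @param scaling per-feature input standardization fitted on the
#'   training partition: `"zscore"` (default; mean 0, sd 1), `"minmax"`
#'   (map the training range to \[-1, 1\]) or `"none"`. FFT magnitudes
#'   are heavy-tailed, which leaves min-max-scaled features pinned near
#'   -1; z-scoring keeps full-batch training well-conditioned.
#' @param seed seed for the split, weight init and any shuffling.
#' @return A `NetConfig` list.
#' @examples
#' netConfig(hiddenSize = 49)
#' @export
netConfig <- function(hiddenSize = 49, splitFractions = c(0.70, 0.15, 0.15),
                      maxEpochs = 1000, patience = 6, minDelta = 1e-4,
                      learningRate = 0.01,
                      scaling = c("zscore", "minmax", "none"),
                      seed = 1L) {
  scaling <- match.arg(scaling)
  if (length(splitFractions) != 3L || any(splitFractions < 0) ||
      abs(sum(splitFractions) - 1) > 1e-9)
    stopf("splitFractions must be 3 non-negative values summing to 1")
  cfg <- list(hiddenSize = as.integer(hiddenSize),
              splitFractions = splitFractions,
              maxEpochs = as.integer(maxEpochs), patience = patience,
              minDelta = minDelta, learningRate = learningRate,
              scaling = scaling, seed = as.integer(seed))
  class(cfg) <- c("NetConfig", "list")
  cfg
}

## Largest-remainder allocation of n_c class instances to the 3 partitions.
## Remainder ties alternate direction with the class index so leftovers
## spread evenly across partitions (540 instances at 0.70/0.15/0.15 ->
## 378/81/81: odd classes send the spare instance to validation, even
## classes to test).
classQuota <- function(nc, fractions, classIndex) {
  exact <- nc * fractions
  base <- floor(exact)
  left <- nc - sum(base)
  if (left > 0) {
    frac <- exact - base
    tie <- if (classIndex %% 2L) seq_along(frac) else rev(seq_along(frac))
    pri <- order(-frac, tie)
    base[pri[seq_len(left)]] <- base[pri[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Random partition stratified by movement class: within each class the
#' instances are shuffled (seeded) and allocated to the three partitions
#' by largest-remainder quotas, the per-class tie-break rotating across
#' classes so global partition sizes match the rounded fractions (540
#' instances at 0.70/0.15/0.15 give 378/81/81). Disjoint and exhaustive.
#'
#' @param gd a [GestureDataset-class] (or a character vector of labels).
#' @param config a [netConfig()].
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(gd, config = netConfig()) {
  labels <- if (is.character(gd)) gd
            else as.character(SummarizedExperiment::colData(gd)$movement)
  lv <- unique(labels)
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  withSeed(deriveSeed(config$seed, 1L), {
    for (ci in seq_along(lv)) {
      idx <- which(labels == lv[ci])
      if (length(idx) < sum(config$splitFractions > 0))
        stopf("class %s has too few instances (%d) to stratify",
              lv[ci], length(idx))
      idx <- sample(idx)
      q <- classQuota(length(idx), config$splitFractions, ci)
      parts$train <- c(parts$train, idx[seq_len(q[1L])])
      parts$validation <- c(parts$validation,
                            idx[q[1L] + seq_len(q[2L])])
      parts$test <- c(parts$test, idx[q[1L] + q[2L] + seq_len(q[3L])])
    }
  })
  lapply(parts, sort)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

netForward <- function(X, W1, b1, W2, b2) {
  H <- sigmoid(sweep(X %*% W1, 2L, b1, "+"))
  P <- softmaxRows(sweep(H %*% W2, 2L, b2, "+"))
  list(H = H, P = P)
}

crossEntropy <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

#' Train the gesture classification network
#'
#' Fits the two-layer sigmoid/softmax network by full-batch Adam on the
#' cross-entropy of the training partition. Training stops at
#' `maxEpochs`, or once the validation loss has failed to improve for
#' `patience` consecutive epochs; the weights at the best validation loss
#' are kept. Deterministic given `config$seed`.
#'
#' @param gd a [GestureDataset-class].
#' @param config a [netConfig()].
#' @param partitions optional partition list from [splitDataset()]
#'   (recomputed from `config` when omitted).
#' @return A [GestureNet-class]; `@history` records the loss traces,
#'   epochs run, stop reason and wall time.
#' @examples
#' \donttest{
#' co <- synthCohort(cohortSpec(nSubjects = 2, armsPerSubject = 1))
#' segs <- unlist(lapply(co$sessions, segmentSession), recursive = FALSE)
#' gd <- assembleMatrix(segs, mode = "average")
#' net <- trainGestureNet(gd, netConfig(hiddenSize = 20, maxEpochs = 150))
#' }
#' @export
trainGestureNet <- function(gd, config = netConfig(), partitions = NULL) {
  X <- featureMatrix(gd)
  Y <- labelMatrix(gd)
  lv <- colnames(Y)
  if (is.null(partitions)) partitions <- splitDataset(gd, config)
  if (!length(partitions$validation) && is.finite(config$patience))
    stopf("patience-based stopping requires a non-empty validation partition")
  tr <- partitions$train
  va <- partitions$validation
  if (config$scaling == "minmax") {
    lo <- apply(X[tr, , drop = FALSE], 2L, min)
    hi <- apply(X[tr, , drop = FALSE], 2L, max)
    center <- (hi + lo) / 2
    half <- (hi - lo) / 2
    half[half <= 0] <- 1
  } else if (config$scaling == "zscore") {
    center <- colMeans(X[tr, , drop = FALSE])
    half <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    half[half <= 0] <- 1
  } else {
    center <- rep(0, ncol(X)); half <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, half, "/")
  d <- ncol(X); h <- config$hiddenSize; k <- ncol(Y)
  withSeed(deriveSeed(config$seed, 2L), {
    W1 <- matrix(runif(d * h, -1, 1) * sqrt(6 / (d + h)), d, h)
    W2 <- matrix(runif(h * k, -1, 1) * sqrt(6 / (h + k)), h, k)
  })
  b1 <- numeric(h); b2 <- numeric(k)
  m <- list(W1 = W1 * 0, b1 = b1, W2 = W2 * 0, b2 = b2)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learningRate
  Xtr <- Xs[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xva <- Xs[va, , drop = FALSE]; Yva <- Y[va, , drop = FALSE]
  n <- nrow(Xtr)
  best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0L)
  fails <- 0L
  trainLoss <- valLoss <- numeric(0)
  stopReason <- "max epochs reached"
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(config$maxEpochs)) {
    fw <- netForward(Xtr, W1, b1, W2, b2)
    loss <- crossEntropy(fw$P, Ytr)
    if (!is.finite(loss))
      stopf("training diverged: non-finite loss at epoch %d", epoch)
    dZ <- (fw$P - Ytr) / n
    gW2 <- crossprod(fw$H, dZ); gb2 <- colSums(dZ)
    dH <- (dZ %*% t(W2)) * fw$H * (1 - fw$H)
    gW1 <- crossprod(Xtr, dH); gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (p in names(grads)) {
      m[[p]] <- beta1 * m[[p]] + (1 - beta1) * grads[[p]]
      v[[p]] <- beta2 * v[[p]] + (1 - beta2) * grads[[p]]^2
      mh <- m[[p]] / (1 - beta1^epoch)
      vh <- v[[p]] / (1 - beta2^epoch)
      step <- lr * mh / (sqrt(vh) + eps)
      if (p == "W1") W1 <- W1 - step
      if (p == "b1") b1 <- b1 - step
      if (p == "W2") W2 <- W2 - step
      if (p == "b2") b2 <- b2 - step
    }
    trainLoss <- c(trainLoss, loss)
    if (length(va)) {
      vl <- crossEntropy(netForward(Xva, W1, b1, W2, b2)$P, Yva)
      valLoss <- c(valLoss, vl)
      if (vl < best$loss - config$minDelta) {
        best <- list(loss = vl, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     epoch = epoch)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$patience) {
          stopReason <- sprintf("validation stop after %d failures", fails)
          break
        }
      }
    }
  }
  wall <- proc.time()[["elapsed"]] - t0
  if (length(va) && is.finite(best$loss)) {
    W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
  }
  new("GestureNet", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      scaleCenter = center, scaleHalf = half, classLevels = lv,
      config = unclass(config),
      history = list(epochs = length(trainLoss), trainLoss = trainLoss,
                     valLoss = valLoss, stopReason = stopReason,
                     bestEpoch = best$epoch, wallTime = wall))
}

#' Predict with a trained GestureNet
#'
#' @param net a [GestureNet-class].
#' @param X instances x features matrix (raw feature scale; the net
#'   applies its stored scaling) or a [GestureDataset-class].
#' @param type `"class"` for labels, `"prob"` for the softmax matrix
#'   (rows sum to 1).
#' @return Character vector of class labels, or a probability matrix.
#' @export
predictGestureNet <- function(net, X, type = c("class", "prob")) {
  type <- match.arg(type)
  if (is(X, "GestureDataset")) X <- featureMatrix(X)
  if (ncol(X) != nrow(net@W1))
    stopf("feature dimension mismatch: net expects %d, got %d",
          nrow(net@W1), ncol(X))
  Xs <- sweep(sweep(X, 2L, net@scaleCenter), 2L, net@scaleHalf, "/")
  P <- netForward(Xs, net@W1, net@b1, net@W2, net@b2)$P
  colnames(P) <- net@classLevels
  if (type == "prob") return(P)
  net@classLevels[max.col(P, ties.method = "first")]
}

#' Confusion counts for a set of predictions
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param levels class levels fixing the matrix order.
#' @return Square count matrix, rows = true class, columns = predicted.
#' @export
confusionCounts <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels)) |>
    unclass()
}

reportFromConfusion <- function(confusion, epochs = NA_integer_) {
  lv <- rownames(confusion[[1L]])
  acc <- vapply(confusion, function(cm) sum(diag(cm)) / max(sum(cm), 1), 0)
  sens <- vapply(confusion, function(cm) {
    rs <- rowSums(cm)
    ifelse(rs > 0, diag(cm) / rs, 0)
  }, numeric(length(lv)))
  prec <- vapply(confusion, function(cm) {
    cs <- colSums(cm)
    ifelse(cs > 0, diag(cm) / cs, 0)
  }, numeric(length(lv)))
  rownames(sens) <- rownames(prec) <- lv
  new("ConfusionReport", confusion = confusion, accuracy = acc,
      sensitivity = sens, precision = prec,
      epochsRun = as.integer(epochs))
}

#' Evaluate a trained network on the dataset partitions
#'
#' Argmax-of-softmax decisions, summarized per partition as a confusion
#' matrix (rows = true class, columns = predicted) with per-class
#' sensitivity (diagonal over row sum), per-class precision (diagonal
#' over column sum, 0 for empty columns) and overall accuracy (trace over
#' total).
#'
#' @param net a [GestureNet-class].
#' @param gd the [GestureDataset-class] it was trained on.
#' @param partitions partition list from [splitDataset()].
#' @return A [ConfusionReport-class].
#' @export
evaluateGestureNet <- function(net, gd, partitions) {
  X <- featureMatrix(gd)
  truth <- as.character(SummarizedExperiment::colData(gd)$movement)
  pred <- predictGestureNet(net, X)
  lv <- net@classLevels
  parts <- c(partitions[c("train", "validation", "test")],
             list(overall = sort(unlist(partitions, use.names = FALSE))))
  confusion <- lapply(parts, function(idx)
    confusionCounts(truth[idx], pred[idx], lv))
  reportFromConfusion(confusion, net@history$epochs)
}

#' Accessors for ConfusionReport
#'
#' @param report a [ConfusionReport-class].
#' @param partition `"train"`, `"validation"`, `"test"` or `"overall"`.
#' @return `confusion()` the count matrix; `accuracy()` the fraction
#'   correct; `sensitivity()`/`precision()` per-class vectors.
#' @name report-accessors
#' @export
confusion <- function(report, partition = "test")
  report@confusion[[partition]]

#' @rdname report-accessors
#' @export
accuracy <- function(report, partition = "test")
  unname(report@accuracy[partition])

#' @rdname report-accessors
#' @export
sensitivity <- function(report, partition = "test")
  report@sensitivity[, partition]

#' @rdname report-accessors
#' @export
precision <- function(report, partition = "test")
  report@precision[, partition]

#' Nearest-centroid baseline
#'
#' Brute-force reference classifier: per-class mean feature vectors on
#' the z-scored training partition, Euclidean nearest centroid at
#' prediction. Used as an independent floor when judging the network's
#' accuracy on separable synthetic cohorts.
#'
#' @param gd a [GestureDataset-class].
#' @param partitions partition list from [splitDataset()].
#' @return Test-partition accuracy (fraction).
#' @export
baselineNearestCentroid <- function(gd, partitions) {
  X <- featureMatrix(gd)
  yy <- as.character(SummarizedExperiment::colData(gd)$movement)
  tr <- partitions$train; te <- partitions$test
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  sdv[sdv <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  lv <- sort(unique(yy[tr]))
  cen <- t(vapply(lv, function(cl)
    colMeans(Xs[tr[yy[tr] == cl], , drop = FALSE]), numeric(ncol(Xs))))
  d2 <- vapply(seq_len(nrow(cen)), function(i)
    rowSums(sweep(Xs[te, , drop = FALSE], 2L, cen[i, ])^2),
    numeric(length(te)))
  pred <- lv[max.col(-d2, ties.method = "first")]
  mean(pred == yy[te])
}

#' Save / load a trained network as portable JSON
#'
#' @param net a [GestureNet-class].
#' @param path output `.json` path.
#' @return `writeGestureNet()` returns `path` invisibly;
#'   `readGestureNet()` the reconstructed [GestureNet-class].
#' @export
writeGestureNet <- function(net, path) {
  jsonlite::write_json(
    list(dims = c(nrow(net@W1), ncol(net@W1), ncol(net@W2)),
         W1 = net@W1, b1 = net@b1, W2 = net@W2, b2 = net@b2,
         scaleCenter = net@scaleCenter, scaleHalf = net@scaleHalf,
         classLevels = net@classLevels, config = net@config,
         history = net@history[c("epochs", "stopReason", "wallTime")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGestureNet
#' @export
readGestureNet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- j$config
  new("GestureNet", W1 = as.matrix(j$W1), b1 = as.numeric(j$b1),
      W2 = as.matrix(j$W2), b2 = as.numeric(j$b2),
      scaleCenter = as.numeric(j$scaleCenter),
      scaleHalf = as.numeric(j$scaleHalf),
      classLevels = as.character(j$classLevels), config = as.list(cfg),
      history = list(epochs = j$history$epochs,
                     stopReason = j$history$stopReason,
                     wallTime = j$history$wallTime))
}

#' Run the mode x hidden-size experiment grid
#'
#' Trains and evaluates one network per (feature mode, hidden size) cell
#' and reports the per-partition accuracies, epochs run and wall time,
#' mirroring the summary-table layout of the reference experiment.
#'
#' @param datasets named list with the assembled [GestureDataset-class]
#'   objects to use per mode, e.g. `list(average = gdAvg, full = gdFull)`
#'   (omit a mode to skip it).
#' @param hidden hidden sizes to evaluate (default 34, 49, 63).
#' @param config base [netConfig()]; `hiddenSize` is overridden per cell.
#' @return data.frame with one row per cell: mode, hidden, train /
#'   validation / test / overall accuracy, epochs, seconds.
#' @export
runExperimentGrid <- function(datasets, hidden = c(34, 49, 63),
                              config = netConfig()) {
  rows <- list()
  for (mode in names(datasets)) {
    for (h in hidden) {
      cfg <- config
      cfg$hiddenSize <- as.integer(h)
      parts <- splitDataset(datasets[[mode]], cfg)
      net <- trainGestureNet(datasets[[mode]], cfg, parts)
      rep <- evaluateGestureNet(net, datasets[[mode]], parts)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, hidden = as.integer(h),
        train = accuracy(rep, "train"),
        validation = accuracy(rep, "validation"),
        test = accuracy(rep, "test"),
        overall = accuracy(rep, "overall"),
        epochs = net@history$epochs,
        seconds = round(net@history$wallTime, 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot a confusion matrix
#'
#' Simple count heatmap with per-cell counts, rows = true class,
#' columns = predicted.
#'
#' @param report a [ConfusionReport-class].
#' @param partition which partition to plot.
#' @param main plot title.
#' @return Invisibly, the plotted matrix.
#' @export
plotConfusion <- function(report, partition = "test", main = NULL) {
  cm <- report@confusion[[partition]]
  k <- nrow(cm)
  if (is.null(main))
    main <- sprintf("%s confusion (accuracy %.1f%%)", partition,
                    100 * report@accuracy[[partition]])
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, ]),
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = main)
  graphics::axis(1, seq_len(k), colnames(cm))
  graphics::axis(2, seq_len(k), rev(rownames(cm)), las = 2)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i, cm[i, j],
                   col = if (cm[i, j] > max(cm) / 2) "white" else "black")
  invisible(cm)
}
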