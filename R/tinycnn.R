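#' A desk-scale trainable CNN with swappable activations
#'
#' `makeTinyCNN()` builds a small two-conv-block image classifier (two valid
#' 3x3 convolutions with mean pooling, a dense softmax head, well under 50k
#' parameters) that conforms to the trainer port, so it can be driven by
#' [runAFCS()]. Both convolution nonlinearities are registered as swappable
#' activation sites; the softmax head is not a site and is never swapped.
#' Training uses mini-batch Adamax (the infinity-norm variant of Adam) at its
#' default step size with categorical cross-entropy, and every source of
#' randomness (weight init, batch order) is a deterministic function of the
#' seed and epoch counter, so snapshot/restore round-trips are exact and runs
#' are bit-reproducible.
#'
#' @param dataset a dataset from [makeBlobDataset()], or any list with
#'   `images` (`n x S x S x 3`, values 0–255) and `labels` (integer `1..K`).
#' @param split named list of index vectors (`train`, `validation`, `test`);
#'   default: a stratified 70/15/15 split with the trainer's seed.
#' @param activation initial activation name.
#' @param seed integer seed for initialisation and batch order.
#' @param batchSize mini-batch size (default 16).
#' @param learningRate Adamax step size (default 0.002).
#' @param filters filter counts of the two conv blocks.
#' @param catalog candidate [activationCatalog()] the trainer can swap among.
#' @return a `TinyCNNTrainer`.
#' @examples
#' ds <- makeBlobDataset(nClasses = 2, nPerClass = 8, imageSize = 16, seed = 1)
#' tr <- makeTinyCNN(ds, seed = 1)
#' loss <- trainOneEpoch(tr)
#' @export
makeTinyCNN <- function(dataset, split = NULL, activation = "ReLU", seed = 1L,
                        batchSize = 16L, learningRate = 0.002,
                        filters = c(8L, 12L),
                        catalog = activationCatalog(defaultActivationNames())) {
  X <- dataset$images; y <- as.integer(dataset$labels)
  stopifnot(length(dim(X)) == 4L, dim(X)[1] == length(y))
  K <- max(y)
  if (is.null(split))
    split <- splitDataset(y, c(0.7, 0.15, 0.15), seed = seed, stratified = TRUE)
  S <- dim(X)[2]
  if (S < 12L) stop("images too small for two conv blocks", call. = FALSE)
  F1 <- as.integer(filters[1]); F2 <- as.integer(filters[2])
  H1 <- S - 2L; H2 <- H1 %/% 2L; H3 <- H2 - 2L; H4 <- H3 %/% 2L
  D <- H4 * H4 * F2
  e <- new.env(parent = emptyenv())
  e$dims <- list(S = S, K = K, F1 = F1, F2 = F2, D = D)
  e$data <- lapply(stats::setNames(nm = names(split)), function(s)
    list(X = X[split[[s]], , , , drop = FALSE] / 255, y = y[split[[s]]]))
  e$catalog <- catalog
  e$sites <- c("conv1", "conv2")
  if (!activation %in% names(catalog))
    stop("activation '", activation, "' not in catalog", call. = FALSE)
  e$af <- activation
  e$seed <- as.integer(seed)
  e$lr <- learningRate; e$batch <- as.integer(batchSize)
  e$beta1 <- 0.9; e$beta2 <- 0.999; e$epsAdam <- 1e-7
  e$epoch <- 0L; e$adamT <- 0L
  withr::with_seed(e$seed, {
    he <- function(fanIn, ...) array(stats::rnorm(prod(c(...))) * sqrt(2 / fanIn), c(...))
    e$W <- list(W1 = he(9 * 3, 3, 3, 3, F1),   b1 = numeric(F1),
                W2 = he(9 * F1, 3, 3, F1, F2), b2 = numeric(F2),
                W3 = he(D, D, K),              b3 = numeric(K))
  })
  e$m <- lapply(e$W, function(w) array(0, dim(w) %||% length(w)))
  e$u <- lapply(e$W, function(w) array(0, dim(w) %||% length(w)))
  e$idxCache <- list()
  new("TinyCNNTrainer", state = e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname makeTinyCNN
#' @export
setClass("TinyCNNTrainer", representation(state = "environment"))

setMethod("show", "TinyCNNTrainer", function(object) {
  e <- object@state
  cat("TinyCNNTrainer:", e$dims$K, "classes,",
    sum(vapply(e$W, length, 1L)), "parameters; epoch", e$epoch,
    "; active:", e$af, "\n")
})

# ---- array helpers ------------------------------------------------------

# patch-index matrix for valid 3x3 conv over X of dim (B, H, W, C):
# rows ordered (b, i, j) fastest-first, cols ordered (di, dj, c) to match the
# column-major flattening of a (3, 3, C, K) weight array
.convIdx <- function(B, H, W, C) {
  OH <- H - 2L; OW <- W - 2L
  g <- expand.grid(b = seq_len(B), i = seq_len(OH), j = seq_len(OW))
  base <- g$b + B * ((g$i - 1L) + H * (g$j - 1L))
  o <- expand.grid(di = 0:2, dj = 0:2, c = 0:(C - 1L))
  off <- B * (o$di + H * (o$dj + W * o$c))
  list(idx = outer(base, off, "+"), OH = OH, OW = OW)
}

.getIdx <- function(e, B, H, W, C) {
  key <- paste(B, H, W, C, sep = "_")
  if (is.null(e$idxCache[[key]])) e$idxCache[[key]] <- .convIdx(B, H, W, C)
  e$idxCache[[key]]
}

.convFwd <- function(e, X, W, b) {
  d <- dim(X)
  ix <- .getIdx(e, d[1], d[2], d[3], d[4])
  XC <- matrix(X[ix$idx], nrow = nrow(ix$idx))
  out <- sweep(XC %*% matrix(W, ncol = dim(W)[4]), 2, b, "+")
  list(out = array(out, c(d[1], ix$OH, ix$OW, dim(W)[4])), XC = XC, inDim = d)
}

.convBwd <- function(e, fwd, W, dOut) {
  K <- dim(W)[4]
  dM <- matrix(dOut, ncol = K)
  dW <- array(crossprod(fwd$XC, dM), dim(W))
  db <- colSums(dM)
  dXC <- tcrossprod(dM, matrix(W, ncol = K))
  d <- fwd$inDim
  ix <- .getIdx(e, d[1], d[2], d[3], d[4])
  dX <- numeric(prod(d))
  for (col in seq_len(ncol(dXC))) {
    ii <- ix$idx[, col]
    dX[ii] <- dX[ii] + dXC[, col]
  }
  list(dX = array(dX, d), dW = dW, db = db)
}

# 2x2 non-overlapping mean pool (odd trailing row/col cropped)
.poolFwd <- function(a) {
  d <- dim(a); H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  o1 <- seq.int(1L, 2L * H2, 2L); o2 <- seq.int(1L, 2L * W2, 2L)
  p <- (a[, o1, o2, , drop = FALSE] + a[, o1 + 1L, o2, , drop = FALSE] +
        a[, o1, o2 + 1L, , drop = FALSE] + a[, o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
  list(p = p, inDim = d)
}

.poolBwd <- function(fwd, dP) {
  d <- fwd$inDim; H2 <- dim(dP)[2]; W2 <- dim(dP)[3]
  o1 <- seq.int(1L, 2L * H2, 2L); o2 <- seq.int(1L, 2L * W2, 2L)
  da <- array(0, d)
  q <- dP / 4
  da[, o1, o2, ] <- q; da[, o1 + 1L, o2, ] <- q
  da[, o1, o2 + 1L, ] <- q; da[, o1 + 1L, o2 + 1L, ] <- q
  da
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# full forward pass; returns caches when training
.tinyForward <- function(e, X, keep = FALSE) {
  spec <- e$catalog[[e$af]]
  c1 <- .convFwd(e, X, e$W$W1, e$W$b1)
  a1 <- spec@f(c1$out)
  p1 <- .poolFwd(a1)
  c2 <- .convFwd(e, p1$p, e$W$W2, e$W$b2)
  a2 <- spec@f(c2$out)
  p2 <- .poolFwd(a2)
  B <- dim(X)[1]
  flat <- matrix(p2$p, nrow = B)
  z <- sweep(flat %*% e$W$W3, 2, e$W$b3, "+")
  probs <- .softmax(z)
  if (!keep) return(list(probs = probs))
  list(probs = probs, c1 = c1, c2 = c2, p1 = p1, p2 = p2, flat = flat, spec = spec)
}

.tinyBackward <- function(e, fw, y) {
  B <- nrow(fw$probs); K <- ncol(fw$probs)
  dz <- fw$probs
  dz[cbind(seq_len(B), y)] <- dz[cbind(seq_len(B), y)] - 1
  dz <- dz / B
  g <- list()
  g$W3 <- crossprod(fw$flat, dz); g$b3 <- colSums(dz)
  dFlat <- tcrossprod(dz, e$W$W3)
  dP2 <- array(dFlat, dim(fw$p2$p))
  dA2 <- .poolBwd(fw$p2, dP2)
  dC2 <- dA2 * fw$spec@g(fw$c2$out)
  b2g <- .convBwd(e, fw$c2, e$W$W2, dC2)
  g$W2 <- b2g$dW; g$b2 <- b2g$db
  dA1 <- .poolBwd(fw$p1, b2g$dX)
  dC1 <- dA1 * fw$spec@g(fw$c1$out)
  b1g <- .convBwd(e, fw$c1, e$W$W1, dC1)
  g$W1 <- b1g$dW; g$b1 <- b1g$db
  g[names(e$W)]
}

.adamaxStep <- function(e, grads) {
  e$adamT <- e$adamT + 1L
  corr <- e$lr / (1 - e$beta1^e$adamT)
  for (nm in names(e$W)) {
    e$m[[nm]] <- e$beta1 * e$m[[nm]] + (1 - e$beta1) * grads[[nm]]
    e$u[[nm]] <- pmax(e$beta2 * e$u[[nm]], abs(grads[[nm]]))
    e$W[[nm]] <- e$W[[nm]] - corr * e$m[[nm]] / (e$u[[nm]] + e$epsAdam)
  }
}

.mixSeed <- function(seed, epoch) {
  as.integer((as.double(seed) * 1009 + as.double(epoch) * 7919) %% 2147483647)
}

.valLoss <- function(e) {
  v <- e$data$validation %||% e$data$test
  fw <- .tinyForward(e, v$X)
  p <- fw$probs[cbind(seq_along(v$y), v$y)]
  -mean(log(pmin(pmax(p, 1e-7), 1)))
}

# ---- trainer port -------------------------------------------------------

#' @rdname trainer-port
#' @export
setMethod("trainOneEpoch", "TinyCNNTrainer", function(object, ...) {
  e <- object@state
  e$epoch <- e$epoch + 1L
  tr <- e$data$train
  n <- length(tr$y)
  ord <- withr::with_seed(.mixSeed(e$seed, e$epoch), sample.int(n))
  starts <- seq.int(1L, n, by = e$batch)
  for (s in starts) {
    take <- ord[s:min(s + e$batch - 1L, n)]
    fw <- .tinyForward(e, tr$X[take, , , , drop = FALSE], keep = TRUE)
    .adamaxStep(e, .tinyBackward(e, fw, tr$y[take]))
  }
  .valLoss(e)
})

#' @rdname trainer-port
#' @export
setMethod("snapshotModel", "TinyCNNTrainer", function(object, ...) {
  e <- object@state
  list(W = e$W, m = e$m, u = e$u, adamT = e$adamT, epoch = e$epoch, af = e$af)
})

#' @rdname trainer-port
#' @export
setMethod("restoreModel", "TinyCNNTrainer", function(object, token, ...) {
  e <- object@state
  e$W <- token$W; e$m <- token$m; e$u <- token$u
  e$adamT <- token$adamT; e$epoch <- token$epoch; e$af <- token$af
  invisible(object)
})

#' @rdname trainer-port
#' @export
setMethod("setActivation", "TinyCNNTrainer", function(object, name, ...) {
  e <- object@state
  if (length(e$sites) == 0L)
    stop("model declares no swappable activation sites", call. = FALSE)
  if (!name %in% names(e$catalog))
    stop("activation '", name, "' not in catalog", call. = FALSE)
  e$af <- name
  invisible(object)
})

#' @rdname trainer-port
#' @export
setMethod("currentEpoch", "TinyCNNTrainer", function(object) object@state$epoch)

#' @rdname trainer-port
#' @export
setMethod("activeActivation", "TinyCNNTrainer", function(object) object@state$af)

#' @rdname trainer-port
#' @export
setMethod("modelParameters", "TinyCNNTrainer", function(object) object@state$W)

#' @rdname trainer-port
#' @export
setMethod("seedModel", "TinyCNNTrainer", function(object, seed) {
  object@state$seed <- as.integer(seed)
  invisible(object)
})

#' @rdname trainer-port
#' @export
setMethod("evaluateModel", "TinyCNNTrainer", function(object, split = "test", ...) {
  e <- object@state
  d <- e$data[[split]]
  if (is.null(d)) stop("no '", split, "' split on this trainer", call. = FALSE)
  fw <- .tinyForward(e, d$X)
  pred <- max.col(fw$probs, ties.method = "first")
  cm <- confusionMatrix(d$y, pred, e$dims$K)
  m <- classificationMetrics(cm)
  m$loss <- categoricalCrossentropy(fw$probs, d$y)
  m$confusion <- cm
  m
})

#' Class probabilities from a trainer
#'
#' Runs the forward pass of a [makeTinyCNN()] trainer on a batch of images.
#'
#' @param object a `TinyCNNTrainer`.
#' @param images `n x S x S x 3` array, values 0–255.
#' @return `n x K` matrix of class probabilities.
#' @export
setGeneric("predictModel", function(object, images) standardGeneric("predictModel"))

#' @rdname predictModel
#' @export
setMethod("predictModel", "TinyCNNTrainer", function(object, images) {
  .tinyForward(object@state, images / 255)$probs
})

# hidden activations at the two swappable sites (used by contract tests)
.tinyHidden <- function(object, images) {
  e <- object@state
  fw <- .tinyForward(e, images / 255, keep = TRUE)
  spec <- e$catalog[[e$af]]
  list(a1 = spec@f(fw$c1$out), a2 = spec@f(fw$c2$out))
}
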