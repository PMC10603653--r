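# The self-attention MLP head. This is the only trainable component of
# the method: a shallow fully connected trunk (nHiddenLayers hidden
# dense layers, ReLU, dropout) over a fusion-weight row, with additive
# self-attention branches over the role slices of the row (features /
# names / descriptions) merged into the trunk after the first dense
# layer, and a residual input projection gated by a learned scalar.
# Forward, backprop and Adam are implemented directly in base R.

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Adapter configuration
#'
#' Shape and regularisation of the self-attention MLP head. The
#' defaults are the reported best structure: two hidden dense layers,
#' three attention branches, 256 hidden nodes, dropout 0.1.
#'
#' @param inputDim fusion-row length 2K+M.
#' @param outputDim class count K (inputDim >= outputDim >= 2).
#' @param hiddenDim hidden nodes per dense layer (default 256).
#' @param nHiddenLayers hidden dense layers (default 2).
#' @param nBranches self-attention branches (default 3). With 3
#'   branches and role information available, branches are role-aligned
#'   (features / names / descriptions); otherwise the input is split
#'   into contiguous near-equal slices.
#' @param attnDim dimensionality of the additive-attention scoring
#'   space inside each branch (default 64); the branch summary itself
#'   is always hiddenDim wide.
#' @param dropout dropout rate in [0,1) after each hidden layer
#'   (default 0.1); active only in training mode.
#' @param useAttention,useResidual structural ablation flags; turning
#'   either off removes the corresponding parameters entirely.
#' @param nFeatures M, used for role-aligned slicing; \code{NA} falls
#'   back to contiguous slices.
#' @param nClasses bank species count K used for role-aligned slicing
#'   (the name and description blocks are K positions each). Defaults
#'   to \code{(inputDim - nFeatures)/2}; it may exceed outputDim when
#'   the head is trained over a subset of bank classes.
#' @param seed initialisation seed.
#' @return validated config list (class \code{"adapterConfig"}).
#' @export
adapterConfig <- function(inputDim, outputDim, hiddenDim = 256L,
                          nHiddenLayers = 2L, nBranches = 3L,
                          attnDim = 64L, dropout = 0.1, useAttention = TRUE,
                          useResidual = TRUE, nFeatures = NA_integer_,
                          nClasses = NA_integer_, seed = 0L) {
  inputDim <- as.integer(inputDim); outputDim <- as.integer(outputDim)
  if (is.na(inputDim) || is.na(outputDim) || inputDim < outputDim ||
      outputDim < 2L)
    stop("need inputDim >= outputDim >= 2", call. = FALSE)
  if (hiddenDim < 1L || nHiddenLayers < 1L || nBranches < 1L || attnDim < 1L)
    stop("hiddenDim, nHiddenLayers, nBranches and attnDim must be positive",
         call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  nFeatures <- as.integer(nFeatures); nClasses <- as.integer(nClasses)
  roleAligned <- nBranches == 3L && !is.na(nFeatures)
  if (roleAligned) {
    if (is.na(nClasses)) nClasses <- (inputDim - nFeatures) %/% 2L
    if (inputDim != 2L * nClasses + nFeatures)
      stop("nFeatures/nClasses inconsistent with inputDim = 2K+M",
           call. = FALSE)
  }
  if (!roleAligned && nBranches > inputDim)
    stop("more branches than input positions", call. = FALSE)
  structure(list(inputDim = inputDim, outputDim = outputDim,
                 hiddenDim = as.integer(hiddenDim),
                 nHiddenLayers = as.integer(nHiddenLayers),
                 nBranches = as.integer(nBranches),
                 attnDim = as.integer(attnDim), dropout = dropout,
                 useAttention = isTRUE(useAttention),
                 useResidual = isTRUE(useResidual),
                 nFeatures = nFeatures, nClasses = nClasses,
                 roleAligned = roleAligned, seed = as.integer(seed)),
            class = "adapterConfig")
}

# index slices fed to each attention branch
branchSlices <- function(config) {
  D <- config$inputDim
  if (config$roleAligned) {
    M <- config$nFeatures; K <- config$nClasses
    sl <- list(feature = seq_len(M),
               name = M + seq_len(K),
               description = M + K + seq_len(K))
    sl[lengths(sl) > 0L]
  } else {
    split(seq_len(D), cut(seq_len(D), config$nBranches, labels = FALSE))
  }
}

#' Initialise adapter parameters
#'
#' Deterministic seeded initialisation; repeated calls with the same
#' config are bit-identical. Parameter shapes are fully determined by
#' the config; ablation flags drop the attention and/or residual
#' parameter groups.
#'
#' @param config an [adapterConfig()].
#' @return a [SAMLPAdapter-class] holding config and parameters.
#' @export
initAdapter <- function(config) {
  stopifnot(inherits(config, "adapterConfig"))
  D <- config$inputDim; h <- config$hiddenDim; K <- config$outputDim
  params <- withLocalSeed(config$seed, {
    p <- list()
    p$W1 <- matrix(rnorm(h * D, sd = sqrt(2 / D)), h, D)
    p$b1 <- numeric(h)
    if (config$nHiddenLayers > 1L) {
      for (l in 2:config$nHiddenLayers) {
        p[[paste0("W", l)]] <- matrix(rnorm(h * h, sd = sqrt(2 / h)), h, h)
        p[[paste0("b", l)]] <- numeric(h)
      }
    }
    p$Wout <- matrix(rnorm(K * h, sd = sqrt(1 / h)), K, h)
    p$bout <- numeric(K)
    if (config$useAttention) {
      da <- config$attnDim
      for (b in seq_along(branchSlices(config))) {
        L <- length(branchSlices(config)[[b]])
        p[[paste0("E", b)]] <- matrix(rnorm(L * h, sd = 0.1), L, h)
        p[[paste0("Q", b)]] <- matrix(rnorm(L * da, sd = 0.1), L, da)
        p[[paste0("a", b)]] <- rnorm(da, sd = 0.1)
        p[[paste0("g", b)]] <- numeric(da)
      }
    }
    if (config$useResidual) {
      p$R <- matrix(rnorm(K * D, sd = sqrt(1 / D)), K, D)
      p$gateRaw <- 0
    }
    p
  })
  new("SAMLPAdapter", config = unclass(config), params = params)
}

adapterConfigOf <- function(adapter) {
  structure(adapter@config, class = "adapterConfig")
}

setMethod("show", "SAMLPAdapter", function(object) {
  cfg <- object@config
  cat("SAMLPAdapter:", cfg$inputDim, "->", cfg$nHiddenLayers, "x",
      cfg$hiddenDim, "->", cfg$outputDim, "logits;",
      if (cfg$useAttention) paste0(cfg$nBranches, " attention branch(es);")
      else "no attention;",
      if (cfg$useResidual) "gated residual;" else "no residual;",
      adapterParameterCount(object), "parameters\n")
})

#' Trainable parameter count (closed form)
#'
#' The total parameter count grows linearly in inputDim and hiddenDim —
#' the shallow-network contract that keeps training cheap.
#'
#' @param x a [SAMLPAdapter-class] or an [adapterConfig()].
#' @return integer count.
#' @export
adapterParameterCount <- function(x) {
  config <- if (is(x, "SAMLPAdapter")) adapterConfigOf(x) else x
  D <- config$inputDim; h <- config$hiddenDim; K <- config$outputDim
  n <- h * D + h + (config$nHiddenLayers - 1L) * (h * h + h) + K * h + K
  if (config$useAttention) {
    da <- config$attnDim
    lens <- vapply(branchSlices(config), length, integer(1))
    n <- n + sum(lens) * (h + da) + 2L * da * length(lens)
  }
  if (config$useResidual) n <- n + K * D + 1L
  as.integer(n)
}

# One attention branch forward. Position p of the slice is a token
# x_p * E[p,] (a value embedding scaled by the fusion weight); additive
# attention scores each position in an attnDim-dimensional space,
# e[,p] = a' tanh(x_p * Q[p,] + g), and the softmax-weighted token sum
# is the branch's hidden_dim summary. The context path is pure matrix
# algebra; only the (small) scoring space needs a nonlinearity.
branchForward <- function(X, idx, E, Q, a, g) {
  n <- nrow(X); L <- length(idx); da <- ncol(Q)
  Xb <- X[, idx, drop = FALSE]
  XrepS <- Xb[, rep(seq_len(L), each = da), drop = FALSE]
  Pre <- XrepS * rep(as.vector(t(Q)), each = n) +
    rep(rep(g, L), each = n)
  U <- tanh(Pre)
  Ua <- U * rep(rep(a, L), each = n)
  e <- colSums(aperm(array(Ua, c(n, da, L)), c(2, 1, 3)), dims = 1)
  if (!is.matrix(e)) e <- matrix(e, n, L)
  alpha <- softmaxRows(e)
  AX <- alpha * Xb
  list(C = AX %*% E, Xb = Xb, XrepS = XrepS, U = U, alpha = alpha, AX = AX)
}

# gradients of one branch given the upstream gradient on its context
branchBackward <- function(dC, br, idx, E, Q, a, g) {
  n <- nrow(dC); L <- length(idx); da <- ncol(Q)
  dE <- crossprod(br$AX, dC)
  dAX <- tcrossprod(dC, E)
  dalpha <- dAX * br$Xb
  de <- br$alpha * (dalpha - .rowSums(dalpha * br$alpha, n, L))
  debig <- de[, rep(seq_len(L), each = da), drop = FALSE]
  da_ <- .rowSums(matrix(.colSums(br$U * debig, n, L * da), da, L), da, L)
  dU <- debig * rep(rep(a, L), each = n)
  dPre <- dU * (1 - br$U^2)
  dg <- .rowSums(matrix(.colSums(dPre, n, L * da), da, L), da, L)
  dQ <- t(matrix(.colSums(br$XrepS * dPre, n, L * da), da, L))
  list(E = dE, Q = dQ, a = da_, g = dg)
}

softmaxRows <- function(m) {
  m <- m - apply(m, 1, max)
  em <- exp(m)
  em / rowSums(em)
}

# full forward pass with cached intermediates for backprop
adapterForwardFull <- function(adapter, X, trainMode = FALSE) {
  config <- adapterConfigOf(adapter); p <- adapter@params
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != config$inputDim)
    stop(sprintf("row length %d does not match adapter inputDim %d",
                 ncol(X), config$inputDim), call. = FALSE)
  n <- nrow(X)
  cache <- list(X = X, branches = NULL, masks = list())
  Z1 <- tcrossprod(X, p$W1) + rep(p$b1, each = n)
  if (config$useAttention) {
    sl <- branchSlices(config)
    br <- vector("list", length(sl))
    for (b in seq_along(sl)) {
      br[[b]] <- branchForward(X, sl[[b]], p[[paste0("E", b)]],
                               p[[paste0("Q", b)]], p[[paste0("a", b)]],
                               p[[paste0("g", b)]])
      Z1 <- Z1 + br[[b]]$C
    }
    cache$branches <- br
  }
  cache$Z <- list(Z1)
  H <- pmax(Z1, 0)
  cache$H <- list(H)
  drop1 <- if (trainMode && config$dropout > 0)
    matrix(rbinom(length(H), 1, 1 - config$dropout), nrow(H)) /
      (1 - config$dropout) else NULL
  if (!is.null(drop1)) H <- H * drop1
  cache$masks[1] <- list(drop1)
  cache$D <- list(H)
  if (config$nHiddenLayers > 1L) {
    for (l in 2:config$nHiddenLayers) {
      Z <- tcrossprod(H, p[[paste0("W", l)]]) +
        rep(p[[paste0("b", l)]], each = n)
      cache$Z[[l]] <- Z
      Hl <- pmax(Z, 0)
      cache$H[[l]] <- Hl
      dm <- if (trainMode && config$dropout > 0)
        matrix(rbinom(length(Hl), 1, 1 - config$dropout), nrow(Hl)) /
          (1 - config$dropout) else NULL
      if (!is.null(dm)) Hl <- Hl * dm
      cache$masks[l] <- list(dm)
      cache$D[[l]] <- Hl
      H <- Hl
    }
  }
  logits <- tcrossprod(H, p$Wout) + rep(p$bout, each = n)
  if (config$useResidual) {
    gate <- 1 / (1 + exp(-p$gateRaw))
    cache$res <- tcrossprod(X, p$R)
    cache$gate <- gate
    logits <- logits + gate * cache$res
  }
  if (any(!is.finite(logits)))
    stop("non-finite logits", call. = FALSE)
  list(logits = logits, cache = cache)
}

#' Adapter forward pass
#'
#' Maps fusion-weight rows to K class logits. With \code{trainMode =
#' FALSE} (the default) dropout is disabled and the output is
#' deterministic.
#'
#' @param adapter a [SAMLPAdapter-class].
#' @param rows numeric matrix of fusion rows (or a single row vector, or
#'   a [FusionWeights-class]).
#' @param trainMode logical; enables dropout (draws from the current R
#'   RNG stream).
#' @return numeric matrix, n x K logits.
#' @export
adapterForward <- function(adapter, rows, trainMode = FALSE) {
  if (is(rows, "FusionWeights")) rows <- rows@W
  adapterForwardFull(adapter, rows, trainMode = trainMode)$logits
}

#' Softmax class probabilities
#'
#' Numerically stable softmax (max-subtraction) over logits, row-wise
#' for a matrix. Entries are positive and each row sums to 1 within
#' 1e-9.
#'
#' @param logits numeric vector of K logits, or an n x K matrix.
#' @return probability vector or matrix of the same shape.
#' @export
classProbabilities <- function(logits) {
  if (any(!is.finite(logits)))
    stop("non-finite logits", call. = FALSE)
  if (is.matrix(logits)) return(softmaxRows(logits))
  e <- exp(logits - max(logits))
  e / sum(e)
}

# gradient of mean cross-entropy wrt all adapter parameters.
# labels are 0-based. Returns list(loss, grads) with grads named like
# params; also records the probabilities for accuracy bookkeeping.
adapterGradients <- function(adapter, X, labels, trainMode = TRUE) {
  config <- adapterConfigOf(adapter); p <- adapter@params
  fw <- adapterForwardFull(adapter, X, trainMode = trainMode)
  n <- nrow(fw$logits); K <- config$outputDim
  probs <- softmaxRows(fw$logits)
  li <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(probs[li], 1e-300)))
  dlog <- probs
  dlog[li] <- dlog[li] - 1
  dlog <- dlog / n
  g <- list()
  cache <- fw$cache
  if (config$useResidual) {
    g$R <- cache$gate * crossprod(dlog, cache$X)
    g$gateRaw <- cache$gate * (1 - cache$gate) * sum(dlog * cache$res)
  }
  Hlast <- cache$D[[config$nHiddenLayers]]
  g$Wout <- crossprod(dlog, Hlast)
  g$bout <- colSums(dlog)
  dH <- dlog %*% p$Wout
  dZ1 <- NULL
  for (l in config$nHiddenLayers:1) {
    if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
    dZ <- dH * (cache$Z[[l]] > 0)
    inp <- if (l == 1L) cache$X else cache$D[[l - 1L]]
    g[[paste0("W", l)]] <- crossprod(dZ, inp)
    g[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) dH <- dZ %*% p[[paste0("W", l)]]
    else dZ1 <- dZ
  }
  if (config$useAttention) {
    sl <- branchSlices(config)
    for (b in seq_along(sl)) {
      # dC = dZ1 for every branch (branch outputs are summed into Z1)
      gb <- branchBackward(dZ1, cache$branches[[b]], sl[[b]],
                           p[[paste0("E", b)]], p[[paste0("Q", b)]],
                           p[[paste0("a", b)]], p[[paste0("g", b)]])
      g[[paste0("E", b)]] <- gb$E
      g[[paste0("Q", b)]] <- gb$Q
      g[[paste0("a", b)]] <- gb$a
      g[[paste0("g", b)]] <- gb$g
    }
  }
  list(loss = loss, grads = g, probs = probs)
}
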