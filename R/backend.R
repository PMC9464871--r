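#' Classifier backends
#'
#' Ensemble members are trained through a pluggable backend contract; a
#' backend is a `tile_backend` object exposing four functions:
#'
#' * `featurize(img)` — image array to numeric feature vector,
#' * `init(d, seed)` — fresh model state for `d` features,
#' * `train_epoch(state, X, y, seed)` — one optimization epoch,
#' * `predict(state, X)` — probability of class 1 per row.
#'
#' Epoch-wise training is what allows best-epoch checkpointing on
#' validation accuracy in [train_member()]. The default backend
#' ([pooled_mlp_backend()]) is a CPU-scale neural network that trains in
#' well under a second on desk-sized cohorts.
#'
#' @name tile_backend
NULL

new_tile_backend <- function(name, params, featurize, init, train_epoch, predict) {
  structure(list(name = name, params = params, featurize = featurize,
                 init = init, train_epoch = train_epoch, predict = predict),
            class = "tile_backend")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

block_stats <- function(img, grid) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ry <- pmin(grid, ceiling(seq_len(h) / (h / grid)))
  rx <- pmin(grid, ceiling(seq_len(w) / (w / grid)))
  out <- numeric(0)
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    s1 <- rowsum(m, ry)            # sum over rows into grid bands
    s1 <- t(rowsum(t(s1), rx))     # then over columns
    n <- t(rowsum(t(rowsum(m * 0 + 1, ry)), rx))
    mu <- s1 / n
    m2 <- m * m
    s2 <- t(rowsum(t(rowsum(m2, ry)), rx)) / n
    sd <- sqrt(pmax(0, s2 - mu^2))
    out <- c(out, as.vector(mu), as.vector(sd))
  }
  out
}

#' Default CPU-scale backend: block-pooled features + small neural net
#'
#' Features are per-block mean and standard deviation of each RGB
#' channel on a `grid x grid` partition of the tile (default 8x8 blocks,
#' 384 features for 64-px tiles) — a cheap stand-in for early
#' convolutional pooling that is sensitive to both color (means) and
#' texture scale/sharpness (block SDs). The classifier is a one-hidden-
#' layer network (tanh units, sigmoid head) trained by mini-batch
#' Adamax on binary cross-entropy; features are standardized with
#' training-set statistics.
#'
#' @param grid Pooling grid edge (default 8).
#' @param hidden Hidden units (default 32).
#' @param lr Adamax step size (default 0.01).
#' @param batch_size Mini-batch size (default 16).
#' @param beta1,beta2 Adamax moment decays.
#' @return A `tile_backend`.
#' @export
pooled_mlp_backend <- function(grid = 8L, hidden = 32L, lr = 0.01,
                               batch_size = 16L, beta1 = 0.9, beta2 = 0.999) {
  params <- list(grid = as.integer(grid), hidden = as.integer(hidden),
                 lr = lr, batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2)

  init <- function(d, seed) {
    with_seed(seed, {
      h <- params$hidden
      W1 <- matrix(stats::rnorm(d * h, 0, sqrt(1 / d)), d, h)
      b1 <- numeric(h)
      W2 <- matrix(stats::rnorm(h, 0, sqrt(1 / h)), h, 1)
      b2 <- 0
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
           m = NULL, u = NULL, step = 0L, center = NULL, scale = NULL)
    })
  }

  forward <- function(state, X) {
    Z1 <- sweep(X %*% state$W1, 2, state$b1, `+`)
    H <- tanh(Z1)
    z2 <- as.vector(H %*% state$W2) + state$b2
    list(H = H, p = sigmoid(z2))
  }

  standardize <- function(state, X) {
    sweep(sweep(X, 2, state$center, `-`), 2, state$scale, `/`)
  }

  train_epoch <- function(state, X, y, seed) {
    if (is.null(state$center)) {
      state$center <- colMeans(X)
      state$scale <- pmax(apply(X, 2, stats::sd), 1e-6)
    }
    Xs <- standardize(state, X)
    n <- nrow(Xs)
    idx <- with_seed(seed, sample.int(n))
    bs <- params$batch_size
    eps <- 1e-7
    for (start in seq(1, n, by = bs)) {
      b <- idx[start:min(start + bs - 1L, n)]
      Xb <- Xs[b, , drop = FALSE]
      yb <- y[b]
      fw <- forward(state, Xb)
      # BCE gradient at the logit: (p - y) / batch
      dz2 <- (fw$p - yb) / length(b)
      gW2 <- crossprod(fw$H, dz2)
      gb2 <- sum(dz2)
      dH <- outer(dz2, as.vector(state$W2)) * (1 - fw$H^2)
      gW1 <- crossprod(Xb, dH)
      gb1 <- colSums(dH)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      if (is.null(state$m)) {
        state$m <- lapply(g, function(x) x * 0)
        state$u <- lapply(g, function(x) x * 0)
      }
      state$step <- state$step + 1L
      corr <- 1 - params$beta1^state$step
      for (nm in names(g)) {
        state$m[[nm]] <- params$beta1 * state$m[[nm]] +
          (1 - params$beta1) * g[[nm]]
        state$u[[nm]] <- pmax(params$beta2 * state$u[[nm]], abs(g[[nm]]))
        upd <- (params$lr / corr) * state$m[[nm]] / (state$u[[nm]] + eps)
        if (nm == "W1") state$W1 <- state$W1 - upd
        if (nm == "b1") state$b1 <- state$b1 - as.vector(upd)
        if (nm == "W2") state$W2 <- state$W2 - upd
        if (nm == "b2") state$b2 <- state$b2 - as.numeric(upd)
      }
    }
    state
  }

  predict_fn <- function(state, X) {
    forward(state, standardize(state, X))$p
  }

  new_tile_backend("pooled_mlp", params,
                   featurize = function(img) block_stats(img, params$grid),
                   init = init, train_epoch = train_epoch,
                   predict = predict_fn)
}

#' Reconstruct a backend from its name and parameters
#' @param name Backend name (currently `"pooled_mlp"`).
#' @param params Parameter list as stored in a model manifest.
#' @return A `tile_backend`.
#' @export
backend_from_spec <- function(name, params = list()) {
  switch(name,
         pooled_mlp = do.call(pooled_mlp_backend, params),
         abort_bad("unknown backend: ", name))
}

#' Compute the feature matrix of a set of tiles
#'
#' Reads each tile image from disk and applies the backend's
#' featurizer. Row names are tile ids, so the matrix can be indexed by
#' any split.
#'
#' @param tiles Rows of a `tile_cohort` (needs `tile_id`, `image_path`).
#' @param backend A `tile_backend`.
#' @return Numeric matrix, one row per tile.
#' @export
tile_features <- function(tiles, backend) {
  stopifnot(inherits(backend, "tile_backend"))
  feats <- lapply(tiles$image_path, function(p) {
    if (!file.exists(p)) abort_bad("cannot read tile image: ", p)
    backend$featurize(read_tile_image(p))
  })
  X <- do.call(rbind, feats)
  rownames(X) <- tiles$tile_id
  X
}
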