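#' Model configuration for the dense graph convolutional classifier
#'
#' One dense graph-convolution layer (features `F` to latent width `W`
#' over the symmetrically normalized adjacency with self-loops), batch
#' normalization, LeakyReLU and dropout, then two fully connected layers
#' (`N*W -> N -> 2`) ending in log-softmax.
#'
#' @param n_nodes `N`, graph nodes / channels (default 29).
#' @param n_features `F`, input features per node (default 11).
#' @param width `W`, latent width (default 14).
#' @param dropout Dropout probability (band/metric-dependent in use;
#'   default 0.3).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param bn_eps Batch-normalization epsilon (default 1e-5).
#' @param batch_size Mini-batch size (default 32).
#' @return A `model_config` list.
#' @export
model_config <- function(n_nodes = 29, n_features = 11, width = 14,
                         dropout = 0.3, leaky_slope = 0.01, bn_eps = 1e-5,
                         batch_size = 32) {
  stopifnot(n_nodes > 0, n_features > 0, width > 0,
            dropout > 0 && dropout < 1, leaky_slope > 0 && leaky_slope < 1)
  structure(list(n_nodes = n_nodes, n_features = n_features, width = width,
                 dropout = dropout, leaky_slope = leaky_slope,
                 bn_eps = bn_eps, batch_size = batch_size),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 150).
#' @param folds Cross-validation folds (default 10).
#' @param lr0 Initial Adam learning rate (band-dependent in use;
#'   default 1e-3).
#' @param lr_decay_every Epoch interval of the step decay (default 50).
#' @param lr_decay_factor Learning-rate division factor (default 10).
#' @param seed RNG seed controlling shuffling, initialization and
#'   dropout (default 42).
#' @param test_ids Fixed held-out test subject ids, excluded from every
#'   fold. The default is the reference protocol's 14-subject list
#'   (ids above 50 are SMOTE-synthesized subjects).
#' @param positive_class Class treated as positive (default
#'   `"moderate"`).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 150, folds = 10, lr0 = 1e-3,
                         lr_decay_every = 50, lr_decay_factor = 10,
                         seed = 42, test_ids = default_test_ids(),
                         positive_class = "moderate") {
  stopifnot(epochs > 0, folds > 0, lr0 > 0)
  structure(list(epochs = as.integer(epochs), folds = as.integer(folds),
                 lr0 = lr0, lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed),
                 test_ids = as.character(test_ids),
                 positive_class = positive_class),
            class = "train_config")
}

#' Fixed independent test subjects of the reference protocol
#' @return Character vector of 14 subject ids.
#' @export
default_test_ids <- function() {
  c("32", "48", "14", "20", "44", "60", "65", "7", "51", "28", "62", "10",
    "47", "6")
}

#' Trainable parameter counts per block
#'
#' Graph convolution `F*W + W`, batch normalization `2W`, first fully
#' connected layer `N*W*N + N`, output layer `N*2 + 2`; also reports the
#' flattened embedding width `N*W`.
#'
#' @param cfg A [model_config()].
#' @return Named list of counts.
#' @export
param_counts <- function(cfg) {
  with(cfg, list(
    gcn = n_features * width + width,
    batchnorm = 2 * width,
    fc1 = n_nodes * width * n_nodes + n_nodes,
    fc2 = n_nodes * 2 + 2,
    embedding_dim = n_nodes * width))
}

uniform_init <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -b, b), nr, nc)
}

#' Initialize the classifier
#'
#' Uniform fan-based initialization of all weights and biases,
#' deterministic given `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed RNG seed (default 42).
#' @return An `eeggcn` model object.
#' @export
init_eeggcn <- function(cfg, seed = 42) {
  with_local_seed(seed, {
    N <- cfg$n_nodes; Fin <- cfg$n_features; W <- cfg$width
    structure(list(
      cfg = cfg,
      theta = uniform_init(Fin, W, Fin),
      b_gcn = as.numeric(uniform_init(1, W, Fin)),
      gamma = rep(1, W), beta = rep(0, W),
      run_mean = rep(0, W), run_var = rep(1, W),
      w1 = uniform_init(N * W, N, N * W),
      b1 = as.numeric(uniform_init(1, N, N * W)),
      w2 = uniform_init(N, 2, N),
      b2 = as.numeric(uniform_init(1, 2, N)),
      classes = c("mild", "moderate")),
      class = "eeggcn")
  })
}

# D^(-1/2) (A + I) D^(-1/2)
normalize_adjacency <- function(a) {
  if (max(abs(a - t(a))) > 1e-8) stop("non-symmetric adjacency",
                                      call. = FALSE)
  ai <- a + diag(nrow(a))
  d <- rowSums(ai)
  inv <- 1 / sqrt(pmax(d, 1e-12))
  ai * outer(inv, inv)
}

# stack Ahat_b %*% X_b over the batch into a (B*N) x F matrix; this is
# the fixed, parameter-free part of the graph convolution
stack_ax <- function(features, adjacency) {
  do.call(rbind, lapply(seq_along(features), function(b)
    normalize_adjacency(adjacency[[b]]) %*% features[[b]]))
}

leaky <- function(x, a) ifelse(x > 0, x, a * x)

#' Forward pass of the classifier
#'
#' Dense graph convolution, batch normalization (batch statistics in
#' training mode, running statistics in evaluation), LeakyReLU and
#' dropout, flatten to the `N*W` embedding, two fully connected layers,
#' log-softmax. In training mode dropout masks are drawn from the
#' current RNG state; evaluation is deterministic.
#'
#' @param model An `eeggcn` from [init_eeggcn()].
#' @param features List of `N x F` matrices (one per sample).
#' @param adjacency List of symmetric `N x N` matrices.
#' @param training Logical; enables batch statistics and dropout.
#' @param keep_cache Keep intermediates for the backward pass.
#' @param ax Optional precomputed stacked `Ahat %*% X` matrix
#'   (`(B*N) x F`); skips the graph-convolution aggregation.
#' @return List with `log_probs` (`B x 2`), updated `model`, and (if
#'   requested) a `cache`.
#' @export
gcn_forward <- function(model, features, adjacency, training = FALSE,
                        keep_cache = FALSE, ax = NULL) {
  cfg <- model$cfg
  B <- length(features)
  N <- cfg$n_nodes; W <- cfg$width
  if (is.null(ax)) ax <- stack_ax(features, adjacency)
  if (ncol(ax) != cfg$n_features || nrow(ax) != B * N)
    stop("shape mismatch: expected ", B, " x ", N, " x ", cfg$n_features,
         call. = FALSE)
  h <- ax %*% model$theta
  h <- sweep(h, 2, model$b_gcn, "+")
  if (training) {
    mu <- colMeans(h)
    v <- colMeans(sweep(h, 2, mu)^2)
    n_rows <- nrow(h)
    model$run_mean <- 0.9 * model$run_mean + 0.1 * mu
    model$run_var <- 0.9 * model$run_var +
      0.1 * v * n_rows / max(1, n_rows - 1)
  } else {
    mu <- model$run_mean
    v <- model$run_var
  }
  xhat <- sweep(sweep(h, 2, mu), 2, sqrt(v + cfg$bn_eps), "/")
  bn <- sweep(sweep(xhat, 2, model$gamma, "*"), 2, model$beta, "+")
  act1 <- leaky(bn, cfg$leaky_slope)
  if (training) {
    m1 <- matrix(stats::rbinom(length(act1), 1, 1 - cfg$dropout),
                 nrow(act1)) / (1 - cfg$dropout)
    act1d <- act1 * m1
  } else { m1 <- NULL; act1d <- act1 }
  y <- matrix(as.numeric(t(act1d)), nrow = B, byrow = TRUE)  # B x N*W
  z1 <- sweep(y %*% model$w1, 2, model$b1, "+")
  a1 <- leaky(z1, cfg$leaky_slope)
  if (training) {
    m2 <- matrix(stats::rbinom(length(a1), 1, 1 - cfg$dropout),
                 nrow(a1)) / (1 - cfg$dropout)
    a1d <- a1 * m2
  } else { m2 <- NULL; a1d <- a1 }
  z2 <- sweep(a1d %*% model$w2, 2, model$b2, "+")
  mx <- apply(z2, 1, max)
  lse <- mx + log(rowSums(exp(z2 - mx)))
  log_probs <- z2 - lse
  out <- list(log_probs = log_probs, model = model)
  if (keep_cache)
    out$cache <- list(ax = ax, h = h, mu = mu, v = v, xhat = xhat, bn = bn,
                      act1 = act1, m1 = m1, y = y, z1 = z1, a1 = a1,
                      m2 = m2, a1d = a1d, z2 = z2, B = B)
  out
}

# gradients of the mean NLL loss w.r.t. all trainable parameters
gcn_backward <- function(model, cache, y_idx) {
  cfg <- model$cfg
  B <- cache$B; N <- cfg$n_nodes; W <- cfg$width
  p <- exp(cache$z2 - apply(cache$z2, 1, max))
  p <- p / rowSums(p)
  dz2 <- p
  dz2[cbind(seq_len(B), y_idx)] <- dz2[cbind(seq_len(B), y_idx)] - 1
  dz2 <- dz2 / B
  g_w2 <- t(cache$a1d) %*% dz2
  g_b2 <- colSums(dz2)
  da1d <- dz2 %*% t(model$w2)
  da1 <- if (is.null(cache$m2)) da1d else da1d * cache$m2
  dz1 <- da1 * ifelse(cache$z1 > 0, 1, cfg$leaky_slope)
  g_w1 <- t(cache$y) %*% dz1
  g_b1 <- colSums(dz1)
  dy <- dz1 %*% t(model$w1)
  dact1d <- matrix(as.numeric(t(dy)), ncol = W, byrow = TRUE)
  dact1 <- if (is.null(cache$m1)) dact1d else dact1d * cache$m1
  dbn <- dact1 * ifelse(cache$bn > 0, 1, cfg$leaky_slope)
  g_gamma <- colSums(dbn * cache$xhat)
  g_beta <- colSums(dbn)
  dxhat <- sweep(dbn, 2, model$gamma, "*")
  istd <- 1 / sqrt(cache$v + cfg$bn_eps)
  n_rows <- nrow(cache$h)
  xmu <- sweep(cache$h, 2, cache$mu)
  dv <- colSums(dxhat * xmu) * (-0.5) * istd^3
  dmu <- colSums(sweep(dxhat, 2, -istd, "*")) +
    dv * colMeans(-2 * xmu)
  dh <- sweep(dxhat, 2, istd, "*") +
    sweep(xmu, 2, 2 * dv / n_rows, "*") +
    matrix(dmu / n_rows, n_rows, W, byrow = TRUE)
  g_theta <- t(cache$ax) %*% dh
  g_bgcn <- colSums(dh)
  list(theta = g_theta, b_gcn = g_bgcn, gamma = g_gamma, beta = g_beta,
       w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

adam_state <- function(model) {
  pars <- c("theta", "b_gcn", "gamma", "beta", "w1", "b1", "w2", "b2")
  st <- lapply(pars, function(p) list(m = model[[p]] * 0,
                                      v = model[[p]] * 0))
  names(st) <- pars
  st
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (p in names(state)) {
    state[[p]]$m <- beta1 * state[[p]]$m + (1 - beta1) * grads[[p]]
    state[[p]]$v <- beta2 * state[[p]]$v + (1 - beta2) * grads[[p]]^2
    mhat <- state[[p]]$m / (1 - beta1^t)
    vhat <- state[[p]]$v / (1 - beta2^t)
    model[[p]] <- model[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(model = model, state = state)
}

sample_matrices <- function(samples) {
  list(features = lapply(samples, `[[`, "features"),
       adjacency = lapply(samples, function(s)
         if (inherits(s$adjacency, "adjacency")) s$adjacency$values
         else s$adjacency),
       labels = vapply(samples, `[[`, "", "label"))
}

nll_loss <- function(log_probs, y_idx) {
  -mean(log_probs[cbind(seq_len(nrow(log_probs)), y_idx)])
}

#' Train the classifier
#'
#' Mini-batch Adam on the cross-entropy (negative log-likelihood) loss
#' with a step learning-rate decay (divide by `lr_decay_factor` every
#' `lr_decay_every` epochs). Deterministic given `train_cfg$seed`.
#'
#' @param samples Training `graph_sample`s (normalized, selected
#'   features).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param validation Optional held-out samples for a per-epoch loss
#'   trajectory.
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, lr, train_loss, val_loss).
#' @export
train_gcn <- function(samples, model_cfg = model_config(),
                      train_cfg = train_config(), validation = NULL) {
  sm <- sample_matrices(samples)
  classes <- c("mild", "moderate")
  if (length(unique(sm$labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  y_idx <- match(sm$labels, classes)
  ax_all <- stack_ax(sm$features, sm$adjacency)
  N <- model_cfg$n_nodes
  vd <- if (!is.null(validation)) {
    vsm <- sample_matrices(validation)
    list(ax = stack_ax(vsm$features, vsm$adjacency),
         y = match(vsm$labels, classes), n = length(validation))
  }
  model <- init_eeggcn(model_cfg, seed = train_cfg$seed)
  state <- adam_state(model)
  nb <- length(samples)
  history <- vector("list", train_cfg$epochs)
  step <- 0
  with_local_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      lr <- train_cfg$lr0 /
        train_cfg$lr_decay_factor^((epoch - 1) %/% train_cfg$lr_decay_every)
      ord <- sample(nb)
      batches <- split(ord, ceiling(seq_along(ord) / model_cfg$batch_size))
      ep_loss <- 0
      for (ib in batches) {
        rows <- as.numeric(vapply(ib, function(b) ((b - 1) * N + 1):(b * N),
                                  numeric(N)))
        fw <- gcn_forward(model, features = vector("list", length(ib)),
                          adjacency = NULL, training = TRUE,
                          keep_cache = TRUE,
                          ax = ax_all[rows, , drop = FALSE])
        model <- fw$model
        loss <- nll_loss(fw$log_probs, y_idx[ib])
        if (!is.finite(loss))
          stop("training diverged (loss is not finite) at epoch ", epoch,
               call. = FALSE)
        grads <- gcn_backward(model, fw$cache, y_idx[ib])
        step <- step + 1
        upd <- adam_step(model, grads, state, lr, step)
        model <- upd$model; state <- upd$state
        ep_loss <- ep_loss + loss * length(ib)
      }
      val_loss <- NA_real_
      if (!is.null(vd)) {
        vf <- gcn_forward(model, vector("list", vd$n), NULL,
                          training = FALSE, ax = vd$ax)
        val_loss <- nll_loss(vf$log_probs, vd$y)
      }
      history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = ep_loss / nb,
                                     val_loss = val_loss)
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Predict class probabilities
#'
#' @param model A trained `eeggcn`.
#' @param samples List of `graph_sample`s.
#' @return Data frame with `subject_id`, `label`, `prob_moderate` and
#'   the predicted `pred` class.
#' @export
predict_gcn <- function(model, samples) {
  sm <- sample_matrices(samples)
  fw <- gcn_forward(model, sm$features, sm$adjacency, training = FALSE)
  prob <- exp(fw$log_probs[, 2])
  data.frame(subject_id = vapply(samples, `[[`, "", "subject_id"),
             label = sm$labels, prob_moderate = prob,
             pred = model$classes[max.col(fw$log_probs)])
}

#' Classification metrics from probabilities
#'
#' Accuracy, precision, recall and F1 from the 2 x 2 confusion matrix
#' (class decided at probability 0.5), plus AUC via the rank (Mann-
#' Whitney) statistic on the positive-class probabilities.
#'
#' @param prob Numeric vector of positive-class probabilities.
#' @param labels True class labels.
#' @param positive_class Label counted as positive (default
#'   `"moderate"`).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `confusion`.
#' @export
compute_metrics <- function(prob, labels, positive_class = "moderate") {
  if (length(prob) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- labels == positive_class
  if (all(pos) || !any(pos))
    stop("labels contain a single class; AUC undefined", call. = FALSE)
  pred_pos <- prob >= 0.5
  tp <- sum(pred_pos & pos); fp <- sum(pred_pos & !pos)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & !pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  r <- rank(prob)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  list(accuracy = (tp + tn) / length(prob), precision = precision,
       recall = recall, f1 = f1, auc = auc,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(truth = c("pos", "neg"),
                                          pred = c("pos", "neg"))))
}

#' ROC curve
#'
#' Monotone curve from (0, 0) to (1, 1) over all score thresholds, with
#' trapezoidal AUC (equal to the rank-statistic AUC up to ties handled
#' by the trapezoid).
#'
#' @param scores Positive-class scores.
#' @param labels True labels.
#' @param positive_class Positive label (default `"moderate"`).
#' @return List with data frame `points` (`fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive_class = "moderate") {
  pos <- labels == positive_class
  if (all(pos) || !any(pos))
    stop("labels contain a single class", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Subject-wise cross-validation with a fixed test set
#'
#' The fixed test subjects are removed first; the remaining subjects are
#' partitioned into `folds` label-stratified groups. For each fold, a
#' model is trained on the other folds' subjects (feature normalization
#' statistics computed on those training samples only and frozen) and
#' evaluated on the fixed test set, so segments of one subject never
#' straddle a split.
#'
#' @param samples All `graph_sample`s (real and synthetic).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()] (supplies `folds`, `test_ids`,
#'   `seed`).
#' @param smote `"none"` (default): the caller has already balanced the
#'   classes, e.g. with a global [smote_oversample()] pass over all
#'   samples (the reference protocol, whose fixed test list contains
#'   synthetic subjects — note that pre-split oversampling lets
#'   synthetic training samples interpolate test-subject segments, an
#'   acknowledged leakage of that protocol). `"fold"`: samples must be
#'   real only; each fold's training partition is oversampled
#'   independently, so no synthetic sample ever spans the train/test
#'   boundary.
#' @return List with `fold_metrics` (data frame), `mean`, `sd`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(samples, model_cfg = model_config(),
                           train_cfg = train_config(),
                           smote = c("none", "fold")) {
  smote <- match.arg(smote)
  ids <- vapply(samples, `[[`, "", "subject_id")
  labels <- vapply(samples, `[[`, "", "label")
  missing <- setdiff(train_cfg$test_ids, ids)
  if (length(missing))
    stop("test ids missing from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  is_test <- ids %in% train_cfg$test_ids
  test_samples <- samples[is_test]
  rest_ids <- unique(ids[!is_test])
  rest_lab <- labels[match(rest_ids, ids)]
  folds <- with_local_seed(train_cfg$seed, {
    f <- integer(length(rest_ids))
    for (cl in unique(rest_lab)) {
      sel <- which(rest_lab == cl)
      f[sel] <- sample(rep_len(seq_len(train_cfg$folds), length(sel)))
    }
    f
  })
  rows <- vector("list", train_cfg$folds)
  for (k in seq_len(train_cfg$folds)) {
    tr_ids <- rest_ids[folds != k]
    tr <- samples[!is_test & ids %in% tr_ids]
    if (smote == "fold")
      tr <- smote_oversample(tr, seed = train_cfg$seed + k)
    norm_tr <- normalize_features(tr)
    norm_te <- normalize_features(tr, test_samples)
    cfg_k <- train_cfg
    cfg_k$seed <- train_cfg$seed + k
    fit <- train_gcn(norm_tr, model_cfg, cfg_k)
    pr <- predict_gcn(fit$model, norm_te)
    m <- compute_metrics(pr$prob_moderate, pr$label,
                         train_cfg$positive_class)
    rows[[k]] <- data.frame(fold = k, accuracy = m$accuracy, f1 = m$f1,
                            recall = m$recall, precision = m$precision,
                            auc = m$auc)
  }
  fm <- do.call(rbind, rows)
  list(fold_metrics = fm,
       mean = colMeans(fm[, -1]),
       sd = apply(fm[, -1], 2, sd),
       fold_assignment = data.frame(subject_id = rest_ids, fold = folds))
}
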