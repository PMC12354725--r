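#' Shallow network specifications
#'
#' Architectures follow the `A:B-C(-D)-E:F` code used for the published
#' models, where `A` is the number of input features, `B`..`D` the units per
#' layer (the first and last entries repeat the input/output widths) and `F`
#' the number of outputs: e.g. `"9:9-20-9-1:1"` is a 9-input MLP with hidden
#' layers of 20 and 9 units; `"9:9-70-1:1"` an RBF network with 70 centers.
#' MLP hidden layers are capped at 20 units and RBF centers at 300, the
#' search bounds used for the published models.
#'
#' @param arch_code architecture string.
#' @param family `"MLP"`, `"RBF"`, `"GRNN"` or `"LNN"`.
#' @param task `"regression"` or `"classification"`.
#' @param epochs,learn_rate,patience MLP training controls (Adam + early
#'   stopping on a held-out shard of the training set).
#' @param holdout fraction of training rows used as the early-stopping shard.
#' @return an object of class `ptml_network_spec`.
#' @export
network_spec <- function(arch_code, family = c("MLP", "RBF", "GRNN", "LNN"),
                         task = c("regression", "classification"),
                         epochs = 400, learn_rate = 0.01, patience = 40,
                         holdout = 0.15) {
  family <- match.arg(family)
  task <- match.arg(task)
  parts <- strsplit(arch_code, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) abort("arch_code must look like 'A:B-C-D-E:F'")
  n_in <- as.integer(parts[1])
  n_out <- as.integer(parts[3])
  widths <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
  if (widths[1] != n_in || widths[length(widths)] != n_out) {
    abort("inner width list must start with A and end with F")
  }
  hidden <- widths[-c(1, length(widths))]
  if (family == "MLP" && any(hidden > 20)) {
    abort("MLP hidden layers are capped at 20 units")
  }
  if (family == "RBF") {
    if (length(hidden) != 1) abort("RBF takes exactly one hidden (center) layer")
    if (hidden > 300) abort("RBF centers are capped at 300")
  }
  if (family %in% c("LNN", "GRNN") && length(hidden) > 0 && any(hidden != 0)) {
    # LNN/GRNN codes conventionally carry no hidden layer; tolerate "A:A-F:F"
  }
  structure(
    list(arch_code = arch_code, family = family, task = task,
         n_in = n_in, n_out = n_out, hidden = hidden,
         epochs = epochs, learn_rate = learn_rate, patience = patience,
         holdout = holdout),
    class = "ptml_network_spec"
  )
}

#' @export
print.ptml_network_spec <- function(x, ...) {
  cat("<ptml_network_spec ", x$family, " ", x$arch_code, " (", x$task, ")>\n",
      sep = "")
  invisible(x)
}

# ---- feature-matrix plumbing ----------------------------------------------

.feature_matrix <- function(features) {
  cols <- c("yield_ref", .feature_terms(features))
  as.matrix(features[cols])
}

.standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# ---- MLP core (tanh hidden layers, Adam, early stopping) -------------------

.mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(1 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

.mlp_forward <- function(layers, x, task) {
  acts <- list(x)
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < L) tanh(z) else z
  }
  out <- acts[[L + 1]]
  if (task == "classification") out <- 1 / (1 + exp(-out))
  list(out = out, acts = acts)
}

.mlp_grad <- function(layers, x, y, task) {
  fw <- .mlp_forward(layers, x, task)
  n <- nrow(x)
  # dL/dz_out: MSE w/ identity output, or log-loss w/ sigmoid — same form
  delta <- (fw$out - y) / n
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                      b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - fw$acts[[l]]^2)
    }
  }
  grads
}

.mlp_loss <- function(layers, x, y, task) {
  out <- .mlp_forward(layers, x, task)$out
  if (task == "classification") {
    p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((out - y)^2)
  }
}

.mlp_train <- function(x, y, spec, seed) {
  with_local_seed(seed, {
    std <- .standardize(x)
    ysd <- 1; ymu <- 0
    yt <- y
    if (spec$task == "regression") {
      ymu <- mean(y); ysd <- if (sd(y) > 0) sd(y) else 1
      yt <- (y - ymu) / ysd
    }
    yt <- matrix(yt, ncol = 1)
    n <- nrow(x)
    n_hold <- max(1, round(spec$holdout * n))
    hold <- sample.int(n, n_hold)
    tr <- setdiff(seq_len(n), hold)
    if (spec$task == "classification" && length(unique(yt[tr, 1])) < 2) {
      # keep both classes in the gradient shard
      tr <- seq_len(n); hold <- seq_len(n)
    }
    layers <- .mlp_init(ncol(x), spec$hidden, 1)
    m <- v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(loss = Inf, layers = layers, epoch = 0)
    stall <- 0
    for (ep in seq_len(spec$epochs)) {
      g <- .mlp_grad(layers, std$x[tr, , drop = FALSE],
                     yt[tr, , drop = FALSE], spec$task)
      for (l in seq_along(layers)) {
        for (p in c("W", "b")) {
          m[[l]][[p]] <- b1 * m[[l]][[p]] + (1 - b1) * g[[l]][[p]]
          v[[l]][[p]] <- b2 * v[[l]][[p]] + (1 - b2) * g[[l]][[p]]^2
          mhat <- m[[l]][[p]] / (1 - b1^ep)
          vhat <- v[[l]][[p]] / (1 - b2^ep)
          layers[[l]][[p]] <- layers[[l]][[p]] -
            spec$learn_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      hl <- .mlp_loss(layers, std$x[hold, , drop = FALSE],
                      yt[hold, , drop = FALSE], spec$task)
      if (!is.finite(hl)) {
        abort("divergent training: non-finite loss", class = "ptml_training_error")
      }
      if (hl < best$loss - 1e-9) {
        best <- list(loss = hl, layers = layers, epoch = ep)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= spec$patience) break
      }
    }
    list(layers = best$layers, center = std$center, scale = std$scale,
         y_center = ymu, y_scale = ysd, stopped_epoch = best$epoch)
  })
}

.mlp_predict <- function(net, x, task) {
  xs <- sweep(sweep(x, 2, net$center), 2, net$scale, "/")
  out <- .mlp_forward(net$layers, xs, task)$out[, 1]
  if (task == "regression") out * net$y_scale + net$y_center else out
}

# ---- RBF network (k-means centers, kNN widths, pseudo-inverse) -------------

#' Fit a radial-basis-function network
#'
#' Three-stage fit: centers by k-means on the (standardized) inputs, one
#' Gaussian width per center from the mean distance to its `k_width` nearest
#' neighbouring centers, and output weights by linear least squares through
#' the pseudo-inverse of the design (radial activations plus intercept).
#'
#' @param x numeric input matrix.
#' @param targets numeric targets (0/1 for classification use).
#' @param centers number of RBF centers (`<=` rows).
#' @param seed RNG seed (k-means initialization).
#' @param k_width neighbours per center for the width assignment.
#' @return a `ptml_rbf` model.
#' @export
rbf_fit <- function(x, targets, centers, seed = 1, k_width = 2) {
  x <- as.matrix(x)
  if (centers > nrow(x)) {
    abort("more centers than rows", class = "ptml_config_error")
  }
  with_local_seed(seed, {
    std <- .standardize(x)
    cen <- if (centers == nrow(x)) {
      std$x
    } else {
      kmeans(std$x, centers = centers, nstart = 3, iter.max = 50)$centers
    }
    dmat <- as.matrix(stats::dist(cen))
    diag(dmat) <- Inf
    widths <- apply(dmat, 1, function(d) {
      k <- min(k_width, sum(is.finite(d)))
      if (k == 0) return(1)
      mean(sort(d)[seq_len(k)])
    })
    widths[!is.finite(widths) | widths <= 0] <- 1
    phi <- .rbf_design(std$x, cen, widths)
    # pseudo-inverse via SVD for rank-safety in the interpolation regime
    sv <- svd(phi)
    pos <- sv$d > max(sv$d) * 1e-10
    w <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], matrix(targets, ncol = 1)) / sv$d[pos])
    structure(
      list(centers = cen, widths = widths, weights = drop(w),
           center = std$center, scale = std$scale, n_centers = centers),
      class = "ptml_rbf"
    )
  })
}

.rbf_design <- function(xs, cen, widths) {
  d2 <- outer(rowSums(xs^2), rep(1, nrow(cen))) +
    outer(rep(1, nrow(xs)), rowSums(cen^2)) - 2 * xs %*% t(cen)
  d2[d2 < 0] <- 0
  phi <- exp(-sweep(d2, 2, 2 * widths^2, "/"))
  cbind(1, phi)
}

#' @export
predict.ptml_rbf <- function(object, x, ...) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(.rbf_design(xs, object$centers, object$widths) %*% object$weights)
}

# ---- GRNN (Nadaraya-Watson) and LNN (linear network) -----------------------

.grnn_fit <- function(x, y, seed, holdout = 0.15,
                      bandwidths = c(0.1, 0.2, 0.3, 0.5, 0.8, 1.2, 2)) {
  with_local_seed(seed, {
    std <- .standardize(as.matrix(x))
    n <- nrow(std$x)
    hold <- sample.int(n, max(1, round(holdout * n)))
    tr <- setdiff(seq_len(n), hold)
    if (!length(tr)) tr <- seq_len(n)
    score <- vapply(bandwidths, function(h) {
      p <- .grnn_eval(std$x[tr, , drop = FALSE], y[tr],
                      std$x[hold, , drop = FALSE], h)
      mean((p - y[hold])^2)
    }, double(1))
    h <- bandwidths[which.min(score)]
    structure(list(x = std$x, y = y, h = h,
                   center = std$center, scale = std$scale),
              class = "ptml_grnn")
  })
}

.grnn_eval <- function(xtr, ytr, xnew, h) {
  d2 <- outer(rowSums(xnew^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xnew)), rowSums(xtr^2)) - 2 * xnew %*% t(xtr)
  d2[d2 < 0] <- 0
  w <- exp(-d2 / (2 * h^2))
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  drop(w %*% ytr) / rs
}

#' @export
predict.ptml_grnn <- function(object, x, ...) {
  xs <- sweep(sweep(as.matrix(x), 2, object$center), 2, object$scale, "/")
  .grnn_eval(object$x, object$y, xs, object$h)
}

# ---- unified trainers ------------------------------------------------------

.fit_family <- function(x, y, spec, seed) {
  switch(spec$family,
    MLP = structure(.mlp_train(x, y, spec, seed), class = "ptml_mlp"),
    RBF = rbf_fit(x, y, centers = spec$hidden[1], seed = seed),
    GRNN = .grnn_fit(x, y, seed, holdout = spec$holdout),
    LNN = {
      df <- as.data.frame(x); df$.y <- y
      structure(list(fit = lm(.y ~ ., data = df)), class = "ptml_lnn")
    }
  )
}

.predict_family <- function(net, x, spec) {
  p <- switch(spec$family,
    MLP = .mlp_predict(net, x, spec$task),
    RBF = predict(net, x),
    GRNN = predict(net, x),
    LNN = unname(predict(net$fit, as.data.frame(x)))
  )
  if (spec$task == "classification") p <- pmin(pmax(p, 0), 1)
  p
}

#' Train a shallow-network yield regressor
#'
#' Trains the requested network family on the training rows of a feature
#' table and reports train/test regression metrics. Training is a pure
#' function of `(features, yields, spec, seed)`.
#'
#' @param features feature table ([assemble_features()]).
#' @param yields observed yields.
#' @param spec a [network_spec()] with `task = "regression"`.
#' @param seed integer seed controlling all randomness.
#' @param split per-record labels (`"t"`/`"v"`); defaults to the features'
#'   records all being training.
#' @return a `ptml_ann` object with the fitted network, the spec, and a
#'   `metrics` tibble (one row per subset: `subset`, `r`, `mae`, `rmse`).
#' @export
train_regressor <- function(features, yields, spec, seed = 1, split = NULL) {
  y <- .align_yields(features, yields)
  x <- .feature_matrix(features)
  if (spec$n_in != ncol(x)) {
    abort(paste0("spec expects ", spec$n_in, " inputs but the feature table has ",
                 ncol(x)))
  }
  split <- split %||% rep("t", nrow(x))
  tr <- split == "t"
  if (!any(tr)) abort("no training rows")
  net <- .fit_family(x[tr, , drop = FALSE], y[tr], spec, seed)
  pred <- .predict_family(net, x, spec)
  metrics <- bind_rows(lapply(intersect(c("t", "v"), unique(split)), function(s) {
    idx <- split == s
    m <- regression_metrics(y[idx], pred[idx])
    tibble(subset = if (s == "t") "train" else "test",
           r = m$r, mae = m$mae, rmse = m$rmse)
  }))
  structure(list(net = net, spec = spec, seed = seed, metrics = metrics,
                 predictions = pred, split = split, observed = y),
            class = "ptml_ann")
}

#' Train a shallow-network yield classifier
#'
#' Binary classifier over the PTML features (labels typically from
#' [binarize_yield()]). Outputs class-1 probabilities; metrics include
#' accuracy, precision, recall, F1, TPR/TNR, confusion counts and rank-based
#' AUC for both subsets.
#'
#' @param features feature table.
#' @param labels binary 0/1 labels.
#' @param spec a [network_spec()] with `task = "classification"`.
#' @param seed integer seed.
#' @param split per-record `"t"`/`"v"` labels.
#' @param cutoff probability cutoff for the confusion matrix.
#' @return a `ptml_ann_classifier` with the network, per-subset metrics
#'   (list of [classification_metrics()] reports) and probabilities.
#' @export
train_classifier <- function(features, labels, spec, seed = 1, split = NULL,
                             cutoff = 0.5) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1")
  x <- .feature_matrix(features)
  if (spec$n_in != ncol(x)) {
    abort(paste0("spec expects ", spec$n_in, " inputs but the feature table has ",
                 ncol(x)))
  }
  split <- split %||% rep("t", nrow(x))
  tr <- split == "t"
  if (length(unique(labels[tr])) < 2) {
    abort("single-class training set", class = "ptml_degenerate_label_error")
  }
  net <- .fit_family(x[tr, , drop = FALSE], labels[tr], spec, seed)
  prob <- .predict_family(net, x, spec)
  metrics <- lapply(
    setNames(intersect(c("t", "v"), unique(split)),
             ifelse(intersect(c("t", "v"), unique(split)) == "t", "train", "test")),
    function(s) classification_metrics(labels[split == s], prob[split == s],
                                       cutoff = cutoff)
  )
  structure(list(net = net, spec = spec, seed = seed, metrics = metrics,
                 probabilities = prob, split = split, labels = labels,
                 cutoff = cutoff),
            class = "ptml_ann_classifier")
}

#' Per-cycle class prevalence reference
#'
#' Classifier analogue of the reference yield: the probability of the
#' "desired" class estimated as the class-1 prevalence within each reuse
#' cycle cohort of the training population.
#'
#' @param records canonical records.
#' @param labels binary labels aligned with `records`.
#' @param fit_rows rows defining the training population (default: all).
#' @return numeric vector of per-record reference probabilities.
#' @export
reference_class_probability <- function(records, labels, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(records))
  g <- as.character(records$reuse_cycle)
  prev <- tapply(labels[fit_rows], g[fit_rows], mean)
  out <- unname(prev[g])
  if (anyNA(out)) out[is.na(out)] <- mean(labels[fit_rows])
  as.numeric(out)
}

#' @export
print.ptml_ann <- function(x, ...) {
  cat("<ptml_ann ", x$spec$family, " ", x$spec$arch_code, ">\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @method glance ptml_ann
#' @export
glance.ptml_ann <- function(x, ...) x$metrics
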