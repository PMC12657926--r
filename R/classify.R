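#' SMOTE oversampling of minority classes
#'
#' Synthetic minority oversampling: each minority class is augmented up to
#' the majority-class count by interpolated points `x_i + lambda * (x_nn -
#' x_i)`, with `lambda` uniform on `(0, 1)` and `x_nn` one of the `k`
#' nearest same-class neighbours (Euclidean distance). Originals are kept;
#' already-balanced input is returned unchanged. Seed the RNG for
#' reproducibility.
#'
#' @param features numeric matrix or data.frame of feature rows.
#' @param labels factor (or coercible) of class labels, one per row.
#' @param k number of candidate nearest neighbours (default 5, capped at
#'   class size minus 1).
#' @return List with `features` (matrix) and `labels` (factor), synthetic
#'   rows appended.
#' @export
smote_oversample <- function(features, labels, k = 5) {
  x <- as.matrix(features)
  y <- as.factor(labels)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  counts <- table(y)
  target <- max(counts)
  singles <- names(counts)[counts == 1 & counts < target]
  if (length(singles)) {
    stop("cannot SMOTE singleton class: ", paste(singles, collapse = ", "),
         call. = FALSE)
  }
  new_x <- list(); new_y <- list()
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    rows <- which(y == cl)
    xc <- x[rows, , drop = FALSE]
    nc <- nrow(xc)
    kk <- min(k, nc - 1L)
    d <- as.matrix(stats::dist(xc))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(kk)]))
    base <- sample(nc, need, replace = TRUE)
    pick <- nn[cbind(base, sample(kk, need, replace = TRUE))]
    lam <- stats::runif(need)
    new_x[[cl]] <- xc[base, , drop = FALSE] +
      lam * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    new_y[[cl]] <- rep(cl, need)
  }
  if (!length(new_x)) return(list(features = x, labels = y))
  list(features = rbind(x, do.call(rbind, new_x)),
       labels = factor(c(as.character(y), unlist(new_y)), levels = levels(y)))
}

#' Stratified train/test split
#'
#' Splits rows into train and test sets with class proportions preserved.
#' Balancing (SMOTE) is applied to the training side only, downstream.
#'
#' @param labels factor of class labels.
#' @param test_fraction fraction held out, strictly in `(0, 1)`.
#' @return List with integer vectors `train` and `test` of row indices.
#' @export
train_test_split <- function(labels, test_fraction = 0.2) {
  y <- as.factor(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (any(table(y) < 5)) stop("each class needs at least 5 records", call. = FALSE)
  test <- unlist(lapply(levels(y), function(cl) {
    rows <- which(y == cl)
    sample(rows, max(1L, round(test_fraction * length(rows))))
  }))
  list(train = sort(setdiff(seq_along(y), test)), test = sort(test))
}

#' Radial basis function kernel
#'
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, the Gaussian similarity
#' used by the SVM classifier (default width `sigma = 1`, i.e. kernel
#' coefficient `1/(2 sigma^2) = 0.5`).
#'
#' @param x,xp equal-length numeric vectors.
#' @param sigma kernel width, `> 0`.
#' @return Value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, xp, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(x) != length(xp)) stop("x and xp must have equal length", call. = FALSE)
  exp(-sum((x - xp)^2) / (2 * sigma^2))
}

#' Categorical cross-entropy
#'
#' `J(y, y') = -sum(y_i log y'_i)` over one-hot targets: the negative log of
#' the predicted probability of the true class. Predicted probabilities are
#' clipped at `1e-12` (with a warning) to keep the loss finite.
#'
#' @param y_onehot one-hot matrix (or vector) of true classes.
#' @param y_pred matrix (or vector) of predicted class probabilities, rows
#'   summing to 1.
#' @return Mean loss over rows.
#' @export
categorical_cross_entropy <- function(y_onehot, y_pred) {
  y <- rbind(y_onehot); p <- rbind(y_pred)
  stopifnot(all(dim(y) == dim(p)))
  pt <- rowSums(y * p)
  if (any(pt < 1e-12)) {
    warning("predicted probability below 1e-12 clipped", call. = FALSE)
    pt <- pmax(pt, 1e-12)
  }
  mean(-log(pt))
}

one_hot <- function(y) {
  y <- as.factor(y)
  oh <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  oh[cbind(seq_along(y), as.integer(y))] <- 1
  oh
}

# ---- multilayer perceptron (ReLU hidden layers, softmax output, Adam) ----
# Written in plain matrix algebra: the preinstalled stack has no
# multi-hidden-layer feed-forward trainer, and the network is small (6
# inputs, 4 outputs).

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

mlp_forward <- function(layers, x, dropout = 0, train = FALSE) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L); acts[[1]] <- x
  masks <- vector("list", nl)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        # inverted dropout: scale at train time so inference needs no rescale
        mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                       nrow(a), ncol(a))
        a <- a * mask
        masks[[l]] <- mask
      }
    } else {
      zs <- z - apply(z, 1, max)
      ez <- exp(zs)
      a <- ez / rowSums(ez)
    }
    acts[[l + 1L]] <- a
  }
  list(acts = acts, masks = masks)
}

mlp_train <- function(x, y_onehot, hidden, dropout = 0, epochs = 100,
                      batch = 32, lr = 1e-3, x_val = NULL, y_val = NULL) {
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, ncol(y_onehot))
  layers <- mlp_init(sizes)
  nl <- length(layers)
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  val_loss <- rep(NA_real_, epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch)) {
      ids <- ord[start:min(start + batch - 1L, n)]
      xb <- x[ids, , drop = FALSE]; yb <- y_onehot[ids, , drop = FALSE]
      fw <- mlp_forward(layers, xb, dropout, train = TRUE)
      delta <- (fw$acts[[nl + 1L]] - yb) / nrow(xb)  # softmax + CCE gradient
      t <- t + 1
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(fw$acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(layers[[l]]$W)
          delta <- delta * (fw$acts[[l]] > 0)
          if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
        }
        m <- mom[[l]]
        m$mW <- b1 * m$mW + (1 - b1) * gW; m$vW <- b2 * m$vW + (1 - b2) * gW^2
        m$mb <- b1 * m$mb + (1 - b1) * gb; m$vb <- b2 * m$vb + (1 - b2) * gb^2
        mom[[l]] <- m
        corr <- sqrt(1 - b2^t) / (1 - b1^t)
        layers[[l]]$W <- layers[[l]]$W - lr * corr * m$mW / (sqrt(m$vW) + eps)
        layers[[l]]$b <- layers[[l]]$b - lr * corr * m$mb / (sqrt(m$vb) + eps)
      }
    }
    if (!is.null(x_val)) {
      pv <- mlp_forward(layers, x_val)$acts[[nl + 1L]]
      val_loss[ep] <- suppressWarnings(categorical_cross_entropy(y_val, pv))
    }
  }
  list(layers = layers, val_loss = val_loss)
}

mlp_predict_prob <- function(fit, x) {
  fw <- mlp_forward(fit$layers, x)
  fw$acts[[length(fw$acts)]]
}

#' Fit a classifier and predict stage labels
#'
#' Five model kinds over the six-feature index vectors: `tree` (CART via
#' rpart), `logistic` (multinomial regression via nnet), `svm_rbf` (RBF
#' kernel with width `sigma = 1`, i.e. gamma 0.5, via e1071), and the
#' neural networks `nn2` (hidden layers 64, 32) and `nn4` (hidden layers
#' 128, 64, 32, 16 with dropout 0.3), trained with categorical
#' cross-entropy, Adam (step 1e-3), batch 32. Features are standardized
#' internally using training-set statistics. Seed the RNG for
#' reproducibility.
#'
#' @param model_kind one of `"tree"`, `"logistic"`, `"svm_rbf"`, `"nn2"`,
#'   `"nn4"`.
#' @param train,test lists with `features` (matrix) and `labels` (factor;
#'   `test$labels` optional).
#' @param hyper optional overrides: `epochs`, `batch`, `lr`, `dropout`,
#'   `hidden`, `sigma`.
#' @return List with `pred` (factor), `prob` (row-stochastic matrix with one
#'   column per class), and `val_loss` (per-epoch validation loss, neural
#'   nets only).
#' @export
fit_predict <- function(model_kind, train, test, hyper = list()) {
  kinds <- c("tree", "logistic", "svm_rbf", "nn2", "nn4")
  if (!model_kind %in% kinds) {
    stop("unknown model_kind: ", model_kind, call. = FALSE)
  }
  xtr <- as.matrix(train$features); ytr <- as.factor(train$labels)
  xte <- as.matrix(test$features)
  lev <- levels(ytr)
  if (nlevels(droplevels(ytr)) == 1L) {
    cl <- as.character(unique(droplevels(ytr)))
    prob <- matrix(0, nrow(xte), length(lev), dimnames = list(NULL, lev))
    prob[, cl] <- 1
    return(list(pred = factor(rep(cl, nrow(xte)), levels = lev),
                prob = prob, val_loss = NULL))
  }
  mu <- colMeans(xtr); sdv <- apply(xtr, 2, stats::sd); sdv[sdv == 0] <- 1
  ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  zte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  val_loss <- NULL
  if (model_kind == "tree") {
    df <- data.frame(ztr, y = ytr)
    fit <- rpart::rpart(y ~ ., df, method = "class")
    prob <- stats::predict(fit, data.frame(zte), type = "prob")
  } else if (model_kind == "logistic") {
    df <- data.frame(ztr, y = ytr)
    fit <- nnet::multinom(y ~ ., df, trace = FALSE, maxit = 200)
    prob <- stats::predict(fit, data.frame(zte), type = "probs")
    if (is.null(dim(prob))) {  # two-class case returns a vector
      prob <- cbind(1 - prob, prob)
      colnames(prob) <- fit$lev
    }
  } else if (model_kind == "svm_rbf") {
    sigma <- hyper$sigma %||% 1
    fit <- e1071::svm(ztr, ytr, kernel = "radial", gamma = 1 / (2 * sigma^2),
                      probability = TRUE)
    pr <- stats::predict(fit, zte, probability = TRUE)
    prob <- attr(pr, "probabilities")
    prob <- prob[, order(match(colnames(prob), lev)), drop = FALSE]
  } else {
    hidden <- hyper$hidden %||% if (model_kind == "nn2") c(64, 32) else c(128, 64, 32, 16)
    dropout <- hyper$dropout %||% if (model_kind == "nn4") 0.3 else 0
    epochs <- hyper$epochs %||% 150
    ytr_oh <- one_hot(ytr)
    yte_oh <- if (!is.null(test$labels)) {
      one_hot(factor(test$labels, levels = lev))
    } else NULL
    fit <- mlp_train(ztr, ytr_oh, hidden = hidden, dropout = dropout,
                     epochs = epochs, batch = hyper$batch %||% 32,
                     lr = hyper$lr %||% 1e-3,
                     x_val = if (is.null(yte_oh)) NULL else zte,
                     y_val = yte_oh)
    prob <- mlp_predict_prob(fit, zte)
    colnames(prob) <- lev
    val_loss <- fit$val_loss
  }
  full <- matrix(0, nrow(zte), length(lev), dimnames = list(NULL, lev))
  full[, colnames(prob)] <- as.matrix(prob)
  pred <- factor(lev[max.col(full, ties.method = "first")], levels = lev)
  list(pred = pred, prob = full, val_loss = val_loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification metrics for multi-class predictions
#'
#' Accuracy, support-weighted precision/recall/F1, macro-averaged
#' one-vs-rest AUC (classes absent from the truth are excluded, with a
#' message), and the confusion matrix.
#'
#' @param pred factor of predicted labels.
#' @param prob row-stochastic matrix of class probabilities (columns named
#'   by class); may be `NULL`, in which case AUC is `NA`.
#' @param truth factor of true labels.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `confusion`.
#' @export
evaluate <- function(pred, prob, truth) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  pred <- factor(as.character(pred), levels = lev)
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  support <- rowSums(cm)
  prec_c <- diag(cm) / pmax(colSums(cm), 1)
  rec_c <- diag(cm) / pmax(support, 1)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / sum(support)
  auc <- NA_real_
  if (!is.null(prob)) {
    present <- lev[support > 0 & support < sum(support)]
    if (length(present) < length(lev[support > 0])) {
      message("AUC: classes without both positives and negatives excluded")
    }
    aucs <- vapply(present, function(cl) {
      resp <- as.integer(truth == cl)
      as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, 0)
    auc <- mean(aucs)
  }
  list(accuracy = acc,
       precision = sum(w * prec_c),
       recall = sum(w * rec_c),
       f1 = sum(w * f1_c),
       auc = auc,
       confusion = cm)
}

#' Stratified K-fold cross-validation with in-fold SMOTE
#'
#' Splits the records into stratified folds, then for each fold applies
#' SMOTE to the training partition only (the held-out fold is never
#' resampled, avoiding leakage), fits the requested model, and evaluates on
#' the held-out fold. Reports per-fold metrics and their means.
#'
#' @param features numeric matrix of index features.
#' @param labels factor of stage labels.
#' @param model_kind passed to [fit_predict()].
#' @param folds number of folds (default 5); every class must have at least
#'   `folds` members.
#' @param smote_k SMOTE neighbour count.
#' @param hyper passed to [fit_predict()].
#' @param seed optional seed applied once before folding.
#' @return An object of class `eval_report`: list with `folds` (per-fold
#'   metric lists), `mean` (named vector of mean metrics), `confusion`
#'   (summed confusion matrix), `val_loss` (per-fold loss curves, neural
#'   nets), `model_kind`.
#' @export
cross_validate <- function(features, labels, model_kind = "nn4", folds = 5,
                           smote_k = 5, hyper = list(), seed = NULL) {
  x <- as.matrix(features); y <- as.factor(labels)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (any(table(y) < folds)) {
    stop("every class needs at least `folds` members", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    rows <- sample(which(y == cl))
    fold_id[rows] <- rep_len(seq_len(folds), length(rows))
  }
  fold_res <- vector("list", folds)
  loss_curves <- list()
  cm_total <- NULL
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    bal <- smote_oversample(x[tr, , drop = FALSE], droplevels(y[tr]), k = smote_k)
    bal$labels <- factor(as.character(bal$labels), levels = levels(y))
    fp <- fit_predict(model_kind,
                      train = list(features = bal$features, labels = bal$labels),
                      test = list(features = x[te, , drop = FALSE],
                                  labels = y[te]),
                      hyper = hyper)
    ev <- evaluate(fp$pred, fp$prob, y[te])
    fold_res[[f]] <- ev
    if (!is.null(fp$val_loss)) loss_curves[[f]] <- fp$val_loss
    cm_total <- if (is.null(cm_total)) ev$confusion else cm_total + ev$confusion
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  mt <- sapply(metric_names, function(m) mean(vapply(fold_res, `[[`, 0, m)))
  structure(list(folds = fold_res, mean = mt, confusion = cm_total,
                 val_loss = loss_curves, model_kind = model_kind,
                 n_folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s, %d-fold cross-validation>\n",
              x$model_kind, x$n_folds))
  tab <- t(vapply(x$folds, function(f)
    unlist(f[c("accuracy", "precision", "recall", "f1", "auc")]),
    numeric(5)))
  tab <- rbind(tab, mean = x$mean)
  rownames(tab)[seq_len(x$n_folds)] <- paste0("fold", seq_len(x$n_folds))
  print(round(tab, 4))
  invisible(x)
}
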