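# Precomputed-kernel SVM pipeline: one-vs-all training on mixture-derived
# Gram matrices, the evaluation metrics (ACC / DR / FPR / AUC), stratified
# cross-validation, and the Gaussian-mixture baseline used by the synthetic
# ordering check.

# ---- Gaussian-mixture baseline ---------------------------------------------
# Library-backed (mclust). Compositions live on a (D-1)-dimensional affine
# subspace, so the Gaussian mixture is fitted on the first D-1 coordinates
# to keep covariances non-singular.

#' Fit a Gaussian mixture to a bag (baseline model family)
#'
#' Fits an mclust Gaussian mixture to the first `D - 1` coordinates of the
#' bag's compositions (the last coordinate is redundant on the simplex).
#' Only used as the comparison baseline in the synthetic ordering
#' experiment; implements [mixture_log_density()] and [mixture_sample()] so
#' the Monte Carlo kernels apply unchanged.
#'
#' @param bag a [feature_bag()] or `N x D` matrix of compositions.
#' @param G number of Gaussian components.
#' @param seed integer seed.
#' @return object of class `"gmm_model"`.
#' @export
fit_gmm_bag <- function(bag, G = 2L, seed = 0L) {
  Y <- if (inherits(bag, "feature_bag")) bag$vectors else as.matrix(bag)
  X <- Y[, -ncol(Y), drop = FALSE]
  set.seed(seed)
  # Mclust resolves mclustBIC in the calling frame; bind it locally so the
  # package need not attach mclust.
  mclustBIC <- mclust::mclustBIC
  fit <- NULL
  for (mn in list(c("VVV", "VVI", "VII", "EII"), "EII")) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(X, G = G, modelNames = mn, verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$parameters)) break
    fit <- NULL
  }
  if (is.null(fit)) stop("Gaussian mixture fit failed", call. = FALSE)
  structure(list(modelName = fit$modelName, parameters = fit$parameters,
                 dim = ncol(X)),
            class = "gmm_model")
}

#' @export
mixture_log_density.gmm_model <- function(model, x) {
  mclust::dens(data = as.matrix(x), modelName = model$modelName,
               parameters = model$parameters, logarithm = TRUE)
}

#' @export
mixture_sample.gmm_model <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # mclust::sim dispatches to simVVV etc. in the calling frame
  simfun <- get(paste0("sim", model$modelName), envir = asNamespace("mclust"))
  out <- simfun(parameters = model$parameters, n = n)
  as.matrix(out[, -1L, drop = FALSE])   # first column is the component label
}

#' @export
mixture_dim.gmm_model <- function(model) model$dim

# ---- SVM on a precomputed Gram matrix ---------------------------------------

#' Train a one-vs-all SVM on a precomputed kernel matrix
#'
#' One binary C-SVM per class against the rest (a single machine when there
#' are two classes behaves identically); prediction takes the class whose
#' machine gives the largest decision value. Decision-value orientation is
#' checked on the training data so that larger always means "this class".
#'
#' @param K symmetric `M x M` training Gram matrix (PSD; see
#'   [ensure_psd()]), dimnames = image ids.
#' @param labels named character vector of class labels covering the
#'   training ids.
#' @param C SVM cost parameter.
#' @return object of class `"ssdmix_svm"`.
#' @export
train_svm <- function(K, labels, C = 1) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  y <- as.character(labels[ids])
  if (anyNA(y)) stop("labels missing for some training ids", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training labels contain a single class", call. = FALSE)
  machines <- lapply(classes, function(cls) {
    yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("neg", "pos"))
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yy, type = "C-svc", C = C)
    dec <- kernlab::predict(
      m, kernlab::as.kernelMatrix(K[, kernlab::SVindex(m), drop = FALSE]),
      type = "decision")
    flip <- mean(dec[yy == "pos"]) < mean(dec[yy == "neg"])
    list(model = m, flip = flip)
  })
  names(machines) <- classes
  structure(list(machines = machines, classes = classes, train_ids = ids, C = C),
            class = "ssdmix_svm")
}

#' Predict from a one-vs-all precomputed-kernel SVM
#'
#' @param object an `"ssdmix_svm"` from [train_svm()].
#' @param K_test_train `M_test x M_train` kernel block between test and
#'   training images (columns in training-id order).
#' @param ... unused.
#' @return list with `class` (predicted labels), `scores`
#'   (`M_test x n_classes` decision values).
#' @export
predict.ssdmix_svm <- function(object, K_test_train, ...) {
  K_test_train <- as.matrix(K_test_train)
  scores <- sapply(object$classes, function(cls) {
    mc <- object$machines[[cls]]
    sv <- kernlab::SVindex(mc$model)
    dec <- kernlab::predict(
      mc$model, kernlab::as.kernelMatrix(K_test_train[, sv, drop = FALSE]),
      type = "decision")
    if (mc$flip) -drop(dec) else drop(dec)
  })
  scores <- matrix(scores, nrow = nrow(K_test_train),
                   dimnames = list(rownames(K_test_train), object$classes))
  list(class = object$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

# ---- metrics ----------------------------------------------------------------

# Rank-statistic (Mann-Whitney) AUC of scores for the positive class.
auc_rank <- function(scores, y_true, positive) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics: accuracy, detection rate, false-positive rate, AUC
#'
#' For binary problems: `ACC = (TP+TN)/(TP+FP+TN+FN)` (reported as a
#' percentage), `DR = TP/(TP+FN)` (sensitivity, percentage),
#' `FPR = FP/(FP+TN)` (a proportion), and AUC by the rank statistic over
#' the positive-class scores.
#'
#' @param y_true,y_pred character vectors of true and predicted labels.
#' @param scores optional numeric scores for the positive class (needed
#'   for AUC).
#' @param positive label of the positive class; defaults to the
#'   alphabetically last label.
#' @return object of class `"metrics_report"`: list with `acc`, `dr`
#'   (percentages), `fpr` (proportion), `auc`, and `confusion`
#'   (`TP`, `FP`, `TN`, `FN`).
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length", call. = FALSE)
  }
  if (is.null(positive)) positive <- utils::tail(sort(unique(y_true)), 1)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  acc <- 100 * (tp + tn) / length(y_true)
  dr <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  auc <- if (!is.null(scores)) auc_rank(scores, y_true, positive) else NA_real_
  structure(list(acc = acc, dr = dr, fpr = fpr, auc = auc,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 positive = positive),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  DR %.2f%%  FPR %.3f  AUC %s\n",
              x$acc, x$dr, x$fpr,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

# ---- cross-validation -------------------------------------------------------

# Stratified fold assignment: named integer vector of fold ids.
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold_of <- integer(length(labels)); names(fold_of) <- names(labels)
  for (cls in unique(labels)) {
    ids <- names(labels)[labels == cls]
    if (length(ids) < folds) {
      stop(sprintf("class '%s' has fewer images (%d) than folds (%d)",
                   cls, length(ids), folds), call. = FALSE)
    }
    ids <- sample(ids)
    fold_of[ids] <- rep_len(seq_len(folds), length(ids))
  }
  fold_of
}

#' Fit one mixture per image
#'
#' Fits an independent mixture to every bag (no label information is used):
#' the inputs the divergence kernels compare. Per-image seeds are derived
#' deterministically from the master seed.
#'
#' @param bags named list of [feature_bag()] objects.
#' @param family `"ssd"` (default) or `"gmm"` (the Gaussian baseline).
#' @param K_image components per mixture (capped at the bag size).
#' @param seed master integer seed.
#' @param ... further arguments passed to [fit_em()].
#' @return named list of fitted mixture models.
#' @export
fit_image_models <- function(bags, family = c("ssd", "gmm"), K_image = 2L,
                             seed = 0L, ...) {
  family <- match.arg(family)
  models <- vector("list", length(bags))
  for (i in seq_along(bags)) {
    s <- derive_seed(seed, i)
    models[[i]] <- if (family == "ssd") {
      fit_em(bags[[i]]$vectors, K = min(K_image, nrow(bags[[i]]$vectors)),
             seed = s, ...)$model
    } else {
      fit_gmm_bag(bags[[i]], G = K_image, seed = s)
    }
  }
  names(models) <- vapply(bags, function(b) b$image_id, character(1))
  models
}

#' Cross-validated classification with mixture-derived kernels
#'
#' Stratified k-fold cross-validation of the full pipeline. For the Fisher
#' kernel a background SSD mixture is fitted per fold on pooled training
#' descriptors only (score standardisation statistics likewise); for the
#' symmetrized-KL and Bhattacharyya kernels one mixture is fitted per image
#' on its own bag (no label information), the pairwise kernel is computed
#' once, and PSD repair is applied to each fold's training block only.
#' `kernel_type = "gmm_skk"` is the Gaussian-mixture baseline: per-image
#' Gaussian mixtures compared with the same symmetrized-KL kernel.
#'
#' @param bags named list of [feature_bag()] objects.
#' @param labels named character vector of class labels (names = image ids).
#' @param kernel_type one of `"fisher"`, `"skk"`, `"bk"`, `"gmm_skk"`.
#' @param folds number of folds (default 10).
#' @param C SVM cost.
#' @param seed master seed (folds, per-image fits, Monte Carlo draws).
#' @param K_image components per per-image mixture (default 2).
#' @param K_background components of the Fisher background model (default 3).
#' @param B symmetrized-KL kernel scale.
#' @param L Monte Carlo samples per side per pair.
#' @param max_pool_vectors cap on pooled descriptors used to fit the
#'   background model (subsampled deterministically beyond this).
#' @param holdout optional proportion in (0, 1): a single stratified
#'   train/test split with this test fraction instead of k-fold CV.
#' @return `"metrics_report"` with extra fields `per_fold` (data.frame) and
#'   `kernel_type`; attribute `fold_info` records per-fold train/test ids
#'   (and the ids whose descriptors formed the background model).
#' @export
cross_validate <- function(bags, labels, kernel_type = c("skk", "bk", "fisher", "gmm_skk"),
                           folds = 10L, C = 1, seed = 0L, K_image = 2L,
                           K_background = 3L, B = 1, L = 5000L,
                           max_pool_vectors = 2000L, holdout = NULL) {
  kernel_type <- match.arg(kernel_type)
  ids <- vapply(bags, function(b) b$image_id, character(1))
  names(bags) <- ids
  labels <- labels[ids]
  if (anyNA(labels)) stop("labels missing for some bags", call. = FALSE)
  if (!is.null(holdout)) {
    stopifnot(holdout > 0, holdout < 1)
    set.seed(seed)
    fold_of <- stats::setNames(rep(0L, length(ids)), ids)
    for (cls in unique(labels)) {
      cid <- sample(names(labels)[labels == cls])
      fold_of[cid[seq_len(max(1L, round(holdout * length(cid))))]] <- 1L
    }
    nfold <- 1L
  } else {
    fold_of <- stratified_folds(labels, folds, seed)
    nfold <- folds
  }

  # per-image mixtures and the full pairwise kernel (label-free) are shared
  # across folds for the divergence kernels
  Kfull <- NULL; models <- NULL
  if (kernel_type %in% c("skk", "bk", "gmm_skk")) {
    family <- if (kernel_type == "gmm_skk") "gmm" else "ssd"
    models <- fit_image_models(bags, family = family, K_image = K_image,
                               seed = derive_seed(seed, 1L))
    Kfull <- if (kernel_type == "bk") {
      bk_kernel_matrix(models, L = L, seed = derive_seed(seed, 2L),
                       psd_repair = FALSE)
    } else {
      skk_kernel_matrix(models, B = B, L = L, seed = derive_seed(seed, 2L),
                        psd_repair = FALSE)
    }
  }

  per_fold <- list(); fold_info <- list()
  y_all <- character(0); p_all <- character(0); s_all <- numeric(0)
  positive <- utils::tail(sort(unique(as.character(labels))), 1)
  for (f in seq_len(nfold)) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- setdiff(ids, test_ids)
    if (length(unique(labels[train_ids])) < 2L) next
    if (kernel_type == "fisher") {
      pool <- do.call(rbind, lapply(bags[train_ids], function(b) b$vectors))
      if (nrow(pool) > max_pool_vectors) {
        set.seed(derive_seed(seed, 3L, f))
        pool <- pool[sample.int(nrow(pool), max_pool_vectors), , drop = FALSE]
      }
      bg <- fit_em(pool, K = K_background, seed = derive_seed(seed, 4L, f))$model
      Km <- fisher_kernel_matrix(bags, bg, stats_from = bags[train_ids])
      fold_info[[f]] <- list(train = train_ids, test = test_ids,
                             background_ids = train_ids)
    } else {
      Km <- Kfull
      fold_info[[f]] <- list(train = train_ids, test = test_ids,
                             background_ids = character(0))
    }
    Ktr <- ensure_psd(Km[train_ids, train_ids, drop = FALSE])
    svm <- train_svm(Ktr, labels[train_ids], C = C)
    pred <- predict(svm, Km[test_ids, train_ids, drop = FALSE])
    sc <- if (positive %in% colnames(pred$scores)) {
      pred$scores[, positive]
    } else {
      pred$scores[, 1L]
    }
    m <- compute_metrics(labels[test_ids], pred$class, scores = sc,
                         positive = positive)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, n_test = length(test_ids), acc = m$acc, dr = m$dr,
                 fpr = m$fpr, auc = m$auc)
    y_all <- c(y_all, labels[test_ids]); p_all <- c(p_all, pred$class)
    s_all <- c(s_all, sc)
  }
  pf <- do.call(rbind, per_fold)
  overall <- compute_metrics(y_all, p_all, scores = s_all, positive = positive)
  out <- structure(list(acc = mean(pf$acc), dr = mean(pf$dr, na.rm = TRUE),
                        fpr = mean(pf$fpr, na.rm = TRUE),
                        auc = overall$auc, confusion = overall$confusion,
                        positive = positive, per_fold = pf,
                        kernel_type = kernel_type),
                   class = "metrics_report")
  attr(out, "fold_info") <- fold_info
  out
}
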