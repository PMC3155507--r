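#' Training configuration for the two-layer model
#'
#' Defaults are the published operating point: two K-means clusters of the
#' positive windows, negatives drawn at three times each positive subset,
#' RBF kernels with `(C, gamma) = (0.5, 2^-7)` for both first-layer
#' clustered models and `(32, 8)` for the second layer.
#'
#' @param k_clusters Number of K-means clusters of the positive set.
#' @param neg_ratio Negative:positive sampling ratio per clustered model.
#' @param first_layer_C,first_layer_gamma RBF parameters of both clustered
#'   models.
#' @param second_layer_C,second_layer_gamma RBF parameters of the stacked
#'   classifier.
#' @param seed Master seed; all internal randomness (K-means restarts,
#'   negative sampling, probability calibration) derives from it.
#' @param grid_search If `TRUE`, `(C, gamma)` pairs are tuned by
#'   [grid_search_svm()] instead of the defaults.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(k_clusters = 2L, neg_ratio = 3,
                            first_layer_C = 0.5, first_layer_gamma = 0.0078125,
                            second_layer_C = 32, second_layer_gamma = 8,
                            seed = 1L, grid_search = FALSE) {
  stopifnot(k_clusters >= 1, neg_ratio >= 1,
            first_layer_C > 0, first_layer_gamma > 0,
            second_layer_C > 0, second_layer_gamma > 0)
  structure(
    list(k_clusters = as.integer(k_clusters), neg_ratio = neg_ratio,
         first_layer_C = first_layer_C, first_layer_gamma = first_layer_gamma,
         second_layer_C = second_layer_C, second_layer_gamma = second_layer_gamma,
         kernel = "rbf", seed = as.integer(seed), grid_search = grid_search),
    class = "training_config"
  )
}

#' K-means split of the positive windows
#'
#' Clusters the positive feature vectors on the original variables with
#' standard K-means (Euclidean distance, 10 random restarts, deterministic
#' under the seed). Clusters are renumbered so that cluster 1 is the
#' larger; size ties go to the centroid with the smaller norm.
#'
#' @param features Numeric matrix of positive-sample feature vectors.
#' @param k Number of clusters (default 2).
#' @param seed RNG seed.
#' @return A list with `assignments` (integer vector in `1..k`) and
#'   `centers` (`k x d` matrix).
#' @export
cluster_positives <- function(features, k = 2L, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < k) {
    stop_bt("need at least %d positive samples to form %d clusters (got %d)",
            k, k, nrow(features))
  }
  km <- with_seed(seed, stats::kmeans(features, centers = k, nstart = 10L,
                                      iter.max = 100L))
  sizes <- tabulate(km$cluster, nbins = k)
  norms <- sqrt(rowSums(km$centers^2))
  ord <- order(-sizes, norms)
  relabel <- match(seq_len(k), ord)
  list(assignments = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE])
}

#' Draw the negative training set for one clustered model
#'
#' Uniform sample without replacement of `round(ratio * n_positive)` rows
#' from the negative pool. If the pool is smaller than that, the whole
#' pool is returned with a warning.
#'
#' @param pool Matrix or data frame of negative samples (rows).
#' @param n_positive Size of the positive subset being paired.
#' @param ratio Negative:positive ratio (default 3).
#' @param seed RNG seed.
#' @return A row subset of `pool`.
#' @export
sample_negatives <- function(pool, n_positive, ratio = 3, seed = 1L) {
  n_pool <- nrow(pool)
  if (is.null(n_pool) || n_pool == 0L) stop_bt("negative pool is empty")
  want <- round(ratio * n_positive)
  if (n_pool <= want) {
    if (n_pool < want) {
      warn_bt("negative pool (%d) smaller than requested %d; using the whole pool",
              n_pool, want)
    }
    return(pool)
  }
  idx <- with_seed(seed, sample.int(n_pool, want))
  pool[idx, , drop = FALSE]
}

#' Train one first-layer clustered model
#'
#' Fits an RBF-kernel SVM with probability calibration (libsvm's
#' pairwise-coupling sigmoid fit, via \pkg{e1071}) on one positive cluster
#' plus its sampled negatives. The model is a probability generator for
#' the second layer, not a final predictor.
#'
#' @param positives,negatives Feature matrices of the two classes.
#' @param C,gamma RBF parameters.
#' @param seed RNG seed (probability calibration shuffles internally).
#' @param cluster_index 1 or 2, recorded for provenance.
#' @return A list of class `"clustered_model"` with the fitted `svm` and
#'   training metadata.
#' @export
train_clustered_model <- function(positives, negatives, C = 0.5,
                                  gamma = 0.0078125, seed = 1L,
                                  cluster_index = 1L) {
  positives <- as.matrix(positives); negatives <- as.matrix(negatives)
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop_bt("both classes must be non-empty to train a clustered model")
  }
  x <- rbind(positives, negatives)
  y <- factor(rep(c("pos", "neg"), c(nrow(positives), nrow(negatives))),
              levels = c("pos", "neg"))
  fit <- with_seed(seed, e1071::svm(x, y, kernel = "radial", cost = C,
                                    gamma = gamma, probability = TRUE,
                                    scale = FALSE))
  structure(
    list(fit = fit, cluster_index = as.integer(cluster_index),
         C = C, gamma = gamma,
         n_pos = nrow(positives), n_neg = nrow(negatives)),
    class = "clustered_model"
  )
}

#' @export
print.clustered_model <- function(x, ...) {
  cat(sprintf("<clustered_model %d> RBF SVM (C=%g, gamma=%g), %d pos / %d neg\n",
              x$cluster_index, x$C, x$gamma, x$n_pos, x$n_neg))
  invisible(x)
}

# (p_pos, p_neg) estimates of one clustered model for a feature matrix.
clustered_proba <- function(model, features) {
  pr <- attr(stats::predict(model$fit, as.matrix(features), probability = TRUE),
             "probabilities")
  cbind(pos = pr[, "pos"], neg = pr[, "neg"])
}

#' Meta-features: stacked probability estimates
#'
#' Every sample is pushed through both frozen clustered models; the four
#' probability estimates `(p1_pos, p1_neg, p2_pos, p2_neg)` form the
#' second layer's input vector. The component order is fixed and recorded
#' in the model archive.
#'
#' @param features Feature matrix (samples in rows).
#' @param model1,model2 The two `"clustered_model"` objects.
#' @return An `n x 4` matrix with columns `p1_pos, p1_neg, p2_pos, p2_neg`.
#' @export
meta_features <- function(features, model1, model2) {
  features <- as.matrix(features)
  p1 <- clustered_proba(model1, features)
  p2 <- clustered_proba(model2, features)
  out <- cbind(p1[, "pos"], p1[, "neg"], p2[, "pos"], p2[, "neg"])
  colnames(out) <- c("p1_pos", "p1_neg", "p2_pos", "p2_neg")
  out
}

#' Train the full two-layer beta-turn classifier
#'
#' The published architecture: (1) split the positive windows into two
#' K-means clusters on the original feature vectors; (2) pair each cluster
#' with freshly sampled negatives (1:`neg_ratio`) and fit one probability-
#' calibrated RBF SVM per cluster ("clustered model 1" / "2"); (3) push
#' ALL training samples through both frozen clustered models and fit a
#' second-layer RBF SVM on the resulting 4-dimensional probability
#' vectors. If K-means produces an empty cluster the clustering is retried
#' with fresh derived seeds a bounded number of times.
#'
#' @param samples Window-sample tibble from [slice_windows()] (columns
#'   `label` and matrix-column `features`).
#' @param config A [training_config()].
#' @return A list of class `"two_layer_model"` holding both clustered
#'   models, the second-layer SVM, the encoding width and the config.
#' @export
train_two_layer <- function(samples, config = training_config()) {
  x <- as.matrix(samples$features)
  y <- samples$label
  if (!any(y) || all(y)) stop_bt("training set must contain both classes")
  if (isTRUE(config$grid_search)) {
    tuned <- grid_search_svm(samples, seed = config$seed)
    config$first_layer_C <- tuned$C
    config$first_layer_gamma <- tuned$gamma
  }
  pos <- x[y, , drop = FALSE]
  neg <- x[!y, , drop = FALSE]
  k <- config$k_clusters

  cl <- NULL
  for (attempt in 0:4) {
    cand <- cluster_positives(pos, k = k, seed = config$seed + attempt)
    if (all(tabulate(cand$assignments, nbins = k) > 0L)) { cl <- cand; break }
  }
  if (is.null(cl)) stop_bt("K-means produced an empty cluster after 5 attempts")

  cms <- vector("list", k)
  for (j in seq_len(k)) {
    pos_j <- pos[cl$assignments == j, , drop = FALSE]
    neg_j <- sample_negatives(neg, nrow(pos_j), ratio = config$neg_ratio,
                              seed = config$seed + 100L * j)
    cms[[j]] <- train_clustered_model(pos_j, neg_j,
                                      C = config$first_layer_C,
                                      gamma = config$first_layer_gamma,
                                      seed = config$seed + 200L + j,
                                      cluster_index = j)
  }

  meta <- meta_features(x, cms[[1L]], cms[[2L]])
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  second <- with_seed(config$seed + 300L,
                      e1071::svm(meta, yf, kernel = "radial",
                                 cost = config$second_layer_C,
                                 gamma = config$second_layer_gamma,
                                 probability = TRUE, scale = FALSE))
  structure(
    list(cluster_models = cms, second_layer = second,
         feature_width = ncol(x), meta_order = colnames(meta),
         config = config),
    class = "two_layer_model"
  )
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat(sprintf(paste0("<two_layer_model> %d-dim features; clustered models ",
                     "(C=%g, gamma=%g) x%d; second layer (C=%g, gamma=%g)\n"),
              x$feature_width, x$config$first_layer_C, x$config$first_layer_gamma,
              length(x$cluster_models), x$config$second_layer_C,
              x$config$second_layer_gamma))
  invisible(x)
}

#' Predict beta-turn windows with a trained model
#'
#' @param object A `"two_layer_model"` (or `"single_svm_model"`).
#' @param samples Window-sample tibble with a `features` matrix-column, or
#'   a bare feature matrix.
#' @param threshold Positive-label threshold on the score (default 0.5).
#' @param ... Unused.
#' @return A tibble with `score` (second-layer positive-class probability)
#'   and `label` (`score >= threshold`); `chain_id`/`start` are carried
#'   through when present in `samples`.
#' @export
predict.two_layer_model <- function(object, samples, threshold = 0.5, ...) {
  x <- sample_matrix(samples, object$feature_width)
  meta <- meta_features(x, object$cluster_models[[1L]], object$cluster_models[[2L]])
  pr <- attr(stats::predict(object$second_layer, meta, probability = TRUE),
             "probabilities")
  score_tbl(samples, pr[, "pos"], threshold)
}

sample_matrix <- function(samples, expected_width) {
  x <- if (is.matrix(samples)) samples else as.matrix(samples$features)
  if (ncol(x) != expected_width) {
    stop_bt("sample encoding has %d features but the model expects %d",
            ncol(x), expected_width)
  }
  x
}

score_tbl <- function(samples, score, threshold) {
  out <- tibble::tibble(score = as.numeric(score),
                        label = as.numeric(score) >= threshold)
  if (!is.matrix(samples)) {
    if ("chain_id" %in% names(samples)) out <- dplyr::bind_cols(
      samples[, intersect(c("chain_id", "start"), names(samples))], out)
  }
  out
}

#' Persist and restore a trained model archive
#'
#' The archive is a single RDS file bundling the model, its training
#' configuration, the meta-feature order, the feature width and format /
#' package version metadata; [read_model()] refuses archives written in
#' an unknown format so trained models cannot silently be applied to a
#' mismatched encoding.
#'
#' @param model A `"two_layer_model"` or `"single_svm_model"`.
#' @param path Archive path.
#' @return `write_model()`: `path`, invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("two_layer_model", "single_svm_model")))
  saveRDS(list(format = "betaturn-model/1", model = model,
               package_version = as.character(utils::packageVersion("betaturn"))),
          path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format, "betaturn-model/1")) {
    stop_bt("unrecognised model archive format in %s", path)
  }
  archive$model
}

#' Train a single (unstacked) SVM baseline
#'
#' One RBF SVM on the raw window features, used as the flat baseline the
#' two-layer architecture is compared against.
#'
#' @param samples Window-sample tibble.
#' @param C,gamma RBF parameters (defaults match the clustered models).
#' @param seed RNG seed.
#' @return A list of class `"single_svm_model"`.
#' @export
train_single_svm <- function(samples, C = 0.5, gamma = 0.0078125, seed = 1L) {
  x <- as.matrix(samples$features)
  y <- factor(ifelse(samples$label, "pos", "neg"), levels = c("pos", "neg"))
  if (nlevels(droplevels(y)) < 2L) stop_bt("training set must contain both classes")
  fit <- with_seed(seed, e1071::svm(x, y, kernel = "radial", cost = C,
                                    gamma = gamma, probability = TRUE,
                                    scale = FALSE))
  structure(list(fit = fit, feature_width = ncol(x), C = C, gamma = gamma),
            class = "single_svm_model")
}

#' @rdname predict.two_layer_model
#' @export
predict.single_svm_model <- function(object, samples, threshold = 0.5, ...) {
  x <- sample_matrix(samples, object$feature_width)
  pr <- attr(stats::predict(object$fit, x, probability = TRUE),
             "probabilities")
  score_tbl(samples, pr[, "pos"], threshold)
}

#' Grid search for RBF SVM parameters
#'
#' Exhaustive search over a `(C, gamma)` grid maximising inner
#' cross-validated accuracy of a single RBF SVM on the given samples.
#' Ties prefer the smallest `C`, then the smallest `gamma`. The default
#' grid is the customary libsvm sweep `C = 2^-5..2^15`, `gamma =
#' 2^-15..2^3` in multiplicative steps of 4.
#'
#' @param samples Window-sample tibble.
#' @param C_grid,gamma_grid Candidate values.
#' @param inner_folds Number of inner CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return A list with `C`, `gamma` and the full `results` tibble
#'   (accuracy per grid point).
#' @export
grid_search_svm <- function(samples,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            inner_folds = 5L, seed = 1L) {
  if (!length(C_grid) || !length(gamma_grid)) stop_bt("grids must be non-empty")
  x <- as.matrix(samples$features)
  y <- factor(ifelse(samples$label, "pos", "neg"), levels = c("pos", "neg"))
  folds <- assign_folds(nrow(x), inner_folds, seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2L) {
        warn_bt("inner fold %d has a single training class; skipped", f)
        next
      }
      fit <- with_seed(seed + f, e1071::svm(x[tr, , drop = FALSE], y[tr],
                                            kernel = "radial",
                                            cost = grid$C[g],
                                            gamma = grid$gamma[g],
                                            scale = FALSE))
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
      total <- total + sum(!tr)
    }
    acc[g] <- if (total > 0L) correct / total else 0
  }
  best <- order(-acc, grid$C, grid$gamma)[1L]
  list(C = grid$C[best], gamma = grid$gamma[best],
       results = tibble::tibble(C = grid$C, gamma = grid$gamma, accuracy = acc))
}
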