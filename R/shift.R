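#' Standardize a feature table for analysis
#'
#' Per feature column: missing values are imputed by the column median, then
#' the column is z-scored (mean 0, population SD 1).  Constant columns map to
#' all zeros.  Label and id columns are untouched.
#'
#' @param table Feature table data frame with `scan_id` and the 22 feature
#'   columns.
#' @return The table with standardized feature columns.
#' @export
standardize_features <- function(table) {
  check_feature_columns(table)
  if (nrow(table) < 2L) stop("standardization needs at least 2 scans")
  for (fn in FEATURE_NAMES) {
    x <- table[[fn]]
    x[!is.finite(x)] <- NA_real_
    if (all(is.na(x))) { table[[fn]] <- rep(0, length(x)); next }
    med <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    s <- pop_sd(x)
    table[[fn]] <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  table
}

rbf_kernel <- function(x, y, h) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / (2 * h^2))
}

resolve_bandwidth <- function(pooled, bandwidth) {
  if (is.numeric(bandwidth)) {
    stopifnot(bandwidth > 0)
    return(bandwidth)
  }
  d2 <- outer(rowSums(pooled^2), rowSums(pooled^2), `+`) -
    2 * tcrossprod(pooled)
  d <- sqrt(pmax(d2[upper.tri(d2)], 0))
  h <- stats::median(d)
  if (!is.finite(h) || h == 0) 1 else h
}

#' Kernel maximum mean discrepancy between two samples
#'
#' Biased (V-statistic) squared-MMD estimator with an RBF kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 h^2))`:
#' `mean(K_aa) + mean(K_bb) - 2 mean(K_ab)`, clipped at 0 against floating
#' point error.  With `bandwidth = "median-heuristic"` (default), `h` is the
#' median pairwise Euclidean distance of the pooled sample.
#'
#' @param a,b Numeric matrices (rows = observations) of equal column count.
#' @param bandwidth Positive number or `"median-heuristic"`.
#' @return Non-negative squared MMD.
#' @export
mmd_distance <- function(a, b, bandwidth = "median-heuristic") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("dimension mismatch: ", ncol(a), " vs ", ncol(b), " columns")
  stopifnot(nrow(a) > 0L, nrow(b) > 0L)
  h <- resolve_bandwidth(rbind(a, b), bandwidth)
  v <- mean(rbf_kernel(a, a, h)) + mean(rbf_kernel(b, b, h)) -
    2 * mean(rbf_kernel(a, b, h))
  max(v, 0)
}

#' Pairwise MMD matrix over domain labels
#'
#' @param table Feature table (standardized internally unless
#'   `standardize = FALSE`).
#' @param label_col Name of the categorical domain-label column.
#' @param bandwidth Passed to [mmd_distance()]; the median heuristic is
#'   resolved per pair on the pooled pair sample.
#' @param standardize Standardize the features first (default TRUE).
#' @return Symmetric matrix of squared MMD with zero diagonal, labelled by
#'   domain.
#' @export
pairwise_mmd <- function(table, label_col, bandwidth = "median-heuristic",
                         standardize = TRUE) {
  lab <- domain_labels(table, label_col)
  if (standardize) table <- standardize_features(table)
  X <- as.matrix(table[, FEATURE_NAMES])
  doms <- levels(lab)
  M <- matrix(0, length(doms), length(doms), dimnames = list(doms, doms))
  for (i in seq_along(doms)) for (j in seq_along(doms)) {
    if (j <= i) next
    v <- mmd_distance(X[lab == doms[i], , drop = FALSE],
                      X[lab == doms[j], , drop = FALSE], bandwidth)
    M[i, j] <- M[j, i] <- v
  }
  M
}

domain_labels <- function(table, label_col) {
  if (!label_col %in% names(table))
    stop("no such label column: ", label_col)
  lab <- table[[label_col]]
  if (anyNA(lab) || any(!nzchar(as.character(lab))))
    stop("label column '", label_col, "' has empty entries")
  factor(lab)
}

# Seeded stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(lab, folds, seed) {
  assign <- integer(length(lab))
  with_seed(seed, {
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      if (length(idx) < folds)
        stop("class '", cl, "' has ", length(idx),
             " members, fewer than the ", folds, " folds")
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Cross-validated domain-classification accuracy
#'
#' Mean accuracy of a stratified k-fold cross-validation (default 5 folds)
#' of a domain discriminator on the standardized features: either a linear
#' SVM (cost 1) or a random forest with 500 trees.  High accuracy means the
#' domains are easily told apart, i.e. strong domain shift.
#'
#' @param table Feature table.
#' @param label_col Domain-label column name.
#' @param classifier `"svm_linear"` or `"random_forest"`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment and the forest.
#' @param standardize Standardize features first (default TRUE).
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
domain_classification <- function(table, label_col,
                                  classifier = c("svm_linear",
                                                 "random_forest"),
                                  folds = 5L, seed = 1L,
                                  standardize = TRUE) {
  classifier <- match.arg(classifier)
  lab <- domain_labels(table, label_col)
  if (nlevels(lab) < 2L) stop("need at least 2 domain classes, got 1")
  if (standardize) table <- standardize_features(table)
  X <- as.matrix(table[, FEATURE_NAMES])
  fold_of <- stratified_folds(lab, folds, derive_seed(seed, "folds"))
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold_of != k; te <- !tr
    pred <- with_seed(derive_seed(seed, "fit", k), {
      if (classifier == "svm_linear") {
        fit <- e1071::svm(X[tr, , drop = FALSE], droplevels(lab[tr]),
                          kernel = "linear", cost = 1, scale = FALSE)
        as.character(stats::predict(fit, X[te, , drop = FALSE]))
      } else {
        fit <- randomForest::randomForest(X[tr, , drop = FALSE],
                                          droplevels(lab[tr]), ntree = 500)
        as.character(stats::predict(fit, X[te, , drop = FALSE]))
      }
    })
    mean(pred == as.character(lab[te]))
  }, numeric(1))
  mean(acc)
}

#' Random-forest feature-importance ranking
#'
#' Fits one seeded random forest (500 trees) on the full standardized table
#' and returns the 22 features ranked by impurity (Gini) importance,
#' normalized to sum 1.
#'
#' @inheritParams domain_classification
#' @return Data frame with columns `feature` and `importance`, sorted
#'   decreasing.
#' @export
feature_importance <- function(table, label_col, seed = 1L,
                               standardize = TRUE) {
  lab <- domain_labels(table, label_col)
  if (nlevels(lab) < 2L) stop("need at least 2 domain classes, got 1")
  if (standardize) table <- standardize_features(table)
  X <- as.matrix(table[, FEATURE_NAMES])
  fit <- with_seed(derive_seed(seed, "importance"),
                   randomForest::randomForest(X, lab, ntree = 500))
  imp <- randomForest::importance(fit, type = 2)[, 1]
  imp <- imp[FEATURE_NAMES]
  tot <- sum(imp)
  score <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  out <- data.frame(feature = FEATURE_NAMES, importance = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' 2-D embedding of a feature table
#'
#' t-SNE (perplexity 30) or UMAP (15 neighbours, min_dist 0.1) on the
#' standardized features, seeded for determinism.  For small samples the
#' t-SNE perplexity is reduced to `(n - 1) / 3` and the UMAP neighbour count
#' to `n - 1`, with a message.
#'
#' @inheritParams domain_classification
#' @param method `"tsne"` or `"umap"`.
#' @return n x 2 matrix of coordinates with the method recorded in attribute
#'   `method` and rownames set to `scan_id`.
#' @export
embed_2d <- function(table, method = c("tsne", "umap"), seed = 1L,
                     standardize = TRUE) {
  method <- match.arg(method)
  n <- nrow(table)
  if (n < 5L) stop("embedding needs at least 5 scans, got ", n)
  if (standardize) table <- standardize_features(table)
  X <- as.matrix(table[, FEATURE_NAMES])
  coords <- if (method == "tsne") {
    perp <- 30
    if (n - 1 < 3 * perp) {
      perp <- floor((n - 1) / 3)
      message("t-SNE perplexity reduced to ", perp, " for n = ", n)
    }
    with_seed(derive_seed(seed, "tsne"),
              Rtsne::Rtsne(X, dims = 2, perplexity = perp,
                           check_duplicates = FALSE)$Y)
  } else {
    nb <- 15L
    if (n <= nb) {
      nb <- n - 1L
      message("UMAP n_neighbors reduced to ", nb, " for n = ", n)
    }
    with_seed(derive_seed(seed, "umap"),
              uwot::umap(X, n_components = 2, n_neighbors = nb,
                         min_dist = 0.1, metric = "euclidean",
                         n_threads = 1, n_sgd_threads = 1))
  }
  coords <- as.matrix(coords)
  dimnames(coords) <- list(table$scan_id, c("dim1", "dim2"))
  attr(coords, "method") <- method
  coords
}

#' Quantify domain shift in a feature table
#'
#' The package's main analysis entry point.  Standardizes the feature table
#' once, then computes the pairwise squared-MMD matrix over domains,
#' cross-validated domain-classification accuracies (linear SVM and
#' 500-tree random forest), the random-forest importance ranking of the 22
#' features, and seeded 2-D embeddings.
#'
#' @param table Feature table from [extract_features()] (or
#'   [read_feature_table()]) including the label column.
#' @param label_col Domain-label column name (e.g. site or manufacturer).
#' @param classifiers Subset of `c("svm_linear", "random_forest")`.
#' @param embed_methods Subset of `c("tsne", "umap")`; `NULL` to skip.
#' @param folds Cross-validation folds (default 5).
#' @param bandwidth MMD kernel bandwidth (default median heuristic).
#' @param seed Integer seed covering folds, forests and embeddings.
#' @return Object of class `shift_report`: list with elements `mmd`
#'   (pairwise matrix), `accuracy` (named vector), `importance` (ranked data
#'   frame), `embedding` (named list of coordinate matrices), `labels`,
#'   `label_col`, `n`, `seed`, `call`.
#' @seealso [print.shift_report()], [summary.shift_report()],
#'   [plot.shift_report()]
#' @export
domain_shift <- function(table, label_col,
                         classifiers = c("svm_linear", "random_forest"),
                         embed_methods = c("tsne", "umap"),
                         folds = 5L, bandwidth = "median-heuristic",
                         seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  lab <- domain_labels(table, label_col)
  std <- standardize_features(table)
  acc <- vapply(classifiers, function(cl)
    domain_classification(std, label_col, cl, folds = folds, seed = seed,
                          standardize = FALSE), numeric(1))
  emb <- list()
  for (m in (embed_methods %||% character(0)))
    emb[[m]] <- embed_2d(std, m, seed = seed, standardize = FALSE)
  structure(list(
    mmd = pairwise_mmd(std, label_col, bandwidth, standardize = FALSE),
    accuracy = acc,
    importance = feature_importance(std, label_col, seed = seed,
                                    standardize = FALSE),
    embedding = emb,
    labels = lab,
    label_col = label_col,
    n = nrow(table),
    seed = seed,
    call = match.call()
  ), class = "shift_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print shift_report
#' @export
print.shift_report <- function(x, ...) {
  cat("Domain-shift report (", x$n, " scans, label: ", x$label_col, ")\n",
      sep = "")
  cat("\nPairwise squared MMD:\n")
  print(round(x$mmd, 4))
  cat("\n5-fold domain-classification accuracy:\n")
  print(round(x$accuracy, 3))
  cat("\nTop 5 features by RF importance:\n")
  top <- utils::head(x$importance, 5)
  cat(paste(sprintf("  %-14s %.3f", top$feature, top$importance),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Summarize a shift report
#'
#' @param object A `shift_report`.
#' @param ... Unused.
#' @return The report with a compact overview printed.
#' @method summary shift_report
#' @export
summary.shift_report <- function(object, ...) {
  print(object)
  cat("\nScans per domain:\n")
  print(table(object$labels))
  if (length(object$embedding))
    cat("\nEmbeddings computed:",
        paste(names(object$embedding), collapse = ", "), "\n")
  invisible(object)
}

#' Plot the 2-D embedding of a shift report
#'
#' Scatter plot of the chosen embedding, coloured by domain label.
#'
#' @param x A `shift_report`.
#' @param method Which embedding to plot (default: first available).
#' @param ... Passed on to [graphics::plot()].
#' @method plot shift_report
#' @export
plot.shift_report <- function(x, method = names(x$embedding)[1], ...) {
  if (length(x$embedding) == 0L) stop("report holds no embedding")
  co <- x$embedding[[method]]
  cols <- as.integer(x$labels)
  graphics::plot(co[, 1], co[, 2], col = cols, pch = 19,
                 xlab = "dim 1", ylab = "dim 2",
                 main = paste0(toupper(method), " embedding by ",
                               x$label_col), ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = seq_len(nlevels(x$labels)), pch = 19, cex = 0.8)
  invisible(x)
}
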