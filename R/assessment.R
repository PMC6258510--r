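## Classifier-assessment protocol: repeated class-stratified 80/20 splits
## of the marker set, macro and per-class F1 on hard assignments, and the
## quadratic loss on probabilistic assignments. Baselines: a probabilistic
## K-nearest-neighbour classifier with Laplace smoothing and (optionally) a
## weighted SVM consumed from e1071.

#' Class-stratified train/test split of the marker set
#'
#' Per class, a seeded shuffle puts `floor(train_fraction * n_c)` markers in
#' the training partition and the remainder in the test partition.
#'
#' @param markers A [marker_annotation()]; every class needs at least two
#'   markers.
#' @param train_fraction Fraction in `(0, 1)` assigned to training
#'   (default 0.8).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list of class `split_spec` with disjoint `train_ids` and
#'   `test_ids` whose union is the marker set.
#' @export
stratified_split <- function(markers, train_fraction = 0.8, seed = NULL) {
  stopifnot(inherits(markers, "marker_annotation"),
            train_fraction > 0, train_fraction < 1)
  cnt <- table(factor(markers$labels, levels = markers$classes))
  small <- names(cnt)[cnt < 2L]
  if (length(small))
    stop("cannot stratify classes with fewer than two markers: ",
         paste(small, collapse = ", "))
  with_seed(seed, {
    train <- character(0)
    for (cl in markers$classes) {
      ids <- names(markers$labels)[markers$labels == cl]
      ids <- ids[sample.int(length(ids))]
      n_tr <- floor(train_fraction * length(ids))
      train <- c(train, ids[seq_len(n_tr)])
    }
    structure(list(train_ids = train,
                   test_ids = setdiff(names(markers$labels), train),
                   seed = seed),
              class = "split_spec")
  })
}

#' Macro and per-class F1 scores
#'
#' Per class, precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and their
#' harmonic mean; a class with a zero denominator (`2 tp + fp + fn = 0`)
#' contributes F1 = 0. The macro F1 is the unweighted mean across classes.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param classes Optional class catalogue; defaults to the classes present
#'   in `true_labels`.
#' @return A list with `macro_f1` and the named vector `per_class`.
#' @export
f1_scores <- function(true_labels, predicted_labels, classes = NULL) {
  if (!length(true_labels)) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(classes)) classes <- unique(true_labels)
  per <- vapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
  list(macro_f1 = mean(per), per_class = per)
}

#' Quadratic loss of probabilistic assignments
#'
#' `Q2 = sum_i || q_i - p_i ||^2` over proteins, where `q_i` is the one-hot
#' truth and `p_i` the predicted class-probability vector — a sum, not a
#' mean, so the loss grows with the test-set size. Rewards calibrated, not
#' merely correct, assignments.
#'
#' @param true_onehot `N x C` one-hot truth matrix.
#' @param predicted_prob `N x C` matrix of predicted probabilities with
#'   rows summing to 1.
#' @return Scalar loss (at most `2 N`).
#' @export
quadratic_loss <- function(true_onehot, predicted_prob) {
  q <- as.matrix(true_onehot); p <- as.matrix(predicted_prob)
  if (!all(dim(q) == dim(p))) stop("shape mismatch between truth and prediction")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("predicted probability rows must sum to 1")
  if (any(rowSums(q == 1) != 1L) || any(q != 0 & q != 1))
    stop("`true_onehot` rows must be one-hot")
  sum((q - p)^2)
}

## one-hot encode labels over a class catalogue
onehot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(names(labels), classes))
  m[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  m
}

## neighbour class counts among the k nearest training profiles
knn_counts <- function(train_x, train_labels, test_x, k, classes) {
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  t(apply(d2, 1L, function(row) {
    nb <- order(row)[seq_len(k)]
    tabulate(match(train_labels[nb], classes), length(classes))
  }))
}

#' Probabilistic K-nearest-neighbour classifier with Laplace smoothing
#'
#' Interprets the proportion of neighbours per class as a posterior
#' probability, smoothed with pseudo-counts proportional to the training
#' incidence of each class:
#' `p(z = k | x) = (N_k + alpha * d_k * C) / (K + alpha * C)`,
#' where `N_k` counts neighbours of class `k` among the `K` nearest,
#' `C` is the number of classes and `d_k` the class incidence. The
#' neighbourhood size is selected by stratified 5-fold cross-validation on
#' the training set over `k_grid` (smallest k wins ties).
#'
#' @param train_x,train_labels Training profiles and labels.
#' @param test_x Test profiles.
#' @param alpha Nonnegative smoothing pseudo-count (default 0.5, a
#'   Jeffreys-type prior).
#' @param k_grid Candidate neighbourhood sizes.
#' @param classes Optional class catalogue.
#' @param cv_seed Seed for the internal cross-validation folds.
#' @return An `N_test x C` probability matrix with rows summing to 1; the
#'   selected `k` is attached as attribute `"k"`.
#' @export
knn_probabilistic <- function(train_x, train_labels, test_x, alpha = 0.5,
                              k_grid = c(3, 5, 7, 9, 11, 13, 15),
                              classes = NULL, cv_seed = NULL) {
  stopifnot(alpha >= 0)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_labels <- as.character(train_labels)
  if (is.null(classes)) classes <- unique(train_labels)
  C <- length(classes)
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid >= 1L]
  if (any(k_grid > nrow(train_x)))
    stop("neighbourhood size exceeds the training-set size")
  k <- k_grid[1L]
  if (length(k_grid) > 1L) {
    folds <- with_seed(cv_seed, make_folds(train_labels, 5L))
    acc <- vapply(k_grid, function(kk) {
      hits <- 0L
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        if (kk > sum(tr)) return(-Inf)
        cnts <- knn_counts(train_x[tr, , drop = FALSE], train_labels[tr],
                           train_x[!tr, , drop = FALSE], kk, classes)
        pred <- classes[max.col(cnts, ties.method = "first")]
        hits <- hits + sum(pred == train_labels[!tr])
      }
      hits / length(train_labels)
    }, numeric(1))
    k <- k_grid[which.max(acc)]
  }
  cnts <- knn_counts(train_x, train_labels, test_x, k, classes)
  d <- as.numeric(table(factor(train_labels, levels = classes))) /
    length(train_labels)
  p <- sweep(cnts, 2L, alpha * d * C, "+") / (k + alpha * C)
  dimnames(p) <- list(rownames(test_x), classes)
  attr(p, "k") <- k
  p
}

## stratified fold assignment
make_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

## SVM baseline consumed from e1071; NULL when unavailable
svm_probabilistic <- function(train_x, train_labels, test_x, classes,
                              cv_seed = NULL) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    warning("e1071 not available; SVM method skipped")
    return(NULL)
  }
  y <- factor(train_labels, levels = classes)
  fit <- with_seed(cv_seed, {
    tuned <- e1071::tune.svm(train_x, y, gamma = 2^(-4:1) / ncol(train_x),
                             cost = c(0.5, 1, 4, 16),
                             tunecontrol = e1071::tune.control(cross = 5))
    e1071::svm(train_x, y, gamma = tuned$best.parameters$gamma,
               cost = tuned$best.parameters$cost, probability = TRUE)
  })
  pr <- attr(stats::predict(fit, test_x, probability = TRUE), "probabilities")
  pr[, classes, drop = FALSE]
}

#' Repeated stratified assessment of localisation classifiers
#'
#' Runs `rounds` class-stratified 80/20 splits of the marker set. In each
#' round every method is trained on the training markers and predicts class
#' probabilities for the withheld test markers; the macro F1 of the hard
#' (argmax) assignments and the quadratic loss of the probability vectors
#' are recorded. The TAGM methods are fitted on the marker subset of the
#' quantitation matrix, with test markers treated as unlabelled proteins.
#'
#' @param X Quantitation matrix.
#' @param markers A [marker_annotation()].
#' @param methods Subset of `c("tagm_map", "tagm_mcmc", "knn", "svm")`.
#' @param rounds Number of resampling rounds.
#' @param seed Integer seed driving every round.
#' @param train_fraction Training fraction per class (default 0.8).
#' @param map_control List of arguments (`tol`, `max_iter`) for
#'   [fit_tagm_map()].
#' @param mcmc_control An [mcmc_settings()] for the (scaled-down) MCMC runs.
#' @param knn_alpha,knn_grid Smoothing and neighbourhood grid for the KNN
#'   baseline.
#' @return A data frame with one row per round and method: `round`,
#'   `method`, `macro_f1`, `quadratic_loss`. Per-class F1 vectors are
#'   attached as attribute `"per_class_f1"`. Failed method/rounds are
#'   recorded with `NA`.
#' @export
crossval_compare <- function(X, markers,
                             methods = c("tagm_map", "knn"),
                             rounds = 10L, seed = 1L,
                             train_fraction = 0.8,
                             map_control = list(tol = 1e-6, max_iter = 100L),
                             mcmc_control = mcmc_settings(n_chains = 1L,
                                                          n_iter = 400L,
                                                          burn_in = 100L,
                                                          thin = 3L),
                             knn_alpha = 0.5,
                             knn_grid = c(3, 5, 7, 9, 11)) {
  stopifnot(rounds >= 1L)
  methods <- match.arg(methods, c("tagm_map", "tagm_mcmc", "knn", "svm"),
                       several.ok = TRUE)
  X <- quantitation_matrix(X)
  check_markers(X, markers)
  classes <- markers$classes
  Xm <- X[names(markers$labels), , drop = FALSE]
  round_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            3L * rounds))
  out <- list(); percls <- list()
  for (r in seq_len(rounds)) {
    sp <- stratified_split(markers, train_fraction, seed = round_seeds[r])
    truth <- markers$labels[sp$test_ids]
    q <- onehot(truth, classes)
    train_mk <- marker_annotation(markers$labels[sp$train_ids],
                                  classes = classes)
    for (m in methods) {
      prob <- tryCatch(switch(m,
        tagm_map = {
          ctl <- map_control
          fit <- fit_tagm_map(Xm, train_mk, tol = ctl$tol,
                              max_iter = ctl$max_iter)
          ## p(z = k | x) = a_ik + b_ik, where the outlier-route mass
          ## factorises as outlier_prob * pi_k
          w <- fit$localisation + outer(fit$outlier_prob, fit$params$weights)
          w[sp$test_ids, , drop = FALSE]
        },
        tagm_mcmc = {
          st <- mcmc_control
          st$seed <- round_seeds[rounds + r]
          ch <- run_tagm_chains(Xm, train_mk, settings = st)
          su <- summarize_posterior(pool_chains(ch))
          renorm_rows(su$mean_localisation)[sp$test_ids, , drop = FALSE]
        },
        knn = knn_probabilistic(Xm[sp$train_ids, , drop = FALSE],
                                markers$labels[sp$train_ids],
                                Xm[sp$test_ids, , drop = FALSE],
                                alpha = knn_alpha, k_grid = knn_grid,
                                classes = classes,
                                cv_seed = round_seeds[2L * rounds + r]),
        svm = svm_probabilistic(Xm[sp$train_ids, , drop = FALSE],
                                markers$labels[sp$train_ids],
                                Xm[sp$test_ids, , drop = FALSE], classes,
                                cv_seed = round_seeds[2L * rounds + r])),
        error = function(e) {
          warning("method ", m, " failed in round ", r, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(prob)) {
        out[[length(out) + 1L]] <- data.frame(round = r, method = m,
                                              macro_f1 = NA_real_,
                                              quadratic_loss = NA_real_)
        next
      }
      pred <- classes[max.col(prob, ties.method = "first")]
      f1 <- f1_scores(truth, pred, classes = classes)
      out[[length(out) + 1L]] <- data.frame(
        round = r, method = m, macro_f1 = f1$macro_f1,
        quadratic_loss = quadratic_loss(q, prob / rowSums(prob)))
      percls[[paste(m, r, sep = "_")]] <- f1$per_class
    }
  }
  res <- do.call(rbind, out)
  attr(res, "per_class_f1") <- percls
  res
}

## spread residual probability mass proportionally across classes so rows
## sum to one (used when conditioning probabilistic output on the K classes)
renorm_rows <- function(p) {
  s <- rowSums(p)
  s[s == 0] <- 1
  p / s
}

#' Pairwise significance tests between classifiers
#'
#' Two-sided pairwise t-tests on a per-round metric from
#' [crossval_compare()], with Benjamini-Hochberg correction.
#'
#' @param results Data frame from [crossval_compare()].
#' @param metric `"macro_f1"` or `"quadratic_loss"`.
#' @return A data frame of method pairs with raw and adjusted p-values.
#' @export
compare_classifier_scores <- function(results, metric = "macro_f1") {
  stopifnot(metric %in% c("macro_f1", "quadratic_loss"))
  methods <- unique(results$method)
  if (length(methods) < 2L) stop("need at least two methods to compare")
  pairs <- utils::combn(methods, 2L)
  pv <- apply(pairs, 2L, function(pr) {
    a <- results[results$method == pr[1L], metric]
    b <- results[results$method == pr[2L], metric]
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  })
  data.frame(method_a = pairs[1L, ], method_b = pairs[2L, ],
             p_value = pv, p_adjusted = p.adjust(pv, "BH"))
}

#' Cross-classifier contingency table
#'
#' Entry `(j, k)` is the proportion of the common proteins labelled `j` by
#' classifier `a` that are labelled `k` by classifier `b`; rows sum to 1.
#' Diagonal mass indicates agreement.
#'
#' @param labels_a,labels_b Named label vectors (names are protein IDs);
#'   only the intersection of the names is tabulated.
#' @param restrict Optional character vector of protein IDs to restrict to
#'   (e.g. proteins above a probability threshold for classifier `a`).
#' @return A row-proportion matrix.
#' @export
contingency_table <- function(labels_a, labels_b, restrict = NULL) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("label vectors must be named by protein ID")
  common <- intersect(names(labels_a), names(labels_b))
  if (!is.null(restrict)) common <- intersect(common, restrict)
  if (!length(common)) stop("no common proteins after restriction")
  a <- as.character(labels_a[common]); b <- as.character(labels_b[common])
  tab <- table(a, b)
  prop <- tab / rowSums(tab)
  dn <- dimnames(tab)
  names(dn) <- NULL
  matrix(prop, nrow(tab), ncol(tab), dimnames = dn)
}
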