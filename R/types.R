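## Core data containers: quantitation matrix, marker annotation, prior
## hyperparameters and mixture component parameters. Plain matrices and
## lightweight S3 lists keep the package free of heavyweight dependencies
## while mirroring the shape of LOPIT/hyperLOPIT data.

#' Validate and construct a protein quantitation matrix
#'
#' A quantitation matrix holds `N` protein profiles over `D` fractions of a
#' density-gradient experiment. Row names are protein identifiers (the
#' canonical protein index used by every downstream structure) and column
#' names are fraction identifiers.
#'
#' @param values Numeric `N x D` matrix, or a data frame coercible to one.
#' @param protein_ids Optional character vector of unique protein IDs;
#'   defaults to `rownames(values)`.
#' @param fraction_ids Optional character vector of fraction names; defaults
#'   to `colnames(values)`.
#' @return A numeric matrix with validated dim names.
#' @export
quantitation_matrix <- function(values, protein_ids = NULL, fraction_ids = NULL) {
  X <- as.matrix(values)
  storage.mode(X) <- "double"
  if (!is.null(protein_ids)) rownames(X) <- protein_ids
  if (!is.null(fraction_ids)) colnames(X) <- fraction_ids
  if (nrow(X) < 1L || ncol(X) < 1L) stop("quantitation matrix must be at least 1 x 1")
  if (is.null(rownames(X))) stop("protein identifiers (row names) are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("fraction_", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X)))
    stop("duplicate protein identifiers: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (anyNA(X) || any(!is.finite(X))) stop("quantitation matrix contains missing or non-finite values")
  X
}

#' Marker annotation
#'
#' Curated assignment of a subset of proteins (the markers) to sub-cellular
#' classes. Markers are the labelled set; everything else in the
#' quantitation matrix is unlabelled and will be assigned probabilistically.
#'
#' @param labels Named character vector mapping protein ID to class name, or
#'   a two-column data frame (protein ID, class).
#' @param classes Optional ordered class catalogue; defaults to
#'   first-appearance order of `labels`.
#' @return An object of class `marker_annotation` with elements `labels`
#'   (named character vector) and `classes`.
#' @export
marker_annotation <- function(labels, classes = NULL) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop("marker table needs two columns: protein ID, class")
    labels <- setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
  }
  labels <- unlist(labels)
  if (length(labels) && is.null(names(labels))) stop("marker labels must be named by protein ID")
  labels <- setNames(as.character(labels), names(labels))
  if (anyDuplicated(names(labels)))
    stop("duplicate marker protein IDs: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  if (any(!nzchar(labels))) stop("empty class name in marker annotation")
  if (is.null(classes)) classes <- unique(unname(labels))
  classes <- as.character(classes)
  if (length(classes) < 1L) stop("at least one class is required")
  if (anyDuplicated(classes)) stop("duplicate class names")
  if (!all(labels %in% classes))
    stop("marker labels outside the class catalogue: ",
         paste(setdiff(labels, classes), collapse = ", "))
  structure(list(labels = labels, classes = classes),
            class = "marker_annotation")
}

#' @export
print.marker_annotation <- function(x, ...) {
  cat("Marker annotation:", length(x$labels), "markers in",
      length(x$classes), "classes\n")
  print(table(factor(x$labels, levels = x$classes)))
  invisible(x)
}

## check markers against a quantitation matrix; returns integer row indices
## of the markers in X
check_markers <- function(X, markers) {
  stopifnot(inherits(markers, "marker_annotation"))
  miss <- setdiff(names(markers$labels), rownames(X))
  if (length(miss))
    stop("marker proteins absent from the quantitation matrix: ",
         paste(miss, collapse = ", "))
  match(names(markers$labels), rownames(X))
}

#' Prior hyperparameters for the TAGM model
#'
#' Bundles every fixed prior quantity: the Dirichlet concentration `beta` on
#' mixture weights, the normal-inverse-Wishart parameters (`mu0`, `lambda0`,
#' `nu0`, `S0`) shared by all niche components, the Beta shapes (`u`, `v`)
#' on the prior outlier probability, and the Student-t outlier parameters
#' (`kappa` degrees of freedom, location `M`, scale `V`).
#'
#' @param beta Numeric vector of `K` positive Dirichlet concentrations.
#' @param mu0 Prior mean vector (length `D`).
#' @param lambda0 Positive prior shrinkage.
#' @param nu0 Prior degrees of freedom, `> D - 1`.
#' @param S0 Positive-definite `D x D` prior scale matrix.
#' @param u,v Positive Beta shape parameters for the outlier weight.
#' @param kappa Positive degrees of freedom of the outlier t component.
#' @param M Outlier location vector (length `D`).
#' @param V Positive-definite `D x D` outlier scale matrix.
#' @return An object of class `tagm_hyper`.
#' @seealso [default_hyperparameters()] for data-driven defaults.
#' @export
hyperparameters <- function(beta, mu0, lambda0, nu0, S0, u, v, kappa, M, V) {
  h <- structure(list(beta = as.numeric(beta), mu0 = as.numeric(mu0),
                      lambda0 = lambda0, nu0 = nu0, S0 = as.matrix(S0),
                      u = u, v = v, kappa = kappa, M = as.numeric(M),
                      V = as.matrix(V)),
                 class = "tagm_hyper")
  validate_hyper(h)
}

validate_hyper <- function(h) {
  D <- length(h$mu0)
  stopifnot(length(h$M) == D, all(dim(h$S0) == D), all(dim(h$V) == D))
  if (any(h$beta <= 0)) stop("Dirichlet concentrations beta must be positive")
  for (nm in c("lambda0", "u", "v", "kappa"))
    if (!is.numeric(h[[nm]]) || length(h[[nm]]) != 1L || h[[nm]] <= 0)
      stop("`", nm, "` must be a positive scalar")
  if (h$nu0 <= D - 1) stop("`nu0` must exceed D - 1")
  if (h$nu0 - D + 1 <= 0) stop("prior predictive degrees of freedom nu0 - D + 1 must be positive")
  chol_pd(h$S0, "prior scale S0")
  chol_pd(h$V, "outlier scale V")
  h
}

#' @export
print.tagm_hyper <- function(x, ...) {
  cat("TAGM hyperparameters: K =", length(x$beta), ", D =", length(x$mu0), "\n")
  cat("  kappa =", x$kappa, "; lambda0 =", x$lambda0, "; nu0 =", x$nu0,
      "; Beta(u, v) = (", x$u, ",", x$v, ")\n")
  invisible(x)
}

#' Data-driven default hyperparameters
#'
#' Default priors following the model's stated conventions: the outlier
#' t component has `kappa = 4` degrees of freedom, location `M` equal to the
#' global per-fraction mean over all proteins (labelled and unlabelled) and
#' scale `V` equal to half the global empirical covariance, giving a flat,
#' heavy-tailed component relative to the annotated niches. The NIW prior is
#' centred on the global mean with weak shrinkage (`lambda0 = 0.01`), the
#' smallest degrees of freedom yielding a finite inverse-Wishart mean
#' (`nu0 = D + 2`) and scale `S0` equal to the global covariance divided by
#' `K^(2/D)` so prior component volumes scale with the number of niches. The
#' Dirichlet concentration is flat (`beta = 1`) and the Beta prior on the
#' outlier weight (`u = 2`, `v = 10`) weakly favours a minority outlier
#' fraction.
#'
#' @param X Quantitation matrix (see [quantitation_matrix()]).
#' @param markers A [marker_annotation()] providing the class catalogue.
#' @param ... Named overrides for any [hyperparameters()] field.
#' @return A validated `tagm_hyper` object. Deterministic: identical inputs
#'   give identical output.
#' @export
default_hyperparameters <- function(X, markers, ...) {
  X <- quantitation_matrix(X)
  check_markers(X, markers)
  N <- nrow(X); D <- ncol(X); K <- length(markers$classes)
  if (N < 2L) stop("degenerate data: need at least two proteins to form a covariance")
  gmean <- unname(colMeans(X))
  gcov <- unname(cov(X))             # (n - 1) convention
  if (all(abs(gcov) < .Machine$double.eps * 100))
    stop("degenerate data: all protein profiles are identical")
  V <- gcov / 2
  if (is.null(tryCatch(chol(V), error = function(e) NULL))) {
    ridge <- 1e-6 * sum(diag(gcov)) / D
    V <- V + diag(ridge, D)
    gcov <- gcov + diag(ridge, D)
  }
  defaults <- list(beta = rep(1, K), mu0 = gmean, lambda0 = 0.01,
                   nu0 = D + 2, S0 = gcov / K^(2 / D), u = 2, v = 10,
                   kappa = 4, M = gmean, V = V)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown hyperparameter override: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(hyperparameters, defaults)
}

#' Mixture component parameters
#'
#' @param means `K x D` matrix of component means.
#' @param covariances List of `K` positive-definite `D x D` covariance
#'   matrices.
#' @param weights Mixture weights on the `K`-simplex.
#' @param epsilon Prior outlier probability in `[0, 1]`.
#' @return An object of class `tagm_params`.
#' @export
component_params <- function(means, covariances, weights, epsilon) {
  means <- as.matrix(means)
  K <- nrow(means)
  stopifnot(length(covariances) == K, length(weights) == K)
  if (abs(sum(weights) - 1) > 1e-10) stop("mixture weights must sum to 1")
  if (any(weights < -1e-12)) stop("negative mixture weight")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  for (k in seq_len(K)) chol_pd(covariances[[k]])
  structure(list(means = means, covariances = covariances,
                 weights = as.numeric(weights), epsilon = epsilon),
            class = "tagm_params")
}
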