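## Delimited-text I/O for quantitation matrices, marker tables and result
## tables, plus a flat key-value run manifest so any run can be
## reconstructed from its output directory alone.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read a quantitation matrix from delimited text
#'
#' Expects a header row of fraction names and a first column of protein
#' IDs; the delimiter (tab or comma) is auto-detected. UTF-8, dot decimal
#' separator.
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated quantitation matrix.
#' @export
read_quantitation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric value in ", path, ", column '", names(vals)[j],
           "', line ", bad + 1L)
    }
    vals[[j]] <- v
  }
  quantitation_matrix(as.matrix(vals), protein_ids = ids,
                      fraction_ids = names(vals))
}

#' Read a marker annotation from delimited text
#'
#' Two columns (protein ID, class); a header row is auto-detected by
#' checking whether the first field is a known protein ID. The class
#' catalogue is the first-appearance order of the class column.
#'
#' @param path Path to a two-column TSV/CSV file.
#' @param X Quantitation matrix used to validate protein IDs.
#' @return A validated [marker_annotation()].
#' @export
read_markers <- function(path, X) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- read.table(path, header = FALSE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("marker file needs two columns: protein ID, class")
  if (nrow(df) > 0L && !(as.character(df[1L, 1L]) %in% rownames(X)))
    df <- df[-1L, , drop = FALSE]           # header row
  mk <- marker_annotation(setNames(as.character(df[[2L]]),
                                   as.character(df[[1L]])))
  miss <- setdiff(names(mk$labels), rownames(X))
  if (length(miss))
    stop("marker protein(s) absent from the quantitation matrix: ",
         paste(miss, collapse = ", "))
  mk
}

#' Write a quantitation matrix or marker annotation to TSV
#'
#' @param x A quantitation matrix or [marker_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantitation <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quantitation
#' @export
write_markers <- function(x, path) {
  stopifnot(inherits(x, "marker_annotation"))
  df <- data.frame(protein_id = names(x$labels), class = unname(x$labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) signif(x, 6)

#' Write result tables and a run manifest
#'
#' For a MAP fit: one row per protein with the per-class localisation
#' probabilities (class-catalogue order), the outlier probability, the
#' classification at `threshold` and the winning probability. For an MCMC
#' summary: additionally the per-class 95% equi-tailed interval bounds and
#' the Monte-Carlo averaged Shannon entropy. A flat key-value
#' `manifest.txt` (seed, settings, package version, diagnostics when
#' supplied) is written alongside. Probabilities carry 6 significant
#' digits.
#'
#' @param result A `tagm_map` fit or `tagm_summary`.
#' @param out_dir Output directory (created if absent).
#' @param threshold Classification threshold (default 0.95).
#' @param manifest Named list of extra key-value pairs (e.g. seed,
#'   Gelman-Rubin statistic) to record.
#' @return Path of the results table, invisibly.
#' @export
write_tagm_results <- function(result, out_dir, threshold = 0.95,
                               manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  cls <- tagm_classify(result, threshold = threshold)
  if (inherits(result, "tagm_map")) {
    loc <- result$localisation
    df <- data.frame(protein_id = rownames(loc), fmt6(loc),
                     outlier_prob = fmt6(result$outlier_prob),
                     classification = as.character(cls),
                     max_probability = fmt6(apply(
                       cbind(loc, result$outlier_prob), 1L, max)),
                     check.names = FALSE)
    kind <- "tagm-map"
  } else if (inherits(result, "tagm_summary")) {
    loc <- result$mean_localisation
    lw <- result$lower95; up <- result$upper95
    colnames(lw) <- paste0("lower95_", result$classes)
    colnames(up) <- paste0("upper95_", result$classes)
    df <- data.frame(protein_id = result$protein_ids, fmt6(loc),
                     outlier_prob = fmt6(result$outlier_prob),
                     shannon = fmt6(result$shannon),
                     fmt6(lw), fmt6(up),
                     classification = as.character(cls),
                     check.names = FALSE)
    kind <- "tagm-mcmc"
  } else stop("unsupported result type")
  out <- file.path(out_dir, paste0(kind, "-results.tsv"))
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)

  mf <- c(list(kind = kind, package = "tagmix",
               version = as.character(packageVersion("tagmix")),
               threshold = threshold,
               n_proteins = nrow(df),
               classes = paste(if (inherits(result, "tagm_map"))
                 result$classes else result$classes, collapse = ",")),
          manifest)
  lines <- paste0(names(mf), "=", vapply(mf, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out)
}
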