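#' Fit a PCA feature model
#'
#' Mean-centered (not variance-scaled: channels share units after \[0, 1\]
#' normalization) principal component analysis of a batch of preprocessed
#' spectra. For reproducible plots each component's largest-magnitude loading
#' is forced positive. When the scores feed a classifier, fit on the training
#' partition only; [predict.raman_pca()] then projects any batch.
#'
#' @param x Either a numeric matrix (spectra in rows) or a list of
#'   preprocessed [raman_spectrum()] objects on a common axis.
#' @param n_components Number of components to retain; clipped to the matrix
#'   rank with a warning when it exceeds it.
#' @return Object of class `raman_pca`: `mean` (channel means), `components`
#'   (channels x k matrix with orthonormal columns), `explained_variance`
#'   (non-increasing), `total_variance`, `n_components`.
#' @export
fit_pca <- function(x, n_components) {
  if (is.list(x) && !is.data.frame(x)) x <- spectra_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 spectra")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  max_k <- min(rank, nrow(x) - 1L, ncol(x))
  if (n_components > max_k) {
    warning("n_components = ", n_components, " exceeds the data rank; ",
            "clipped to ", max_k)
    n_components <- max_k
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(mean = pc$center,
                 components = rot,
                 explained_variance = pc$sdev[seq_len(n_components)]^2,
                 total_variance = sum(pc$sdev^2),
                 n_components = n_components),
            class = "raman_pca")
}

#' @export
print.raman_pca <- function(x, ...) {
  cum <- sum(x$explained_variance) / x$total_variance
  cat(sprintf("<raman_pca> %d components over %d channels (%.1f%% variance)\n",
              x$n_components, nrow(x$components), 100 * cum))
  invisible(x)
}

#' Project spectra on a fitted PCA model
#'
#' @param object A [fit_pca()] model.
#' @param newdata Matrix (spectra in rows) or list of spectra on the model's
#'   axis.
#' @param ... Unused.
#' @return Score matrix, one row per spectrum, `n_components` columns.
#' @export
predict.raman_pca <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- spectra_matrix(newdata)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean)) {
    stop("shape error: ", ncol(newdata), " channels but the model was fit on ",
         length(object$mean))
  }
  scores <- sweep(newdata, 2, object$mean) %*% object$components
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Reconstruct spectra from PCA scores
#'
#' @param model A [fit_pca()] model.
#' @param scores Score matrix from [predict.raman_pca()].
#' @return Matrix of reconstructed spectra (exact when the model keeps the
#'   full rank).
#' @export
inverse_pca <- function(model, scores) {
  sweep(scores %*% t(model$components), 2, model$mean, "+")
}

#' Per-group distribution summaries of leading components
#'
#' For each outcome group and each of the first `k` principal components,
#' histogram counts (shared break points across groups) and a Gaussian
#' kernel density estimate with Silverman's rule-of-thumb bandwidth --
#' the exploratory view in which well-separated groups show shifted score
#' distributions.
#'
#' @param model A [fit_pca()] model.
#' @param x Batch (matrix or list of spectra) to score.
#' @param labels Outcome label per spectrum (recycled from the spectra's own
#'   labels when `NULL` and `x` is a list of labeled spectra).
#' @param k Number of leading components to summarize (default 3).
#' @param bins Number of histogram bins (default 30).
#' @return Object of class `pc_summary`: list per component, each holding
#'   per-group `histogram` and `density`, plus the score matrix.
#' @export
summarize_components <- function(model, x, labels = NULL, k = 3, bins = 30) {
  if (is.null(labels)) {
    if (is.list(x) && !is.data.frame(x)) {
      labels <- vapply(x, function(s) s$label, character(1))
    } else stop("labels are required when x is a matrix")
  }
  scores <- predict(model, x)
  k <- min(k, ncol(scores))
  labels <- as.character(labels)
  groups <- unique(labels[!is.na(labels)])
  out <- vector("list", k)
  for (j in seq_len(k)) {
    v <- scores[, j]
    breaks <- seq(min(v), max(v), length.out = bins + 1)
    per_group <- lapply(groups, function(g) {
      vg <- v[labels == g & !is.na(labels)]
      list(histogram = graphics::hist(vg, breaks = breaks, plot = FALSE),
           density = stats::density(vg, bw = "nrd0"))
    })
    names(per_group) <- groups
    out[[j]] <- per_group
  }
  names(out) <- paste0("PC", seq_len(k))
  structure(list(components = out, scores = scores[, seq_len(k), drop = FALSE],
                 labels = labels), class = "pc_summary")
}

#' @export
plot.pc_summary <- function(x, ...) {
  k <- length(x$components)
  old <- graphics::par(mfrow = c(1, k)); on.exit(graphics::par(old))
  cols <- c(pregnancy = "#2166ac", non_pregnancy = "#b2182b")
  for (j in seq_len(k)) {
    dens <- lapply(x$components[[j]], `[[`, "density")
    xlim <- range(unlist(lapply(dens, `[[`, "x")))
    ylim <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = names(x$components)[j],
                   ylab = "Density", main = names(x$components)[j])
    for (g in names(dens)) graphics::lines(dens[[g]], col = cols[[g]], lwd = 2)
  }
  invisible(x)
}

#' Persist / restore a PCA model as JSON
#'
#' @param model A [fit_pca()] model.
#' @param path JSON file path.
#' @return `path` (save) or the restored `raman_pca` (load).
#' @export
save_pca <- function(model, path) {
  jsonlite::write_json(
    list(mean = model$mean, components = model$components,
         explained_variance = model$explained_variance,
         total_variance = model$total_variance,
         n_components = model$n_components),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pca
#' @export
load_pca <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- o$components
  if (!is.matrix(comp)) comp <- matrix(as.numeric(comp), nrow = length(o$mean))
  structure(list(mean = as.numeric(o$mean),
                 components = comp,
                 explained_variance = as.numeric(o$explained_variance),
                 total_variance = as.numeric(o$total_variance),
                 n_components = as.integer(o$n_components)),
            class = "raman_pca")
}
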