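# Canonical discriminant analysis of well-level feature vectors.  Canonical
# functions come from the between/within generalized eigenproblem on
# internally standardized features; wells are reclassified to the nearest
# group centroid in canonical space (resubstitution, with an optional
# leave-one-out mode), and group envelopes are chi-square confidence
# ellipses of the canonical scores.

default_features <- c("mfr", "nb_rate", "mean_nbd", "pct_outside", "cv_nibi")

as_feature_matrix <- function(data, features, labels) {
  if (is.data.frame(data)) {
    missing_cols <- setdiff(features, names(data))
    if (length(missing_cols)) {
      stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    x <- as.matrix(data[features])
  } else {
    x <- as.matrix(data)
    colnames(x) <- features
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix contains missing or non-finite values",
         call. = FALSE)
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("every group needs at least 2 rows", call. = FALSE)
  }
  list(x = x, labels = labels)
}

#' Fit canonical discriminant functions
#'
#' Features are standardized internally; the pooled within-group covariance
#' `W` receives a small ridge (`ridge * trace(W)` on the diagonal), and the
#' canonical coefficient vectors solve the between/within eigenproblem,
#' ordered by eigenvalue and scaled to unit pooled within-group variance.
#' The number of canonical functions is `min(groups - 1, features)`.
#'
#' @param data Data frame (or matrix) holding the feature columns.
#' @param labels Group label per row.
#' @param features Feature column names (default: mean firing rate, network
#'   burst rate, network burst duration, percent of spikes outside network
#'   bursts, CV of the inter-burst interval).
#' @param ridge Ridge factor relative to `trace(W)` (default 1e-8).
#' @param priors `"equal"` (default) or `"proportional"` group priors used at
#'   classification.
#' @return An object of class `discriminant_model`: canonical coefficients
#'   (on the standardized scale), feature centering/scaling, group centroids
#'   in canonical space, eigenvalues, priors and group levels.
#' @export
fit_discriminant <- function(data, labels, features = default_features,
                             ridge = 1e-8,
                             priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  fm <- as_feature_matrix(data, features, labels)
  x <- fm$x
  g <- fm$labels
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  if (any(scale_ == 0)) {
    stop("constant feature column; remove it before fitting", call. = FALSE)
  }
  z <- scale(x, center = center, scale = scale_)
  p <- ncol(z)
  n <- nrow(z)
  k <- nlevels(g)

  means <- rowsum(z, g) / as.vector(table(g))
  zc <- z - means[g, , drop = FALSE]
  W <- crossprod(zc) / (n - k)
  W <- W + diag(ridge * sum(diag(W)), p)
  ng <- as.vector(table(g))
  grand <- colMeans(z)
  md <- sweep(means, 2L, grand)
  B <- crossprod(md * sqrt(ng)) / (k - 1)

  ei <- eigen(solve(W, B))
  ord <- order(Re(ei$values), decreasing = TRUE)
  n_fun <- min(k - 1L, p)
  vec <- Re(ei$vectors[, ord[seq_len(n_fun)], drop = FALSE])
  # unit pooled within-group variance per canonical variate
  for (j in seq_len(n_fun)) {
    vec[, j] <- vec[, j] / sqrt(drop(t(vec[, j]) %*% W %*% vec[, j]))
  }
  colnames(vec) <- paste0("LD", seq_len(n_fun))

  centroids <- means %*% vec
  prior_w <- if (priors == "equal") rep(1 / k, k) else ng / n
  names(prior_w) <- levels(g)

  structure(
    list(coefficients = vec, center = center, scale = scale_,
         centroids = centroids, eigenvalues = Re(ei$values[ord[seq_len(n_fun)]]),
         priors = prior_w, levels = levels(g), features = colnames(x),
         ridge = ridge),
    class = "discriminant_model"
  )
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d groups, %d features, %d canonical function(s)\n",
              length(x$levels), length(x$features), ncol(x$coefficients)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Canonical scores of observations
#'
#' @param model A [fit_discriminant()] model.
#' @param data Data with the same feature columns.
#' @return Matrix of canonical scores (one column per canonical function).
#' @export
discriminant_scores <- function(model, data) {
  stopifnot(inherits(model, "discriminant_model"))
  x <- if (is.data.frame(data)) {
    missing_cols <- setdiff(model$features, names(data))
    if (length(missing_cols)) {
      stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    as.matrix(data[model$features])
  } else as.matrix(data)
  z <- scale(x, center = model$center, scale = model$scale)
  z %*% model$coefficients
}

#' Reclassify observations by nearest group centroid
#'
#' Each row is assigned to the group whose centroid is nearest in canonical
#' space (squared Euclidean distance, minus `2 log prior` for non-equal
#' priors).  With `method = "resubstitution"` (default) the supplied model is
#' applied to its own training data, matching the reclassification-of-group-
#' membership convention; `method = "loo"` refits the model leaving each row
#' out for an honest error estimate.
#'
#' @param model A [fit_discriminant()] model.
#' @param data Data with the model's feature columns.
#' @param labels Optional true labels; enables `percent_correct`.
#' @param method `"resubstitution"` or `"loo"` (leave-one-out; requires
#'   `labels`).
#' @return List with `predicted` (factor), `percent_correct` (or `NA` without
#'   labels) and the canonical `scores`.
#' @export
reclassify <- function(model, data, labels = NULL,
                       method = c("resubstitution", "loo")) {
  method <- match.arg(method)
  if (method == "loo") {
    if (is.null(labels)) stop("leave-one-out needs labels", call. = FALSE)
    n <- if (is.data.frame(data)) nrow(data) else nrow(as.matrix(data))
    pred <- character(n)
    for (i in seq_len(n)) {
      m_i <- fit_discriminant(data[-i, , drop = FALSE], labels[-i],
                              features = model$features, ridge = model$ridge)
      pred[i] <- as.character(
        reclassify(m_i, data[i, , drop = FALSE])$predicted
      )
    }
    pred <- factor(pred, levels = model$levels)
    return(list(predicted = pred,
                percent_correct = 100 * mean(pred == labels),
                scores = discriminant_scores(model, data)))
  }
  scores <- discriminant_scores(model, data)
  cen <- model$centroids
  d2 <- sapply(seq_len(nrow(cen)), function(j) {
    rowSums(sweep(scores, 2L, cen[j, ])^2)
  })
  d2 <- matrix(d2, nrow = nrow(scores))
  d2 <- sweep(d2, 2L, 2 * log(model$priors))
  pred <- factor(model$levels[max.col(-d2, ties.method = "first")],
                 levels = model$levels)
  pc <- if (!is.null(labels)) 100 * mean(pred == labels) else NA_real_
  list(predicted = pred, percent_correct = pc, scores = scores)
}

#' Group confidence ellipses in canonical space
#'
#' Per-group confidence ellipse of the canonical scores at the chi-square
#' quantile (2 df), centered on the group centroid.  With a single canonical
#' dimension the scores are padded with a zero second dimension.
#'
#' @param model A [fit_discriminant()] model.
#' @param data,labels Training data and group labels.
#' @param confidence Coverage probability (default 0.95).
#' @return Data frame with one row per group: `group`, `center1`, `center2`,
#'   `axis1`, `axis2` (half-axis lengths), `angle` (radians of the major
#'   axis).  Degenerate group covariances give zero radii with a warning.
#' @export
group_envelopes <- function(model, data, labels, confidence = 0.95) {
  scores <- discriminant_scores(model, data)
  padded <- ncol(scores) == 1L
  if (padded) scores <- cbind(scores, 0)
  scores <- scores[, 1:2, drop = FALSE]
  labels <- factor(labels, levels = model$levels)
  q <- stats::qchisq(confidence, df = 2)
  out <- lapply(levels(labels), function(g) {
    s <- scores[labels == g, , drop = FALSE]
    if (nrow(s) < 3L) stop("need at least 3 rows per group for an envelope",
                           call. = FALSE)
    cen <- colMeans(s)
    cv <- stats::cov(s)
    ei <- eigen(cv, symmetric = TRUE)
    # a zero-padded second dimension is flat by construction; only a
    # degenerate spread of real canonical scores is worth a warning
    n_real <- if (padded) 1L else 2L
    if (any(ei$values[seq_len(n_real)] <= 1e-12)) {
      warning(sprintf("group %s: degenerate score covariance; zero-radius envelope", g))
    }
    ei$values <- pmax(ei$values, 0)
    ang <- atan2(ei$vectors[2L, 1L], ei$vectors[1L, 1L])
    if (ang > pi / 2) ang <- ang - pi
    if (ang <= -pi / 2) ang <- ang + pi
    data.frame(group = g, center1 = cen[1L], center2 = cen[2L],
               axis1 = sqrt(ei$values[1L] * q), axis2 = sqrt(ei$values[2L] * q),
               angle = ang,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
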