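# User-facing modelling interface: fit the two-group discriminant from a
# feature table, in the style of classic R model fits (formula + data in,
# classed object out, print/summary/coef/predict/plot/simulate methods).

#' Two-group HRV discriminant model
#'
#' Fits the 12-term Fisher linear discriminant separating two diagnostic
#' groups from their Rest levels and Task/Rest, After/Rest responsiveness
#' ratios of HF, LF, LF/HF and HR. The D-score is positive when the first
#' group of `pair` is supported.
#'
#' @param x a `data.frame` of subjects containing a grouping column and the
#'   12 feature columns ([FEATURE_NAMES]), or a numeric feature matrix.
#' @param ... passed on to methods.
#' @return an object of class `hrv_lda`; see [fit_lda()] for the underlying
#'   estimates. The object carries the training scores, the resubstitution
#'   confusion table with sensitivity/specificity, and the Mahalanobis
#'   separation with its Hotelling T^2 significance.
#' @examples
#' set.seed(1)
#' cohort <- simulate_cohort(sim_config(n_per_group = c(control = 0, AJD = 8, PPD = 8),
#'                                      seed = 1))
#' feats <- cohort_features(cohort)
#' fit <- hrv_lda(group ~ ., data = feats, pair = c("PPD", "AJD"))
#' summary(fit)
#' @export
hrv_lda <- function(x, ...) UseMethod("hrv_lda")

#' @rdname hrv_lda
#' @param formula a formula whose left-hand side names the grouping column,
#'   e.g. `group ~ .` (the right-hand side is ignored; the 12 canonical
#'   feature columns are always used).
#' @param data a `data.frame` with the grouping column and feature columns.
#' @param pair character length-2: (former, latter) group labels; D > 0
#'   supports the former.
#' @param ridge ridge regularisation weight, as in [fit_lda()].
#' @export
hrv_lda.formula <- function(formula, data, pair, ridge = NULL, ...) {
  resp <- all.vars(formula[[2]])
  if (length(resp) != 1L || !resp %in% names(data)) {
    stop("the formula's left-hand side must name the grouping column", call. = FALSE)
  }
  missing_feat <- setdiff(FEATURE_NAMES, names(data))
  if (length(missing_feat)) {
    stop("data lacks feature column(s): ", paste(missing_feat, collapse = ", "),
         call. = FALSE)
  }
  labels <- as.character(data[[resp]])
  keep <- labels %in% pair
  X <- as.matrix(data[keep, FEATURE_NAMES, drop = FALSE])
  hrv_lda.default(X, labels[keep], pair = pair, ridge = ridge, ...)
}

#' @rdname hrv_lda
#' @param grouping character vector of group labels, one per row of `x`.
#' @export
hrv_lda.default <- function(x, grouping, pair = unique(grouping), ridge = NULL, ...) {
  X <- as.matrix(x)
  grouping <- as.character(grouping)
  if (length(pair) != 2L) stop("`pair` must name exactly two groups", call. = FALSE)
  if (nrow(X) != length(grouping)) stop("one label per row required", call. = FALSE)
  keep <- grouping %in% pair
  X <- X[keep, , drop = FALSE]
  grouping <- grouping[keep]
  fit <- fit_lda(X[grouping == pair[1], , drop = FALSE],
                 X[grouping == pair[2], , drop = FALSE],
                 ridge = ridge, group_pair = pair)
  scores <- d_score(fit, X)
  ct <- classify_cohort(fit, X, grouping)
  md <- mahalanobis_distance(fit)
  ht <- if (sum(fit$n) > ncol(X) + 1) {
    hotelling_p(md, fit$n[["former"]], fit$n[["latter"]], ncol(X))
  } else {
    # too few subjects for the T^2 reference distribution
    list(md = md, t2 = NA_real_, f = NA_real_,
         df = c(NA_real_, NA_real_), p = NA_real_)
  }
  structure(list(fit = fit, scores = scores, labels = grouping,
                 confusion = ct, performance = sens_spec(ct),
                 separation = ht, call = match.call()),
            class = "hrv_lda")
}

#' @export
print.hrv_lda <- function(x, ...) {
  cat(sprintf("HRV three-state discriminant: %s (D > 0) vs %s (D < 0)\n",
              x$fit$group_pair[1], x$fit$group_pair[2]))
  cat(sprintf("  n = %d / %d, Mahalanobis distance %.3f (p = %.3g)\n",
              x$fit$n[1], x$fit$n[2], x$separation$md, x$separation$p))
  cat(sprintf("  resubstitution sensitivity %.1f%%, specificity %.1f%%\n",
              x$performance$sensitivity, x$performance$specificity))
  invisible(x)
}

#' @export
summary.hrv_lda <- function(object, ...) {
  structure(list(model = object), class = "summary.hrv_lda")
}

#' @export
print.summary.hrv_lda <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nCoefficients (D-score units per feature unit):\n")
  print(signif(m$fit$coefficients, 4))
  cat(sprintf("Discriminant point: %.4g\n", m$fit$discriminant_point))
  cat(sprintf("Hotelling T^2 = %.3f, F(%d, %d) = %.3f\n",
              m$separation$t2, m$separation$df[1], m$separation$df[2],
              m$separation$f))
  cat("\nResubstitution confusion (rows: true group):\n")
  print(m$confusion)
  invisible(x)
}

#' @export
coef.hrv_lda <- function(object, ...) object$fit$coefficients

#' Predict D-scores and group membership
#'
#' @param object an [hrv_lda()] fit.
#' @param newdata `data.frame` with the 12 feature columns, or a feature
#'   matrix; defaults to the training data scores.
#' @param type `"score"` for raw D-scores, `"class"` for group labels
#'   (`D > 0` maps to the former group; ties to the latter).
#' @param ... unused.
#' @export
predict.hrv_lda <- function(object, newdata = NULL,
                            type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- if (is.null(newdata)) {
    object$scores
  } else {
    X <- if (is.data.frame(newdata)) as.matrix(newdata[, FEATURE_NAMES, drop = FALSE])
         else as.matrix(newdata)
    d_score(object$fit, X)
  }
  if (type == "score") s
  else ifelse(s > 0, object$fit$group_pair[1], object$fit$group_pair[2])
}

#' Strip chart of training D-scores by group
#'
#' @param x an [hrv_lda()] fit.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.hrv_lda <- function(x, ...) {
  graphics::stripchart(split(x$scores, factor(x$labels, levels = x$fit$group_pair)),
                       vertical = TRUE, method = "jitter", pch = 16,
                       ylab = "D-score", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::mtext(sprintf("Md = %.2f, p = %.3g", x$separation$md, x$separation$p),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Simulate feature vectors from the fitted two-Gaussian model
#'
#' Draws subjects from multivariate normals with the fitted group means and
#' the (regularised) pooled covariance — the generative model implicit in
#' the linear discriminant.
#'
#' @param object an [hrv_lda()] fit.
#' @param nsim number of subjects per group.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return `data.frame` with a `group` column and the 12 feature columns.
#' @export
simulate.hrv_lda <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- object$fit$pooled_cov + diag(object$fit$ridge, ncol(object$fit$pooled_cov))
  L <- chol(S)
  draw <- function(mu, n) {
    Z <- matrix(stats::rnorm(n * length(mu)), n)
    sweep(Z %*% L, 2, mu, `+`)
  }
  out <- rbind(draw(object$fit$means["former", ], nsim),
               draw(object$fit$means["latter", ], nsim))
  colnames(out) <- names(object$fit$coefficients)
  data.frame(group = rep(object$fit$group_pair, each = nsim), out,
             check.names = FALSE)
}
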