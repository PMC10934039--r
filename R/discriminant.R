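# Two-group Fisher linear discriminant on the 12 Rest/Task-Rest/After-Rest
# features, with Mahalanobis separation and Hotelling two-sample T^2
# significance. The discriminant score (D-score) is positive when the
# first-named ("former") group of the pair is supported.

.coef_letters <- letters[1:12]

#' Fit the two-group Fisher discriminant
#'
#' Coefficients solve `(S_pooled + ridge * I) w = mu_former - mu_latter`;
#' the discriminant point is `w . (mu_former + mu_latter) / 2` (equal
#' priors, midpoint threshold), so the D-score `w . x - point` is positive
#' at the former group's mean and negative at the latter's. The pooled
#' covariance weights each group by `n - 1`. With 12 features and clinical
#' group sizes the pooled covariance can be ill-conditioned; a small ridge
#' (default `1e-6 *` mean diagonal) keeps the solve stable without
#' materially moving the solution.
#'
#' @param x_former,x_latter numeric matrices (subjects x 12 features, in
#'   [FEATURE_NAMES] order) for the former and latter group of the pair.
#' @param ridge ridge weight added to the covariance diagonal; `NULL`
#'   (default) uses `1e-6 * mean(diag(S))`, `0` disables regularisation.
#' @param group_pair character length-2, labels of (former, latter).
#' @return object of class `lda_model`: list with `group_pair`,
#'   `coefficients` (named a-l), `discriminant_point`, `means`,
#'   `pooled_cov`, `ridge`, `n` and `degenerate`.
#' @export
fit_lda <- function(x_former, x_latter, ridge = NULL,
                    group_pair = c("former", "latter")) {
  x_former <- as.matrix(x_former)
  x_latter <- as.matrix(x_latter)
  if (ncol(x_former) != ncol(x_latter)) {
    stop("feature matrices must have the same number of columns", call. = FALSE)
  }
  n1 <- nrow(x_former); n2 <- nrow(x_latter)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects", call. = FALSE)
  p <- ncol(x_former)
  mu1 <- colMeans(x_former)
  mu2 <- colMeans(x_latter)
  S <- ((n1 - 1) * stats::cov(x_former) + (n2 - 1) * stats::cov(x_latter)) / (n1 + n2 - 2)
  if (is.null(ridge)) ridge <- 1e-6 * mean(diag(S))
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  Sr <- S + diag(ridge, p)
  delta <- mu1 - mu2
  degenerate <- all(abs(delta) < .Machine$double.eps^0.5)
  if (degenerate) {
    w <- numeric(p)
  } else {
    w <- tryCatch(solve(Sr, delta), error = function(e) {
      stop("singular pooled covariance; supply a positive `ridge` ",
           "(or more subjects per group)", call. = FALSE)
    })
  }
  cf <- as.numeric(w)
  names(cf) <- if (p == 12L) paste0(.coef_letters, "_", colnames(x_former) %||% FEATURE_NAMES)
               else colnames(x_former) %||% paste0("x", seq_len(p))
  structure(list(group_pair = group_pair,
                 coefficients = cf,
                 discriminant_point = sum(cf * (mu1 + mu2) / 2),
                 means = rbind(former = mu1, latter = mu2),
                 pooled_cov = S, ridge = ridge,
                 n = c(former = n1, latter = n2),
                 degenerate = degenerate),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s (D > 0) vs %s (D < 0), n = %d/%d%s\n",
              x$group_pair[1], x$group_pair[2], x$n[1], x$n[2],
              if (x$degenerate) " [degenerate]" else ""))
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  discriminant point: %.4g  (ridge %.3g)\n",
              x$discriminant_point, x$ridge))
  invisible(x)
}

#' Discriminant score of one or more feature vectors
#'
#' `D = sum_k coefficient_k * feature_k - discriminant_point`; positive
#' supports the former diagnosis of the model's group pair.
#'
#' @param model an [fit_lda()] model.
#' @param features numeric vector of length 12 (one subject) or matrix
#'   (subjects x 12).
#' @return numeric vector of D-scores.
#' @export
d_score <- function(model, features) {
  stopifnot(inherits(model, "lda_model"))
  X <- if (is.matrix(features) || is.data.frame(features)) as.matrix(features)
       else matrix(features, nrow = 1L)
  if (ncol(X) != length(model$coefficients)) {
    stop("feature length ", ncol(X), " does not match the model's ",
         length(model$coefficients), " coefficients", call. = FALSE)
  }
  drop(X %*% model$coefficients) - model$discriminant_point
}

#' Classify a labeled cohort and count the confusion table
#'
#' Subjects of the former group with `D > 0` are true positives; a D-score
#' of exactly zero counts as the negative (latter) class, so the partition
#' into `D > 0` and `D < 0` is deterministic.
#'
#' @param model an [fit_lda()] model.
#' @param features subjects x 12 matrix.
#' @param labels character vector of group labels, all within
#'   `model$group_pair`.
#' @return object of class `confusion_table`: list `tp`, `fn`, `fp`, `tn`.
#' @export
classify_cohort <- function(model, features, labels) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(features)
  if (nrow(X) == 0L) stop("empty cohort", call. = FALSE)
  if (nrow(X) != length(labels)) stop("one label per subject required", call. = FALSE)
  foreign <- setdiff(unique(labels), model$group_pair)
  if (length(foreign)) {
    stop("label(s) outside the model's group pair: ",
         paste(foreign, collapse = ", "), call. = FALSE)
  }
  s <- d_score(model, X)
  former <- labels == model$group_pair[1]
  confusion_table(tp = sum(former & s > 0), fn = sum(former & s <= 0),
                  fp = sum(!former & s > 0), tn = sum(!former & s <= 0))
}

#' Confusion table constructor
#'
#' Former-group-positive convention: `tp + fn` is the former group size,
#' `fp + tn` the latter group size.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table>  D>0  D<0\n  former %5d %5d\n  latter %5d %5d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' Percentages rounded half-up to one decimal, as conventionally reported.
#'
#' @param ct a [confusion_table()].
#' @return list with `sensitivity` and `specificity` in percent.
#' @export
sens_spec <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tp + ct$fn == 0 || ct$fp + ct$tn == 0) {
    stop("undefined metric: a group margin of the confusion table is empty",
         call. = FALSE)
  }
  list(sensitivity = round_half_up(100 * ct$tp / (ct$tp + ct$fn), 1),
       specificity = round_half_up(100 * ct$tn / (ct$fp + ct$tn), 1))
}

#' Mahalanobis distance between the two group means
#'
#' `sqrt((mu_f - mu_l)' (S + ridge I)^-1 (mu_f - mu_l))`, using the same
#' regularised pooled covariance as the fit.
#'
#' @param model an [fit_lda()] model.
#' @return non-negative scalar.
#' @export
mahalanobis_distance <- function(model) {
  stopifnot(inherits(model, "lda_model"))
  delta <- model$means["former", ] - model$means["latter", ]
  if (model$degenerate) return(0)
  # w already solves (S + ridge I) w = delta
  sqrt(max(0, sum(model$coefficients * delta)))
}

#' Hotelling two-sample T^2 significance of a Mahalanobis separation
#'
#' `T^2 = (n1 n2 / (n1 + n2)) * md^2`, referred to an F distribution:
#' `F = T^2 (n1 + n2 - p - 1) / (p (n1 + n2 - 2))` on
#' `(p, n1 + n2 - p - 1)` degrees of freedom.
#'
#' @param md Mahalanobis distance between the group means.
#' @param n1,n2 group sizes.
#' @param p_dim feature dimension.
#' @return list with `md`, `t2`, `f`, `df` and `p`.
#' @export
hotelling_p <- function(md, n1, n2, p_dim) {
  if (n1 + n2 <= p_dim + 1) {
    stop("insufficient degrees of freedom: need n1 + n2 > p_dim + 1", call. = FALSE)
  }
  t2 <- (n1 * n2 / (n1 + n2)) * md^2
  f <- t2 * (n1 + n2 - p_dim - 1) / (p_dim * (n1 + n2 - 2))
  df <- c(p_dim, n1 + n2 - p_dim - 1)
  list(md = md, t2 = t2, f = f, df = df,
       p = stats::pf(f, df[1], df[2], lower.tail = FALSE))
}

#' Serialise a discriminant model to JSON
#'
#' @param model an [fit_lda()] or [hrv_lda()] model.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "hrv_lda")) model <- model$fit
  stopifnot(inherits(model, "lda_model"))
  md <- mahalanobis_distance(model)
  p_dim <- length(model$coefficients)
  ht <- if (sum(model$n) > p_dim + 1) {
    hotelling_p(md, model$n[["former"]], model$n[["latter"]], p_dim)
  } else {
    list(p = NA_real_)
  }
  jsonlite::write_json(
    list(group_pair = model$group_pair,
         coefficients = as.list(model$coefficients),
         discriminant_point = model$discriminant_point,
         ridge = model$ridge,
         n = as.list(model$n),
         mahalanobis = md,
         p = ht$p),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
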