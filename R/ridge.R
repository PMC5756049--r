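#' Ridge regression with 10-fold cross-validation and the one-SE rule
#'
#' Fits the ridge path `beta(lambda) = (X'X + lambda I)^-1 X'y` by singular
#' value decomposition over a 100-value lambda grid, log-spaced over six
#' decades down from a `lambda_max` at which the coefficient norm has
#' shrunk below 1e-3 of the ordinary-least-squares norm. The penalty is
#' chosen by k-fold cross-validation with the one-standard-error rule: the
#' largest lambda whose mean CV error is within one standard error of the
#' minimum, i.e. the most regularized model that is statistically
#' indistinguishable from the best. Final coefficients are refit on all
#' training data at the chosen lambda.
#'
#' Features are standardized to unit variance internally (and centered when
#' an intercept is requested); coefficients are reported on the
#' standardized scale, and [predict.ridge_fit()] applies the stored scaling.
#'
#' @param X numeric feature matrix with column names.
#' @param y numeric response, `length(y) == nrow(X)`.
#' @param folds number of CV folds (default 10).
#' @param rule `"1se"` (default) or `"min"`.
#' @param intercept include an intercept/offset term (default FALSE, as for
#'   composition features that sum to a constant).
#' @param standardize scale features to unit variance (default TRUE).
#' @param lambda optional explicit lambda grid (decreasing).
#' @param seed seed for the CV fold assignment.
#' @return Object of class `ridge_fit`; `coefficients` are on the
#'   standardized scale, `coefficients_raw` on the original feature scale.
#' @export
fit_ridge <- function(X, y, folds = 10L, rule = c("1se", "min"),
                      intercept = FALSE, standardize = TRUE,
                      lambda = NULL, seed = 1L) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  if (folds > nrow(X)) stop("more CV folds than samples")
  n <- nrow(X)

  center <- if (intercept) colMeans(X) else rep(0, ncol(X))
  scalev <- if (standardize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scalev[scalev == 0 | is.na(scalev)] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scalev, "/")
  ymean <- if (intercept) mean(y) else 0
  yc <- y - ymean

  ridge_path <- function(Xm, ym, lambdas) {
    sv <- svd(Xm)
    uty <- crossprod(sv$u, ym)
    sapply(lambdas, function(l) {
      sv$v %*% (uty * sv$d / (sv$d^2 + l))
    })
  }

  if (is.null(lambda)) {
    sv <- svd(Xs)
    uty <- crossprod(sv$u, yc)
    dd <- sv$d
    pos <- dd > max(dd) * 1e-10
    ols_norm <- sqrt(sum((uty[pos] / dd[pos])^2))
    bnorm <- function(l) sqrt(sum((uty * dd / (dd^2 + l))^2))
    lmax <- max(dd)^2
    while (bnorm(lmax) > 1e-3 * ols_norm) lmax <- lmax * 2
    lambda <- 10^seq(log10(lmax), log10(lmax) - 6, length.out = 100L)
  }

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_err <- matrix(NA_real_, nrow = folds, ncol = length(lambda))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    B <- ridge_path(Xs[tr, , drop = FALSE], yc[tr], lambda)
    pred <- Xs[!tr, , drop = FALSE] %*% B
    cv_err[f, ] <- colMeans((pred - yc[!tr])^2)
  }
  cvm <- colMeans(cv_err)
  cvsd <- apply(cv_err, 2, stats::sd) / sqrt(folds)
  imin <- which.min(cvm)
  i1se <- which(cvm <= cvm[imin] + cvsd[imin])[1]  # grid is decreasing
  ichosen <- if (rule == "1se") i1se else imin

  beta <- drop(ridge_path(Xs, yc, lambda[ichosen]))
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    coefficients_raw = beta / scalev,
    intercept = ymean,
    lambda = lambda[ichosen],
    lambda_min = lambda[imin],
    lambda_path = lambda,
    cvm = cvm, cvsd = cvsd,
    folds = folds, rule = rule,
    center = center, scale = scalev,
    has_intercept = intercept, standardized = standardize
  ), class = "ridge_fit")
}

#' @export
coef.ridge_fit <- function(object, ...) {
  if (object$has_intercept) {
    c("(Intercept)" = object$intercept, object$coefficients)
  } else {
    object$coefficients
  }
}

#' Predict from a ridge fit
#' @param object a `ridge_fit`.
#' @param newx feature matrix with the same columns as the training matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ridge_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  Xs <- sweep(sweep(newx, 2, object$center, "-"), 2, object$scale, "/")
  drop(Xs %*% object$coefficients) + object$intercept
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf(paste0("ridge_fit: %d features, lambda = %.4g (%s rule, ",
                     "%d-fold CV)\n"), length(x$coefficients), x$lambda,
              x$rule, x$folds))
  invisible(x)
}

#' Test-set performance of a fitted model
#'
#' @param fit a `ridge_fit` (or any object with a `predict` method).
#' @param X_test,y_test held-out features and response.
#' @return List with `r` (Pearson correlation; NA when the predictions have
#'   zero variance) and `rmsd` (root-mean-square deviation).
#' @export
evaluate <- function(fit, X_test, y_test) {
  pred <- stats::predict(fit, X_test)
  r <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, y_test)
  list(r = r, rmsd = sqrt(mean((pred - y_test)^2)))
}

#' Strand consistency of k-mer coefficients
#'
#' Features are counted on the plus strand only while the underlying data
#' carry no strand information, so the coefficient of each k-mer should
#' match the coefficient of its reverse complement. Returns the Pearson
#' correlation over all (k-mer, reverse-complement) pairs; palindromes pair
#' with themselves and sit on the identity line.
#'
#' @param fit a `ridge_fit` whose feature names are k-mers.
#' @return Pearson correlation coefficient.
#' @export
revcomp_consistency <- function(fit) {
  b <- fit$coefficients
  rc <- revcomp_chr(names(b))
  stopifnot(all(rc %in% names(b)))
  stats::cor(b, b[rc])
}

#' Spatial-proximity linear model of binding
#'
#' Ordinary least squares (with intercept) of mutant-normalized enrichment
#' in each 1 kb window on the AT content of the window itself and of its
#' `1..n_flank` neighbouring windows up- and downstream. Retained windows
#' must have all `n_flank` neighbours present on the same chromosome, all
#' at or above the mappability threshold, and (like the center) outside CpG
#' islands. Balanced sampling over the central window's enrichment and an
#' equal train/test split precede the fit; models of every size
#' `0..n_flank` are fitted and evaluated by test-set Pearson correlation.
#'
#' @param windows annotated window data frame (contiguous tiling with
#'   `mappable_fraction` and `at_content`).
#' @param delta_e mutant-normalized enrichment, one value per window.
#' @param n_flank maximum number of flanking windows per side (default 3).
#' @param cpg_overlap optional logical vector marking windows overlapping
#'   CpG islands.
#' @param min_mappable mappability threshold (default 0.8).
#' @param balance balance the training sample over the enrichment range
#'   (default). Balancing over the response induces a small upward selection
#'   bias in the fitted slope when residual noise is non-negligible; set
#'   FALSE for a plain random equal split.
#' @param seed seed for the balanced split.
#' @return Object of class `proximity_fit`: list with `fits` (per model
#'   size: `coefficients` and test `r`), `coefficients` (full model,
#'   positions -n_flank..+n_flank), `test_r` (named by flank count), and
#'   the split.
#' @export
proximity_fit <- function(windows, delta_e, n_flank = 3L,
                          cpg_overlap = NULL, min_mappable = 0.8,
                          balance = TRUE, seed = 1L) {
  nw <- nrow(windows)
  stopifnot(length(delta_e) == nw)
  if (is.null(cpg_overlap)) cpg_overlap <- rep(FALSE, nw)
  offs <- -n_flank:n_flank
  off_names <- paste0("AT_", ifelse(offs < 0, paste0("m", -offs), offs))
  atm <- matrix(NA_real_, nrow = nw, ncol = length(offs),
                dimnames = list(NULL, off_names))
  okm <- matrix(FALSE, nrow = nw, ncol = length(offs))
  wsize <- windows$end - windows$start
  for (j in seq_along(offs)) {
    o <- offs[j]
    src <- seq_len(nw) + o
    valid <- src >= 1L & src <= nw
    src_ok <- rep(FALSE, nw)
    iv <- which(valid)
    src_ok[iv] <- windows$chrom[src[iv]] == windows$chrom[iv] &
      windows$start[src[iv]] == windows$start[iv] + o * wsize[iv]
    src_idx <- ifelse(src_ok, src, NA_integer_)
    atm[, j] <- windows$at_content[src_idx]
    okm[, j] <- !is.na(src_idx) &
      windows$mappable_fraction[pmax(src_idx, 1L)] >= min_mappable &
      !cpg_overlap[pmax(src_idx, 1L)]
  }
  retained <- rowSums(okm) == length(offs) & !is.na(delta_e)
  if (sum(retained) < 24L) stop("too few retained windows for the proximity model")
  if (stats::var(atm[retained, n_flank + 1L]) == 0) {
    stop("collinear design: AT content is constant over retained windows")
  }
  ydum <- rep(NA_real_, nw)
  ydum[retained] <- delta_e[retained]
  split <- if (balance) {
    balanced_split(ydum, seed = seed)
  } else {
    idx <- which(!is.na(ydum))
    with_seed(seed, {
      perm <- sample(idx)
      half <- length(perm) %/% 2L
      list(train = sort(perm[seq_len(half)]),
           test = sort(perm[(half + 1L):(2L * half)]))
    })
  }

  fits <- list()
  test_r <- numeric(n_flank + 1L)
  for (m in 0:n_flank) {
    cols <- which(abs(offs) <= m)
    df_tr <- data.frame(y = delta_e[split$train],
                        atm[split$train, cols, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    df_te <- data.frame(atm[split$test, cols, drop = FALSE])
    pred <- stats::predict(fit, newdata = df_te)
    test_r[m + 1L] <- stats::cor(pred, delta_e[split$test])
    fits[[m + 1L]] <- list(coefficients = stats::coef(fit), r = test_r[m + 1L])
  }
  names(test_r) <- paste0("flank", 0:n_flank)
  full <- fits[[n_flank + 1L]]$coefficients
  cc <- full[off_names]
  names(cc) <- paste0("AT_", offs)
  structure(list(
    fits = fits,
    coefficients = cc,
    intercept = full[["(Intercept)"]],
    test_r = test_r,
    split = split,
    n_flank = n_flank
  ), class = "proximity_fit")
}

#' @export
print.proximity_fit <- function(x, ...) {
  cat("proximity_fit: OLS of enrichment on window AT content +/-",
      x$n_flank, "neighbours\n  coefficients:\n")
  print(round(x$coefficients, 4))
  cat("  test r by flank count:",
      paste(sprintf("%s=%.3f", names(x$test_r), x$test_r), collapse = " "),
      "\n")
  invisible(x)
}
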