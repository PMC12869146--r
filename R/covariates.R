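#' Standardize area-level covariates
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1), the preparation applied to every area-level factor
#' before model fitting so coefficients read as log relative risks per 1 SD.
#' The centre/scale parameters are retained as attributes so coefficients
#' can be mapped back to the raw scale.
#'
#' @param covariates numeric matrix or data.frame of covariates (unique
#'   column names; no missing values; no constant column).
#' @return numeric matrix with attributes `center` and `scale`.
#' @export
#' @examples
#' standardize_covariates(cbind(x = c(1, 2, 3)))
standardize_covariates <- function(covariates) {
  X <- as.matrix(covariates)
  if (!is.numeric(X)) abort("covariates must be numeric")
  if (anyNA(X)) abort("covariates contain missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) abort("covariate names must be unique")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort("constant column(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- sds
  Z
}

#' Invert a standardization
#'
#' @param standardized output of [standardize_covariates].
#' @return the original covariate matrix.
#' @export
unstandardize_covariates <- function(standardized) {
  ctr <- attr(standardized, "center"); sc <- attr(standardized, "scale")
  if (is.null(ctr) || is.null(sc)) abort("no standardization parameters found")
  Z <- sweep(sweep(unclass(standardized), 2, sc, "*"), 2, ctr, "+")
  attr(Z, "center") <- NULL; attr(Z, "scale") <- NULL
  Z
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is from the linear regression of
#' column j on all other columns (plus an intercept). A VIF of 1 means the
#' column is orthogonal to the rest; perfect collinearity yields `Inf`.
#'
#' @param covariates numeric matrix/data.frame with >= 2 columns and more
#'   rows than columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(covariates) {
  X <- as.matrix(covariates)
  if (ncol(X) < 2) abort("VIF needs at least 2 covariates")
  if (nrow(X) <= ncol(X)) abort("need more areas than covariates")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Screen covariates for multicollinearity by iterative VIF removal
#'
#' Computes VIFs for the full covariate set and repeatedly removes the worst
#' offender above `threshold`, recomputing after each removal, until every
#' remaining (finite) VIF is at or below the threshold or only one column
#' remains. Ties on the worst VIF are broken by dropping the later column in
#' the supplied order — so callers encode substantive priority (construct
#' validity, data completeness) by listing the variables they most want to
#' keep first; the code does not invent that judgment.
#'
#' @param covariates numeric matrix/data.frame; column order encodes
#'   retention priority (earlier = keep preferentially).
#' @param threshold VIF above which a covariate is considered collinear;
#'   default 5.0.
#' @return data.frame of class `vif_report`, one row per input covariate:
#'   `covariate`, `vif` (final VIF for retained columns, VIF at removal for
#'   dropped ones), `retained`, `drop_reason` (`""`, or
#'   `"vif_above_threshold"` / `"perfect_collinearity"`), `drop_order`.
#' @export
#' @examples
#' z <- cbind(a = rnorm(100))
#' z <- cbind(z, b = 0.9 * z[, "a"] + sqrt(1 - 0.81) * rnorm(100))
#' vif_screen(z, threshold = 5)
vif_screen <- function(covariates, threshold = 5.0) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  order0 <- colnames(X)
  report <- data.frame(covariate = order0, vif = NA_real_, retained = TRUE,
                       drop_reason = "", drop_order = NA_integer_,
                       stringsAsFactors = FALSE)
  keep <- colnames(X)
  dropped <- 0L
  while (length(keep) >= 2) {
    v <- vif(X[, keep, drop = FALSE])
    worst <- max(v)
    if (worst <= threshold) break
    # ties (incl. multiple Inf): drop the later-listed column
    cand <- names(v)[v >= worst - 1e-8 | (is.infinite(worst) & is.infinite(v))]
    victim <- cand[which.max(match(cand, order0))]
    dropped <- dropped + 1L
    i <- match(victim, report$covariate)
    report$vif[i] <- v[victim]
    report$retained[i] <- FALSE
    report$drop_reason[i] <- if (is.infinite(v[victim]))
      "perfect_collinearity" else "vif_above_threshold"
    report$drop_order[i] <- dropped
    keep <- setdiff(keep, victim)
  }
  if (length(keep) >= 2) {
    v <- vif(X[, keep, drop = FALSE])
    report$vif[match(names(v), report$covariate)] <- v
  } else if (length(keep) == 1) {
    report$vif[match(keep, report$covariate)] <- 1
  }
  attr(report, "threshold") <- threshold
  attr(report, "retained") <- keep
  class(report) <- c("vif_report", "data.frame")
  report
}

#' Write a VIF report as JSON
#' @param report a `vif_report`.
#' @param path file path.
#' @export
write_vif_json <- function(report, path) {
  jsonlite::write_json(list(threshold = attr(report, "threshold"),
                            retained = attr(report, "retained"),
                            table = as.data.frame(report)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
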