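#' Ordinary least squares gradient model
#'
#' Fits the general linear model used throughout the gradient analyses and
#' collects everything the reports need: raw and standardized coefficients
#' with standard errors, t statistics, two-sided p values and 95% confidence
#' intervals; the overall F test with its degrees of freedom; R-squared; and
#' externally studentized residuals (each observation's residual scaled by a
#' fit that excludes it, exactly t-distributed under the model).
#'
#' @param y numeric response vector.
#' @param predictors named list, data.frame, or matrix of predictor columns.
#' @param include_intercept logical, default TRUE.
#' @param standardize logical; if TRUE, z-scores the predictors (and reports
#'   coefficients on that scale). Default FALSE: raw units, with
#'   standardized coefficients reported alongside.
#' @param conf_level confidence level for the intervals, default 0.95.
#' @return object of class `gradient_glm`: list with `coefficients`
#'   (data.frame: term, estimate, se, t, p, ci_lo, ci_hi, std_estimate),
#'   `f_statistic`, `df_model`, `df_residual`, `f_p_value`, `r_squared`,
#'   `studentized_residuals`, `n`, and the underlying `lm` fit.
#' @export
fit_glm <- function(y, predictors, include_intercept = TRUE,
                    standardize = FALSE, conf_level = 0.95) {
  X <- as.data.frame(predictors)
  if (!ncol(X)) stop("no predictors given")
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("predictor length does not match response")
  if (n <= ncol(X) + include_intercept)
    stop("too few observations (n = ", n, ") for ",
         ncol(X) + include_intercept, " coefficients")
  if (standardize) X[] <- lapply(X, function(v) as.numeric(scale(v)))
  dat <- cbind(data.frame(.y = y), X)
  form <- stats::as.formula(paste(".y ~",
    paste(c(if (!include_intercept) "0", names(X)), collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: drop collinear predictors (",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), ")")
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- stats::confint(fit, level = conf_level)
  sdy <- stats::sd(y)
  std_est <- vapply(rownames(ct), function(term) {
    if (term == "(Intercept)") return(NA_real_)
    if (sdy == 0) return(0)
    ct[term, 1] * stats::sd(dat[[term]]) / sdy
  }, numeric(1))
  coefs <- data.frame(term = rownames(ct),
                      estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      std_estimate = std_est,
                      row.names = NULL)
  fstat <- sm$fstatistic
  r2 <- sm$r.squared
  fval <- if (is.null(fstat)) NA_real_ else unname(fstat[1])
  fp <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  rstud <- stats::rstudent(fit)
  if (sdy == 0) {
    # a constant response carries no variance to explain
    r2 <- 0; fval <- 0; fp <- 1; rstud[] <- 0
  } else if (sm$sigma < 1e-8 * sdy) {
    rstud[] <- 0  # numerically perfect fit: no observation deviates
  }
  res <- list(
    coefficients = coefs,
    r_squared = r2,
    f_statistic = fval,
    df_model = if (is.null(fstat)) ncol(X) else unname(fstat[2]),
    df_residual = fit$df.residual,
    f_p_value = fp,
    studentized_residuals = rstud,
    n = n,
    conf_level = conf_level,
    lm = fit)
  class(res) <- "gradient_glm"
  res
}

#' @export
print.gradient_glm <- function(x, digits = 3, ...) {
  cat(sprintf("gradient GLM: n = %d, F(%g, %g) = %.*f, p = %.3g, R2 = %.*f\n",
              x$n, x$df_model, x$df_residual, digits, x$f_statistic,
              x$f_p_value, digits, x$r_squared))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Functional gradient test
#'
#' Regresses each area's mean functional connectivity distance on its mean
#' geodesic distance from the closest primary-area border (single predictor
#' plus intercept). With a full 91-area parcellation this is the model with
#' residual df = 89. Areas with a missing connectivity distance are dropped.
#'
#' @param area_cd per-area mean FC distance (mm): the `mean_cd_mm` column of
#'   [aggregate_maps()], or a named vector keyed by area id.
#' @param area_dist_primary per-area mean of the border-distance map (mm),
#'   matched to `area_cd`.
#' @return a `gradient_glm`; observations carry area ids as names.
#' @export
functional_gradient_test <- function(area_cd, area_dist_primary) {
  if (is.data.frame(area_cd)) area_cd <-
      stats::setNames(area_cd$mean_cd_mm, area_cd$area_id)
  if (length(area_cd) != length(area_dist_primary))
    stop("area vectors have different lengths")
  keep <- !is.na(area_cd) & !is.na(area_dist_primary)
  y <- area_cd[keep]
  x <- area_dist_primary[keep]
  res <- fit_glm(as.numeric(y), list(dist_primary_mm = as.numeric(x)))
  names(res$studentized_residuals) <- names(y)
  res
}

#' Structural gradient test
#'
#' Regresses per-injection structural connectivity distance on distance from
#' the closest primary border, with region size (vertex count of the injected
#' area) and geometric centrality as covariates of no interest. With 29
#' injections this is the model with residual df = 25. A covariate constant
#' across injections carries no information and is dropped with a warning
#' rather than breaking the fit.
#'
#' @param rows data.frame from [build_sc_table()].
#' @return a `gradient_glm`; observations carry injection ids as names.
#' @export
structural_gradient_test <- function(rows) {
  if (nrow(rows) < 6L) stop("need at least 6 injections")
  preds <- list(dist_primary_mm = rows$dist_primary_mm,
                region_size_vertices = as.numeric(rows$region_size_vertices),
                centrality_mm = rows$centrality_mm)
  const <- vapply(preds, function(v) stats::sd(v) == 0, logical(1))
  if (const[["dist_primary_mm"]])
    stop("distance-from-primary predictor is constant across injections")
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(preds)[const], collapse = ", "))
    preds <- preds[!const]
  }
  res <- fit_glm(rows$cd_mm, preds)
  names(res$studentized_residuals) <- rows$injection
  res
}

#' Flag outliers by externally studentized residuals
#'
#' Observations whose absolute externally studentized residual exceeds the
#' threshold (default 2) deviate from the overall gradient.
#'
#' @param res a `gradient_glm`.
#' @param threshold absolute residual threshold, default 2.
#' @return character vector of observation ids (names when available,
#'   otherwise indices as character).
#' @export
flag_outliers <- function(res, threshold = 2) {
  r <- res$studentized_residuals
  ids <- names(r)
  if (is.null(ids)) ids <- as.character(seq_along(r))
  ids[!is.na(r) & abs(r) > threshold]
}

#' JSON-ready report of a gradient GLM
#' @param res a `gradient_glm`.
#' @param outlier_threshold passed to [flag_outliers()].
#' @return list serializable with jsonlite.
#' @export
glm_report <- function(res, outlier_threshold = 2) {
  list(n = res$n,
       f_statistic = res$f_statistic,
       df_model = res$df_model,
       df_residual = res$df_residual,
       f_p_value = res$f_p_value,
       r_squared = res$r_squared,
       coefficients = res$coefficients,
       outliers = flag_outliers(res, outlier_threshold))
}
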