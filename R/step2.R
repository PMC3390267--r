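# Step 2: dispersion model on the log squared estimated residuals.

#' Build the dispersion response from step-1 residuals
#'
#' The per-record measure of residual variance is `ln(e^2)` (default) or the
#' cube-root `(e^2)^(1/3)`, which is closer to normal. For the log
#' transform, squared residuals below a small quantile-based floor are
#' raised to it so the response stays finite; the number of floored records
#' is reported, never silently absorbed.
#'
#' @param ehat numeric vector of estimated residuals from a converged
#'   step-1 fit (names, if any, are kept).
#' @param transform `"log"` or `"cuberoot"`.
#' @param floor_quantile for `"log"`: the quantile of the positive squared
#'   residuals used as floor (scale-free by construction).
#' @return list of class `"dispersion_response"` with `values`, `transform`
#'   and `floored_count`.
#' @export
dispersion_response <- function(ehat, transform = c("log", "cuberoot"),
                                floor_quantile = 1e-6) {
  transform <- match.arg(transform)
  e2 <- ehat^2
  if (all(e2 == 0)) stop("all residuals are zero: degenerate first-step fit")
  floored <- 0L
  if (transform == "log") {
    # never floor the smallest positive residual itself (small samples)
    floor <- min(stats::quantile(e2[e2 > 0], floor_quantile, names = FALSE),
                 min(e2[e2 > 0]))
    floored <- sum(e2 < floor)
    values <- log(pmax(e2, floor))
  } else {
    values <- e2^(1 / 3)
  }
  structure(list(values = setNames(values, names(ehat)),
                 transform = transform, floored_count = floored),
            class = "dispersion_response")
}

#' Fit the dispersion animal model
#'
#' Fits the second-step model
#' \deqn{\ln(\hat e^2) = X b^* + Z_1 a^* + Z_2 m^* + \epsilon}
#' by REML, with the same contemporary-group fixed factor as step 1 (step-1
#' covariates are not carried over), direct additive dispersion effects
#' `a* ~ N(0, A sigma2_Av_exp)`, optional maternal dispersion effects, and
#' homoscedastic residual `sigma2_eps`. Dispersion EBVs are returned for
#' every pedigree animal.
#'
#' @param step1 a converged [fit_animal_model()] object, or a
#'   `"dispersion_response"` (then `data` and `ped` are required).
#' @param data,ped required when `step1` is a response object; otherwise
#'   taken from the step-1 fit.
#' @param transform passed to [dispersion_response()] when `step1` is an
#'   `"animal_fit"`.
#' @param maternal include maternal additive effects on the dispersion.
#' @param direct include direct additive effects (set `FALSE` for the
#'   fixed-effects-only reduced model of the likelihood-ratio test).
#' @param init,control see [fit_animal_model()].
#' @return object of class `"dispersion_fit"` with components
#'   `sigma2_Av_exp`, `sigma2_m_exp` (or `NA`), `sigma2_eps`, `fixed`,
#'   `ebv` (dispersion EBVs a*, log scale), `h2_ln` and its `h2_ln_se`,
#'   `loglik`, plus the response bookkeeping.
#' @export
fit_dispersion_model <- function(step1, data = NULL, ped = NULL,
                                 transform = "log", maternal = FALSE,
                                 direct = TRUE, init = NULL,
                                 control = reml_control()) {
  if (inherits(step1, "animal_fit")) {
    resp <- dispersion_response(residuals(step1), transform)
    data <- step1$data
    ped <- step1$ped
    cg_var <- step1$design$labels[1L]
  } else if (inherits(step1, "dispersion_response")) {
    resp <- step1
    if (is.null(data) || is.null(ped))
      stop("data and ped are required with a raw dispersion_response")
    cg_var <- "cg"
  } else stop("step1 must be an animal_fit or a dispersion_response")
  if (length(resp$values) != nrow(data))
    stop("response and data are not aligned")

  d2 <- data
  d2$.disp <- as.numeric(resp$values)
  fml <- stats::reformulate(cg_var, response = ".disp")

  n <- nrow(d2)
  aidx <- ped_index(ped, d2$animal)
  des <- build_fixed_design(fml, d2)
  fac <- inbreeding(ped)
  uf <- ainv_factor(ped, fac)
  terms_list <- list()
  if (direct) {
    terms_list <- c(terms_list, list(reml_term(
      "sigma2_Av_exp",
      Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                           dims = c(n, ped$n)),
      uf$u, uf$logdet_a)))
  }
  if (maternal) {
    if (!"dam" %in% names(d2)) stop("maternal term needs a 'dam' column")
    known <- !is.na(d2$dam)
    didx <- rep(NA_integer_, n)
    didx[known] <- ped_index(ped, d2$dam[known])
    terms_list <- c(terms_list, list(reml_term(
      "sigma2_m_exp",
      Matrix::sparseMatrix(i = which(known), j = didx[known], x = 1,
                           dims = c(n, ped$n)),
      uf$u, uf$logdet_a)))
  }

  eng <- reml_fit_engine(des$y, des$X, terms_list, rep(1L, n),
                         init = init, control = control)

  r <- length(terms_list)
  comp_names <- c(vapply(terms_list, `[[`, "", "name"), "sigma2_eps")
  sigma2_Av <- if (direct) eng$theta[1L] else NA_real_
  sigma2_m <- if (maternal) eng$theta[r] else NA_real_
  sigma2_eps <- eng$theta[r + 1L]

  # log-scale heritability of the response and its delta-method SE
  h2_ln <- h2_ln_se <- NA_real_
  if (direct) {
    tot <- sum(eng$theta)
    h2_ln <- sigma2_Av / tot
    if (!is.null(eng$vcov_theta)) {
      # delta method on h2 = s2Av / sum(theta)
      g <- rep(-sigma2_Av / tot^2, length(eng$theta))
      g[1L] <- (tot - sigma2_Av) / tot^2
      h2_ln_se <- sqrt(max(as.numeric(t(g) %*% eng$vcov_theta %*% g), 0))
    }
  }

  out <- list(
    call = match.call(), transform = resp$transform,
    floored_count = resp$floored_count,
    n = n, rank_x = ncol(des$X),
    components = data.frame(component = comp_names, estimate = eng$theta,
                            se = eng$se, boundary = eng$boundary,
                            stringsAsFactors = FALSE),
    sigma2_Av_exp = sigma2_Av, sigma2_m_exp = sigma2_m,
    sigma2_eps = sigma2_eps,
    fixed = setNames(eng$fixed, colnames(des$X)),
    ebv = if (direct) setNames(eng$u_hat[[1L]], ped$id),
    maternal_ebv = if (maternal) setNames(eng$u_hat[[r]], ped$id),
    residuals = setNames(eng$residuals, d2$animal),
    response = resp,
    h2_ln = h2_ln, h2_ln_se = h2_ln_se,
    loglik = eng$logLik, n_varcomp = length(eng$theta),
    boundary = any(eng$boundary), iterations = eng$iterations,
    vcov_theta = eng$vcov_theta,
    data = data, ped = ped
  )
  class(out) <- "dispersion_fit"
  out
}

#' @method print dispersion_fit
#' @export
print.dispersion_fit <- function(x, ...) {
  cat("Dispersion model REML fit on ",
      if (x$transform == "log") "ln(e^2)" else "(e^2)^(1/3)",
      " (", x$n, " records)\n", sep = "")
  if (x$floored_count > 0L)
    cat("  ", x$floored_count, "squared residuals raised to the floor\n")
  print(x$components, row.names = FALSE, digits = 4)
  if (!is.na(x$h2_ln))
    cat(sprintf("  h2 of the response = %.4f (se %.4f)\n",
                x$h2_ln, x$h2_ln_se))
  cat(sprintf("  logLik(REML) = %.4f after %d iterations\n",
              x$loglik, x$iterations))
  invisible(x)
}

#' @method logLik dispersion_fit
#' @export
logLik.dispersion_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_varcomp,
            nobs = object$n - object$rank_x, class = "logLik")
}

#' @method coef dispersion_fit
#' @export
coef.dispersion_fit <- function(object, ...) object$fixed

#' @method residuals dispersion_fit
#' @export
residuals.dispersion_fit <- function(object, ...) object$residuals

#' Likelihood-ratio comparison of nested dispersion models
#'
#' Tests the random terms present in `full` but not in `reduced`. Because a
#' variance component is tested on the boundary of its parameter space, the
#' reference distribution for a single component is the equal mixture of a
#' point mass at zero and chi-square(1); for `df > 1` the plain
#' chi-square(df) is used (conservative). The naive chi-square p-value is
#' reported alongside.
#'
#' @param full,reduced fits from [fit_dispersion_model()] (or any objects
#'   with `logLik` methods and `n_varcomp` elements) on the same data with
#'   the same fixed effects.
#' @return list of class `"model_comparison"`: `lrt`, `df`, `p_value`
#'   (mixture), `p_naive`, `delta_aic`, `delta_bic` (full minus reduced) and
#'   the favoured model per criterion.
#' @export
compare_models <- function(full, reduced) {
  if (full$n != reduced$n || full$rank_x != reduced$rank_x)
    stop("models must share data and fixed effects")
  df <- full$n_varcomp - reduced$n_varcomp
  if (df <= 0) stop("'full' must have more variance components")
  lrt <- 2 * (full$loglik - reduced$loglik)
  if (lrt < 0) {
    warning("negative LRT statistic (", format(lrt),
            ") clipped to zero; check convergence")
    lrt <- 0
  }
  p_naive <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  p_mix <- if (df == 1L) {
    if (lrt == 0) 1 else 0.5 * p_naive
  } else p_naive
  ic_f <- information_criteria(full)
  ic_r <- information_criteria(reduced)
  structure(list(
    lrt = lrt, df = df, p_value = p_mix, p_naive = p_naive,
    delta_aic = ic_f[["aic"]] - ic_r[["aic"]],
    delta_bic = ic_f[["bic"]] - ic_r[["bic"]],
    favored = c(
      lrt = if (p_mix < 0.05) "full" else "reduced",
      aic = if (ic_f[["aic"]] < ic_r[["aic"]]) "full" else "reduced",
      bic = if (ic_f[["bic"]] < ic_r[["bic"]]) "full" else "reduced")
  ), class = "model_comparison")
}

#' @method print model_comparison
#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT = %.4f on %d component(s): mixture p = %.4g (naive %.4g)\n",
              x$lrt, x$df, x$p_value, x$p_naive))
  cat(sprintf("  dAIC = %.2f  dBIC = %.2f (full - reduced)\n",
              x$delta_aic, x$delta_bic))
  cat("  favored:", paste(names(x$favored), x$favored, sep = "=",
                          collapse = "  "), "\n")
  invisible(x)
}

#' Sample skewness and excess kurtosis
#'
#' Standard moment-based diagnostics of the dispersion response: the log of
#' a squared standard-normal residual has skewness about -1.53 and excess
#' kurtosis about 4; shrunk BLUP residuals move these towards the values
#' seen in practice.
#'
#' @param x numeric vector (length >= 4) or a `"dispersion_response"`.
#' @return named vector `c(skewness, excess_kurtosis)`.
#' @export
response_moments <- function(x) {
  if (inherits(x, "dispersion_response")) x <- x$values
  if (length(x) < 4L) stop("need at least 4 records")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("zero variance response")
  c(skewness = mean((x - m)^3) / v^1.5,
    excess_kurtosis = mean((x - m)^4) / v^2 - 3)
}
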