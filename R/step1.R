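# Step 1: animal-model REML for the trait, with homogeneous (HOM) or
# sire-family-specific (HET) residual variances.

# Build the sparse fixed-effect design. The first right-hand-side term must
# be a factor (the contemporary group); it is coded as cell means, so its
# solutions are directly the CG effects. Later factors are treatment-coded
# against their first level; numeric terms enter as given.
build_fixed_design <- function(formula, data) {
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0L) stop("the fixed part must contain at least a CG factor")
  resp <- as.character(attr(tt, "variables"))[attr(tt, "response") + 1L]
  y <- data[[resp]]
  if (is.null(y)) stop("response '", resp, "' not found in data")

  is_fac <- vapply(labels, function(l) {
    v <- tryCatch(eval(parse(text = l), data), error = function(e) NULL)
    is.factor(v) || is.character(v)
  }, TRUE)
  if (!is_fac[1L])
    stop("the first fixed term must be a grouping factor (contemporary group)")

  # build the design blocks directly: cell means for the first factor,
  # drop-first dummies for later factors, numeric terms as given; this
  # also handles single-level factors, which model.matrix refuses
  n <- nrow(data)
  blocks <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (is_fac[i]) {
      f <- factor(eval(parse(text = l), data))
      lev <- levels(f)
      keep <- if (i == 1L) lev else lev[-1L]
      j <- match(as.character(f), keep)
      rows <- which(!is.na(j))
      blocks[[i]] <- Matrix::sparseMatrix(
        i = rows, j = j[rows], x = 1, dims = c(n, length(keep)),
        dimnames = list(NULL, paste0(l, keep)))
    } else {
      v <- as.numeric(eval(parse(text = l), data))
      blocks[[i]] <- Matrix::Matrix(v, ncol = 1, sparse = TRUE,
                                    dimnames = list(NULL, l))
    }
  }
  X <- Reduce(Matrix::cbind2, blocks)
  X <- methods::as(X, "CsparseMatrix")

  XtX <- as.matrix(Matrix::crossprod(X))
  qrx <- qr(XtX)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("fixed design is singular; confounded columns: ",
         paste(aliased, collapse = ", "))
  }
  xlev <- lapply(data[labels[is_fac]], function(v) levels(factor(v)))
  list(y = as.numeric(y), X = X, response = resp, labels = labels,
       is_factor = is_fac, xlev = xlev)
}

# residual grouping for the HET structure: one class per sire family,
# records with an unknown sire share a single pooled class
het_resid_groups <- function(sire) {
  lev <- sort(unique(sire[!is.na(sire)]))
  g <- match(sire, lev)
  labels <- paste0("sigma2_e.", lev)
  if (anyNA(g)) {
    g[is.na(g)] <- length(lev) + 1L
    labels <- c(labels, "sigma2_e.(pooled)")
  }
  list(group = g, labels = labels)
}

#' Fit the trait animal model by REML
#'
#' Fits the univariate animal model
#' \deqn{y = Xb + Z_1 a + Z_2 m + W c + e}
#' with direct additive genetic effects `a ~ N(0, A sigma2_a)` (always
#' present), optional maternal additive effects `m ~ N(0, A sigma2_m)` and
#' maternal permanent environmental effects `c ~ N(0, I sigma2_c)`, and
#' residuals that are either homoscedastic (`residual = "hom"`) or carry one
#' variance per sire family (`residual = "het_sire"`). The direct-maternal
#' genetic covariance is fixed at zero. Estimation is by average-information
#' REML with expectation-maximisation fallback steps (see [reml_control()]).
#'
#' @param formula fixed-effect formula, e.g. `y ~ cg` or
#'   `y ~ cg + age + I(age^2)`. The first right-hand-side term must be the
#'   contemporary-group factor; further factors are treatment-coded and
#'   numeric covariates enter as given.
#' @param data data.frame with the model variables plus `animal` and, for
#'   `"het_sire"` or maternal terms, `sire` / `dam` columns of tokens
#'   (`NA` = unknown).
#' @param ped a [pedigree()] covering every animal in `data`.
#' @param residual `"hom"` for a single residual variance, `"het_sire"` for
#'   one residual variance per sire family (unknown-sire records pool into
#'   one extra class).
#' @param maternal include maternal additive genetic effects.
#' @param maternal_pe include maternal permanent environmental effects.
#' @param init optional start values for the variance components, in the
#'   order direct, (maternal), (maternal PE), residual group(s).
#' @param control a [reml_control()] list.
#' @return An object of class `"animal_fit"`; see Details.
#' @details The returned object has elements `components` (data.frame of
#'   variance components with approximate standard errors from the inverse
#'   average-information matrix and a boundary flag), `fixed` (named fixed
#'   solutions), `ebv` (direct EBVs, one per pedigree animal),
#'   `maternal_ebv`, `pe`, `residuals` (per record, `y` minus all fitted
#'   fixed and random effects), `loglik`, `h2_direct`, and the data/pedigree
#'   references needed by the second step. `logLik()`, `AIC()` and `BIC()`
#'   work as usual; the information criteria count only the free variance
#'   components as parameters and `BIC()` uses `n - rank(X)` as sample size.
#' @export
fit_animal_model <- function(formula, data, ped,
                             residual = c("hom", "het_sire"),
                             maternal = FALSE, maternal_pe = FALSE,
                             init = NULL, control = reml_control()) {
  residual <- match.arg(residual)
  stopifnot(inherits(ped, "pedigree"))
  if (!"animal" %in% names(data)) stop("data must have an 'animal' column")
  des <- build_fixed_design(formula, data)
  n <- nrow(data)
  aidx <- ped_index(ped, data$animal)

  fac <- inbreeding(ped)
  uf <- ainv_factor(ped, fac)
  terms_list <- list(reml_term(
    "sigma2_a",
    Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                         dims = c(n, ped$n)),
    uf$u, uf$logdet_a))

  if (maternal || maternal_pe) {
    if (!"dam" %in% names(data)) stop("maternal terms need a 'dam' column")
    known <- !is.na(data$dam)
    didx <- rep(NA_integer_, n)
    didx[known] <- ped_index(ped, data$dam[known])
    if (maternal) {
      terms_list <- c(terms_list, list(reml_term(
        "sigma2_m",
        Matrix::sparseMatrix(i = which(known), j = didx[known], x = 1,
                             dims = c(n, ped$n)),
        uf$u, uf$logdet_a)))
    }
    if (maternal_pe) {
      dlev <- sort(unique(data$dam[known]))
      terms_list <- c(terms_list, list(reml_term(
        "sigma2_c",
        Matrix::sparseMatrix(i = which(known),
                             j = match(data$dam[known], dlev), x = 1,
                             dims = c(n, length(dlev))),
        Matrix::Diagonal(length(dlev)), 0)))
    }
  }

  if (residual == "hom") {
    groups <- list(group = rep(1L, n), labels = "sigma2_e")
  } else {
    if (!"sire" %in% names(data)) stop("het_sire needs a 'sire' column")
    groups <- het_resid_groups(data$sire)
  }

  eng <- reml_fit_engine(des$y, des$X, terms_list, groups$group,
                         init = init, control = control)

  r <- length(terms_list)
  comp_names <- c(vapply(terms_list, `[[`, "", "name"), groups$labels)
  components <- data.frame(
    component = comp_names,
    estimate = eng$theta,
    se = eng$se,
    boundary = eng$boundary,
    stringsAsFactors = FALSE
  )
  resid_var <- eng$theta[r + seq_along(groups$labels)]
  names(resid_var) <- if (residual == "hom") "e" else
    sub("^sigma2_e\\.", "", groups$labels)
  sigma2_a <- eng$theta[1L]
  sigma2_m <- if (maternal) eng$theta[2L] else NA_real_
  sigma2_c <- if (maternal_pe) eng$theta[r] else NA_real_
  sigma2_p <- sigma2_a + sum(c(sigma2_m, sigma2_c), na.rm = TRUE) +
    mean(resid_var)

  out <- list(
    call = match.call(), formula = formula, residual = residual,
    maternal = maternal, maternal_pe = maternal_pe,
    n = n, rank_x = ncol(des$X),
    fixed = setNames(eng$fixed, colnames(des$X)),
    components = components,
    sigma2_a = sigma2_a, sigma2_m = sigma2_m, sigma2_c = sigma2_c,
    resid_var = resid_var,
    ebv = setNames(eng$u_hat[[1L]], ped$id),
    maternal_ebv = if (maternal) setNames(eng$u_hat[[2L]], ped$id),
    residuals = setNames(eng$residuals, data$animal),
    resid_group = setNames(groups$group, data$animal),
    h2_direct = sigma2_a / sigma2_p,
    loglik = eng$logLik, n_varcomp = length(eng$theta),
    boundary = any(eng$boundary), iterations = eng$iterations,
    vcov_theta = eng$vcov_theta,
    design = des[c("response", "labels", "is_factor", "xlev")],
    data = data, ped = ped
  )
  class(out) <- "animal_fit"
  out
}

#' @method print animal_fit
#' @export
print.animal_fit <- function(x, ...) {
  cat("Animal model REML fit (", toupper(x$residual), " residuals )\n",
      sep = "")
  cat("  records:", x$n, " pedigree animals:", x$ped$n, "\n")
  cat(sprintf("  logLik(REML) = %.4f after %d iterations\n",
              x$loglik, x$iterations))
  comp <- x$components
  if (nrow(comp) > 8L)
    comp <- rbind(comp[seq_len(4L), ],
                  data.frame(component = sprintf("... %d more residual classes",
                                                 nrow(x$components) - 8L),
                             estimate = NA, se = NA, boundary = NA),
                  comp[seq(nrow(comp) - 3L, nrow(comp)), ])
  print(comp, row.names = FALSE, digits = 4)
  cat(sprintf("  h2 (direct) = %.3f\n", x$h2_direct))
  invisible(x)
}

#' @method summary animal_fit
#' @export
summary.animal_fit <- function(object, ...) {
  ic <- information_criteria(object)
  structure(list(fit = object, aic = ic[["aic"]], bic = ic[["bic"]]),
            class = "summary.animal_fit")
}

#' @method print summary.animal_fit
#' @export
print.summary.animal_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC = %.2f  BIC = %.2f  (p = %d variance components)\n",
              x$aic, x$bic, x$fit$n_varcomp))
  invisible(x)
}

#' @method coef animal_fit
#' @export
coef.animal_fit <- function(object, ...) object$fixed

#' @method residuals animal_fit
#' @export
residuals.animal_fit <- function(object, ...) object$residuals

#' @method fitted animal_fit
#' @export
fitted.animal_fit <- function(object, ...) {
  object$data[[object$design$response]] - object$residuals
}

#' @method logLik animal_fit
#' @export
logLik.animal_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_varcomp,
            nobs = object$n - object$rank_x, class = "logLik")
}

#' Information criteria of a REML fit
#'
#' AIC = -2 logL + 2 p and BIC = -2 logL + p log(n - rank(X)), with p the
#' number of free variance components (REML solutions are predictions, not
#' parameters) and the BIC sample size the residual degrees of freedom.
#'
#' @param fit an `"animal_fit"` or `"dispersion_fit"` object.
#' @return named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  ll <- logLik(fit)
  c(aic = stats::AIC(ll), bic = stats::BIC(ll))
}

#' Predict records from a fitted animal model
#'
#' Fixed effects are looked up from the solutions (a contemporary group not
#' seen in training is predicted by the mean of the fitted CG effects);
#' random effects are the pedigree-propagated BLUPs of the record's animal
#' (and dam, for maternal terms).
#'
#' @param object an `"animal_fit"`.
#' @param newdata data.frame with the model variables plus `animal` (and
#'   `dam` when maternal terms are in the model).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @method predict animal_fit
#' @export
predict.animal_fit <- function(object, newdata, ...) {
  des <- object$design
  pred <- numeric(nrow(newdata))
  first <- TRUE
  for (i in seq_along(des$labels)) {
    lab <- des$labels[i]
    if (des$is_factor[i]) {
      lev <- as.character(newdata[[lab]])
      cn <- paste0(lab, lev)
      val <- object$fixed[cn]
      if (first) {
        # unseen CG: grand mean of fitted CG effects
        cg_coef <- object$fixed[startsWith(names(object$fixed), lab)]
        val[is.na(val)] <- mean(cg_coef)
        first <- FALSE
      } else {
        val[is.na(val)] <- 0  # reference or unseen level
      }
      pred <- pred + as.numeric(val)
    } else {
      x <- eval(parse(text = lab), newdata)
      pred <- pred + as.numeric(x) * object$fixed[[lab]]
    }
  }
  pred <- pred + object$ebv[ped_index(object$ped, newdata$animal)]
  if (object$maternal || !is.null(object$maternal_ebv)) {
    if (!is.null(object$maternal_ebv) && "dam" %in% names(newdata)) {
      known <- !is.na(newdata$dam)
      pred[known] <- pred[known] +
        object$maternal_ebv[ped_index(object$ped, newdata$dam[known])]
    }
  }
  unname(pred)
}

#' k-fold cross-validation of the animal model
#'
#' Randomly partitions the records into `k` near-equal folds, refits the
#' model on each training set and predicts the held-out records as fitted
#' fixed effects plus pedigree-propagated BLUPs. Partitions in which some
#' contemporary group falls entirely inside one fold are re-randomised a
#' bounded number of times; if that fails, the offending CGs are predicted
#' by the mean fitted CG effect (with a warning).
#'
#' @inheritParams fit_animal_model
#' @param k number of folds (>= 2).
#' @param seed integer seed for the partition.
#' @param ... passed on to [fit_animal_model()].
#' @return list with `mse` (mean of per-fold MSEs), `fold_mse`, `k`,
#'   and `folds` (the record partition).
#' @export
cross_validate <- function(formula, data, ped, k = 10, seed = 1, ...) {
  stopifnot(k >= 2, nrow(data) >= k)
  des <- build_fixed_design(formula, data)
  cg_var <- des$labels[1L]
  set.seed(derive_seed(seed, "cv_partition"))
  n <- nrow(data)
  for (try in 1:10) {
    folds <- sample(rep_len(seq_len(k), n))
    spread <- tapply(folds, data[[cg_var]],
                     function(f) length(unique(f)))
    if (all(spread >= 2L)) break
  }
  if (any(spread < 2L))
    warning("CG(s) confined to one fold after retries: ",
            paste(names(spread)[spread < 2L], collapse = ", "),
            "; they are predicted by the mean CG effect")

  fold_mse <- numeric(k)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    fit <- fit_animal_model(formula, train, ped, ...)
    pred <- predict(fit, test)
    fold_mse[f] <- mean((test[[des$response]] - pred)^2)
  }
  list(mse = mean(fold_mse), fold_mse = fold_mse, k = k, folds = folds)
}
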