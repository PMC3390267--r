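# Genetic parameters of residual variance: scale conversion, evolvability,
# heritability of residual variance, and the sire-EBV correlation.

#' Reference residual variance of a step-1 fit
#'
#' The residual variance used to anchor the dispersion-scale conversion:
#' the REML estimate under the HOM model, or the unweighted mean of the
#' sire-family residual variances under the HET model (the pooled class for
#' unknown-sire records, if present, is not a sire family and is excluded).
#'
#' @param step1 an `"animal_fit"`.
#' @return scalar residual variance, kg^2.
#' @export
reference_residual_variance <- function(step1) {
  stopifnot(inherits(step1, "animal_fit"))
  v <- step1$resid_var
  if (step1$residual == "hom") return(unname(v))
  mean(v[names(v) != "(pooled)"])
}

#' Convert a log-scale dispersion variance to the residual-variance scale
#'
#' Under the multiplicative exponential model the residual variance of an
#' animal is lognormal, so the additive variance of the residual variance is
#' \deqn{\sigma^2_{AV} = (\sigma^2_{\hat e})^2 (\exp(\sigma^2_{Av,exp}) - 1),}
#' the lognormal variance identity anchored at the reference residual
#' variance.
#'
#' @param sigma2_Av_exp additive variance of the log residual variance.
#' @param sigma2_e reference residual variance (see
#'   [reference_residual_variance()]), kg^2.
#' @return additive variance of residual variance, kg^4.
#' @export
sigma2_av_from_exp <- function(sigma2_Av_exp, sigma2_e) {
  stopifnot(sigma2_Av_exp >= 0, sigma2_e >= 0)
  sigma2_e^2 * (exp(sigma2_Av_exp) - 1)
}

#' Evolvability of residual variance
#'
#' The genetic coefficient of variation of the residual variance,
#' \eqn{Ev = \sigma_{AV} / \sigma^2_{\hat e}}, in percent. It measures the
#' scope for changing the average residual variance by selection, and is
#' scale-free: from [sigma2_av_from_exp()], \eqn{Ev =
#' \sqrt{\exp(\sigma^2_{Av,exp}) - 1}} whatever the reference variance.
#'
#' @param sigma2_av additive variance of residual variance, kg^4.
#' @param sigma2_e reference residual variance, kg^2 (> 0).
#' @return evolvability, %.
#' @export
evolvability <- function(sigma2_av, sigma2_e) {
  if (sigma2_e <= 0) stop("sigma2_e must be > 0")
  stopifnot(sigma2_av >= 0)
  100 * sqrt(sigma2_av) / sigma2_e
}

#' Heritability of residual variance
#'
#' The regression of dispersion breeding values on squared phenotypes,
#' \deqn{h^2_v = \sigma^2_{AV} / (2 \sigma^4_P + 3 \sigma^2_{AV}),}
#' the key parameter governing how much information is needed for accurate
#' dispersion EBVs. An approximate standard error can be attached by
#' first-order propagation from the log-scale heritability.
#'
#' @param sigma2_av additive variance of residual variance, kg^4.
#' @param sigma2_p phenotypic variance, kg^2 (> 0).
#' @return heritability of residual variance (proportion, not %).
#' @export
h2v <- function(sigma2_av, sigma2_p) {
  if (sigma2_p <= 0) stop("sigma2_p must be > 0")
  stopifnot(sigma2_av >= 0)
  sigma2_av / (2 * sigma2_p^2 + 3 * sigma2_av)
}

#' Pearson correlation of sire EBVs for mean and dispersion
#'
#' A rough indicator of the genetic correlation between the trait mean and
#' its residual variance: the correlation of sire EBVs from the two steps,
#' restricted to sires with more than `min_progeny` progeny so that both
#' EBVs are reasonably accurate.
#'
#' @param mean_ebv,dispersion_ebv aligned named vectors of sire EBVs.
#' @param progeny_count progeny counts aligned with the EBV vectors.
#' @param min_progeny only sires with `progeny_count > min_progeny` enter.
#' @return Pearson correlation over the qualifying sires.
#' @export
ebv_correlation <- function(mean_ebv, dispersion_ebv, progeny_count,
                            min_progeny = 50) {
  stopifnot(length(mean_ebv) == length(dispersion_ebv),
            length(progeny_count) == length(mean_ebv))
  keep <- progeny_count > min_progeny
  if (sum(keep) < 3L)
    stop("fewer than 3 sires with more than ", min_progeny, " progeny")
  x <- mean_ebv[keep]; y <- dispersion_ebv[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant EBV vector: correlation undefined")
  stats::cor(x, y)
}

#' Summary of genetic parameters for residual variance
#'
#' Combines a step-1 and step-2 fit into the one-row parameter table used
#' to report each (trait, model) analysis: the log-scale components, the
#' residual-scale additive variance, evolvability, heritability of residual
#' variance and the sire-EBV correlation.
#'
#' @param step1 an `"animal_fit"`.
#' @param step2 a `"dispersion_fit"` from the same data.
#' @param min_progeny sire progeny threshold for the EBV correlation.
#' @return one-row data.frame with columns `model`, `sigma2_Av_exp`,
#'   `sigma2_m_exp`, `sigma2_AV`, `ev_pct`, `h2v_pct`, `h2_ln`, `h2_ln_se`,
#'   `r_mv_hat`, `sigma2_e_ref`.
#' @export
dispersion_summary <- function(step1, step2, min_progeny = 50) {
  stopifnot(inherits(step1, "animal_fit"), inherits(step2, "dispersion_fit"))
  s2e <- reference_residual_variance(step1)
  s2av <- sigma2_av_from_exp(step2$sigma2_Av_exp, s2e)
  s2p <- step1$sigma2_a +
    sum(c(step1$sigma2_m, step1$sigma2_c), na.rm = TRUE) + s2e
  counts <- sire_progeny_counts(step1$ped)
  sires <- names(counts)
  r_mv <- tryCatch(
    ebv_correlation(step1$ebv[sires], step2$ebv[sires], counts,
                    min_progeny = min_progeny),
    error = function(e) NA_real_)
  data.frame(
    model = toupper(step1$residual),
    sigma2_Av_exp = step2$sigma2_Av_exp,
    sigma2_m_exp = step2$sigma2_m_exp,
    sigma2_AV = s2av,
    ev_pct = evolvability(s2av, s2e),
    h2v_pct = 100 * h2v(s2av, s2p),
    h2_ln = step2$h2_ln, h2_ln_se = step2$h2_ln_se,
    r_mv_hat = r_mv,
    sigma2_e_ref = s2e,
    stringsAsFactors = FALSE
  )
}

# progeny counts per sire (named by sire token), from the pedigree
sire_progeny_counts <- function(ped) {
  s <- ped$sire[!is.na(ped$sire)]
  tab <- table(ped$id[s])
  setNames(as.integer(tab), names(tab))
}
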