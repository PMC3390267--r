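# Replicated simulation study: bias of dispersion-variance estimates and
# accuracy of dispersion EBVs over a scenario grid.

#' Relative bias of an estimator over replicates
#'
#' @param estimates numeric vector of per-replicate estimates (>= 2).
#' @param true_value true parameter value (> 0; for a zero true value use
#'   absolute bias instead).
#' @return named vector: `bias_pct` = 100 (mean - true)/true, `sd` over
#'   replicates, `se` = sd/sqrt(replicates).
#' @export
relative_bias <- function(estimates, true_value) {
  if (true_value <= 0)
    stop("true_value must be > 0; use absolute bias for a zero true value")
  if (length(estimates) < 2L) stop("need at least 2 estimates")
  s <- stats::sd(estimates)
  c(bias_pct = 100 * (mean(estimates) - true_value) / true_value,
    sd = s, se = s / sqrt(length(estimates)))
}

#' Accuracy of dispersion EBVs by animal group
#'
#' Pearson correlation between true and estimated breeding values over all
#' pedigree animals, over sires (animals with at least one progeny as sire)
#' or over dams.
#'
#' @param truth named numeric vector of true breeding values (pedigree
#'   animals).
#' @param ebv named numeric vector of EBVs aligned with `truth`.
#' @param ped the [pedigree()] defining the groups.
#' @param group `"all"`, `"sires"` or `"dams"`.
#' @return Pearson correlation.
#' @export
ebv_accuracy <- function(truth, ebv, ped, group = c("all", "sires", "dams")) {
  group <- match.arg(group)
  stopifnot(inherits(ped, "pedigree"))
  ids <- switch(group,
    all = ped$id,
    sires = unique(ped$id[ped$sire[!is.na(ped$sire)]]),
    dams = unique(ped$id[ped$dam[!is.na(ped$dam)]]))
  x <- truth[ids]; y <- ebv[ids]
  if (anyNA(x) || anyNA(y)) stop("truth/ebv do not cover the group")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: accuracy undefined")
  stats::cor(x, y)
}

#' Run one simulation scenario of the two-step pipeline
#'
#' For each replicate: simulate a dataset, apply the edit rules, fit the
#' step-1 animal model (HOM or HET residuals), build the log-squared
#' residual response, fit the step-2 dispersion model, and collect the
#' dispersion variance estimate, the sire-EBV correlation and the EBV
#' accuracies by animal group. A failed replicate is logged and redrawn
#' with the next seed (bounded); the scenario aborts if more than 20% of
#' the requested replicates fail.
#'
#' @param design a [sim_design()].
#' @param params a [genetic_params()].
#' @param step1_model `"hom"` or `"het_sire"`.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate r uses the derived stream
#'   `scenario:<r>`.
#' @param rules [edit_rules()] applied inside each replicate.
#' @param transform dispersion response transform (`"log"` or `"cuberoot"`).
#' @param control [reml_control()] for both REML fits.
#' @param min_progeny sire progeny threshold for the EBV correlation.
#' @return list of class `"scenario_result"`: `replicates` (data.frame, one
#'   row per replicate), `scenario` (the inputs), `failures` (messages).
#' @export
run_scenario <- function(design, params, step1_model = c("hom", "het_sire"),
                         n_reps = 5, seed = 1, rules = edit_rules(),
                         transform = "log", control = reml_control(),
                         min_progeny = 50) {
  step1_model <- match.arg(step1_model)
  reps <- vector("list", n_reps)
  failures <- character(0)
  max_fail <- ceiling(0.2 * n_reps)
  r_done <- 0L
  draw <- 0L
  while (r_done < n_reps) {
    draw <- draw + 1L
    rep_seed <- derive_seed(seed, paste0("scenario:", draw))
    res <- tryCatch(
      run_replicate(design, params, step1_model, rep_seed, rules,
                    transform, control, min_progeny),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("draw %d (seed %d): %s", draw,
                                      rep_seed, conditionMessage(res)))
      if (length(failures) > max_fail)
        stop("scenario aborted: ", length(failures),
             " replicate failures\n", paste(failures, collapse = "\n"))
      next
    }
    r_done <- r_done + 1L
    res$replicate <- r_done
    res$seed <- rep_seed
    reps[[r_done]] <- res
  }
  structure(list(
    replicates = do.call(rbind, lapply(reps, as.data.frame)),
    scenario = list(design = design, params = params,
                    step1_model = step1_model, n_reps = n_reps,
                    seed = seed, transform = transform),
    failures = failures
  ), class = "scenario_result")
}

# one full replicate: simulate -> edit -> step 1 -> step 2 -> summaries
run_replicate <- function(design, params, step1_model, rep_seed, rules,
                          transform, control, min_progeny) {
  sim <- simulate_dataset(design, params, rep_seed)
  dat <- apply_edit_rules(sim$data, rules)
  s1 <- fit_animal_model(y ~ cg, dat, sim$ped, residual = step1_model,
                         control = control)
  s2 <- fit_dispersion_model(s1, transform = transform, control = control)
  gp <- dispersion_summary(s1, s2, min_progeny = min_progeny)
  truth_av <- sim$truth$a_v
  list(
    sigma2_Av_exp_hat = s2$sigma2_Av_exp,
    sigma2_a_hat = s1$sigma2_a,
    sigma2_e_hat = reference_residual_variance(s1),
    h2_ln = s2$h2_ln,
    r_mv_hat = gp$r_mv_hat,
    acc_all = ebv_accuracy(truth_av, s2$ebv, sim$ped, "all"),
    acc_sires = ebv_accuracy(truth_av, s2$ebv, sim$ped, "sires"),
    acc_dams = ebv_accuracy(truth_av, s2$ebv, sim$ped, "dams"),
    n_records = nrow(dat)
  )
}

#' @method print scenario_result
#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Scenario: %s step 1, sigma2_Av_exp = %g, r_mv = %g (%d replicates)\n",
    toupper(sub("_sire", "", s$step1_model)), s$params$sigma2_Av_exp,
    s$params$r_mv, nrow(x$replicates)))
  print(x$replicates, row.names = FALSE, digits = 3)
  if (length(x$failures) > 0L)
    cat("  redrawn replicates:", length(x$failures), "\n")
  invisible(x)
}

#' Summarise scenario results into bias and accuracy tables
#'
#' Deterministic aggregation of one or more [run_scenario()] results:
#' per scenario and step-1 model, the relative bias of the dispersion
#' variance estimate (with SD and SE over replicates), the mean sire-EBV
#' correlation, and the mean EBV accuracies by animal group. With a single
#' replicate the dispersion measures are reported as `NA`.
#'
#' @param ... `"scenario_result"` objects (or one list of them).
#' @return list of class `"mc_summary"` with data.frames `bias` and
#'   `accuracy`, one row per scenario.
#' @export
summarize_mc <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1L]], "scenario_result"))
    args <- args[[1L]]
  stopifnot(all(vapply(args, inherits, TRUE, "scenario_result")))
  one <- function(sc) {
    r <- sc$replicates
    p <- sc$scenario$params
    true_av <- p$sigma2_Av_exp
    nrep <- nrow(r)
    msd <- function(x) if (nrep > 1L) stats::sd(x) else NA_real_
    bias <- if (true_av > 0 && nrep > 1L)
      relative_bias(r$sigma2_Av_exp_hat, true_av)
    else c(bias_pct = NA_real_, sd = NA_real_, se = NA_real_)
    data.frame(
      model = toupper(sub("_sire", "", sc$scenario$step1_model)),
      sigma2_Av_exp = true_av, r_mv = p$r_mv, n_reps = nrep,
      mean_est = mean(r$sigma2_Av_exp_hat),
      bias_pct = bias[["bias_pct"]], bias_sd = bias[["sd"]],
      bias_se = bias[["se"]],
      r_mv_hat = mean(r$r_mv_hat), r_mv_hat_se = msd(r$r_mv_hat) / sqrt(nrep),
      acc_all = mean(r$acc_all), acc_all_se = msd(r$acc_all) / sqrt(nrep),
      acc_sires = mean(r$acc_sires),
      acc_sires_se = msd(r$acc_sires) / sqrt(nrep),
      acc_dams = mean(r$acc_dams),
      acc_dams_se = msd(r$acc_dams) / sqrt(nrep),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, lapply(args, one))
  tab <- tab[order(tab$model, tab$sigma2_Av_exp, tab$r_mv), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    bias = tab[c("model", "r_mv", "sigma2_Av_exp", "n_reps", "mean_est",
                 "bias_pct", "bias_sd", "bias_se", "r_mv_hat",
                 "r_mv_hat_se")],
    accuracy = tab[c("model", "r_mv", "sigma2_Av_exp", "n_reps", "acc_all",
                     "acc_all_se", "acc_sires", "acc_sires_se", "acc_dams",
                     "acc_dams_se")]
  ), class = "mc_summary")
}

#' @method print mc_summary
#' @export
print.mc_summary <- function(x, ...) {
  cat("Bias of dispersion-variance estimates (% of true value):\n")
  print(x$bias, row.names = FALSE, digits = 4)
  cat("\nDispersion-EBV accuracy by animal group:\n")
  print(x$accuracy, row.names = FALSE, digits = 3)
  invisible(x)
}
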