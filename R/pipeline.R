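# Configuration-driven end-to-end runs: simulate -> edit -> step 1 ->
# step 2 -> genetic parameters, with a file manifest for reproducibility.

config_spec <- function() {
  list(
    out_dir = list(type = "character", default = NULL),
    seed = list(type = "integer", default = 1L),
    design = list(type = "character", default = "small",
                  allowed = c("small", "full")),
    pedigree = list(type = "character", default = NA_character_),
    phenotypes = list(type = "character", default = NA_character_),
    sigma2_a = list(type = "numeric", default = 200, min = 0),
    sigma2_Av_exp = list(type = "numeric", default = 0.09, min = 0),
    r_mv = list(type = "numeric", default = 0, min = -1, max = 1),
    b_m_min = list(type = "numeric", default = 300),
    b_m_max = list(type = "numeric", default = 400),
    b_v_min = list(type = "numeric", default = 5.40),
    b_v_max = list(type = "numeric", default = 5.80),
    sd_trim = list(type = "numeric", default = 3.5, min = 0),
    min_cg_size = list(type = "integer", default = 25L, min = 1),
    min_sire_progeny = list(type = "integer", default = 50L, min = 1),
    residual = list(type = "character", default = "hom",
                    allowed = c("hom", "het_sire")),
    maternal = list(type = "logical", default = FALSE),
    maternal_pe = list(type = "logical", default = FALSE),
    transform = list(type = "character", default = "log",
                     allowed = c("log", "cuberoot")),
    maternal_step2 = list(type = "logical", default = FALSE),
    min_progeny = list(type = "integer", default = 50L, min = 1),
    tol = list(type = "numeric", default = 1e-7, min = 0),
    max_iter = list(type = "integer", default = 200L, min = 1)
  )
}

#' Validate a plain-text run configuration
#'
#' Parses `key = value` lines (`#` starts a comment). Unknown keys, type
#' mismatches and out-of-range values are all collected and reported
#' together; the parse itself never throws.
#'
#' @param x path to a config file, or a character vector of config lines.
#' @return A list of class `"run_config"` with all keys filled with
#'   documented defaults, or, when anything is invalid, a list of class
#'   `"config_errors"` with an `errors` character vector.
#' @export
validate_config <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  spec <- config_spec()
  cfg <- lapply(spec, `[[`, "default")
  errors <- character(0)

  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      errors <- c(errors, paste0("not a key = value line: '", ln, "'"))
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(spec)) {
      errors <- c(errors, paste0("unknown key '", key, "'"))
      next
    }
    s <- spec[[key]]
    parsed <- switch(s$type,
      character = val,
      logical = if (tolower(val) %in% c("true", "false"))
        as.logical(toupper(val)) else NA,
      integer = suppressWarnings(as.integer(val)),
      numeric = suppressWarnings(as.numeric(val)))
    if (is.na(parsed) && !identical(s$default, NA_character_)) {
      errors <- c(errors, paste0("key '", key, "': cannot parse '", val,
                                 "' as ", s$type))
      next
    }
    if (!is.null(s$allowed) && !parsed %in% s$allowed) {
      errors <- c(errors, paste0("key '", key, "': '", val,
                                 "' not one of ",
                                 paste(s$allowed, collapse = "|")))
      next
    }
    if (!is.null(s$min) && is.numeric(parsed) && parsed < s$min)
      errors <- c(errors, paste0("key '", key, "': ", val, " below ", s$min))
    if (!is.null(s$max) && is.numeric(parsed) && parsed > s$max)
      errors <- c(errors, paste0("key '", key, "': ", val, " above ", s$max))
    cfg[[key]] <- parsed
  }
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir))
    errors <- c(errors, "key 'out_dir' is required")
  ext <- c(pedigree = cfg$pedigree, phenotypes = cfg$phenotypes)
  if (xor(is.na(ext[1L]), is.na(ext[2L])))
    errors <- c(errors, "pedigree and phenotypes must be given together")
  for (k in names(ext)[!is.na(ext)])
    if (!file.exists(ext[[k]]))
      errors <- c(errors, paste0("key '", k, "': file not found: ", ext[[k]]))
  if (cfg$b_m_min > cfg$b_m_max || cfg$b_v_min > cfg$b_v_max)
    errors <- c(errors, "effect ranges must be ordered (min <= max)")

  if (length(errors) > 0L)
    return(structure(list(errors = errors), class = "config_errors"))
  structure(cfg, class = "run_config")
}

#' @method print config_errors
#' @export
print.config_errors <- function(x, ...) {
  cat("Invalid configuration (", length(x$errors), " error(s) ):\n", sep = "")
  for (e in x$errors) cat("  -", e, "\n")
  invisible(x)
}

write_tab <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) format(x, digits = 10, trim = TRUE))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-step pipeline from a configuration
#'
#' Executes simulate (or load) -> edit -> step-1 REML -> step-2 dispersion
#' model -> genetic-parameter summary, writing every stage's outputs under
#' `out_dir` and a `manifest.csv` with an md5 hash per file. Rerunning with
#' the same configuration and seed reproduces every hash. On a stage
#' failure the partial outputs are kept next to a `FAILED` marker file and
#' the returned status is non-zero.
#'
#' @param config a `"run_config"` from [validate_config()] (or a path /
#'   character vector, validated on the fly).
#' @return list with `status` (0 on success), `manifest` (data.frame of
#'   file, md5) and, on success, the fitted objects (`step1`, `step2`,
#'   `params`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (inherits(config, "config_errors")) {
    print(config)
    stop("configuration invalid: fix the errors above")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- "simulate"
  result <- tryCatch({
    ctrl <- reml_control(tol = config$tol, max_iter = config$max_iter)
    if (!is.na(config$pedigree)) {
      ped <- read_pedigree(config$pedigree)
      pheno <- utils::read.table(config$phenotypes, header = TRUE, sep = ",",
                                 stringsAsFactors = FALSE)
      idx <- ped_index(ped, pheno$animal)
      pheno$sire <- ifelse(is.na(ped$sire[idx]), NA_character_,
                           ped$id[ped$sire[idx]])
      pheno$dam <- ifelse(is.na(ped$dam[idx]), NA_character_,
                          ped$id[ped$dam[idx]])
      sim <- NULL
      dat0 <- pheno
    } else {
      des <- if (config$design == "full") sim_design() else design_small()
      par <- genetic_params(config$sigma2_a, config$sigma2_Av_exp,
                            config$r_mv,
                            c(config$b_m_min, config$b_m_max),
                            c(config$b_v_min, config$b_v_max))
      sim <- simulate_dataset(des, par, config$seed)
      ped <- sim$ped
      dat0 <- sim$data
      files <- c(files, write_dataset(sim, file.path(config$out_dir,
                                                     "simulate")))
    }

    stage <- "edit"
    rules <- edit_rules(config$sd_trim, config$min_cg_size,
                        config$min_sire_progeny)
    dat <- apply_edit_rules(dat0, rules)
    log <- attr(dat, "removal_log")
    files <- c(files, write_tab(
      data.frame(rule = names(log), removed = as.integer(log)),
      file.path(config$out_dir, "edit_log.csv")))

    stage <- "step1"
    s1 <- fit_animal_model(y ~ cg, dat, ped, residual = config$residual,
                           maternal = config$maternal,
                           maternal_pe = config$maternal_pe, control = ctrl)
    ic1 <- information_criteria(s1)
    files <- c(files,
      write_tab(s1$components, file.path(config$out_dir,
                                         "step1_components.csv")),
      write_tab(data.frame(effect = "cg", level = names(s1$fixed),
                           estimate = s1$fixed),
                file.path(config$out_dir, "step1_fixed.csv")),
      write_tab(data.frame(animal = names(s1$ebv), ebv = s1$ebv),
                file.path(config$out_dir, "step1_ebv.csv")),
      write_tab(data.frame(animal = names(s1$residuals),
                           residual = s1$residuals),
                file.path(config$out_dir, "step1_residuals.csv")),
      write_tab(data.frame(stat = c("loglik", "aic", "bic", "h2_direct"),
                           value = c(s1$loglik, ic1, s1$h2_direct)),
                file.path(config$out_dir, "step1_fitstats.csv")))

    stage <- "step2"
    s2 <- fit_dispersion_model(s1, transform = config$transform,
                               maternal = config$maternal_step2,
                               control = ctrl)
    s2_null <- fit_dispersion_model(s1, transform = config$transform,
                                    maternal = config$maternal_step2,
                                    direct = FALSE, control = ctrl)
    cmp <- compare_models(s2, s2_null)
    files <- c(files,
      write_tab(s2$components, file.path(config$out_dir,
                                         "step2_components.csv")),
      write_tab(data.frame(animal = names(s2$ebv), ebv = s2$ebv),
                file.path(config$out_dir, "step2_ebv.csv")),
      write_tab(data.frame(stat = c("lrt", "df", "p_mixture", "p_naive",
                                    "delta_aic", "delta_bic"),
                           value = c(cmp$lrt, cmp$df, cmp$p_value,
                                     cmp$p_naive, cmp$delta_aic,
                                     cmp$delta_bic)),
                file.path(config$out_dir, "step2_lrt.csv")))

    stage <- "params"
    gp <- dispersion_summary(s1, s2, min_progeny = config$min_progeny)
    files <- c(files, write_tab(gp, file.path(config$out_dir,
                                              "params_summary.csv")))
    list(step1 = s1, step2 = s2, comparison = cmp, params = gp, sim = sim)
  }, error = function(e) e)

  if (inherits(result, "error")) {
    writeLines(c(paste("stage:", stage), conditionMessage(result)),
               file.path(config$out_dir, "FAILED"))
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(files)))
    return(list(status = 1L, stage = stage,
                error = conditionMessage(result), manifest = manifest))
  }
  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)))
  write_tab(manifest, file.path(config$out_dir, "manifest.csv"))
  c(list(status = 0L, manifest = manifest), result)
}
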