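#' Simulation design for the balanced multi-generation population
#'
#' Describes the balanced population used in the simulation study: a base
#' population of unrecorded sires and dams, a fixed number of discrete
#' offspring generations, random mating with partial replacement of parents
#' each generation, and contemporary groups (CG) composed of fixed-size
#' progeny blocks from a fixed number of sires.
#'
#' The default design produces 5 generations x 5 000 records = 25 000
#' recorded animals from 100 sires and 5 000 dams: every dam has one
#' offspring per generation, every sire has 50, and each CG holds the progeny
#' of five sires, ten offspring each, i.e. 100 CG per generation.
#'
#' @param n_base_sires,n_base_dams base-population counts.
#' @param offspring_per_sire,offspring_per_dam progeny per active parent and
#'   generation.
#' @param n_generations number of recorded generations.
#' @param replacement_rate fraction of active sires and dams replaced each
#'   generation by randomly chosen previous-generation animals of the
#'   correct sex (no selection).
#' @param sires_per_cg,offspring_per_sire_per_cg CG composition; the number
#'   of CG per generation follows as
#'   records / (sires_per_cg * offspring_per_sire_per_cg).
#' @return list of class `"sim_design"`.
#' @seealso [design_small()] for the reduced preset used in replicated runs.
#' @export
sim_design <- function(n_base_sires = 100, n_base_dams = 5000,
                       offspring_per_sire = 50, offspring_per_dam = 1,
                       n_generations = 5, replacement_rate = 0.20,
                       sires_per_cg = 5, offspring_per_sire_per_cg = 10) {
  d <- list(
    n_base_sires = as.integer(n_base_sires),
    n_base_dams = as.integer(n_base_dams),
    offspring_per_sire = as.integer(offspring_per_sire),
    offspring_per_dam = as.integer(offspring_per_dam),
    n_generations = as.integer(n_generations),
    replacement_rate = replacement_rate,
    sires_per_cg = as.integer(sires_per_cg),
    offspring_per_sire_per_cg = as.integer(offspring_per_sire_per_cg)
  )
  rec_gen <- d$n_base_dams * d$offspring_per_dam
  if (rec_gen != d$n_base_sires * d$offspring_per_sire)
    stop("infeasible design: dams x offspring_per_dam must equal ",
         "sires x offspring_per_sire")
  blocks_per_sire <- d$offspring_per_sire / d$offspring_per_sire_per_cg
  if (blocks_per_sire != round(blocks_per_sire))
    stop("infeasible design: offspring_per_sire must be a multiple of ",
         "offspring_per_sire_per_cg")
  d$cg_per_generation <-
    rec_gen %/% (d$sires_per_cg * d$offspring_per_sire_per_cg)
  if (d$cg_per_generation * d$sires_per_cg * d$offspring_per_sire_per_cg
      != rec_gen)
    stop("infeasible design: records per generation not divisible into CG")
  if (d$n_base_sires %% d$sires_per_cg != 0L)
    stop("infeasible design: sire count not divisible by sires_per_cg")
  if (d$replacement_rate < 0 || d$replacement_rate >= 1)
    stop("replacement_rate must be in [0, 1)")
  d$records_per_generation <- rec_gen
  class(d) <- "sim_design"
  d
}

#' Reduced preset of the simulation design
#'
#' A desk-scale version of the full design used for replicated evaluation
#' runs: 2 generations of 20 sires x 1 000 dams (1 000 records per
#' generation), keeping 50 progeny per sire and the 5-sires-by-10-offspring
#' CG composition of the full design.
#'
#' @return list of class `"sim_design"`.
#' @export
design_small <- function() {
  sim_design(n_base_sires = 20, n_base_dams = 1000, n_generations = 2)
}

#' Genetic parameters of the exponential dispersion model
#'
#' Parameters of the generative model for a trait with genetically
#' heterogeneous residual variance,
#' \deqn{y_{ij} = b_{m i} + a_{m ij} + \exp((b_{v i} + a_{v ij})/2)\,
#'       \epsilon_{ij}, \quad \epsilon_{ij} \sim N(0, 1),}
#' where \eqn{b_m, b_v} are fixed CG effects on the mean (kg) and on the log
#' residual variance (log kg^2), and the animal breeding values
#' \eqn{(a_m, a_v)} are bivariate normal with additive variances
#' `sigma2_a` (kg^2) and `sigma2_Av_exp` (log scale) and correlation `r_mv`.
#'
#' Defaults give a trait with mean 350 kg, heritability around 0.40 and
#' phenotypic variance around 480 kg^2.
#'
#' @param sigma2_a additive variance of the trait mean, kg^2.
#' @param sigma2_Av_exp additive variance of the log residual variance.
#' @param r_mv genetic correlation between mean and dispersion effects.
#' @param b_m_range,b_v_range uniform bounds for the CG effects on the mean
#'   and on the log residual variance.
#' @return list of class `"genetic_params"`.
#' @export
genetic_params <- function(sigma2_a = 200, sigma2_Av_exp = 0.09, r_mv = 0,
                           b_m_range = c(300, 400),
                           b_v_range = c(5.40, 5.80)) {
  if (sigma2_a < 0 || sigma2_Av_exp < 0) stop("variances must be >= 0")
  if (abs(r_mv) > 1) stop("|r_mv| must be <= 1")
  if (diff(b_m_range) < 0 || diff(b_v_range) < 0)
    stop("ranges must be ordered")
  structure(
    list(sigma2_a = sigma2_a, sigma2_Av_exp = sigma2_Av_exp, r_mv = r_mv,
         sigma_mv = r_mv * sqrt(sigma2_a * sigma2_Av_exp),
         b_m_range = b_m_range, b_v_range = b_v_range),
    class = "genetic_params"
  )
}

# Deterministic named sub-streams of a master seed, so that pedigree
# structure, CG effects, breeding values and residual draws are
# independently reproducible.
derive_seed <- function(seed, stream) {
  h <- 5381
  for (ch in utf8ToInt(paste0(stream, ":", as.integer(seed))))
    h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

#' Build the multi-generation population structure
#'
#' Simulates the pedigree and CG assignment of [sim_design()]: random mating
#' of active parents, `offspring_per_dam` offspring per dam per generation,
#' each sire's progeny split into blocks of `offspring_per_sire_per_cg`
#' assigned to distinct CG holding `sires_per_cg` sires each, offspring sex
#' Bernoulli(0.5), and partial replacement of active parents by
#' previous-generation animals of the correct sex.
#'
#' @param design a [sim_design()] object.
#' @param seed integer seed (a dedicated stream is derived from it).
#' @return list of class `"population"`: `ped` (a [pedigree()]), `cg`
#'   (data.frame `animal`, `cg` for recorded animals) and the `design`.
#' @export
build_population <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(derive_seed(seed, "pedigree"))
  ns <- design$n_base_sires
  nd <- design$n_base_dams
  fmt <- function(prefix, g, i)
    sprintf("%s%d_%0*d", prefix, g, nchar(as.character(max(i))) + 1L, i)

  id <- c(fmt("S", 0, seq_len(ns)), fmt("D", 0, seq_len(nd)))
  sire <- dam <- rep(NA_character_, ns + nd)
  sex <- c(rep("M", ns), rep("F", nd))
  active_sires <- id[seq_len(ns)]
  active_dams <- id[ns + seq_len(nd)]

  rec_animal <- rec_cg <- character(0)
  n_cg <- design$cg_per_generation
  cg_stride <- ns %/% design$sires_per_cg
  blocks_per_sire <- design$offspring_per_sire %/%
    design$offspring_per_sire_per_cg

  for (g in seq_len(design$n_generations)) {
    # mate: shuffle dams, chunk them across shuffled sires
    sires_g <- sample(active_sires)
    dams_g <- sample(active_dams)
    n_off <- length(dams_g) * design$offspring_per_dam
    off_dam <- rep(dams_g, times = design$offspring_per_dam)
    off_sire <- rep(sires_g, each = design$offspring_per_sire)
    off_id <- fmt("A", g, seq_len(n_off))
    off_sex <- ifelse(stats::runif(n_off) < 0.5, "M", "F")

    # CG: block b (0-based) of sire s (0-based in shuffled order) goes to
    # CG (s + b * stride) mod n_cg, giving each CG sires_per_cg distinct
    # sires with offspring_per_sire_per_cg offspring each
    s_idx <- rep(seq_len(ns) - 1L, each = design$offspring_per_sire)
    b_idx <- rep(rep(seq_len(blocks_per_sire) - 1L,
                     each = design$offspring_per_sire_per_cg), times = ns)
    cg_idx <- (s_idx + b_idx * cg_stride) %% n_cg
    off_cg <- fmt("G", g, cg_idx + 1L)

    id <- c(id, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, off_sex)
    rec_animal <- c(rec_animal, off_id)
    rec_cg <- c(rec_cg, off_cg)

    # replacement for the next generation
    if (g < design$n_generations && design$replacement_rate > 0) {
      n_rs <- round(design$replacement_rate * ns)
      n_rd <- round(design$replacement_rate * nd)
      males <- off_id[off_sex == "M"]
      females <- off_id[off_sex == "F"]
      if (length(males) < n_rs || length(females) < n_rd)
        stop("not enough offspring of required sex for replacement")
      if (n_rs > 0) {
        out_s <- sample(seq_along(active_sires), n_rs)
        active_sires[out_s] <- sample(males, n_rs)
      }
      if (n_rd > 0) {
        out_d <- sample(seq_along(active_dams), n_rd)
        active_dams[out_d] <- sample(females, n_rd)
      }
    }
  }

  ped <- pedigree(id, ifelse(is.na(sire), "0", sire),
                  ifelse(is.na(dam), "0", dam), sex = sex)
  structure(
    list(ped = ped,
         cg = data.frame(animal = rec_animal, cg = rec_cg,
                         stringsAsFactors = FALSE),
         design = design),
    class = "population"
  )
}

#' @method print population
#' @export
print.population <- function(x, ...) {
  cat("Simulated population:", nrow(x$cg), "recorded animals in",
      length(unique(x$cg$cg)), "contemporary groups\n")
  print(x$ped)
  invisible(x)
}

#' Draw true genetic and fixed effects on mean and dispersion
#'
#' Samples contemporary-group effects `b_m ~ U(b_m_range)` and
#' `b_v ~ U(b_v_range)`, and bivariate-normal breeding values `(a_m, a_v)`
#' for every pedigree animal: founders from MVN(0, G_mv) with
#' \eqn{G_{mv} = [\sigma^2_a, \sigma_{mv}; \sigma_{mv}, \sigma^2_{Av,exp}]},
#' non-founders as the parent average plus a Mendelian sampling term with
#' covariance \eqn{0.5 (1 - (F_s + F_d)/2) G_{mv}} (an unknown parent
#' contributes F = 0 and its own term of 0.25 G_mv).
#'
#' @param ped a [pedigree()] object.
#' @param cg_levels character vector of CG identifiers.
#' @param params a [genetic_params()] object.
#' @param seed integer seed (dedicated streams are derived from it).
#' @return list of class `"true_effects"`: `a_m`, `a_v` (named by animal),
#'   `cg`, `b_m`, `b_v` (named by CG).
#' @export
draw_effects <- function(ped, cg_levels, params, seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "genetic_params"))
  cg_levels <- unique(as.character(cg_levels))

  set.seed(derive_seed(seed, "cg_effects"))
  b_m <- stats::runif(length(cg_levels), params$b_m_range[1],
                      params$b_m_range[2])
  b_v <- stats::runif(length(cg_levels), params$b_v_range[1],
                      params$b_v_range[2])

  # lower-triangular factor of G_mv, robust to zero variances
  s2a <- params$sigma2_a; s2v <- params$sigma2_Av_exp; smv <- params$sigma_mv
  l11 <- sqrt(s2a)
  l21 <- if (l11 > 0) smv / l11 else 0
  l22 <- sqrt(max(s2v - l21^2, 0))

  set.seed(derive_seed(seed, "breeding_values"))
  n <- ped$n
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  # Mendelian sampling scaling equals the d of Henderson's rules:
  # 1 for founders, 0.75 - 0.25 F_p with one known parent,
  # 0.5 (1 - (F_s + F_d)/2) with both known
  k <- inbreeding(ped)$d
  a_m <- a_v <- numeric(n)
  # process by generation: parents always lie in earlier generations
  for (g in sort(unique(ped$generation))) {
    i <- which(ped$generation == g)
    s <- ped$sire[i]; d <- ped$dam[i]
    sk <- sqrt(k[i])
    pa_m <- ifelse(is.na(s), 0, a_m[pmax(s, 1)] / 2) +
      ifelse(is.na(d), 0, a_m[pmax(d, 1)] / 2)
    pa_v <- ifelse(is.na(s), 0, a_v[pmax(s, 1)] / 2) +
      ifelse(is.na(d), 0, a_v[pmax(d, 1)] / 2)
    a_m[i] <- pa_m + sk * l11 * z1[i]
    a_v[i] <- pa_v + sk * (l21 * z1[i] + l22 * z2[i])
  }
  structure(
    list(a_m = setNames(a_m, ped$id), a_v = setNames(a_v, ped$id),
         cg = cg_levels, b_m = setNames(b_m, cg_levels),
         b_v = setNames(b_v, cg_levels)),
    class = "true_effects"
  )
}

#' Simulate phenotypes under the exponential dispersion model
#'
#' Evaluates \eqn{y = b_m + a_m + \exp((b_v + a_v)/2)\,\epsilon} with
#' \eqn{\epsilon \sim N(0,1)} i.i.d. for every recorded animal. The standard
#' normal draws are stored so the dataset is bit-exactly reproducible from
#' `(truth, epsilon)`.
#'
#' @param ped a [pedigree()] object.
#' @param cg data.frame with columns `animal`, `cg` (the recorded animals).
#' @param truth a [draw_effects()] object covering all animals and CG.
#' @param seed integer seed (a dedicated residual stream is derived).
#' @return list of class `"sim_dataset"`: `data` (data.frame `animal`, `cg`,
#'   `sire`, `dam`, `y`), `truth`, `epsilon`, `ped`.
#' @export
simulate_phenotypes <- function(ped, cg, truth, seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(truth, "true_effects"))
  if (!all(c("animal", "cg") %in% names(cg)))
    stop("cg must have columns animal, cg")
  idx <- ped_index(ped, cg$animal)
  ig <- match(cg$cg, truth$cg)
  if (anyNA(ig)) stop("recorded animal with CG missing from truth")

  set.seed(derive_seed(seed, "epsilon"))
  eps <- stats::rnorm(nrow(cg))
  y <- truth$b_m[ig] + truth$a_m[idx] +
    exp((truth$b_v[ig] + truth$a_v[idx]) / 2) * eps

  data <- data.frame(
    animal = cg$animal,
    cg = cg$cg,
    sire = ifelse(is.na(ped$sire[idx]), NA_character_, ped$id[ped$sire[idx]]),
    dam = ifelse(is.na(ped$dam[idx]), NA_character_, ped$id[ped$dam[idx]]),
    y = as.numeric(y),
    stringsAsFactors = FALSE
  )
  structure(list(data = data, truth = truth, epsilon = eps, ped = ped),
            class = "sim_dataset")
}

#' @method print sim_dataset
#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$data), "records,",
      length(unique(x$data$cg)), "CG, pedigree of", x$ped$n, "animals\n")
  cat(sprintf("  mean y = %.2f, var y = %.2f\n",
              mean(x$data$y), stats::var(x$data$y)))
  invisible(x)
}

#' Simulate phenotypes on an arbitrary pedigree
#'
#' Runs the full generative model — CG effects, breeding values, residual
#' draws — on an externally supplied pedigree and CG assignment.
#'
#' @inheritParams simulate_phenotypes
#' @param params a [genetic_params()] object.
#' @return A `"sim_dataset"` (see [simulate_phenotypes()]).
#' @export
simulate_on_pedigree <- function(ped, cg, params, seed) {
  truth <- draw_effects(ped, cg$cg, params, seed)
  simulate_phenotypes(ped, cg, truth, seed)
}

#' Simulate a complete dataset from a design
#'
#' Convenience wrapper: [build_population()] then [simulate_on_pedigree()]
#' under one master seed.
#'
#' @param design a [sim_design()] object.
#' @param params a [genetic_params()] object.
#' @param seed integer master seed.
#' @return A `"sim_dataset"` with an extra `population` element.
#' @export
simulate_dataset <- function(design, params, seed) {
  pop <- build_population(design, seed)
  out <- simulate_on_pedigree(pop$ped, pop$cg, params, seed)
  out$population <- pop
  out
}

#' Expected residual variance under the exponential model
#'
#' For a contemporary group with log-variance effect `b_v` and additive
#' dispersion variance `sigma2_Av_exp`, the residual variance of the trait is
#' \deqn{E[\sigma^2_e] = \exp(b_v)\,\exp(\sigma^2_{Av,exp}/2),}
#' the lognormal mean of \eqn{\exp(b_v + a_v)} over
#' \eqn{a_v \sim N(0, \sigma^2_{Av,exp})}.
#'
#' @param b_v log residual variance fixed effect (log kg^2); vectorised.
#' @param sigma2_Av_exp additive variance of the log residual variance.
#' @return expected residual variance, kg^2.
#' @export
expected_residual_variance <- function(b_v, sigma2_Av_exp) {
  stopifnot(is.finite(b_v), is.finite(sigma2_Av_exp))
  exp(b_v) * exp(sigma2_Av_exp / 2)
}

#' Write a simulated dataset to delimited files
#'
#' Emits the pedigree (see [write_pedigree()]), phenotypes
#' (`animal,cg,y`) and the true effects (`animal,a_m,a_v` and `cg,b_m,b_v`)
#' for downstream evaluation.
#'
#' @param sim a `"sim_dataset"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("pedigree.csv", "phenotypes.csv",
                            "true_bv.csv", "true_cg.csv"))
  write_pedigree(sim$ped, files[1])
  utils::write.table(sim$data[c("animal", "cg", "y")], files[2], sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(animal = names(sim$truth$a_m), a_m = sim$truth$a_m,
               a_v = sim$truth$a_v),
    files[3], sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cg = sim$truth$cg, b_m = sim$truth$b_m, b_v = sim$truth$b_v),
    files[4], sep = ",", quote = FALSE, row.names = FALSE)
  invisible(files)
}
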