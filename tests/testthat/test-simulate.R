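test_that("design bookkeeping and feasibility checks", {
  d <- sim_design()
  expect_equal(d$records_per_generation, 5000L)
  expect_equal(d$cg_per_generation, 100L)
  expect_error(sim_design(n_base_sires = 3, n_base_dams = 100),
               "infeasible")
  expect_error(sim_design(offspring_per_sire_per_cg = 7), "infeasible")

  # tiny counting case: 1 generation, 2 sires, 10 dams, 5 offspring/sire
  dt <- sim_design(n_base_sires = 2, n_base_dams = 10,
                   offspring_per_sire = 5, n_generations = 1,
                   sires_per_cg = 2, offspring_per_sire_per_cg = 5)
  pop <- build_population(dt, seed = 1)
  expect_equal(nrow(pop$cg), 10L)
})

test_that("the full design yields the paper-scale population structure", {
  pop <- build_population(sim_design(), seed = 3)
  expect_equal(nrow(pop$cg), 25000L)
  expect_equal(pop$ped$n, 30100L)
  expect_equal(sum(is.na(pop$ped$sire) & is.na(pop$ped$dam)), 5100L)
  # every CG holds exactly 50 records from exactly 5 sires
  tab <- table(pop$cg$cg)
  expect_equal(length(tab), 500L)
  expect_true(all(tab == 50L))
  idx <- ped_index(pop$ped, pop$cg$animal)
  sires <- pop$ped$id[pop$ped$sire[idx]]
  expect_true(all(tapply(sires, pop$cg$cg,
                         function(s) length(unique(s))) == 5L))
})

test_that("breeding-value sampler matches its bivariate-normal target", {
  ped <- pedigree(as.character(1:5000), rep("0", 5000), rep("0", 5000))
  pars <- genetic_params(sigma2_a = 200, sigma2_Av_exp = 0.25, r_mv = 0.5)
  tr <- draw_effects(ped, "cg1", pars, seed = 4)
  expect_equal(cor(tr$a_m, tr$a_v), 0.5, tolerance = 0.03 / 0.5)
  expect_equal(var(tr$a_m), 200, tolerance = 0.05)
  expect_equal(var(tr$a_v), 0.25, tolerance = 0.05)

  # degenerate dispersion variance: a_v exactly zero
  tr0 <- draw_effects(ped, "cg1", genetic_params(sigma2_Av_exp = 0),
                      seed = 4)
  expect_true(all(tr0$a_v == 0))
  expect_error(genetic_params(r_mv = 1.2), "r_mv")
})

test_that("phenotypes follow the exponential model exactly", {
  d <- sim_design(n_base_sires = 4, n_base_dams = 100,
                  offspring_per_sire = 25, n_generations = 2,
                  sires_per_cg = 2, offspring_per_sire_per_cg = 5)
  pars <- genetic_params(sigma2_Av_exp = 0.09)
  sim <- simulate_dataset(d, pars, seed = 8)
  # bit-exact reconstruction from truth and stored epsilon
  idx <- ped_index(sim$ped, sim$data$animal)
  ig <- match(sim$data$cg, sim$truth$cg)
  y2 <- sim$truth$b_m[ig] + sim$truth$a_m[idx] +
    exp((sim$truth$b_v[ig] + sim$truth$a_v[idx]) / 2) * sim$epsilon
  expect_identical(sim$data$y, as.numeric(y2))
  # a record with epsilon = 0 reduces exactly to its mean part
  y0 <- sim$truth$b_m[ig] + sim$truth$a_m[idx] +
    exp((sim$truth$b_v[ig] + sim$truth$a_v[idx]) / 2) * 0
  expect_identical(as.numeric(y0), as.numeric(sim$truth$b_m[ig] +
                                                sim$truth$a_m[idx]))

  # reproducibility and seed separation
  sim2 <- simulate_dataset(d, pars, seed = 8)
  expect_identical(sim$data$y, sim2$data$y)
  sim3 <- simulate_dataset(d, pars, seed = 9)
  expect_false(any(sim$epsilon == sim3$epsilon))
})

test_that("expected residual variance matches the generative model", {
  expect_equal(expected_residual_variance(0, 0), 1)
  # closed form vs Monte Carlo for b_v = 5.4, sigma2 = 0.01
  expect_equal(expected_residual_variance(5.4, 0.01), 222.516,
               tolerance = 1e-5)
  set.seed(1)
  av <- rnorm(2e6, 0, sqrt(0.01))
  mc <- mean(exp(5.4 + av))  # Var(exp((b+a)/2) eps) = E exp(b+a)
  expect_equal(expected_residual_variance(5.4, 0.01), mc, tolerance = 0.01)

  # law of total variance: pooled within-CG variance of (y - a_m) matches
  # the mean expected residual variance over the realised b_v
  d <- design_small()
  pars <- genetic_params(sigma2_Av_exp = 0.09)
  sim <- simulate_dataset(d, pars, seed = 21)
  idx <- ped_index(sim$ped, sim$data$animal)
  resid_true <- sim$data$y - sim$truth$b_m[match(sim$data$cg, sim$truth$cg)] -
    sim$truth$a_m[idx]
  target <- mean(expected_residual_variance(sim$truth$b_v, 0.09))
  expect_equal(var(resid_true), target, tolerance = 0.1)
})

test_that("offspring regress on midparent with slope one", {
  sim <- simulate_dataset(design_small(),
                          genetic_params(sigma2_Av_exp = 0.09), seed = 31)
  np <- !is.na(sim$ped$sire) & !is.na(sim$ped$dam)
  mp_m <- (sim$truth$a_m[sim$ped$sire[np]] + sim$truth$a_m[sim$ped$dam[np]]) / 2
  slope_m <- coef(lm(sim$truth$a_m[np] ~ mp_m))[2]
  expect_equal(unname(slope_m), 1, tolerance = 0.05)
  mp_v <- (sim$truth$a_v[sim$ped$sire[np]] + sim$truth$a_v[sim$ped$dam[np]]) / 2
  slope_v <- coef(lm(sim$truth$a_v[np] ~ mp_v))[2]
  expect_equal(unname(slope_v), 1, tolerance = 0.08)
})

test_that("zero dispersion variance gives equal family variances", {
  d <- design_small()
  pars <- genetic_params(sigma2_Av_exp = 0, b_v_range = c(5.6, 5.6))
  sim <- simulate_dataset(d, pars, seed = 41)
  idx <- ped_index(sim$ped, sim$data$animal)
  resid_true <- sim$data$y - sim$truth$b_m[match(sim$data$cg, sim$truth$cg)] -
    sim$truth$a_m[idx]
  fam_var <- tapply(resid_true, sim$data$sire, var)
  fam_n <- tapply(resid_true, sim$data$sire, length)
  # log variance of a family of n has sampling SD ~ sqrt(2/(n-1))
  z <- log(fam_var / exp(5.6)) / sqrt(2 / (fam_n - 1))
  expect_lt(max(abs(z)), 4.5)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("simulate_on_pedigree covers arbitrary pedigrees and CG maps", {
  ped <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
  cg <- data.frame(animal = c("s", "d", "o"), cg = "g1")
  sim <- simulate_on_pedigree(ped, cg, genetic_params(), seed = 2)
  expect_equal(nrow(sim$data), 3L)
  expect_error(
    simulate_phenotypes(ped, data.frame(animal = "o", cg = "g9"),
                        sim$truth, seed = 2),
    "missing")

  # consistency: simulate_dataset is build_population + simulate_on_pedigree
  d <- sim_design(n_base_sires = 2, n_base_dams = 10,
                  offspring_per_sire = 5, n_generations = 1,
                  sires_per_cg = 2, offspring_per_sire_per_cg = 5)
  pop <- build_population(d, seed = 6)
  s1 <- simulate_on_pedigree(pop$ped, pop$cg, genetic_params(), seed = 6)
  s2 <- simulate_dataset(d, genetic_params(), seed = 6)
  expect_identical(s1$data$y, s2$data$y)

  # within-CG residual variance matches the closed form at high dispersion
  pedb <- pedigree(as.character(1:4000), rep("0", 4000), rep("0", 4000))
  cgb <- data.frame(animal = pedb$id, cg = "g1")
  parsb <- genetic_params(sigma2_Av_exp = 0.25, b_v_range = c(5.6, 5.6))
  simb <- simulate_on_pedigree(pedb, cgb, parsb, seed = 11)
  resid_true <- simb$data$y - simb$truth$b_m[1] - simb$truth$a_m
  expect_equal(var(resid_true), expected_residual_variance(5.6, 0.25),
               tolerance = 0.08)
})

test_that("datasets write out and the truth files align", {
  sim <- simulate_on_pedigree(
    pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d")),
    data.frame(animal = "o", cg = "g1"), genetic_params(), seed = 3)
  dir <- file.path(tempdir(), "simout")
  files <- write_dataset(sim, dir)
  expect_true(all(file.exists(files)))
  tb <- read.table(files[3], header = TRUE, sep = ",")
  expect_equal(tb$a_m, unname(sim$truth$a_m), tolerance = 1e-12)
})
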