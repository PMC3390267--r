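test_that("edit rules trim outliers and prune small CG and sire families", {
  set.seed(1)
  base <- data.frame(
    animal = as.character(1:100), cg = "g1", sire = "s1",
    y = rnorm(100, 100, 5), stringsAsFactors = FALSE)
  rules <- edit_rules(sd_trim = 3.5, min_cg_size = 25, min_sire_progeny = 50)
  kept <- apply_edit_rules(base, rules)
  expect_equal(nrow(kept), 100L)
  expect_equal(sum(attr(kept, "removal_log")), 0L)

  # a single record at mean + 4 SD is trimmed
  out <- base
  out$y[1] <- mean(base$y[-1]) + 4 * sd(base$y[-1]) * 3  # far outside
  kept2 <- apply_edit_rules(out, rules)
  expect_equal(attr(kept2, "removal_log")[["sd_trim"]], 1L)
  expect_false("1" %in% kept2$animal)

  # a CG of 24 records is dropped entirely
  small_cg <- base
  small_cg$cg[1:24] <- "g2"
  small_cg$sire <- rep(c("s1", "s2"), 50)  # keep sire families large enough
  small_cg$sire <- "s1"
  kept3 <- apply_edit_rules(small_cg, rules)
  expect_equal(attr(kept3, "removal_log")[["min_cg_size"]], 24L)

  # iteration to a fixed point: dropping CG gB (24 records of sB) leaves
  # sB with 30 < 50 progeny, whose removal leaves a clean gA of 50
  two <- rbind(
    data.frame(animal = as.character(1:80), cg = "gA",
               sire = rep(c("sA", "sB"), c(50, 30)),
               y = rnorm(80, 100, 5)),
    data.frame(animal = as.character(81:104), cg = "gB", sire = "sB",
               y = rnorm(24, 100, 5)))
  kept4 <- apply_edit_rules(two, rules)
  expect_equal(nrow(kept4), 50L)
  expect_equal(attr(kept4, "removal_log")[["min_cg_size"]], 24L)
  expect_equal(attr(kept4, "removal_log")[["min_sire_progeny"]], 30L)

  # everything removed is a hard error
  expect_error(apply_edit_rules(two[81:104, ], rules), "no records survive")
  expect_error(edit_rules(sd_trim = -1))
})

test_that("sparse MME solutions equal the dense GLS/BLUP oracle", {
  for (seed in 1:2) {
    td <- tiny_dataset(n_rec = 60, seed = seed)
    fit <- fit_animal_model(y ~ cg, td$data, td$ped, residual = "hom")
    Z <- Matrix::sparseMatrix(i = seq_len(nrow(td$data)),
                              j = ped_index(td$ped, td$data$animal), x = 1,
                              dims = c(nrow(td$data), td$ped$n))
    X <- Matrix::sparse.model.matrix(~ 0 + factor(cg), td$data)
    theta <- fit$components$estimate
    oracle <- dense_blup(td$data$y, X, list(Z), list(td$A),
                         s2u = theta[1], group = rep(1L, nrow(td$data)),
                         s2e = theta[2])
    expect_equal(unname(fit$fixed), oracle$b, tolerance = 1e-8)
    expect_equal(unname(fit$ebv), oracle$u[[1]], tolerance = 1e-8)
    ll <- dense_reml_loglik(td$data$y, X, list(Z), list(td$A),
                            s2u = theta[1], group = rep(1L, nrow(td$data)),
                            s2e = theta[2])
    expect_equal(fit$loglik, ll, tolerance = 1e-8)
  }
})

test_that("HET residual structure agrees with the dense oracle", {
  td <- tiny_dataset(n_rec = 80, seed = 3)
  td$data$sire[is.na(td$data$sire)] <- NA  # keep NA class
  fit <- fit_animal_model(y ~ cg, td$data, td$ped, residual = "het_sire")
  n <- nrow(td$data)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = ped_index(td$ped, td$data$animal), x = 1,
                            dims = c(n, td$ped$n))
  X <- Matrix::sparse.model.matrix(~ 0 + factor(cg), td$data)
  theta <- fit$components$estimate
  grp <- unname(fit$resid_group)
  oracle <- dense_blup(td$data$y, X, list(Z), list(td$A),
                       s2u = theta[1], group = grp, s2e = theta[-1])
  expect_equal(unname(fit$fixed), oracle$b, tolerance = 1e-7)
  expect_equal(unname(fit$ebv), oracle$u[[1]], tolerance = 1e-7)
  ll <- dense_reml_loglik(td$data$y, X, list(Z), list(td$A),
                          s2u = theta[1], group = grp, s2e = theta[-1])
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("restricted logL never decreases over accepted iterations", {
  td <- tiny_dataset(n_rec = 100, seed = 4)
  n <- nrow(td$data)
  X <- Matrix::sparse.model.matrix(~ 0 + factor(cg), td$data)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = ped_index(td$ped, td$data$animal), x = 1,
                            dims = c(n, td$ped$n))
  uf <- hetvar:::ainv_factor(td$ped)
  eng <- hetvar:::reml_fit_engine(
    td$data$y, X, list(hetvar:::reml_term("a", Z, uf$u, uf$logdet_a)),
    rep(1L, n))
  expect_true(all(diff(eng$trace$logL) > -1e-9))
})

test_that("HET with all family variances equal reproduces HOM", {
  td <- tiny_dataset(n_rec = 80, seed = 5)
  n <- nrow(td$data)
  X <- Matrix::sparse.model.matrix(~ 0 + factor(cg), td$data)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = ped_index(td$ped, td$data$animal), x = 1,
                            dims = c(n, td$ped$n))
  uf <- hetvar:::ainv_factor(td$ped)
  terms <- list(hetvar:::reml_term("a", Z, uf$u, uf$logdet_a))
  hom <- fit_animal_model(y ~ cg, td$data, td$ped, residual = "hom")
  grp <- hetvar:::het_resid_groups(td$data$sire)
  # evaluate the HET parameterisation at the HOM solution
  st <- hetvar:::reml_state(td$data$y, X, terms, grp$group)
  theta_het <- c(hom$sigma2_a, rep(hom$resid_var, max(grp$group)))
  ev <- hetvar:::reml_evaluate(st, theta_het)
  expect_equal(ev$logL, hom$loglik, tolerance = 1e-6)
  expect_equal(ev$sol[seq_len(ncol(X))], unname(hom$fixed),
               tolerance = 1e-6)
})

test_that("data without genetic signal push additive variance to zero", {
  # y = CG effect + iid noise on a related pedigree: sigma2_a collapses,
  # hitting the boundary floor for this realisation
  td <- tiny_dataset(n_rec = 100, seed = 3, s2a = 0, s2e = 4)
  fit <- fit_animal_model(y ~ cg, td$data, td$ped)
  expect_true(fit$components$boundary[1])
  expect_lt(fit$sigma2_a, 1e-4)
  # and stays a small fraction of the residual variance across seeds
  for (seed in c(1, 4)) {
    tdk <- tiny_dataset(n_rec = 100, seed = seed, s2a = 0, s2e = 4)
    fk <- fit_animal_model(y ~ cg, tdk$data, tdk$ped)
    expect_lt(fk$sigma2_a, 0.5 * fk$resid_var)
  }
})

test_that("residuals reconstruct the fit and centre within CG", {
  td <- tiny_dataset(n_rec = 100, seed = 7)
  fit <- fit_animal_model(y ~ cg, td$data, td$ped)
  expect_equal(unname(fitted(fit) + residuals(fit)), td$data$y,
               tolerance = 1e-10)
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.5 * sd(r))
  cg_means <- tapply(r, td$data$cg, mean)
  expect_true(all(abs(cg_means) < 0.5 * sd(r)))
})

test_that("information criteria count variance components only", {
  td <- tiny_dataset(n_rec = 60, seed = 8)
  hom <- fit_animal_model(y ~ cg, td$data, td$ped, residual = "hom")
  ic <- information_criteria(hom)
  expect_equal(attr(logLik(hom), "df"), 2L)  # sigma2_a, sigma2_e
  expect_equal(ic[["aic"]], -2 * hom$loglik + 2 * 2)
  expect_equal(ic[["bic"]],
               -2 * hom$loglik + 2 * log(hom$n - hom$rank_x))
  het <- fit_animal_model(y ~ cg, td$data, td$ped, residual = "het_sire")
  n_fam <- length(het$resid_var)
  expect_equal(attr(logLik(het), "df"), 1L + n_fam)
  # two fits with equal logL and p differing by one
  expect_equal((-2 * hom$loglik + 2 * 3) - (-2 * hom$loglik + 2 * 2), 2)
})

test_that("a singular fixed design is refused with named columns", {
  td <- tiny_dataset(n_rec = 40, seed = 9)
  td$data$cg2 <- td$data$cg  # perfectly confounded copy
  expect_error(fit_animal_model(y ~ cg + cg2, td$data, td$ped),
               "singular")
})

test_that("cross-validation partitions correctly and tracks noise level", {
  td <- tiny_dataset(n_rec = 100, seed = 10)
  cv <- cross_validate(y ~ cg, td$data, td$ped, k = 5, seed = 3)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), nrow(td$data))
  expect_equal(cv$mse, mean(cv$fold_mse))

  # pure-noise trait: prediction MSE is close to the sample variance
  set.seed(11)
  ped <- pedigree(as.character(1:200), rep("0", 200), rep("0", 200))
  dat <- data.frame(animal = ped$id, cg = "g1", sire = NA_character_,
                    y = rnorm(200))
  cvn <- cross_validate(y ~ cg, dat, ped, k = 5, seed = 4)
  expect_equal(cvn$mse, var(dat$y), tolerance = 0.15)
})
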