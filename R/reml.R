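# Sparse REML engine for Gaussian mixed models with pedigree (or identity)
# random terms and grouped diagonal residuals.
#
# Model: y = X b + sum_k Z_k u_k + e,  u_k ~ N(0, sigma2_k K_k),
#        e ~ N(0, diag(sigma2_e[group])).
# Each K_k is supplied through the sparse lower-triangular factor U_k of its
# inverse (K_k^-1 = U_k' U_k) plus log|K_k|, so the mixed-model equations
# stay sparse. Maximisation is by average-information (AI) updates with
# step-halving and an expectation-maximisation fallback whenever an AI step
# leaves the parameter space; components are kept above a positive floor.

#' REML engine control parameters
#'
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood between accepted iterations.
#' @param tol_comp tolerance on the maximum relative change of any
#'   variance component not at the boundary floor.
#' @param max_iter maximum number of accepted iterations.
#' @param floor_frac boundary floor for every component, as a fraction of
#'   the phenotypic variance of the response.
#' @param verbose print the iteration trace.
#' @return list of control values.
#' @export
reml_control <- function(tol = 1e-7, tol_comp = 1e-6, max_iter = 200,
                         floor_frac = 1e-8, verbose = FALSE) {
  list(tol = tol, tol_comp = tol_comp, max_iter = max_iter,
       floor_frac = floor_frac, verbose = verbose)
}

# random term constructor used by the fitting front-ends
# Z: n x q sparse incidence; uinv: q x q sparse factor with K^-1 = uinv'uinv
reml_term <- function(name, Z, uinv, logdet_k = 0) {
  # force a general sparse form: unit-triangular / diagonal classes keep an
  # implicit diagonal that would be lost when reading the triplet slots
  uinv <- methods::as(methods::as(uinv, "generalMatrix"), "CsparseMatrix")
  list(name = name, Z = methods::as(Z, "CsparseMatrix"),
       uinv = uinv, logdet_k = logdet_k, q = ncol(Z))
}

# one full evaluation of the restricted likelihood and its derivatives at
# theta = c(sigma2 per random term, sigma2_e per residual group)
reml_evaluate <- function(st, theta) {
  r <- st$r; m <- st$m; n <- st$n; p <- st$p
  s2u <- theta[seq_len(r)]
  s2e <- theta[r + seq_len(m)]
  w <- 1 / s2e[st$resid_group]

  C <- Matrix::forceSymmetric(
    Matrix::crossprod(st$W, st$W * w))
  for (k in seq_len(r)) C <- C + st$Kfull[[k]] / s2u[k]
  ch <- Matrix::Cholesky(methods::as(C, "CsparseMatrix"),
                         LDL = FALSE, perm = TRUE)
  rhs <- Matrix::crossprod(st$W, st$y * w)
  sol <- as.vector(Matrix::solve(ch, rhs))
  ehat <- st$y - as.vector(st$W %*% sol)
  quad <- sum(w * st$y * ehat)
  logdet_c <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)

  n_j <- st$n_group
  logL <- -0.5 * ((n - p) * log(2 * pi) +
                  sum(n_j * log(s2e)) +
                  sum(st$q * log(s2u) + st$logdet_k) +
                  logdet_c + quad)

  # h_i = w_i' C^-1 w_i for every record, via chunked triangular solves
  h <- numeric(n)
  for (idx in st$col_chunks) {
    z <- Matrix::solve(ch, Matrix::solve(ch, st$Wt[, idx, drop = FALSE],
                                         system = "P"), system = "L")
    h[idx] <- Matrix::colSums(z^2)
  }
  H_j <- as.vector(rowsum(h, st$resid_group))

  # T_k = tr(K_k^-1 C^kk) via the same route on the embedded factors
  T_k <- numeric(r)
  for (k in seq_len(r)) {
    tk <- 0
    for (idx in chunk_cols(ncol(st$Ublock[[k]]), st$chunk)) {
      z <- Matrix::solve(ch, Matrix::solve(ch,
             st$Ublock[[k]][, idx, drop = FALSE], system = "P"),
             system = "L")
      tk <- tk + sum(z^2)
    }
    T_k[k] <- tk
  }

  # sufficient statistics per parameter
  u_hat <- vector("list", r)
  uKu <- numeric(r)
  for (k in seq_len(r)) {
    u_hat[[k]] <- sol[st$block[[k]]]
    uKu[k] <- sum((st$terms[[k]]$uinv %*% u_hat[[k]])^2)
  }
  e2_j <- as.vector(rowsum(ehat^2, st$resid_group))

  grad <- numeric(r + m)
  em <- numeric(r + m)
  for (k in seq_len(r)) {
    grad[k] <- -0.5 * ((st$q[k] - T_k[k] / s2u[k]) / s2u[k] -
                       uKu[k] / s2u[k]^2)
    em[k] <- (uKu[k] + T_k[k]) / st$q[k]
  }
  for (j in seq_len(m)) {
    grad[r + j] <- -0.5 * (n_j[j] / s2e[j] - H_j[j] / s2e[j]^2 -
                           e2_j[j] / s2e[j]^2)
    em[r + j] <- (e2_j[j] + H_j[j]) / n_j[j]
  }

  # average-information matrix: AI_ab = 0.5 f_a' P f_b with
  # f = (dV/dtheta) P y; P f = w f - w W C^-1 W' (w f)
  Fm <- matrix(0, n, r + m)
  wehat <- w * ehat
  for (k in seq_len(r))
    Fm[, k] <- as.vector(st$terms[[k]]$Z %*% u_hat[[k]]) / s2u[k]
  for (j in seq_len(m)) {
    mask <- st$resid_group == j
    Fm[mask, r + j] <- wehat[mask]
  }
  G1 <- Fm * w
  S <- Matrix::solve(ch, Matrix::crossprod(st$W, G1))
  PF <- G1 - w * as.matrix(st$W %*% S)
  AI <- 0.5 * crossprod(Fm, PF)
  AI <- (AI + t(AI)) / 2

  list(theta = theta, logL = logL, grad = grad, em = em, AI = AI,
       sol = sol, ehat = ehat, u_hat = u_hat, h = h)
}

chunk_cols <- function(nc, chunk) {
  if (nc == 0L) return(list())
  split(seq_len(nc), (seq_len(nc) - 1L) %/% chunk)
}

# set up the constant part of the engine state
reml_state <- function(y, X, terms, resid_group, chunk = 1024L) {
  n <- length(y)
  p <- ncol(X)
  r <- length(terms)
  W <- X
  block <- vector("list", r)
  off <- p
  for (k in seq_len(r)) {
    W <- Matrix::cbind2(W, terms[[k]]$Z)
    block[[k]] <- off + seq_len(terms[[k]]$q)
    off <- off + terms[[k]]$q
  }
  W <- methods::as(W, "CsparseMatrix")
  ptot <- off
  Kfull <- Ublock <- vector("list", r)
  for (k in seq_len(r)) {
    u <- terms[[k]]$uinv
    trip <- methods::as(u, "TsparseMatrix")
    # embed U_k' as a ptot x q_k block: column j = row j of U_k
    Ublock[[k]] <- Matrix::sparseMatrix(
      i = block[[k]][1L] - 1L + trip@j + 1L,
      j = trip@i + 1L, x = trip@x, dims = c(ptot, terms[[k]]$q))
    kin <- methods::as(Matrix::crossprod(u), "TsparseMatrix")
    Kfull[[k]] <- Matrix::sparseMatrix(
      i = block[[k]][1L] - 1L + kin@i + 1L,
      j = block[[k]][1L] - 1L + kin@j + 1L,
      x = kin@x, dims = c(ptot, ptot), symmetric = FALSE)
    Kfull[[k]] <- Matrix::forceSymmetric(Kfull[[k]])
  }
  m <- max(resid_group)
  list(y = y, X = X, W = W, Wt = Matrix::t(W), terms = terms, r = r, m = m,
       n = n, p = p, q = vapply(terms, `[[`, 0, "q"),
       logdet_k = vapply(terms, `[[`, 0, "logdet_k"),
       resid_group = resid_group, n_group = tabulate(resid_group, m),
       block = block, Kfull = Kfull, Ublock = Ublock,
       col_chunks = chunk_cols(n, chunk), chunk = chunk)
}

# full REML maximisation; returns the converged evaluation plus bookkeeping
reml_fit_engine <- function(y, X, terms, resid_group, init = NULL,
                            control = reml_control()) {
  st <- reml_state(y, X, terms, resid_group)
  if (any(st$n_group == 0L)) stop("empty residual group")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("response has no variance")
  floor_v <- control$floor_frac * vy
  r <- st$r; m <- st$m

  theta <- init
  if (is.null(theta))
    theta <- c(rep(0.5 * vy / max(r, 1), r), rep(0.5 * vy, m))
  theta <- pmax(theta, floor_v)

  cur <- reml_evaluate(st, theta)
  trace <- data.frame(iter = 0L, logL = cur$logL, step = "init")
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    step_type <- "AI"
    # AI (Newton) proposal on the components not pinned at the floor
    # (a floored component re-enters when its gradient points inward);
    # overshoot is handled by projection at the floor plus step halving,
    # with an EM fallback when no AI step improves the likelihood
    active <- cur$theta > floor_v * (1 + 1e-12) | cur$grad > 0
    delta <- rep(0, length(cur$theta))
    delta[active] <- tryCatch(
      solve(cur$AI[active, active, drop = FALSE], cur$grad[active]),
      error = function(e) rep(NA_real_, sum(active)))
    cand <- NULL
    if (!anyNA(delta)) {
      fac <- 1
      for (half in 1:12) {
        prop <- pmax(cur$theta + fac * delta, floor_v)
        if (any(prop != cur$theta)) {
          ev <- reml_evaluate(st, prop)
          if (ev$logL >= cur$logL - 1e-10) { cand <- ev; break }
        }
        fac <- fac / 2
      }
    }
    if (is.null(cand)) {
      step_type <- "EM"
      prop <- pmax(cur$em, floor_v)
      cand <- reml_evaluate(st, prop)
      if (cand$logL < cur$logL - 1e-6) {
        # neither AI nor EM improves: numerically converged
        cand <- cur
      }
    }
    d_logL <- cand$logL - cur$logL
    at_floor <- cand$theta <= floor_v * (1 + 1e-12)
    rel <- abs(cand$theta - cur$theta) / pmax(abs(cur$theta), floor_v)
    rel[at_floor] <- 0
    prev <- cur
    cur <- cand
    trace <- rbind(trace,
                   data.frame(iter = it, logL = cur$logL, step = step_type))
    if (control$verbose)
      cat(sprintf("iter %3d  logL %.8f  (%s)\n", it, cur$logL, step_type))
    if (abs(d_logL) < control$tol && max(rel) < control$tol_comp) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- sprintf(
      "REML did not converge in %d iterations (last logL %.6f)",
      control$max_iter, cur$logL)
    err <- simpleError(msg)
    err$last <- cur
    stop(err)
  }

  se <- rep(NA_real_, r + m)
  vcov_theta <- tryCatch(solve(cur$AI), error = function(e) NULL)
  if (!is.null(vcov_theta)) se <- sqrt(pmax(diag(vcov_theta), 0))

  list(
    theta = cur$theta, se = se, vcov_theta = vcov_theta,
    logLik = cur$logL, fixed = cur$sol[seq_len(st$p)],
    u_hat = cur$u_hat, residuals = cur$ehat,
    boundary = cur$theta <= floor_v * (1 + 1e-12),
    floor = floor_v, iterations = max(trace$iter), trace = trace,
    n = st$n, p = st$p, converged = converged
  )
}
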