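# Dense brute-force oracles, independent of the sparse engine paths.

# restricted log-likelihood from the covariance representation
# V = sum_k s2u[k] Z_k K_k Z_k' + diag(s2e[group])
dense_reml_loglik <- function(y, X, Zs, Ks, s2u, group, s2e) {
  Zs <- lapply(Zs, as.matrix)
  n <- length(y)
  V <- diag(s2e[group], n)
  for (k in seq_along(Zs))
    V <- V + s2u[k] * (Zs[[k]] %*% Ks[[k]] %*% t(Zs[[k]]))
  Xd <- as.matrix(X)
  Vi <- solve(V)
  XVX <- t(Xd) %*% Vi %*% Xd
  P <- Vi - Vi %*% Xd %*% solve(XVX, t(Xd) %*% Vi)
  as.numeric(-0.5 * ((n - ncol(Xd)) * log(2 * pi) +
                     determinant(V)$modulus + determinant(XVX)$modulus +
                     t(y) %*% P %*% y))
}

# dense GLS fixed effects and BLUP random effects at fixed components
dense_blup <- function(y, X, Zs, Ks, s2u, group, s2e) {
  Zs <- lapply(Zs, as.matrix)
  n <- length(y)
  V <- diag(s2e[group], n)
  for (k in seq_along(Zs))
    V <- V + s2u[k] * (Zs[[k]] %*% Ks[[k]] %*% t(Zs[[k]]))
  Xd <- as.matrix(X)
  Vi <- solve(V)
  b <- solve(t(Xd) %*% Vi %*% Xd, t(Xd) %*% Vi %*% y)
  r <- Vi %*% (y - Xd %*% b)
  u <- lapply(seq_along(Zs), function(k) s2u[k] * Ks[[k]] %*% t(Zs[[k]]) %*% r)
  list(b = as.numeric(b), u = lapply(u, as.numeric))
}

# random pedigree generator: founders then random matings
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1) {
  set.seed(seed)
  sire <- dam <- rep("0", n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) > 0L) sire[i] <- as.character(sample(males, 1L))
    if (length(females) > 0L) dam[i] <- as.character(sample(females, 1L))
  }
  pedigree(as.character(seq_len(n)), sire, dam, sex = sex)
}

# small simulated dataset for engine tests: a few CG, two sire families
tiny_dataset <- function(n_rec = 60, seed = 1, s2a = 3, s2e = 2) {
  set.seed(seed)
  ped <- random_pedigree(n_rec + 20L, n_founders = 10L, seed = seed)
  rec <- (ped$n - n_rec + 1L):ped$n
  A <- relationship_matrix(ped)
  a <- as.numeric(t(chol(A)) %*% rnorm(ped$n)) * sqrt(s2a)
  cg <- sample(paste0("c", 1:4), n_rec, replace = TRUE)
  mu <- c(c1 = 10, c2 = 14, c3 = 9, c4 = 12)
  y <- mu[cg] + a[rec] + rnorm(n_rec, 0, sqrt(s2e))
  data.frame(
    animal = ped$id[rec], cg = cg,
    sire = ifelse(is.na(ped$sire[rec]), NA_character_, ped$id[ped$sire[rec]]),
    dam = ifelse(is.na(ped$dam[rec]), NA_character_, ped$id[ped$dam[rec]]),
    y = as.numeric(y), stringsAsFactors = FALSE
  ) -> dat
  list(data = dat, ped = ped, A = A)
}
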