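test_that("pedigree construction sorts, deduplicates and promotes parents", {
  p1 <- pedigree("a", "0", "0")
  expect_equal(p1$n, 1L)
  expect_equal(p1$generation, 0L)

  # trio given out of order is topologically sorted
  p3 <- pedigree(c("o", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
  expect_equal(p3$id, c("s", "d", "o"))
  expect_equal(p3$generation, c(0L, 0L, 1L))

  # unlisted sire becomes a founder, with a warning and a count
  expect_warning(px <- pedigree(c("a", "b"), c("X", "0"), c("0", "0")),
                 "added as founders")
  expect_equal(px$n, 3L)
  expect_equal(px$n_added_founders, 1L)
  expect_true("X" %in% px$id)

  # exact duplicate records collapse; conflicting ones are an error
  pd <- pedigree(c("s", "d", "o", "o"), c("0", "0", "s", "s"),
                 c("0", "0", "d", "d"))
  expect_equal(pd$n, 3L)
  expect_error(
    pedigree(c("s", "d", "o", "o"), c("0", "0", "s", "d"),
             c("0", "0", "d", "d")),
    "conflicting parents")
})

test_that("cycles and self-parentage are hard errors naming an animal", {
  expect_error(pedigree(c("a", "b"), c("b", "a"), c("0", "0")), "cycle")
  expect_error(pedigree("a", "a", "0"), "own parent")
})

test_that("inbreeding matches the tabular method and known cases", {
  # founders only
  pf <- pedigree(c("a", "b"), c("0", "0"), c("0", "0"))
  expect_equal(inbreeding(pf)$f, c(0, 0))

  # offspring of unrelated parents: F = 0, d = 0.5
  p3 <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
  fac <- inbreeding(p3)
  expect_equal(fac$f, c(0, 0, 0))
  expect_equal(fac$d, c(1, 1, 0.5))

  # offspring of full sibs: F = A_sd / 2 = 0.25
  pfs <- pedigree(c("s", "d", "a", "b", "x"),
                  c("0", "0", "s", "s", "a"),
                  c("0", "0", "d", "d", "b"))
  ffs <- inbreeding(pfs)
  expect_equal(ffs$f[match("x", pfs$id)], 0.25)
  A <- relationship_matrix(pfs)
  expect_equal(A["a", "b"] / 2, 0.25)
  expect_equal(A["x", "x"], 1.25)

  # one known parent: d = 0.75
  p1p <- pedigree(c("d", "o"), c("0", "0"), c("0", "d"))
  expect_equal(inbreeding(p1p)$d, c(1, 0.75))

  # tabular diagonal equals 1 + F on random pedigrees
  for (seed in 1:3) {
    ped <- random_pedigree(80, seed = seed)
    expect_equal(diag(relationship_matrix(ped)) - 1, inbreeding(ped)$f,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a_inverse follows Henderson's rules and inverts the tabular A", {
  # single founder
  expect_equal(as.matrix(a_inverse(pedigree("a", "0", "0"))),
               matrix(1, dimnames = list("a", "a")))

  # non-inbred trio: known dense inverse
  p3 <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
  expect_equal(unname(as.matrix(a_inverse(p3))),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)

  # oracle equivalence on random pedigrees up to 200 animals
  for (seed in 1:4) {
    n <- c(50, 120, 200, 160)[seed]
    ped <- random_pedigree(n, seed = seed)
    A <- relationship_matrix(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(n))), 1e-8)
    # the triangular factor reproduces A-inverse and log det A
    uf <- hetvar:::ainv_factor(ped)
    expect_lt(max(abs(as.matrix(Matrix::crossprod(uf$u)) - Ai)), 1e-10)
    expect_equal(uf$logdet_a, as.numeric(determinant(A)$modulus),
                 tolerance = 1e-8)
  }
})

test_that("relationship_matrix handles selected ids", {
  p3 <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
  expect_equal(relationship_matrix(p3, "s")[1, 1], 1.0)
  expect_equal(relationship_matrix(p3, c("s", "o"))["s", "o"], 0.5)
  expect_error(relationship_matrix(p3, "nope"), "unknown animal")
})

test_that("F is order-invariant and unaffected by unrelated founders", {
  ped <- random_pedigree(60, seed = 5)
  df <- as.data.frame(ped)
  set.seed(9)
  perm <- sample(nrow(df))
  ped2 <- pedigree(df$animal[perm],
                   ifelse(is.na(df$sire[perm]), "0", df$sire[perm]),
                   ifelse(is.na(df$dam[perm]), "0", df$dam[perm]))
  f1 <- setNames(inbreeding(ped)$f, ped$id)
  f2 <- setNames(inbreeding(ped2)$f, ped2$id)
  expect_equal(f1[ped$id], f2[ped$id])

  # adding an unrelated founder changes no existing F or A entry
  ped3 <- pedigree(c(df$animal, "ZZ"),
                   c(ifelse(is.na(df$sire), "0", df$sire), "0"),
                   c(ifelse(is.na(df$dam), "0", df$dam), "0"))
  f3 <- setNames(inbreeding(ped3)$f, ped3$id)
  expect_equal(f3[ped$id], f1[ped$id])
  expect_equal(relationship_matrix(ped3, ped$id), relationship_matrix(ped))
})

test_that("pedigree files round-trip losslessly", {
  ped <- random_pedigree(40, seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_pedigree(ped, tf)
  ped2 <- read_pedigree(tf)
  expect_equal(as.data.frame(ped), as.data.frame(ped2))
  # tab-delimited too
  tf2 <- tempfile(fileext = ".tsv")
  write_pedigree(ped, tf2, sep = "\t")
  expect_equal(as.data.frame(read_pedigree(tf2)), as.data.frame(ped))
})
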