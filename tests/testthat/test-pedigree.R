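test_that("read_pedigree validates, sorts, and inserts phantom founders", {
  f <- write_ped_csv(data.frame(animal = c(3, 1, 2), sire = c(1, 0, 0),
                                dam = c(2, 0, 0), birth_year = c(2002, 2000, 2000),
                                sex = c("M", "M", "F")))
  ped <- read_pedigree(f)
  expect_s3_class(ped, "gait_pedigree")
  expect_equal(nrow(ped), 3L)
  expect_true(all(ped$si <= seq_len(3) - 1))  # parents precede offspring
  expect_equal(ped$id[3], 3L)

  # self-parenthood is a cycle
  f2 <- write_ped_csv(data.frame(animal = 1, sire = 1, dam = 0,
                                 birth_year = 2000, sex = "M"))
  expect_error(read_pedigree(f2), "cycle")

  # two-animal cycle names an animal on it
  f3 <- write_ped_csv(data.frame(animal = c(1, 2), sire = c(2, 1), dam = c(0, 0),
                                 birth_year = c(2000, 2000), sex = c("M", "M")))
  expect_error(read_pedigree(f3), "cycle")

  # duplicate id
  f4 <- write_ped_csv(data.frame(animal = c(1, 1), sire = 0, dam = 0,
                                 birth_year = 2000, sex = "M"))
  expect_error(read_pedigree(f4), "duplicate")

  # unlisted sire 99 becomes a phantom founder
  f5 <- write_ped_csv(data.frame(animal = c(1, 2), sire = c(0, 99), dam = c(0, 1),
                                 birth_year = c(2000, 2002), sex = c("F", "M")))
  ped5 <- read_pedigree(f5)
  expect_equal(nrow(ped5), 3L)
  expect_true(99 %in% ped5$id)
  expect_equal(attr(ped5, "phantom_founders"), 99L)
  expect_equal(ped5$birth_year[ped5$id == 99], 1999L)
})

test_that("inbreeding matches definition and the tabular oracle", {
  # founders have F = 0
  ped <- pedigree(data.frame(id = 1:2, sire = 0, dam = 0,
                             birth_year = 2000, sex = c("M", "F")))
  expect_equal(as.vector(compute_inbreeding(ped)), c(0, 0), ignore_attr = TRUE)

  # offspring of non-inbred full sibs: F = 0.25
  ped <- pedigree(data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                             dam = c(0, 0, 2, 2, 4),
                             birth_year = c(2000, 2000, 2001, 2001, 2003),
                             sex = c("M", "F", "M", "F", "M")))
  expect_equal(as.vector(compute_inbreeding(ped))[5], 0.25)

  # random pedigree: F equals diag(tabular A) - 1
  ped <- random_pedigree(50, seed = 4)
  Fv <- compute_inbreeding(ped)
  A <- tabular_A(ped$si, ped$di)
  expect_equal(as.vector(Fv), diag(A) - 1, tolerance = 1e-12, ignore_attr = TRUE)

  # agreement also at 200 animals
  ped <- random_pedigree(200, seed = 9)
  expect_equal(as.vector(compute_inbreeding(ped)),
               diag(tabular_A(ped$si, ped$di)) - 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("build_A matches classical values and the Cholesky factor oracle", {
  ped <- pedigree(data.frame(id = 1:2, sire = 0, dam = 0,
                             birth_year = 2000, sex = c("M", "F")))
  expect_equal(unname(build_A(ped)), diag(2))

  # full sibs of unrelated founders are related 0.5
  ped <- pedigree(data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2),
                             birth_year = c(2000, 2000, 2001, 2001),
                             sex = c("M", "F", "M", "F")))
  expect_equal(build_A(ped)[3, 4], 0.5)
  # parent-offspring relationship is exactly 0.5
  expect_equal(build_A(ped)[1, 3], 0.5)

  # 20-animal random pedigree: A = L L' from the Mendelian-sampling recursion
  ped <- random_pedigree(20, seed = 2)
  A <- build_A(ped)
  Fv <- compute_inbreeding(ped)
  d <- attr(Fv, "d")
  L <- matrix(0, 20, 20)
  for (i in 1:20) {
    if (ped$si[i] > 0) L[i, ] <- L[i, ] + 0.5 * L[ped$si[i], ]
    if (ped$di[i] > 0) L[i, ] <- L[i, ] + 0.5 * L[ped$di[i], ]
    L[i, i] <- sqrt(d[i])
  }
  expect_equal(unname(A), L %*% t(L), tolerance = 1e-12)

  # size guard
  expect_error(build_A(random_pedigree(30), dense_limit = 10), "truncate")
})

test_that("A is PSD and consistent with its sparse inverse and submatrices", {
  ped <- random_pedigree(120, seed = 6)
  A <- build_A(ped)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  Ainv <- build_Ainv(ped)
  expect_equal(as.matrix(Ainv %*% A), diag(120), tolerance = 1e-8,
               ignore_attr = TRUE)
  ids <- ped$id[c(5, 40, 90, 117)]
  expect_equal(A_submatrix(ped, ids), A[as.character(ids), as.character(ids)],
               tolerance = 1e-10)
})

test_that("top_eigenvectors returns ordered unit eigenpairs with fixed signs", {
  expect_error(top_eigenvectors(diag(3), k = 4), "exceeds")

  A3 <- diag(3)
  V <- top_eigenvectors(A3, k = 3)
  expect_equal(A3 %*% V, V %*% diag(attr(V, "values")), ignore_attr = TRUE)

  ped <- random_pedigree(30, seed = 3)
  A <- build_A(ped)
  V <- top_eigenvectors(A, k = 5)
  lam <- attr(V, "values")
  expect_true(all(diff(lam) <= 1e-12))
  for (j in 1:5) {
    expect_lt(max(abs(A %*% V[, j] - lam[j] * V[, j])), 1e-8)
    expect_equal(sum(V[, j]^2), 1)
    expect_gt(V[which.max(abs(V[, j])), j], 0)  # sign convention
  }

  # full basis reconstructs A
  ped5 <- random_pedigree(5, seed = 8)
  A5 <- build_A(ped5)
  V5 <- top_eigenvectors(A5, k = 5)
  expect_lt(max(abs(A5 - V5 %*% diag(attr(V5, "values")) %*% t(V5))), 1e-8)
})

test_that("truncate_pedigree keeps the requested ancestral depth", {
  expect_error(truncate_pedigree(random_pedigree(10), integer(0)), "empty")

  # generations = 0: only phenotyped animals, all founders
  ped <- random_pedigree(40, seed = 5)
  keep <- ped$id[30:40]
  t0 <- truncate_pedigree(ped, keep, generations = 0L)
  expect_setequal(t0$id, keep)
  expect_true(all(t0$sire == 0 & t0$dam == 0))

  # chain of depth 5, keep 3 generations: 4 animals, oldest becomes founder
  chain <- pedigree(data.frame(id = 1:6, sire = c(0, 1:5), dam = 0,
                               birth_year = 2000:2005, sex = "M"))
  t3 <- truncate_pedigree(chain, 6L, generations = 3L)
  expect_setequal(t3$id, 3:6)
  expect_equal(t3$sire[t3$id == 3], 0L)

  # no retained animal has an ancestor path longer than 3, and idempotence
  ped <- random_pedigree(150, seed = 12)
  phen <- ped$id[120:150]
  tr <- truncate_pedigree(ped, phen, generations = 3L)
  depth <- setNames(rep(0L, nrow(tr)), tr$id)
  for (i in seq_len(nrow(tr))) {
    s <- tr$si[i]; d <- tr$di[i]
    depth[i] <- 1L + max(0L, if (s > 0) depth[s] else 0L,
                         if (d > 0) depth[d] else 0L) - 1L
    # ancestors-of-phenotyped depth is checked from the top instead below
  }
  # longest ancestor path within the output, per animal
  longest_up <- rep(0L, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    s <- tr$si[i]; d <- tr$di[i]
    longest_up[i] <- 1L + max(if (s > 0) longest_up[s] else -1L,
                              if (d > 0) longest_up[d] else -1L)
  }
  expect_lte(max(longest_up[match(phen, tr$id)]), 3L)
  tr2 <- truncate_pedigree(tr, phen, generations = 3L)
  expect_equal(as.data.frame(tr)[c("id", "sire", "dam")],
               as.data.frame(tr2)[c("id", "sire", "dam")])
})
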