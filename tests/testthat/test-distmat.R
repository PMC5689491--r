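test_that("GENPOFAD site distances follow the state-set overlap formula", {
  # hom {A} vs hom {A} everywhere -> 0
  a <- haplotype_alignment(rep(c("X", "Y"), each = 2L), rep(c(0L, 1L), 2L),
                           rep("AAAAAAAAAA", 4L), "L", "nuclear")
  D <- genpofad_locus_matrix(a)
  expect_equal(unname(D["X", "Y"]), 0)

  # het {A,G} vs hom {A} at one site of ten -> 0.5 / 10
  b <- haplotype_alignment(rep(c("X", "Y"), each = 2L), rep(c(0L, 1L), 2L),
                           c("GAAAAAAAAA", "AAAAAAAAAA",
                             "AAAAAAAAAA", "AAAAAAAAAA"), "L", "nuclear")
  D <- genpofad_locus_matrix(b)
  expect_equal(unname(D["X", "Y"]), 0.05)

  # hom {A} vs hom {G} at a single-site locus -> 1; IUPAC R == {A,G}
  c1 <- haplotype_alignment(rep(c("X", "Y"), each = 2L), rep(c(0L, 1L), 2L),
                            c("A", "A", "G", "G"), "L", "nuclear")
  expect_equal(unname(genpofad_locus_matrix(c1)["X", "Y"]), 1)
  c2 <- haplotype_alignment(rep(c("X", "Y"), each = 2L), rep(c(0L, 1L), 2L),
                            c("R", "R", "A", "A"), "L", "nuclear")
  expect_equal(unname(genpofad_locus_matrix(c2)["X", "Y"]), 0.5)

  # missing sites are skipped pairwise
  c3 <- haplotype_alignment(rep(c("X", "Y"), each = 2L), rep(c(0L, 1L), 2L),
                            c("NA", "NA", "TA", "TA"), "L", "nuclear")
  expect_equal(unname(genpofad_locus_matrix(c3)["X", "Y"]), 0)
})

test_that("per-locus matrices combine with POFAD standardisation", {
  m1 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  # single matrix, standardise off -> identity
  expect_equal(combine_locus_matrices(list(m1), standardize = FALSE), m1)
  # two equal matrices -> either one
  expect_equal(combine_locus_matrices(list(m1, m1), standardize = FALSE), m1)
  # maxima 2 and 4 scaled to 1 then averaged -> off-diagonal 1
  comb <- combine_locus_matrices(list(m1, m2), standardize = TRUE)
  expect_equal(unname(comb["a", "b"]), 1)
  m3 <- m2; rownames(m3) <- colnames(m3) <- c("a", "z")
  expect_error(combine_locus_matrices(list(m1, m3)), "label sets differ")
})

test_that("site-level aggregation averages cross-site pairs", {
  D <- matrix(c(0, 1, 3,
                1, 0, 5,
                3, 5, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tab <- data.frame(individual_id = c("a", "b", "c"),
                    site_id = c("s1", "s1", "s2"),
                    lat = c(0, 0, 1), lon = c(0, 0, 1))
  S <- site_level_matrix(D, validate_sample_table(tab))
  expect_equal(unname(S["s1", "s2"]), (3 + 5) / 2)
  expect_equal(unname(diag(S)), c(0, 0))

  # one individual per site reproduces the individual matrix
  tab2 <- data.frame(individual_id = c("a", "b", "c"),
                     site_id = c("s1", "s2", "s3"),
                     lat = 0:2, lon = 0:2)
  S2 <- site_level_matrix(D, validate_sample_table(tab2))
  expect_equal(unname(S2), unname(D))
})

test_that("great-circle distances use the haversine closed form", {
  tab <- validate_sample_table(data.frame(
    individual_id = c("a", "b", "c"),
    site_id = c("s1", "s2", "s3"),
    lat = c(0, 0, 0), lon = c(0, 90, 0)))
  G <- geographic_distance_matrix(tab)
  expect_equal(unname(G["s1", "s2"]), 2 * pi * 6371 / 4, tolerance = 1e-6)
  expect_equal(unname(G["s1", "s3"]), 0)
  expect_equal(G, t(G))
})

test_that("Mantel statistic equals the hand Pearson value on the triangles", {
  set.seed(7)
  A <- matrix(0, 4, 4); A[upper.tri(A)] <- c(1, 2, 3, 4, 5, 6)
  A <- A + t(A)
  B <- matrix(0, 4, 4); B[upper.tri(B)] <- c(2, 1, 4, 3, 7, 5)
  B <- B + t(B)
  dimnames(A) <- dimnames(B) <- list(letters[1:4], letters[1:4])
  res <- mantel_test(A, B, n_perm = 99, rng_seed = 1)
  expect_equal(res$r, cor(A[upper.tri(A)], B[upper.tri(B)]))
  expect_equal(res$r_squared, res$r^2)

  # identical matrices: r = 1, smallest attainable one-tailed p
  big <- as.matrix(dist(matrix(rnorm(16), 8)))
  dimnames(big) <- list(letters[1:8], letters[1:8])
  res2 <- mantel_test(big, big, n_perm = 999, rng_seed = 1)
  expect_equal(res2$r, 1)
  expect_lte(res2$p, 2 / (999 + 1))
})

test_that("Mantel is invariant to consistent relabeling and rejects degenerate input", {
  set.seed(8)
  A <- as.matrix(dist(matrix(rnorm(10), 5)))
  B <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(A) <- dimnames(B) <- list(letters[1:5], letters[1:5])
  r1 <- mantel_test(A, B, n_perm = 49, rng_seed = 2)$r
  perm <- c(3, 1, 5, 2, 4)
  A2 <- A[perm, perm]; B2 <- B[perm, perm]
  r2 <- mantel_test(A2, B2, n_perm = 49, rng_seed = 2)$r
  expect_equal(r1, r2)

  Z <- matrix(1, 5, 5); diag(Z) <- 0
  dimnames(Z) <- dimnames(A)
  expect_error(mantel_test(Z, B, n_perm = 9), "zero variance")
})

test_that("log10 transform replaces zeros by half the smallest positive entry", {
  A <- matrix(c(0, 0, 2,
                0, 0, 4,
                2, 4, 0), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  B <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- mantel_test(A, B, n_perm = 9, transform = "log10", rng_seed = 1)
  va <- log10(c(1, 2, 4))  # zero -> min(2,4)/2 = 1
  vb <- log10(c(1, 2, 3))
  expect_equal(res$r, cor(va, vb))
})

test_that("distance matrices round-trip through TSV", {
  set.seed(9)
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  tmp <- tempfile(fileext = ".tsv")
  write_distance_matrix(D, tmp)
  expect_equal(read_distance_matrix(tmp), D)
})
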