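# a minimal synthetic dataset: two spatial groups fixed for alternative
# alleles at three loci
two_group_data <- function(n_per = 20L) {
  ids <- sprintf("i%02d", seq_len(2L * n_per))
  grp <- rep(c("L", "R"), each = n_per)
  seqs <- ifelse(grp == "L", "AAAA", "TTTT")
  alns <- lapply(1:3, function(l)
    haplotype_alignment(ids, rep(0L, length(ids)), seqs,
                        paste0("loc", l), "mitochondrial"))
  tab <- validate_sample_table(data.frame(
    individual_id = ids,
    site_id = rep(c("s1", "s2", "s3", "s4"), each = n_per / 2L),
    lat = rep(c(0, 0.1, 5, 5.1), each = n_per / 2L),
    lon = rep(c(0, 0.1, 5, 5.1), each = n_per / 2L)))
  list(alignments = alns, sample_table = tab, truth = setNames(grp, ids))
}

test_that("collapsed likelihood equals the Dirichlet-multinomial integral", {
  # 2 alleles, 3 individuals: P(data | one colour) = Beta(n1+1, n2+1)
  aln <- haplotype_alignment(c("a", "b", "c"), rep(0L, 3L),
                             c("A", "A", "T"), "x", "mitochondrial")
  ad <- esudelim:::.allele_data(list(aln), c("a", "b", "c"))
  ll1 <- esudelim:::.cluster_loglik(c(1L, 1L, 1L), ad, 5L)
  quad <- integrate(function(p) p^2 * (1 - p), 0, 1)$value  # flat Dirichlet prior
  expect_equal(ll1, log(quad), tolerance = 1e-8)

  # split colouring {a,b | c}: product of two marginals
  ll2 <- esudelim:::.cluster_loglik(c(1L, 1L, 2L), ad, 5L)
  quad2 <- integrate(function(p) p^2, 0, 1)$value *
           integrate(function(p) (1 - p), 0, 1)$value
  expect_equal(ll2, log(quad2), tolerance = 1e-8)
})

test_that("two runs with the same seed give identical traces", {
  d <- two_group_data(6L)
  cfg <- cluster_config(n_iter = 2000, thinning = 10, rng_seed = 42)
  t1 <- run_mcmc(d$alignments, d$sample_table, cfg)
  t2 <- run_mcmc(d$alignments, d$sample_table, cfg)
  expect_identical(t1$cols, t2$cols)
  expect_identical(t1$log_post, t2$log_post)
  expect_identical(t1$effK, t2$effK)
})

test_that("strongly differentiated spatial groups are split into two units", {
  d <- two_group_data(20L)
  hits <- 0L
  for (seed in 1:3) {
    tr <- run_mcmc(d$alignments, d$sample_table,
                   cluster_config(n_iter = 8000, thinning = 10, rng_seed = seed))
    pk <- posterior_K(tr)
    if (names(pk)[which.max(pk)] == "2") hits <- hits + 1L
    mp <- modal_partition(tr)
    expect_true(all(table(mp, d$truth[names(mp)]) %in% c(0L, 20L)))
  }
  expect_gte(hits, 2L)
})

test_that("monomorphic data collapse to a single unit", {
  d <- two_group_data(10L)
  mono <- lapply(d$alignments, function(a) { a$seq[] <- "A"; a })
  tr <- run_mcmc(mono, d$sample_table,
                 cluster_config(n_iter = 6000, thinning = 10, rng_seed = 9))
  pk <- posterior_K(tr)
  expect_equal(names(pk)[which.max(pk)], "1")
})

test_that("posterior_K and modal_partition obey their contracts on a fixed trace", {
  # hand-built trace: two iterations that are label-swapped copies
  fake <- structure(list(
    ind_ids = c("a", "b", "c", "d"),
    coords = cbind(c(0, 0, 1, 1), c(0, 0, 1, 1)),
    bbox = c(-0.5, 1.5, -0.5, 1.5), K_max = 10L, lambda = 4,
    cols = cbind(c(1L, 1L, 2L, 2L), c(5L, 5L, 3L, 3L)),
    effK = c(2L, 2L), log_post = c(-10, -11),
    nuclei = list(list(xy = cbind(c(0, 1), c(0, 1)), col = c(1L, 2L)),
                  list(xy = cbind(c(0, 1), c(0, 1)), col = c(5L, 3L)))),
    class = "cluster_trace")
  pk <- posterior_K(fake)
  expect_equal(unname(pk[["2"]]), 1)
  mp <- modal_partition(fake)
  expect_equal(unname(mp["a"]), unname(mp["b"]))
  expect_equal(unname(mp["c"]), unname(mp["d"]))
  expect_false(unname(mp["a"]) == unname(mp["c"]))
  co <- attr(mp, "coassignment")
  expect_equal(unname(co["a", "b"]), 1)   # same colour in every iteration
  expect_equal(unname(co["a", "c"]), 0)

  surf <- membership_surface(fake, list(nx = 4L, ny = 4L))
  expect_true(all(abs(rowSums(surf$prob) - 1) < 1e-9))

  empty <- fake; empty$effK <- integer(0); empty$cols <- fake$cols[, 0]
  expect_error(posterior_K(empty), "empty trace")
  expect_error(membership_surface(fake, list(nx = 0L, ny = 0L)), "empty grid")
})

test_that("membership surface is consistent with individual co-assignment", {
  d <- two_group_data(10L)
  tr <- run_mcmc(d$alignments, d$sample_table,
                 cluster_config(n_iter = 6000, thinning = 10, rng_seed = 3))
  surf <- membership_surface(tr, list(nx = 25L, ny = 25L))
  expect_true(all(surf$prob >= 0 & surf$prob <= 1))
  expect_true(all(abs(rowSums(surf$prob) - 1) < 1e-9))
  # the cell nearest a sampled individual should agree with its modal colour
  mp <- modal_partition(tr)
  al <- esudelim:::.align_trace(tr)$aligned
  ind_modal_col <- apply(al, 1L, function(v) which.max(tabulate(v, tr$K_max)))
  cells <- cbind(rep(surf$x, times = length(surf$y)),
                 rep(surf$y, each = length(surf$x)))
  for (i in c(1L, 15L)) {
    ci <- which.min((cells[, 1] - tr$coords[i, 1])^2 +
                    (cells[, 2] - tr$coords[i, 2])^2)
    expect_equal(which.max(surf$prob[ci, ]), unname(ind_modal_col[i]))
  }
})
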