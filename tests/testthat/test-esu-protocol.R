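test_that("the catalogue encodes the eight migration/collapse hypotheses", {
  cat3 <- model_catalogue(c("C", "P", "Q"))
  expect_length(cat3, 8L)

  n_routes <- vapply(cat3, function(s) length(s$routes), 0L)
  expect_equal(unname(n_routes), c(3L, 2L, 2L, 1L, 0L, 1L, 0L, 0L))

  # gene flow, when present, is bidirectional: two directed M per route
  for (s in cat3)
    expect_equal(sum(s$param_type == "M"), 2L * length(s$routes))

  # model 2 isolates P-Q, model 3 isolates C-Q; the sister route stays open
  expect_false(list(c("P", "Q")) %in% cat3[["2"]]$routes)
  expect_true(all(vapply(cat3[["2"]]$routes, function(r)
    setequal(r, c("C", "P")) || setequal(r, c("C", "Q")), TRUE)))
  expect_true(all(vapply(cat3[["3"]]$routes, function(r)
    setequal(r, c("C", "P")) || setequal(r, c("P", "Q")), TRUE)))

  # collapse structure: 6/7 have two demes, 8 has one
  expect_length(cat3[["6"]]$demes, 2L)
  expect_length(cat3[["7"]]$demes, 2L)
  expect_length(cat3[["8"]]$demes, 1L)
  # forced root join only where the migration graph is disconnected
  expect_equal(names(which(!vapply(cat3, function(s)
    is.null(s$root_cap), TRUE))), c("4", "5", "7"))
  for (m in c("4", "5", "7")) {
    p <- numeric(length(cat3[[m]]$param_type)); p[] <- 1
    mod <- cat3[[m]]$make(p); mod$root_cap <- NULL
    expect_equal(isolation_check(mod), "needs_root_cap")
  }
  expect_error(model_catalogue(c("A", "B")), "3 BUs")
})

test_that("the ESU decision rule is a function of the collapse structure only", {
  cat3 <- model_catalogue(c("C", "P", "Q"))
  expect_equal(lengths(esu_set_from_model(cat3[["3"]])),
               c(C = 1L, P = 1L, Q = 1L))
  e7 <- esu_set_from_model(cat3[["7"]])
  expect_length(e7, 2L)
  expect_setequal(e7$CP, c("C", "P"))
  expect_equal(e7$Q, "Q")
  expect_length(esu_set_from_model(cat3[["8"]]), 1L)
  expect_setequal(esu_set_from_model(cat3[["8"]])$ALL, c("C", "P", "Q"))
})

test_that("mtDNA exclusivity flags shared haplotypes per ESU pair", {
  ids <- sprintf("i%d", 1:6)
  esu <- setNames(rep(c("C", "P", "Q"), each = 2L), ids)
  # disjoint haplotype sets -> all exclusive
  aln <- haplotype_alignment(ids, rep(0L, 6L),
                             c("AA", "AA", "TT", "TT", "GG", "GG"),
                             "mt", "mitochondrial")
  ex <- mtdna_exclusivity(aln, esu)
  expect_true(all(ex[upper.tri(ex)]))
  expect_true(attr(ex, "all_exclusive"))

  # one haplotype shared between C and P only
  aln2 <- haplotype_alignment(ids, rep(0L, 6L),
                              c("AA", "AA", "AA", "TT", "GG", "GG"),
                              "mt", "mitochondrial")
  ex2 <- mtdna_exclusivity(aln2, esu)
  expect_false(ex2["C", "P"])
  expect_true(ex2["C", "Q"])
  expect_true(ex2["P", "Q"])
  expect_false(attr(ex2, "all_exclusive"))
})

test_that("mtDNA exclusivity becomes more likely with deeper splits", {
  L1 <- single_locus()
  ss <- matrix(c(12L, 12L), 1, 2, dimnames = list("L1", c("A", "B")))
  frac_excl <- vapply(c(0.1, 2), function(tau) {
    m <- demographic_model(c(A = 2, B = 2),
                           splits = data.frame(time = tau, from = "A", to = "B"),
                           loci = L1)
    set.seed(500 + round(tau * 10))
    mean(replicate(40, {
      sim <- simulate_dataset(m, ss, want_matrix = TRUE)
      geno <- sim$genotypes[[1L]]
      seqs <- if (ncol(geno)) apply(geno, 1L, paste, collapse = "") else
        rep("0", nrow(geno))
      !any(duplicated(unique(cbind(sim$leaf_group[[1L]], seqs))[, 2L]))
    }))
  }, 0.0)
  expect_gt(frac_excl[2L], frac_excl[1L])
  expect_gt(frac_excl[2L], 0.8)
})

test_that("model averaging mixes posteriors with point mass at absent parameters", {
  mk_post <- function(pars, means, n = 50L) {
    draws <- matrix(rep(means, each = n), n, dimnames = list(NULL, pars))
    structure(list(raw = draws, adjusted = draws, weights = rep(1, n),
                   summary = data.frame(parameter = pars, mean = means,
                                        median = means, hpd_lower = means,
                                        hpd_upper = means),
                   tolerance = 0.1, method = "loclinear", level = 0.95),
              class = "abc_posterior")
  }
  pA <- mk_post(c("theta_C", "M_C.P"), c(2, 10))
  pB <- mk_post("theta_C", 4)

  # single model with probability 1 -> identity
  one <- model_average_params(list(A = pA), c(A = 1))
  expect_equal(one$mean[["theta_C"]], 2)

  # 0.5/0.5 with M present in one model only -> averaged M halves
  set.seed(1)
  avg <- model_average_params(list(A = pA, B = pB), c(A = 0.5, B = 0.5))
  expect_equal(avg$mean[["theta_C"]], 3)
  expect_equal(avg$mean[["M_C.P"]], 5)
  expect_true(all(avg$draws[, "M_C.P"] %in% c(0, 10)))

  # weights not summing to 1 are renormalised with a warning
  expect_warning(model_average_params(list(A = pA, B = pB), c(A = 2, B = 2)),
                 "renormalising")
  expect_error(model_average_params(list(A = pA), c(Z = 1)), "differ")
})

test_that("validation selects a strongly supported model and maps the ESU set", {
  ss <- study_sample_sizes()
  cat3 <- model_catalogue(c("C", "P", "Q"))
  # pseudo-observed data from model 7 (sisters collapsed, isolated from Q):
  # extreme contrast, identifiable even with small tables
  p7 <- c(2, 2)
  set.seed(77)
  obs <- sim_summary_vector(simulate_dataset(cat3[["7"]]$make(p7), ss,
                                             group_deme = cat3[["7"]]$group_deme),
                            deme_labels = c("C", "P", "Q"))
  val <- validate_esus(obs, cat3, ss, n_sims = 400L, tolerance = 0.02,
                       rng_seed = 3L)
  expect_s3_class(val, "esu_validation")
  expect_equal(sum(val$prob), 1)
  expect_equal(val$best, "7")
  expect_length(val$esus, 2L)
  expect_setequal(val$esus$CP, c("C", "P"))
})

test_that("the full pipeline runs end-to-end on a synthetic fixture", {
  d <- generate_study_like_dataset(study_template(rng_seed = 1))
  cfg <- list(cluster = cluster_config(n_iter = 12000, thinning = 20,
                                       rng_seed = 5),
              n_perm = 499, n_sims_choice = 250, n_sims_est = 400,
              tolerance_choice = 0.02, tolerance_est = 0.1, rng_seed = 5)
  rep1 <- run_pipeline(d$alignments, d$sample_table, cfg)
  expect_s3_class(rep1, "esu_report")
  expect_equal(names(which.max(rep1$posterior_K)), "3")
  expect_equal(sum(rep1$validation$prob), 1)
  expect_true(rep1$ibd$p > 0 & rep1$ibd$p <= 1)
  expect_length(rep1$summaries, 3L)
  expect_false(is.null(rep1$mtdna_exclusivity))

  # reruns with the same configuration reproduce the same numbers
  rep2 <- run_pipeline(d$alignments, d$sample_table, cfg)
  expect_identical(rep1$assignment, rep2$assignment)
  expect_identical(rep1$validation$prob, rep2$validation$prob)
  expect_identical(rep1$ibd$r, rep2$ibd$r)
  if (!is.null(rep1$estimation))
    expect_identical(rep1$estimation$posterior$summary,
                     rep2$estimation$posterior$summary)

  # a missing locus file fails validation before any compute
  expect_error(run_pipeline(d$alignments,
                            d$sample_table[-1, ], cfg),
               "without sample-table rows")
})
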