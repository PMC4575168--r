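test_that("homolog frequencies use square-root replicate weighting", {
  # one sequence repeated 9x (weight 3) and one unique (weight 1):
  # a site where they differ gives 0.75 / 0.25
  aln <- c(rep("AY", 9), "AW")
  sm <- c(s1 = 1L, s2 = 2L)
  fm <- homolog_frequency_matrix(aln, sm)
  expect_equal(unname(fm["s2", c("Y", "W")]), c(0.75, 0.25))
  expect_equal(unname(fm["s1", "A"]), 1)
  # all-unique alignment reduces to plain counting
  aln2 <- c("AY", "AW", "AY", "AF")  # note: AY repeated -> weight sqrt(2)
  fm2 <- homolog_frequency_matrix(c("AY", "AW", "CF"), sm)
  expect_equal(unname(fm2["s1", c("A", "C")]), c(2 / 3, 1 / 3))
  # gaps are excluded per site
  fm3 <- homolog_frequency_matrix(c("A-", "AY"), sm)
  expect_equal(unname(fm3["s2", "Y"]), 1)
  expect_error(homolog_frequency_matrix(c("AY"), c(s1 = 1, s2 = 5)),
               "outside")
})

test_that("packaged homolog fixture matches a brute-force weighted count", {
  path <- system.file("extdata", "synthetic_fn3_homologs.fasta",
                      package = "loopscape")
  aln <- as.character(Biostrings::readAAStringSet(path))
  site_map <- c(D23 = 23L, V29 = 29L, G52 = 52L, S85 = 85L)
  fm <- homolog_frequency_matrix(path, site_map)
  for (s in names(site_map)) {
    tab <- table(unname(aln))
    col <- substr(names(tab), site_map[[s]], site_map[[s]])
    w <- sqrt(as.numeric(tab))
    keep <- col %in% AA20
    expect_gt(sum(keep), 0)
    ora <- tapply(w[keep], col[keep], sum)
    ora <- ora / sum(ora)
    expect_equal(fm[s, names(ora)], ora[names(ora)], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("stability matrices convert by Boltzmann weighting", {
  sm <- matrix(0, 3, 20, dimnames = list(c("a", "b", "c"), AA20))
  sm["a", "C"] <- -2
  sm["c", ] <- rnorm(20)
  f <- stability_to_frequency(sm, RT = 0.59)
  expect_equal(unname(f["b", ]), rep(0.05, 20))
  expect_equal(unname(f["a", "C"]), exp(2 / 0.59) / (exp(2 / 0.59) + 19),
               tolerance = 1e-12)
  # RT -> Inf limit is uniform
  f_inf <- stability_to_frequency(sm, RT = 1e9)
  expect_equal(unname(f_inf["c", ]), rep(0.05, 20), tolerance = 1e-6)
  expect_error(stability_to_frequency(sm, RT = 0))
})

test_that("mutational tolerance counts minimally destabilising residues", {
  sm <- matrix(5, 2, 20, dimnames = list(c("a", "b"), AA20))
  sm["a", ] <- 0
  sm["b", 1:5] <- 0.5
  expect_equal(unname(mutational_tolerance(sm)), c(20, 5))
  expect_equal(unname(mutational_tolerance(sm, threshold = 6)), c(20, 20))
})

test_that("the convergence driver stops by the running-mean rule", {
  # constant oracle: converges at exactly min_n + 1 with the exact value
  cv <- convergence_driver(function(s, r) 1.25, "a", "A")
  expect_equal(cv$mean, 1.25)
  expect_equal(cv$n, 51)
  # noisy oracle: converged mean within 0.1 of truth across seeds
  errs <- vapply(1:10, function(seed) {
    set.seed(seed)
    cv <- convergence_driver(function(s, r) 0.8 + rnorm(1, 0, 0.05),
                             "a", "A")
    abs(cv$mean - 0.8)
  }, numeric(1))
  expect_true(all(errs < 0.1))
  # diverging oracle never converges
  env <- new.env(); env$i <- 0
  bad <- function(s, r) { env$i <- env$i + 1; env$i * 0.5 }
  expect_error(convergence_driver(bad, "a", "A", max_n = 200),
               "did not converge")
  expect_error(convergence_driver(function(s, r) NaN, "a", "A"),
               "non-finite")
})

test_that("constrained least squares recovers planted weights exactly", {
  for (seed in 1:10) {
    cs <- planted_fit_case(seed)
    fit <- fit_weights(cs$objective, cs$inputs, cs$eps)
    expect_lt(max(abs(fit$alpha - cs$alpha)), 1e-6)
    expect_lt(max(abs(fit$beta - cs$beta)), 1e-6)
    expect_lt(fit$residual, 1e-12)
    expect_equal(sum(fit$alpha), 1, tolerance = 1e-9)
    expect_equal(sum(fit$beta), 0, tolerance = 1e-9)
  }
})

test_that("fit edge cases: single input, rank deficiency, residual invariance", {
  cs <- planted_fit_case(42)
  # single input forces alpha = 1, beta = 0
  f1 <- fit_weights(cs$inputs[[1]], cs$inputs[1], cs$eps)
  expect_equal(unname(f1$alpha), 1)
  expect_equal(unname(f1$beta), 0)
  expect_equal(f1$residual, 0, tolerance = 1e-20)
  # duplicated inputs are non-identifiable
  expect_error(fit_weights(cs$objective,
                           list(a = cs$inputs[[1]], b = cs$inputs[[1]]),
                           cs$eps), "non-identifiable")
  # residual is invariant to site permutation and to a consistent
  # amino-acid column permutation
  fit <- fit_weights(cs$objective, cs$inputs, cs$eps)
  perm <- sample(rownames(cs$objective))
  permute <- function(fm) {
    m <- unclass(fm)[perm, ]
    as_fm(m)
  }
  fit_p <- fit_weights(permute(cs$objective), lapply(cs$inputs, permute),
                       cs$eps[perm])
  expect_equal(fit_p$residual, fit$residual, tolerance = 1e-9)
  aaperm <- sample(AA20)
  permaa <- function(fm) as_fm(unclass(fm)[, aaperm])
  fit_a <- fit_weights(permaa(cs$objective), lapply(cs$inputs, permaa),
                       cs$eps)
  expect_equal(fit_a$residual, fit$residual, tolerance = 1e-9)
  expect_equal(fit_a$alpha, fit$alpha, tolerance = 1e-9)
})

test_that("effective weights are linear in exposure and sum to one", {
  cs <- planted_fit_case(7)
  fit <- fit_weights(cs$objective, cs$inputs, cs$eps)
  ew <- effective_weights(fit, c(0, 0.5, 0.7, 1))
  expect_equal(unname(ew["0", ]), unname(fit$alpha), tolerance = 1e-9)
  expect_equal(unname(rowSums(ew)), rep(1, 4), tolerance = 1e-9)
  # slope in eps equals beta
  expect_equal(unname(ew["1", ] - ew["0", ]), unname(fit$beta),
               tolerance = 1e-9)
})

test_that("z-score separates informative inputs from the unbiased control", {
  cs <- planted_fit_case(3)
  fit <- fit_weights(cs$objective, cs$inputs, cs$eps)
  z <- zscore_vs_unbiased(fit, cs$objective, cs$inputs, cs$eps,
                          n_boot = 100, seed = 9)
  expect_gt(z$z, 5)
  # deterministic under a fixed seed
  z2 <- zscore_vs_unbiased(fit, cs$objective, cs$inputs, cs$eps,
                           n_boot = 100, seed = 9)
  expect_identical(z$z, z2$z)
  # near-uniform inputs give |z| < 0.5 (null)
  set.seed(31)
  uni <- lapply(1:3, function(i)
    as_fm(matrix(0.05, 25, 20, dimnames = dimnames(cs$objective)) +
            matrix(rnorm(500, 0, 1e-4), 25, 20)))
  obj_u <- as_fm(matrix(0.05, 25, 20, dimnames = dimnames(cs$objective)) +
                   matrix(rnorm(500, 0, 0.01), 25, 20))
  fit_u <- fit_weights(obj_u, uni, cs$eps)
  z_u <- zscore_vs_unbiased(fit_u, obj_u, uni, cs$eps, n_boot = 100,
                            seed = 11)
  expect_lt(abs(z_u$z), 0.5)
  small <- as_fm(unclass(cs$objective)[1:3, ])
  fit_s <- fit_weights(small, lapply(cs$inputs, function(f)
    as_fm(unclass(f)[1:3, ])), cs$eps[1:3])
  expect_error(zscore_vs_unbiased(fit_s, small,
                                  lapply(cs$inputs, function(f)
                                    as_fm(unclass(f)[1:3, ])),
                                  cs$eps[1:3]), "at least 5")
})

test_that("site-matrix TSV round-trips", {
  fm <- random_fm(5)
  tmp <- tempfile(fileext = ".tsv")
  write_site_matrix(fm, tmp)
  back <- read_site_matrix(tmp, frequency = TRUE)
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
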