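b16 <- receptor_context("B16F0")

fake_fit <- function(sse, n_obs, model_id = "canonical") {
  structure(list(model_id = model_id, readout = "pAkt", cell_line = "B16F0",
                 params = mechanism_params(k_c = 1, tots = 1, k_d_phos = 1),
                 sse = sse, n_obs = n_obs, n_free = 3),
            class = "mechanism_fit")
}

test_that("noise-free canonical data are recovered to optimizer tolerance", {
  truth <- mechanism_params(k_c = 60.7, tots = 2000, k_d_phos = 5e4)
  d <- suppressMessages(gen_phospho(
    phospho_design(mechanism = "canonical", truth = truth, noise_frac = 0,
                   seed = 5), b16))
  f <- fit_mechanism("canonical", d, b16)
  expect_lt(f$sse, 1e-6)
  expect_equal(f$params$k_c, 60.7, tolerance = 1e-3)
  expect_equal(f$params$tots, 2000, tolerance = 1e-3)
  expect_equal(f$params$k_d_phos, 5e4, tolerance = 1e-3)
  expect_gt(f$n_obs, f$n_free)
})

test_that("constant-MFI data are explained ligand-independently", {
  d <- expand.grid(il12_ng_ml = c(0, 7, 100, 300),
                   il12rb2_copies = c(1e4, 1e5, 1e6))
  d$cell_line <- "B16F0"; d$readout <- "pAkt"; d$mfi <- 500
  non <- fit_mechanism("noncanonical", d, b16)
  can <- suppressWarnings(fit_mechanism("canonical", d, b16))
  expect_lt(non$sse, 1e-4)
  # the canonical model predicts zero signal for the unstimulated rows,
  # so its SSE is bounded below by those residuals
  n_zero <- sum(d$il12_ng_ml == 0)
  expect_gt(can$sse, 0.9 * n_zero * 500^2)
})

test_that("Bayes factors follow the SSE^(-N/2) arithmetic exactly", {
  expect_equal(bayes_factor(fake_fit(1, 2), fake_fit(4, 2)), 4)
  expect_equal(bayes_factor(fake_fit(3, 10), fake_fit(3, 10)), 1)
  # reciprocal identity and oracle agreement on random fits
  withr::with_seed(23, {
    for (i in 1:10) {
      si <- runif(1, 0.1, 50); sj <- runif(1, 0.1, 50); n <- sample(5:80, 1)
      bij <- bayes_factor(fake_fit(si, n), fake_fit(sj, n))
      bji <- bayes_factor(fake_fit(sj, n), fake_fit(si, n))
      expect_equal(bij * bji, 1, tolerance = 1e-10)
      expect_equal(bij, (si / sj)^(-n / 2), tolerance = 1e-10)
    }
  })
  expect_error(bayes_factor(fake_fit(1, 2), fake_fit(1, 3)), "n_obs")
  expect_error(bayes_factor(fake_fit(1, 2), fake_fit(0, 2)), "degenerate")
})

test_that("evidence grading uses the 3 / 20 / 150 scale with reciprocity", {
  expect_identical(as.character(grade_evidence(2)), "weak")
  expect_identical(as.character(grade_evidence(1)), "weak")
  expect_identical(as.character(grade_evidence(5)), "positive")
  expect_identical(as.character(grade_evidence(30)), "strong")
  expect_identical(as.character(grade_evidence(151)), "very_strong")
  expect_identical(as.character(grade_evidence(Inf)), "very_strong")
  g <- grade_evidence(0.1)
  expect_identical(as.character(g), "positive")
  expect_identical(attr(g, "favors"), "j")
  expect_error(grade_evidence(0), "positive number")
})

test_that("hybrid data favor the hybrid model over the canonical one", {
  d <- suppressMessages(gen_phospho(phospho_design(seed = 11), b16))
  sel <- select_mechanism(d, b16)
  expect_lt(sel$fits$hybrid$sse, sel$fits$canonical$sse)
  expect_identical(sel$ranking[1], "hybrid")
  expect_true(all(diag(sel$bf) == 1))
  # pairwise reciprocity on the log scale
  expect_equal(sel$log_bf, -t(sel$log_bf), tolerance = 1e-10)
})

test_that("the hybrid fit never loses to the models it nests", {
  designs <- list(
    phospho_design(mechanism = "canonical",
                   truth = mechanism_params(k_c = 60.7, tots = 2000,
                                            k_d_phos = 5e4), seed = 2),
    phospho_design(mechanism = "noncanonical",
                   truth = mechanism_params(k_n = 4, tots = 2000,
                                            k_d_phos = 5e4), seed = 3),
    phospho_design(seed = 4))
  for (des in designs) {
    d <- suppressMessages(gen_phospho(des, b16))
    sel <- select_mechanism(d, b16)
    sse <- vapply(sel$fits, `[[`, numeric(1), "sse")
    expect_lte(sse["hybrid"],
               min(sse["canonical"], sse["noncanonical"]) * (1 + 1e-6))
  }
})

test_that("a shared ligand constant couples readouts within a cell line", {
  truth_akt <- mechanism_params(k_c = 60.7, k_n = 4, tots = 2000,
                                k_d_phos = 5e4)
  truth_stat4 <- mechanism_params(k_c = 60.7, k_n = 12, tots = 900,
                                  k_d_phos = 2e4)
  mk <- function(truth, readout, seed)
    suppressMessages(gen_phospho(
      phospho_design(truth = truth, noise_frac = 0.02, seed = seed), b16,
      readout = readout))
  datasets <- list(pAkt = mk(truth_akt, "pAkt", 31),
                   pSTAT4 = mk(truth_stat4, "pSTAT4", 32))

  # single readout reduces to the independent fit
  solo <- fit_shared_kc(datasets["pAkt"], "hybrid", b16)
  indep <- fit_mechanism("hybrid", datasets$pAkt, b16)
  expect_equal(solo$fits[[1]]$sse, indep$sse, tolerance = 1e-6)

  # common k_c generated the two readouts: the joint fit recovers it
  joint <- fit_shared_kc(datasets, "hybrid", b16)
  expect_equal(joint$k_c, 60.7, tolerance = 0.05)
  expect_equal(joint$fits$pAkt$params$k_c, joint$fits$pSTAT4$params$k_c)

  # wildly different k_c: the constrained optimum must be worse than the
  # sum of unconstrained optima
  far <- list(pAkt = datasets$pAkt,
              pSTAT4 = suppressMessages(gen_phospho(
                phospho_design(truth = mechanism_params(
                  k_c = 0.05, k_n = 12, tots = 900, k_d_phos = 2e4),
                  noise_frac = 0.02, seed = 33), b16, readout = "pSTAT4")))
  joint_far <- fit_shared_kc(far, "hybrid", b16)
  indep_sse <- fit_mechanism("hybrid", far$pAkt, b16)$sse +
    fit_mechanism("hybrid", far$pSTAT4, b16)$sse
  expect_gt(joint_far$joint_sse, indep_sse)
})
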