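test_that("activation mechanisms reproduce hand-evaluated equilibria", {
  # canonical: no ligand -> none; half-saturation; B16F0-like constant
  expect_equal(arc_canonical(1e5, 0, 60.7)$arc1, 0)
  expect_equal(arc_canonical(1e5, 60.7, 60.7)$arc1, 5e4)
  expect_equal(arc_canonical(1e5, 100, 60.7)$arc1, 1e5 * 100 / 160.7)
  expect_equal(arc_canonical(1e5, 100, 60.7)$arc2, 0)

  # non-canonical: density-driven, ligand never enters
  expect_equal(arc_noncanonical(1000, 1)$arc2, 500)
  expect_lt(arc_noncanonical(1000, 1e12)$arc2, 1e-6)
  # melanoma-scale homodimer pool: 330,000 copies -> 165,000 complexes
  totrc <- complexes_from_copies(330000, receptor_context("B16F0"))
  expect_equal(totrc, 165000)
  expect_equal(arc_noncanonical(totrc, 4)$arc2, 33000)

  # hybrid at il12 = k_c, k_n = 1: f = g = 1/2 -> arc1 = totrc/3
  st <- arc_hybrid(1000, 25, 25, 1)
  expect_equal(st$arc1, 1000 / 3)
  expect_equal(st$arc2, (1000 - 1000 / 3) / 2)
})

test_that("mechanisms conserve receptors and respond monotonically to ligand", {
  withr::with_seed(17, {
    for (i in 1:20) {
      totrc <- runif(1, 10, 1e6)
      k_c <- 10^runif(1, -2, 3)
      k_n <- 10^runif(1, -2, 3)
      il12 <- sort(c(0, 10^runif(5, -2, 3)))
      can <- arc_canonical(totrc, il12, k_c)
      non <- arc_noncanonical(rep(totrc, 6), k_n)
      hyb <- arc_hybrid(totrc, il12, k_c, k_n)
      for (st in list(can, non, hyb)) {
        expect_true(all(st$arc1 >= 0 & st$arc2 >= 0))
        expect_true(all(st$arc1 + st$arc2 <= totrc * (1 + 1e-12)))
      }
      expect_true(all(diff(can$arc1) > 0))
      expect_true(all(diff(hyb$arc1 + hyb$arc2) > 0))
      expect_true(all(non$arc2 == non$arc2[1]))
    }
  })
})

test_that("hybrid mechanism nests both pure mechanisms in its limits", {
  totrc <- 2.4e5; k_c <- 60.7; k_n <- 4
  il12 <- c(0, 7, 100, 300)

  # il12 = 0 reduces to the non-canonical state
  at0 <- arc_hybrid(totrc, 0, k_c, k_n)
  expect_equal(at0$arc1, 0)
  expect_equal(at0$arc2, arc_noncanonical(totrc, k_n)$arc2)

  # k_n -> Inf reduces to the canonical state
  lim <- arc_hybrid(totrc, il12, k_c, 1e9)
  can <- arc_canonical(totrc, il12, k_c)
  expect_equal(lim$arc1, can$arc1, tolerance = 1e-6)
  expect_lt(max(lim$arc2 / totrc), 1e-6)
})

test_that("equilibria agree with ODE relaxation of the mass-action schemes", {
  library(deSolve)
  relax <- function(deriv, y0, parms, idx) {
    out <- deSolve::lsoda(y0, c(0, 1e7), deriv, parms,
                          rtol = 1e-10, atol = 1e-8)
    out[nrow(out), idx + 1]   # first column is time
  }
  cases <- list(list(totrc = 1000, il12 = 5, k_c = 2, k_n = 0.5),
                list(totrc = 5e4, il12 = 120, k_c = 60.7, k_n = 4),
                list(totrc = 300, il12 = 0.4, k_c = 0.32, k_n = 30))
  for (cs in cases) {
    # canonical: dARC/dt = kf*IL12*(TOTRC - ARC) - kr*ARC, K_C = kr/kf
    d_can <- function(t, y, p)
      list(p$kf * p$il12 * (p$totrc - y[1]) - p$kr * y[1])
    arc_ode <- relax(d_can, c(arc = 0),
                     list(kf = 1, kr = cs$k_c, il12 = cs$il12,
                          totrc = cs$totrc), 1)
    expect_equal(arc_ode, arc_canonical(cs$totrc, cs$il12, cs$k_c)$arc1,
                 tolerance = 1e-4, ignore_attr = TRUE)

    # non-canonical: dARC/dt = kf*(TOTRC - ARC) - kr*ARC, K_N = kr/kf
    d_non <- function(t, y, p)
      list(p$kf * (p$totrc - y[1]) - p$kr * y[1])
    arc_ode <- relax(d_non, c(arc = 0),
                     list(kf = 1, kr = cs$k_n, totrc = cs$totrc), 1)
    expect_equal(arc_ode, arc_noncanonical(cs$totrc, cs$k_n)$arc2,
                 tolerance = 1e-4, ignore_attr = TRUE)

    # hybrid: both routes drain the shared free pool
    d_hyb <- function(t, y, p) {
      rc <- p$totrc - y[1] - y[2]
      list(c(p$kf1 * p$il12 * rc - p$kr1 * y[1],
             p$kf2 * rc - p$kr2 * y[2]))
    }
    arc_ode <- relax(d_hyb, c(arc1 = 0, arc2 = 0),
                     list(kf1 = 1, kr1 = cs$k_c, kf2 = 1, kr2 = cs$k_n,
                          il12 = cs$il12, totrc = cs$totrc), 1:2)
    exp_st <- arc_hybrid(cs$totrc, cs$il12, cs$k_c, cs$k_n)
    expect_equal(unname(arc_ode), c(exp_st$arc1, exp_st$arc2),
                 tolerance = 1e-4)
  }
})

test_that("phosphorylation stage saturates with hand-checked values", {
  p <- mechanism_params(tots = 1000, k_d_phos = 500)
  expect_equal(phospho_response(p, list(arc1 = 0, arc2 = 0)), 0)
  expect_equal(phospho_response(p, list(arc1 = 300, arc2 = 200)), 500)
  expect_equal(phospho_response(p, list(arc1 = 1500, arc2 = 0)), 750)
  # strictly increasing in total activated complexes, bounded by tots
  arc <- seq(0, 1e6, length.out = 50)
  ps <- phospho_response(p, list(arc1 = arc, arc2 = 0))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps < 1000))
  # only the sum arc1 + arc2 matters
  expect_equal(phospho_response(p, list(arc1 = 120, arc2 = 80)),
               phospho_response(p, list(arc1 = 0, arc2 = 200)))
})

test_that("surface densities follow the stoichiometry and size rules", {
  d6 <- receptor_context("2D6")
  b16 <- receptor_context("B16F0")
  expect_equal(complex_density(19500, d6), 187.5)
  expect_equal(complex_density(330000, b16), 165000 / 344)
  # forward-scatter scaling divides the density
  big <- receptor_context("B16F0", fsc_scale = 2)
  expect_equal(complex_density(330000, big), complex_density(330000, b16) / 2)
  expect_error(receptor_context("B16F0", area_um2 = -1), "area_um2")
  expect_error(receptor_context("unknown-line"), "unknown")
})

test_that("total-Akt correction is the documented linear relationship", {
  expect_equal(total_akt_correction(0), 382)
  expect_equal(total_akt_correction(1000), 734)
  expect_error(total_akt_correction(-5), "density")
})
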