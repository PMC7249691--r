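#' @title Seeded synthetic-data generators
#' @description Generators producing inputs with the statistical structure
#'   each pipeline stage assumes - viability tables from the rescue model,
#'   IL12RB2-stratified phospho tables from a chosen activation mechanism,
#'   and zero-inflated two-gene single-cell expression - so every stage is
#'   testable without downloads. All generators are bit-reproducible under
#'   a fixed seed and emit exactly the schemas the corresponding readers
#'   consume.
#' @name synthetic_data
NULL

#' Viability assay design
#'
#' Full-factorial drug x IL-12 dose grid. The default doses mirror the
#' acute rescue assay: imatinib at 0/5/10/20 uM crossed with IL-12 at
#' 0/40/100/200 ng/mL, giving 16 observations per replicate. Noise is
#' additive Gaussian in percent-viability units and observations are not
#' clipped (raw assay values may exceed 100).
#'
#' @param im_doses Imatinib doses (uM).
#' @param il12_doses IL-12 doses (ng/mL).
#' @param replicates Replicates per dose combination.
#' @param noise_sd Additive Gaussian noise sd (percent-viability units).
#' @param truth True [dose_response_params()].
#' @param seed Integer seed.
#' @return List of class `viability_design`.
#' @export
viability_design <- function(im_doses = c(0, 5, 10, 20),
                             il12_doses = c(0, 40, 100, 200),
                             replicates = 1L, noise_sd = 3,
                             truth = dose_response_params(10, 1, 40),
                             seed = 1L) {
  stopifnot(all(im_doses >= 0), all(il12_doses >= 0),
            replicates >= 1L, noise_sd >= 0)
  truth <- as_dose_response_params(truth)
  structure(list(im_doses = im_doses, il12_doses = il12_doses,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 truth = truth, seed = as.integer(seed)),
            class = "viability_design")
}

#' Generate a synthetic viability table
#'
#' @param design A [viability_design()].
#' @return Data frame with columns `c_im_uM`, `c_il12_ng_ml`, `live_pct`,
#'   `assay` (the schema of [read_viability_csv()]).
#' @export
gen_viability <- function(design) {
  stopifnot(inherits(design, "viability_design"))
  grid <- expand.grid(c_im_uM = design$im_doses,
                      c_il12_ng_ml = design$il12_doses,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  pred <- predict_viability(design$truth, grid$c_im_uM, grid$c_il12_ng_ml)
  live <- withr::with_seed(design$seed,
    pred + stats::rnorm(nrow(grid), 0, design$noise_sd))
  data.frame(c_im_uM = grid$c_im_uM, c_il12_ng_ml = grid$c_il12_ng_ml,
             live_pct = live, assay = "flow", stringsAsFactors = FALSE)
}

#' Stratified phospho-assay design
#'
#' Emulates flow-cytometry stratification: per-cell IL12RB2 copies are
#' drawn log-normally (the default spans ~1e3-1e6 copies, covering the
#' measured range of both cell-line models), binned into subsets by
#' `bin_edges`, and each subset is assigned the geometric mean of its bin
#' edges as representative copy number. The mean phospho-MFI of each
#' (subset x dose) combination is computed from the chosen mechanism and
#' perturbed by multiplicative log-normal noise with
#' `sdlog = noise_frac`, so the absolute noise sd at the top of the
#' response range is about `noise_frac` times the dynamic range.
#'
#' @param mechanism `"canonical"`, `"noncanonical"` or `"hybrid"`.
#' @param truth True [mechanism_params()].
#' @param copies_logmean,copies_logsd Log-scale (natural log) parameters
#'   of the per-cell IL12RB2 copy distribution.
#' @param bin_edges Strictly increasing copy-number bin edges.
#' @param il12_doses IL-12 doses (ng/mL); default 0/7/100/300.
#' @param n_cells Cells per replicate experiment.
#' @param replicates Independent replicate experiments.
#' @param noise_frac Noise scale as a fraction of dynamic range.
#' @param seed Integer seed.
#' @return List of class `phospho_design`.
#' @export
phospho_design <- function(mechanism = "hybrid",
                           truth = mechanism_params(k_c = 60.7, k_n = 4,
                                                    tots = 2000,
                                                    k_d_phos = 5e4),
                           copies_logmean = log(10^4.5),
                           copies_logsd = 1.15,
                           bin_edges = 10^seq(3, 6, by = 0.375),
                           il12_doses = c(0, 7, 100, 300),
                           n_cells = 2000L, replicates = 3L,
                           noise_frac = 0.05, seed = 1L) {
  mechanism <- match.arg(mechanism, c("canonical", "noncanonical", "hybrid"))
  stopifnot(inherits(truth, "mechanism_params"),
            all(diff(bin_edges) > 0), all(il12_doses >= 0),
            n_cells >= 1L, replicates >= 1L, noise_frac >= 0)
  structure(list(mechanism = mechanism, truth = truth,
                 copies_logmean = copies_logmean, copies_logsd = copies_logsd,
                 bin_edges = bin_edges, il12_doses = il12_doses,
                 n_cells = as.integer(n_cells),
                 replicates = as.integer(replicates),
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "phospho_design")
}

#' Generate a synthetic stratified phospho table
#'
#' @param design A [phospho_design()].
#' @param ctx A [receptor_context()]; defaults to the homodimer melanoma
#'   context.
#' @param readout Readout label carried into the table.
#' @return Data frame with columns `cell_line`, `readout`, `il12_ng_ml`,
#'   `il12rb2_copies`, `mfi`, `n_events`, `replicate` (the schema of
#'   [read_phospho_csv()]). Empty bins are dropped with a message.
#' @export
gen_phospho <- function(design, ctx = receptor_context("B16F0"),
                        readout = "pAkt") {
  stopifnot(inherits(design, "phospho_design"),
            inherits(ctx, "receptor_context"))
  edges <- design$bin_edges
  n_bins <- length(edges) - 1L
  rep_copies <- sqrt(edges[-length(edges)] * edges[-1])  # geometric mean
  rows <- withr::with_seed(design$seed, {
    out <- list()
    dropped <- 0L
    for (r in seq_len(design$replicates)) {
      copies <- stats::rlnorm(design$n_cells, design$copies_logmean,
                              design$copies_logsd)
      counts <- tabulate(findInterval(copies, edges,
                                      rightmost.closed = TRUE),
                         nbins = n_bins + 1L)[seq_len(n_bins)]
      for (b in seq_len(n_bins)) {
        if (counts[b] == 0L) { dropped <- dropped + 1L; next }
        pred <- predict_phospho(design$mechanism, design$truth,
                                rep(rep_copies[b], length(design$il12_doses)),
                                design$il12_doses, ctx)
        mfi <- pred * exp(stats::rnorm(length(pred), 0, design$noise_frac))
        out[[length(out) + 1L]] <- data.frame(
          cell_line = ctx$cell_line, readout = readout,
          il12_ng_ml = design$il12_doses,
          il12rb2_copies = rep_copies[b], mfi = mfi,
          n_events = counts[b], replicate = r,
          stringsAsFactors = FALSE)
      }
    }
    if (dropped > 0L)
      message(dropped, " empty copy-number bin(s) dropped")
    out
  })
  do.call(rbind, rows)
}

#' Two-gene single-cell expression design
#'
#' Zero-inflated per-cell-type expression of IL12RB1 and IL12RB2: each
#' cell draws a class (both expressed / only IL12RB1 / only IL12RB2 /
#' neither) from the type's multinomial, and expressed genes draw
#' log-normal TPM. The default class probabilities and cell counts mirror
#' the observed skew in human melanoma single-cell data (malignant cells
#' shifted toward IL12RB2, CD8+ T cells strongly IL12RB1-dominant, with a
#' median malignant ratio > 1 and CD8 median ratio ~0.085).
#'
#' @param types Named list; each element a list with `n_cells`, `p`
#'   (probabilities for both/rb1_only/rb2_only/neither, summing to 1),
#'   `mu1`, `mu2` (meanlog of IL12RB1 / IL12RB2 TPM when expressed) and
#'   `sdlog`.
#' @param seed Integer seed.
#' @return List of class `scrna_design`.
#' @export
scrna_design <- function(types = NULL, seed = 1L) {
  if (is.null(types)) {
    mk <- function(n, p, delta) list(n_cells = n, p = p, mu1 = log(10),
                                     mu2 = log(10) + delta, sdlog = 1.5)
    types <- list(
      malignant = mk(2018L, c(0.207, 0.559, 0.052, 0.182), log(2)),
      NK        = mk(92L,   c(0.239, 0.652, 0.022, 0.087), log(0.3)),
      CD4T      = mk(856L,  c(0.218, 0.727, 0.008, 0.047), log(0.3)),
      CD8T      = mk(1759L, c(0.103, 0.816, 0.003, 0.078), log(0.085))
    )
  }
  for (nm in names(types)) {
    t <- types[[nm]]
    stopifnot(t$n_cells > 0, length(t$p) == 4L, all(t$p >= 0))
    if (abs(sum(t$p) - 1) > 1e-8)
      stop("class probabilities for `", nm, "` must sum to 1", call. = FALSE)
  }
  structure(list(types = types, seed = as.integer(seed)),
            class = "scrna_design")
}

#' Generate synthetic per-cell expression records
#'
#' @param design An [scrna_design()].
#' @return Data frame with columns `cell_id`, `cell_type`, `il12rb1`,
#'   `il12rb2` (the schema consumed by [classify_cells()] and
#'   [ratio_distribution()]).
#' @export
gen_scrna <- function(design) {
  stopifnot(inherits(design, "scrna_design"))
  withr::with_seed(design$seed, {
    out <- lapply(names(design$types), function(nm) {
      t <- design$types[[nm]]
      n <- t$n_cells
      cls <- sample.int(4L, n, replace = TRUE, prob = t$p)
      rb1 <- ifelse(cls %in% c(1L, 2L),
                    stats::rlnorm(n, t$mu1, t$sdlog), 0)
      rb2 <- ifelse(cls %in% c(1L, 3L),
                    stats::rlnorm(n, t$mu2, t$sdlog), 0)
      data.frame(cell_id = sprintf("%s_%05d", nm, seq_len(n)),
                 cell_type = nm, il12rb1 = rb1, il12rb2 = rb2,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
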