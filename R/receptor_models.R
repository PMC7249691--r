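#' @title Equilibrium receptor-activation mechanisms
#' @description Three competing equilibrium mechanisms generate activated
#'   IL-12 receptor complexes (ARC) from the total complex pool (TOTRC):
#'   canonical ligand-dependent binding, non-canonical (spontaneous,
#'   density-driven) activation, and a hybrid of both. A shared saturable
#'   phosphorylation stage maps total activated complexes to the measured
#'   phospho-signal (pAkt or pSTAT4 MFI).
#' @name receptor_models
NULL

#' Mechanism parameters
#'
#' Equilibrium and phospho-stage constants for one mechanism fit. All raw
#' rate constants enter only through these ratios and are individually
#' unidentifiable at equilibrium.
#'
#' @param k_c Ligand binding constant (ng/mL; ratio of reverse to forward
#'   ligand-binding rates). `NULL` for the pure non-canonical model.
#' @param k_n Spontaneous-activation constant (dimensionless; reverse over
#'   forward spontaneous rates). `NULL` for the pure canonical model.
#' @param tots Total signaling intermediate (MFI units).
#' @param k_d_phos Phospho-stage half-saturation constant, in activated
#'   complex copies (phosphatase-scaled dephosphorylation over
#'   phosphorylation rate).
#' @return Object of class `mechanism_params`.
#' @export
mechanism_params <- function(k_c = NULL, k_n = NULL, tots, k_d_phos) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0))
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  if (missing(tots) || missing(k_d_phos))
    stop("`tots` and `k_d_phos` are required", call. = FALSE)
  chk(k_c, "k_c"); chk(k_n, "k_n"); chk(tots, "tots"); chk(k_d_phos, "k_d_phos")
  structure(list(k_c = k_c, k_n = k_n, tots = tots, k_d_phos = k_d_phos),
            class = "mechanism_params")
}

#' Receptor context for a cell line
#'
#' Describes how measured IL12RB2 copies map to receptor complexes and to
#' membrane surface density for one cell line. In T cells the complex is
#' the IL12RB1:IL12RB2 heterodimer (complexes = IL12RB2 copies); in
#' IL12RB2-overexpressing melanoma cells the complex is the IL12RB2
#' homodimer (complexes = IL12RB2 copies / 2).
#'
#' @param cell_line Label. Defaults for `"2D6"` (heterodimer, 104 um^2) and
#'   `"B16F0"` (homodimer, 344 um^2) are built in; other cell lines must
#'   supply `stoichiometry` and `area_um2`.
#' @param stoichiometry `"heterodimer"` or `"homodimer"`.
#' @param area_um2 Membrane surface area (um^2, > 0).
#' @param fsc_scale Dimensionless forward-scatter size normalization,
#'   defined as (subset mean FSC-A) / (cell-line reference mean FSC-A) and
#'   applied multiplicatively to the area; default 1 when no FSC data are
#'   available.
#' @return Object of class `receptor_context`.
#' @export
receptor_context <- function(cell_line = "B16F0", stoichiometry = NULL,
                             area_um2 = NULL, fsc_scale = 1) {
  defaults <- list(
    `2D6`   = list(stoichiometry = "heterodimer", area_um2 = 104),
    B16F0   = list(stoichiometry = "homodimer",   area_um2 = 344)
  )
  d <- defaults[[cell_line]]
  if (is.null(stoichiometry)) stoichiometry <- d$stoichiometry
  if (is.null(area_um2)) area_um2 <- d$area_um2
  if (is.null(stoichiometry) || is.null(area_um2))
    stop("unknown cell line `", cell_line,
         "`: supply `stoichiometry` and `area_um2`", call. = FALSE)
  stoichiometry <- match.arg(stoichiometry, c("heterodimer", "homodimer"))
  if (!is.numeric(area_um2) || area_um2 <= 0)
    stop("`area_um2` must be > 0", call. = FALSE)
  if (!is.numeric(fsc_scale) || fsc_scale <= 0)
    stop("`fsc_scale` must be > 0", call. = FALSE)
  structure(list(cell_line = cell_line, stoichiometry = stoichiometry,
                 area_um2 = area_um2, fsc_scale = fsc_scale),
            class = "receptor_context")
}

#' Receptor complexes from measured IL12RB2 copies
#'
#' @param copies IL12RB2 copies per cell (vectorized).
#' @param ctx A [receptor_context()].
#' @return Total receptor complexes per cell (TOTRC).
#' @export
complexes_from_copies <- function(copies, ctx) {
  stopifnot(inherits(ctx, "receptor_context"))
  if (any(copies < 0)) stop("`copies` must be >= 0", call. = FALSE)
  if (ctx$stoichiometry == "homodimer") copies / 2 else copies
}

#' Canonical ligand-dependent activation
#'
#' Reversible ligand binding to the receptor complex gives, at
#' equilibrium, `ARC = TOTRC * IL12 / (K_C + IL12)`.
#'
#' @param totrc Total receptor complexes per cell (vectorized).
#' @param il12 IL-12 concentration (ng/mL, >= 0).
#' @param k_c Ligand binding constant (ng/mL, > 0).
#' @return List with components `arc1` (ligand-activated complexes) and
#'   `arc2` (always 0 for this mechanism).
#' @export
arc_canonical <- function(totrc, il12, k_c) {
  check_arc_inputs(totrc, il12)
  stopifnot(k_c > 0)
  arc1 <- totrc * il12 / (k_c + il12)
  list(arc1 = arc1, arc2 = rep_len(0, length(arc1)))
}

#' Non-canonical receptor-dependent activation
#'
#' Spontaneous (ligand-independent) activation of the receptor complex
#' gives `ARC = TOTRC / (K_N + 1)`, independent of IL-12. By convention
#' the spontaneously activated pool is reported as `arc2` and `arc1 = 0`,
#' keeping the activation state uniform across mechanisms.
#'
#' @inheritParams arc_canonical
#' @param k_n Spontaneous-activation constant (dimensionless, > 0).
#' @export
arc_noncanonical <- function(totrc, k_n) {
  check_arc_inputs(totrc, 0)
  stopifnot(k_n > 0)
  arc2 <- totrc / (k_n + 1)
  list(arc1 = rep_len(0, length(arc2)), arc2 = arc2)
}

#' Hybrid ligand- and density-dependent activation
#'
#' Both routes operate on the shared complex pool; at equilibrium
#' \deqn{ARC_1 = \frac{TOTRC\, f (1 - g)}{1 - f g}, \qquad
#'       ARC_2 = \frac{TOTRC - ARC_1}{K_N + 1},}
#' with `f = IL12/(K_C + IL12)` and `g = 1/(K_N + 1)`. The hybrid nests
#' both pure mechanisms: `il12 = 0` reduces it to the non-canonical state
#' and `k_n -> Inf` to the canonical state.
#'
#' @inheritParams arc_canonical
#' @inheritParams arc_noncanonical
#' @export
arc_hybrid <- function(totrc, il12, k_c, k_n) {
  check_arc_inputs(totrc, il12)
  stopifnot(k_c > 0, k_n > 0)
  f <- il12 / (k_c + il12)
  g <- 1 / (k_n + 1)
  arc1 <- totrc * f * (1 - g) / (1 - f * g)
  arc2 <- (totrc - arc1) / (k_n + 1)
  list(arc1 = arc1, arc2 = arc2)
}

check_arc_inputs <- function(totrc, il12) {
  if (any(totrc < 0)) stop("`totrc` must be >= 0", call. = FALSE)
  if (any(il12 < 0)) stop("`il12` must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Saturable phosphorylation stage
#'
#' Maps total activated complexes to the phospho-signal:
#' `pS = TOTS * (ARC1 + ARC2) / (K_D + ARC1 + ARC2)`. The phosphorylation
#' kinetics are assumed identical for ligand-activated and spontaneously
#' activated complexes, so only the sum matters.
#'
#' @param params A [mechanism_params()] (uses `tots`, `k_d_phos`).
#' @param state Activation state from one of the `arc_*` functions (list
#'   with `arc1`, `arc2`).
#' @return Predicted phospho-MFI; in `[0, tots)`.
#' @export
phospho_response <- function(params, state) {
  stopifnot(inherits(params, "mechanism_params"))
  arc <- state$arc1 + state$arc2
  if (any(arc < 0)) stop("activated complexes must be >= 0", call. = FALSE)
  params$tots * arc / (params$k_d_phos + arc)
}

#' Predict phospho-MFI for observations under one mechanism
#'
#' Convenience wrapper combining the stoichiometry rule, the chosen
#' activation mechanism and the phosphorylation stage, vectorized over
#' observations.
#'
#' @param model_id `"canonical"`, `"noncanonical"` or `"hybrid"`.
#' @param params A [mechanism_params()] with the constants the mechanism
#'   needs.
#' @param copies IL12RB2 copies per cell (subset representative values).
#' @param il12 IL-12 dose(s), ng/mL.
#' @param ctx A [receptor_context()].
#' @param tots Optional per-observation total signaling intermediate
#'   overriding `params$tots` (used by the total-Akt correction).
#' @return Predicted MFI vector.
#' @export
predict_phospho <- function(model_id, params, copies, il12, ctx,
                            tots = NULL) {
  model_id <- match.arg(model_id, c("canonical", "noncanonical", "hybrid"))
  totrc <- complexes_from_copies(copies, ctx)
  state <- switch(model_id,
    canonical    = arc_canonical(totrc, il12, params$k_c),
    noncanonical = arc_noncanonical(totrc, params$k_n),
    hybrid       = arc_hybrid(totrc, il12, params$k_c, params$k_n))
  if (is.null(tots)) {
    phospho_response(params, state)
  } else {
    arc <- state$arc1 + state$arc2
    tots * arc / (params$k_d_phos + arc)
  }
}

#' Receptor-complex surface density
#'
#' Complexes per um^2 of membrane: the stoichiometry rule converts
#' measured IL12RB2 copies to complexes, and the cell-line surface area is
#' scaled by the forward-scatter size normalization.
#'
#' @inheritParams complexes_from_copies
#' @return Complexes per um^2.
#' @export
#' @examples
#' complex_density(19500, receptor_context("2D6"))   # 187.5
#' complex_density(330000, receptor_context("B16F0")) # ~479.7
complex_density <- function(copies, ctx) {
  stopifnot(inherits(ctx, "receptor_context"))
  complexes_from_copies(copies, ctx) / (ctx$area_um2 * ctx$fsc_scale)
}

#' Total-Akt linear correction
#'
#' Total Akt scales linearly with IL12RB2 surface density:
#' `Total Akt (MFI) = 0.352 * density + 382`, with density in complexes or
#' copies per um^2. When enabled, the result replaces the fitted `TOTS`
#' of the phosphorylation stage for the Akt readout, so the corrected
#' ratio pS/TOTS can be examined; when disabled, `TOTS` stays a free
#' fitted parameter.
#'
#' @param density Receptor surface density (copies per um^2, >= 0).
#' @param slope,intercept Coefficients of the linear relationship.
#' @return Estimated total Akt (MFI units).
#' @export
total_akt_correction <- function(density, slope = 0.352, intercept = 382) {
  if (any(density < 0)) stop("`density` must be >= 0", call. = FALSE)
  slope * density + intercept
}

#' Reported reference estimates
#'
#' Point estimates reported for the two cell-line models, exposed as the
#' package's documented defaults: ligand binding constants K_C (ng/mL),
#' measured IL12RB2 copy numbers, membrane surface areas (um^2), the
#' total-Akt linear coefficients, and the fixed IL-12 binding constant of
#' the viability model.
#'
#' @return Named list of reference values.
#' @export
#' @examples
#' est <- il12_reference_estimates()
#' unname(est$k_c["B16F0"] / est$k_c["2D6"])  # ~190-fold affinity difference
il12_reference_estimates <- function() {
  list(
    k_c = c(`2D6` = 0.320, B16F0 = 60.7),
    il12rb2_copies = c(`2D6` = 19500, B16F0 = 330000, MelanA = 214000),
    il12rb1_copies = c(`2D6` = 43000, B16F0 = 1000),
    area_um2 = c(`2D6` = 104, B16F0 = 344),
    total_akt = c(slope = 0.352, intercept = 382),
    kd_il12_ng_ml = 40
  )
}

#' Read / write a stratified phospho-signaling table
#'
#' CSV schema: `cell_line, readout, il12_ng_ml, il12rb2_copies, mfi`
#' with optional `n_events` (used only for reporting) and `replicate`.
#'
#' @param path File path.
#' @return `read_phospho_csv` returns the validated data frame.
#' @export
read_phospho_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phospho_table(df)
}

#' @rdname read_phospho_csv
#' @param obs Data frame as produced by [gen_phospho()].
#' @export
write_phospho_csv <- function(obs, path) {
  validate_phospho_table(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_phospho_table <- function(obs) {
  if (!is.data.frame(obs)) stop("phospho data must be a data frame", call. = FALSE)
  required <- c("cell_line", "readout", "il12_ng_ml", "il12rb2_copies", "mfi")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0L)
    stop("phospho table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(obs$il12_ng_ml < 0) || any(obs$il12rb2_copies < 0) || any(obs$mfi < 0))
    stop("`il12_ng_ml`, `il12rb2_copies` and `mfi` must be >= 0", call. = FALSE)
  obs
}
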