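#' Parameters of the IL-12 rescue dose-response model
#'
#' Container for the parameters of the viability model in which IL-12
#' right-shifts the EC50 of a cytotoxic drug (imatinib):
#' \deqn{Live(\%) = 100 \left[1 - \frac{C_{Im}}{C_{Im} + EC_{50}\,
#'   (1 + \alpha\, C_{IL12}/(C_{IL12} + K_d))}\right]}
#'
#' @param ec50 Drug concentration producing a 50% viability drop in the
#'   absence of IL-12 (same units as the drug doses, typically uM). Must be
#'   positive.
#' @param alpha Dimensionless rescue effect of IL-12. At saturating IL-12
#'   the effective EC50 is `ec50 * (1 + alpha)`, so `alpha = 1` doubles the
#'   EC50 (a 100% right shift). Must be greater than -1 so the effective
#'   EC50 stays positive.
#' @param kd Equilibrium binding constant of IL-12 (ng/mL). Fixed at
#'   40 ng/mL by default and not inferred; override here if needed.
#'
#' @return An object of class `dose_response_params`.
#' @seealso [predict_viability()], [viability_neg_log_lik()]
#' @export
#' @examples
#' p <- dose_response_params(ec50 = 10, alpha = 1)
#' predict_viability(p, c_im = 10, c_il12 = 40)
dose_response_params <- function(ec50, alpha, kd = 40) {
  if (!is.numeric(ec50) || length(ec50) != 1L || !is.finite(ec50) || ec50 <= 0)
    stop("`ec50` must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= -1)
    stop("`alpha` must be a single number greater than -1", call. = FALSE)
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("`kd` must be a single positive number", call. = FALSE)
  structure(list(ec50 = ec50, alpha = alpha, kd = kd),
            class = "dose_response_params")
}

#' @export
print.dose_response_params <- function(x, ...) {
  cat("IL-12 rescue dose-response parameters\n")
  cat(sprintf("  EC50  = %g (drug units)\n", x$ec50))
  cat(sprintf("  alpha = %g (EC50 multiplier at saturation: %g)\n",
              x$alpha, 1 + x$alpha))
  cat(sprintf("  Kd    = %g ng/mL (fixed)\n", x$kd))
  invisible(x)
}

as_dose_response_params <- function(params) {
  if (inherits(params, "dose_response_params")) return(params)
  if (is.list(params) && all(c("ec50", "alpha") %in% names(params)))
    return(dose_response_params(params$ec50, params$alpha,
                                if (is.null(params$kd)) 40 else params$kd))
  stop("`params` must be a dose_response_params object", call. = FALSE)
}

#' Predict percent live cells under drug and IL-12 co-treatment
#'
#' Evaluates the rescue model for vectors of drug and IL-12 concentrations.
#' With `c_im = 0` the prediction is exactly 100; the value is always in
#' (0, 100]. Infinite `c_il12` is taken at the saturating limit, where the
#' effective EC50 equals `ec50 * (1 + alpha)`.
#'
#' @param params A [dose_response_params()] object.
#' @param c_im Drug (imatinib) concentration(s), >= 0.
#' @param c_il12 IL-12 concentration(s) in ng/mL, >= 0 (may be `Inf`).
#' @return Numeric vector of predicted percent live cells.
#' @export
predict_viability <- function(params, c_im, c_il12) {
  params <- as_dose_response_params(params)
  if (any(c_im < 0, na.rm = TRUE)) stop("`c_im` must be >= 0", call. = FALSE)
  if (any(c_il12 < 0, na.rm = TRUE)) stop("`c_il12` must be >= 0", call. = FALSE)
  occ <- ifelse(is.infinite(c_il12), 1, c_il12 / (c_il12 + params$kd))
  eff_ec50 <- params$ec50 * (1 + params$alpha * occ)
  100 * (1 - c_im / (c_im + eff_ec50))
}

#' Negative log-likelihood of viability observations
#'
#' The likelihood is the SSE-marginalized form proportional to
#' `SSE^(-N/2)`, so the negative log-likelihood is `(N/2) * log(SSE)` with
#' `SSE` the sum of squared residuals between observed percent-live values
#' and [predict_viability()]. No noise-variance parameter is sampled.
#' Observations above 100% (assay noise) enter unmodified.
#'
#' A perfect fit (`SSE = 0`) is degenerate under this likelihood and
#' returns `-Inf`.
#'
#' @param params A [dose_response_params()] object.
#' @param obs Data frame with columns `c_im_uM`, `c_il12_ng_ml`, `live_pct`
#'   (the schema written by [gen_viability()] / read by
#'   [read_viability_csv()]).
#' @return Scalar negative log-likelihood; lower is better.
#' @export
viability_neg_log_lik <- function(params, obs) {
  params <- as_dose_response_params(params)
  obs <- validate_viability_table(obs)
  if (nrow(obs) == 0L) stop("`obs` must be non-empty", call. = FALSE)
  pred <- predict_viability(params, obs$c_im_uM, obs$c_il12_ng_ml)
  sse <- sum((obs$live_pct - pred)^2)
  if (sse == 0) return(-Inf)
  (nrow(obs) / 2) * log(sse)
}

validate_viability_table <- function(obs) {
  if (!is.data.frame(obs)) stop("viability data must be a data frame", call. = FALSE)
  required <- c("c_im_uM", "c_il12_ng_ml", "live_pct")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0L)
    stop("viability table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(obs$c_im_uM < 0) || any(obs$c_il12_ng_ml < 0))
    stop("doses must be non-negative", call. = FALSE)
  obs
}

#' Read / write a viability table
#'
#' CSV schema: header row with columns `c_im_uM, c_il12_ng_ml, live_pct,
#' assay` (decimal point, UTF-8). `assay` labels the readout
#' (`"flow"` or `"atplite"`) and is carried through unmodified.
#'
#' @param path File path.
#' @return `read_viability_csv` returns the validated data frame.
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_viability_table(df)
}

#' @rdname read_viability_csv
#' @param obs Data frame as produced by [gen_viability()].
#' @export
write_viability_csv <- function(obs, path) {
  validate_viability_table(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
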