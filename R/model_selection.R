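#' @title Mechanism fitting and Bayes-factor model selection
#' @description Maximum-likelihood (minimum-SSE) fitting of the three
#'   receptor-activation mechanisms to IL12RB2-stratified phospho data,
#'   optionally with a ligand binding constant shared across readouts of
#'   one cell line, and pairwise Bayes-factor comparison with evidence
#'   grading.
#' @name model_selection
NULL

model_par_names <- function(model_id) {
  switch(model_id,
    canonical    = c("k_c", "tots", "k_d_phos"),
    noncanonical = c("k_n", "tots", "k_d_phos"),
    hybrid       = c("k_c", "k_n", "tots", "k_d_phos"))
}

params_from_vector <- function(model_id, theta) {
  nm <- model_par_names(model_id)
  v <- as.list(stats::setNames(theta, nm))
  mechanism_params(k_c = v$k_c, k_n = v$k_n,
                   tots = v$tots, k_d_phos = v$k_d_phos)
}

phospho_sse_fn <- function(model_id, obs, ctx, tots_correction = FALSE) {
  copies <- obs$il12rb2_copies
  il12 <- obs$il12_ng_ml
  mfi <- obs$mfi
  tots_fixed <- NULL
  if (tots_correction)
    tots_fixed <- total_akt_correction(complex_density(copies, ctx))
  nm <- model_par_names(model_id)
  if (tots_correction) nm <- setdiff(nm, "tots")
  function(log_theta) {
    theta <- exp(log_theta)
    v <- as.list(stats::setNames(theta, nm))
    if (tots_correction) v$tots <- 1  # placeholder, overridden per-row
    p <- mechanism_params(k_c = v$k_c, k_n = v$k_n,
                          tots = v$tots, k_d_phos = v$k_d_phos)
    pred <- predict_phospho(model_id, p, copies, il12, ctx,
                            tots = tots_fixed)
    sum((mfi - pred)^2)
  }
}

# Deterministic multi-start grid on the log scale, anchored to the data:
# TOTS near the observed maximum, K_D near the complex-count quantiles,
# K_C / K_N spanning several decades.
default_starts <- function(model_id, obs, ctx, tots_correction = FALSE) {
  complexes <- complexes_from_copies(obs$il12rb2_copies, ctx)
  kd_g <- unname(stats::quantile(complexes[complexes > 0], c(0.3, 0.7)))
  if (length(kd_g) == 0L || any(!is.finite(kd_g))) kd_g <- c(1e3, 1e5)
  tots_g <- max(obs$mfi) * 1.2
  if (tots_g <= 0) tots_g <- 1
  kc_g <- c(1, 30, 300)
  kn_g <- c(0.3, 3, 30)
  grid <- switch(model_id,
    canonical    = expand.grid(k_c = kc_g, tots = tots_g, k_d_phos = kd_g),
    noncanonical = expand.grid(k_n = kn_g, tots = tots_g, k_d_phos = kd_g),
    hybrid       = expand.grid(k_c = kc_g, k_n = kn_g, tots = tots_g,
                               k_d_phos = mean(kd_g)))
  grid <- grid[, model_par_names(model_id), drop = FALSE]
  if (tots_correction) grid$tots <- NULL
  lapply(seq_len(nrow(grid)), function(i) log(as.numeric(grid[i, ])))
}

# Nelder-Mead from each start, then a BFGS polish of the best; everything
# on the log scale so positivity holds by construction.
minimize_sse <- function(sse_fn, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  for (i in 1:2) {
    polish <- tryCatch(
      stats::optim(best$par, sse_fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value < best$value) best <- polish
    polish2 <- tryCatch(
      stats::optim(best$par, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(polish2) && polish2$value < best$value) best <- polish2
  }
  best
}

#' Fit one activation mechanism to stratified phospho data
#'
#' Minimizes the summed squared error between observed MFI and the
#' mechanism prediction over the model's free parameters, on the log scale
#' (positivity by construction) from a deterministic grid of multi-starts.
#' The fit is deterministic given the data and configuration.
#'
#' @param model_id `"canonical"`, `"noncanonical"` or `"hybrid"`.
#' @param obs Phospho table (see [read_phospho_csv()]) for a single
#'   cell line and readout.
#' @param ctx A [receptor_context()].
#' @param tots_correction If `TRUE`, `TOTS` is not fitted but computed
#'   per observation from [total_akt_correction()] of the complex surface
#'   density (intended for the Akt readout; off by default).
#' @param extra_starts Optional list of additional log-scale start vectors.
#' @return Object of class `mechanism_fit`: `model_id`, `readout`,
#'   `cell_line`, `params` ([mechanism_params()] at the optimum), `sse`,
#'   `n_obs`, `n_free`.
#' @export
fit_mechanism <- function(model_id, obs, ctx, tots_correction = FALSE,
                          extra_starts = NULL) {
  model_id <- match.arg(model_id, c("canonical", "noncanonical", "hybrid"))
  obs <- validate_phospho_table(obs)
  if (length(unique(obs$il12rb2_copies)) < 2L)
    stop("need >= 2 distinct IL12RB2 copy values", call. = FALSE)
  if (model_id != "noncanonical" && length(unique(obs$il12_ng_ml)) < 2L)
    warning("fewer than 2 distinct IL-12 doses: k_c is not identifiable",
            call. = FALSE)
  sse_fn <- phospho_sse_fn(model_id, obs, ctx, tots_correction)
  starts <- c(default_starts(model_id, obs, ctx, tots_correction),
              extra_starts)
  best <- minimize_sse(sse_fn, starts)
  nm <- model_par_names(model_id)
  if (tots_correction) nm <- setdiff(nm, "tots")
  theta <- stats::setNames(exp(best$par), nm)
  v <- as.list(theta)
  if (tots_correction) v$tots <- NA_real_
  params <- if (tots_correction) {
    structure(list(k_c = v$k_c, k_n = v$k_n, tots = NA_real_,
                   k_d_phos = v$k_d_phos), class = "mechanism_params")
  } else params_from_vector(model_id, theta)
  structure(list(
    model_id = model_id,
    readout = if (length(unique(obs$readout)) == 1L) obs$readout[1] else NA,
    cell_line = if (length(unique(obs$cell_line)) == 1L) obs$cell_line[1] else NA,
    params = params,
    sse = best$value,
    n_obs = nrow(obs),
    n_free = length(nm),
    tots_correction = tots_correction
  ), class = "mechanism_fit")
}

#' @export
print.mechanism_fit <- function(x, ...) {
  cat(sprintf("%s mechanism fit (%s / %s): SSE = %.6g over %d obs, %d free parameters\n",
              x$model_id, x$cell_line, x$readout, x$sse, x$n_obs, x$n_free))
  p <- x$params
  vals <- c(k_c = p$k_c, k_n = p$k_n, tots = p$tots, k_d_phos = p$k_d_phos)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  cat("  ", paste(sprintf("%s = %.4g", names(vals), unlist(vals)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Fit one mechanism to several readouts with a shared ligand constant
#'
#' The ligand binding constant `k_c` reflects extracellular affinity and
#' so is shared across the Akt and STAT4 readouts of one cell line, while
#' every other parameter is fitted per readout. For the non-canonical
#' model (no `k_c`) this reduces to independent fits.
#'
#' @param datasets Named list of phospho tables, one per readout.
#' @param model_id Mechanism to fit.
#' @param ctx A [receptor_context()].
#' @return List with per-readout `fits` (class `mechanism_fit`, all
#'   sharing `k_c`), `k_c`, and `joint_sse`.
#' @export
fit_shared_kc <- function(datasets, model_id, ctx) {
  model_id <- match.arg(model_id, c("canonical", "noncanonical", "hybrid"))
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  datasets <- lapply(datasets, validate_phospho_table)
  indep <- lapply(datasets, function(d) fit_mechanism(model_id, d, ctx))
  if (model_id == "noncanonical" || length(datasets) == 1L) {
    return(list(fits = indep,
                k_c = if (model_id != "noncanonical") indep[[1]]$params$k_c else NULL,
                joint_sse = sum(vapply(indep, `[[`, numeric(1), "sse"))))
  }
  other_nm <- setdiff(model_par_names(model_id), "k_c")
  n_other <- length(other_nm)
  sse_fns <- lapply(datasets, function(d) phospho_sse_fn(model_id, d, ctx))
  joint_fn <- function(log_theta) {
    log_kc <- log_theta[1]
    total <- 0
    for (i in seq_along(sse_fns)) {
      block <- log_theta[(2 + (i - 1) * n_other):(1 + i * n_other)]
      # reassemble in model parameter order (k_c first by construction)
      total <- total + sse_fns[[i]](c(log_kc, block))
    }
    total
  }
  kc_indep <- vapply(indep, function(f) f$params$k_c, numeric(1))
  kc_starts <- unique(c(exp(mean(log(kc_indep))), kc_indep, 1, 100))
  starts <- lapply(kc_starts, function(kc) {
    c(log(kc), unlist(lapply(indep, function(f) {
      p <- f$params
      log(vapply(other_nm, function(nm) p[[nm]], numeric(1)))
    })))
  })
  best <- minimize_sse(joint_fn, starts)
  k_c <- unname(exp(best$par[1]))
  fits <- vector("list", length(datasets))
  names(fits) <- names(datasets)
  for (i in seq_along(datasets)) {
    block <- exp(best$par[(2 + (i - 1) * n_other):(1 + i * n_other)])
    theta <- stats::setNames(c(k_c, block), c("k_c", other_nm))
    fits[[i]] <- structure(list(
      model_id = model_id,
      readout = if (length(unique(datasets[[i]]$readout)) == 1L)
        datasets[[i]]$readout[1] else NA,
      cell_line = if (length(unique(datasets[[i]]$cell_line)) == 1L)
        datasets[[i]]$cell_line[1] else NA,
      params = params_from_vector(model_id, theta[model_par_names(model_id)]),
      sse = sse_fns[[i]](log(theta[c("k_c", other_nm)])),
      n_obs = nrow(datasets[[i]]),
      n_free = n_other + 1 / length(datasets),  # k_c shared across readouts
      tots_correction = FALSE
    ), class = "mechanism_fit")
  }
  list(fits = fits, k_c = k_c, joint_sse = best$value)
}

#' Bayes factor between two mechanism fits
#'
#' The likelihood at the maximum-likelihood parameters is estimated as
#' proportional to `SSE^(-N_obs/2)`, so the Bayes factor comparing model i
#' to model j fitted to the same data is
#' `B_ij = (SSE_i / SSE_j)^(-N_obs / 2)`.
#'
#' @param fit_i,fit_j `mechanism_fit` objects fitted to the same
#'   observations (`n_obs` must match).
#' @return Scalar Bayes factor (> 1 favors model i).
#' @seealso [grade_evidence()], [select_mechanism()]
#' @export
bayes_factor <- function(fit_i, fit_j) {
  stopifnot(inherits(fit_i, "mechanism_fit"), inherits(fit_j, "mechanism_fit"))
  if (fit_i$n_obs != fit_j$n_obs)
    stop("fits compare different data (n_obs ", fit_i$n_obs, " vs ",
         fit_j$n_obs, ")", call. = FALSE)
  if (fit_j$sse == 0 || fit_i$sse == 0)
    stop("degenerate comparison: a fit has SSE = 0", call. = FALSE)
  exp(log_bayes_factor(fit_i$sse, fit_j$sse, fit_i$n_obs))
}

log_bayes_factor <- function(sse_i, sse_j, n_obs) {
  -(n_obs / 2) * (log(sse_i) - log(sse_j))
}

#' Grade the strength of evidence of a Bayes factor
#'
#' Interpretation scale: values between 1 and 3 are weak, 3 to 20
#' positive, 20 to 150 strong, and above 150 very strong evidence for
#' model i over model j. For `b < 1` the grade of the reciprocal is
#' reported, with the `favors` attribute set to `"j"`.
#'
#' @param b Bayes factor (> 0; may be `Inf`).
#' @return Character scalar (`"weak"`, `"positive"`, `"strong"`,
#'   `"very_strong"`) with attribute `favors` (`"i"` or `"j"`).
#' @export
grade_evidence <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0)
    stop("`b` must be a single positive number", call. = FALSE)
  favors <- if (b >= 1) "i" else "j"
  m <- max(b, 1 / b)
  grade <- if (m < 3) "weak"
           else if (m < 20) "positive"
           else if (m <= 150) "strong"
           else "very_strong"
  structure(grade, favors = favors)
}

#' Fit all three mechanisms and compare them by Bayes factors
#'
#' Fits the canonical, non-canonical and hybrid mechanisms to one phospho
#' dataset and assembles the 3 x 3 Bayes-factor matrix (rows = model i,
#' columns = model j) with evidence grades; entries above 150 are very
#' strong evidence for the row model. The hybrid fit receives extra
#' optimizer starts at the canonical (`k_n` large) and non-canonical
#' (`k_c` large) solutions, so the nested-model inequality
#' `SSE_hybrid <= min(SSE_canonical, SSE_noncanonical)` holds up to
#' optimizer tolerance by construction.
#'
#' @inheritParams fit_mechanism
#' @return Object of class `mechanism_selection`: `fits` (named list),
#'   `bf` (3 x 3 matrix, possibly containing `Inf`), `log_bf`, `grades`
#'   (character matrix), `ranking` (model ids ordered by increasing SSE).
#' @export
select_mechanism <- function(obs, ctx, tots_correction = FALSE) {
  obs <- validate_phospho_table(obs)
  fit_c <- fit_mechanism("canonical", obs, ctx, tots_correction)
  fit_n <- fit_mechanism("noncanonical", obs, ctx, tots_correction)
  nested_starts <- list()
  if (!tots_correction) {
    nested_starts <- list(
      log(c(fit_c$params$k_c, 1e8, fit_c$params$tots, fit_c$params$k_d_phos)),
      log(c(1e8, fit_n$params$k_n, fit_n$params$tots, fit_n$params$k_d_phos)))
  } else {
    nested_starts <- list(
      log(c(fit_c$params$k_c, 1e8, fit_c$params$k_d_phos)),
      log(c(1e8, fit_n$params$k_n, fit_n$params$k_d_phos)))
  }
  fit_h <- fit_mechanism("hybrid", obs, ctx, tots_correction,
                         extra_starts = nested_starts)
  fits <- list(canonical = fit_c, noncanonical = fit_n, hybrid = fit_h)
  models <- names(fits)
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  n <- nrow(obs)
  log_bf <- outer(log(sse), log(sse), function(a, b) -(n / 2) * (a - b))
  bf <- exp(log_bf)
  dimnames(bf) <- dimnames(log_bf) <- list(models, models)
  grades <- matrix("", 3, 3, dimnames = dimnames(bf))
  for (i in 1:3) for (j in 1:3)
    grades[i, j] <- as.character(grade_evidence(max(bf[i, j], .Machine$double.xmin)))
  structure(list(fits = fits, bf = bf, log_bf = log_bf, grades = grades,
                 ranking = models[order(sse)], n_obs = n),
            class = "mechanism_selection")
}

#' @export
print.mechanism_selection <- function(x, ...) {
  cat("Mechanism selection by Bayes factors (rows = model i, cols = model j)\n")
  cat(sprintf("  n_obs = %d; ranking by SSE: %s\n", x$n_obs,
              paste(x$ranking, collapse = " > ")))
  sse <- vapply(x$fits, `[[`, numeric(1), "sse")
  for (m in names(sse)) cat(sprintf("  SSE %-13s %.6g\n", m, sse[m]))
  print(signif(x$bf, 3))
  invisible(x)
}
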