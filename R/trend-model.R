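#' Fit the three-term trend model for one metabolite
#'
#' Models a metabolite's concentration time course in a two-group
#' elicitation design as
#' `g(E[C(t)]) = intercept + Treatment + s_cm(t) + 1[treated] * s_diff(t)`,
#' where `s_cm` is the common smoother shared by both groups, `s_diff` is
#' the differential smoother fitted to treated observations only, and the
#' Treatment factor captures a constant (multiplicative, under the log
#' link) shift.  The differential smoother is centred over the treated
#' observations so that a pure constant shift is absorbed by the Treatment
#' factor and the smoother captures genuine trend differences.  Smoothing
#' parameters are selected by REML.
#'
#' @param data long-format data.frame with columns `metabolite`, `day`,
#'   `replicate`, `group` (values `control`/`treated`), `concentration`.
#' @param metabolite label of the response to fit (omit or `NULL` if `data`
#'   is already a single response, e.g. a ratio series).
#' @param k basis dimension of each smoother (default 10).
#' @param family `"gamma"` for a Gamma GLM with log link on the raw
#'   concentrations (the default), or `"gaussian-log"` for a gaussian model
#'   on log-transformed concentrations.  Both encode multiplicative
#'   effects; the Gamma model keeps the response on its original scale.
#' @param elicitation_day annotation recorded in the result (the model
#'   itself is a function of day only).
#' @param band_grid times at which bands are evaluated; defaults to the
#'   distinct observed days.  The differential band is reported only over
#'   days with treated observations.
#' @return an object of class `trend_fit`: response label, treatment
#'   coefficient and SE, common and differential smoother summaries
#'   (e.d.f., approximate p, band), residual diagnostics, and the
#'   underlying `fitted_gam`.
#' @export
fit_trend_model <- function(data, metabolite = NULL, k = 10,
                            family = c("gamma", "gaussian-log"),
                            elicitation_day = NA_real_,
                            band_grid = NULL) {
  family <- match.arg(family)
  d <- as.data.frame(data)
  if (!is.null(metabolite)) {
    d <- d[d$metabolite == metabolite, , drop = FALSE]
    if (nrow(d) == 0)
      stop(sprintf("metabolite '%s' not found in data", metabolite),
           call. = FALSE)
  }
  need <- c("day", "group", "concentration")
  if (!all(need %in% names(d)))
    stop("data must contain columns day, group, concentration", call. = FALSE)
  groups <- unique(d$group)
  if (!all(c("control", "treated") %in% groups))
    stop("both groups ('control' and 'treated') must be present",
         call. = FALSE)
  days <- sort(unique(d$day))
  if (length(days) < 10)
    stop(paste("fewer than 10 distinct days: generalized additive models",
               "are not suitable for designs with only a limited number of",
               "time points"), call. = FALSE)
  bad <- which(!is.finite(d$concentration) | d$concentration <= 0)
  if (length(bad) > 0 && family == "gamma")
    stop(sprintf("non-positive or non-finite concentrations under the Gamma family; offending rows: %s",
                 paste(utils::head(bad, 20), collapse = ", ")), call. = FALSE)
  if (length(bad) > 0 && family == "gaussian-log")
    stop(sprintf("non-positive concentrations cannot be log-transformed; offending rows: %s",
                 paste(utils::head(bad, 20), collapse = ", ")), call. = FALSE)

  tvec <- d$day
  treated <- as.numeric(d$group == "treated")
  y <- if (family == "gamma") d$concentration else log(d$concentration)
  fam <- if (family == "gamma") "gamma" else "gaussian"

  bs_cm <- cr_basis(tvec, k = k)
  cb_cm <- center_basis(bs_cm, tvec)
  t_trt <- tvec[treated == 1]
  bs_df <- cr_basis(t_trt, k = k)
  cb_df <- center_basis(bs_df, t_trt)

  Xp <- cbind(`(Intercept)` = rep(1, nrow(d)), Treatment = treated)
  spec <- gam_model_spec(Xp, list(
    gam_smooth("s_cm", cb_cm, tvec),
    gam_smooth("s_diff", cb_df, tvec, by = treated)
  ), family = fam)

  fit <- optimize_reml(spec, y)

  tr_idx <- 2L
  treatment_coef <- fit$coefficients[tr_idx]
  treatment_se <- sqrt(fit$Vb[tr_idx, tr_idx])

  if (is.null(band_grid)) band_grid <- days
  trt_days <- sort(unique(t_trt))
  grid_df <- band_grid[band_grid >= min(trt_days) & band_grid <= max(trt_days)]
  common <- c(list(edf = fit$edf[["s_cm"]]),
              approx_pvalue(fit, "s_cm")[c("p_value", "statistic", "rank")],
              list(band = confidence_band(fit, "s_cm", band_grid)))
  differential <- c(list(edf = fit$edf[["s_diff"]]),
                    approx_pvalue(fit, "s_diff")[c("p_value", "statistic", "rank")],
                    list(band = confidence_band(fit, "s_diff", grid_df)))

  structure(list(
    response = if (is.null(metabolite)) "response" else metabolite,
    family = family, k = k,
    treatment_coef = unname(treatment_coef),
    treatment_se = unname(treatment_se),
    common = common, differential = differential,
    diagnostics = residual_diagnostics(fit),
    elicitation_day = elicitation_day,
    fit = fit), class = "trend_fit")
}

#' Fit a ratio-trend model for a pair of metabolites
#'
#' Computes the per-observation ratio of two metabolites (matched on day,
#' replicate and group) and fits the same three-term trend model to the
#' ratio series.  When an elicitor scales both metabolites by the same
#' factor, the ratio is unchanged and the differential smoother should be
#' non-significant — the device used to ask whether a treatment affects
#' two pathway neighbours "in the same way".
#'
#' @inheritParams fit_trend_model
#' @param numerator,denominator metabolite labels.
#' @return a `trend_fit` for the ratio series, labelled
#'   `"numerator/denominator"`.
#' @export
fit_ratio_model <- function(data, numerator, denominator, k = 10,
                            family = c("gamma", "gaussian-log"),
                            elicitation_day = NA_real_) {
  family <- match.arg(family)
  d <- as.data.frame(data)
  dn <- d[d$metabolite == numerator, ]
  dd <- d[d$metabolite == denominator, ]
  if (nrow(dn) == 0) stop(sprintf("metabolite '%s' not found", numerator),
                          call. = FALSE)
  if (nrow(dd) == 0) stop(sprintf("metabolite '%s' not found", denominator),
                          call. = FALSE)
  key <- function(x) paste(x$day, x$replicate, x$group, sep = "\r")
  kn <- key(dn); kd <- key(dd)
  miss_n <- setdiff(kd, kn); miss_d <- setdiff(kn, kd)
  if (length(miss_n) + length(miss_d) > 0) {
    ex <- utils::head(gsub("\r", "/", c(miss_n, miss_d)), 10)
    stop(sprintf("unmatched observations between '%s' and '%s' (day/replicate/group): %s",
                 numerator, denominator, paste(ex, collapse = ", ")),
         call. = FALSE)
  }
  dd <- dd[match(kn, kd), ]
  if (any(dd$concentration == 0))
    stop("zero denominator concentrations; ratio undefined", call. = FALSE)
  ratio <- data.frame(metabolite = paste0(numerator, "/", denominator),
                      day = dn$day, replicate = dn$replicate,
                      group = dn$group,
                      concentration = dn$concentration / dd$concentration)
  fit_trend_model(ratio, metabolite = NULL, k = k, family = family,
                  elicitation_day = elicitation_day) -> tf
  tf$response <- paste0(numerator, "/", denominator)
  tf
}

#' Fit trend models across a panel of metabolites and ratios
#'
#' Applies [fit_trend_model()] to each response and [fit_ratio_model()] to
#' each pair, collecting one summary row per response.  Individual fit
#' failures are recorded in the row, not fatal.  No multiplicity
#' adjustment is applied across metabolites.
#'
#' @inheritParams fit_trend_model
#' @param responses character vector of metabolite labels (may be empty).
#' @param ratios list of length-2 character vectors
#'   `c(numerator, denominator)`.
#' @return data.frame with one row per response/ratio: `response`, `type`,
#'   `treatment_coef`, `treatment_se`, `edf_common`, `p_common`,
#'   `edf_differential`, `p_differential`, `converged`, `message`; the
#'   fitted objects are attached as the `"fits"` attribute.
#' @export
fit_all <- function(data, responses = NULL, ratios = list(), k = 10,
                    family = c("gamma", "gaussian-log"),
                    elicitation_day = NA_real_) {
  family <- match.arg(family)
  if (is.null(responses)) responses <- sort(unique(as.character(data$metabolite)))
  rows <- list(); fits <- list()
  one <- function(label, type, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(response = label, type = type,
                 treatment_coef = NA_real_, treatment_se = NA_real_,
                 edf_common = NA_real_, p_common = NA_real_,
                 edf_differential = NA_real_, p_differential = NA_real_,
                 converged = FALSE, message = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      fits[[label]] <<- res
      data.frame(response = label, type = type,
                 treatment_coef = res$treatment_coef,
                 treatment_se = res$treatment_se,
                 edf_common = res$common$edf,
                 p_common = res$common$p_value,
                 edf_differential = res$differential$edf,
                 p_differential = res$differential$p_value,
                 converged = res$fit$converged, message = "",
                 stringsAsFactors = FALSE)
    }
  }
  for (m in responses)
    rows[[length(rows) + 1L]] <- one(m, "metabolite",
      fit_trend_model(data, m, k = k, family = family,
                      elicitation_day = elicitation_day))
  for (pr in ratios)
    rows[[length(rows) + 1L]] <- one(paste0(pr[1], "/", pr[2]), "ratio",
      fit_ratio_model(data, pr[1], pr[2], k = k, family = family,
                      elicitation_day = elicitation_day))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(response = character(0), type = character(0),
               treatment_coef = numeric(0), treatment_se = numeric(0),
               edf_common = numeric(0), p_common = numeric(0),
               edf_differential = numeric(0), p_differential = numeric(0),
               converged = logical(0), message = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend model for %s (%s, k = %d)\n", x$response, x$family, x$k))
  cat(sprintf("  Treatment shift: %.4f (SE %.4f)%s\n", x$treatment_coef,
              x$treatment_se,
              if (x$family == "gamma") sprintf("  [fold %.3f]", exp(x$treatment_coef)) else ""))
  cat(sprintf("  Common smoother:       e.d.f. %.3f, approx p = %.4g\n",
              x$common$edf, x$common$p_value))
  cat(sprintf("  Differential smoother: e.d.f. %.3f, approx p = %.4g\n",
              x$differential$edf, x$differential$p_value))
  if (is.finite(x$elicitation_day))
    cat(sprintf("  Elicitation day (annotation): %g\n", x$elicitation_day))
  invisible(x)
}
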