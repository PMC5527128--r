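#' Default anthocyanin roster for the synthetic design
#'
#' Fifteen compounds: five aglycones (Dp, Cy, Pt, Pn, Mv) each as the
#' 3-O-glucoside, the acetyl-glucoside, and the p-coumaroyl-glucoside.
#' Dp, Pt and Mv form the delphinidin pathway branch (Dp is the precursor
#' of Pt and Mv); Cy and Pn form the cyanidin branch.
#'
#' @return data.frame with columns `metabolite`, `aglycone`, `conjugate`,
#'   `branch`.
#' @export
anthocyanin_roster <- function() {
  agly <- c("Dp", "Cy", "Pt", "Pn", "Mv")
  conj <- c("glu", "ac-glu", "pc-glu")
  branch <- c(Dp = "delphinidin", Cy = "cyanidin", Pt = "delphinidin",
              Pn = "cyanidin", Mv = "delphinidin")
  g <- expand.grid(aglycone = agly, conjugate = conj,
                   stringsAsFactors = FALSE)
  g <- g[order(match(g$aglycone, agly), match(g$conjugate, conj)), ]
  data.frame(metabolite = paste(g$aglycone, g$conjugate, sep = "-"),
             aglycone = g$aglycone, conjugate = g$conjugate,
             branch = unname(branch[g$aglycone]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# piecewise fold-change curve: exactly 1 up to onset, then a rescaled
# logistic rise reaching the plateau fold by `plateau_day`
.fold_curve <- function(t, fold, onset, plateau_day, steepness = 10) {
  u <- (t - onset) / (plateau_day - onset)
  L <- function(u) stats::plogis(steepness * (u - 0.5))
  g <- (L(pmin(pmax(u, 0), 1)) - L(0)) / (L(1) - L(0))
  ifelse(t <= onset, 1, 1 + (fold - 1) * g)
}

.logistic_growth <- function(t, asymptote, rate, midpoint) {
  asymptote / (1 + exp(-rate * (t - midpoint)))
}

#' Configuration for the synthetic time-course generator
#'
#' Encodes the statistical structure of a daily-sampled two-group
#' elicitation experiment: smooth positive baseline trends per metabolite,
#' a treatment fold-change curve that is exactly 1 up to the onset day and
#' rises smoothly to a plateau, Gamma multiplicative noise with constant
#' coefficient of variation, and within-branch correlation induced by a
#' shared per-replicate lognormal factor.
#'
#' Defaults mirror the emulated study design: days 1..20 sampled daily,
#' elicitation at day 5, 3 biological replicates per group, 15 anthocyanins
#' in two pathway branches, treated/control divergence starting after day 9
#' and stabilising by day 13, a 3-fold plateau for the delphinidin branch,
#' 1.63-fold for the cyanidin branch, no effect (fold 1) on the
#' acetyl-glucosides, and noise CV 0.10.
#'
#' @param days sampling days.
#' @param elicitation_day annotation carried into the dataset attributes.
#' @param replicates biological replicates per group.
#' @param roster metabolite roster as from [anthocyanin_roster()].
#' @param baseline data.frame of per-metabolite baseline parameters
#'   (`metabolite`, `shape` in `logistic-growth`/`flat`/`linear`,
#'   `asymptote`, `rate`, `midpoint`); `NULL` for built-in defaults.
#' @param effect data.frame of per-metabolite fold parameters
#'   (`metabolite`, `fold`); `NULL` for branch defaults above.
#' @param effect_onset,effect_plateau_day days bracketing the smooth rise
#'   of the fold-change curve.
#' @param noise_cv coefficient of variation of the observation noise.
#' @param noise `"gamma"` (shape 1/CV^2, matching the analysis family) or
#'   `"lognormal"` (same CV, for robustness checks).
#' @param branch_sd standard deviation (log scale) of the shared
#'   per-replicate branch factor (0 disables it); the factor has mean 1.
#' @param seed integer seed used by [simulate_timecourse()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(days = 1:20, elicitation_day = 5,
                             replicates = 3,
                             roster = anthocyanin_roster(),
                             baseline = NULL, effect = NULL,
                             effect_onset = 9, effect_plateau_day = 13,
                             noise_cv = 0.10,
                             noise = c("gamma", "lognormal"),
                             branch_sd = 0.2, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(baseline)) {
    # asymptotes loosely follow the reported relative abundances:
    # Pn and Cy glucosides dominant, Dp/Pt/Mv minor; acetyl forms scarce,
    # p-coumaroyl forms more abundant than the plain glucosides
    base_asym <- c(Dp = 35, Cy = 120, Pt = 15, Pn = 180, Mv = 10)
    conj_mult <- c("glu" = 1, "ac-glu" = 0.3, "pc-glu" = 2)
    baseline <- data.frame(
      metabolite = roster$metabolite,
      shape = "logistic-growth",
      asymptote = unname(base_asym[roster$aglycone] *
                           conj_mult[roster$conjugate]),
      rate = 0.6, midpoint = 5,
      stringsAsFactors = FALSE)
  }
  if (is.null(effect)) {
    fold <- ifelse(roster$conjugate == "ac-glu", 1,
                   ifelse(roster$branch == "delphinidin", 3, 1.63))
    effect <- data.frame(metabolite = roster$metabolite, fold = fold,
                         stringsAsFactors = FALSE)
  }
  if (any(baseline$asymptote <= 0) || any(baseline$rate <= 0))
    stop("baseline trend parameters must be positive", call. = FALSE)
  if (any(effect$fold < 0)) stop("fold must be non-negative", call. = FALSE)
  if (noise_cv <= 0) stop("noise_cv must be positive", call. = FALSE)
  structure(list(days = days, elicitation_day = elicitation_day,
                 replicates = replicates, roster = roster,
                 baseline = baseline, effect = effect,
                 effect_onset = effect_onset,
                 effect_plateau_day = effect_plateau_day,
                 noise_cv = noise_cv, noise = noise,
                 branch_sd = branch_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

.baseline_mean <- function(bl, t) {
  switch(bl$shape,
         "logistic-growth" = .logistic_growth(t, bl$asymptote, bl$rate,
                                              bl$midpoint),
         "flat" = rep(bl$asymptote, length(t)),
         "linear" = bl$asymptote * (0.2 + 0.8 * (t - min(t)) /
                                      max(diff(range(t)), 1)),
         stop(sprintf("unknown baseline shape '%s'", bl$shape),
              call. = FALSE))
}

.noise_draw <- function(n, mean, cv, kind) {
  if (kind == "gamma") {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, scale = mean * cv^2)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Simulate a full synthetic time-course dataset
#'
#' Generates `|days| x replicates x 2 groups x |metabolites|` observations.
#' The mean of each cell is `baseline(t) * fold(t)^[treated] * branch
#' factor`, where the branch factor is a shared per-replicate lognormal
#' multiplier (mean 1) common to all metabolites of a pathway branch, and
#' observation noise is Gamma (or lognormal) with the configured CV.
#'
#' @param config a [synthetic_config()].
#' @return long-format data.frame (`metabolite`, `day`, `replicate`,
#'   `group`, `concentration`) with the config attached as attribute
#'   `"config"`; all concentrations are strictly positive.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ro <- config$roster
  groups <- c("control", "treated")
  reps <- seq_len(config$replicates)
  # shared branch factors: one per (group, replicate, branch), mean 1
  branches <- unique(ro$branch)
  bf <- array(1, dim = c(2, config$replicates, length(branches)),
              dimnames = list(groups, NULL, branches))
  if (config$branch_sd > 0) {
    s <- config$branch_sd
    bf[] <- stats::rlnorm(length(bf), meanlog = -s^2 / 2, sdlog = s)
  }
  out <- vector("list", nrow(ro))
  for (i in seq_len(nrow(ro))) {
    m <- ro$metabolite[i]
    bl <- config$baseline[config$baseline$metabolite == m, ]
    fold <- config$effect$fold[config$effect$metabolite == m]
    mu_t <- .baseline_mean(bl, config$days)
    fc_t <- .fold_curve(config$days, fold, config$effect_onset,
                        config$effect_plateau_day)
    cells <- expand.grid(day = config$days, replicate = reps,
                         group = groups, stringsAsFactors = FALSE)
    di <- match(cells$day, config$days)
    mean_vec <- mu_t[di] * ifelse(cells$group == "treated", fc_t[di], 1) *
      bf[cbind(match(cells$group, groups), cells$replicate,
               match(ro$branch[i], branches))]
    conc <- .noise_draw(nrow(cells), mean_vec, config$noise_cv,
                        config$noise)
    out[[i]] <- data.frame(metabolite = m, day = cells$day,
                           replicate = paste0("R", cells$replicate),
                           group = cells$group, concentration = conc,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  res
}

#' Simulate from an explicit log-scale truth for parameter recovery
#'
#' Generates a single-response dataset whose log mean is
#' `intercept + shift * 1[treated] + g(t) + d(t) * 1[treated]`, exactly the
#' structure the trend model estimates, and returns the dataset together
#' with the truth so fitted smoothers can be compared against it.
#'
#' @param g common smooth: function of day, or vector over `days`.
#' @param d differential smooth (treated-only addition): function or
#'   vector; `d = 0` gives a null treatment-trend effect.
#' @param days sampling days.
#' @param replicates replicates per group.
#' @param intercept log-scale intercept.
#' @param shift log-scale constant treatment shift.
#' @param noise_cv CV of the Gamma observation noise.
#' @param seed integer seed.
#' @return list with `data` (long-format data.frame) and `truth` (list:
#'   `days`, `g`, `d`, `intercept`, `shift`, and the design-centred
#'   versions `g_centered` — centred over all observations — and
#'   `d_centered` — centred over treated observations — which are the
#'   estimands of the two smoothers).
#' @export
simulate_for_recovery <- function(g, d = 0, days = 1:20, replicates = 3,
                                  intercept = log(50), shift = 0,
                                  noise_cv = 0.10, seed = 1L) {
  gv <- if (is.function(g)) g(days) else rep_len(g, length(days))
  dv <- if (is.function(d)) d(days) else rep_len(d, length(days))
  if (any(!is.finite(gv)) || any(!is.finite(dv)))
    stop("truth functions must be finite on the design days", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(day = days, replicate = seq_len(replicates),
                       group = c("control", "treated"),
                       stringsAsFactors = FALSE)
  di <- match(cells$day, days)
  trt <- as.numeric(cells$group == "treated")
  logmu <- intercept + shift * trt + gv[di] + dv[di] * trt
  conc <- .noise_draw(nrow(cells), exp(logmu), noise_cv, "gamma")
  dat <- data.frame(metabolite = "synthetic", day = cells$day,
                    replicate = paste0("R", cells$replicate),
                    group = cells$group, concentration = conc,
                    stringsAsFactors = FALSE)
  truth <- list(days = days, g = gv, d = dv, intercept = intercept,
                shift = shift,
                g_centered = gv - mean(gv[di]),
                d_centered = dv - mean(dv[di][trt == 1]))
  list(data = dat, truth = truth)
}
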