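test_that("the emulated study design yields a three-term trend fit", {
  sim <- paper_design_sim(function(t) 0.1 * t, seed = 71)
  tf <- fit_trend_model(sim$data, "synthetic", elicitation_day = 5)
  expect_s3_class(tf, "trend_fit")
  # three model terms: Treatment factor + common + differential smoother
  expect_identical(tf$fit$spec$par_names, c("(Intercept)", "Treatment"))
  expect_named(tf$fit$spec$term_idx, c("s_cm", "s_diff"))
  expect_true(tf$fit$converged)
  # differential band reported only over days with treated observations
  expect_true(all(tf$differential$band$time %in%
                    sim$data$day[sim$data$group == "treated"]))
  # e.d.f. respect the gam_core invariants
  expect_gt(tf$common$edf, 0)
  expect_lte(tf$common$edf, 9 + 1e-8)
})

test_that("unsuitable designs are rejected with explicit messages", {
  sim <- paper_design_sim(function(t) 0.1 * t, seed = 72)
  d <- sim$data
  expect_error(fit_trend_model(d[d$group == "control", ]), "both groups")
  expect_error(fit_trend_model(d[d$day <= 8, ]),
               "not suitable .* limited number of time points")
  d2 <- d; d2$concentration[5] <- -1
  expect_error(fit_trend_model(d2), "offending rows: 5")
  expect_error(fit_trend_model(d, metabolite = "nope"), "not found")
})

test_that("a constant ratio is recovered exactly and judged trend-free", {
  sim <- paper_design_sim(function(t) 0.1 * t, seed = 73)
  d <- sim$data
  num <- d; num$metabolite <- "num"
  num$concentration <- 2 * d$concentration
  den <- d; den$metabolite <- "den"
  both <- rbind(num, den)
  tf <- fit_ratio_model(both, "num", "den")
  # ratio is identically 2: intercept recovers it on the log scale
  expect_equal(exp(tf$fit$coefficients[[1]]), 2, tolerance = 1e-6)
  expect_equal(tf$treatment_coef, 0, tolerance = 1e-6)
})

test_that("numerator identical to denominator gives a unit, trend-free
           ratio", {
  # the ratio of a noisy series with itself is identically 1: the fit
  # degenerates to the intercept and the differential test is vacuous
  sim <- paper_design_sim(function(t) 0.1 * t, seed = 740)
  a <- sim$data; a$metabolite <- "a"
  b <- sim$data; b$metabolite <- "b"
  tf <- fit_ratio_model(rbind(a, b), "a", "b")
  expect_equal(exp(tf$fit$coefficients[[1]]), 1, tolerance = 1e-8)
  expect_lte(tf$common$edf, 1.1)
  expect_true(is.na(tf$differential$p_value) ||
                tf$differential$p_value > 0.05)
})

test_that("a shared-law pair gives a near-unit, trend-free ratio", {
  # numerator and denominator follow the same mean curve with independent
  # noise: the ratio hovers around 1.  REML occasionally keeps mild
  # spurious wiggle on pure noise (mgcv behaves identically), so the
  # common smoother is held to the null-simulation bound (median e.d.f.
  # <= 1.5) while the differential test must stay non-significant.
  edfs <- numeric(30); ns <- 0L; n_sim <- 30
  for (i in seq_len(n_sim)) {
    s1 <- paper_design_sim(function(t) 0.1 * t, seed = 7400 + i)
    s2 <- paper_design_sim(function(t) 0.1 * t, seed = 9400 + i)
    a <- s1$data; a$metabolite <- "a"
    b <- s2$data; b$metabolite <- "b"
    tf <- fit_ratio_model(rbind(a, b), "a", "b")
    edfs[i] <- tf$common$edf
    if (is.na(tf$differential$p_value) || tf$differential$p_value > 0.05)
      ns <- ns + 1L
  }
  expect_lte(median(edfs), 1.5)
  expect_gte(ns, round(0.9 * n_sim))
})

test_that("ratio models reject unmatched pairs and zero denominators", {
  sim <- paper_design_sim(function(t) 0.1 * t, seed = 75)
  a <- sim$data; a$metabolite <- "a"
  b <- sim$data; b$metabolite <- "b"
  expect_error(fit_ratio_model(rbind(a, b[-1, ]), "a", "b"), "unmatched")
  expect_error(fit_ratio_model(rbind(a, b), "a", "c"), "not found")
})

test_that("a constant multiplicative treatment effect is absorbed by the
           Treatment factor", {
  hits <- 0L
  for (i in 1:20) {
    sim <- paper_design_sim(function(t) 0.08 * t, d = 0, shift = log(1.5),
                            seed = 7600 + i)
    tf <- fit_trend_model(sim$data, "synthetic")
    if (tf$differential$edf <= 1.5) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # and the shift lands on the Treatment coefficient
  sim <- paper_design_sim(function(t) 0.08 * t, d = 0, shift = log(1.5),
                          seed = 77, noise_cv = 0.02)
  tf <- fit_trend_model(sim$data, "synthetic")
  expect_equal(tf$treatment_coef, log(1.5), tolerance = 0.05)
})

test_that("relabelling groups is an exact symmetry in the unpenalized limit", {
  # with REML-chosen smoothing the two labelings penalize different
  # decompositions; at near-zero lambda the spans coincide and the
  # symmetry is exact (see methods vignette)
  sim <- paper_design_sim(function(t) 0.1 * t,
                          d = function(t) 0.3 * sin(t / 5), seed = 78)
  d <- sim$data
  y <- log(d$concentration)
  build <- function(treat_label) {
    trt <- as.numeric(d$group == treat_label)
    bs <- cr_basis(d$day, 10)
    cb_cm <- center_basis(bs, d$day)
    cb_df <- center_basis(cr_basis(d$day[trt == 1], 10), d$day[trt == 1])
    Xp <- cbind(`(Intercept)` = rep(1, nrow(d)), Treatment = trt)
    gam_model_spec(Xp, list(gam_smooth("s_cm", cb_cm, d$day),
                            gam_smooth("s_diff", cb_df, d$day, by = trt)),
                   family = "gaussian")
  }
  f1 <- pirls_fit(build("treated"), y, c(1e-8, 1e-8))
  f2 <- pirls_fit(build("control"), y, c(1e-8, 1e-8))
  expect_equal(f1$eta, f2$eta, tolerance = 1e-6)            # total fit invariant
  expect_equal(f1$coefficients[[2]], -f2$coefficients[[2]], # shift negates
               tolerance = 1e-6)
})

test_that("fit_all covers every response, tolerates failures, and is
           deterministic", {
  cfg <- synthetic_config(seed = 79)
  dat <- simulate_timecourse(cfg)
  tab <- fit_all(dat)
  expect_identical(nrow(tab), 15L)
  expect_true(all(tab$converged))
  expect_identical(sort(tab$response), sort(unique(dat$metabolite)))
  # rerun on the same data: byte-identical summary
  tab2 <- fit_all(dat)
  attr(tab, "fits") <- attr(tab2, "fits") <- NULL
  expect_identical(tab, tab2)
  # empty response list -> empty table, no error
  empty <- fit_all(dat, responses = character(0))
  expect_identical(nrow(empty), 0L)
  # individual failure recorded per-row, not fatal
  bad <- dat[dat$metabolite %in% c("Dp-glu", "Cy-glu"), ]
  bad <- bad[!(bad$metabolite == "Cy-glu" & bad$group == "treated"), ]
  tab3 <- fit_all(bad)
  expect_identical(nrow(tab3), 2L)
  expect_false(tab3$converged[tab3$response == "Cy-glu"])
  expect_match(tab3$message[tab3$response == "Cy-glu"], "both groups")
  expect_true(tab3$converged[tab3$response == "Dp-glu"])
})

test_that("ratios are included in fit_all summaries", {
  cfg <- synthetic_config(seed = 80,
                          roster = anthocyanin_roster()[c(1, 3), ])
  dat <- simulate_timecourse(cfg)
  tab <- fit_all(dat, responses = character(0),
                 ratios = list(c("Dp-pc-glu", "Dp-glu")))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$type, "ratio")
  expect_identical(tab$response, "Dp-pc-glu/Dp-glu")
})
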