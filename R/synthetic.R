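#' Default arm-level copy-number profile
#'
#' Diploid (copy 2) on every included arm except the alterations most
#' frequently seen in hormone-receptor-positive breast cancer cfDNA:
#' gains (copy 3) on 1q and 8q, losses (copy 1) on 8p, 10q, 13q and 17p.
#'
#' @param arms arm definitions; only included arms are used.
#' @return named numeric vector of copy numbers per included arm.
#' @export
defaultCNProfile <- function(arms = defaultArmDefinitions()) {
  ids <- includedArms(arms)$arm_id
  cn <- setNames(rep(2, length(ids)), ids)
  cn[c("1q", "8q")] <- 3
  cn[c("8p", "10q", "13q", "17p")] <- 1
  cn
}

#' Baseline per-arm read weights proportional to arm length
#' @param arms arm definitions.
#' @return named numeric vector summing to 1 over included arms.
#' @export
baselineArmWeights <- function(arms = defaultArmDefinitions()) {
  inc <- includedArms(arms)
  w <- GenomicRanges::width(inc)
  setNames(w / sum(w), inc$arm_id)
}

#' Expected arm fractions under a cfDNA tumor-fraction mixture
#'
#' Plasma cfDNA is modelled as a mixture of normal (diploid) and tumor
#' DNA: at tumor fraction \code{tf} the expected unnormalized weight of
#' arm \eqn{a} with tumor copy number \eqn{c_a} is
#' \eqn{w_a = p_a (1 + tf \cdot (c_a - 2)/2)}, renormalized to sum to 1.
#' \code{tf = 0} returns the baseline exactly; the altered-arm fractions
#' are continuous and monotone in \code{tf}.
#'
#' @param baseline named baseline fractions \eqn{p_a} (sum to 1).
#' @param profile named copy-number vector (same arms as baseline).
#' @param tf tumor fraction in [0, 1].
#' @return named expected fractions \eqn{q_a} summing to 1.
#' @export
expectedFractions <- function(baseline, profile, tf) {
  if (!is.numeric(tf) || length(tf) != 1 || tf < 0 || tf > 1)
    stopf("tf must be a single value in [0, 1]")
  if (abs(sum(baseline) - 1) > 1e-9) stopf("baseline must sum to 1")
  if (!setequal(names(baseline), names(profile)))
    stopf("baseline and profile must cover the same arms")
  cn <- profile[names(baseline)]
  if (any(cn < 0)) stopf("copy numbers must be >= 0")
  w <- baseline * (1 + tf * (cn - 2) / 2)
  w / sum(w)
}

#' Draw one sample's arm counts (Dirichlet-multinomial)
#'
#' The sample's realized composition is drawn from a Dirichlet with
#' concentration \code{overdispersion * q} (capturing sample-to-sample
#' amplicon variability beyond counting noise), then counts are a
#' multinomial draw of \code{library_size} reads from that composition.
#' Larger \code{overdispersion} approaches the pure multinomial limit.
#'
#' @param q named expected fractions summing to 1.
#' @param library_size total reads (default 90000).
#' @param overdispersion Dirichlet concentration (default 2000).
#' @param seed optional integer seed for a reproducible single draw.
#' @return named integer vector of counts summing to \code{library_size}.
#' @export
simulateCounts <- function(q, library_size = 90000,
                           overdispersion = 50000, seed = NULL) {
  if (!is.numeric(overdispersion) || overdispersion <= 0)
    stopf("overdispersion must be > 0")
  if (library_size <= 0) stopf("library_size must be > 0")
  if (abs(sum(q) - 1) > 1e-9) stopf("q must sum to 1")
  withSeed(seed, {
    g <- rgamma(length(q), shape = overdispersion * q)
    comp <- g / sum(g)
    setNames(as.integer(rmultinom(1, library_size, comp)), names(q))
  })
}

#' Simulation configuration for a synthetic cfDNA cohort
#'
#' Encodes the generative assumptions the scoring pipeline relies on.
#' Defaults emulate a first-line metastatic breast cancer cohort profiled
#' by LINE-1 amplicon sequencing: libraries of 90,000 single-end reads;
#' baseline arm weights proportional to arm length; Dirichlet
#' overdispersion giving a few-percent extra coefficient of variation per
#' arm in controls; a tumor-fraction mixture with a 40% ctDNA-negative
#' share and the remainder uniform on [0.05, 0.5]; negative-binomial CTC
#' counts whose log-mean rises with tumor fraction (so CTC count and
#' aneuploidy score correlate positively without being deterministically
#' linked); and exponential progression/death times whose hazard depends
#' on the expected score class through a proportional-hazards effect.
#'
#' @param n_controls,n_patients cohort sizes.
#' @param library_size reads per sample.
#' @param overdispersion Dirichlet concentration.
#' @param baseline_arm_weights named baseline fractions (default:
#'   arm-length weights).
#' @param cn_profile named copy-number profile ([defaultCNProfile()]).
#' @param tf_zero_prob zero-inflation share of tumor fraction.
#' @param tf_min,tf_max uniform range of non-zero tumor fractions.
#' @param ctc_size,ctc_intercept,ctc_slope negative-binomial size and
#'   log-mean link \code{log(mu) = ctc_intercept + ctc_slope * tf}.
#' @param vaf_slope,vaf_sd optional VAF covariate \code{vaf =
#'   max(0, vaf_slope * tf + noise)}.
#' @param pfs_median_low,os_median_low baseline (low-class) median
#'   event times in months.
#' @param log_hr log hazard ratio of the high expected-score class
#'   (default log 2.5).
#' @param censor_max months; censoring uniform on (0, censor_max].
#' @param arms arm definitions.
#' @param seed mandatory integer master seed; module-level draws use
#'   deterministic sub-streams of it.
#' @return list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(n_controls = 25, n_patients = 130,
                             library_size = 90000, overdispersion = 50000,
                             baseline_arm_weights = NULL,
                             cn_profile = NULL,
                             tf_zero_prob = 0.4, tf_min = 0.05,
                             tf_max = 0.5,
                             ctc_size = 1, ctc_intercept = log(1.5),
                             ctc_slope = 6,
                             vaf_slope = 0.8, vaf_sd = 0.03,
                             pfs_median_low = 12, os_median_low = 40,
                             log_hr = log(2.5), censor_max = 60,
                             arms = defaultArmDefinitions(),
                             seed = NULL) {
  if (is.null(seed)) stopf("a seed is mandatory")
  if (is.null(baseline_arm_weights))
    baseline_arm_weights <- baselineArmWeights(arms)
  if (is.null(cn_profile)) cn_profile <- defaultCNProfile(arms)
  cfg <- list(n_controls = n_controls, n_patients = n_patients,
              library_size = library_size,
              overdispersion = overdispersion,
              baseline_arm_weights = baseline_arm_weights,
              cn_profile = cn_profile, tf_zero_prob = tf_zero_prob,
              tf_min = tf_min, tf_max = tf_max, ctc_size = ctc_size,
              ctc_intercept = ctc_intercept, ctc_slope = ctc_slope,
              vaf_slope = vaf_slope, vaf_sd = vaf_sd,
              pfs_median_low = pfs_median_low,
              os_median_low = os_median_low, log_hr = log_hr,
              censor_max = censor_max, arms = arms,
              seed = as.integer(seed))
  with(cfg, {
    if (n_controls < 4 || n_patients < 1) stopf("cohort sizes too small")
    if (library_size <= 0 || overdispersion <= 0)
      stopf("library_size and overdispersion must be positive")
    if (tf_zero_prob < 0 || tf_zero_prob > 1 ||
        tf_min < 0 || tf_max > 1 || tf_min > tf_max)
      stopf("invalid tumor-fraction distribution")
    if (censor_max <= 0 || pfs_median_low <= 0 || os_median_low <= 0)
      stopf("survival parameters must be positive")
  })
  structure(cfg, class = "simulationConfig")
}

#' Simulate healthy controls (tumor fraction 0)
#' @param n number of controls.
#' @param config optional \code{simulationConfig}; if given, \code{n}
#'   defaults to its \code{n_controls}.
#' @param seed integer seed (ignored when \code{config} is given; the
#'   config's control stream is used).
#' @return an \linkS4class{ArmCounts} of \code{n} control samples.
#' @export
simulateControls <- function(n = NULL, config = NULL, seed = NULL) {
  if (is.null(config))
    config <- simulationConfig(n_controls = n, seed = seed)
  if (is.null(n)) n <- config$n_controls
  q <- config$baseline_arm_weights
  counts <- withSeed(subSeed(config$seed, 1), {
    t(vapply(seq_len(n), function(i)
      simulateCounts(q, config$library_size, config$overdispersion),
      numeric(length(q))))
  })
  rownames(counts) <- sprintf("control%03d", seq_len(n))
  armCounts(counts, config$arms)
}

#' Simulate a full patient cohort with controls, clinical covariates and
#' survival outcomes
#'
#' Controls are drawn at tumor fraction 0. Each patient draws a tumor
#' fraction from the zero-inflated mixture, arm counts from the
#' Dirichlet-multinomial at the tf-mixed expected fractions, a CTC count
#' from the tf-linked negative binomial, and a VAF covariate proportional
#' to tf with noise. The "true" score class of a patient is the class its
#' noise-free expected fractions receive against the control panel built
#' from the simulated controls; progression and death times are
#' exponential with hazard \code{h0 * exp(log_hr)} for true-high
#' patients, independently uniformly censored. Because CTC count is tied
#' to tumor fraction rather than to the realized score, marker
#' discordance arises naturally.
#'
#' @param config a [simulationConfig()].
#' @return list with elements \code{controls}, \code{patients} (both
#'   \linkS4class{ArmCounts}), \code{clinical} (data.frame: patient_id,
#'   ctc_count, vaf, age, who_ps, visceral, dfi_months, cdk46i,
#'   ca153_high, pfs_months, pfs_event, os_months, os_event),
#'   \code{truth} (data.frame: patient_id, tf, expected_score,
#'   true_class, true_pfs, true_os) and \code{panel} (the
#'   \linkS4class{ControlPanel} used for the truth labels).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  controls <- simulateControls(config = config)
  panel <- buildPanel(normalizeToFractions(controls), loo = TRUE)
  p <- config$baseline_arm_weights
  n <- config$n_patients

  tf <- withSeed(subSeed(config$seed, 2), {
    zero <- rbinom(n, 1, config$tf_zero_prob) == 1
    ifelse(zero, 0, runif(n, config$tf_min, config$tf_max))
  })
  qs <- vapply(tf, function(t)
    expectedFractions(p, config$cn_profile, t), numeric(length(p)))
  counts <- withSeed(subSeed(config$seed, 3), {
    t(vapply(seq_len(n), function(i)
      simulateCounts(qs[, i], config$library_size,
                     config$overdispersion), numeric(length(p))))
  })
  rownames(counts) <- sprintf("patient%03d", seq_len(n))
  patients <- armCounts(counts, config$arms)

  # truth label: deterministic excess of the expected composition over the
  # control mean, in control-SD units of the genome-wide statistic (the
  # stochastic part of S is already absorbed into the panel's sMean)
  expected_score <- vapply(seq_len(n), function(i) {
    z <- (qs[, i] - panel@armMean) / panel@armSd
    sum(z^2) / panel@sSd
  }, numeric(1))
  true_class <- classifyScore(expected_score)

  clinical <- withSeed(subSeed(config$seed, 4), {
    ctc <- rnbinom(n, size = config$ctc_size,
                   mu = exp(config$ctc_intercept + config$ctc_slope * tf))
    vaf <- pmax(0, config$vaf_slope * tf + rnorm(n, 0, config$vaf_sd))
    vaf[tf == 0] <- 0
    data.frame(
      patient_id = rownames(counts),
      ctc_count = ctc, vaf = vaf,
      age = round(rnorm(n, 68, 10)),
      who_ps = factor(sample(0:2, n, replace = TRUE,
                             prob = c(0.32, 0.57, 0.11))),
      visceral = rbinom(n, 1, 0.49),
      dfi_months = round(rexp(n, 1 / 180)),
      cdk46i = rbinom(n, 1, 0.28),
      ca153_high = rbinom(n, 1, 0.78))
  })

  surv <- withSeed(subSeed(config$seed, 5), {
    hi <- as.numeric(true_class == "high")
    h_pfs <- log(2) / config$pfs_median_low * exp(config$log_hr * hi)
    h_os <- log(2) / config$os_median_low * exp(config$log_hr * hi)
    t_pfs <- rexp(n, h_pfs)
    t_os <- rexp(n, h_os)
    cens <- runif(n, 0, config$censor_max)
    data.frame(true_pfs = t_pfs, true_os = t_os,
               pfs_months = pmin(t_pfs, cens),
               pfs_event = as.integer(t_pfs <= cens),
               os_months = pmin(t_os, cens),
               os_event = as.integer(t_os <= cens))
  })
  clinical <- cbind(clinical,
                    surv[, c("pfs_months", "pfs_event", "os_months",
                             "os_event")])
  truth <- data.frame(patient_id = rownames(counts), tf = tf,
                      expected_score = expected_score,
                      true_class = as.character(true_class),
                      true_pfs = surv$true_pfs, true_os = surv$true_os)
  list(controls = controls, patients = patients, clinical = clinical,
       truth = truth, panel = panel)
}

#' Simulate a clinical-only survival cohort with a dichotomous marker
#'
#' Lightweight generator for validating the survival stack: a binary
#' high-score class with given prevalence, exponential event times under
#' a proportional-hazards class effect, uniform censoring, plus
#' outcome-independent clinical noise covariates (age, WHO performance
#' status, visceral disease, disease-free interval, CDK4/6 inhibitor use,
#' CA15.3 class, and a CTC class correlated with the score class).
#'
#' @param n patients.
#' @param hr true hazard ratio of the high class (default 2.5).
#' @param prevalence_high P(high class) (default 0.36).
#' @param median_low baseline median event time in months (default 12).
#' @param censor_max censoring window upper bound in months (default 60).
#' @param seed integer seed.
#' @return data.frame with \code{time}, \code{event}, \code{score_high}
#'   and the noise covariates.
#' @export
simulateClinicalCohort <- function(n, hr = 2.5, prevalence_high = 0.36,
                                   median_low = 12, censor_max = 60,
                                   seed) {
  withSeed(seed, {
    score_high <- rbinom(n, 1, prevalence_high)
    h <- log(2) / median_low * exp(log(hr) * score_high)
    t_event <- rexp(n, h)
    cens <- runif(n, 0, censor_max)
    data.frame(
      time = pmin(t_event, cens),
      event = as.integer(t_event <= cens),
      score_high = score_high,
      ctc_high = rbinom(n, 1, ifelse(score_high == 1, 0.65, 0.3)),
      age = round(rnorm(n, 68, 10)),
      who_ps = factor(sample(0:2, n, replace = TRUE,
                             prob = c(0.32, 0.57, 0.11))),
      visceral = rbinom(n, 1, 0.49),
      dfi_months = round(rexp(n, 1 / 180)),
      cdk46i = rbinom(n, 1, 0.28),
      ca153_high = rbinom(n, 1, 0.78))
  })
}
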