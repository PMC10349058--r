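#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

checkSurvival <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("survival times must be positive and finite")
  if (!all(event %in% c(0, 1, FALSE, TRUE)))
    stopf("event must be 0/1")
}

#' Kaplan-Meier estimate with median survival and CI
#'
#' Product-limit estimator; at tied times events are processed before
#' censorings (the standard risk-set convention). The median is the first
#' time at which the survival curve drops to 0.5 or below, undefined if
#' the curve never reaches it; its confidence interval uses the
#' complementary log-log transform.
#'
#' @param time positive event/censoring times (months from blood draw).
#' @param event 1 = event (progression or death, per endpoint),
#'   0 = censored at last contact.
#' @param conf_level CI level (default 0.95).
#' @return list of class \code{kmCurve}: \code{curve} (data.frame with
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{survival},
#'   \code{lower}, \code{upper}), \code{median}, \code{median_ci},
#'   \code{n}, \code{n_events}.
#' @export
kaplanMeier <- function(time, event, conf_level = 0.95) {
  checkSurvival(time, event)
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "log-log",
                 conf.int = conf_level)
  tab <- summary(fit, censored = TRUE)
  curve <- data.frame(time = tab$time, n_risk = tab$n.risk,
                      n_event = tab$n.event, survival = tab$surv,
                      lower = tab$lower, upper = tab$upper)
  st <- summary(fit)$table
  med <- unname(st["median"])
  ci <- unname(st[c(grep("LCL$", names(st)), grep("UCL$", names(st)))])
  structure(list(curve = curve,
                 median = if (is.na(med)) NA_real_ else med,
                 median_ci = ci, n = fit$n, n_events = sum(event)),
            class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n,
              x$n_events))
  if (is.na(x$median)) cat("  median survival not reached\n")
  else cat(sprintf("  median %.2f (95%% CI %.2f-%.2f)\n", x$median,
                   x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Export a KM curve as tidy TSV
#' @param km a \code{kmCurve}.
#' @param path output path.
#' @export
writeKmTsv <- function(km, path) {
  write.table(km$curve, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Per-event-time risk table across groups: observed events, expected
# events and the hypergeometric covariance of the observed counts.
logrankComponents <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  etimes <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in etimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g)
      sum(event == 1 & time == t & group == g), numeric(1))
    O <- O + d_g
    E <- E + n_g * d_t / n_t
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + c_t * (diag(n_g / n_t, k) -
                        tcrossprod(n_g / n_t))
    }
  }
  list(O = O, E = E, V = V, levels = levels(group), k = k)
}

#' Log-rank test across groups
#'
#' Standard O-E chi-square over the shared risk sets, df = number of
#' groups minus 1.
#'
#' @param time,event as in [kaplanMeier()].
#' @param group group membership (factor/character/numeric).
#' @return a test result.
#' @export
logrankTest <- function(time, event, group) {
  checkSurvival(time, event)
  if (sum(event) == 0) stopf("log-rank test needs at least one event")
  if (length(unique(group)) < 2) stopf("need at least 2 groups")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  testResult("Log-rank test", sd$chisq,
             pchisq(sd$chisq, df, lower.tail = FALSE),
             length(time), details = list(df = df))
}

#' Log-rank test for trend across ordered groups
#'
#' A 1-df test contrasting the per-group observed-minus-expected event
#' counts with monotone scores: the statistic is
#' \eqn{(c'(O-E))^2 / (c' V c)} with \eqn{V} the hypergeometric
#' covariance of the observed counts over the shared risk sets. With two
#' groups it reduces to the ordinary log-rank test.
#'
#' @param time,event as in [kaplanMeier()].
#' @param group ordered group membership; factor level order (or sorted
#'   unique order) defines the trend direction.
#' @param scores numeric trend scores, one per group (default
#'   equally spaced 1..k).
#' @return a test result, df = 1.
#' @export
logrankTrend <- function(time, event, group, scores = NULL) {
  checkSurvival(time, event)
  if (sum(event) == 0) stopf("trend test needs at least one event")
  comp <- logrankComponents(time, event, group)
  if (is.null(scores)) scores <- seq_len(comp$k)
  if (length(scores) != comp$k)
    stopf("need one score per group (%d groups, %d scores)", comp$k,
          length(scores))
  num <- sum(scores * (comp$O - comp$E))
  den <- drop(t(scores) %*% comp$V %*% scores)
  if (den <= 0) stopf("degenerate risk table: zero trend variance")
  stat <- num^2 / den
  testResult("Log-rank test for trend", stat,
             pchisq(stat, 1, lower.tail = FALSE), length(time),
             details = list(df = 1, scores = scores,
                            direction = sign(num)))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron approximation for tied
#' event times (a \code{ties} flag switches to Breslow, which some legacy
#' software defaults to and which produces slightly different estimates
#' in the presence of ties). Wald confidence intervals at 95%.
#'
#' @param data data.frame with columns \code{time}, \code{event} and the
#'   covariates.
#' @param covariates character vector of covariate column names;
#'   categorical covariates should be factors with the reference level
#'   first.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param conf_level CI level (default 0.95).
#' @return list of class \code{coxFit}: \code{terms} (data.frame: term,
#'   coef, hr, ci_low, ci_high, p), \code{n}, \code{n_events},
#'   \code{converged}, \code{loglik}, and the underlying \code{fit}.
#' @export
coxFit <- function(data, covariates, ties = c("efron", "breslow"),
                   conf_level = 0.95) {
  ties <- match.arg(ties)
  checkSurvival(data$time, data$event)
  if (sum(data$event) == 0) stopf("Cox fit needs at least one event")
  const <- vapply(covariates, function(v)
    length(unique(data[[v]][!is.na(data[[v]])])) < 2, logical(1))
  if (any(const))
    stopf("constant covariate(s): %s",
          paste(covariates[const], collapse = ", "))
  if (any(covariates != make.names(covariates)))
    stopf("covariate names must be syntactic")
  fm <- as.formula(paste("Surv(time, event) ~",
                         paste(covariates, collapse = " + ")))
  warn <- character()
  fit <- withCallingHandlers(
    coxph(fm, data = data, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  terms <- data.frame(term = rownames(co), coef = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      ci_low = ci[, 3], ci_high = ci[, 4],
                      p = co[, "Pr(>|z|)"], row.names = NULL)
  separation <- any(grepl("converged before|infinite", warn)) ||
    any(abs(co[, "coef"]) > 15)
  structure(list(terms = terms, n = sm$n, n_events = sm$nevent,
                 converged = !separation && fit$iter < 20 &&
                   all(is.finite(co[, "coef"])),
                 warnings = warn, loglik = fit$loglik, fit = fit),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  df <- x$terms
  df$summary <- sprintf("HR %.2f (%.2f-%.2f), p = %.3g", df$hr,
                        df$ci_low, df$ci_high, df$p)
  print(df[, c("term", "summary")], row.names = FALSE)
  invisible(x)
}

# Term-level p-value: single-coefficient Wald p, or an aggregate Wald
# chi-square for multi-level factor terms.
termPvalue <- function(fit, term) {
  asg <- fit$fit$assign[[term]]
  if (is.null(asg)) stopf("term %s not in fit", term)
  beta <- stats::coef(fit$fit)[asg]
  V <- fit$fit$var[asg, asg, drop = FALSE]
  stat <- drop(t(beta) %*% solve(V) %*% beta)
  pchisq(stat, length(asg), lower.tail = FALSE)
}

#' Univariable screen plus backward stepwise Cox selection
#'
#' Mirrors the conventional biomarker-validation recipe: (1) fit each
#' candidate in its own univariable Cox model; (2) candidates with
#' p < \code{enter_p} (default 0.1, lenient to avoid falsely rejecting
#' borderline factors) enter the multivariable model; (3) backward
#' elimination repeatedly removes the term with the largest p-value
#' while any term has p >= \code{stay_p} (default 0.05). Multi-level
#' factors are screened and eliminated as whole terms via an aggregate
#' Wald test.
#'
#' @param data data.frame with \code{time}, \code{event} and candidates.
#' @param candidates character vector of candidate covariate names.
#' @param enter_p univariable admission threshold (default 0.1).
#' @param stay_p multivariable retention threshold (default 0.05).
#' @param ties tie handling, see [coxFit()].
#' @return list of class \code{stepwiseCox}: \code{final} (a
#'   \code{coxFit}, or NULL when no candidate passes the screen),
#'   \code{univariable} (data.frame term/p/admitted), \code{trace}
#'   (data.frame of elimination steps), \code{selected} (character).
#' @export
stepwiseCox <- function(data, candidates, enter_p = 0.1, stay_p = 0.05,
                        ties = "efron") {
  uni <- lapply(candidates, function(v) {
    fit <- coxFit(data, v, ties = ties)
    data.frame(term = v, p = termPvalue(fit, v))
  })
  uni <- do.call(rbind, uni)
  uni$admitted <- uni$p < enter_p
  current <- uni$term[uni$admitted]
  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric())
  if (!length(current))
    return(structure(list(final = NULL, univariable = uni, trace = trace,
                          selected = character()),
                     class = "stepwiseCox"))
  step <- 0L
  repeat {
    fit <- coxFit(data, current, ties = ties)
    pvals <- vapply(current, function(v) termPvalue(fit, v), numeric(1))
    if (all(pvals < stay_p)) break
    worst <- which.max(pvals)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = current[worst],
                                     p = unname(pvals[worst])))
    current <- current[-worst]
    if (!length(current)) {
      fit <- NULL
      break
    }
  }
  structure(list(final = fit, univariable = uni, trace = trace,
                 selected = current),
            class = "stepwiseCox")
}

#' @export
print.stepwiseCox <- function(x, ...) {
  cat("Stepwise Cox selection\n  univariable screen (p < 0.1):\n")
  print(x$univariable, row.names = FALSE)
  if (nrow(x$trace)) {
    cat("  eliminations:\n")
    print(x$trace, row.names = FALSE)
  }
  if (is.null(x$final)) cat("  no covariate retained (null model)\n")
  else {
    cat("  final model:\n")
    print(x$final)
  }
  invisible(x)
}
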