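PANEL_SCHEMA_VERSION <- 1L
PANEL_FIELDS <- c("schema_version", "arm_ids", "arm_mean", "arm_sd",
                  "s_mean", "s_sd", "n_controls", "loo", "control_s",
                  "build_metadata")

# Column means and n-1 sd of a samples-in-columns matrix, leave-one-out:
# row i of the result is the mean/sd over all samples except sample i.
looMeanSd <- function(f) {
  n <- ncol(f)
  tot <- rowSums(f)
  tot2 <- rowSums(f^2)
  loo_mean <- (matrix(tot, nrow(f), n) - f) / (n - 1)
  loo_ss <- (matrix(tot2, nrow(f), n) - f^2) - (n - 1) * loo_mean^2
  loo_sd <- sqrt(pmax(loo_ss, 0) / (n - 2))
  list(mean = loo_mean, sd = loo_sd)
}

#' Build a healthy-control reference panel
#'
#' Computes the per-arm mean and standard deviation (denominator n-1) of
#' the control read fractions, plus the location and scale of the
#' genome-wide sum-of-squared-Z statistic in the controls. With
#' \code{loo = TRUE} (default) each control's statistic is computed
#' against the panel built from the remaining controls, so the resulting
#' calibration is honest for new samples; with \code{loo = FALSE}
#' controls are scored against the full panel containing themselves,
#' which biases the statistic low and is provided only for comparison.
#'
#' @param control_fractions an \linkS4class{ArmFractions} of at least 3
#'   healthy controls.
#' @param loo logical, leave-one-out calibration (default \code{TRUE}).
#' @return a \linkS4class{ControlPanel}.
#' @examples
#' sim <- simulateControls(n = 20, seed = 7)
#' panel <- buildPanel(normalizeToFractions(sim))
#' panel
#' @export
buildPanel <- function(control_fractions, loo = TRUE) {
  f <- fractionsMatrix(control_fractions)
  n <- ncol(f)
  if (n < 3L) stopf("need at least 3 controls, got %d", n)
  mu <- rowMeans(f)
  sdev <- apply(f, 1, sd)
  if (any(sdev == 0))
    stopf("zero control variance for arm(s) %s; provide more or more varied controls",
          paste(armIds(control_fractions)[sdev == 0], collapse = ", "))
  if (loo) {
    if (n < 4L) stopf("leave-one-out calibration needs at least 4 controls")
    ls <- looMeanSd(f)
    if (any(ls$sd == 0))
      stopf("zero leave-one-out control variance; provide more varied controls")
    z <- (f - ls$mean) / ls$sd
  } else {
    z <- (f - mu) / sdev
  }
  s <- colSums(z^2)
  new("ControlPanel", armIds = armIds(control_fractions),
      armMean = unname(mu), armSd = unname(sdev),
      sMean = mean(s), sSd = sd(s), nControls = as.integer(n),
      loo = loo, controlS = unname(s),
      buildMetadata = list(built = format(Sys.time(), "%Y-%m-%d"),
                           n_arms = nrow(f)))
}

#' Out-of-sample aneuploidy scores of a set of controls
#'
#' For each control, builds a panel from the remaining controls
#' (leave-one-out calibrated) and scores the held-out control against it.
#' For a well-behaved control set these scores have mean near 0 and
#' standard deviation near 1; systematic departure indicates panel
#' miscalibration.
#'
#' @param control_fractions an \linkS4class{ArmFractions} of at least 5
#'   controls.
#' @return named numeric vector of held-out scores.
#' @export
looControlScores <- function(control_fractions) {
  f <- fractionsMatrix(control_fractions)
  n <- ncol(f)
  if (n < 5L) stopf("need at least 5 controls for held-out scoring")
  vapply(seq_len(n), function(i) {
    panel <- buildPanel(control_fractions[, -i], loo = TRUE)
    z <- (f[, i] - panel@armMean) / panel@armSd
    (sum(z^2) - panel@sMean) / panel@sSd
  }, numeric(1)) |> setNames(colnames(f))
}

#' Save / load a control panel
#'
#' Panels serialize to JSON with an explicit schema-version key; loading
#' validates the schema (missing or extra fields are an error naming the
#' field) and re-checks the panel invariants.
#'
#' @param panel a \linkS4class{ControlPanel}.
#' @param path JSON file path.
#' @export
savePanel <- function(panel, path) {
  stopifnot(is(panel, "ControlPanel"))
  obj <- list(schema_version = PANEL_SCHEMA_VERSION,
              arm_ids = panel@armIds, arm_mean = panel@armMean,
              arm_sd = panel@armSd, s_mean = panel@sMean,
              s_sd = panel@sSd, n_controls = panel@nControls,
              loo = panel@loo, control_s = panel@controlS,
              build_metadata = panel@buildMetadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname savePanel
#' @return \code{loadPanel}: the restored \linkS4class{ControlPanel}.
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(PANEL_FIELDS, names(obj))
  if (length(missing))
    stopf("panel file missing field(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(names(obj), PANEL_FIELDS)
  if (length(extra))
    stopf("panel file has unknown field(s): %s", paste(extra, collapse = ", "))
  if (!identical(as.integer(obj$schema_version), PANEL_SCHEMA_VERSION))
    stopf("unsupported panel schema version %s", obj$schema_version)
  new("ControlPanel", armIds = as.character(obj$arm_ids),
      armMean = as.numeric(obj$arm_mean), armSd = as.numeric(obj$arm_sd),
      sMean = as.numeric(obj$s_mean), sSd = as.numeric(obj$s_sd),
      nControls = as.integer(obj$n_controls), loo = as.logical(obj$loo),
      controlS = as.numeric(obj$control_s),
      buildMetadata = as.list(obj$build_metadata))
}

#' Export per-arm panel statistics as TSV
#' @param panel a \linkS4class{ControlPanel}.
#' @param path output TSV path.
#' @export
exportPanelTsv <- function(panel, path) {
  write.table(data.frame(arm_id = panel@armIds, mean = panel@armMean,
                         sd = panel@armSd),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
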