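.startleBaseline <- function(trials, baselineType) {
  stopifnot(is.data.frame(trials),
            all(c("trial_type", "amplitude") %in% colnames(trials)))
  if (any(trials$amplitude < 0)) stop("amplitudes must be nonnegative")
  base <- trials$amplitude[trials$trial_type == baselineType]
  if (!length(base)) stop("no '", baselineType, "' trials for the baseline")
  baseline <- mean(base)
  if (baseline <= 0) stop("baseline startle response is zero")
  baseline
}

#' Percent prepulse inhibition per trial type
#'
#' Baseline startle is the mean amplitude over the startle-alone trials.
#' For each prepulse trial type the inhibition is
#' `%PPI = (1 - mean(amplitude) / baseline) * 100`, floored at 0% (a
#' prepulse response at or above baseline is reported as 0% PPI). The raw
#' response ratio `mean / baseline * 100` is emitted alongside as a
#' diagnostic.
#'
#' @param trials data.frame with columns `trial_type` and `amplitude`.
#' @param baselineType label of the startle-alone trials
#'   (default `"startle_alone"`).
#' @return list with `baseline` and `table`, a data.frame per prepulse
#'   trial type: `trial_type`, `meanAmplitude`, `responseRatioPct`, `ppi`.
#' @examples
#' tr <- data.frame(trial_type = rep(c("startle_alone", "pp75"), each = 2),
#'                  amplitude = c(100, 100, 40, 40))
#' percentPPI(tr)$table$ppi  # 60
#' @export
percentPPI <- function(trials, baselineType = "startle_alone") {
  baseline <- .startleBaseline(trials, baselineType)
  types <- setdiff(unique(trials$trial_type), baselineType)
  if (!length(types)) stop("no prepulse trials")
  mu <- vapply(types, function(tt)
    mean(trials$amplitude[trials$trial_type == tt]), numeric(1))
  data.frame(trial_type = types, meanAmplitude = unname(mu),
             responseRatioPct = unname(mu / baseline * 100),
             ppi = pmax(0, (1 - unname(mu) / baseline) * 100),
             stringsAsFactors = FALSE, row.names = NULL) -> tab
  list(baseline = baseline, table = tab)
}

#' Baseline-normalized startle and sensitization count
#'
#' Each prepulse trial type's mean amplitude is expressed as a percentage of
#' the baseline startle; a trial type is sensitized when that normalized
#' response exceeds 100% (startle beyond baseline).
#'
#' @inheritParams percentPPI
#' @return list with `baseline`, `table` (data.frame `trial_type`,
#'   `normalizedPct`, `sensitized`) and `nSensitized`.
#' @export
sensitizationTrials <- function(trials, baselineType = "startle_alone") {
  baseline <- .startleBaseline(trials, baselineType)
  types <- setdiff(unique(trials$trial_type), baselineType)
  if (!length(types)) stop("no prepulse trials")
  mu <- vapply(types, function(tt)
    mean(trials$amplitude[trials$trial_type == tt]), numeric(1))
  norm <- unname(mu / baseline * 100)
  tab <- data.frame(trial_type = types, normalizedPct = norm,
                    sensitized = norm > 100,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(baseline = baseline, table = tab, nSensitized = sum(tab$sensitized))
}
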