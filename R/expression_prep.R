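#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) onto the identical distribution: the
#' reference distribution is the across-column mean of the order
#' statistics. Tied values within a column receive the mean of the
#' reference values at their tied ranks.
#'
#' @param mat numeric matrix, features x samples, no missing values.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("quantile_normalize: missing values not supported")
  if (ncol(mat) < 2) {
    warning("quantile_normalize: single-sample matrix returned unchanged")
    return(mat)
  }
  ref <- rowMeans(apply(mat, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(mat, 2, function(x) {
    # a tied group occupying ranks rmin..rmax gets mean(ref[rmin:rmax])
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    (cs[rmax + 1] - cs[rmin]) / (rmax - rmin + 1)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Detection rule for miRNA probes
#'
#' A feature is called detected when its intensity exceeds the
#' negative-control mean plus `sd_multiplier` negative-control SDs in at
#' least a `min_sample_fraction` of samples.
#'
#' @param min_sample_fraction required fraction of samples, in (0, 1].
#' @param sd_multiplier number of negative-control SDs above the mean.
#' @export
detection_rule <- function(min_sample_fraction = 1 / 3, sd_multiplier = 1.5) {
  if (min_sample_fraction <= 0 || min_sample_fraction > 1)
    stop("min_sample_fraction must lie in (0, 1]")
  if (sd_multiplier < 0) stop("sd_multiplier must be >= 0")
  structure(list(min_sample_fraction = min_sample_fraction,
                 sd_multiplier = sd_multiplier), class = "detection_rule")
}

#' Apply the negative-control detection filter
#'
#' The intensity comparison is strict (`>`): a feature sitting exactly at
#' the threshold does not count as expressed in that sample. The sample
#' fraction comparison is `>=`, so e.g. 2 of 6 samples satisfies a 1/3
#' requirement.
#'
#' @param mat features x samples intensity matrix.
#' @param negctrl_mean,negctrl_sd negative-control summary statistics.
#' @param rule a [detection_rule()].
#' @return character vector of detected feature ids.
#' @export
detection_filter <- function(mat, negctrl_mean, negctrl_sd,
                             rule = detection_rule()) {
  if (negctrl_sd < 0) stop("negctrl_sd must be >= 0")
  mat <- as.matrix(mat)
  if (nrow(mat) == 0 || ncol(mat) == 0) return(character(0))
  thr <- negctrl_mean + rule$sd_multiplier * negctrl_sd
  frac <- rowMeans(mat > thr)
  rownames(mat)[frac >= rule$min_sample_fraction]
}

#' Collapse replicated probes to features by median
#'
#' @param mat probes x samples matrix.
#' @param groups feature id per probe row.
#' @return features x samples matrix of per-group medians.
#' @export
collapse_probes <- function(mat, groups) {
  mat <- as.matrix(mat)
  stopifnot(length(groups) == nrow(mat))
  ug <- unique(groups)
  out <- t(vapply(ug, function(g)
    apply(mat[groups == g, , drop = FALSE], 2, median),
    numeric(ncol(mat))))
  rownames(out) <- ug
  out
}
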