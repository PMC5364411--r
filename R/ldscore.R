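#' Compute per-variant LD scores from a haplotype panel
#'
#' For each reported variant j, `ell[j]` is the sum of adjusted squared
#' correlations `r2 - (1 - r2) / (n - 2)` over all panel variants within
#' `windowCm` of j on the same chromosome (self term included, contributing
#' exactly 1).  When `regressionSubset` is given, scores are reported only
#' for those variants but the sum still runs over every panel variant in
#' the window.
#'
#' @param panel a [HaplotypePanel-class].
#' @param windowCm window half-width in centiMorgans (default 1).
#' @param regressionSubset optional character vector of variant ids to
#'   report.
#' @return an [LDScoreTable-class].
#' @export
computeLDScores <- function(panel, windowCm = 1, regressionSubset = NULL) {
  if (windowCm <= 0) stop("windowCm must be positive")
  vt <- panel@variants
  M <- nVariants(vt)
  if (M == 0) stop("panel is empty")
  n <- nrow(panel@haplotypes)
  X <- scale(panel@haplotypes)
  report <- if (is.null(regressionSubset)) seq_len(M)
            else sort(match(regressionSubset, vt@id))
  if (anyNA(report)) stop("regressionSubset contains unknown variant ids")
  ell <- numeric(length(report))
  adj <- function(r2) r2 - (1 - r2) / (n - 2)
  for (k in seq_along(report)) {
    j <- report[k]
    win <- which(vt@chrom == vt@chrom[j] &
                 abs(vt@cm - vt@cm[j]) <= windowCm)
    r <- as.numeric(crossprod(X[, win, drop = FALSE], X[, j])) / (n - 1)
    ell[k] <- sum(adj(r^2))
  }
  new("LDScoreTable", variants = subsetVariants(vt, report),
      ell = pmax(ell, 1e-6), nHaplotypes = as.integer(n))
}
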