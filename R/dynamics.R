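## Backbone dynamics and solvent exchange: heteronuclear NOE ratios with
## Monte-Carlo uncertainties, flexibility flagging, and H/D-exchange
## extent and protection classing.

#' Heteronuclear NOE ratios with Monte-Carlo errors
#'
#' The \{1H\}-15N NOE is the ratio of the peak intensity measured with
#' proton saturation to the intensity without. Uncertainties are
#' estimated by Monte-Carlo resampling: Gaussian noise of standard
#' deviation `noise_sd` (the spectrum baseline noise) is added
#' independently to both intensities `nMc` times and the standard
#' deviation of the resampled ratios reported.
#'
#' @param pairs data.frame with columns `resno`, `i_sat`, `i_ref`,
#'   `noise_sd` (intensities in arbitrary units, one row per residue).
#' @param nMc number of Monte-Carlo draws (default 500).
#' @param seed RNG seed for reproducible errors.
#' @return data.frame with columns `resno`, `ratio`, `ratio_error`.
#' @export
hetNoe <- function(pairs, nMc = 500L, seed = NULL) {
  stopifnot(nMc >= 1L)
  need <- c("resno", "i_sat", "i_ref", "noise_sd")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  if (any(pairs$noise_sd < 0)) stop("noise_sd must be >= 0")
  bad <- pairs$i_ref == 0
  if (any(bad)) {
    warning("skipping residues with zero reference intensity: ",
            paste(pairs$resno[bad], collapse = " "))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  withSeed(seed, {
    n <- nrow(pairs)
    err <- numeric(n)
    for (i in seq_len(n)) {
      if (pairs$noise_sd[i] == 0) { err[i] <- 0; next }
      satDraw <- pairs$i_sat[i] + stats::rnorm(nMc, 0, pairs$noise_sd[i])
      refDraw <- pairs$i_ref[i] + stats::rnorm(nMc, 0, pairs$noise_sd[i])
      err[i] <- stats::sd(satDraw / refDraw)
    }
    data.frame(resno = pairs$resno, ratio = pairs$i_sat / pairs$i_ref,
               ratio_error = err)
  })
}

#' Flag fast-timescale flexible residues
#'
#' Residues with a hetNOE ratio strictly below the cutoff (conventionally
#' 0.7) are flagged as flexible on the fast (ps-ns) timescale.
#'
#' @param records data.frame from [hetNoe()].
#' @param cutoff ratio threshold (default 0.7, strict `<`).
#' @return sorted integer vector of residue numbers.
#' @export
flagFlexible <- function(records, cutoff = 0.7) {
  sort(records$resno[records$ratio < cutoff])
}

#' Classify H/D-exchange protection from timed peak intensities
#'
#' After transfer into D2O buffer, amide peaks are recorded at a series of
#' delays (classically 15 min, 24 h, 48 h). A peak is "detected" at a
#' timepoint if its intensity exceeds `detectK` times the noise standard
#' deviation. Classes follow the longest prefix of detected timepoints:
#' \describe{
#'   \item{unprotected}{not detected at the first timepoint}
#'   \item{short}{detected at the first timepoint only}
#'   \item{medium}{detected at the first two but not the last}
#'   \item{persistent}{detected at all three}
#' }
#'
#' @param series long data.frame with columns `resno`, `time_min`,
#'   `intensity`, `noise_sd`; every residue must share the same
#'   three-point time grid.
#' @param detectK detection threshold multiplier (default 3).
#' @return data.frame with columns `resno`, `class`.
#' @export
hdxClassify <- function(series, detectK = 3) {
  need <- c("resno", "time_min", "intensity", "noise_sd")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  grids <- split(series$time_min, series$resno)
  grid <- sort(unique(series$time_min))
  ok <- vapply(grids, function(g) identical(sort(g), grid), logical(1))
  if (!all(ok))
    stop("inconsistent timepoint grids across residues: ",
         paste(names(grids)[!ok], collapse = " "))
  if (length(grid) != 3L)
    stop("protection classing expects exactly 3 timepoints, got ",
         length(grid))
  classes <- c("unprotected", "short", "medium", "persistent")
  out <- lapply(split(series, series$resno), function(s) {
    s <- s[order(s$time_min), , drop = FALSE]
    det <- s$intensity > detectK * s$noise_sd
    ## longest detected prefix decides the class
    k <- match(FALSE, det, nomatch = length(det) + 1L) - 1L
    data.frame(resno = s$resno[1], class = classes[k + 1L])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extent of hydrogen-deuterium exchange
#'
#' Fractional exchange at each timepoint, `1 - intensity / reference`,
#' clamped to [0, 1]. The reference is the pre-exchange peak intensity
#' (or a first-point proxy).
#'
#' @param series long data.frame with columns `resno`, `time_min`,
#'   `intensity`.
#' @param referenceIntensity positive scalar, or named numeric vector
#'   keyed by residue number.
#' @return data.frame with columns `resno`, `time_min`, `extent`.
#' @export
hdxExtent <- function(series, referenceIntensity) {
  if (any(referenceIntensity <= 0))
    stop("referenceIntensity must be > 0")
  ref <- if (length(referenceIntensity) == 1L) {
    rep(referenceIntensity, nrow(series))
  } else {
    r <- referenceIntensity[as.character(series$resno)]
    if (any(is.na(r))) stop("referenceIntensity missing for some residues")
    r
  }
  extent <- pmin(1, pmax(0, 1 - series$intensity / ref))
  data.frame(resno = series$resno, time_min = series$time_min,
             extent = extent)
}
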