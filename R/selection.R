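#' Gaussian least-squares AIC
#'
#' AIC = n * ln(RSS / n) + 2 k, the Akaike criterion for a linear model
#' with Gaussian errors when the error variance is profiled out. Smaller is
#' better. The parameter count used by the model-selection routines is
#' k = q + 2 W N: the basis coefficients plus an amplitude and a derivative
#' coefficient per trial per waveform component (the split location itself
#' is not counted).
#'
#' @param rss Residual sum of squares (> 0).
#' @param k Number of estimated parameters, 0 <= k < n.
#' @param n Number of data points (N * T).
#' @return Numeric scalar.
#' @examples
#' swaleAIC(100, k = 0, n = 100)  # 0
#' @export
swaleAIC <- function(rss, k, n) {
  if (length(rss) != 1L || !is.finite(rss) || rss <= 0)
    stop("rss must be a positive scalar (a perfect fit has no finite AIC)")
  if (n <= k || k < 0)
    stop("need n > k >= 0")
  n * log(rss / n) + 2 * k
}

## Local extrema of a vector on the sample grid: strict inequality against
## both neighbours; on plateaus only the leftmost sample counts.
.localExtrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  core <- 2:(n - 1)
  isMax <- y[core] > y[core - 1] & y[core] > y[core + 1]
  isMin <- y[core] < y[core - 1] & y[core] < y[core + 1]
  sort(core[isMax | isMin])
}

#' Candidate split points between adjacent peaks of a waveform
#'
#' Evaluates the (masked) waveform on the sample grid, finds its local
#' extrema inside the given range, and returns every sample index strictly
#' between each pair of adjacent extrema. These are the candidate time
#' points at which the waveform may be split into two components.
#'
#' @param waveform A \linkS4class{Waveform}.
#' @param basis The matching \linkS4class{BasisSet}.
#' @param range A \linkS4class{PeakRange} delimiting the search.
#' @return Integer vector of candidate sample indices (1-based); empty if
#'   fewer than two extrema lie inside the range.
#' @export
findSplitCandidates <- function(waveform, basis, range) {
  tax <- timeAxis(basis)
  if (range@tLo < min(tax) - 1e-9 || range@tHi > max(tax) + 1e-9)
    stop("range lies outside the epoch's time axis")
  y <- evalWaveform(waveform, basis)
  ext <- .localExtrema(y)
  inRange <- ext[tax[ext] >= range@tLo & tax[ext] <= range@tHi &
                   waveform@support[ext]]
  if (length(inRange) < 2L) return(integer(0))
  out <- integer(0)
  for (j in seq_len(length(inRange) - 1L)) {
    lo <- inRange[j]; hi <- inRange[j + 1L]
    if (hi - lo > 1L) out <- c(out, (lo + 1L):(hi - 1L))
  }
  out
}

## Score one candidate split of component `component`: freeze all
## coefficients, split that component's mask at sample s (before-s /
## from-s), re-estimate per-trial parameters jointly, return the RSS.
.scoreSplit <- function(Y, fit, component, s, ampFloor) {
  wfs <- fit@waveforms
  target <- wfs[[component]]
  m1 <- target@support & (seq_along(target@support) < s)
  m2 <- target@support & (seq_along(target@support) >= s)
  if (!any(m1) || !any(m2)) return(NULL)
  newWfs <- append(wfs[-component],
                   list(Waveform(target@coeffs, support = m1),
                        Waveform(target@coeffs, support = m2)))
  upd <- tryCatch(.trialParamsAll(Y, newWfs, fit@basis, ampFloor),
                  error = function(e) NULL)
  if (is.null(upd)) return(NULL)
  rss <- residualSS(Y, predictTrials(newWfs, fit@basis, upd$params))
  list(masks = lapply(newWfs, slot, "support"), rss = rss,
       m1 = m1, m2 = m2)
}

#' Best split of a fitted waveform into two components
#'
#' Implements the split-search: every sample between two adjacent peaks of
#' the fitted waveform (inside the range) is a candidate split point. For
#' each candidate the waveform coefficients are frozen, the component is cut
#' into a before/from pair of masked waveforms, per-trial amplitude and
#' derivative coefficients are re-estimated jointly for all components, and
#' the RSS is recorded. The minimum-RSS split wins; by default the full
#' alternating fit is then re-run with the winning masks.
#'
#' @param data \linkS4class{ErpEpochs} (or \linkS4class{SwaleSim}).
#' @param fit A converged \linkS4class{SwaleFit} to split.
#' @param range \linkS4class{PeakRange} containing the peaks of interest.
#' @param component Index of the waveform component to split (default 1).
#' @param refit If TRUE (default), re-run the alternating fit with the
#'   winning masks; if FALSE, return the frozen-coefficient split fit.
#' @return A list with elements \code{splitSample} (winning split index),
#'   \code{candidates} (data.frame of sample, time_ms, rss, aic for every
#'   candidate), and \code{fit} (the resulting multi-component
#'   \linkS4class{SwaleFit}).
#' @export
bestSplit <- function(data, fit, range, component = 1L, refit = TRUE) {
  if (is(data, "SwaleSim")) data <- simEpochs(data)
  Y <- epochData(data)
  cand <- findSplitCandidates(fit@waveforms[[component]], fit@basis, range)
  if (length(cand) == 0L)
    stop("no split candidates: fewer than two peaks inside the range")
  ampFloor <- fit@control$ampFloor %||% 0.05
  scores <- lapply(cand, function(s)
    .scoreSplit(Y, fit, component, s, ampFloor))
  ok <- !vapply(scores, is.null, TRUE)
  if (!any(ok))
    stop("all candidate split regressions were rank-deficient")
  cand <- cand[ok]; scores <- scores[ok]
  rssV <- vapply(scores, `[[`, 0, "rss")
  W2 <- length(fit@waveforms) + 1L
  k2 <- as.integer(nBasis(fit) + 2L * W2 * nTrials(fit))
  aicV <- vapply(rssV, function(r)
    if (r > 0) swaleAIC(r, k2, fit@n) else -Inf, 0)
  best <- which.min(rssV)
  winMasks <- scores[[best]]$masks
  control <- do.call(swaleControl, fit@control)
  outFit <- if (refit) {
    ErpEp <- if (is(data, "ErpEpochs")) data else
      ErpEpochs(Y, sfreq = fit@sfreq, timeAxis = timeAxis(fit))
    swaleFit(ErpEp, control = control, masks = winMasks)
  } else {
    .frozenSplitFit(Y, fit, winMasks, control)
  }
  list(splitSample = cand[best],
       candidates = data.frame(sample = cand,
                               time_ms = timeAxis(fit)[cand],
                               rss = rssV, aic = aicV),
       fit = outFit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Frozen-coefficient variant: keep the one-component coefficients, only
## re-estimate per-trial parameters under the split masks.
.frozenSplitFit <- function(Y, fit, masks, control) {
  q <- nBasis(fit)
  # coefficients for new masks: reuse the source component's coefficients
  coefPool <- lapply(fit@waveforms, slot, "coeffs")
  wfs <- lapply(masks, function(m) {
    src <- which.max(vapply(fit@waveforms, function(w)
      sum(w@support & m), 0L))
    Waveform(coefPool[[src]], support = m)
  })
  upd <- .trialParamsAll(Y, wfs, fit@basis, control$ampFloor)
  rss <- residualSS(Y, predictTrials(wfs, fit@basis, upd$params))
  W <- length(masks); N <- nrow(Y)
  k <- as.integer(q + 2L * W * N)
  new("SwaleFit", waveforms = wfs, params = upd$params, basis = fit@basis,
      sfreq = fit@sfreq, rssTrace = rss, nIter = 0L, converged = TRUE,
      aic = if (rss > 0) swaleAIC(rss, k, fit@n) else -Inf,
      k = k, n = fit@n, control = unclass(control),
      collinearFallback = upd$collinear)
}

#' AIC-guided selection of the number of waveform components
#'
#' Fits the one-waveform model, then greedily applies the split-search: at
#' each stage every current component with at least two peaks inside the
#' range is tried, the best resulting split (lowest refitted AIC) is
#' accepted if it strictly lowers the AIC, and the search stops otherwise
#' or when \code{maxWaveforms} is reached.
#'
#' @param data \linkS4class{ErpEpochs} (or \linkS4class{SwaleSim}).
#' @param range \linkS4class{PeakRange} for the split-search.
#' @param control A \code{\link{swaleControl}} list.
#' @param maxWaveforms Upper bound on the number of components.
#' @return The minimum-AIC \linkS4class{SwaleFit}.
#' @export
selectModel <- function(data, range, control = swaleControl(),
                        maxWaveforms = 2L) {
  if (is(data, "SwaleSim")) data <- simEpochs(data)
  stopifnot(maxWaveforms >= 1L)
  best <- swaleFit(data, control = control)
  if (maxWaveforms == 1L) return(best)
  repeat {
    W <- length(best@waveforms)
    if (W >= maxWaveforms) break
    trials <- list()
    for (comp in seq_len(W)) {
      res <- tryCatch(bestSplit(data, best, range, component = comp),
                      error = function(e) NULL)
      if (!is.null(res)) trials[[length(trials) + 1L]] <- res
    }
    if (length(trials) == 0L) break
    aics <- vapply(trials, function(r) modelAIC(r$fit), 0)
    cand <- trials[[which.min(aics)]]
    if (modelAIC(cand$fit) < modelAIC(best)) best <- cand$fit else break
  }
  best
}

#' AIC-guided selection of the number of basis functions
#'
#' Fits the one-waveform model for each candidate basis size and returns
#' the size minimising the AIC with k = q + 2 N.
#'
#' @param data \linkS4class{ErpEpochs} (or \linkS4class{SwaleSim}).
#' @param candidateQs Integer vector of basis sizes to try (each <= T).
#' @param control A \code{\link{swaleControl}} list; its nBasis entry is
#'   overridden per candidate.
#' @return A list with \code{nBasis} (the winner), and \code{table}
#'   (data.frame of q, rss, aic).
#' @export
selectNBasis <- function(data, candidateQs, control = swaleControl()) {
  if (is(data, "SwaleSim")) data <- simEpochs(data)
  stopifnot(length(candidateQs) >= 1L)
  rows <- lapply(as.integer(candidateQs), function(q) {
    ctl <- control; ctl$nBasis <- q
    f <- swaleFit(data, control = do.call(swaleControl, unclass(ctl)))
    data.frame(q = q, rss = utils::tail(rssTrace(f), 1), aic = modelAIC(f))
  })
  tab <- do.call(rbind, rows)
  list(nBasis = tab$q[which.min(tab$aic)], table = tab)
}
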