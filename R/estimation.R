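#' Control parameters for the alternating least-squares fit
#'
#' @param nBasis Number of orthogonal polynomial basis functions (default
#'   20).
#' @param maxIter Maximum number of full alternating iterations.
#' @param relTol Convergence threshold on the relative RSS decrease per
#'   full iteration.
#' @param ampFloor Relative amplitude floor below which a trial's latency
#'   shift is reported as NA (fraction of the median absolute amplitude).
#' @param normalizeEachIter If TRUE (default), rescale after every waveform
#'   update so that each component's mean amplitude is 1, fixing the scale
#'   indeterminacy (b -> c b, a -> a/c, rho -> rho/c leaves predictions
#'   unchanged).
#' @param accelerate If TRUE (default), take an exact line-search step
#'   along the waveform-shift direction after each waveform update. With a
#'   polynomial basis the derivative span lies inside the basis span, so
#'   shifting the waveform while subtracting the shift from every trial's
#'   latency changes predictions only to second order; plain alternation
#'   crawls along this nearly flat ridge, while the quartic 1-D
#'   minimization jumps along it. The step is only accepted when it lowers
#'   the RSS, so monotone convergence is preserved.
#' @return A named list of class \code{swaleControl}.
#' @export
swaleControl <- function(nBasis = 20L, maxIter = 200L, relTol = 1e-8,
                         ampFloor = 0.05, normalizeEachIter = TRUE,
                         accelerate = TRUE) {
  stopifnot(nBasis >= 1L, maxIter >= 1L, relTol > 0, ampFloor >= 0)
  structure(list(nBasis = as.integer(nBasis), maxIter = as.integer(maxIter),
                 relTol = relTol, ampFloor = ampFloor,
                 normalizeEachIter = isTRUE(normalizeEachIter),
                 accelerate = isTRUE(accelerate)),
            class = "swaleControl")
}

## Design matrix shared by all trials: columns (B b_w), (D b_w) per
## component. The per-trial regression is the same two(-per-component)
## column least-squares problem for every trial, so one QR serves all N.
.trialDesign <- function(waveforms, basis) {
  cols <- lapply(waveforms, function(w)
    cbind(evalWaveform(w, basis), evalWaveform(w, basis, deriv = TRUE)))
  do.call(cbind, cols)
}

## Batch per-trial parameter update. Returns W TrialParams plus a
## collinearity flag; on a rank-deficient design the derivative regressors
## are dropped (rho = 0) for all trials, as the amplitude-only fallback.
.trialParamsAll <- function(Y, waveforms, basis, ampFloor) {
  W <- length(waveforms)
  X <- .trialDesign(waveforms, basis)
  qrX <- qr(X, tol = 1e-10)
  collinear <- qrX$rank < ncol(X)
  if (collinear) {
    Xa <- X[, seq(1, 2 * W, by = 2), drop = FALSE]
    qra <- qr(Xa, tol = 1e-10)
    if (qra$rank < ncol(Xa))
      stop("degenerate per-trial regression: amplitude regressors are ",
           "collinear")
    amp <- matrix(qr.coef(qra, t(Y)), nrow = W)
    coefs <- matrix(0, 2 * W, ncol(amp))
    coefs[seq(1, 2 * W, by = 2), ] <- amp
  } else {
    coefs <- matrix(qr.coef(qrX, t(Y)), nrow = 2 * W)
  }
  params <- lapply(seq_len(W), function(w)
    TrialParams(coefs[2 * w - 1, ], coefs[2 * w, ], ampFloor = ampFloor))
  list(params = params, collinear = collinear)
}

#' Per-trial amplitude and latency-coefficient regression
#'
#' Ordinary least-squares fit of one trial onto the evaluated waveform and
#' its derivative: trial ~ a (B b) + rho (D b), jointly over all waveform
#' components. If the regressors are numerically collinear (e.g. a flat
#' waveform makes the derivative term unidentifiable) the fit falls back to
#' amplitude-only regression with rho = 0 and raises a warning.
#'
#' @param trial Numeric T-vector (one epoch).
#' @param waveform A \linkS4class{Waveform} or list of them.
#' @param basis The matching \linkS4class{BasisSet}.
#' @param ampFloor Relative amplitude floor passed through to the result.
#' @return A list with elements \code{amplitude} and \code{rho} (numeric,
#'   one entry per waveform component) and \code{collinear} (logical).
#' @export
fitTrialParams <- function(trial, waveform, basis, ampFloor = 0.05) {
  if (is(waveform, "Waveform")) waveform <- list(waveform)
  if (length(trial) != nSamples(basis))
    stop("trial length does not match the basis sample count")
  res <- .trialParamsAll(matrix(trial, nrow = 1), waveform, basis, ampFloor)
  if (res$collinear)
    warning("collinear regressors: derivative term dropped (rho = 0)")
  list(amplitude = vapply(res$params, function(p) p@amplitude[1], 0),
       rho = vapply(res$params, function(p) p@rho[1], 0),
       collinear = res$collinear)
}

## Waveform update given fixed per-trial parameters: global least squares
## of the stacked system. The normal matrix is assembled from q x q
## cross-product blocks of the masked basis matrices instead of
## materialising the (N T) x (W q) stacked design. High-degree global
## polynomials restricted to a sub-window are nearly dependent, so each
## component block is first re-orthonormalised on its own support by a
## rank-revealing (pivoted) QR; the normal equations are solved in those
## well-conditioned coordinates and mapped back.
.fitWaveformCore <- function(Y, basis, params, masks) {
  W <- length(masks)
  q <- nBasis(basis)
  B <- basisMatrix(basis); D <- derivMatrix(basis)
  N <- nrow(Y)
  A <- matrix(vapply(params, function(p) p@amplitude, numeric(N)), ncol = W)
  R <- matrix(vapply(params, function(p) p@rho, numeric(N)), ncol = W)
  Qb <- vector("list", W); Dt <- vector("list", W)
  R1 <- vector("list", W); piv <- vector("list", W)
  for (w in seq_len(W)) {
    Bm <- B * masks[[w]]
    qrw <- qr(Bm, LAPACK = TRUE)
    dR <- abs(diag(qr.R(qrw)))
    k <- sum(dR > 1e-10 * max(dR))
    if (k == 0L)
      stop("support mask ", w, " carries no representable signal")
    piv[[w]] <- qrw$pivot[seq_len(k)]
    R1[[w]] <- qr.R(qrw)[seq_len(k), seq_len(k), drop = FALSE]
    Qb[[w]] <- qr.Q(qrw)[, seq_len(k), drop = FALSE]
    Dm1 <- (D * masks[[w]])[, piv[[w]], drop = FALSE]
    Dt[[w]] <- t(backsolve(R1[[w]], t(Dm1), transpose = TRUE))
  }
  ks <- vapply(Qb, ncol, 0L)
  off <- cumsum(c(0L, ks))
  XtX <- matrix(0, sum(ks), sum(ks))
  Xty <- numeric(sum(ks))
  Yt <- t(Y)
  for (w in seq_len(W)) {
    iw <- off[w] + seq_len(ks[w])
    for (v in seq_len(W)) {
      iv <- off[v] + seq_len(ks[v])
      XtX[iw, iv] <-
        sum(A[, w] * A[, v]) * crossprod(Qb[[w]], Qb[[v]]) +
        sum(A[, w] * R[, v]) * crossprod(Qb[[w]], Dt[[v]]) +
        sum(R[, w] * A[, v]) * crossprod(Dt[[w]], Qb[[v]]) +
        sum(R[, w] * R[, v]) * crossprod(Dt[[w]], Dt[[v]])
    }
    Xty[iw] <- crossprod(Qb[[w]], Yt %*% A[, w]) +
      crossprod(Dt[[w]], Yt %*% R[, w])
  }
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch))
    stop("singular stacked normal matrix in the waveform update ",
         "(all amplitudes zero, or a support mask carries no signal); ",
         "reciprocal condition ~ ", format(rcond(XtX), digits = 3))
  cc <- backsolve(ch, backsolve(ch, Xty, transpose = TRUE))
  lapply(seq_len(W), function(w) {
    b <- numeric(q)
    b[piv[[w]]] <- backsolve(R1[[w]], cc[off[w] + seq_len(ks[w])])
    Waveform(b, support = masks[[w]])
  })
}

#' Waveform update given fixed per-trial parameters
#'
#' Solves the global least-squares problem for the basis coefficients with
#' all per-trial amplitudes and derivative coefficients held fixed: each
#' trial contributes the design a_i B + rho_i D (masked per component) and
#' the stacked system over all trials is solved exactly.
#'
#' @param data An \linkS4class{ErpEpochs} or N x T matrix.
#' @param basis The \linkS4class{BasisSet}.
#' @param params List of \linkS4class{TrialParams}, one per component.
#' @param masks List of logical support masks (default: one all-TRUE mask).
#' @return List of \linkS4class{Waveform} objects.
#' @export
fitWaveform <- function(data, basis, params, masks = NULL) {
  if (is(data, "ErpEpochs")) data <- epochData(data)
  if (is(params, "TrialParams")) params <- list(params)
  if (is.null(masks))
    masks <- rep(list(rep(TRUE, nSamples(basis))), length(params))
  if (length(masks) != length(params))
    stop("need one support mask per TrialParams")
  .fitWaveformCore(as.matrix(data), basis, params, masks)
}

## Exact line search along the waveform-shift ridge of one component:
## replacing b by b + delta s (with B s = D b, which holds exactly because
## derivative polynomials stay inside the basis span) and rho_i by
## rho_i - delta a_i changes trial i's prediction by
## delta rho_i u - delta^2 a_i u with u = (masked) D s, so the RSS is an
## explicit quartic in delta. Returns the updated (waveforms, params);
## only RSS-decreasing steps are taken.
.ridgeStep <- function(Y, basis, waveforms, params) {
  B <- basisMatrix(basis); D <- derivMatrix(basis)
  resid <- Y - predictTrials(waveforms, basis, params)
  for (w in seq_along(waveforms)) {
    b <- waveforms[[w]]@coeffs
    m <- waveforms[[w]]@support
    s <- drop(crossprod(B, D %*% b))
    u <- drop((D * m) %*% s)
    uu <- sum(u^2)
    if (uu < .Machine$double.eps) next
    a <- params[[w]]@amplitude; r <- params[[w]]@rho
    ru <- drop(resid %*% u)               # <resid_i, u>
    # RSS(delta) - RSS(0) = -2 d Sum(r_i ru_i) + 2 d^2 Sum(a_i ru_i)
    #   + d^2 Sum(r_i^2) uu - 2 d^3 Sum(a_i r_i) uu + d^4 Sum(a_i^2) uu
    c1 <- -2 * sum(r * ru)
    c2 <- 2 * sum(a * ru) + sum(r^2) * uu
    c3 <- -2 * sum(a * r) * uu
    c4 <- sum(a^2) * uu
    f <- function(d) c1 * d + c2 * d^2 + c3 * d^3 + c4 * d^4
    opt <- stats::optimize(f, interval = c(-200, 200), tol = 1e-12)
    if (opt$objective < 0) {
      d <- opt$minimum
      waveforms[[w]]@coeffs <- b + d * s
      params[[w]]@rho <- r - d * a
      resid <- Y - predictTrials(waveforms, basis, params)
    }
  }
  list(waveforms = waveforms, params = params)
}

## Apply the scale gauge: component-wise, rescale so mean amplitude is 1.
.gaugeFix <- function(waveforms, params) {
  for (w in seq_along(waveforms)) {
    cc <- mean(params[[w]]@amplitude)
    if (is.finite(cc) && abs(cc) > 1e-12) {
      waveforms[[w]]@coeffs <- waveforms[[w]]@coeffs * cc
      params[[w]]@amplitude <- params[[w]]@amplitude / cc
      params[[w]]@rho <- params[[w]]@rho / cc
    }
  }
  list(waveforms = waveforms, params = params)
}

#' Fit the single-trial waveform/amplitude/latency model
#'
#' Alternating least squares: the grand average of the data, projected onto
#' the basis (per support mask when fitting multiple components), is the
#' starting waveform; the algorithm then alternates exact per-trial
#' amplitude/latency regressions and the global waveform update until the
#' relative decrease in residual sum-of-squares falls below
#' \code{control$relTol} or \code{control$maxIter} is reached. Both
#' half-steps are exact least-squares solves, so the RSS trace is
#' non-increasing. After every waveform update the scale indeterminacy is
#' fixed by rescaling each component to mean amplitude 1.
#'
#' @param data An \linkS4class{ErpEpochs} (or \linkS4class{SwaleSim}, whose
#'   noisy epochs are used).
#' @param control A \code{\link{swaleControl}} list.
#' @param masks Optional list of disjoint logical support masks, one per
#'   waveform component; default is a single full-epoch component.
#' @return A \linkS4class{SwaleFit}.
#' @examples
#' sim <- simulateErp(simConfig(nTrials = 20, nSamples = 128, sfreq = 250,
#'                              snr = 2, seed = 1))
#' fit <- swaleFit(sim, swaleControl(nBasis = 10))
#' isConverged(fit)
#' @export
swaleFit <- function(data, control = swaleControl(), masks = NULL) {
  if (is(data, "SwaleSim")) data <- simEpochs(data)
  if (!is(data, "ErpEpochs"))
    stop("data must be an ErpEpochs (or SwaleSim) object")
  Y <- epochData(data)
  N <- nrow(Y); Tn <- ncol(Y)
  q <- control$nBasis
  if (q > Tn)
    stop("nBasis (", q, ") exceeds the number of samples (", Tn, ")")
  basis <- makePolynomialBasis(Tn, q, timeAxis(data))
  if (is.null(masks)) masks <- list(rep(TRUE, Tn))
  W <- length(masks)
  if (W > 1L) {
    overlap <- Reduce(`+`, lapply(masks, as.integer))
    if (any(overlap > 1L))
      stop("support masks must be disjoint")
  }

  # starting waveform: masked projection of the grand average
  ybar <- colMeans(Y)
  B <- basisMatrix(basis)
  wfs <- lapply(masks, function(m) {
    Bm <- B * m
    b0 <- qr.coef(qr(Bm, tol = 1e-10), ybar)
    b0[is.na(b0)] <- 0
    Waveform(b0, support = m)
  })

  rssTraceV <- numeric(0)
  params <- NULL
  collinearAny <- FALSE
  converged <- FALSE
  rssPrevIter <- Inf
  # differences below this are numerically meaningless at the data scale
  rssEps <- 1e-12 * sum(Y^2)
  iter <- 0L
  while (iter < control$maxIter) {
    iter <- iter + 1L
    upd <- .trialParamsAll(Y, wfs, basis, control$ampFloor)
    params <- upd$params
    collinearAny <- collinearAny || upd$collinear
    rss1 <- residualSS(Y, predictTrials(wfs, basis, params))
    prev <- if (length(rssTraceV)) rssTraceV[length(rssTraceV)] else Inf
    if (rss1 > prev && rss1 - prev < rssEps) rss1 <- prev  # roundoff
    wfsNew <- .fitWaveformCore(Y, basis, params, masks)
    rss2 <- residualSS(Y, predictTrials(wfsNew, basis, params))
    if (!is.finite(rss1) || !is.finite(rss2))
      stop("non-finite RSS at iteration ", iter,
           " (rss after parameter step: ", rss1, ")")
    if (rss2 > rss1) {   # roundoff guard for near-singular masked updates
      wfsNew <- wfs
      rss2 <- rss1
    }
    wfs <- wfsNew
    if (control$accelerate) {
      st <- .ridgeStep(Y, basis, wfs, params)
      wfs <- st$waveforms; params <- st$params
      rss2 <- min(rss2, residualSS(Y, predictTrials(wfs, basis, params)))
    }
    if (control$normalizeEachIter) {
      g <- .gaugeFix(wfs, params)   # predictions (and RSS) unchanged
      wfs <- g$waveforms; params <- g$params
    }
    rssTraceV <- c(rssTraceV, rss1, rss2)
    if (is.finite(rssPrevIter) &&
        (rssPrevIter - rss2) <= control$relTol * rssPrevIter) {
      converged <- TRUE
      break
    }
    rssPrevIter <- rss2
  }
  # final parameter refresh so reported (a, rho) match the final waveform,
  # followed by a last gauge fix so mean amplitude is exactly 1
  upd <- .trialParamsAll(Y, wfs, basis, control$ampFloor)
  params <- upd$params
  collinearAny <- collinearAny || upd$collinear
  if (control$normalizeEachIter) {
    g <- .gaugeFix(wfs, params)
    wfs <- g$waveforms; params <- g$params
  }
  rssFinal <- residualSS(Y, predictTrials(wfs, basis, params))
  prev <- if (length(rssTraceV)) rssTraceV[length(rssTraceV)] else Inf
  if (rssFinal > prev && rssFinal - prev < rssEps) rssFinal <- prev
  rssTraceV <- c(rssTraceV, rssFinal)

  k <- as.integer(q + 2L * W * N)
  n <- as.integer(N * Tn)
  aicVal <- if (rssFinal > 0) swaleAIC(rssFinal, k, n) else -Inf
  new("SwaleFit", waveforms = wfs, params = params, basis = basis,
      sfreq = samplingRate(data), rssTrace = rssTraceV,
      nIter = iter, converged = converged, aic = aicVal,
      k = k, n = n, control = unclass(control),
      collinearFallback = collinearAny)
}
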