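#' Construct an orthonormal polynomial basis and its analytic derivative
#'
#' Builds a discretely orthonormal polynomial basis on the sample grid by a
#' Stieltjes three-term recurrence in a rescaled time variable mapped to
#' [-1, 1], together with the exact first-derivative matrix obtained by
#' differentiating the recurrence (never by finite differences). Column j of
#' the basis is a polynomial of exact degree j; columns are orthonormal
#' under the ordinary discrete inner product over the grid, so least-squares
#' projections onto the basis reduce to crossproducts.
#'
#' The rescaling keeps the recurrence well conditioned at 20+ basis
#' functions; the derivative matrix carries the 2/(t_max - t_min) chain-rule
#' factor so that it is expressed per millisecond of the original time axis.
#'
#' @param nSamples Number of time samples T.
#' @param nBasis Number of basis functions q, 1 <= q <= T. The package-wide
#'   default for model fitting is 20.
#' @param timeAxis Optional strictly increasing vector of sample times in
#'   ms (default: 0, 1, ..., T-1).
#' @return A \linkS4class{BasisSet}.
#' @examples
#' bs <- makePolynomialBasis(128, 10)
#' max(abs(crossprod(basisMatrix(bs)) - diag(10)))  # ~1e-15
#' @export
makePolynomialBasis <- function(nSamples, nBasis, timeAxis = NULL) {
  nSamples <- as.integer(nSamples)
  nBasis <- as.integer(nBasis)
  if (nSamples < 1L || nBasis < 1L)
    stop("nSamples and nBasis must be positive")
  if (nBasis > nSamples)
    stop("nBasis must not exceed nSamples")
  if (is.null(timeAxis)) timeAxis <- as.numeric(seq_len(nSamples) - 1L)
  timeAxis <- as.numeric(timeAxis)
  if (length(timeAxis) != nSamples)
    stop("timeAxis must have length nSamples")
  if (anyDuplicated(timeAxis) || any(diff(timeAxis) <= 0))
    stop("timeAxis must be strictly increasing (no duplicate times)")

  tRange <- range(timeAxis)
  scale <- 2 / (tRange[2] - tRange[1])       # dx/dt, x in [-1, 1]
  x <- (timeAxis - tRange[1]) * scale - 1

  B <- matrix(0, nSamples, nBasis)
  Dx <- matrix(0, nSamples, nBasis)          # derivatives w.r.t. x
  # monic recurrence pi_{k+1} = (x - a_k) pi_k - b_k pi_{k-1};
  # normalized columns stored, so carry the norms explicitly
  p_prev <- numeric(nSamples)                # pi_{k-1}
  dp_prev <- numeric(nSamples)
  p_cur <- rep(1, nSamples)                  # pi_0
  dp_cur <- numeric(nSamples)
  nrm_prev <- 1
  nrm_cur <- sqrt(sum(p_cur^2))
  B[, 1] <- p_cur / nrm_cur
  for (k in seq_len(nBasis - 1L)) {
    a_k <- sum(x * p_cur^2) / sum(p_cur^2)
    b_k <- if (k == 1L) 0 else sum(p_cur^2) / sum(p_prev^2)
    p_next <- (x - a_k) * p_cur - b_k * p_prev
    dp_next <- p_cur + (x - a_k) * dp_cur - b_k * dp_prev
    p_prev <- p_cur; dp_prev <- dp_cur
    p_cur <- p_next; dp_cur <- dp_next
    nrm_cur <- sqrt(sum(p_cur^2))
    if (nrm_cur == 0)
      stop("degenerate grid: polynomial basis collapsed at degree ", k)
    B[, k + 1L] <- p_cur / nrm_cur
    Dx[, k + 1L] <- dp_cur / nrm_cur
  }
  new("BasisSet", nSamples = nSamples, nBasis = nBasis,
      timeAxis = timeAxis, B = B, D = Dx * scale)
}

#' Export basis matrices as delimited text
#'
#' Writes the basis values and derivatives side by side with the time axis,
#' mainly for external inspection or plotting.
#'
#' @param basis A \linkS4class{BasisSet}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the path.
#' @export
writeBasis <- function(basis, path, sep = "\t") {
  q <- nBasis(basis)
  out <- cbind(time_ms = timeAxis(basis), basisMatrix(basis),
               derivMatrix(basis))
  colnames(out) <- c("time_ms", paste0("B", seq_len(q) - 1L),
                     paste0("D", seq_len(q) - 1L))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
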