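#' Generate a synthetic structural connectome (EDR plus long-range boosts)
#'
#' Base weights follow the exponential distance rule
#' \eqn{w_{jk} = \exp(-\gamma d_{jk})}; a chosen number of long-distance
#' pairs (d > 40 mm) is then boosted to weights drawn Uniform(0.5, 1),
#' emulating the long-range exceptions that diffusion MRI adds on top of
#' the EDR. Symmetric, hollow, max weight 1.
#'
#' @param geom a [ParcelGeometry-class].
#' @param edrDecay EDR decay rate in 1/mm (default 0.18).
#' @param nLongrange number of boosted long-range pairs (default 0).
#' @param seed integer seed for pair selection and boost weights.
#' @return N x N numeric weight matrix.
#' @export
generateConnectome <- function(geom, edrDecay = 0.18, nLongrange = 0L, seed = 1L) {
  stopifnot(is(geom, "ParcelGeometry"), edrDecay > 0, nLongrange >= 0)
  d <- distances(geom)
  w <- exp(-edrDecay * d)
  diag(w) <- 0
  if (nLongrange > 0L) {
    ut <- which(upper.tri(d) & d > 40, arr.ind = TRUE)
    if (nrow(ut) < nLongrange)
      stop("generateConnectome: only ", nrow(ut), " pairs exceed 40 mm")
    .with_seed(seed, {
      pick <- ut[sample.int(nrow(ut), nLongrange), , drop = FALSE]
      boost <- stats::runif(nLongrange, 0.5, 1)
      for (i in seq_len(nLongrange)) {
        w[pick[i, 1L], pick[i, 2L]] <- boost[i]
        w[pick[i, 2L], pick[i, 1L]] <- boost[i]
      }
    })
  }
  w
}

#' Build the model coupling matrix from geometry and an optional connectome
#'
#' The coupling is the EDR kernel \eqn{\exp(-\gamma d_{jk})} with, where a
#' connectome is supplied, long-range exceptions merged on top by an
#' elementwise maximum after normalizing the connectome to a unit maximum.
#'
#' @param geom a [ParcelGeometry-class].
#' @param connectome optional N x N symmetric nonnegative matrix.
#' @param edrDecay EDR decay rate in 1/mm (default 0.18).
#' @return a [CouplingMatrix-class].
#' @export
buildCoupling <- function(geom, connectome = NULL, edrDecay = 0.18) {
  stopifnot(is(geom, "ParcelGeometry"), edrDecay > 0)
  C <- exp(-edrDecay * distances(geom))
  diag(C) <- 0
  src <- "none"
  if (!is.null(connectome)) {
    connectome <- as.matrix(connectome)
    if (nrow(connectome) != nRegions(geom) || ncol(connectome) != nRegions(geom))
      stop("buildCoupling: connectome dimension does not match geometry")
    if (max(abs(connectome - t(connectome))) > 1e-9)
      stop("buildCoupling: connectome must be symmetric")
    if (any(connectome < 0)) stop("buildCoupling: connectome must be nonnegative")
    mx <- max(connectome)
    if (mx > 1) connectome <- connectome / mx
    diag(connectome) <- 0
    C <- pmax(C, connectome)
    src <- "file"
  }
  new("CouplingMatrix", weights = C, edrDecay = edrDecay, longrangeSource = src)
}
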