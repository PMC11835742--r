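# Seed handling: every stochastic entry point takes an integer seed and
# restores the caller's RNG state on exit, so package calls never disturb
# user-level reproducibility.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive stage/subject seeds from one master seed by a fixed affine counter
# scheme, kept inside 32-bit integer range.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}

.rsn_names <- c("CON", "DMN", "TP", "VIS", "SOM", "ATT", "SAL", "LIM")

#' Construct a ParcelGeometry from centroid coordinates
#'
#' @param coords N x 3 numeric matrix of centroid positions in mm.
#' @param rsnLabels optional character vector of network labels (length N);
#'   defaults to "NA" for every region.
#' @return a [ParcelGeometry-class]; the distance matrix is computed from
#'   the coordinates.
#' @export
ParcelGeometry <- function(coords, rsnLabels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(rsnLabels)) rsnLabels <- rep("NA", nrow(coords))
  new("ParcelGeometry", coords = coords,
    dist = as.matrix(stats::dist(coords)), rsnLabels = as.character(rsnLabels))
}

#' Generate a brain-like synthetic parcellation geometry
#'
#' Samples region centroids uniformly inside an ellipsoid of brain-like
#' extent (semi-axes 70 x 85 x 60 mm) with a minimum inter-centroid spacing
#' of 3 mm (dart throwing), then assigns resting-state-network labels by
#' spatial k-means so that labels form contiguous clusters.
#'
#' @param nRegions number of parcels (>= 10).
#' @param seed integer seed; the construction is deterministic per seed.
#' @param nNetworks number of RSN clusters, 7 or 8 (default 8, the
#'   canonical CON/DMN/TP/VIS/SOM/ATT/SAL/LIM set).
#' @param minSpacing minimum centroid separation in mm (default 3).
#' @return a [ParcelGeometry-class].
#' @examples
#' geom <- generateGeometry(60, seed = 1)
#' range(distances(geom)[upper.tri(distances(geom))])
#' @export
generateGeometry <- function(nRegions, seed, nNetworks = 8L, minSpacing = 3) {
  stopifnot(nRegions >= 10, nNetworks %in% c(7L, 8L))
  semi <- c(70, 85, 60)
  .with_seed(seed, {
    pts <- matrix(NA_real_, nRegions, 3L)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 20000L * nRegions
    while (placed < nRegions) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("generateGeometry: could not place ", nRegions,
             " centroids with ", minSpacing, " mm spacing")
      cand <- stats::runif(3L, -1, 1) * semi
      if (sum((cand / semi)^2) > 1) next
      if (placed > 0L) {
        d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < minSpacing^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
    km <- stats::kmeans(pts, centers = min(nNetworks, nRegions),
      nstart = 5L, iter.max = 50L)
    labels <- .rsn_names[seq_len(min(nNetworks, nRegions))][km$cluster]
    ParcelGeometry(pts, labels)
  })
}
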