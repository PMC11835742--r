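#' Permutation test on the Wilcoxon rank-sum statistic
#'
#' The observed statistic is the rank sum of \code{x} in the pooled
#' ranking; the null is built by shuffling group labels \code{nPerm}
#' times. The two-sided p-value uses the add-one convention
#' \eqn{p = (1 + \#\{|T^{perm} - E| \ge |T^{obs} - E|\}) / (1 + nPerm)}
#' with E the null expectation of the rank sum, so the smallest attainable
#' p is 1/(nPerm + 1).
#'
#' @param x,y numeric vectors, each with >= 3 observations.
#' @param nPerm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
permRanksum <- function(x, y, nPerm = 1000L, seed = 1L) {
  stopifnot(length(x) >= 3L, length(y) >= 3L, nPerm >= 1L)
  pooled <- c(x, y)
  if (stats::sd(pooled) == 0)
    stop("permRanksum: pooled data are constant")
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  e0 <- nx * (n + 1) / 2
  t_obs <- abs(sum(r[seq_len(nx)]) - e0)
  .with_seed(seed, {
    t_perm <- vapply(seq_len(nPerm), function(i)
      abs(sum(r[sample.int(n, nx)]) - e0), 0)
    (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + nPerm)
  })
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (\bar x - \bar y) / s_p} with the pooled SD using the
#' \eqn{n_x + n_y - 2} denominator.
#'
#' @param x,y numeric vectors.
#' @return signed effect size.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("cohensD: zero pooled variance")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment with rejection mask
#'
#' Step-up adjusted p-values (min over j >= i of m p_(j)/j, clipped at 1)
#' and the rejection set at level \code{q}.
#'
#' @param p vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (same order as \code{p}) and
#'   \code{reject} (logical mask).
#' @export
fdrBH <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("fdrBH: p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Pearson correlation between a baseline measure and clinical outcome
#'
#' @param measure numeric vector over patients (e.g. baseline turbulence).
#' @param pctChange outcome vector (e.g. HAMD6 percent change), same order.
#' @return list with \code{rho} and two-sided \code{p} from the t
#'   distribution.
#' @export
outcomeCorrelation <- function(measure, pctChange) {
  stopifnot(length(measure) == length(pctChange), length(measure) >= 5L)
  if (stats::sd(measure) == 0 || stats::sd(pctChange) == 0)
    stop("outcomeCorrelation: constant input")
  ct <- stats::cor.test(measure, pctChange, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Scalar group comparison: effect size plus permutation p-value
#'
#' Convenience wrapper pairing [cohensD()] with [permRanksum()] for one
#' measure and one group pair.
#'
#' @param x,y numeric vectors (group a, group b).
#' @param nPerm,seed passed to [permRanksum()].
#' @return list with \code{cohensD} and \code{pPerm}.
#' @export
groupComparison <- function(x, y, nPerm = 1000L, seed = 1L) {
  list(cohensD = cohensD(x, y), pPerm = permRanksum(x, y, nPerm, seed))
}

#' Node-level group analysis with RSN attribution
#'
#' For each pair of groups, tests every node's metastability with the
#' permutation rank-sum test, applies BH-FDR across nodes, then selects,
#' among FDR-significant nodes, those whose raw p-value lies in the bottom
#' \code{quantile} of the p distribution, and tallies the resting-state
#' networks of the selected nodes. Setting \code{quantileOver = "all"}
#' takes the quantile over all N p-values instead of the significant ones.
#'
#' @param groups named list mapping group label to a subjects x N matrix
#'   of node metastability values.
#' @param geom a [ParcelGeometry-class] supplying RSN labels.
#' @param quantile bottom-quantile fraction for node selection
#'   (default 0.30).
#' @param nPerm permutations per node (default 1000).
#' @param alpha FDR significance level (default 0.05).
#' @param seed integer master seed; per-node seeds are derived.
#' @param quantileOver "significant" (default) or "all".
#' @return named list, one entry per group pair ("a_vs_b"), each a list
#'   with \code{nodeP}, \code{nodePFdr}, \code{significantMask},
#'   \code{selectedMask} and \code{rsnCounts}.
#' @export
nodeLevelAnalysis <- function(groups, geom, quantile = 0.30, nPerm = 1000L,
    alpha = 0.05, seed = 1L, quantileOver = c("significant", "all")) {
  quantileOver <- match.arg(quantileOver)
  stopifnot(length(groups) >= 2L, is(geom, "ParcelGeometry"),
    quantile > 0, quantile < 1)
  nn <- nRegions(geom)
  for (g in names(groups))
    if (ncol(groups[[g]]) != nn)
      stop("nodeLevelAnalysis: group ", g, " has ", ncol(groups[[g]]),
           " nodes, geometry has ", nn)
  labels <- names(groups)
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    a <- groups[[pr[1L]]]; b <- groups[[pr[2L]]]
    node_p <- vapply(seq_len(nn), function(j)
      permRanksum(a[, j], b[, j], nPerm = nPerm,
        seed = .derive_seed(seed, j)), 0)
    bh <- fdrBH(node_p, q = alpha)
    sig <- bh$reject
    pool <- if (quantileOver == "significant") node_p[sig] else node_p
    selected <- rep(FALSE, nn)
    if (length(pool) && any(sig)) {
      thr <- stats::quantile(pool, probs = quantile, type = 7, names = FALSE)
      selected <- sig & node_p <= thr
    }
    counts <- table(factor(rsnLabels(geom)[selected],
      levels = sort(unique(rsnLabels(geom)))))
    out[[paste(pr, collapse = "_vs_")]] <- list(
      nodeP = node_p, nodePFdr = bh$adjusted, significantMask = sig,
      selectedMask = selected, rsnCounts = counts)
  }
  out
}
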