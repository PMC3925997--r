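# B-spline mutual information and CLR background correction.
#
# The estimator assigns each sample soft membership weights over n_bins bins
# using a B-spline basis evaluated on rank-scaled data, accumulates a
# weighted joint histogram for each gene pair, and computes plugin entropies.
# Marginals are derived from the same weighted joint, which guarantees
# MI <= min(H(X), H(Y)) so the normalized score is bounded by 1 by
# construction. Rank scaling makes the estimator invariant to monotone
# transformations of the data and robust to outliers.

# Soft bin-membership weights: n x n_bins matrix, rows sum to 1.
# Knot vector is uniform on [0, n_bins - order + 1]; order 1 reduces to hard
# equal-width binning of the rank-scaled values.
bspline_weights <- function(x, n_bins, spline_order) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  W <- matrix(0, n, n_bins)
  if (max(r) == min(r)) {       # constant input: everything in one bin
    W[, 1] <- 1
    return(W)
  }
  top <- n_bins - spline_order + 1
  z <- (r - 1) / (n - 1) * top
  z <- pmin(z, top - 1e-9)      # keep the right boundary inside the support
  knots <- c(rep(0, spline_order), seq_len(n_bins - spline_order), rep(top, spline_order))
  W[] <- splines::splineDesign(knots, z, ord = spline_order, outer.ok = FALSE)
  W
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' B-spline mutual information between two sample vectors
#'
#' Normalized mutual information in \[0, 1\]: plugin entropies from a
#' B-spline-weighted joint histogram on rank-scaled values, with
#' MI = H(X) + H(Y) - H(X,Y) divided by min(H(X), H(Y)). With
#' `spline_order = 1` the estimator reduces exactly to hard-binned histogram
#' MI. Constant input has zero marginal entropy and scores 0 against
#' anything.
#'
#' @param x,y numeric vectors of equal length (>= 8 samples).
#' @param n_bins number of bins (>= 2).
#' @param spline_order B-spline order, between 1 and `n_bins`.
#' @return Normalized MI in \[0, 1\].
#' @export
bspline_mi <- function(x, y, n_bins = 10L, spline_order = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 samples")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (spline_order < 1 || spline_order > n_bins) {
    stop("spline_order must be in [1, n_bins]")
  }
  Wx <- bspline_weights(x, n_bins, spline_order)
  Wy <- bspline_weights(y, n_bins, spline_order)
  joint <- crossprod(Wx, Wy) / length(x)
  hx <- entropy_nat(rowSums(joint))
  hy <- entropy_nat(colSums(joint))
  denom <- min(hx, hy)
  if (denom < 1e-12) return(0)
  mi <- hx + hy - entropy_nat(joint)
  min(1, max(0, mi / denom))
}

#' Default bin count for the B-spline MI estimator
#'
#' Square-root scaling with the number of samples, clamped to \[4, 16\].
#' @param n_samples sample count.
#' @return Integer bin count.
#' @export
default_bins <- function(n_samples) {
  as.integer(min(16, max(4, round(sqrt(n_samples)))))
}

#' Score matrix (MI or CLR)
#'
#' @param scores symmetric numeric matrix with gene dimnames; diagonal is NA
#'   and excluded from all downstream use.
#' @param kind `"MI"` or `"CLR"`.
#' @param n_bins,spline_order estimator parameters (MI kind).
#' @return Object of class `score_matrix`.
#' @export
score_matrix <- function(scores, kind = c("MI", "CLR"), n_bins = NA_integer_,
                         spline_order = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            !is.null(rownames(scores)))
  off <- scores[upper.tri(scores)]
  if (kind == "MI" && any(off < -1e-9 | off > 1 + 1e-9, na.rm = TRUE)) {
    stop("MI scores must lie in [0, 1]")
  }
  if (kind == "CLR" && any(off < -1e-9, na.rm = TRUE)) {
    stop("CLR scores must be non-negative")
  }
  structure(list(gene_ids = rownames(scores), scores = scores, kind = kind,
                 n_bins = n_bins, spline_order = spline_order),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(x$kind, "score matrix:", length(x$gene_ids), "genes")
  if (!is.na(x$n_bins)) cat(" (", x$n_bins, " bins, order ", x$spline_order, ")", sep = "")
  cat("\n  off-diagonal range:",
      paste(signif(range(x$scores[upper.tri(x$scores)], na.rm = TRUE), 4),
            collapse = " .. "), "\n")
  invisible(x)
}

#' Mutual information matrix for all gene pairs
#'
#' Computes the full symmetric normalized-MI matrix with the B-spline
#' estimator. Bin count defaults to square-root-of-samples scaling clamped to
#' \[4, 16\]. Zero-variance genes score 0 against everything (rather than
#' being dropped), keeping the gene universe aligned across thresholds.
#'
#' @param expr an [expression_matrix()] (genes x samples, >= 2 genes, >= 8
#'   samples).
#' @param n_bins bin count; `NULL` for the default rule.
#' @param spline_order B-spline order (default 3).
#' @return A [score_matrix()] of kind `"MI"`.
#' @export
mi_matrix <- function(expr, n_bins = NULL, spline_order = 3L) {
  if (nrow(expr) < 2) stop("need at least 2 genes")
  n <- ncol(expr)
  if (n < 8) stop("need at least 8 samples; the estimator is unreliable below that")
  b <- as.integer(n_bins %||% default_bins(n))
  if (spline_order < 1 || spline_order > b) stop("spline_order must be in [1, n_bins]")
  G <- nrow(expr)
  genes <- rownames(expr)
  # stacked weight matrix: n x (G*b); gene g occupies columns (g-1)*b + 1:b
  Wall <- matrix(0, n, G * b)
  for (g in seq_len(G)) {
    Wall[, (g - 1L) * b + seq_len(b)] <- bspline_weights(expr[g, ], b, spline_order)
  }
  marg <- t(matrix(colSums(Wall) / n, b, G))       # per-gene marginal dist
  H <- apply(marg, 1, entropy_nat)
  grp <- rep(seq_len(G), each = b)
  M <- matrix(0, G, G)
  for (g in seq_len(G)) {
    P <- crossprod(Wall[, (g - 1L) * b + seq_len(b), drop = FALSE], Wall) / n
    PL <- P * log(P)
    PL[P <= 0] <- 0
    Hxy <- -rowsum(colSums(PL), grp)[, 1]
    denom <- pmin(H[g], H)
    mi <- H[g] + H - Hxy
    v <- ifelse(denom < 1e-12, 0, pmin(1, pmax(0, mi / denom)))
    M[g, ] <- v
  }
  M <- (M + t(M)) / 2     # symmetrize away float asymmetry
  diag(M) <- NA_real_
  dimnames(M) <- list(genes, genes)
  score_matrix(M, "MI", n_bins = b, spline_order = as.integer(spline_order))
}

#' CLR background correction
#'
#' Context likelihood of relatedness: each gene's off-diagonal MI scores form
#' its background distribution; the pair score is
#' sqrt(z_i(j)^2 + z_j(i)^2) with z_i(j) = max(0, (MI_ij - mu_i) / sigma_i).
#' A gene with zero background spread contributes z = 0.
#'
#' @param mi a [score_matrix()] of kind `"MI"` with >= 3 genes.
#' @return A [score_matrix()] of kind `"CLR"`.
#' @export
clr_transform <- function(mi) {
  stopifnot(inherits(mi, "score_matrix"))
  if (mi$kind != "MI") stop("clr_transform expects an MI score matrix")
  S <- mi$scores
  G <- nrow(S)
  if (G < 3) stop("CLR background undefined for fewer than 3 genes")
  mu <- rowMeans(S, na.rm = TRUE)
  sg <- apply(S, 1, stats::sd, na.rm = TRUE)
  Z <- (S - mu) / ifelse(sg > 0, sg, Inf)   # sigma 0 -> z 0
  Z[Z < 0] <- 0
  Z[is.na(Z)] <- 0
  C <- sqrt(Z^2 + t(Z)^2)
  diag(C) <- NA_real_
  dimnames(C) <- dimnames(S)
  score_matrix(C, "CLR", n_bins = mi$n_bins, spline_order = mi$spline_order)
}
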