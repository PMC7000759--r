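#' Principal coordinate decomposition of a distance matrix
#'
#' Gower-centered double decomposition; negative eigenvalues are discarded
#' (Euclidean input makes them zero to machine precision anyway).
#'
#' @param dm `distance_matrix`.
#' @return list with orthonormal axes `vectors` (N x k), `values`
#'   (positive eigenvalues) and `scores` (= vectors scaled by sqrt(values)).
#' @keywords internal
pcoa_decompose <- function(dm) {
  d2 <- dm$d^2
  n <- nrow(d2)
  a <- -0.5 * d2
  g <- a - matrix(rowMeans(a), n, n) - matrix(colMeans(a), n, n, byrow = TRUE) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tol)
  list(vectors = e$vectors[, pos, drop = FALSE],
       values = e$values[pos],
       scores = sweep(e$vectors[, pos, drop = FALSE], 2,
                      sqrt(e$values[pos]), `*`),
       g = g)
}

# hat matrix of the centered group-indicator design
group_hat <- function(groups) {
  x <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  qx <- qr(x)
  qmat <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(qmat)
}

# canonical analysis of orthonormal PCoA axes against group labels:
# eigen-decomposition of Q' H Q gives the squared canonical correlations
cap_core <- function(q_m, groups) {
  h <- group_hat(groups)
  m_mat <- crossprod(q_m, h %*% q_m)
  e <- eigen(m_mat, symmetric = TRUE)
  k <- min(ncol(q_m), nlevels(groups) - 1)
  list(trc = sum(diag(m_mat)),
       delta2 = pmax(e$values[seq_len(k)], 0),
       u = e$vectors[, seq_len(k), drop = FALSE])
}

# nearest-centroid assignment in canonical space; ties to lowest group index
classify_centroid <- function(scores_train, groups_train, scores_test) {
  levs <- levels(groups_train)
  k <- ncol(scores_train)
  cent <- matrix(vapply(levs, function(l) {
    colMeans(scores_train[groups_train == l, , drop = FALSE])
  }, numeric(k)), ncol = k, byrow = TRUE)
  if (is.null(dim(scores_test))) scores_test <- matrix(scores_test, nrow = 1)
  apply(scores_test, 1, function(s) {
    dd <- sqrt(rowSums(sweep(cent, 2, s)^2))
    levs[which.min(dd)]
  })
}

# project a held-out point onto the orthonormal PCoA axes of the training set
# (Gower add-a-point): q_new = Lambda^-1 V' s with s the centered inner
# products implied by the new point's squared distances to the training set
project_point <- function(dec, d2_new) {
  g <- dec$g
  norm2 <- (sum(d2_new) - sum(diag(g))) / nrow(g)
  s <- 0.5 * (norm2 + diag(g) - d2_new)
  as.numeric(crossprod(dec$vectors, s) / dec$values)
}

#' Canonical analysis of principal coordinates with LOO cross-validation
#'
#' Constrained ordination of a distance matrix on a grouping factor:
#' principal coordinates are computed, the first m orthonormal axes
#' retained, and a canonical discriminant analysis of the group labels run
#' on them. The trace statistic (sum of squared canonical correlations,
#' tr(Q'HQ)) is tested by label permutation. Classification accuracy is
#' assessed by leave-one-out cross-validation: each sample is held out, the
#' principal coordinate and canonical analyses refit on the rest (m fixed),
#' the sample projected in, and assigned to the nearest group centroid in
#' canonical space (ties to the lowest group index).
#'
#' `m = "auto"` picks the m in 1..N-2 that maximizes LOO accuracy (ties to
#' the smallest m), the classical recommendation for choosing the retained
#' dimensionality; m can also be fixed by the user.
#'
#' @param d `distance_matrix` (or square matrix / `dist`).
#' @param groups group labels.
#' @param m number of principal coordinate axes to retain, or `"auto"`.
#' @param n_perm permutations for the trace statistic.
#' @param seed permutation seed.
#' @return object of class `cap_result`: `m`, `g_prop` (% of positive
#'   eigenvalue mass in the m axes), `trc_stat`, `p_value`, `delta2`
#'   (squared canonical correlations), `scores` (canonical scores),
#'   `confusion` (rows = true groups), `loo_accuracy` (%), `pcc`
#'   ([pcc_test()] of the LOO result), `seed`.
#' @export
cap_fit <- function(d, groups, m = "auto", n_perm = 999, seed = 1L) {
  dm <- as_dm(d)
  groups <- droplevels(as.factor(groups))
  n <- length(dm$ids)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  dec <- pcoa_decompose(dm)
  k_pos <- ncol(dec$vectors)
  m_max <- min(n - 2, k_pos)
  if (!identical(m, "auto")) {
    m <- as.integer(m)
    if (m >= n - 1) stop("m must be < N - 1 (over-parameterized)")
    if (m < 1) stop("m must be >= 1")
    if (m > k_pos) stop("only ", k_pos, " positive principal coordinate axes")
  }

  # per-fold decompositions reused across candidate m
  d2 <- dm$d^2
  folds <- lapply(seq_len(n), function(i) {
    sub <- structure(list(ids = dm$ids[-i], d = dm$d[-i, -i, drop = FALSE]),
                     class = "distance_matrix")
    dec_i <- pcoa_decompose(sub)
    list(dec = dec_i, q_new = project_point(dec_i, d2[i, -i]),
         groups = groups[-i], truth = as.character(groups[i]))
  })
  loo_at <- function(mm) {
    pred <- vapply(seq_len(n), function(i) {
      f <- folds[[i]]
      m_i <- min(mm, ncol(f$dec$vectors))
      q_tr <- f$dec$vectors[, seq_len(m_i), drop = FALSE]
      cc <- cap_core(q_tr, f$groups)
      sc_tr <- q_tr %*% cc$u
      sc_te <- as.numeric(crossprod(cc$u, f$q_new[seq_len(m_i)]))
      classify_centroid(sc_tr, f$groups, sc_te)
    }, character(1))
    pred
  }
  if (identical(m, "auto")) {
    accs <- vapply(seq_len(m_max), function(mm) {
      mean(loo_at(mm) == as.character(groups))
    }, numeric(1))
    m <- which.max(accs) # which.max takes the first (smallest) maximizer
  }
  pred <- loo_at(m)
  confusion <- table(truth = groups, predicted = factor(pred,
                                                        levels = levels(groups)))
  correct <- sum(diag(confusion))
  loo_accuracy <- 100 * correct / n

  q_m <- dec$vectors[, seq_len(m), drop = FALSE]
  cc <- cap_core(q_m, groups)
  perm_trc <- with_substream(seed, "cap_perm", {
    vapply(seq_len(n_perm), function(b) {
      cap_core(q_m, groups[sample.int(n)])$trc
    }, numeric(1))
  })
  p <- (sum(perm_trc >= cc$trc) + 1) / (n_perm + 1)
  scores <- q_m %*% cc$u
  rownames(scores) <- dm$ids

  structure(list(m = m, g_prop = 100 * sum(dec$values[seq_len(m)]) /
                   sum(dec$values),
                 trc_stat = cc$trc, p_value = p, delta2 = cc$delta2,
                 scores = scores, confusion = confusion,
                 loo_accuracy = loo_accuracy,
                 pcc = pcc_test(as.integer(table(groups)), correct),
                 n_perm = n_perm, seed = seed),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf(
    "CAP: m = %d, G_prop = %.1f%%, Trc_stat = %.3g, P = %.4g\n",
    x$m, x$g_prop, x$trc_stat, x$p_value))
  cat(sprintf("  LOO accuracy %.1f%% vs chance %.1f%% (PCC P = %.4g)\n",
              x$loo_accuracy, x$pcc$chance_accuracy, x$pcc$p_value))
  invisible(x)
}
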