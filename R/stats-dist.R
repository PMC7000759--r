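#' Euclidean distance matrix from a feature matrix
#'
#' @param x numeric matrix, rows = samples; no missing values allowed.
#' @param ids sample ids (default rownames).
#' @return object of class `distance_matrix`: list with `ids` and the
#'   symmetric nonnegative matrix `d` (zero diagonal).
#' @export
euclidean_dm <- function(x, ids = rownames(x)) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    bad <- if (!is.null(rownames(x))) {
      rownames(x)[apply(is.na(x), 1, any)]
    } else which(apply(is.na(x), 1, any))
    stop("missing values in rows: ", paste(bad, collapse = ", "))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

as_dm <- function(d) {
  if (inherits(d, "distance_matrix")) return(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared interpoint distances (SS_T = sum of d^2 over all pairs /
#' N) into among- and within-group components (SS_W summed per group with
#' its own size as divisor), forms the pseudo-F
#' F = (SS_A / (a-1)) / (SS_W / (N-a)), and assesses it by random
#' permutation of the group labels. On Euclidean distances of univariate
#' data the pseudo-F equals the classical one-way ANOVA F exactly.
#'
#' @param d `distance_matrix` (or square matrix / `dist`).
#' @param groups group labels, one per sample.
#' @param n_perm number of label permutations.
#' @param seed permutation seed.
#' @return object of class `permanova_result` with `pseudo_f`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `ss_total`,
#'   `p_value` (= (b+1)/(B+1) including the observed statistic),
#'   `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as_dm(d)
  groups <- as.factor(groups)
  n <- length(dm$ids)
  stopifnot(length(groups) == n)
  a <- nlevels(droplevels(groups))
  if (a < 2) stop("need >= 2 groups")
  if (max(table(groups)) < 2) stop("at least one group must have size >= 2")
  d2 <- dm$d^2

  f_stat <- function(g) {
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      if (length(i) > 1) {
        ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
      }
    }
    ss_a <- ss_t - ss_w
    c(f = (ss_a / (a - 1)) / (ss_w / (n - a)), ss_a = ss_a, ss_w = ss_w,
      ss_t = ss_t)
  }
  obs <- f_stat(groups)
  perm_f <- with_substream(seed, "permanova", {
    vapply(seq_len(n_perm), function(b) {
      f_stat(groups[sample.int(n)])[["f"]]
    }, numeric(1))
  })
  p <- (sum(perm_f >= obs[["f"]]) + 1) / (n_perm + 1)
  structure(list(pseudo_f = obs[["f"]], df_between = a - 1, df_within = n - a,
                 ss_between = obs[["ss_a"]], ss_within = obs[["ss_w"]],
                 ss_total = obs[["ss_t"]], p_value = p, n_perm = n_perm,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4g, P = %.4g (%d permutations)\n",
    x$df_between, x$df_within, x$pseudo_f, x$p_value, x$n_perm))
  invisible(x)
}

#' Proportional chance criterion for classification accuracy
#'
#' Expected accuracy under assignment proportional to group sizes:
#' p0 = sum((n_i / N)^2), reported as a percentage; with k equal groups it
#' is 100/k. Significance of an observed correct count is the exact
#' one-sided binomial tail P(X >= observed) with X ~ Binomial(N, p0).
#'
#' @param group_sizes integer group sizes.
#' @param observed_correct observed number of correctly classified samples
#'   (optional; `NA` skips the test).
#' @return object of class `pcc_result` with `chance_accuracy` (\%),
#'   `observed_accuracy` (\%), `p_value`.
#' @export
#' @examples
#' pcc_test(c(4, 3, 3, 4))$chance_accuracy # 25.5
pcc_test <- function(group_sizes, observed_correct = NA_integer_) {
  stopifnot(all(group_sizes >= 1))
  n <- sum(group_sizes)
  p0 <- sum((group_sizes / n)^2)
  obs_acc <- NA_real_
  p <- NA_real_
  if (!is.na(observed_correct)) {
    stopifnot(observed_correct >= 0, observed_correct <= n)
    obs_acc <- 100 * observed_correct / n
    p <- stats::pbinom(observed_correct - 1, n, p0, lower.tail = FALSE)
  }
  structure(list(group_sizes = group_sizes, chance_accuracy = 100 * p0,
                 observed_correct = observed_correct,
                 observed_accuracy = obs_acc, p_value = p),
            class = "pcc_result")
}

#' @export
print.pcc_result <- function(x, ...) {
  cat(sprintf("PCC: chance accuracy %.1f%%", x$chance_accuracy))
  if (!is.na(x$observed_accuracy)) {
    cat(sprintf(" | observed %.1f%% (P = %.4g)", x$observed_accuracy,
                x$p_value))
  }
  cat("\n")
  invisible(x)
}
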