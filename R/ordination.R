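#' Bray-Curtis dissimilarity between sample rows
#'
#' `d(s,t) = sum |x_s - x_t| / sum (x_s + x_t)` over features. A pair of
#' all-zero samples is defined as d = 0 (with a warning).
#'
#' @param abund Non-negative matrix, samples x features.
#' @return Square symmetric matrix in `[0, 1]`, zero diagonal, sample labels
#'   preserved.
#' @export
bray_curtis <- function(abund) {
  abund <- as.matrix(abund)
  if (any(abund < 0)) rlang::abort("bray_curtis: negative values")
  n <- nrow(abund)
  d <- matrix(0, n, n, dimnames = list(rownames(abund), rownames(abund)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- sum(abund[i, ] + abund[j, ])
      if (tot == 0) {
        if (!warned) {
          rlang::warn("bray_curtis: pair of all-zero samples; distance set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(abund[i, ] - abund[j, ])) / tot
      }
    }
  }
  d
}

#' Hellinger transform of a community table
#'
#' `h[s,f] = sqrt(x[s,f] / rowsum_s)`; Euclidean distances on the transformed
#' table equal Hellinger distances on the raw compositions, which makes
#' PCA/ordination of count-like data ecologically interpretable.
#'
#' @param abund Non-negative matrix, samples x features, positive row sums.
#' @return Matrix of the same shape; each row's squared values sum to 1.
#' @export
hellinger <- function(abund) {
  abund <- as.matrix(abund)
  if (any(abund < 0)) rlang::abort("hellinger: negative values")
  rs <- rowSums(abund)
  if (any(rs == 0)) {
    bad <- rownames(abund)[rs == 0][1]
    if (is.null(bad)) bad <- which(rs == 0)[1]
    rlang::abort(paste0("hellinger: sample '", bad, "' has zero total abundance"),
                 class = "hadalguilds_validation_error")
  }
  sqrt(sweep(abund, 1, rs, "/"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Gower-centered eigendecomposition of the squared dissimilarities. Negative
#' eigenvalues (possible for non-Euclidean input such as Bray-Curtis) are
#' reported, never silently dropped; coordinates span the positive axes.
#' Variance proportions are eigenvalues over the sum of positive eigenvalues.
#'
#' @param d Square symmetric dissimilarity matrix, zero diagonal.
#' @param correction `"none"` (default) or `"cailliez"` (additive constant
#'   making the matrix Euclidean).
#' @return Object of class `"hg_ordination"`: list with `coordinates`
#'   (samples x axes), `eigenvalues`, `prop_variance`.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    rlang::abort("pcoa: dissimilarity matrix is not symmetric")
  }
  if (correction == "cailliez") {
    d <- cailliez_constant(d)
  }
  n <- nrow(d)
  k <- n - 1L
  # cmdscale warns when some eigenvalues are negative; that is the expected
  # case for Bray-Curtis input and the eigenvalues are reported as-is
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- cs$eig
  pts <- cs$points
  # enforce exact centering (cmdscale leaves ~1e-9 drift on null axes)
  pts <- sweep(pts, 2, colMeans(pts))
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(coordinates = pts,
                 eigenvalues = eig,
                 prop_variance = eig / sum(eig[eig > 0])),
            class = "hg_ordination")
}

cailliez_constant <- function(d) {
  # smallest additive constant c such that d + c (off-diagonal) is Euclidean
  n <- nrow(d)
  ones <- diag(n) - matrix(1 / n, n, n)
  d1 <- -0.5 * ones %*% (d^2) %*% ones
  d2 <- -0.5 * ones %*% d %*% ones
  B <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  cc <- max(Re(eigen(B, only.values = TRUE)$values))
  out <- d + cc
  diag(out) <- 0
  out
}

#' Principal component analysis (covariance-based)
#'
#' Eigendecomposition of the covariance of the column-centered data; used on
#' Hellinger-transformed abundance tables.
#'
#' @param x Matrix, samples x features.
#' @return Object of class `"hg_ordination"` as in [pcoa()].
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pr$sdev^2
  pts <- pr$x
  structure(list(coordinates = pts,
                 eigenvalues = eig,
                 prop_variance = eig / sum(eig)),
            class = "hg_ordination")
}

#' @export
print.hg_ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coordinates), "samples,",
      length(x$eigenvalues), "eigenvalues\n")
  pv <- round(100 * x$prop_variance[1:min(3, length(x$prop_variance))], 1)
  cat("variance explained (first axes):", paste0(pv, "%", collapse = ", "), "\n")
  invisible(x)
}

permanova_ss <- function(D2, groups) {
  n <- nrow(D2)
  ss_t <- sum(D2) / (2 * n)
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(ss_t = ss_t, ss_w = ss_w)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Anderson's pseudo-F from within/between sums of squared dissimilarities,
#' with a permutation p-value over random reassignments of the group labels:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` (add-one estimator, never 0).
#' Samples are internally ordered by label (when the matrix has dimnames) so
#' the permutation stream — hence p — does not depend on input sample order.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations, >= 99.
#' @param seed Integer seed driving the label permutations.
#' @return One-row tibble: pseudo_f, p_value, df_between, df_within, n_perm.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) rlang::abort("permanova: length(groups) != nrow(d)")
  if (n_perm < 99) rlang::abort("permanova: n_perm must be >= 99")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    rlang::abort("permanova: need >= 2 groups, each of size >= 2")
  }
  if (!is.null(rownames(d))) {
    o <- order(rownames(d))
    d <- d[o, o]
    groups <- groups[o]
  }
  D2 <- d^2
  n <- nrow(d)
  a <- length(tab)
  ss <- permanova_ss(D2, groups)
  f_obs <- ((ss["ss_t"] - ss["ss_w"]) / (a - 1)) / (ss["ss_w"] / (n - a))
  exceed <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      gp <- groups[sample.int(n)]
      ssp <- permanova_ss(D2, gp)
      f_p <- ((ssp["ss_t"] - ssp["ss_w"]) / (a - 1)) / (ssp["ss_w"] / (n - a))
      if (f_p >= f_obs) exceed <- exceed + 1L
    }
  })
  tibble::tibble(pseudo_f = unname(f_obs),
                 p_value = (1 + exceed) / (1 + n_perm),
                 df_between = a - 1L, df_within = n - a,
                 n_perm = as.integer(n_perm))
}

#' Pairwise PERMANOVA with FDR adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values with
#' Benjamini-Hochberg (the `p.adjust = "fdr"` convention).
#'
#' @inheritParams permanova
#' @return Tibble: group_a, group_b, pseudo_f, p_value, p_adjusted.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) < 2) rlang::abort("pairwise_permanova: need >= 2 groups")
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    keep <- groups %in% pr
    res <- permanova(d[keep, keep, drop = FALSE], groups[keep],
                     n_perm = n_perm, seed = seed + k)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   pseudo_f = res$pseudo_f, p_value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite fractional degrees
#' of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors, each with `n >= 2` and finite variance.
#' @return One-row tibble: t, df, p_value.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) rlang::abort("welch_t: each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    # degenerate identical constant samples: no evidence of difference
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Ward clustering order of group profiles
#'
#' Hierarchical clustering with Ward's criterion on Euclidean distances
#' (hclust `"ward.D2"`), as used to order heatmap columns of median
#' abundances. Rows are pre-sorted lexicographically by label so that ties in
#' the merge sequence break deterministically.
#'
#' @param x Matrix, groups x variables (e.g. median abundance per depth), with
#'   row names.
#' @return List: `order` (labels in dendrogram order), `hclust` (the tree).
#' @export
ward_order <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) rlang::abort("ward_order: need >= 2 groups")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  list(order = rownames(x)[hc$order], hclust = hc)
}
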