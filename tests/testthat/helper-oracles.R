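# Independent oracles, written from the rule definitions directly and kept
# free of any package internals.

# Brute-force truth table for the respiratory marker rules.
oracle_rule_flags <- function(genes) {
  has <- function(...) c(...) %in% genes
  n_nar <- sum(has("narG", "narH", "narI"))
  flags <- list(
    napAB  = all(has("napA", "napB")),
    narGHI = n_nar >= 2,
    nrfAH  = all(has("nrfA", "nrfH")),
    nirBD  = all(has("nirB", "nirD")),
    nirKS  = sum(has("nirK", "nirS")) >= 1,
    norBC  = sum(has("norB", "norC")) >= 1,
    nosZ   = "nosZ" %in% genes,
    dsrAB  = all(has("dsrA", "dsrB"))
  )
  flags$full_denitrifier <- (flags$napAB || flags$narGHI) && flags$nirKS &&
    flags$norBC && flags$nosZ
  flags$nitrogen <- flags$napAB || flags$narGHI || flags$nrfAH ||
    flags$nirBD || flags$nirKS || flags$norBC || flags$nosZ
  flags
}

# Brute-force Venn region counting over exact capability subsets.
oracle_overlap_counts <- function(assignments) {
  caps <- c("aerobic", "nitrogen", "sulfur_resp", "metal_resp")
  lab <- apply(assignments[caps], 1, function(r) {
    on <- caps[as.logical(r)]
    if (length(on) == 0) "fermenter" else paste(on, collapse = "+")
  })
  table(lab)
}

# Grid search for the decay/growth constant minimising squared log-error,
# profiling out the intercept; refined to ~1e-9 absolute.
oracle_grid_lambda <- function(age, abund, lo = -1, hi = 1) {
  obj <- function(s) {
    b0 <- mean(log(abund)) - s * mean(age)
    sum((log(abund) - b0 - s * age)^2)
  }
  for (it in 1:12) {
    grid <- seq(lo, hi, length.out = 201)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  (lo + hi) / 2
}

# Brute-force Ward agglomeration: at each step merge the pair of clusters
# whose union gives the smallest increase in total within-cluster sum of
# squares. Returns the sequence of partitions (as sorted member strings).
oracle_ward_merges <- function(x) {
  ess <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(rownames(x))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best_inc - 1e-12) {
          best_inc <- inc
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# hclust merge table -> the same sequence-of-merged-member-sets encoding.
hclust_merges <- function(hc) {
  members <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) hc$labels[-v] else members[[v]]
    m <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
    members[[k]] <- m
    out[[k]] <- m
  }
  out
}

random_gene_set <- function(universe, p = 0.35) {
  universe[stats::runif(length(universe)) < p]
}

gene_universe <- c("narG", "narH", "narI", "napA", "napB", "norB", "norC",
                   "nirK", "nirS", "nosZ", "dsrA", "dsrB")
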