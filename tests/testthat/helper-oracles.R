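# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive re-derivation, kept free of the package's code paths.

# Pearson correlation via the textbook covariance/SD formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  if (sx == 0 || sy == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
}

# Upper-tail hypergeometric probability by explicit combinatorial sum.
oracle_hyper_sum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(n, js) * choose(N - n, K - js)) / choose(N, K)
}

# Upper-tail hypergeometric probability by full enumeration of all draws
# of size K from 1..N (feasible for tiny N only).
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, K)
  hits <- colSums(draws <= n)          # items 1..n are the successes
  mean(hits >= k)
}

# Two-sided Fisher p for a 2x2 table with fixed margins, by enumerating
# every feasible table and summing probabilities <= the observed one.
oracle_fisher_two_sided <- function(k, n_top, n_pos, n_total) {
  ks <- max(0, n_top + n_pos - n_total):min(n_top, n_pos)
  probs <- stats::dhyper(ks, n_pos, n_total - n_pos, n_top)
  p_obs <- stats::dhyper(k, n_pos, n_total - n_pos, n_top)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Enrichment statistic by a plain counting loop.
oracle_enrichment <- function(int_r, non_r, th, direction) {
  n_int <- 0L
  for (r in int_r) {
    if ((direction == "co" && r > th) || (direction == "anti" && r < th)) {
      n_int <- n_int + 1L
    }
  }
  n_non <- 0L
  for (r in non_r) {
    if ((direction == "co" && r > th) || (direction == "anti" && r < th)) {
      n_non <- n_non + 1L
    }
  }
  if (n_non == 0) return(NA_real_)
  (n_int - n_non) / n_non
}

# Disordered-region extraction by a linear scan.
oracle_regions <- function(scores, threshold, min_len) {
  out <- list()
  run_start <- NA_integer_
  for (i in seq_along(scores)) {
    if (scores[i] > threshold) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      if (i - run_start >= min_len) {
        out[[length(out) + 1L]] <- c(run_start - 1L, i - 1L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) &&
      length(scores) + 1L - run_start >= min_len) {
    out[[length(out) + 1L]] <- c(run_start - 1L, length(scores))
  }
  out
}

# Greedy longest-first redundancy reduction with a quadratic double loop
# over a dense identity lookup.
oracle_greedy <- function(lengths, identities, cutoff) {
  ord <- order(-lengths$length, lengths$id, method = "radix")
  ids <- lengths$id[ord]
  lookup <- function(a, b) {
    hit <- identities$identity[(identities$seq_a == a & identities$seq_b == b) |
                                 (identities$seq_a == b & identities$seq_b == a)]
    if (length(hit) == 0) 0 else max(hit)
  }
  kept <- character()
  for (id in ids) {
    ok <- TRUE
    for (k in kept) {
      if (lookup(id, k) >= cutoff) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

# Conditional term tests re-derived naively: explicit recursion for
# descendants, explicit set arithmetic, children processed before parents.
oracle_conditional <- function(terms, edges, ann_direct, genes, universe,
                               alpha = 0.05) {
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  anc <- function(t) {
    out <- t
    for (p in parents_of[[t]]) out <- union(out, anc(p))
    out
  }
  desc <- function(t) {
    out <- character()
    for (ch in children_of[[t]]) out <- union(out, c(ch, desc(ch)))
    out
  }
  ann <- lapply(setNames(terms$term, terms$term), function(t) character())
  for (i in seq_len(nrow(ann_direct))) {
    for (t in anc(ann_direct$term[i])) {
      ann[[t]] <- union(ann[[t]], ann_direct$gene[i])
    }
  }
  ann <- lapply(ann, intersect, y = universe)
  # order: number of descendants ascending puts children first
  ndesc <- vapply(terms$term, function(t) length(desc(t)), integer(1))
  ord <- terms$term[order(ndesc)]
  ns <- setNames(terms$namespace, terms$term)
  p_out <- setNames(rep(NA_real_, length(ord)), ord)
  sig <- setNames(rep(FALSE, length(ord)), ord)
  for (t in ord) {
    ds <- desc(t)
    ds <- ds[ns[ds] == ns[t]]
    removed <- unique(unlist(ann[ds[sig[ds]]], use.names = FALSE))
    a <- setdiff(ann[[t]], removed)
    smp <- setdiff(genes, removed)
    k <- length(intersect(smp, a))
    K <- length(smp)
    n <- length(a)
    N <- length(setdiff(universe, removed))
    p <- if (N == 0 || K == 0 || n == 0) 1 else
      sum(stats::dhyper(k:min(K, n), n, N - n, K))
    p_out[t] <- p
    sig[t] <- p < alpha
  }
  p_out
}
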