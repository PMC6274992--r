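# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and enumeration, usable only at toy sizes.

# Majority pairwise-ordering template by explicit looping. Mirrors the
# documented rules: ties are "not less", 50/50 resolves to TRUE.
brute_template <- function(expr, control_ids, genes) {
  genes <- sort(intersect(genes, rownames(expr)))
  pairs <- t(combn(genes, 2))
  ord <- logical(nrow(pairs))
  support <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    votes <- 0L
    for (s in control_ids) {
      r <- rank(expr[genes, s])
      if (r[pairs[p, 1]] < r[pairs[p, 2]]) votes <- votes + 1L
    }
    n <- length(control_ids)
    ord[p] <- votes >= n / 2
    support[p] <- max(votes, n - votes) / n
  }
  list(genes = genes, gene_i = pairs[, 1], gene_j = pairs[, 2],
       order = ord, support = support)
}

# GSR index of one sample against a brute template, pair by pair.
brute_gsr <- function(values, tpl) {
  r <- rank(values[tpl$genes])
  hits <- 0L
  for (p in seq_along(tpl$order)) {
    lt <- r[tpl$gene_i[p]] < r[tpl$gene_j[p]]
    if (lt == tpl$order[p]) hits <- hits + 1L
  }
  hits / length(tpl$order)
}

# Mean matching score of a control cohort under an arbitrary pair
# assignment; used to verify template optimality by exhausting all 2^P.
brute_assignment_score <- function(expr, control_ids, genes, assignment) {
  pairs <- t(combn(sort(genes), 2))
  scores <- vapply(control_ids, function(s) {
    r <- rank(expr[sort(genes), s])
    mean(vapply(seq_len(nrow(pairs)), function(p) {
      (r[pairs[p, 1]] < r[pairs[p, 2]]) == assignment[p]
    }, logical(1)))
  }, numeric(1))
  mean(scores)
}

# Exact two-sided Mann-Whitney p by complete enumeration of rank
# assignments (tie-free inputs, n + m small).
brute_mwu_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_u <- apply(combn(n + m, n), 2, function(idx) {
    sum(idx) - n * (n + 1) / 2
  })
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-up Benjamini-Hochberg by the textbook recursion.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(1, running)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# All-paths shortest depth by recursive enumeration of parent paths.
brute_depth <- function(dag, term, relations = c("is_a", "part_of")) {
  e <- dag$edges[dag$edges$relation %in% relations, ]
  parents <- function(t) e$parent[e$child == t]
  walk <- function(t) {
    ps <- parents(t)
    if (length(ps) == 0) return(0L)
    1L + min(vapply(ps, walk, integer(1)))
  }
  walk(term)
}

# Reachability closure by fixed-point iteration over the edge list.
brute_offspring <- function(dag, ancestors,
                            relations = c("is_a", "part_of")) {
  e <- dag$edges[dag$edges$relation %in% relations, ]
  out <- ancestors
  repeat {
    nxt <- unique(c(out, e$child[e$parent %in% out]))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}
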