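# Independent oracles used to check the implementation. These deliberately
# re-derive results by brute force (per-base enumeration, exhaustive
# topology search, linear scans) and never call the code paths they verify.

# --- per-base coverage enumeration ------------------------------------------

# Depth vector for one scaffold from raw bedGraph lines (0-based half-open).
oracle_depth_vector <- function(bg_lines, scaffold, len) {
  depth <- numeric(len)
  for (ln in bg_lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (f[1] != scaffold) next
    s <- as.integer(f[2]); e <- as.integer(f[3])
    idx <- seq.int(s + 1L, min(e, len))
    depth[idx] <- depth[idx] + as.numeric(f[4])
  }
  depth
}

# Covered exon bases by literal enumeration; exons as 1-based closed
# (start, end) pairs.
oracle_covered_fraction <- function(bg_lines, scaffold, exon_starts, exon_ends,
                                    depth_threshold = 1) {
  len <- max(exon_ends,
             vapply(bg_lines, function(ln) {
               f <- strsplit(ln, "\t")[[1]]
               if (f[1] == scaffold) as.integer(f[3]) else 0L
             }, integer(1)), 0L)
  depth <- oracle_depth_vector(bg_lines, scaffold, len)
  bases <- unlist(mapply(seq.int, exon_starts, exon_ends, SIMPLIFY = FALSE))
  mean(depth[bases] >= depth_threshold)
}

# --- least-squares tree fitting over all topologies -------------------------

# Indicator matrix: tip pairs (rows, combn order) x edges of `tree`.
oracle_edge_path_matrix <- function(tree) {
  n <- length(tree$tip.label)
  pairs <- t(utils::combn(n, 2))
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (k in seq_len(nrow(pairs))) {
    np <- ape::nodepath(tree, pairs[k, 1], pairs[k, 2])
    for (s in seq_len(length(np) - 1L)) {
      e <- which((tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1]) |
                   (tree$edge[, 2] == np[s] & tree$edge[, 1] == np[s + 1]))
      X[k, e] <- 1
    }
  }
  X
}

# Best unrooted topology for a distance matrix by exhaustive enumeration and
# ordinary least-squares branch-length fitting.
oracle_ls_topology <- function(dm) {
  labs <- rownames(dm)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  pairs <- t(utils::combn(length(labs), 2))
  d <- dm[cbind(pairs[, 1], pairs[, 2])]
  best <- NULL
  best_rss <- Inf
  for (t_i in seq_along(tops)) {
    tr <- tops[[t_i]] # `[[` re-attaches the shared tip labels
    X <- oracle_edge_path_matrix(tr)
    b <- qr.coef(qr(X), d)
    b[is.na(b)] <- 0
    rss <- sum((X %*% b - d)^2)
    if (rss < best_rss) {
      best_rss <- rss
      tr$edge.length <- as.numeric(b)
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}

same_topology <- function(t1, t2) {
  isTRUE(all.equal(phangorn::RF.dist(t1, t2), 0))
}

# Additive distance matrix implied by a tree with branch lengths.
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

# --- brute-force screen verdicts --------------------------------------------

# Re-derives every verdict from the raw inputs by explicit scanning; genes is
# a list of list(id, scaffold, starts, ends) with 1-based closed exons.
oracle_verdicts <- function(hit_lines, taxon_map, genes, bg_lines,
                            coverage_threshold = 0.10, depth_threshold = 1,
                            log_margin = 0) {
  parse_hit <- function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    list(query = f[1], subject = f[2], evalue = as.numeric(f[11]))
  }
  hits <- lapply(hit_lines, parse_hit)
  out <- character(length(genes))
  names(out) <- vapply(genes, `[[`, character(1), "id")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    best <- c(bacterial = Inf, arthropod = Inf)
    seen <- c(bacterial = FALSE, arthropod = FALSE)
    for (h in hits) {
      if (h$query != g$id) next
      grp <- taxon_map[h$subject]
      if (is.na(grp) || !grp %in% c("bacterial", "arthropod")) next
      seen[grp] <- TRUE
      best[grp] <- min(best[grp], h$evalue)
    }
    clamp <- function(e) max(e, 1e-300)
    pass_tax <- seen["bacterial"] &&
      (!seen["arthropod"] ||
         log10(clamp(best["arthropod"])) - log10(clamp(best["bacterial"])) > log_margin)
    frac <- oracle_covered_fraction(bg_lines, g$scaffold, g$starts, g$ends,
                                    depth_threshold)
    out[i] <- if (!pass_tax) "rejected_taxonomy"
      else if (!(frac > coverage_threshold)) "rejected_expression"
      else "candidate"
  }
  out
}
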