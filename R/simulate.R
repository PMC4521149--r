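# Truth-labelled synthetic inputs: a genome annotation with host, HGT, and
# contaminant genes, taxon-partitioned hit tables whose log10 e-values are
# drawn around separated means, Poisson coverage tracks, and alignments
# evolved on known trees. Everything is deterministic under the config seed.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defines the synthetic study conditions. Defaults emulate the separation
#' seen in real differential screens: true-origin hits centred at log10
#' e-value -60, cross-taxon hits at -10 (both with spread 5), roughly half
#' the genes carrying any cross-taxon hit; expressed genes at mean read
#' depth 20 per exon base, contaminant scaffolds essentially unread (mean
#' 0.05).
#'
#' @param n_host_genes Host (arthropod-origin) genes; default 60.
#' @param n_hgt_genes Horizontally transferred genes, placed on host
#'   scaffolds with at least two exons; default 10.
#' @param n_contaminant_genes Bacterial-contaminant genes, each alone on a
#'   dedicated scaffold with a single exon; default 10.
#' @param mu_log10e_self Mean log10 e-value against the true-origin taxon
#'   set; default -60.
#' @param mu_log10e_cross Mean log10 e-value against the other taxon set;
#'   default -10. Must be >= `mu_log10e_self` (equal means erase the
#'   separation the screen relies on, useful as a negative control).
#' @param sigma_log10e Spread of log10 e-values; default 5.
#' @param p_cross_hit Probability a gene has any cross-taxon hit; default
#'   0.5.
#' @param depth_mean_expressed Mean read depth per expressed exon base;
#'   default 20.
#' @param depth_mean_contaminant Mean read depth per contaminant exon base;
#'   default 0.05.
#' @param exon_count_range Inclusive range of exon counts per gene; default
#'   c(1, 5).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_host_genes = 60, n_hgt_genes = 10,
                       n_contaminant_genes = 10,
                       mu_log10e_self = -60, mu_log10e_cross = -10,
                       sigma_log10e = 5, p_cross_hit = 0.5,
                       depth_mean_expressed = 20,
                       depth_mean_contaminant = 0.05,
                       exon_count_range = c(1, 5), seed = 1) {
  stopifnot(n_host_genes >= 0, n_hgt_genes >= 0, n_contaminant_genes >= 0,
            mu_log10e_self <= mu_log10e_cross, sigma_log10e >= 0,
            p_cross_hit >= 0, p_cross_hit <= 1,
            depth_mean_expressed >= 0, depth_mean_contaminant >= 0,
            length(exon_count_range) == 2, exon_count_range[1] >= 1,
            exon_count_range[1] <= exon_count_range[2])
  structure(as.list(environment()), class = "sim_config")
}

# One simulated gene's structure: exon intervals (1-based closed) laid out
# from `at`, returning also the position after the gene.
lay_gene <- function(at, n_exons) {
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- at
  for (k in seq_len(n_exons)) {
    len <- sample(150:400, 1)
    starts[k] <- pos
    ends[k] <- pos + len - 1L
    pos <- ends[k] + if (k < n_exons) sample(80:300, 1) else sample(400:800, 1)
  }
  list(starts = starts, ends = ends, next_at = pos)
}

#' Generate a complete synthetic input set
#'
#' Writes `genes.gff3`, `hits.tsv` (12-column BLAST tabular), `taxa.tsv`,
#' `coverage.bedgraph`, and `truth.tsv` into `out_dir`. Host genes are
#' placed several per scaffold; HGT genes sit on host scaffolds with at
#' least two exons; contaminant genes sit alone on dedicated scaffolds with
#' one exon and near-zero coverage. Identical configs (including seed)
#' produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the five file paths (`gff3`, `hits`,
#'   `taxa`, `coverage`, `truth_path`) and the `truth` `data.frame`
#'   (`gene_id`, `label` in host/hgt/contaminant).
#' @export
simulate_inputs <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    lo <- config$exon_count_range[1]
    hi <- config$exon_count_range[2]
    genes <- list()
    # host genes: 3 per scaffold
    n_scaf <- max(1L, ceiling(config$n_host_genes / 3))
    host_scafs <- sprintf("scaffold%03d", seq_len(n_scaf))
    cursor <- stats::setNames(rep(1000L, n_scaf), host_scafs)
    for (i in seq_len(config$n_host_genes)) {
      scaf <- host_scafs[((i - 1L) %% n_scaf) + 1L]
      g <- lay_gene(cursor[[scaf]], sample(lo:hi, 1))
      cursor[[scaf]] <- g$next_at
      genes[[length(genes) + 1L]] <- list(
        id = sprintf("host%03d", i), scaffold = scaf, label = "host",
        starts = g$starts, ends = g$ends)
    }
    # hgt genes: on host scaffolds, >= 2 exons
    for (i in seq_len(config$n_hgt_genes)) {
      scaf <- host_scafs[((i - 1L) %% n_scaf) + 1L]
      g <- lay_gene(cursor[[scaf]], sample(max(2L, lo):max(2L, hi), 1))
      cursor[[scaf]] <- g$next_at
      genes[[length(genes) + 1L]] <- list(
        id = sprintf("hgt%03d", i), scaffold = scaf, label = "hgt",
        starts = g$starts, ends = g$ends)
    }
    # contaminant genes: alone on dedicated scaffolds, single exon
    for (i in seq_len(config$n_contaminant_genes)) {
      scaf <- sprintf("ctg_contam%03d", i)
      g <- lay_gene(500L, 1L)
      genes[[length(genes) + 1L]] <- list(
        id = sprintf("contam%03d", i), scaffold = scaf, label = "contaminant",
        starts = g$starts, ends = g$ends)
    }

    # --- GFF3 ---
    gff <- c("##gff-version 3")
    for (g in genes) {
      strand <- sample(c("+", "-"), 1)
      gff <- c(gff,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold, min(g$starts), max(g$ends), strand, g$id),
               sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       g$scaffold, min(g$starts), max(g$ends), strand, g$id, g$id),
               sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                       g$scaffold, g$starts, g$ends, strand, g$id,
                       seq_along(g$starts), g$id))
    }

    # --- hits + taxon map ---
    hit_lines <- character(0)
    taxa_lines <- character(0)
    subj_counter <- 0L
    emit_hit <- function(gene, group, mu) {
      subj_counter <<- subj_counter + 1L
      subj <- sprintf("UR50_%s%05d", if (group == "bacterial") "B" else "A",
                      subj_counter)
      log10e <- stats::rnorm(1, mu, config$sigma_log10e)
      alen <- sample(100:400, 1)
      pid <- round(stats::runif(1, 30, 90), 1)
      mism <- round(alen * (100 - pid) / 100)
      bits <- round(60 - 1.5 * log10e, 1)
      hit_lines <<- c(hit_lines, sprintf(
        "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
        gene, subj, pid, alen, mism, 0L, 1L, alen, 1L, alen,
        sprintf("%.3e", 10^log10e), bits))
      taxa_lines <<- c(taxa_lines, sprintf("%s\t%s", subj, group))
    }
    for (g in genes) {
      self_group <- if (g$label == "host") "arthropod" else "bacterial"
      cross_group <- if (self_group == "bacterial") "arthropod" else "bacterial"
      emit_hit(g$id, self_group, config$mu_log10e_self)
      if (stats::runif(1) < config$p_cross_hit) {
        emit_hit(g$id, cross_group, config$mu_log10e_cross)
      }
    }

    # --- coverage ---
    bg_lines <- character(0)
    scaf_len <- tapply(vapply(genes, function(g) max(g$ends), numeric(1)),
                       vapply(genes, `[[`, character(1), "scaffold"), max)
    by_scaf <- split(genes, vapply(genes, `[[`, character(1), "scaffold"))
    for (scaf in sort(names(by_scaf))) {
      depth <- integer(scaf_len[[scaf]] + 100L)
      for (g in by_scaf[[scaf]]) {
        mean_depth <- if (g$label == "contaminant") config$depth_mean_contaminant
                      else config$depth_mean_expressed
        for (k in seq_along(g$starts)) {
          idx <- g$starts[k]:g$ends[k]
          depth[idx] <- depth[idx] + stats::rpois(length(idx), mean_depth)
        }
      }
      r <- rle(depth)
      ends <- cumsum(r$lengths)
      starts0 <- c(0L, ends[-length(ends)]) # 0-based half-open
      keep <- r$values > 0L
      if (any(keep)) {
        bg_lines <- c(bg_lines, sprintf("%s\t%d\t%d\t%d", scaf,
                                        starts0[keep], ends[keep],
                                        r$values[keep]))
      }
    }

    # --- truth ---
    truth <- data.frame(gene_id = vapply(genes, `[[`, character(1), "id"),
                        label = vapply(genes, `[[`, character(1), "label"),
                        stringsAsFactors = FALSE)

    paths <- list(gff3 = file.path(out_dir, "genes.gff3"),
                  hits = file.path(out_dir, "hits.tsv"),
                  taxa = file.path(out_dir, "taxa.tsv"),
                  coverage = file.path(out_dir, "coverage.bedgraph"),
                  truth_path = file.path(out_dir, "truth.tsv"))
    writeLines(gff, paths$gff3)
    writeLines(hit_lines, paths$hits)
    writeLines(taxa_lines, paths$taxa)
    writeLines(bg_lines, paths$coverage)
    writeLines(c("gene_id\tlabel",
                 sprintf("%s\t%s", truth$gene_id, truth$label)), paths$truth_path)
    invisible(c(paths, list(truth = truth)))
  })
}

#' Evolve an alignment on a known tree
#'
#' A root sequence over the 20 standard amino acids (uniform composition) is
#' propagated from the root toward the tips; along an edge of length `l`
#' each site substitutes with probability `1 - exp(-subst_rate * l)`, to a
#' uniformly chosen different residue. No rate heterogeneity and no indels:
#' the generator supplies topology signal for the clade test, not a
#' realistic substitution model.
#'
#' @param tree Rooted or unrooted `phylo` with branch lengths.
#' @param taxon_of Named character vector labelling every non-query tip.
#' @param query_id,outgroup_id Designated query and outgroup tips.
#' @param seq_length Alignment columns (>= 1); default 300.
#' @param subst_rate Substitutions per unit branch length; default 1.
#' @param seed Integer RNG seed.
#' @return An [msa()] object.
#' @export
simulate_alignment <- function(tree, taxon_of, query_id, outgroup_id,
                               seq_length = 300, subst_rate = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (seq_length < 1) stop("seq_length must be >= 1", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- sample(AA_ALPHABET, seq_length, replace = TRUE)
    # parents precede children in cladewise edge order
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]
      child <- edge[e, 2]
      len <- tree$edge.length[which(tree$edge[, 1] == parent &
                                      tree$edge[, 2] == child)][1]
      p_sub <- 1 - exp(-subst_rate * len)
      s <- seqs[[parent]]
      mut <- which(stats::runif(seq_length) < p_sub)
      if (length(mut)) {
        old <- match(s[mut], AA_ALPHABET)
        shift <- sample.int(length(AA_ALPHABET) - 1L, length(mut), replace = TRUE)
        s[mut] <- AA_ALPHABET[((old - 1L + shift) %% length(AA_ALPHABET)) + 1L]
      }
      seqs[[child]] <- s
    }
    tipseqs <- vapply(seqs[seq_len(ntip)], paste, character(1), collapse = "")
    msa(stats::setNames(tipseqs, tree$tip.label), taxon_of,
        query_id, outgroup_id)
  })
}
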