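# Readers and writers for the external formats the screen consumes:
# BLAST tabular hit tables, subject->taxon maps, GFF3 gene models, bedGraph
# coverage, newick trees, aligned FASTA, and the candidate report TSV.
# All genomic intervals become IRanges/GRanges (1-based, closed) on entry;
# conversion from 0-based file conventions happens only here, at the
# boundary.

TAXON_GROUPS <- c("bacterial", "arthropod", "other_eukaryote", "archaeal")

BLAST6_COLS <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
  "evalue", "bitscore"
)

#' Read a subject-to-taxon-group map
#'
#' The map partitions homology-search subject sequences into the taxon groups
#' the differential screen compares (bacterial vs arthropod reference sets;
#' other eukaryotes and archaea are carried for phylogenetic labelling).
#'
#' @param path Two-column tab-separated file: `subject_id<TAB>taxon_group`,
#'   no header. Groups must be one of `bacterial`, `arthropod`,
#'   `other_eukaryote`, `archaeal`.
#' @return Named character vector mapping subject id to taxon group.
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", col.names = c("subject_id", "taxon_group"))
  bad <- !tab$taxon_group %in% TAXON_GROUPS
  if (any(bad)) {
    stop(sprintf("unknown taxon group '%s' for subject '%s'",
                 tab$taxon_group[bad][1], tab$subject_id[bad][1]), call. = FALSE)
  }
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) {
    conflicting <- vapply(unique(dup), function(s) {
      length(unique(tab$taxon_group[tab$subject_id == s])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop(sprintf("subject '%s' mapped to more than one taxon group",
                   unique(dup)[conflicting][1]), call. = FALSE)
    }
    tab <- tab[!duplicated(tab$subject_id), ]
  }
  stats::setNames(tab$taxon_group, tab$subject_id)
}

#' Read a BLAST tabular hit file with taxon annotation
#'
#' Parses the standard 12-column tabular dialect (`-outfmt 6`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' and annotates each hit with the subject's taxon group. Subjects absent
#' from the map are annotated `other_eukaryote` with a warning, so an
#' incomplete map degrades conservatively rather than silently inflating the
#' bacterial partition.
#'
#' @param path Tab-separated hit file, one hit per line, no header.
#' @param taxon_map Named character vector from [read_taxon_map()].
#' @return `data.frame` with the 12 standard columns plus `taxon_group`.
#' @export
read_hits <- function(path, taxon_map) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(BLAST6_COLS)), BLAST6_COLS))
    out$taxon_group <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    i <- which(ncols != 12L)[1]
    parse_error(path, i, sprintf("expected 12 tab-separated columns, found %d", ncols[i]))
  }
  mat <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- data.frame(query_id = mat[, 1], subject_id = mat[, 2],
                    stringsAsFactors = FALSE)
  numeric_cols <- c(3:4, 5:12)
  for (j in numeric_cols) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      parse_error(path, i, sprintf("non-numeric value '%s' in column %s",
                                   mat[i, j], BLAST6_COLS[j]))
    }
    out[[BLAST6_COLS[j]]] <- v
  }
  out <- out[, BLAST6_COLS]
  if (any(out$evalue < 0)) {
    i <- which(out$evalue < 0)[1]
    parse_error(path, i, sprintf("negative e-value %g", out$evalue[i]))
  }
  known <- out$subject_id %in% names(taxon_map)
  if (!all(known)) {
    warning(sprintf("%d hit(s) with subjects absent from the taxon map; annotated 'other_eukaryote' (e.g. '%s')",
                    sum(!known), out$subject_id[!known][1]), call. = FALSE)
  }
  out$taxon_group <- ifelse(known, unname(taxon_map[out$subject_id]), "other_eukaryote")
  out
}

#' Read gene models from GFF3
#'
#' Builds one gene model per `gene` feature; the model's exons are the union
#' (interval merge) of all `exon` features over all of the gene's
#' transcripts, so coverage is assessed per gene rather than per isoform.
#' Exons parented directly by a gene (no mRNA level) are also accepted.
#'
#' @param path GFF3 file (1-based inclusive coordinates per the standard).
#' @return A [GenomicRanges::GRangesList] named by gene id; each element is
#'   the reduced exon set of one gene, strand-annotated.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gene_ids <- as.character(genes$ID)
  if (anyNA(gene_ids) || any(!nzchar(gene_ids))) {
    stop("gene feature without an ID attribute", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene id '%s' in %s",
                 gene_ids[duplicated(gene_ids)][1], path), call. = FALSE)
  }
  # transcript -> gene parent table (mRNA or any feature with a gene Parent)
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_parent <- stats::setNames(
    vapply(tx$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1)),
    as.character(tx$ID))
  exons <- gr[type == "exon"]
  if (length(exons)) {
    ex_parent1 <- vapply(exons$Parent, function(p) {
      if (length(p)) p[[1]] else NA_character_
    }, character(1))
    if (anyNA(ex_parent1)) stop("exon feature without a Parent attribute", call. = FALSE)
    # resolve through the transcript level where needed
    ex_gene <- ifelse(ex_parent1 %in% gene_ids, ex_parent1,
                      unname(tx_parent[ex_parent1]))
    if (anyNA(ex_gene) || any(!ex_gene %in% gene_ids)) {
      bad <- ex_parent1[is.na(ex_gene) | !ex_gene %in% gene_ids][1]
      stop(sprintf("exon with unresolvable parent '%s' in %s", bad, path),
           call. = FALSE)
    }
  } else {
    ex_gene <- character(0)
  }
  # inherit the gene's strand so isoform exons on '*' never split the union
  gene_strand <- stats::setNames(as.character(GenomicRanges::strand(genes)), gene_ids)
  GenomicRanges::strand(exons) <- gene_strand[ex_gene]
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(exons, factor(ex_gene, levels = gene_ids)))
  empty <- S4Vectors::elementNROWS(grl) == 0L
  if (any(empty)) {
    stop(sprintf("gene '%s' has no exon features", gene_ids[empty][1]),
         call. = FALSE)
  }
  nscaf <- S4Vectors::elementNROWS(
    S4Vectors::runValue(GenomicRanges::seqnames(grl)))
  if (any(nscaf > 1L)) {
    stop(sprintf("gene '%s' has exons on more than one scaffold",
                 gene_ids[nscaf > 1L][1]), call. = FALSE)
  }
  grl
}

#' Scaffold of each gene model
#'
#' @param gene_models `GRangesList` from [read_gff3()].
#' @return Named character vector of scaffold ids.
#' @export
gene_scaffolds <- function(gene_models) {
  stats::setNames(
    unlist(S4Vectors::runValue(GenomicRanges::seqnames(gene_models)),
           use.names = FALSE),
    names(gene_models))
}

#' Read a per-base depth track from bedGraph
#'
#' @param path bedGraph file (`scaffold start end depth`, 0-based half-open
#'   intervals). Intervals on one scaffold must not overlap; unlisted
#'   positions have depth 0.
#' @return An [IRanges::RleList] of integer depths, one run-length-encoded
#'   vector per scaffold.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  if (!any(nzchar(lines))) {
    return(methods::as(IRanges::RleList(), "SimpleRleList"))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) {
    stop(sprintf("negative depth %g in %s", min(gr$score), path), call. = FALSE)
  }
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov)) {
    i <- S4Vectors::queryHits(ov)[1]
    stop(sprintf("overlapping intervals on scaffold '%s' in %s",
                 as.character(GenomicRanges::seqnames(gr))[i], path), call. = FALSE)
  }
  GenomicRanges::coverage(gr, weight = "score")
}

#' Depth at a single position
#'
#' @param track RleList from [read_bedgraph()].
#' @param scaffold Scaffold name; scaffolds absent from the track have depth
#'   0 everywhere.
#' @param pos 1-based base position.
#' @return Numeric depth (0 beyond the track's extent).
#' @export
track_depth <- function(track, scaffold, pos) {
  if (!scaffold %in% names(track)) return(0)
  v <- track[[scaffold]]
  ifelse(pos >= 1 & pos <= length(v), as.numeric(v[pmin(pos, length(v))]), 0)
}

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape}'s newick support: round-trips preserve
#' topology, tip labels, branch lengths, and any support values stored as
#' internal-node labels.
#'
#' @param path Newick file.
#' @return For `read_newick`, an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop(sprintf("failed to parse newick in %s: %s",
                                                  path, conditionMessage(e)), call. = FALSE))
  if (is.null(tr)) stop(sprintf("failed to parse newick in %s", path), call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

REPORT_COLS <- c(
  "gene_id", "fpkm", "bacterial_match_taxon", "bacterial_evalue",
  "arthropod_match", "arthropod_evalue", "exon_coverage_fraction",
  "intron_flag", "context_flag", "phylo_support", "predicted_function",
  "verdict"
)

#' Write the candidate report
#'
#' One row per screened gene, in the layout of the published ten-candidate
#' evidence table; absent values (no arthropod hit, no expression estimate,
#' no phylogenetic run) are rendered as an em dash.
#'
#' @param candidates `data.frame` of per-gene evidence bundles as produced by
#'   [classify_candidate()] / [run_pipeline()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(candidates, path) {
  stopifnot(is.data.frame(candidates))
  missing_cols <- setdiff(REPORT_COLS, names(candidates))
  for (col in missing_cols) candidates[[col]] <- NA
  out <- candidates[, REPORT_COLS, drop = FALSE]
  for (col in REPORT_COLS) {
    v <- out[[col]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA_character_, ifelse(v, "yes", "no"))
    v <- as.character(v)
    v[is.na(v)] <- "\u2014"
    out[[col]] <- v
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-gene expression (FPKM) table
#'
#' @param path Two-column tab-separated file `gene_id<TAB>fpkm`, no header.
#' @return Named numeric vector of FPKM values.
#' @export
read_fpkm_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           col.names = c("gene_id", "fpkm"),
                           colClasses = c("character", "numeric"))
  if (any(tab$fpkm < 0, na.rm = TRUE)) stop("negative FPKM value", call. = FALSE)
  stats::setNames(tab$fpkm, tab$gene_id)
}
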