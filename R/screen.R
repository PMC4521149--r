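# The core decision procedure: best hits per taxon partition, the
# differential-significance rule, the RNA-seq exon-coverage contamination
# filter, FPKM, integration-context evidence, and the final per-gene verdict.

#' Screening configuration
#'
#' Bundles the thresholds of the screen. Defaults follow the published
#' procedure: a gene is kept only when more than 10\% of its exon bases carry
#' aligned RNA-seq reads (depth >= 1), the differential rule requires the
#' bacterial e-value to be strictly more significant (log10 margin 0), and
#' phylogenetic confirmation uses 100 bootstrap replicates with a 50\%
#' support threshold.
#'
#' @param coverage_fraction_threshold Fraction of exon bases that must be
#'   covered (strictly exceeded) to count as expressed; default 0.10.
#' @param depth_threshold Minimum read depth for a base to count as covered;
#'   default 1.
#' @param evalue_log_margin Required log10 gap between arthropod and
#'   bacterial best e-values; default 0 (strict "more significant").
#' @param bootstrap_reps Bootstrap replicates for phylogenetic confirmation;
#'   default 100.
#' @param support_threshold Bootstrap support (percent) below which a
#'   phylogenetically tested candidate is rejected; default 50.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(coverage_fraction_threshold = 0.10,
                          depth_threshold = 1,
                          evalue_log_margin = 0,
                          bootstrap_reps = 100,
                          support_threshold = 50) {
  stopifnot(coverage_fraction_threshold >= 0, coverage_fraction_threshold <= 1,
            depth_threshold >= 0, bootstrap_reps >= 1,
            support_threshold >= 0, support_threshold <= 100)
  structure(list(coverage_fraction_threshold = coverage_fraction_threshold,
                 depth_threshold = depth_threshold,
                 evalue_log_margin = evalue_log_margin,
                 bootstrap_reps = bootstrap_reps,
                 support_threshold = support_threshold),
            class = "screen_config")
}

#' Read a screening configuration from YAML
#'
#' Any subset of the [screen_config()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path YAML file of key-value pairs.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown screen_config field '%s'", unknown[1]), call. = FALSE)
  }
  do.call(screen_config, vals)
}

#' Best bacterial and arthropod hit per query
#'
#' Reduces an annotated hit table to one row per query: the bacterial-group
#' hit with the smallest e-value and likewise for the arthropod group. Hits
#' to other taxon groups are ignored. Ties on e-value are broken by larger
#' bitscore, then lexicographically smaller subject id, so the result is
#' independent of row order.
#'
#' @param hits `data.frame` from [read_hits()] (must carry `taxon_group`).
#' @return `data.frame` with one row per query: `gene_id`, then
#'   `bacterial_subject`, `bacterial_evalue`, `bacterial_bitscore`,
#'   `bacterial_identity` and the four arthropod counterparts (`NA` when a
#'   partition has no hit).
#' @export
best_hits_per_gene <- function(hits) {
  stopifnot(is.data.frame(hits), "taxon_group" %in% names(hits))
  queries <- sort(unique(hits$query_id))
  pick <- function(h) {
    if (!nrow(h)) {
      return(list(subject = NA_character_, evalue = NA_real_,
                  bitscore = NA_real_, identity = NA_real_))
    }
    o <- order(h$evalue, -h$bitscore, h$subject_id)
    b <- h[o[1], ]
    list(subject = b$subject_id, evalue = b$evalue,
         bitscore = b$bitscore, identity = b$percent_identity)
  }
  rows <- lapply(queries, function(q) {
    hq <- hits[hits$query_id == q, , drop = FALSE]
    bac <- pick(hq[hq$taxon_group == "bacterial", , drop = FALSE])
    art <- pick(hq[hq$taxon_group == "arthropod", , drop = FALSE])
    data.frame(gene_id = q,
               bacterial_subject = bac$subject, bacterial_evalue = bac$evalue,
               bacterial_bitscore = bac$bitscore, bacterial_identity = bac$identity,
               arthropod_subject = art$subject, arthropod_evalue = art$evalue,
               arthropod_bitscore = art$bitscore, arthropod_identity = art$identity,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(gene_id = character(0),
                      bacterial_subject = character(0), bacterial_evalue = numeric(0),
                      bacterial_bitscore = numeric(0), bacterial_identity = numeric(0),
                      arthropod_subject = character(0), arthropod_evalue = numeric(0),
                      arthropod_bitscore = numeric(0), arthropod_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Differential-significance screen
#'
#' A gene passes when it has a bacterial hit and either no arthropod hit at
#' the search's own reporting threshold, or the bacterial e-value is more
#' significant than the arthropod one by more than `evalue_log_margin` log10
#' units (strictly more significant at the default margin of 0). Zero
#' e-values are clamped to 1e-300 before the log comparison.
#'
#' @param bacterial_evalue,arthropod_evalue Best e-values per partition;
#'   `NA` means no hit. Vectorised.
#' @param config A [screen_config()].
#' @return Logical vector.
#' @export
differential_screen <- function(bacterial_evalue, arthropod_evalue,
                                config = screen_config()) {
  n <- max(length(bacterial_evalue), length(arthropod_evalue))
  bacterial_evalue <- rep_len(bacterial_evalue, n)
  arthropod_evalue <- rep_len(arthropod_evalue, n)
  has_bac <- !is.na(bacterial_evalue)
  has_art <- !is.na(arthropod_evalue)
  gap <- log10_evalue(ifelse(has_art, arthropod_evalue, 1)) -
    log10_evalue(ifelse(has_bac, bacterial_evalue, 1))
  has_bac & (!has_art | gap > config$evalue_log_margin)
}

#' Fraction of exon bases covered by RNA-seq reads
#'
#' The contamination filter's statistic: over the gene's exon union, the
#' proportion of bases whose read depth meets `depth_threshold`. Genes on
#' scaffolds absent from the track (the natural state of a contaminant
#' scaffold, which attracts no host mRNA) get fraction 0 rather than an
#' error.
#'
#' @param exons `GRanges` of a gene's (non-overlapping) exons, as one
#'   element of [read_gff3()]'s result.
#' @param track Coverage `RleList` from [read_bedgraph()].
#' @param depth_threshold Minimum depth for a base to count as covered.
#' @return Fraction in \[0, 1\].
#' @export
exon_coverage_fraction <- function(exons, track, depth_threshold = 1) {
  total <- sum(GenomicRanges::width(exons))
  if (total < 1) stop("gene model has zero exon bases", call. = FALSE)
  scaf <- unique(as.character(GenomicRanges::seqnames(exons)))
  stopifnot(length(scaf) == 1L)
  if (!scaf %in% names(track)) return(0)
  depth <- track[[scaf]]
  maxend <- max(GenomicRanges::end(exons))
  if (length(depth) < maxend) {
    depth <- c(depth, S4Vectors::Rle(0L, maxend - length(depth)))
  }
  covered <- depth >= depth_threshold
  views <- IRanges::Views(covered, GenomicRanges::start(exons),
                          GenomicRanges::end(exons))
  n_cov <- sum(vapply(seq_along(views), function(i) sum(as.integer(views[[i]])),
                      integer(1)))
  n_cov / total
}

#' Expression filter
#'
#' @param fraction Exon-coverage fraction in \[0, 1\].
#' @param config A [screen_config()].
#' @return `TRUE` iff the fraction strictly exceeds the configured threshold
#'   (the published rule is ">10\%", so exactly 10\% fails).
#' @export
passes_expression_filter <- function(fraction, config = screen_config()) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  fraction > config$coverage_fraction_threshold
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param fragment_count Fragments assigned to the gene.
#' @param exon_length Exonic length in bases (>= 1).
#' @param total_fragments Library size in mapped fragments (>= 1).
#' @return `fragment_count / ((exon_length/1e3) * (total_fragments/1e6))`.
#' @export
compute_fpkm <- function(fragment_count, exon_length, total_fragments) {
  stopifnot(all(fragment_count >= 0))
  if (any(exon_length < 1)) stop("exon_length must be >= 1", call. = FALSE)
  if (any(total_fragments < 1)) stop("total_fragments must be >= 1", call. = FALSE)
  fragment_count / ((exon_length / 1e3) * (total_fragments / 1e6))
}

#' Genomic-integration evidence
#'
#' Two descriptive flags supporting (never deciding) candidacy:
#' `intron_flag` — the gene model has at least two exons, i.e. contains an
#' intron; `context_flag` — another predicted gene on the same scaffold
#' shows insect homology (it has an arthropod hit that is at least as
#' significant as its bacterial hit, or it has no bacterial hit at all),
#' placing the candidate in a host-genomic neighbourhood.
#'
#' @param gene_id Gene under consideration.
#' @param gene_models `GRangesList` from [read_gff3()].
#' @param best_pairs `data.frame` from [best_hits_per_gene()].
#' @param scaffolds Optional precomputed [gene_scaffolds()] vector (an
#'   optimisation for callers that classify many genes).
#' @return `list(intron_flag =, context_flag =)`.
#' @export
integration_evidence <- function(gene_id, gene_models, best_pairs,
                                 scaffolds = NULL) {
  stopifnot(gene_id %in% names(gene_models))
  if (is.null(scaffolds)) scaffolds <- gene_scaffolds(gene_models)
  intron_flag <- S4Vectors::elementNROWS(gene_models[gene_id]) >= 2L
  neighbours <- setdiff(names(gene_models)[scaffolds == scaffolds[[gene_id]]],
                        gene_id)
  rows <- best_pairs[best_pairs$gene_id %in% neighbours, , drop = FALSE]
  has_art <- !is.na(rows$arthropod_evalue)
  has_bac <- !is.na(rows$bacterial_evalue)
  context_flag <- any(has_art &
                        (!has_bac | rows$arthropod_evalue <= rows$bacterial_evalue))
  list(intron_flag = unname(intron_flag), context_flag = context_flag)
}

#' Classify one gene
#'
#' Applies the evidence in a fixed order so rejection reasons are
#' deterministic: the differential taxonomy rule first, then the
#' exon-coverage expression filter, then (when a phylogenetic test was run)
#' the bootstrap-support threshold. Integration flags are recorded as
#' supporting annotations only.
#'
#' @param gene_id Gene id.
#' @param bacterial_evalue,arthropod_evalue Best e-values (`NA` = no hit).
#' @param coverage_fraction Exon-coverage fraction.
#' @param fpkm Expression estimate or `NA`.
#' @param intron_flag,context_flag Integration evidence.
#' @param phylo_support Bootstrap support (percent) of the candidate's
#'   placement, or `NA` when no phylogenetic test was run.
#' @param bacterial_match,arthropod_match Labels for the best subjects
#'   (subject ids or taxon names), optional.
#' @param predicted_function Annotation string, optional.
#' @param config A [screen_config()].
#' @return One-row `data.frame` with the report columns and a `verdict` of
#'   `candidate`, `rejected_taxonomy`, `rejected_expression`, or
#'   `rejected_phylogeny`.
#' @export
classify_candidate <- function(gene_id, bacterial_evalue, arthropod_evalue,
                               coverage_fraction, fpkm = NA_real_,
                               intron_flag = NA, context_flag = NA,
                               phylo_support = NA_real_,
                               bacterial_match = NA_character_,
                               arthropod_match = NA_character_,
                               predicted_function = NA_character_,
                               config = screen_config()) {
  verdict <- if (!differential_screen(bacterial_evalue, arthropod_evalue, config)) {
    "rejected_taxonomy"
  } else if (!passes_expression_filter(coverage_fraction, config)) {
    "rejected_expression"
  } else if (!is.na(phylo_support) && phylo_support < config$support_threshold) {
    "rejected_phylogeny"
  } else {
    "candidate"
  }
  data.frame(gene_id = gene_id, fpkm = fpkm,
             bacterial_match_taxon = bacterial_match,
             bacterial_evalue = bacterial_evalue,
             arthropod_match = arthropod_match,
             arthropod_evalue = arthropod_evalue,
             exon_coverage_fraction = coverage_fraction,
             intron_flag = intron_flag, context_flag = context_flag,
             phylo_support = phylo_support,
             predicted_function = predicted_function,
             verdict = verdict, stringsAsFactors = FALSE)
}
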