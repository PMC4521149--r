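map4 <- c(b1 = "bacterial", b2 = "bacterial", a1 = "arthropod",
          a2 = "arthropod", o1 = "other_eukaryote")

annotate <- function(lines, map = map4) {
  read_hits(write_tmp(lines, ".tsv"), map)
}

test_that("best hits pick the minimal e-value per taxon partition", {
  h <- annotate(c(hit_line("g", "b1", 1e-37), hit_line("g", "a1", 1e-21),
                  hit_line("g", "b2", 1e-5), hit_line("g", "o1", 1e-90)))
  bp <- best_hits_per_gene(h)
  expect_equal(bp$bacterial_evalue, 1e-37)
  expect_equal(bp$arthropod_evalue, 1e-21)
  expect_equal(bp$bacterial_subject, "b1") # other_eukaryote ignored

  # no hits at all
  expect_equal(nrow(best_hits_per_gene(annotate(character(0)))), 0L)

  # two bacterial hits -> smaller e-value wins
  bp2 <- best_hits_per_gene(annotate(c(hit_line("g", "b1", 1e-5),
                                       hit_line("g", "b2", 1e-8))))
  expect_equal(bp2$bacterial_evalue, 1e-8)
  expect_equal(bp2$bacterial_subject, "b2")
})

test_that("e-value ties break by bitscore then subject id", {
  h <- annotate(c(hit_line("g", "b2", 1e-10, bitscore = 50),
                  hit_line("g", "b1", 1e-10, bitscore = 80)))
  expect_equal(best_hits_per_gene(h)$bacterial_subject, "b1")
  h2 <- annotate(c(hit_line("g", "b2", 1e-10, bitscore = 80),
                   hit_line("g", "b1", 1e-10, bitscore = 80)))
  expect_equal(best_hits_per_gene(h2)$bacterial_subject, "b1")
})

test_that("best hits agree with a linear-scan oracle on random tables", {
  set.seed(11)
  subjects <- names(map4)
  for (rep in 1:20) {
    lines <- vapply(seq_len(sample(5:40, 1)), function(i) {
      hit_line(sprintf("g%d", sample(1:5, 1)), sample(subjects, 1),
               10^stats::runif(1, -100, 1),
               bitscore = round(stats::runif(1, 30, 300), 1))
    }, character(1))
    h <- annotate(lines)
    bp <- best_hits_per_gene(h)
    for (q in unique(h$query_id)) {
      for (grp in c("bacterial", "arthropod")) {
        sub <- h[h$query_id == q & h$taxon_group == grp, ]
        want <- if (nrow(sub)) min(sub$evalue) else NA_real_
        got <- bp[bp$gene_id == q, paste0(grp, "_evalue")]
        expect_equal(got, want)
      }
    }
  }
})

test_that("differential rule requires strictly more significant bacterial hit", {
  expect_true(differential_screen(1e-107, 0.016))
  expect_true(differential_screen(2e-31, NA))   # no arthropod hit
  expect_false(differential_screen(1e-10, 1e-10)) # strict inequality
  expect_false(differential_screen(NA, 1e-50))
  expect_false(differential_screen(NA, NA))
  expect_false(differential_screen(1e-40, 1e-60))
  # zero e-values clamp rather than break the log comparison
  expect_true(differential_screen(0, 2.2))
  expect_false(differential_screen(0, 0))
  # configurable log10 margin
  strict <- screen_config(evalue_log_margin = 20)
  expect_false(differential_screen(1e-37, 1e-21, strict)) # gap 16 < 20
  expect_true(differential_screen(1e-57, 3e-7, strict))   # gap ~50
})

test_that("exon coverage fraction counts covered bases over the exon union", {
  # exons of 50 bases each; depth only over file interval [25,125)
  exons <- GenomicRanges::GRanges("s", IRanges::IRanges(c(1, 101), c(50, 150)))
  track <- read_bedgraph(write_tmp("s\t25\t125\t3", ".bedgraph"))
  expect_equal(exon_coverage_fraction(exons, track, 1), 0.5)

  empty <- read_bedgraph(write_tmp(character(0), ".bedgraph"))
  expect_equal(exon_coverage_fraction(exons, empty, 1), 0)

  full <- read_bedgraph(write_tmp("s\t0\t150\t7", ".bedgraph"))
  expect_equal(exon_coverage_fraction(exons, full, 1), 1)
  # depth 7 fails a higher depth threshold
  expect_equal(exon_coverage_fraction(exons, full, 8), 0)
})

test_that("coverage fraction is monotone in added coverage", {
  exons <- GenomicRanges::GRanges("s", IRanges::IRanges(c(1, 201), c(100, 300)))
  set.seed(3)
  base_iv <- c("s\t0\t50\t2", "s\t220\t260\t1")
  more_iv <- c(base_iv, "s\t60\t120\t4")
  t_base <- read_bedgraph(write_tmp(base_iv, ".bedgraph"))
  t_more <- read_bedgraph(write_tmp(more_iv, ".bedgraph"))
  expect_gte(exon_coverage_fraction(exons, t_more, 1),
             exon_coverage_fraction(exons, t_base, 1))
})

test_that("expression filter is strict at the 10% boundary", {
  expect_true(passes_expression_filter(0.11))
  expect_false(passes_expression_filter(0.10))
  expect_true(passes_expression_filter(1.0))
  expect_false(passes_expression_filter(0))
})

test_that("FPKM follows the fragments-per-kilobase-per-million formula", {
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(2000, 1000, 2e6), 1000) # depth-scale invariance
  set.seed(5)
  for (i in 1:20) {
    frags <- sample(0:5000, 1); len <- sample(200:5000, 1)
    total <- sample(1e5:1e7, 1); k <- sample(2:9, 1)
    expect_equal(compute_fpkm(k * frags, len, k * total),
                 compute_fpkm(frags, len, total))
  }
  expect_error(compute_fpkm(10, 0, 1e6), "exon_length")
  expect_error(compute_fpkm(10, 1000, 0), "total_fragments")
})

test_that("integration evidence reflects introns and scaffold context", {
  gff <- gff3_file(
    gff3_gene("lone", "sA", 1, 300),
    gff3_gene("hgt1", "sB", c(1, 201), c(100, 400)),
    gff3_gene("host1", "sB", c(1001, 1301), c(1200, 1500)),
    gff3_gene("hgt2", "sC", c(1, 201), c(100, 400)),
    gff3_gene("bactneigh", "sC", 1001, 1600))
  models <- read_gff3(gff)
  h <- annotate(c(hit_line("host1", "a1", 1e-50),
                  hit_line("hgt2", "b1", 1e-40),
                  hit_line("bactneigh", "b1", 1e-60),
                  hit_line("bactneigh", "a1", 1e-4)))
  bp <- best_hits_per_gene(h)

  # single-exon gene alone on its scaffold
  ev <- integration_evidence("lone", models, bp)
  expect_false(ev$intron_flag)
  expect_false(ev$context_flag)

  # two-exon gene beside an arthropod-best neighbour
  ev <- integration_evidence("hgt1", models, bp)
  expect_true(ev$intron_flag)
  expect_true(ev$context_flag)

  # neighbour whose best hit is bacterial gives no insect context
  ev <- integration_evidence("hgt2", models, bp)
  expect_true(ev$intron_flag)
  expect_false(ev$context_flag)
})

test_that("verdicts follow the taxonomy -> expression -> phylogeny order", {
  cand <- classify_candidate("scaffold1827.1", 1e-57, 3e-7, 0.88)
  expect_equal(cand$verdict, "candidate")
  expect_equal(classify_candidate("g", 1e-40, 1e-60, 0.9)$verdict,
               "rejected_taxonomy")
  expect_equal(classify_candidate("g", 1e-40, 1e-20, 0.02)$verdict,
               "rejected_expression")
  # taxonomy failure reported even when expression would also fail
  expect_equal(classify_candidate("g", NA, 1e-20, 0.02)$verdict,
               "rejected_taxonomy")
  expect_equal(classify_candidate("g", 1e-40, 1e-20, 0.9,
                                  phylo_support = 32)$verdict,
               "rejected_phylogeny")
  expect_equal(classify_candidate("g", 1e-40, 1e-20, 0.9,
                                  phylo_support = 72)$verdict,
               "candidate")
  # integration flags never decide the verdict
  expect_equal(classify_candidate("g", 1e-40, 1e-20, 0.9,
                                  intron_flag = FALSE,
                                  context_flag = FALSE)$verdict, "candidate")
})

test_that("shuffling hit rows never changes a verdict", {
  set.seed(21)
  lines <- c(hit_line("g1", "b1", 1e-40), hit_line("g1", "a1", 1e-10),
             hit_line("g1", "b2", 1e-20), hit_line("g2", "a1", 1e-60),
             hit_line("g2", "b1", 1e-5), hit_line("g3", "b2", 1e-33))
  gff <- gff3_file(gff3_gene("g1", "s", 1, 200),
                   gff3_gene("g2", "s", 301, 500),
                   gff3_gene("g3", "s", 601, 800))
  models <- read_gff3(gff)
  track <- read_bedgraph(write_tmp("s\t0\t800\t9", ".bedgraph"))
  verdict_of <- function(lns) {
    bp <- best_hits_per_gene(annotate(lns))
    vapply(names(models), function(g) {
      r <- bp[bp$gene_id == g, , drop = FALSE]
      classify_candidate(g,
                         if (nrow(r)) r$bacterial_evalue else NA_real_,
                         if (nrow(r)) r$arthropod_evalue else NA_real_,
                         exon_coverage_fraction(models[[g]], track))$verdict
    }, character(1))
  }
  ref <- verdict_of(lines)
  for (i in 1:10) expect_identical(verdict_of(sample(lines)), ref)
})

test_that("a better bacterial hit cannot flip a candidate to rejected_taxonomy", {
  set.seed(31)
  for (i in 1:25) {
    e_b <- 10^stats::runif(1, -80, 0)
    e_a <- 10^stats::runif(1, -80, 0)
    before <- differential_screen(e_b, e_a)
    after <- differential_screen(min(e_b, 10^stats::runif(1, -120, log10(e_b))), e_a)
    expect_true(!before || after)
  }
})

test_that("verdicts equal brute-force re-evaluation on small instances", {
  set.seed(99)
  map <- c(B1 = "bacterial", B2 = "bacterial", A1 = "arthropod",
           A2 = "arthropod", O1 = "other_eukaryote")
  for (rep in 1:5) {
    n_genes <- sample(5:20, 1)
    genes <- lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(1:3, 1)
      starts <- cumsum(sample(300:500, n_ex)) + (i - 1) * 5000
      ends <- starts + sample(80:200, n_ex)
      list(id = sprintf("g%02d", i), scaffold = sample(c("sX", "sY"), 1),
           starts = starts, ends = ends)
    })
    hit_lines <- unlist(lapply(genes, function(g) {
      n <- sample(0:8, 1)
      vapply(seq_len(n), function(k) {
        hit_line(g$id, sample(names(map), 1), 10^stats::runif(1, -60, 1))
      }, character(1))
    }))
    bg_lines <- unlist(lapply(genes, function(g) {
      if (stats::runif(1) < 0.5) {
        sprintf("%s\t%d\t%d\t%d", g$scaffold, min(g$starts) - 1,
                max(g$ends), sample(1:5, 1))
      } else character(0)
    }))
    if (is.null(bg_lines)) bg_lines <- character(0)
    if (is.null(hit_lines)) hit_lines <- character(0)
    # overlapping emissions are possible on a shared scaffold; drop clashes
    bg_by_scaf <- split(bg_lines, vapply(strsplit(bg_lines, "\t"), `[[`, "", 1))
    bg_lines <- unlist(lapply(bg_by_scaf, function(lns) {
      f <- do.call(rbind, strsplit(lns, "\t"))
      s <- as.integer(f[, 2]); e <- as.integer(f[, 3])
      keep <- rep(TRUE, length(s))
      for (i in seq_along(s)) {
        if (!keep[i]) next
        for (j in seq_along(s)) {
          if (i != j && keep[j] && s[j] < e[i] && s[i] < e[j]) keep[j] <- FALSE
        }
      }
      lns[keep]
    }), use.names = FALSE)

    gff <- gff3_file(unlist(lapply(genes, function(g) {
      gff3_gene(g$id, g$scaffold, g$starts, g$ends)
    })))
    models <- read_gff3(gff)
    track <- read_bedgraph(write_tmp(bg_lines, ".bedgraph"))
    bp <- best_hits_per_gene(annotate(hit_lines, map))
    got <- vapply(names(models), function(gid) {
      r <- bp[bp$gene_id == gid, , drop = FALSE]
      classify_candidate(gid,
                         if (nrow(r)) r$bacterial_evalue else NA_real_,
                         if (nrow(r)) r$arthropod_evalue else NA_real_,
                         exon_coverage_fraction(models[[gid]], track))$verdict
    }, character(1))
    want <- oracle_verdicts(hit_lines, map, genes, bg_lines)
    expect_identical(got[sort(names(got))], want[sort(names(want))])
  }
})
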