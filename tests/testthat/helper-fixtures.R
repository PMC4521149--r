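# Builders for small on-disk fixtures, constructed in code at test time.

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A hit line in the 12-column tabular dialect with sensible filler fields.
hit_line <- function(query, subject, evalue, bitscore = 100, pident = 50,
                     alen = 200) {
  sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
          query, subject, pident, alen, 10L, 1L, 1L, alen, 1L, alen,
          format(evalue), bitscore)
}

taxa_lines <- function(map) sprintf("%s\t%s", names(map), unname(map))

# Minimal GFF3 for one gene with given exons (1-based closed), one mRNA.
gff3_gene <- function(gene_id, scaffold, starts, ends, strand = "+",
                      tx_suffix = ".t1") {
  c(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            scaffold, min(starts), max(ends), strand, gene_id),
    sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s%s;Parent=%s",
            scaffold, min(starts), max(ends), strand, gene_id, tx_suffix, gene_id),
    sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s%s",
            scaffold, starts, ends, strand, gene_id, tx_suffix))
}

gff3_file <- function(...) write_tmp(c("##gff-version 3", ...), ".gff3")

# Nine-tip tree used for clade-placement simulations: the query sits inside
# a bacterial clade, with fungal and arthropod clades and an archaeal
# outgroup; all edges <= 0.3 substitutions/site.
clade_sim_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Q:0.1,B1:0.1):0.15,(B2:0.1,B3:0.1):0.15):0.15,",
    "((F1:0.15,F2:0.15):0.2,(A1:0.15,A2:0.15):0.2):0.15,O:0.3);"))
}

clade_sim_taxa <- function() {
  c(B1 = "bacterial", B2 = "bacterial", B3 = "bacterial",
    F1 = "other_eukaryote", F2 = "other_eukaryote",
    A1 = "arthropod", A2 = "arthropod", O = "archaeal")
}
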