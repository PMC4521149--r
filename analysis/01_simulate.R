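#!/usr/bin/env Rscript
# Generate the synthetic study genome: 60 host genes, 10 planted horizontal
# transfers on host scaffolds, 10 bacterial-contaminant scaffolds, with
# taxon-partitioned hit tables and an RNA-seq coverage track. Output lands
# under results/sim/ and is consumed by 02_screen.R.

suppressPackageStartupMessages(library(hgtscreen))

out_dir <- "results/sim"
cfg <- sim_config(seed = 1)
sim <- simulate_inputs(cfg, out_dir)

message(sprintf("wrote synthetic inputs to %s/", out_dir))
message(sprintf("  %d genes total: %d host, %d hgt, %d contaminant",
                nrow(sim$truth),
                sum(sim$truth$label == "host"),
                sum(sim$truth$label == "hgt"),
                sum(sim$truth$label == "contaminant")))
message(sprintf("  log10 e-value means: self %g, cross %g (sd %g)",
                cfg$mu_log10e_self, cfg$mu_log10e_cross, cfg$sigma_log10e))
message(sprintf("  read depth: expressed %g, contaminant %g per exon base",
                cfg$depth_mean_expressed, cfg$depth_mean_contaminant))
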