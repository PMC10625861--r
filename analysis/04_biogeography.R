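#!/usr/bin/env Rscript
# Biogeography and community structure: richness by sample and depth zone
# (observed and rarefied), province-occupancy partitions and endemism for
# the full column and for each depth zone, Bray-Curtis and Jaccard
# distances, nMDS ordination, and the epipelagic-vs-mesopelagic
# beta-dispersion contrast.

suppressPackageStartupMessages(library(zoopvert))

data_dir <- "results/data"
out <- "results"
seed <- 1L
mat <- read_read_matrix(file.path(data_dir, "reads_main.tsv"), "M1")
meta <- read_sample_meta(file.path(data_dir, "sample_meta.tsv"))
rel <- to_relative(mat)

## richness -------------------------------------------------------------------
for (g in c("sample", "depth_zone", "province")) {
  r_obs <- richness(mat, meta, g)
  r_rar <- suppressWarnings(richness(mat, meta, g, rarefy_to = 10000,
                                     seed = seed))
  r_obs$richness_rarefied_10k <- r_rar$richness
  write.table(r_obs, file.path(out, paste0("richness_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
rz <- read.delim(file.path(out, "richness_depth_zone.tsv"))
message(sprintf("Richness: epipelagic %d, mesopelagic %d taxa",
                rz$richness[rz$group == "epipelagic"],
                rz$richness[rz$group == "mesopelagic"]))

## occupancy partitions -------------------------------------------------------
for (sc in c("full", "epipelagic", "mesopelagic")) {
  part <- occupancy_partition(mat, meta, sc)
  write.table(data.frame(subset = names(part$counts), n_taxa = part$counts),
              file.path(out, paste0("occupancy_", sc, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s scope: %d taxa; endemism %s; cosmopolitan %.0f%%", sc,
    part$n_taxa_observed,
    paste(sprintf("%s %.0f%%", names(part$endemism_pct),
                  part$endemism_pct), collapse = ", "),
    part$cosmopolitan_pct))
}

## distances, ordination, beta-dispersion --------------------------------------
d_bray <- distance_matrix(rel, "bray_curtis")
d_jac <- distance_matrix(mat, "jaccard")
write.csv(as.matrix(d_bray), file.path(out, "bray_curtis.csv"))
write.csv(as.matrix(d_jac), file.path(out, "jaccard.csv"))

ord <- nmds_ordination(d_bray, k = 2, n_starts = 20, seed = seed)
write.table(data.frame(sample_id = rownames(ord$points), ord$points,
                       stress = ord$stress),
            file.path(out, "nmds_bray.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("nMDS stress = %.3f", ord$stress))

zones <- depth_zone(meta)
rows <- lapply(list(bray_curtis = d_bray, jaccard = d_jac), function(d) {
  bd <- beta_dispersion(d, zones, n_perm = 999, seed = seed)
  data.frame(metric = attr(d, "metric"), F = bd$F,
             df1 = bd$df[1], df2 = bd$df[2], p_anova = bd$p_anova,
             p_perm = bd$p_perm,
             mean_dist_epipelagic = bd$group_means["epipelagic"],
             mean_dist_mesopelagic = bd$group_means["mesopelagic"])
})
bd_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.table(bd_tab, file.path(out, "beta_dispersion.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(bd_tab))) {
  message(sprintf(
    "beta-dispersion (%s): F(%d,%d) = %.2f, p = %.2g; epi %.2f vs meso %.2f",
    bd_tab$metric[i], bd_tab$df1[i], bd_tab$df2[i], bd_tab$F[i],
    bd_tab$p_anova[i], bd_tab$mean_dist_epipelagic[i],
    bd_tab$mean_dist_mesopelagic[i]))
}
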