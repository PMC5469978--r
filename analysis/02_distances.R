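#!/usr/bin/env Rscript
# Population-pairwise genetic distances (D_PS, Weir-Cockerham theta) and
# geographic distances, their correlation, and Mantel tests of isolation
# by distance. Writes labelled matrices and a summary table.

library(popgravity)

tab <- read_genotypes("results/data/genotypes.csv", "csv")
sites <- read_sites("results/data/sites.csv")
dir.create("results/distances", showWarnings = FALSE, recursive = TRUE)

dps <- dps_matrix(tab)
fst <- fst_matrix(tab)
geo <- geographic_matrix(sites)

write_dist_matrix(dps, "results/distances/dps.csv")
write_dist_matrix(fst, "results/distances/fst.csv")
write_dist_matrix(geo, "results/distances/geographic.csv")

m_dps <- mantel_test(dps, geo, n_perm = 999, seed = 101)
m_fst <- mantel_test(fst, geo, n_perm = 999, seed = 102)

summary <- data.frame(
  statistic = c("mean_dps", "mean_theta", "mean_geographic_km",
                "cor_dps_theta", "mantel_r_dps", "mantel_p_dps",
                "mantel_r_theta", "mantel_p_theta"),
  value = c(mean(dps[lower.tri(dps)]), mean(fst[lower.tri(fst)]),
            mean(geo[lower.tri(geo)]) / 1000,
            matrix_correlation(dps, fst),
            m_dps$r, m_dps$p, m_fst$r, m_fst$p))
write.csv(summary, "results/distances/summary.csv", row.names = FALSE)

cat(sprintf("mean D_PS %.3f, mean theta %.3f, cor(D_PS, theta) %.2f\n",
            summary$value[1], summary$value[2], summary$value[4]))
cat(sprintf("Mantel (D_PS vs distance): r = %.2f, p = %.3f\n",
            m_dps$r, m_dps$p))
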