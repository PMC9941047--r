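#!/usr/bin/env Rscript
# How well are multiplicity and clonality recovered as sequencing depth
# and purity vary? Sweeps the generator over a depth x purity grid and
# scores the estimates against truth.

suppressPackageStartupMessages(library(ptmb))

dir.create("results", showWarnings = FALSE)

arms <- read_arms("hg19")
arms <- arms[sub("^chr", "", arms$chrom) %in% c("19", "20", "21", "22"), ]

grid <- expand.grid(depth = c(60, 100, 250), purity = c(0.4, 0.6, 0.8))
rows <- lapply(seq_len(nrow(grid)), function(i) {
  params <- sim_params(arms = arms, mean_depth = grid$depth[i],
                       purity_range = rep(grid$purity[i], 2),
                       mutation_rate = 2)
  hits <- 0; total <- 0; cat_hits <- 0; cat_total <- 0
  for (s in 1:5) {
    sim <- simulate_profile(params, seed = 1000 * i + s)
    muts <- simulate_mutations(sim, params, seed = 2000 * i + s)
    ann <- annotate_mutations(muts, sim$profile)
    sel <- muts$true_clonal & muts$true_m %in% 1:3 &
      !is.na(ann$multiplicity)
    hits <- hits + sum(ann$multiplicity[sel] == muts$true_m[sel])
    total <- total + sum(sel)
    ok <- !is.na(ann$category) & ann$category != "EXCLUDED"
    cat_hits <- cat_hits + sum(ann$category[ok] == muts$true_category[ok])
    cat_total <- cat_total + sum(ok)
  }
  data.frame(depth = grid$depth[i], purity = grid$purity[i],
             m_recovery = hits / total,
             category_recovery = cat_hits / cat_total,
             n_clonal = total)
})
out <- do.call(rbind, rows)
write.table(out, "results/multiplicity_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(out, row.names = FALSE)
message("wrote results/multiplicity_recovery.tsv")
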