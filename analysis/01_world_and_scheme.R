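#!/usr/bin/env Rscript
# Step 1: assemble the study world and sampling scheme.
# Builds the default 75x47 lattice, loads the packaged 23-sample scheme,
# maps every sample to its deme and zone, and writes the resolved table.
# Also regroups the synthetic per-genome metadata to confirm the
# grouping rule reproduces the published sample structure (23 samples,
# 267 summary statistics).

library(demicabc)
dir.create("results", showWarnings = FALSE)

world <- world_grid()
scheme <- study_scheme()
demes <- scheme_demes(world, scheme)
tab <- cbind(as.data.frame(scheme), deme = demes,
             zone = zone_of(world, demes))
write.table(tab, "results/01_study_scheme.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d samples on %d demes; %d north / %d south of 43.2N\n",
            nrow(tab), length(unique(tab$deme)),
            sum(tab$zone == "north"), sum(tab$zone == "south")))

md <- study_genome_metadata()
grp <- group_genomes(data.frame(genome = md$genome, site = md$site,
                                layer = md$layer, x = md$x, y = md$y,
                                age = md$age))
cat(sprintf("grouping the %d genomes gives %d samples and %d statistics\n",
            nrow(md), nrow(grp$samples), expected_length(grp)))
write.table(grp$samples, "results/01_grouping.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
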