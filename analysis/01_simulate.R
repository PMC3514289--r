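#!/usr/bin/env Rscript
# Generate the full set of synthetic inputs (phenotype TSV, TPS
# landmarks, GENEPOP genotypes, FASTA alignment, diet counts) under the
# default study conditions, and write them under results/data/.

library(lakestream)

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config()

ph <- gen_phenotypes(cfg, seed = derive_seed(seed, "gen", "phenotypes"))
write_phenotypes(ph, file.path(out, "phenotypes.tsv"))
cat(sprintf("phenotypes: %d individuals over %d sites (lake mean CS %.1f mm, stream %.1f mm)\n",
            nrow(ph), length(unique(ph$site)),
            mean(ph$centroid_size[ph$habitat == "lake"]),
            mean(ph$centroid_size[ph$habitat == "stream"])))

lms <- gen_landmarks(cfg, target_cs = ph$centroid_size,
                     specimen_ids = ph$individual_id,
                     seed = derive_seed(seed, "gen", "landmarks"))
write_tps(lms, file.path(out, "landmarks.tps"))
cat(sprintf("landmarks: %d specimens x 16 landmarks\n", length(lms)))

cfg_ms <- cfg
cfg_ms$microsats$pop_names <- cfg$phenotypes$sites$site
cfg_ms$microsats$n_pops <- length(cfg_ms$microsats$pop_names)
g <- gen_microsats(cfg_ms, seed = derive_seed(seed, "gen", "microsats"))
write_genepop(g, file.path(out, "microsats.gen"))
cat(sprintf("genotypes: %d individuals x %d loci, %d populations\n",
            length(g$ids), length(g$loci), length(populations(g))))

aln <- gen_dloop(cfg, seed = derive_seed(seed, "gen", "dloop"))
write_fasta_alignment(aln, file.path(out, "dloop.fasta"))
cat(sprintf("alignment: %d sequences x %d bp\n", length(aln$seqs),
            aln$length))

diet <- gen_diet(cfg, seed = derive_seed(seed, "gen", "diet"))
write.table(diet, file.path(out, "diet_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("diet: %d stomachs across %d sites\n", nrow(diet),
            length(unique(diet$site))))
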