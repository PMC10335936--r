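#!/usr/bin/env Rscript
# Build the standard synthetic study conditions: a 5 Mb chromosome with
# oriented telomeres, subtelomeric blocks, satellite arrays and a planted
# 2 Mb centromere, plus a 1 Mb chromosome with a 200-copy rDNA-like array
# (70/30 haplotype mixture, 20-copy inversion). Writes the genome and its
# companion files to scratch/ and a feature summary to results/.

suppressPackageStartupMessages(library(repeatscope))

seed <- 1L
dir.create("scratch/standard_genome", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- standard_genome_config(seed)
genome <- make_genome(cfg)

write_fasta(genome$sequences, "scratch/standard_genome/genome.fa")
write_truth_bed(genome$truth, "scratch/standard_genome/truth.bed")
write_fasta(setNames(apply(genome$rdna$msa, 1, paste, collapse = ""),
                     rownames(genome$rdna$msa)) ,
            "scratch/standard_genome/rdna_copies.aln.fa")

track <- simulate_enrichment_track(genome, attr(cfg, "centromere_truth"),
                                   inside_level = 8, outside_level = 1,
                                   noise_sd = 0.5, seed = seed + 4L)
write_bedgraph(track, "scratch/standard_genome/cenh3_enrichment.bedgraph")

reads <- simulate_reads(genome, n_reads = 1000,
                        artifact_rates = c(fused = 0.10, symmetrical = 0.05,
                                           chimeric = 0.05),
                        seed = seed + 2L)
write_fastq(reads$reads, "scratch/standard_genome/reads.fq")
write.table(reads$truth$classes, "scratch/standard_genome/read_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

feat <- genome$truth
summary_tab <- aggregate(cbind(bases = feat$end - feat$start),
                         by = list(kind = feat$kind, label = feat$label),
                         FUN = sum)
summary_tab$n <- aggregate(feat$start,
                           by = list(feat$kind, feat$label),
                           FUN = length)$x
write.table(summary_tab[order(summary_tab$kind, summary_tab$label), ],
            "results/01_genome_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Simulated ", length(genome$sequences), " chromosomes (",
        sum(nchar(genome$sequences)), " bp) with ", nrow(feat),
        " planted truth features and ", length(reads$reads),
        " reads; class mix:")
print(table(reads$truth$classes$class))
message("Summary written to results/01_genome_summary.tsv")
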