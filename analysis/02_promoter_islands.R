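#!/usr/bin/env Rscript
# Promoter CpG-island screen on a synthetic candidate promoter: builds a
# 3 kb promoter with a CpG-dense segment straddling the TSS (22 CpGs inside
# -290..+117), detects islands, flags the candidate, and extracts the
# TSS-relative bisulfite analysis region.

suppressMessages(library(methmark))
seed <- 20260921L
dir.create("results", showWarnings = FALSE)
set.seed(seed)

# synthetic promoter: AT-rich background, CpG-island segment around the TSS
sample_bases <- function(n, prob) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = prob), collapse = "")
}
make_island_segment <- function(len, cpg_at) {
  # cpg_at: 1-based positions within the segment for planted CpG cytosines
  repeat {
    b <- strsplit(sample_bases(len, c(0.23, 0.20, 0.35, 0.22)), "")[[1]]
    cg <- which(b[-len] == "C" & b[-1] == "G")
    b[cg] <- "T"                         # strip accidental CpGs
    b[cpg_at] <- "C"; b[cpg_at + 1] <- "G"
    s <- paste(b, collapse = "")
    n_found <- length(gregexpr("(?=CG)", s, perl = TRUE)[[1]])
    if (n_found == length(cpg_at)) return(s)
  }
}
tss <- 1500L
island_start_rel <- -350L; island_len <- 600L
# 22 CpGs inside the -290..+117 analysis region, flanked by 5 on each side
rel_cpgs <- c(round(seq(-340, -305, length.out = 5)),
              round(seq(-285, 110, length.out = 22)),
              round(seq(130, 240, length.out = 5)))
cpg_at <- rel_cpgs - island_start_rel + 1L
upstream <- sample_bases(tss + island_start_rel, c(0.33, 0.17, 0.17, 0.33))
segment <- make_island_segment(island_len, cpg_at)
downstream <- sample_bases(3000 - nchar(upstream) - island_len,
                           c(0.33, 0.17, 0.17, 0.33))
promoter <- paste0(upstream, segment, downstream)

islands <- find_cpg_islands(promoter)
cat(sprintf("Detected %d CpG island(s):\n", nrow(islands)))
print(islands)
flag <- annotate_candidates(list(candidate = list(sequence = promoter,
                                                  tss_offset = tss)))
cat(sprintf("Candidate flagged for a promoter-proximal island: %s\n",
            flag$flagged[1]))

reg <- extract_region(promoter, tss_offset = tss, -290, 117)
cat(sprintf("Analysis region -290..+117: %d bases, %d CpGs\n",
            nchar(reg$sequence), length(reg$cpg_offsets)))

write_islands_bed(islands, "results/promoter_islands.bed",
                  chrom = "synthetic_promoter")
write_clone_fasta(setNames(reg$sequence, "analysis_region_-290_+117"),
                  "results/analysis_region_synthetic.fa")
write.table(data.frame(cpg_offset = reg$cpg_offsets),
            "results/analysis_region_cpgs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_manifest("results/promoter_manifest.json", "promoter_islands",
               outputs = c("results/promoter_islands.bed",
                           "results/analysis_region_synthetic.fa",
                           "results/analysis_region_cpgs.tsv"),
               parameters = list(region = "-290..+117",
                                 island_criteria = "length>=200, GC>=0.5, OE>=0.6"),
               seed = seed)
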