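#!/usr/bin/env Rscript
# One-command pipeline over a simulated cohort: simulate, preprocess,
# extract pupil/behavior/microsaccade measures, run the 2x2 rmANOVAs and
# write all artifacts (per-trial results, condition tables, stats JSON).
#
#   Rscript scripts/run_pipeline.R --participants 10 --seed 7 --out out/
#   Rscript scripts/run_pipeline.R --seed 7 --out out/ --no-microsaccades

suppressPackageStartupMessages(library(pupilgaze))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(participants = 10L, seed = 1L, out = "pipeline_out",
            microsaccades = TRUE)
i <- 1
while (i <= length(args)) {
  a <- args[i]
  if (a == "--participants") { opt$participants <- as.integer(args[i + 1]); i <- i + 2 }
  else if (a == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (a == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else if (a == "--no-microsaccades") { opt$microsaccades <- FALSE; i <- i + 1 }
  else stop("unknown argument: ", a)
}

sc <- sim_config(n_participants = opt$participants, seed = opt$seed)
res <- run_pipeline(sc, pipeline_config(), microsaccades = opt$microsaccades)
write_report(res, opt$out)
write_trial_table(res$trials, file.path(opt$out, "trials.csv"))

cat(sprintf("participants: %d  trials: %d  excluded: %d (%.1f%%)\n",
            opt$participants, nrow(res$trials),
            res$exclusions$n_excluded, res$exclusions$pct_excluded))
for (nm in names(res$anovas)) {
  cat("\n==", nm, "==\n")
  print(res$anovas[[nm]], row.names = FALSE)
}
cat("\nartifacts written to ", opt$out, "\n", sep = "")
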