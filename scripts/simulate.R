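#!/usr/bin/env Rscript
# Thin command-line front end over the striatlearn package.
#
#   Rscript scripts/simulate.R simulate --config cfg.yaml --out results/
#   Rscript scripts/simulate.R traces   --delay-grid 0,2500,10 --out results/
#   Rscript scripts/simulate.R sweep    --delays 0,250,500,1000,2500 \
#                                       --reps 20 --out results/
#
# `simulate` runs the condition described by a YAML config and writes
# curves.csv / trials.csv / manifest.json. `traces` dumps overlap-vs-delay
# curves for a canonical response-locked spike train. `sweep` runs a grid
# of fixed delays and writes final-block accuracy per delay.

suppressPackageStartupMessages({
  library(optparse)
  library(striatlearn)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1)
  stop("usage: simulate.R <simulate|traces|sweep> [options]")
cmd <- argv[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "results"),
  make_option("--delay-grid", type = "character", default = "0,2500,10",
              dest = "delay_grid", help = "lo,hi,step in ms"),
  make_option("--delays", type = "character", default = "0,500,1000,2500"),
  make_option("--reps", type = "integer", default = 50),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--keep-trials", action = "store_true", default = FALSE,
              dest = "keep_trials")
))
opt <- parse_args(parser, args = argv[-1])
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

if (cmd == "simulate") {
  cfg <- load_config(opt$config)
  spec <- config_condition(cfg)
  message("running: ", spec$task, " task, ", spec$n_blocks, " blocks x ",
          spec$trials_per_block, " trials, ", spec$n_replications,
          " replications")
  lc <- run_condition(spec, keep_trials = opt$keep_trials, progress = TRUE)
  print(lc)
  write_results(list(run = lc), opt$out, config = cfg)
} else if (cmd == "traces") {
  dg <- as.numeric(strsplit(opt$delay_grid, ",")[[1]])
  set.seed(opt$seed)
  spk <- seq(-250, 0, by = 12.5)  # response-locked striatal burst
  best <- optimal_delay(spk, delay_grid = seq(dg[1], dg[2], by = dg[3]))
  ov <- attr(best, "overlap")
  write.csv(ov, file.path(opt$out, "overlap_vs_delay.csv"),
            row.names = FALSE)
  message(sprintf("optimal delay: %g ms (curve in %s)", as.numeric(best),
                  file.path(opt$out, "overlap_vs_delay.csv")))
} else if (cmd == "sweep") {
  delays <- as.numeric(strsplit(opt$delays, ",")[[1]])
  res <- lapply(delays, function(d) {
    lc <- run_condition(condition_spec(delay_ms = d, n_blocks = 5,
                                       n_replications = opt$reps,
                                       seed = opt$seed))
    data.frame(delay_ms = d,
               final_block_accuracy = lc$curve$mean_accuracy[5],
               se = lc$curve$se_accuracy[5])
  })
  df <- do.call(rbind, res)
  print(df, row.names = FALSE)
  write.csv(df, file.path(opt$out, "delay_sweep.csv"), row.names = FALSE)
} else {
  stop("unknown subcommand: ", cmd)
}
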