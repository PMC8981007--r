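#!/usr/bin/env Rscript
# Thin command-line wrapper over rdmprec::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config run.yaml --out DIR [--seed INT]

suppressPackageStartupMessages({
  library(optparse)
  library(rdmprec)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (defaults used when omitted)"),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration seed")
)))

cfg <- if (is.null(opts$config)) run_config() else read_run_config(opts$config)
if (!is.null(opts$seed)) {
  cfg <- run_config(sim = cfg$sim, thresholds = cfg$thresholds,
                    model = cfg$model, eval = cfg$eval, seed = opts$seed)
}
run_pipeline(cfg, opts$out)
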