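#!/usr/bin/env Rscript

# Thin command-line front end over the cleftsim package:
#   cleftsim run --config FILE [--protocol NAME] --seed N --out DIR
#                [--dt X] [--duration Y] [--quiet]

suppressPackageStartupMessages({
  library(optparse)
  library(cleftsim)
})

parser <- OptionParser(
  usage = "cleftsim run [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "configuration file (JSON or YAML); defaults used if omitted"),
    make_option("--protocol", type = "character", default = NULL,
                help = "named protocol (voltage_sweep, ap_pairing, nmdg, antagonist, mglur_pairing, convergence); plain run if omitted"),
    make_option("--seed", type = "integer", default = NULL,
                help = "seed (mandatory)"),
    make_option("--seeds", type = "character", default = NULL,
                help = "comma-separated seed list for protocols (default: seed..seed+9)"),
    make_option("--out", type = "character", default = "cleftsim_out",
                help = "output directory [default %default]"),
    make_option("--dt", type = "double", default = NULL, help = "time step (ms)"),
    make_option("--duration", type = "double", default = NULL,
                help = "run duration (ms)"),
    make_option("--quiet", action = "store_true", default = FALSE,
                help = "suppress progress messages")
  ))
argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0 || argv[1] != "run") {
  print_help(parser)
  quit(status = if (length(argv)) 1 else 0)
}
opt <- parse_args(parser, args = argv[-1])
if (is.null(opt$seed)) stop("--seed is mandatory: no run proceeds without an explicit seed")

say <- function(...) if (!opt$quiet) message(...)

cfg <- if (is.null(opt$config)) list() else unclass(load_config(opt$config))
cfg$run$seed <- opt$seed
if (!is.null(opt$dt)) cfg$run$dt_ms <- opt$dt
if (!is.null(opt$duration)) cfg$run$duration_ms <- opt$duration

dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
log_file <- file.path(opt$out, "run.log")
log_con <- file(log_file, "w")
logmsg <- function(...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(line, log_con); say(line)
}

logmsg("cleftsim ", as.character(utils::packageVersion("cleftsim")),
       " seed=", opt$seed)
write_config(cfg, file.path(opt$out, "resolved_config.json"))

if (is.null(opt$protocol)) {
  logmsg("plain run: dt=", resolve_config(cfg)$run$dt_ms, " ms, duration=",
         resolve_config(cfg)$run$duration_ms, " ms")
  ts <- run_simulation(cfg)
  write_traceset(ts, opt$out)
  logmsg(sprintf("done in %.1f s; peak |I_AMPAR| = %.2f pA", ts$wall_s,
                 max(abs(ts$traces$i_ampar_pA))))
} else {
  seeds <- if (is.null(opt$seeds)) opt$seed + 0:9
           else as.integer(strsplit(opt$seeds, ",")[[1]])
  logmsg("protocol ", opt$protocol, " over seeds ",
         paste(seeds, collapse = ","))
  t0 <- proc.time()[["elapsed"]]
  rep <- run_protocol(opt$protocol, cfg, seeds = seeds)
  # summary: everything scalar/vector-numeric in the report
  flat <- Filter(function(x) is.numeric(x) && length(x) <= 32,
                 rep[!vapply(rep, is.data.frame, logical(1))])
  jsonlite::write_json(flat, file.path(opt$out, "protocol_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(rep)) {
    if (is.data.frame(rep[[nm]]))
      utils::write.csv(rep[[nm]], file.path(opt$out, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  logmsg(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
}
close(log_con)
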