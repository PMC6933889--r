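# Command-line front end. Each subcommand is a thin dispatcher onto the
# exported functions; machine-readable artifacts go to files, logging to
# stderr, and every run writes a provenance JSON (config hash, seed,
# package version) next to its outputs.

.cli_usage <- function() {
  paste(
    "usage: splicescan <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  simulate      --config c.yaml --out dir/ [--seed N]",
    "  build-dataset --fasta g.fa --gtf a.gtf --out dir/ --L 400",
    "                [--n-per-class N] [--seed N] [--rebalance-ratio R]",
    "  train         --fasta g.fa --manifest d.tsv --L 400 --out model/",
    "                [--epochs N] [--batch-size N] [--lr X] [--seed N]",
    "  mine          --fasta g.fa --gtf a.gtf --manifest d.tsv --L 400",
    "                --eval-region chr1:1-50000 --out dir/",
    "                [--max-iterations N] [--patience N] [--epochs N]",
    "                [--seed N] [--resume prev_dir/]",
    "  scan          --model m/ --fasta g.fa --region chr1:1-50000",
    "                --out calls.tsv [--min-score X] [--step N]",
    "  evaluate      --calls calls.tsv --sites sites.tsv --recall X",
    "                --out report.json [--tolerance N]",
    "  attribute     --model m/ --fasta g.fa --sites sites.tsv",
    "                --class donor --out profile.tsv [--n N] [--flank N]",
    sep = "\n")
}

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("usage error: unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args)) stop("usage error: flag --", key,
                                " needs a value")
    flags[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.cli_flag <- function(flags, name, default = NULL, required = FALSE) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (required) stop("usage error: missing --", gsub("_", "-", name))
    return(default)
  }
  v
}

.cli_provenance <- function(out_dir, flags, config_path = NULL) {
  prov <- list(
    package = "splicescan",
    version = as.character(utils::packageVersion("splicescan")),
    seed = .cli_flag(flags, "seed", default = NA),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    flags = flags,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

#' Command-line entry point
#'
#' Dispatches the `splicescan` subcommands (`simulate`, `build-dataset`,
#' `train`, `mine`, `scan`, `evaluate`, `attribute`). Invoked by the
#' `inst/scripts/splicescan` Rscript; callable directly with a character
#' vector of arguments.
#'
#' @param args Character vector, e.g. `c("simulate", "--config", "c.yaml",
#'   "--out", "dir")`.
#' @return Integer exit status, invisibly (0 on success).
#' @export
splicescan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    message(.cli_usage())
    return(invisible(if (length(args) == 0L) 2L else 0L))
  }
  if (args[1L] == "--version") {
    message("splicescan ", utils::packageVersion("splicescan"))
    return(invisible(0L))
  }
  sub <- args[1L]
  handler <- switch(sub,
    "simulate" = .cli_simulate, "build-dataset" = .cli_build_dataset,
    "train" = .cli_train, "mine" = .cli_mine, "scan" = .cli_scan,
    "evaluate" = .cli_evaluate, "attribute" = .cli_attribute, NULL)
  if (is.null(handler)) {
    message("usage error: unknown subcommand '", sub, "'\n", .cli_usage())
    return(invisible(2L))
  }
  flags <- tryCatch(.cli_parse_flags(args[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    return(invisible(2L))
  }
  status <- tryCatch({ handler(flags); 0L }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_simulate <- function(flags) {
  out <- .cli_flag(flags, "out", required = TRUE)
  config_path <- .cli_flag(flags, "config")
  overrides <- if (!is.null(config_path)) yaml::read_yaml(config_path)
               else list()
  if (!is.null(flags$seed)) overrides$seed <- as.integer(flags$seed)
  cfg <- do.call(sim_config, overrides)
  sim <- simulate_genome(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_sim_genome(sim, out)
  yaml::write_yaml(.config_to_yaml(cfg), file.path(out, "config.yaml"))
  .cli_provenance(out, flags, config_path)
  message("simulated ", nchar(sim$genome), " nt, ", nrow(sim$sites),
          " splice sites -> ", out)
}

# round-trippable YAML image of a sim_config
.config_to_yaml <- function(cfg) {
  x <- unclass(cfg)
  for (f in c("exons_per_gene", "exon_len", "intron_len", "intergenic_len"))
    if (inherits(x[[f]], "sim_dist")) x[[f]] <- unclass(x[[f]])
  x$donor_pwm <- as.list(as.data.frame(x$donor_pwm))
  x$acceptor_pwm <- as.list(as.data.frame(x$acceptor_pwm))
  x$background <- as.list(x$background)
  x
}

.cli_build_dataset <- function(flags) {
  genome <- read_fasta(.cli_flag(flags, "fasta", required = TRUE))
  exons <- read_gtf_exons(.cli_flag(flags, "gtf", required = TRUE))
  out <- .cli_flag(flags, "out", required = TRUE)
  L <- as.integer(.cli_flag(flags, "L", required = TRUE))
  n <- as.integer(.cli_flag(flags, "n_per_class", default = "1000"))
  seed <- as.integer(.cli_flag(flags, "seed", default = "1"))
  ratio <- .cli_flag(flags, "rebalance_ratio")
  sites <- extract_splice_sites(exons, genome)
  ds <- build_initial_dataset(sites, genome, L, n, seed = seed)
  if (!is.null(ratio))
    ds <- rebalance_positive_set(ds, as.numeric(ratio), seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_dataset_tsv(ds, file.path(out, "dataset.tsv"))
  write_sites_tsv(sites, file.path(out, "sites.tsv"))
  .cli_provenance(out, flags)
  message("dataset: ", paste(names(class_counts(ds)), class_counts(ds),
                             sep = "=", collapse = " "), " -> ", out)
}

.cli_train <- function(flags) {
  genome <- read_fasta(.cli_flag(flags, "fasta", required = TRUE))
  L <- as.integer(.cli_flag(flags, "L", required = TRUE))
  ds <- read_dataset_tsv(.cli_flag(flags, "manifest", required = TRUE),
                         genome, L)
  out <- .cli_flag(flags, "out", required = TRUE)
  seed <- as.integer(.cli_flag(flags, "seed", default = "1"))
  cfg <- train_config(
    learning_rate = as.numeric(.cli_flag(flags, "lr", default = "1e-4")),
    epochs = as.integer(.cli_flag(flags, "epochs", default = "40")),
    batch_size = as.integer(.cli_flag(flags, "batch_size", default = "50")),
    seed = seed)
  parts <- split_dataset(ds, seed = seed)
  model <- build_model(model_spec(L = L), seed = seed)
  model <- train_model(model, parts$train, parts$validation, cfg)
  p <- predict_proba(model, parts$test)
  rep <- classification_metrics(parts$test$windows$label, p)
  save_model(model, out)
  write_report_json(rep, file.path(out, "test_report.json"))
  .cli_provenance(out, flags)
  message("test accuracy ", round(rep$accuracy, 4), "; model -> ", out)
}

.cli_mine <- function(flags) {
  genome <- read_fasta(.cli_flag(flags, "fasta", required = TRUE))
  exons <- read_gtf_exons(.cli_flag(flags, "gtf", required = TRUE))
  L <- as.integer(.cli_flag(flags, "L", required = TRUE))
  out <- .cli_flag(flags, "out", required = TRUE)
  seed <- as.integer(.cli_flag(flags, "seed", default = "1"))
  resume <- .cli_flag(flags, "resume")
  start_iteration <- 1L
  prior <- NULL
  if (!is.null(resume)) {
    # continue from the last recorded iteration of a previous run; the
    # per-iteration seeds depend only on (seed, iteration index)
    prior <- utils::read.table(file.path(resume, "iterations.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    start_iteration <- max(prior$iteration) + 1L
    ds <- read_dataset_tsv(file.path(resume, "dataset.tsv"), genome, L)
  } else {
    ds <- read_dataset_tsv(.cli_flag(flags, "manifest", required = TRUE),
                           genome, L)
  }
  sites <- extract_splice_sites(exons, genome)
  res <- iterative_reconstruction(
    ds, genome, exons, sites,
    eval_region = .cli_flag(flags, "eval_region", required = TRUE),
    spec = model_spec(L = L),
    config = train_config(
      epochs = as.integer(.cli_flag(flags, "epochs", default = "40")),
      seed = seed),
    max_iterations = as.integer(.cli_flag(flags, "max_iterations",
                                          default = "100")),
    patience = as.integer(.cli_flag(flags, "patience", default = "3")),
    start_iteration = start_iteration,
    prior_fp_counts = if (is.null(prior)) numeric()
                      else prior$eval_fp_count)
  iters <- rbind(prior, res$iterations)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.table(iters, file.path(out, "iterations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_dataset_tsv(res$dataset, file.path(out, "dataset.tsv"))
  save_model(res$model, file.path(out, "model"))
  .cli_provenance(out, flags)
  message(nrow(res$iterations), " iterations; final eval FP ",
          utils::tail(res$iterations$eval_fp_count, 1L), " -> ", out)
}

.cli_scan <- function(flags) {
  model <- load_model(.cli_flag(flags, "model", required = TRUE),
                      expect_classes = 3L)
  genome <- read_fasta(.cli_flag(flags, "fasta", required = TRUE))
  out <- .cli_flag(flags, "out", required = TRUE)
  calls <- scan_sequence(
    model, genome, .cli_flag(flags, "region", required = TRUE),
    step = as.integer(.cli_flag(flags, "step", default = "1")),
    min_score = as.numeric(.cli_flag(flags, "min_score", default = "0")))
  write_calls_tsv(calls, out)
  write_calls_bed(calls, sub("\\.tsv$", ".bed", out))
  message(nrow(calls), " calls -> ", out)
}

.cli_evaluate <- function(flags) {
  calls <- read.table(.cli_flag(flags, "calls", required = TRUE),
                      sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sites <- read_sites_tsv(.cli_flag(flags, "sites", required = TRUE))
  rep <- fp_at_recall(
    calls, sites,
    recall_target = as.numeric(.cli_flag(flags, "recall",
                                         required = TRUE)),
    tolerance = as.integer(.cli_flag(flags, "tolerance", default = "0")))
  write_report_json(rep, .cli_flag(flags, "out", required = TRUE))
  message("combined FP at recall ", flags$recall, ": ", rep$combined_fp)
}

.cli_attribute <- function(flags) {
  model <- load_model(.cli_flag(flags, "model", required = TRUE))
  genome <- read_fasta(.cli_flag(flags, "fasta", required = TRUE))
  sites <- read_sites_tsv(.cli_flag(flags, "sites", required = TRUE))
  cls <- .cli_flag(flags, "class", required = TRUE)
  n <- as.integer(.cli_flag(flags, "n", default = "100"))
  flank <- as.integer(.cli_flag(flags, "flank", default = "10"))
  seed <- as.integer(.cli_flag(flags, "seed", default = "1"))
  L <- model$spec$L
  pool <- sites[sites$site_type == cls, , drop = FALSE]
  lens <- nchar(genome)
  pool <- pool[.window_fits(lens[pool$seq_name], pool$boundary, L), ,
               drop = FALSE]
  set.seed(seed)
  pool <- pool[sample.int(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(pool)), function(i)
    extract_window(genome, pool$seq_name[i], pool$boundary[i], L),
    character(1L))
  prof <- average_profile(model, seqs, cls, flank = flank)
  write_profile_tsv(prof, .cli_flag(flags, "out", required = TRUE))
  message("profile over ", prof$n_sequences, " ", cls, " windows -> ",
          flags$out)
}
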