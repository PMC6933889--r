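# Study conditions for the end-to-end checks: a ~210 kb forty-gene genome
# with decoy dimers planted in non-exonic sequence and a 1-in-11
# non-canonical intron rate (so the 10:1 canonical:non-canonical rebalance
# is near its natural composition), window length 100, 1000 windows per
# class, 20 training epochs. Heavy artifacts are computed once per test run
# and cached.
.study_cache <- new.env(parent = emptyenv())

study_sim_config <- function(seed) {
  sim_config(
    n_genes = 40L, exons_per_gene = 27L,
    exon_len = sim_dist("lognormal", meanlog = log(80), sdlog = 0.3,
                        min = 30L),
    intron_len = sim_dist("lognormal", meanlog = log(120), sdlog = 0.35,
                          min = 60L),
    intergenic_len = sim_dist("lognormal", meanlog = log(200), sdlog = 0.4,
                              min = 120L),
    non_canonical_fraction = 1 / 11, decoy_rate = 1, seed = seed)
}

# full pipeline: simulate, build + rebalance dataset (eval gene excluded),
# split, train, then 3 mining iterations against a set-aside gene with
# planted non-canonical sites
run_study_pipeline <- function(seed, epochs = 20L, mining_iterations = 3L) {
  sim <- simulate_genome(study_sim_config(seed))
  regs <- gene_regions(sim$exons, sim$genome)
  # set aside the gene with the most planted non-canonical sites, so the
  # recovery statistic has support
  nc_b <- sim$sites$boundary[!sim$sites$canonical]
  n_nc <- vapply(seq_len(nrow(regs)), function(i)
    sum(nc_b >= regs$start[i] & nc_b <= regs$end[i]), integer(1))
  ev <- regs[which.max(n_nc), ]
  eval_region <- list(seq_name = ev$seq_name, start = ev$start,
                      end = ev$end)
  in_eval <- sim$sites$boundary >= ev$start & sim$sites$boundary <= ev$end
  ds <- build_initial_dataset(sim$sites[!in_eval, ], sim$genome, L = 100L,
                              n_per_class = 1000L, seed = seed)
  w <- ds$windows
  cap <- min(vapply(c("donor", "acceptor"), function(cl)
    floor(sum(w$label == cl & w$canonical) / 10), numeric(1)))
  ds <- rebalance_positive_set(ds, ratio = 10, seed = seed,
                               max_non_canonical = cap)
  parts <- split_dataset(ds, seed = seed)
  cfg <- train_config(epochs = epochs, seed = seed)
  model <- train_model(build_model(model_spec(L = 100L), seed = seed),
                       parts$train, parts$validation, cfg)
  test_prob <- predict_proba(model, parts$test)
  report <- classification_metrics(parts$test$windows$label, test_prob)
  mining <- iterative_reconstruction(
    ds, sim$genome, sim$exons, sim$sites, eval_region,
    spec = model_spec(L = 100L), config = cfg,
    max_iterations = mining_iterations)
  list(sim = sim, eval_region = eval_region, dataset = ds, parts = parts,
       model = model, report = report, mining = mining)
}

study_results <- function(seed = 101L) {
  key <- paste0("run_", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- run_study_pipeline(seed)
  .study_cache[[key]]
}
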