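test_that("scanning equals brute-force per-window classification", {
  sim <- simulate_genome(sim_config(n_genes = 3, exons_per_gene = 3,
                                    seed = 8))
  L <- 20L
  m <- build_model(tiny_spec(L = L), seed = 4)
  m$trained <- TRUE
  region <- list(seq_name = "chr1", start = 101L, end = 700L)
  for (step in c(1L, 3L)) {
    calls <- scan_sequence(m, sim$genome, region, L = L, step = step)
    # oracle: classify every extracted window independently
    cand <- seq(max(region$start, L / 2),
                min(region$end, nchar(sim$genome) - L / 2), by = step)
    seqs <- vapply(cand, function(b)
      extract_window(sim$genome, "chr1", b, L), character(1))
    p <- predict_proba(m, seqs)
    top <- max.col(p, ties.method = "first")
    hit <- m$label_order[top] %in% c("donor", "acceptor")
    expect_equal(calls$boundary, cand[hit])
    expect_equal(calls$site_type, m$label_order[top][hit])
    expect_equal(calls$score, p[cbind(seq_along(top), top)][hit])
  }
})

test_that("scan respects min_score and degenerate models", {
  g <- toy_genome()
  m <- constant_model("non_splice", L = 10L)
  expect_equal(nrow(scan_sequence(m, g, "chr1", L = 10L)), 0L)
  md <- constant_model("donor", L = 10L)
  calls <- scan_sequence(md, g, "chr1", L = 10L)
  expect_equal(calls$boundary, 5:35)  # every position with a full window
  # strictly-sub-1 probabilities never clear min_score = 1
  soft <- constant_model("donor", L = 10L, bias = 2)
  p <- predict_proba(soft, extract_window(g, "chr1", 10L, 10L))
  expect_lt(max(p), 1)
  expect_equal(nrow(scan_sequence(soft, g, "chr1", L = 10L, min_score = 1)),
               0L)
  expect_error(scan_sequence(md, g, "chr1", L = 10L, step = 0L),
               "parameter error")
})

test_that("non-maximum suppression keeps the best call per neighborhood", {
  calls <- data.frame(seq_name = "chr1", boundary = c(10L, 12L, 30L),
                      site_type = "donor", score = c(0.7, 0.9, 0.8),
                      passed_filter = NA)
  out <- splicescan:::.nms_calls(calls, radius = 3L)
  expect_equal(out$boundary, c(12L, 30L))
})

test_that("binary filters share the architecture with a 2-unit output", {
  spec3 <- model_spec(L = 400L)
  spec2 <- model_spec(L = 400L, n_classes = 2L)
  expect_equal(count_parameters(spec2), count_parameters(spec3) - 303L +
                 202L)
  # train filters on a linearly separable toy problem
  L <- 20L
  pos <- learnable_dataset(n_per_class = 15, L = L, seed = 5)$windows
  pos <- pos[pos$label != "non_splice", ]
  neg <- fake_windows(vapply(1:30, function(i)
    paste(rep(c("T", "C"), L / 2), collapse = ""), character(1)),
    rep("non_splice", 30))
  neg$boundary <- 1000L + seq_len(30) * 10L
  neg$predicted_type <- rep(c("donor", "acceptor"), 15)
  filt <- train_binary_filters(
    splicescan:::.new_dataset(pos, L), neg, tiny_spec(L = L),
    train_config(epochs = 15, batch_size = 10, seed = 5,
                 learning_rate = 2e-3))
  expect_equal(length(filt$donor$params$b2), 2L)
  expect_equal(length(filt$acceptor$params$b2), 2L)
  expect_identical(filt$donor$label_order, c("donor", "non_splice"))
  # training accuracy 1.0 on the separable set
  pd <- predict_proba(filt$donor, pos$sequence[pos$label == "donor"])
  pn <- predict_proba(filt$donor, neg$sequence[neg$predicted_type ==
                                                 "donor"])
  expect_true(all(pd[, "donor"] > 0.5))
  expect_true(all(pn[, "donor"] < 0.5))
})

test_that("filtering is a contraction that preserves boundaries and types", {
  g <- toy_genome()
  md <- constant_model("donor", L = 10L)
  calls <- scan_sequence(md, g, "chr1", L = 10L)
  accept_d <- constant_model("donor", L = 10L)
  accept_d$label_order <- c("donor", "non_splice")
  accept_d$params$W2 <- accept_d$params$W2[, 1:2]
  accept_d$params$b2 <- c(50, 0)
  accept_d$spec$n_classes <- 2L
  reject_d <- accept_d
  reject_d$params$b2 <- c(-50, 0)
  accept_a <- accept_d; accept_a$label_order <- c("acceptor", "non_splice")
  # accept-everything filters: identity with passed_filter TRUE
  kept <- filter_calls(calls, accept_d, accept_a, g, L = 10L)
  expect_equal(kept$boundary, calls$boundary)
  expect_equal(kept$site_type, calls$site_type)
  expect_true(all(kept$passed_filter))
  # reject-everything filters: empty
  none <- filter_calls(calls, reject_d, accept_a, g, L = 10L)
  expect_equal(nrow(none), 0L)
  # missing filter for an observed type is a configuration error
  expect_error(filter_calls(calls, NULL, accept_a, g, L = 10L),
               "configuration error")
})

test_that("calls export to TSV and BED with the coordinate shift", {
  calls <- data.frame(seq_name = "chr1", boundary = c(10L, 20L),
                      site_type = c("donor", "acceptor"),
                      score = c(0.9, 0.25), passed_filter = NA)
  d <- withr::local_tempdir()
  write_calls_tsv(calls, file.path(d, "c.tsv"))
  back <- read.table(file.path(d, "c.tsv"), sep = "\t", header = TRUE)
  expect_equal(back$boundary, calls$boundary)
  write_calls_bed(calls, file.path(d, "c.bed"))
  bed <- read.table(file.path(d, "c.bed"), sep = "\t")
  expect_equal(bed$V2, c(9L, 19L))   # 0-based half-open
  expect_equal(bed$V3, c(10L, 20L))
  expect_equal(bed$V5, c(900L, 250L))
})
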