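test_that("windows are centered so the junction sits between L/2 and L/2+1", {
  g <- toy_genome()
  expect_equal(extract_window(g, "chr1", 6L, 8L), "CATGGTAA")
  # exact fit: boundary 20 on a 40-nt sequence with L = 40
  expect_equal(extract_window(g, "chr1", 20L, 40L), unname(g[["chr1"]]))
  expect_error(extract_window(g, "chr1", 3L, 8L), "out of range")
  expect_error(extract_window(g, "chr1", 38L, 8L), "out of range")
  expect_error(extract_window(g, "chr1", 6L, 9L), "even")
})

test_that("one-hot encoding follows the A/C/G/T/N convention", {
  expect_equal(one_hot_encode("A")[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(one_hot_encode("T")[1, ], c(A = 0, C = 0, G = 0, T = 1))
  expect_equal(one_hot_encode("N")[1, ], c(A = 0, C = 0, G = 0, T = 0))
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_error(one_hot_encode("ACGU"), "alphabet error")
})

test_that("decode inverts encode on N-free sequences; N rows sum to 0", {
  seqs <- c(random_seqs(20, 15, seed = 3), "ANNAT")
  for (s in seqs) {
    m <- one_hot_encode(s)
    expect_true(all(rowSums(m) %in% c(0, 1)))
    expect_identical(one_hot_decode(m), s)
  }
})

test_that("initial dataset samples all three classes deterministically", {
  cfg <- sim_config(n_genes = 6, exons_per_gene = 4, seed = 42)
  sim <- simulate_genome(cfg)
  ds1 <- build_initial_dataset(sim$sites, sim$genome, L = 30,
                               n_per_class = 8, seed = 9)
  ds2 <- build_initial_dataset(sim$sites, sim$genome, L = 30,
                               n_per_class = 8, seed = 9)
  expect_identical(ds1$windows, ds2$windows)
  expect_equal(unname(class_counts(ds1)), rep(8L, 3))
  expect_false(any(duplicated(
    ds1$windows[c("seq_name", "boundary", "label")])))
  # window sequences really come from the stated coordinates
  for (i in sample(nrow(ds1$windows), 5)) {
    w <- ds1$windows[i, ]
    expect_equal(w$sequence, extract_window(sim$genome, w$seq_name,
                                            w$boundary, 30L))
  }
})

test_that("negative centers are midpoints of adjacent boundaries", {
  sites <- extract_splice_sites(toy_exons(), toy_genome())
  # boundaries 6 and 27: unique midpoint floor((6+27)/2) = 16
  ds <- build_initial_dataset(sites, toy_genome(), L = 10, n_per_class = 1,
                              seed = 1)
  neg <- ds$windows[ds$windows$label == "non_splice", ]
  expect_equal(neg$boundary, 16L)
  expect_error(build_initial_dataset(sites, toy_genome(), L = 10,
                                     n_per_class = 2, seed = 1),
               "capacity error")
})

test_that("positive windows carry the junction dinucleotide iff canonical", {
  cfg <- sim_config(n_genes = 10, exons_per_gene = 3,
                    non_canonical_fraction = 0.3, seed = 2)
  sim <- simulate_genome(cfg)
  L <- 30L
  half <- L %/% 2L
  lens <- nchar(sim$genome)
  ok <- splicescan:::.window_fits(lens[sim$sites$seq_name],
                                  sim$sites$boundary, L)
  for (i in which(ok)) {
    s <- sim$sites[i, ]
    w <- extract_window(sim$genome, s$seq_name, s$boundary, L)
    if (s$site_type == "donor") {
      expect_equal(substr(w, half + 1L, half + 2L) == "GT", s$canonical)
    } else {
      expect_equal(substr(w, half - 1L, half) == "AG", s$canonical)
    }
  }
})

test_that("rebalancing keeps non-canonical windows and subsamples canonical", {
  seqs <- random_seqs(3100 + 250 + 50, 10, seed = 4)
  w <- fake_windows(seqs,
                    labels = rep(c("donor", "acceptor", "non_splice"),
                                 c(3100, 250, 50)),
                    canonical = c(rep(c(TRUE, FALSE), c(3000, 100)),
                                  rep(c(TRUE, FALSE), c(230, 20)),
                                  rep(NA, 50)))
  ds <- splicescan:::.new_dataset(w, 10L)
  out <- rebalance_positive_set(ds, ratio = 10, seed = 1,
                                max_non_canonical = 100)
  ow <- out$windows
  don <- ow[ow$label == "donor", ]
  expect_equal(sum(don$canonical), 1000L)
  expect_equal(sum(!don$canonical), 100L)
  acc <- ow[ow$label == "acceptor", ]
  expect_equal(sum(!acc$canonical), 20L)  # all available, under the cap
  expect_equal(sum(acc$canonical), 200L)
  expect_equal(sum(ow$label == "non_splice"), 50L)  # negatives untouched
  # exact 10:1 per positive class
  for (cl in c("donor", "acceptor")) {
    p <- ow[ow$label == cl, ]
    expect_equal(sum(p$canonical), 10L * sum(!p$canonical))
  }
})

test_that("rebalancing a dataset with no non-canonical positives errors", {
  w <- fake_windows(random_seqs(20, 10), rep(c("donor", "acceptor"), 10),
                    canonical = TRUE)
  ds <- splicescan:::.new_dataset(w, 10L)
  expect_error(rebalance_positive_set(ds, ratio = 10), "capacity error")
})

test_that("splits form a stratified partition with the stated sizes", {
  w <- fake_windows(random_seqs(3000, 10, seed = 5),
                    rep(c("donor", "acceptor", "non_splice"), each = 1000))
  ds <- splicescan:::.new_dataset(w, 10L)
  parts <- split_dataset(ds, test_frac = 0.10, val_frac_of_train = 0.20,
                         seed = 2)
  expect_equal(nrow(parts$test$windows), 300L)
  expect_equal(nrow(parts$validation$windows), 540L)
  expect_equal(nrow(parts$train$windows), 2160L)
  # per-stratum proportions
  expect_equal(unname(class_counts(parts$test)), rep(100L, 3))
  # partition: disjoint and exhaustive
  key <- function(d) paste(d$windows$seq_name, d$windows$boundary,
                           d$windows$label)
  all_keys <- c(key(parts$train), key(parts$validation), key(parts$test))
  expect_equal(sort(all_keys), sort(paste(w$seq_name, w$boundary, w$label)))
  expect_false(any(duplicated(all_keys)))
})

test_that("dataset manifests round-trip through TSV plus the genome", {
  sites <- extract_splice_sites(toy_exons(), toy_genome())
  ds <- build_initial_dataset(sites, toy_genome(), L = 10, n_per_class = 1,
                              seed = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, p)
  back <- read_dataset_tsv(p, toy_genome(), 10L)
  expect_equal(back$windows[order(back$windows$boundary), ],
               ds$windows[order(ds$windows$boundary), ],
               ignore_attr = TRUE)
})
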