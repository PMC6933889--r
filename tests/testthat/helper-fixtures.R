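# Shared fixtures, all built in code.

# 40-nt toy genome with one two-exon transcript: exon 1-6 | intron 7-27 |
# exon 28-40. Bases 7-8 are GT (canonical donor after boundary 6), bases
# 26-27 are AG (canonical acceptor at boundary 27).
toy_genome <- function() {
  c(chr1 = "CCCATGGTAAGTTTTTTTTTTTTTCAGGCCGCCTAATAAA")
}

toy_exons <- function() {
  data.frame(seq_name = "chr1", gene_id = "g1", transcript_id = "t1",
             start = c(1L, 28L), end = c(6L, 40L), strand = "+",
             stringsAsFactors = FALSE)
}

# small fast model spec for unit tests
tiny_spec <- function(L = 20L, n_classes = 3L) {
  model_spec(L = L, kernels = 4L, kernel_size = 5L, fc_units = 8L,
             dropout_rate = 0.30, n_classes = n_classes)
}

# a model whose output is forced to one class via an output bias; the
# default bias saturates the softmax, a smaller one keeps probabilities
# strictly below 1
constant_model <- function(cls, L = 20L, bias = 50) {
  m <- build_model(tiny_spec(L = L), seed = 1L)
  m$params$b2[] <- 0
  m$params$b2[match(cls, m$label_order)] <- bias
  m$trained <- TRUE
  m
}

# windows data.frame holding n copies of each label with given sequences
fake_windows <- function(seqs, labels, canonical = NA) {
  data.frame(seq_name = "chr1", boundary = seq_along(seqs) * 100L,
             sequence = seqs, label = labels, canonical = canonical,
             stringsAsFactors = FALSE)
}

random_seqs <- function(n, L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
}

# a small learnable 3-class problem: class decided by the center dinucleotide
learnable_dataset <- function(n_per_class = 30L, L = 20L, seed = 1L) {
  set.seed(seed)
  half <- L %/% 2L
  mk <- function(cls, core) {
    seqs <- vapply(seq_len(n_per_class), function(i) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      s[(half - 1L):(half + 2L)] <- core
      paste(s, collapse = "")
    }, character(1L))
    fake_windows(seqs, cls)
  }
  w <- rbind(mk("donor", c("A", "G", "G", "T")),
             mk("acceptor", c("A", "G", "G", "C")),
             mk("non_splice", c("T", "C", "A", "A")))
  w$boundary <- seq_len(nrow(w)) * 100L
  splicescan:::.new_dataset(w, L)
}
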