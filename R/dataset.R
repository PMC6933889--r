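LABEL_ORDER <- c("acceptor", "donor", "non_splice")

#' Extract the fixed-length window centered on a junction
#'
#' The window covers `genome[boundary - L/2 + 1 .. boundary + L/2]`, so the
#' junction lies between window positions `L/2` and `L/2 + 1` (for L = 400,
#' between positions 200 and 201).
#'
#' @param genome Named character vector of sequences.
#' @param seq_name Sequence identifier.
#' @param boundary 1-based coordinate of the last base before the junction.
#' @param L Even window length.
#' @return Character scalar of length `L`.
#' @export
extract_window <- function(genome, seq_name, boundary, L) {
  if (L %% 2L != 0L) stop("window length L must be even")
  s <- genome[[seq_name]]
  if (is.null(s)) stop("unknown sequence '", seq_name, "'")
  lo <- boundary - L %/% 2L + 1L
  hi <- boundary + L %/% 2L
  if (lo < 1L || hi > nchar(s))
    stop("window out of range: ", seq_name, ":", lo, "-", hi,
         " (sequence length ", nchar(s), ")")
  substr(s, lo, hi)
}

.window_fits <- function(genome_len, boundary, L) {
  (boundary - L %/% 2L + 1L >= 1L) & (boundary + L %/% 2L <= genome_len)
}

#' One-hot encode a DNA sequence
#'
#' `A -> (1,0,0,0)`, `C -> (0,1,0,0)`, `G -> (0,0,1,0)`, `T -> (0,0,0,1)`,
#' `N -> (0,0,0,0)`.
#'
#' @param sequence Character scalar over `A,C,G,T,N`.
#' @return `L x 4` numeric matrix with columns `A,C,G,T`.
#' @export
one_hot_encode <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N"))
    stop("alphabet error: sequence contains characters outside A,C,G,T,N")
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#' @param m `L x 4` one-hot matrix (all-zero rows decode to `N`).
#' @return Character scalar.
#' @export
one_hot_decode <- function(m) {
  hits <- max.col(m, ties.method = "first")
  hits[rowSums(m) == 0] <- 5L
  paste(c("A", "C", "G", "T", "N")[hits], collapse = "")
}

#' Encode a set of equal-length windows as an array
#'
#' @param sequences Character vector of equal-length sequences.
#' @return Numeric array of shape `(n, L, 4)`.
#' @export
encode_windows <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) stop("no sequences to encode")
  L <- nchar(sequences[1L])
  if (any(nchar(sequences) != L)) stop("shape error: mixed window lengths")
  a <- array(0, dim = c(n, L, 4L))
  for (i in seq_len(n)) a[i, , ] <- one_hot_encode(sequences[i])
  a
}

# internal: (L, 4, n) cube layout used by the C++ core
.encode_cube <- function(sequences) {
  a <- encode_windows(sequences)
  aperm(a, c(2L, 3L, 1L))
}

.new_dataset <- function(windows, L, provenance = list()) {
  rownames(windows) <- NULL
  structure(list(windows = windows, L = L, provenance = provenance),
            class = "splice_dataset")
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat("splice_dataset: ", nrow(x$windows), " windows of length ", x$L, "\n",
      sep = "")
  print(class_counts(x))
  invisible(x)
}

#' Per-label window counts of a dataset
#' @param dataset A `splice_dataset`.
#' @return Named integer vector over `acceptor`, `donor`, `non_splice`.
#' @export
class_counts <- function(dataset) {
  tab <- table(factor(dataset$windows$label, levels = LABEL_ORDER))
  stats::setNames(as.integer(tab), LABEL_ORDER)
}

.make_windows <- function(genome, seq_name, boundary, label, canonical, L) {
  if (L %% 2L != 0L) stop("window length L must be even")
  half <- L %/% 2L
  seqs <- character(length(boundary))
  for (sn in unique(seq_name)) {
    i <- which(seq_name == sn)
    s <- genome[[sn]]
    len <- nchar(s)
    lo <- boundary[i] - half + 1L
    hi <- boundary[i] + half
    bad <- lo < 1L | hi > len
    if (any(bad))
      stop("window out of range: ", sn, ":", lo[which(bad)[1L]], "-",
           hi[which(bad)[1L]], " (sequence length ", len, ")")
    seqs[i] <- substring(s, lo, hi)
  }
  data.frame(seq_name = seq_name, boundary = as.integer(boundary),
             sequence = seqs, label = label, canonical = canonical,
             stringsAsFactors = FALSE)
}

#' Build the initial 3-class dataset
#'
#' Positive windows are centered on annotated donor/acceptor boundaries;
#' negative (`non_splice`) windows are centered at the midpoint
#' `floor((b_i + b_{i+1}) / 2)` of each pair of adjacent annotated boundaries
#' on the same sequence, excluding midpoints that coincide with an annotated
#' boundary. `n_per_class` windows per class are sampled uniformly without
#' replacement. Sites whose window would overrun a sequence end are not
#' extractable and are skipped.
#'
#' @param sites Site data.frame from [extract_splice_sites()].
#' @param genome Named character vector of sequences.
#' @param L Even window length.
#' @param n_per_class Windows to draw per class.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param max_n_fraction Skip candidate windows whose fraction of `N` bases
#'   exceeds this (default 1 = filter off).
#' @return A `splice_dataset`.
#' @export
build_initial_dataset <- function(sites, genome, L, n_per_class,
                                  seed = 1L, max_n_fraction = 1.0) {
  stopifnot(n_per_class >= 1L)
  lens <- nchar(genome)
  fits <- .window_fits(lens[sites$seq_name], sites$boundary, L)
  pool <- sites[fits, , drop = FALSE]
  boundary_key <- paste(sites$seq_name, sites$boundary)
  # negative centers: midpoints between adjacent boundaries per sequence
  negs <- list()
  for (sn in unique(sites$seq_name)) {
    b <- sort(unique(sites$boundary[sites$seq_name == sn]))
    if (length(b) < 2L) next
    mid <- (b[-length(b)] + b[-1L]) %/% 2L
    mid <- setdiff(mid, b)
    mid <- mid[.window_fits(lens[[sn]], mid, L)]
    if (length(mid))
      negs[[sn]] <- data.frame(seq_name = sn, boundary = mid,
                               stringsAsFactors = FALSE)
  }
  negs <- if (length(negs)) do.call(rbind, negs) else
    data.frame(seq_name = character(), boundary = integer())
  don <- pool[pool$site_type == "donor", , drop = FALSE]
  acc <- pool[pool$site_type == "acceptor", , drop = FALSE]
  if (nrow(don) < n_per_class || nrow(acc) < n_per_class ||
      nrow(negs) < n_per_class)
    stop("capacity error: available donor=", nrow(don), ", acceptor=",
         nrow(acc), ", non_splice=", nrow(negs), "; need ", n_per_class,
         " per class")
  pick <- function(df, n, seed_off) {
    set.seed(seed + seed_off)
    df[sample.int(nrow(df), n), , drop = FALSE]
  }
  don <- pick(don, n_per_class, 0L)
  acc <- pick(acc, n_per_class, 1L)
  neg <- pick(negs, n_per_class, 2L)
  w <- rbind(
    .make_windows(genome, don$seq_name, don$boundary, "donor",
                  don$canonical, L),
    .make_windows(genome, acc$seq_name, acc$boundary, "acceptor",
                  acc$canonical, L),
    .make_windows(genome, neg$seq_name, neg$boundary, "non_splice", NA, L))
  if (max_n_fraction < 1.0) {
    nfrac <- vapply(w$sequence, function(s)
      lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
      numeric(1L), USE.NAMES = FALSE)
    w <- w[nfrac <= max_n_fraction, , drop = FALSE]
  }
  .new_dataset(w, L, list(source = "build_initial_dataset", seed = seed,
                          n_per_class = n_per_class))
}

#' Rebalance the positive set to a canonical:non-canonical ratio
#'
#' Within each positive class all non-canonical windows are kept (optionally
#' capped or oversampled) and canonical windows are subsampled to exactly
#' `ratio` times the kept non-canonical count. Negative windows are
#' untouched.
#'
#' @param dataset A `splice_dataset`.
#' @param ratio Canonical windows kept per non-canonical window (default 10).
#' @param seed Integer seed for the canonical subsample.
#' @param max_non_canonical Optional per-class cap on kept non-canonical
#'   windows.
#' @param oversample_non_canonical If `TRUE`, draw non-canonical windows with
#'   replacement up to `max_non_canonical` instead of capping.
#' @return A rebalanced `splice_dataset`.
#' @export
rebalance_positive_set <- function(dataset, ratio = 10, seed = 1L,
                                   max_non_canonical = NULL,
                                   oversample_non_canonical = FALSE) {
  stopifnot(ratio >= 1)
  w <- dataset$windows
  keep <- list(w[w$label == "non_splice", , drop = FALSE])
  for (cls in c("donor", "acceptor")) {
    pos <- w[w$label == cls, , drop = FALSE]
    nc <- pos[!pos$canonical, , drop = FALSE]
    can <- pos[pos$canonical, , drop = FALSE]
    if (nrow(nc) == 0L)
      stop("capacity error: no non-canonical ", cls,
           " windows to rebalance around")
    set.seed(seed + match(cls, LABEL_ORDER))
    if (!is.null(max_non_canonical)) {
      if (oversample_non_canonical && nrow(nc) < max_non_canonical) {
        nc <- nc[sample.int(nrow(nc), max_non_canonical, replace = TRUE), ,
                 drop = FALSE]
      } else if (nrow(nc) > max_non_canonical) {
        nc <- nc[sample.int(nrow(nc), max_non_canonical), , drop = FALSE]
      }
    }
    n_can <- round(ratio * nrow(nc))
    if (nrow(can) < n_can)
      stop("capacity error: need ", n_can, " canonical ", cls,
           " windows, have ", nrow(can))
    can <- can[sample.int(nrow(can), n_can), , drop = FALSE]
    keep[[length(keep) + 1L]] <- rbind(can, nc)
  }
  prov <- dataset$provenance
  prov$rebalance_ratio <- ratio
  .new_dataset(do.call(rbind, keep), dataset$L, prov)
}

#' Stratified train/validation/test split
#'
#' First `test_frac` of each label stratum is held out as the test set, then
#' `val_frac_of_train` of the remaining windows become the validation set.
#'
#' @param dataset A `splice_dataset`.
#' @param test_frac Fraction held out for testing (default 0.10).
#' @param val_frac_of_train Fraction of the non-test windows used for
#'   validation (default 0.20).
#' @param seed Integer seed.
#' @return list with `splice_dataset` elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, test_frac = 0.10,
                          val_frac_of_train = 0.20, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1,
            val_frac_of_train > 0, val_frac_of_train < 1)
  w <- dataset$windows
  n <- nrow(w)
  assign_split <- integer(n)  # 1 train, 2 val, 3 test
  set.seed(seed)
  for (cls in unique(w$label)) {
    idx <- which(w$label == cls)
    idx <- idx[sample.int(length(idx))]
    n_test <- round(length(idx) * test_frac)
    n_val <- round((length(idx) - n_test) * val_frac_of_train)
    if (n_test < 1L || n_val < 1L || length(idx) - n_test - n_val < 1L)
      stop("capacity error: stratum '", cls, "' too small (",
           length(idx), " windows) for a non-empty split")
    assign_split[idx[seq_len(n_test)]] <- 3L
    assign_split[idx[n_test + seq_len(n_val)]] <- 2L
    assign_split[idx[(n_test + n_val + 1L):length(idx)]] <- 1L
  }
  mk <- function(which_split, tag) {
    prov <- dataset$provenance
    prov$split <- tag
    .new_dataset(w[assign_split == which_split, , drop = FALSE], dataset$L,
                 prov)
  }
  list(train = mk(1L, "train"), validation = mk(2L, "validation"),
       test = mk(3L, "test"))
}

#' Write a dataset manifest as TSV
#'
#' The manifest stores `seq_name`, `boundary`, `label`, `canonical`; window
#' sequences are re-extracted from the source FASTA on load, so no binary
#' blob is needed.
#'
#' @param dataset A `splice_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, path) {
  cols <- c("seq_name", "boundary", "label", "canonical")
  utils::write.table(dataset$windows[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rebuild a dataset from a TSV manifest and its genome
#' @param path Manifest path from [write_dataset_tsv()].
#' @param genome Named character vector of sequences.
#' @param L Even window length used when the manifest was written.
#' @return A `splice_dataset`.
#' @export
read_dataset_tsv <- function(path, genome, L) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  w <- .make_windows(genome, m$seq_name, m$boundary, m$label, m$canonical, L)
  .new_dataset(w, L, list(source = path))
}
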