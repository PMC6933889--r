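#' Scan a long sequence for splice sites with a sliding window
#'
#' Every `step`-strided candidate boundary in the region whose length-`L`
#' window fits inside the sequence is classified independently; a call is
#' emitted where the argmax class is `donor` or `acceptor` and its
#' probability is at least `min_score`. A site is only called when the
#' junction sits exactly between window positions `L/2` and `L/2 + 1`, so
#' calls are position-exact.
#'
#' @param model A trained 3-class `splice_cnn`.
#' @param genome Named character vector of sequences.
#' @param region Region string `name:start-end` (1-based closed) or list.
#' @param L Window length; defaults to the model's.
#' @param step Stride between candidate boundaries (default 1).
#' @param min_score Minimum class probability to call (default 0 = argmax
#'   only).
#' @param nms_radius If > 0, apply non-maximum suppression: drop any call
#'   with a higher-scoring call of the same type within this many
#'   nucleotides (default 0 = off).
#' @return data.frame of calls: `seq_name`, `boundary`, `site_type`,
#'   `score`, `passed_filter` (NA until [filter_calls()]), sorted by
#'   boundary.
#' @export
scan_sequence <- function(model, genome, region, L = model$spec$L,
                          step = 1L, min_score = 0, nms_radius = 0L) {
  if (step < 1L) stop("parameter error: step must be >= 1")
  r <- parse_region(region, genome)
  len <- nchar(genome[[r$seq_name]])
  half <- L %/% 2L
  lo <- max(r$start, half)            # boundary - L/2 + 1 >= 1
  hi <- min(r$end, len - half)        # boundary + L/2 <= len
  empty <- data.frame(seq_name = character(), boundary = integer(),
                      site_type = character(), score = numeric(),
                      passed_filter = logical(), stringsAsFactors = FALSE)
  if (hi < lo) return(empty)
  cand <- seq.int(lo, hi, by = step)
  calls <- list()
  chunk <- 1024L
  for (c0 in seq(1L, length(cand), by = chunk)) {
    b <- cand[c0:min(length(cand), c0 + chunk - 1L)]
    seqs <- substring(genome[[r$seq_name]], b - half + 1L, b + half)
    p <- predict_proba(model, seqs)
    top <- max.col(p, ties.method = "first")
    cls <- model$label_order[top]
    score <- p[cbind(seq_along(top), top)]
    hit <- cls %in% c("donor", "acceptor") & score >= min_score
    if (any(hit))
      calls[[length(calls) + 1L]] <- data.frame(
        seq_name = r$seq_name, boundary = b[hit], site_type = cls[hit],
        score = score[hit], passed_filter = NA, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(empty)
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$boundary), , drop = FALSE]
  rownames(calls) <- NULL
  if (nms_radius > 0L) calls <- .nms_calls(calls, nms_radius)
  calls
}

.nms_calls <- function(calls, radius) {
  keep <- rep(TRUE, nrow(calls))
  for (ty in unique(calls$site_type)) {
    idx <- which(calls$site_type == ty)
    ord <- idx[order(-calls$score[idx])]
    taken <- integer()
    for (i in ord) {
      if (any(abs(taken - calls$boundary[i]) <= radius)) {
        keep[i] <- FALSE
      } else taken <- c(taken, calls$boundary[i])
    }
  }
  out <- calls[keep, , drop = FALSE]
  out[order(out$boundary), , drop = FALSE]
}

#' Train the two binary confirmation filters
#'
#' Each filter shares the main network's architecture except for a 2-unit
#' output layer, and separates true sites of one type from mined false
#' positives of that type.
#'
#' @param positive_windows `splice_dataset` (or windows data.frame) holding
#'   donor and acceptor windows.
#' @param mined_fp_windows Windows data.frame of mined false positives with
#'   a `predicted_type` column saying which class the miner fired as
#'   (label `non_splice`).
#' @param spec The main model's [model_spec()] (3-class); the filters use it
#'   with `n_classes = 2`.
#' @param config A [train_config()].
#' @return list with trained `donor` and `acceptor` `splice_cnn` filters.
#' @export
train_binary_filters <- function(positive_windows, mined_fp_windows, spec,
                                 config) {
  w <- if (inherits(positive_windows, "splice_dataset"))
    positive_windows$windows else positive_windows
  spec2 <- model_spec(L = spec$L, kernels = spec$kernels,
                      kernel_size = spec$kernel_size,
                      fc_units = spec$fc_units,
                      dropout_rate = spec$dropout_rate, n_classes = 2L,
                      conv_relu = spec$conv_relu)
  out <- list()
  for (cls in c("donor", "acceptor")) {
    pos <- w[w$label == cls, , drop = FALSE]
    neg <- mined_fp_windows[mined_fp_windows$predicted_type == cls, ,
                            drop = FALSE]
    if (nrow(pos) == 0L || nrow(neg) == 0L)
      stop("capacity error: filter '", cls, "' needs positives (",
           nrow(pos), ") and mined negatives (", nrow(neg), ")")
    pos$label <- cls
    neg$label <- "non_splice"
    cols <- c("seq_name", "boundary", "sequence", "label")
    ds <- .new_dataset(rbind(pos[, cols], neg[, cols]), spec$L)
    m <- build_model(spec2, seed = config$seed,
                     label_order = c(cls, "non_splice"))
    out[[cls]] <- train_model(m, ds, NULL, config)
  }
  out
}

#' Re-score scanner calls with the binary filters
#'
#' Each call is re-scored by the filter of its type; calls whose filter
#' probability falls below `min_filter_score` are removed, the rest get
#' `passed_filter = TRUE`. Filtering never adds calls nor changes boundaries
#' or types.
#'
#' @param calls Calls data.frame from [scan_sequence()].
#' @param donor_filter,acceptor_filter 2-class `splice_cnn` filters.
#' @param genome Named character vector of sequences.
#' @param L Window length (defaults to the donor filter's).
#' @param min_filter_score Acceptance threshold (default 0.5).
#' @return Filtered calls with `passed_filter = TRUE` and an added
#'   `filter_score` column.
#' @export
filter_calls <- function(calls, donor_filter, acceptor_filter, genome,
                         L = donor_filter$spec$L, min_filter_score = 0.5) {
  if (nrow(calls) == 0L) {
    calls$filter_score <- numeric(0)
    return(calls)
  }
  filters <- list(donor = donor_filter, acceptor = acceptor_filter)
  fscore <- numeric(nrow(calls))
  for (ty in unique(calls$site_type)) {
    f <- filters[[ty]]
    if (is.null(f)) stop("configuration error: no filter for type '", ty,
                         "'")
    idx <- which(calls$site_type == ty)
    seqs <- vapply(idx, function(i)
      extract_window(genome, calls$seq_name[i], calls$boundary[i], L),
      character(1L))
    p <- predict_proba(f, seqs)
    fscore[idx] <- p[, ty]
  }
  keep <- fscore >= min_filter_score
  out <- calls[keep, , drop = FALSE]
  out$passed_filter <- rep(TRUE, nrow(out))
  out$filter_score <- fscore[keep]
  rownames(out) <- NULL
  out
}

#' Write calls as TSV
#' @param calls Calls data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write calls as BED
#'
#' Single-base intervals in 0-based half-open coordinates; name is the site
#' type; BED score is the call probability scaled to 0-1000.
#'
#' @param calls Calls data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- sprintf("%s\t%d\t%d\t%s\t%d\t+", calls$seq_name,
                  calls$boundary - 1L, calls$boundary, calls$site_type,
                  as.integer(round(1000 * calls$score)))
  writeLines(rows, path)
  invisible(path)
}
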