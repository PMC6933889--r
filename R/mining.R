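#' Harvest a model's false positives from a region
#'
#' Scans the region with the sliding window at argmax; every position whose
#' top class is donor or acceptor but which is not an annotated boundary of
#' that type (within `match_tolerance`) yields one `non_splice` window
#' centered there. Results are de-duplicated against an existing negative
#' set on `(seq_name, boundary)`.
#'
#' @param model Trained 3-class `splice_cnn`.
#' @param genome Named character vector of sequences.
#' @param region Region string or list (see [parse_region()]).
#' @param annotated_sites Site data.frame for the genome.
#' @param L Window length (defaults to the model's).
#' @param existing_negatives Optional data.frame with `seq_name`/`boundary`
#'   of negatives already in the dataset.
#' @param match_tolerance Positions within this distance of a true boundary
#'   of the same type are not counted as false positives (default 0).
#' @return Windows data.frame (label `non_splice`) with a `predicted_type`
#'   column recording which class fired.
#' @export
mine_false_positives <- function(model, genome, region, annotated_sites,
                                 L = model$spec$L,
                                 existing_negatives = NULL,
                                 match_tolerance = 0L) {
  r <- parse_region(region, genome)
  if (r$end - r$start + 1L < L)
    stop("region error: region shorter than the window length ", L)
  calls <- scan_sequence(model, genome, r, L = L, step = 1L, min_score = 0)
  empty <- data.frame(seq_name = character(), boundary = integer(),
                      sequence = character(), label = character(),
                      canonical = logical(), predicted_type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  fp <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    truth <- annotated_sites[
      annotated_sites$seq_name == calls$seq_name[i] &
        annotated_sites$site_type == calls$site_type[i], "boundary"]
    fp[i] <- !any(abs(truth - calls$boundary[i]) <= match_tolerance)
  }
  calls <- calls[fp, , drop = FALSE]
  if (!is.null(existing_negatives) && nrow(calls) > 0L) {
    key <- paste(calls$seq_name, calls$boundary)
    have <- paste(existing_negatives$seq_name, existing_negatives$boundary)
    calls <- calls[!key %in% have, , drop = FALSE]
  }
  if (nrow(calls) == 0L) return(empty)
  w <- .make_windows(genome, calls$seq_name, calls$boundary, "non_splice",
                     NA, L)
  w$predicted_type <- calls$site_type
  rownames(w) <- NULL
  w
}

#' Annotated gene spans usable as mining regions
#'
#' @param exons Exon data.frame.
#' @param genome Named character vector of sequences.
#' @param margin Nucleotides of flanking context added on each side.
#' @return data.frame with `gene_id`, `seq_name`, `start`, `end`.
#' @export
gene_regions <- function(exons, genome, margin = 200L) {
  lens <- vapply(genome, nchar, integer(1L))
  sn <- vapply(split(exons$seq_name, exons$gene_id), `[`, character(1L), 1L)
  lo <- vapply(split(exons$start, exons$gene_id), min, integer(1L))
  hi <- vapply(split(exons$end, exons$gene_id), max, integer(1L))
  res <- data.frame(gene_id = names(sn), seq_name = unname(sn),
                    start = pmax(1L, unname(lo) - margin),
                    end = pmin(unname(lens[unname(sn)]), unname(hi) + margin),
                    stringsAsFactors = FALSE)
  res <- res[match(unique(exons$gene_id), res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Iterative dataset reconstruction (hard-negative mining)
#'
#' Per iteration: retrain from fresh weights on 90% of the current dataset
#' (the remaining 10% measures test accuracy), scan one randomly chosen
#' annotated gene, append the false positives to the negative set, and
#' measure the false-positive count and recall on a set-aside evaluation
#' region that never contributes training windows. The loop stops when the
#' evaluation FP count has failed to decrease (relative to the best seen, by
#' more than `min_relative_decrease`) for `patience` consecutive iterations,
#' or at `max_iterations`.
#'
#' @param dataset Starting `splice_dataset` (positives + initial negatives).
#' @param genome Named character vector of sequences.
#' @param exons Exon annotation data.frame.
#' @param sites Annotated site data.frame for the genome.
#' @param eval_region Region (string or list) set aside for the stopping
#'   signal; its gene is excluded from mining.
#' @param spec The 3-class [model_spec()].
#' @param config A [train_config()] used for each retraining (the
#'   per-iteration seed is derived from `config$seed`).
#' @param max_iterations,patience,min_relative_decrease Stopping controls.
#' @param match_tolerance Passed to [mine_false_positives()].
#' @param checkpoint_dir If non-`NULL`, each iteration's model is saved
#'   under `iter_<i>/`.
#' @param warm_start Continue each retraining from the previous weights
#'   instead of fresh initialization (default `FALSE`).
#' @param start_iteration First iteration index to run (used when resuming
#'   an interrupted loop; per-iteration seeds depend only on the index, so
#'   resumption is deterministic).
#' @param prior_fp_counts Evaluation FP counts of already-completed
#'   iterations, so the stopping rule sees the full trajectory.
#' @return list with `dataset`, `model` (final), and `iterations` (one row
#'   per iteration: `iteration`, `mined_gene`, `n_new_fps`,
#'   `negative_set_size`, `eval_fp_count`, `eval_recall`, `test_accuracy`).
#' @export
iterative_reconstruction <- function(dataset, genome, exons, sites,
                                     eval_region, spec, config,
                                     max_iterations = 100L, patience = 3L,
                                     min_relative_decrease = 0,
                                     match_tolerance = 0L,
                                     checkpoint_dir = NULL,
                                     warm_start = FALSE,
                                     start_iteration = 1L,
                                     prior_fp_counts = numeric()) {
  ev <- parse_region(eval_region, genome)
  regions <- gene_regions(exons, genome)
  overlaps_eval <- regions$seq_name == ev$seq_name &
    regions$start <= ev$end & regions$end >= ev$start
  regions <- regions[!overlaps_eval, , drop = FALSE]
  if (nrow(regions) == 0L)
    stop("capacity error: no annotated genes outside the evaluation region")
  ev_sites <- sites[sites$seq_name == ev$seq_name &
                      sites$boundary >= ev$start &
                      sites$boundary <= ev$end, , drop = FALSE]
  records <- list()
  model <- build_model(spec, seed = config$seed)
  prev_model <- model
  if (start_iteration > max_iterations)
    stop("start_iteration exceeds max_iterations")
  for (it in seq.int(start_iteration, max_iterations)) {
    it_seed <- config$seed + it
    cfg <- config
    cfg$seed <- it_seed
    # 90/10 split of the current dataset; validation not used during mining
    parts <- .mining_split(dataset, it_seed)
    model <- train_model(prev_model, parts$train, NULL, cfg,
                         fresh_init = !warm_start)
    if (warm_start) prev_model <- model
    test_p <- predict_proba(model, parts$test)
    test_acc <- mean(model$label_order[max.col(test_p, "first")] ==
                       parts$test$windows$label)
    # mine one randomly chosen annotated gene
    set.seed(it_seed)
    gi <- sample.int(nrow(regions), 1L)
    reg <- regions[gi, ]
    neg_existing <- dataset$windows[dataset$windows$label == "non_splice",
                                    c("seq_name", "boundary")]
    mined <- mine_false_positives(model, genome,
                                  list(seq_name = reg$seq_name,
                                       start = reg$start, end = reg$end),
                                  sites, L = spec$L,
                                  existing_negatives = neg_existing,
                                  match_tolerance = match_tolerance)
    if (nrow(mined) > 0L) {
      add <- mined[, c("seq_name", "boundary", "sequence", "label",
                       "canonical")]
      dataset <- .new_dataset(rbind(dataset$windows, add), dataset$L,
                              dataset$provenance)
    }
    # stopping signal from the set-aside region
    ev_calls <- scan_sequence(model, genome, ev, L = spec$L)
    evm <- .match_calls(ev_calls, ev_sites, match_tolerance)
    rec <- data.frame(
      iteration = it, mined_gene = reg$gene_id, n_new_fps = nrow(mined),
      negative_set_size = sum(dataset$windows$label == "non_splice"),
      eval_fp_count = sum(!evm$call_matched),
      eval_recall = if (nrow(ev_sites)) mean(evm$site_matched) else NA_real_,
      test_accuracy = test_acc, stringsAsFactors = FALSE)
    records[[length(records) + 1L]] <- rec
    if (!is.null(checkpoint_dir))
      save_model(model, file.path(checkpoint_dir, sprintf("iter_%03d", it)))
    fps <- c(prior_fp_counts,
             vapply(records, function(r) r$eval_fp_count, numeric(1L)))
    if (mining_stalled(fps, patience, min_relative_decrease)) break
  }
  list(dataset = dataset, model = model,
       iterations = do.call(rbind, records))
}

#' Has the mining loop stalled?
#'
#' Applies the stopping rule to an evaluation false-positive trajectory:
#' iterations whose FP count fails to undercut the best count seen so far by
#' more than `min_relative_decrease` (as a fraction) count as stalled; the
#' loop stops once `patience` consecutive iterations have stalled.
#'
#' @param fp_trajectory Numeric vector of per-iteration evaluation FP
#'   counts, oldest first.
#' @param patience Consecutive non-improving iterations tolerated.
#' @param min_relative_decrease Minimum fractional improvement over the best
#'   count that resets the stall counter.
#' @return `TRUE` if the trajectory's tail has stalled for `patience`
#'   iterations.
#' @export
mining_stalled <- function(fp_trajectory, patience = 3L,
                           min_relative_decrease = 0) {
  best <- Inf
  stalled <- 0L
  for (fp in fp_trajectory) {
    if (fp < best * (1 - min_relative_decrease)) {
      best <- fp
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
  }
  stalled >= patience
}

.mining_split <- function(dataset, seed) {
  w <- dataset$windows
  set.seed(seed)
  test_idx <- integer()
  for (cls in unique(w$label)) {
    idx <- which(w$label == cls)
    n_test <- max(1L, round(length(idx) * 0.10))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = .new_dataset(w[-test_idx, , drop = FALSE], dataset$L),
       test = .new_dataset(w[test_idx, , drop = FALSE], dataset$L))
}

# match calls against true sites (same type, boundary within tolerance)
.match_calls <- function(calls, true_sites, tolerance = 0L) {
  call_matched <- logical(nrow(calls))
  site_matched <- logical(nrow(true_sites))
  for (i in seq_len(nrow(calls))) {
    hit <- which(true_sites$site_type == calls$site_type[i] &
                   true_sites$seq_name == calls$seq_name[i] &
                   abs(true_sites$boundary - calls$boundary[i]) <= tolerance)
    if (length(hit)) {
      call_matched[i] <- TRUE
      site_matched[hit] <- TRUE
    }
  }
  list(call_matched = call_matched, site_matched = site_matched)
}
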