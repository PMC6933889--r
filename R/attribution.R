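#' Gradient-times-input contribution scores for one window
#'
#' For each input cell, the score is the input value times the gradient of
#' the target class's pre-softmax logit with respect to that cell, i.e. a
#' first-order decomposition of the logit against an all-zero reference
#' input. For one-hot rows a position's nucleotide score is the single
#' nonzero channel term. Logits (not probabilities) are attributed to avoid
#' softmax saturation. For a network that is affine over the segment from
#' the zero reference to the input, the scores sum exactly to
#' `logit(input) - logit(0)`.
#'
#' @param model Trained `splice_cnn`.
#' @param window Length-`L` sequence (or `L x 4` one-hot matrix).
#' @param target_class Label whose logit is decomposed.
#' @return `L x 4` score matrix (columns `A,C,G,T`).
#' @export
contribution_scores <- function(model, window, target_class) {
  if (!isTRUE(model$trained))
    stop("state error: model is untrained; train it before attribution")
  ti <- match(target_class, model$label_order)
  if (is.na(ti)) stop("unknown target class '", target_class, "'")
  m <- if (is.character(window)) one_hot_encode(window) else window
  x <- array(m, dim = c(nrow(m), 4L, 1L))
  g <- .cnn_input_grad_cpp(x, model$params, target = ti - 1L,
                           conv_relu = model$spec$conv_relu)
  s <- g[, , 1L] * m
  colnames(s) <- c("A", "C", "G", "T")
  s
}

# logits of a batch (pre-softmax); used by the completeness property
.logits <- function(model, windows) {
  p <- predict_proba(model, windows)
  log(pmax(p, 1e-300))  # softmax is shift-invariant; log-probs differ from
                        # logits by a per-row constant, so use the C++ path
}

#' Average per-position contribution profile around the junction
#'
#' Per-position nucleotide scores (channel sums of
#' [contribution_scores()]) averaged over a set of windows, restricted to
#' `flank` positions on each side of the junction: window positions
#' `L/2 - flank + 1 .. L/2 + flank` (for L = 400 and flank 10, positions
#' 191..210, the 20 nucleotides around the junction between 200 and 201).
#'
#' @param model Trained `splice_cnn`.
#' @param windows Character vector of length-`L` sequences.
#' @param target_class Label whose logit is decomposed.
#' @param flank Positions kept on each side of the junction (default 10).
#' @return list of class `contribution_profile`: `positions`, `mean_score`,
#'   `n_sequences`, `target_class`.
#' @export
average_profile <- function(model, windows, target_class, flank = 10L) {
  if (length(windows) < 1L) stop("capacity error: no windows")
  L <- model$spec$L
  if (any(nchar(windows) != L))
    stop("shape error: all windows must have length ", L)
  ti <- match(target_class, model$label_order)
  if (is.na(ti)) stop("unknown target class '", target_class, "'")
  x <- .encode_cube(windows)
  g <- .cnn_input_grad_cpp(x, model$params, target = ti - 1L,
                           conv_relu = model$spec$conv_relu)
  half <- L %/% 2L
  keep <- (half - flank + 1L):(half + flank)
  scores <- matrix(0, length(windows), length(keep))
  for (i in seq_along(windows))
    scores[i, ] <- rowSums(g[keep, , i] * x[keep, , i])
  structure(list(positions = keep, mean_score = colMeans(scores),
                 n_sequences = length(windows),
                 target_class = target_class),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat("contribution_profile (", x$target_class, ", n = ", x$n_sequences,
      ")\n", sep = "")
  print(stats::setNames(round(x$mean_score, 4), x$positions))
  invisible(x)
}

#' Sequence-logo matrix around the junction
#'
#' Column nucleotide frequencies (rows with `N` at that column are excluded
#' from its count) and the per-column information content
#' `IC = 2 + sum(p * log2 p)` bits.
#'
#' @param windows Character vector of equal-length sequences.
#' @param flank Positions kept on each side of the junction (default 10).
#' @return list with `positions`, `freq` (`4 x 2*flank` matrix) and `ic`
#'   (bits per column).
#' @export
logo_matrix <- function(windows, flank = 10L) {
  if (length(windows) == 0L) stop("capacity error: no windows")
  L <- nchar(windows[1L])
  if (any(nchar(windows) != L)) stop("shape error: mixed window lengths")
  half <- L %/% 2L
  keep <- (half - flank + 1L):(half + flank)
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  freq <- sapply(keep, function(j) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (length(col) == 0L) return(rep(NA_real_, 4L))
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- c("A", "C", "G", "T")
  colnames(freq) <- keep
  ic <- apply(freq, 2L, function(p) {
    p <- p[p > 0 & !is.na(p)]
    2 + sum(p * log2(p))
  })
  list(positions = keep, freq = freq, ic = ic)
}

#' Write an average contribution profile as TSV
#' @param profile A `contribution_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(position = profile$positions,
               mean_score = profile$mean_score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
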