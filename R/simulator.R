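# Default position probability matrices for the planted splice motifs.
# Columns of the donor matrix span exon -3..-1 | intron +1..+6 with the GT
# dimer fixed; columns of the acceptor matrix span intron -14..-1 | exon +1
# with the AG dimer fixed and a pyrimidine-rich tract upstream. Values are
# hand-set to resemble the textbook consensus (MAG|GTRAGT, Y-tract + YAG|G).
.default_donor_pwm <- function() {
  m <- matrix(c(
    # A     C     G     T
    0.33, 0.37, 0.18, 0.12,   # exon -3 (M)
    0.60, 0.13, 0.14, 0.13,   # exon -2 (A)
    0.08, 0.04, 0.81, 0.07,   # exon -1 (G)
    0.00, 0.00, 1.00, 0.00,   # intron +1 (G)
    0.00, 0.00, 0.00, 1.00,   # intron +2 (T)
    0.55, 0.03, 0.33, 0.09,   # intron +3 (R)
    0.70, 0.08, 0.12, 0.10,   # intron +4 (A)
    0.08, 0.06, 0.80, 0.06,   # intron +5 (G)
    0.16, 0.17, 0.19, 0.48),  # intron +6 (T)
    nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m / rep(colSums(m), each = 4L)
}

.default_acceptor_pwm <- function() {
  ytract <- c(0.08, 0.35, 0.12, 0.45)  # pyrimidine-rich column
  cols <- c(rep(list(ytract), 10L),            # intron -14..-5
            list(c(0.25, 0.30, 0.15, 0.30)),   # intron -4
            list(c(0.05, 0.40, 0.05, 0.50)),   # intron -3 (Y)
            list(c(1.00, 0.00, 0.00, 0.00)),   # intron -2 (A)
            list(c(0.00, 0.00, 1.00, 0.00)),   # intron -1 (G)
            list(c(0.25, 0.15, 0.50, 0.10)))   # exon +1 (G)
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  m / rep(colSums(m), each = 4L)
}

#' Length distribution for the simulator
#'
#' @param type `"fixed"`, `"poisson_shifted"` (`min + rpois(lambda)`) or
#'   `"lognormal"` (rounded, truncated below at `min`).
#' @param value Fixed value (type `"fixed"`).
#' @param lambda Poisson mean (type `"poisson_shifted"`).
#' @param meanlog,sdlog Log-normal parameters (type `"lognormal"`).
#' @param min Lower truncation bound.
#' @return A `sim_dist` list.
#' @export
sim_dist <- function(type = c("fixed", "poisson_shifted", "lognormal"),
                     value = NULL, lambda = NULL, meanlog = NULL,
                     sdlog = NULL, min = 1L) {
  type <- match.arg(type)
  structure(list(type = type, value = value, lambda = lambda,
                 meanlog = meanlog, sdlog = sdlog, min = as.integer(min)),
            class = "sim_dist")
}

.draw_dist <- function(d, n) {
  if (is.numeric(d) && length(d) == 1L) return(rep(as.integer(d), n))
  out <- switch(d$type,
    fixed = rep(as.integer(d$value), n),
    poisson_shifted = d$min + stats::rpois(n, d$lambda),
    lognormal = pmax(d$min, as.integer(round(
      stats::rlnorm(n, d$meanlog, d$sdlog)))))
  as.integer(out)
}

#' Simulator configuration
#'
#' Defines a multi-gene synthetic genome: genes laid left to right with
#' intergenic gaps, each gene a chain of exons and introns drawn from the
#' configured length distributions over a background base composition.
#' Splice motifs are written across every exon/intron junction from the
#' donor/acceptor position probability matrices; with probability
#' `non_canonical_fraction` an intron is converted to a non-canonical type
#' (GC-AG or AT-AC, both ends consistently). `decoy_rate` plants
#' dimer-bearing pseudo-motifs (sampled from the PWMs flattened halfway
#' toward uniform, consensus dimer kept) in intron/intergenic interiors at
#' the given expected count per kilobase, to make the negative class
#' genuinely hard.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer or [sim_dist()]; minimum 2.
#' @param exon_len,intron_len,intergenic_len Length distributions
#'   ([sim_dist()] or a fixed integer).
#' @param background Base composition (A,C,G,T), summing to 1.
#' @param donor_pwm,acceptor_pwm `4 x w` position probability matrices; the
#'   donor matrix spans exon -3..-1 plus intron +1..+6, the acceptor matrix
#'   intron -14..-1 plus exon +1.
#' @param non_canonical_fraction Probability an intron is non-canonical.
#' @param decoy_rate Expected planted pseudo-motifs per kb of non-exonic
#'   sequence (default 0 = off).
#' @param alt_splicing Add a second, exon-skipping transcript per gene with
#'   at least 3 exons (exercises site de-duplication).
#' @param seq_name Name of the emitted sequence.
#' @param seed Integer seed; the genome is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L,
                       exons_per_gene = 3L,
                       exon_len = sim_dist("lognormal", meanlog = log(120),
                                           sdlog = 0.35, min = 30L),
                       intron_len = sim_dist("lognormal", meanlog = log(300),
                                             sdlog = 0.45, min = 60L),
                       intergenic_len = sim_dist("lognormal",
                                                 meanlog = log(400),
                                                 sdlog = 0.45, min = 120L),
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       donor_pwm = .default_donor_pwm(),
                       acceptor_pwm = .default_acceptor_pwm(),
                       non_canonical_fraction = 0.01,
                       decoy_rate = 0,
                       alt_splicing = FALSE,
                       seq_name = "chr1",
                       seed = 1L) {
  stopifnot(abs(sum(background) - 1) < 1e-8,
            non_canonical_fraction >= 0, non_canonical_fraction <= 1,
            all(abs(colSums(donor_pwm) - 1) < 1e-6),
            all(abs(colSums(acceptor_pwm) - 1) < 1e-6))
  emin <- if (is.numeric(exon_len)) exon_len else exon_len$min
  imin <- if (is.numeric(intron_len)) intron_len else intron_len$min
  if (emin < 4L)
    stop("config error: exon lengths must be >= 4 to carry junction motifs")
  if (imin < 20L)
    stop("config error: intron lengths must be >= 20 to carry both motifs")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 intron_len = intron_len, intergenic_len = intergenic_len,
                 background = background, donor_pwm = donor_pwm,
                 acceptor_pwm = acceptor_pwm,
                 non_canonical_fraction = non_canonical_fraction,
                 decoy_rate = decoy_rate, alt_splicing = alt_splicing,
                 seq_name = seq_name, seed = as.integer(seed)),
            class = "sim_config")
}

.sample_pwm <- function(pwm) {
  bases <- rownames(pwm)
  vapply(seq_len(ncol(pwm)), function(j)
    sample(bases, 1L, prob = pwm[, j]), character(1L))
}

.flatten_pwm <- function(pwm, w = 0.5) {
  m <- w * pwm + (1 - w) * 0.25
  # keep the consensus dimer deterministic
  fixed <- apply(pwm, 2L, max) >= 0.999
  m[, fixed] <- pwm[, fixed]
  m / rep(colSums(m), each = 4L)
}

#' Simulate a synthetic genome with known splice sites
#'
#' @param config A [sim_config()].
#' @return list with `genome` (named character vector), `exons` (data.frame
#'   as from [read_gtf_exons()]) and `sites` (ground-truth data.frame as
#'   from [extract_splice_sites()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  n_ex <- .draw_dist(config$exons_per_gene, config$n_genes)
  if (any(n_ex < 2L)) n_ex[n_ex < 2L] <- 2L
  chars <- list()
  pos <- 0L
  exon_rows <- list()
  intron_spans <- list()   # genomic spans available for decoys
  intergenic_spans <- list()
  nc_flags <- list()       # per intron: canonical dimer assignment
  intron_bounds <- list()  # per intron: c(donor boundary, acceptor boundary)
  gap0 <- .draw_dist(config$intergenic_len, 1L)
  chars[[1L]] <- sample(bases, gap0, replace = TRUE,
                        prob = config$background)
  intergenic_spans[[1L]] <- c(1L, gap0)
  pos <- gap0
  for (g in seq_len(config$n_genes)) {
    k <- n_ex[g]
    elens <- .draw_dist(config$exon_len, k)
    ilens <- .draw_dist(config$intron_len, k - 1L)
    gene_chars <- sample(bases, sum(elens) + sum(ilens), replace = TRUE,
                         prob = config$background)
    # exon coordinates within the gene
    estart <- cumsum(c(1L, head(elens, -1L) + ilens))
    eend <- estart + elens - 1L
    gid <- sprintf("g%04d", g)
    exon_rows[[g]] <- data.frame(
      seq_name = config$seq_name, gene_id = gid,
      transcript_id = paste0(gid, ".t1"),
      start = pos + estart, end = pos + eend, strand = "+",
      stringsAsFactors = FALSE)
    if (config$alt_splicing && k >= 3L) {
      skip <- 1L + sample.int(k - 2L, 1L)  # skip one internal exon
      alt <- exon_rows[[g]][-skip, , drop = FALSE]
      alt$transcript_id <- paste0(gid, ".t2")
      exon_rows[[g]] <- rbind(exon_rows[[g]], alt)
    }
    for (j in seq_len(k - 1L)) {
      # junction j: donor at end of exon j, acceptor before start of exon j+1
      db <- eend[j]          # gene-local donor boundary
      ab <- estart[j + 1L] - 1L
      dm <- .sample_pwm(config$donor_pwm)   # exon -3..-1, intron +1..+6
      am <- .sample_pwm(config$acceptor_pwm)  # intron -14..-1, exon +1
      nc <- stats::runif(1L) < config$non_canonical_fraction
      if (nc) {
        if (stats::runif(1L) < 0.5) {  # GC-AG intron
          dm[4:5] <- c("G", "C")
        } else {                       # AT-AC intron
          dm[4:5] <- c("A", "T")
          am[13:14] <- c("A", "C")
        }
      }
      gene_chars[(db - 2L):(db + 6L)] <- dm
      gene_chars[(ab - 13L):(ab + 1L)] <- am
      nc_flags[[length(nc_flags) + 1L]] <- nc
      intron_bounds[[length(intron_bounds) + 1L]] <-
        c(pos + db, pos + ab)
      # interior of the intron usable for decoys (clear of both motifs)
      lo <- db + 8L
      hi <- ab - 16L
      if (hi - lo >= 16L)
        intron_spans[[length(intron_spans) + 1L]] <- c(pos + lo, pos + hi)
    }
    chars[[length(chars) + 1L]] <- gene_chars
    pos <- pos + length(gene_chars)
    gap <- .draw_dist(config$intergenic_len, 1L)
    chars[[length(chars) + 1L]] <- sample(bases, gap, replace = TRUE,
                                          prob = config$background)
    intergenic_spans[[length(intergenic_spans) + 1L]] <- c(pos + 1L,
                                                           pos + gap)
    pos <- pos + gap
  }
  seq_chars <- unlist(chars, use.names = FALSE)
  # plant decoy pseudo-motifs in non-exonic interiors
  if (config$decoy_rate > 0) {
    spans <- c(intron_spans, intergenic_spans)
    spans <- Filter(function(s) s[2L] - s[1L] >= 20L, spans)
    span_len <- vapply(spans, function(s) s[2L] - s[1L] + 1L, integer(1L))
    n_decoy <- stats::rpois(1L, config$decoy_rate * sum(span_len) / 1000)
    dflat <- .flatten_pwm(config$donor_pwm)
    aflat <- .flatten_pwm(config$acceptor_pwm)
    for (i in seq_len(n_decoy)) {
      sp <- spans[[sample.int(length(spans), 1L, prob = span_len)]]
      if (stats::runif(1L) < 0.5) {
        at <- sp[1L] + sample.int(sp[2L] - sp[1L] - 8L, 1L) - 1L
        seq_chars[at:(at + 8L)] <- .sample_pwm(dflat)
      } else {
        at <- sp[1L] + sample.int(sp[2L] - sp[1L] - 14L, 1L) - 1L
        seq_chars[at:(at + 14L)] <- .sample_pwm(aflat)
      }
    }
  }
  genome <- stats::setNames(paste(seq_chars, collapse = ""),
                            config$seq_name)
  exons <- do.call(rbind, exon_rows)
  sites <- extract_splice_sites(exons, genome)
  res <- list(genome = genome, exons = exons, sites = sites,
              config = config)
  class(res) <- "sim_genome"
  res
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome: ", names(x$genome), " (", nchar(x$genome), " nt), ",
      length(unique(x$exons$gene_id)), " genes, ",
      sum(x$sites$site_type == "donor"), " donors / ",
      sum(x$sites$site_type == "acceptor"), " acceptors (",
      sum(!x$sites$canonical), " non-canonical)\n", sep = "")
  invisible(x)
}

#' Simulate a genome sized for a target site count
#'
#' Chooses `n_genes` (at fixed exons per gene) so that each site type has at
#' least `target_sites_per_type` junctions, then simulates.
#'
#' @param target_sites_per_type Required donors (and acceptors).
#' @param exons_per_gene Fixed exon count per gene (default 11).
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_genome`; its `sites` table has at least the target count
#'   per type.
#' @export
simulate_dataset_genome <- function(target_sites_per_type,
                                    exons_per_gene = 11L, ...) {
  stopifnot(target_sites_per_type >= 1L, exons_per_gene >= 2L)
  n_genes <- as.integer(ceiling(target_sites_per_type /
                                  (exons_per_gene - 1L)))
  cfg <- sim_config(n_genes = n_genes, exons_per_gene = exons_per_gene, ...)
  sim <- simulate_genome(cfg)
  got <- min(sum(sim$sites$site_type == "donor"),
             sum(sim$sites$site_type == "acceptor"))
  if (got < target_sites_per_type)
    stop("config error: achieved ", got, " sites per type, target ",
         target_sites_per_type)
  sim
}

#' Write a simulated genome to FASTA + GTF + ground-truth TSV
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                sites = file.path(dir, "sites.tsv"))
  write_fasta(sim$genome, paths$fasta)
  write_gtf(sim$exons, paths$gtf)
  write_sites_tsv(sim$sites, paths$sites)
  invisible(paths)
}
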