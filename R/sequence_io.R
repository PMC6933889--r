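#' Read genomic sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a named character vector of
#' uppercase DNA sequences. Soft-masked (lowercase) bases are uppercased;
#' masking information is discarded. Only the alphabet `A,C,G,T,N` is
#' accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L)
    stop("FASTA format error at line 1: file is empty")
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error at line ", first,
         ": expected a '>' header, got \"", substr(lines[first], 1, 30), "\"")
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA format error: record '", names(seqs)[which(bad)[1L]],
         "' contains characters outside A,C,G,T,N")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @param line_width Number of bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, line_width = 60L) {
  stopifnot(length(sequences) >= 0, !is.null(names(sequences)) ||
              length(sequences) == 0L)
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = line_width)
  invisible(path)
}

#' Read exon records from a GTF file
#'
#' Keeps only rows whose feature column is `exon`. Coordinates are 1-based
#' closed, as in the file. Rows must carry `gene_id` and `transcript_id`
#' attributes.
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns `seq_name`, `gene_id`, `transcript_id`,
#'   `start`, `end`, `strand`.
#' @export
read_gtf_exons <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  out <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("GTF format error at line ", i, ": expected 9 tab-separated ",
           "fields, got ", length(f))
    if (f[3L] != "exon") next
    gid <- .gtf_attr(f[9L], "gene_id")
    tid <- .gtf_attr(f[9L], "transcript_id")
    if (is.na(gid))
      stop("GTF format error at line ", i, ": missing gene_id attribute")
    if (is.na(tid))
      stop("GTF format error at line ", i, ": missing transcript_id attribute")
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start > end)
      stop("GTF format error at line ", i, ": bad coordinates ",
           f[4L], "-", f[5L])
    out[[length(out) + 1L]] <- data.frame(
      seq_name = f[1L], gene_id = gid, transcript_id = tid,
      start = start, end = end, strand = f[7L],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seq_name = character(), gene_id = character(),
                      transcript_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Write exon records as GTF
#'
#' Emits tab-separated `exon` rows with `gene_id`/`transcript_id` attributes;
#' round-trips through [read_gtf_exons()].
#'
#' @param exons data.frame as returned by [read_gtf_exons()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "splicescan") {
  if (nrow(exons) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$seq_name, source, exons$start, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(rows, path)
  invisible(path)
}

#' Derive annotated splice sites from exon records
#'
#' For each transcript with at least two exons (sorted by start), the right
#' boundary of every non-terminal exon is a donor site and the left boundary
#' of every non-initial exon is an acceptor site. The boundary coordinate is
#' the 1-based position of the last base before the junction: `exon end` for
#' donors, `exon start - 1` for acceptors. Transcript-terminal boundaries
#' (first exon start, last exon end) are transcription start/termination
#' sites, not splice junctions, and are excluded. Sites shared by several
#' transcripts (alternative splicing) are collapsed to one record.
#'
#' A donor is canonical when the first two intronic bases are `GT`; an
#' acceptor when the last two intronic bases are `AG`. With
#' `include_reverse = TRUE`, minus-strand transcripts contribute sites with
#' the dinucleotide checks applied to the reverse complement (`AC` at intron
#' ends for donors, `CT` at intron starts for acceptors, in forward-strand
#' coordinates); by default they are skipped with a warning.
#'
#' @param exons Exon data.frame (see [read_gtf_exons()]).
#' @param genome Named character vector of sequences (see [read_fasta()]).
#' @param include_reverse Process minus-strand transcripts instead of
#'   skipping them.
#' @return data.frame with columns `seq_name`, `site_type`
#'   (`"donor"`/`"acceptor"`), `boundary`, `canonical`, sorted by sequence
#'   and boundary.
#' @export
extract_splice_sites <- function(exons, genome, include_reverse = FALSE) {
  empty <- data.frame(seq_name = character(), site_type = character(),
                      boundary = integer(), canonical = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(exons) == 0L) return(empty)
  bad_seq <- setdiff(unique(exons$seq_name), names(genome))
  if (length(bad_seq))
    stop("exon coordinate error: unknown sequence '", bad_seq[1L], "'")
  lens <- nchar(genome)
  over <- exons$end > lens[exons$seq_name] | exons$start < 1L
  if (any(over))
    stop("exon coordinate error: exon ", exons$start[which(over)[1L]], "-",
         exons$end[which(over)[1L]], " outside sequence '",
         exons$seq_name[which(over)[1L]], "'")
  rev_tx <- unique(exons$transcript_id[exons$strand == "-"])
  if (length(rev_tx) && !include_reverse) {
    warning("skipping ", length(rev_tx),
            " reverse-strand transcript(s); set include_reverse = TRUE ",
            "to process them")
  }
  ord <- order(exons$transcript_id, exons$start)
  sn_v <- exons$seq_name[ord]
  st_v <- exons$start[ord]
  en_v <- exons$end[ord]
  tid_v <- exons$transcript_id[ord]
  strand_v <- exons$strand[ord]
  # junction j sits between consecutive exons of the same transcript
  jx <- which(tid_v[-length(tid_v)] == tid_v[-1L])
  if (length(jx)) {
    minus_j <- strand_v[jx] == "-"
    if (!include_reverse) jx <- jx[!minus_j]
    minus_j <- strand_v[jx] == "-"
  }
  if (length(jx) == 0L) return(empty)
  # forward: donor = left exon end, acceptor = right exon start - 1;
  # minus strand mirrors the roles (transcription runs right to left)
  don_b <- ifelse(minus_j, st_v[jx + 1L] - 1L, en_v[jx])
  acc_b <- ifelse(minus_j, en_v[jx], st_v[jx + 1L] - 1L)
  sites <- data.frame(
    seq_name = c(sn_v[jx], sn_v[jx]),
    site_type = rep(c("donor", "acceptor"), each = length(jx)),
    boundary = as.integer(c(don_b, acc_b)),
    strand = rep(ifelse(minus_j, "-", "+"), 2L),
    stringsAsFactors = FALSE)
  sites <- sites[!duplicated(sites[c("seq_name", "site_type", "boundary",
                                     "strand")]), , drop = FALSE]
  canon <- logical(nrow(sites))
  for (sn in unique(sites$seq_name)) {
    s <- genome[[sn]]
    len <- nchar(s)
    i <- which(sites$seq_name == sn)
    b <- sites$boundary[i]
    after <- substring(s, b + 1L, b + 2L)
    before <- substring(s, b - 1L, b)
    donor_i <- sites$site_type[i] == "donor"
    plus_i <- sites$strand[i] == "+"
    canon[i] <- ifelse(plus_i,
                       ifelse(donor_i, after == "GT", before == "AG"),
                       ifelse(donor_i, before == "AC", after == "CT"))
    canon[i][b < 2L | b > len - 2L] <- FALSE
  }
  sites$canonical <- canon
  sites$strand <- NULL
  sites <- sites[order(sites$seq_name, sites$boundary, sites$site_type), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Write a splice-site table as TSV
#'
#' @param sites Site data.frame from [extract_splice_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a splice-site TSV written by [write_sites_tsv()]
#' @param path Input path.
#' @return Site data.frame.
#' @export
read_sites_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Parse a 1-based closed region string
#'
#' Regions are written `name:start-end` with 1-based closed coordinates
#' (matching GTF). A bare sequence name means the whole sequence.
#'
#' @param region Region string, or a list with `seq_name`, `start`, `end`.
#' @param genome Named character vector of sequences (used to fill in a
#'   missing end and to validate bounds).
#' @return list with `seq_name`, `start`, `end`.
#' @export
parse_region <- function(region, genome) {
  if (is.list(region)) {
    r <- region
  } else {
    m <- regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region)
    g <- regmatches(region, m)[[1L]]
    if (length(g) == 0L) stop("cannot parse region '", region, "'")
    r <- list(seq_name = g[2L],
              start = if (nzchar(g[4L])) as.integer(g[4L]) else 1L,
              end = if (nzchar(g[5L])) as.integer(g[5L]) else NA_integer_)
  }
  if (!r$seq_name %in% names(genome))
    stop("region error: unknown sequence '", r$seq_name, "'")
  len <- nchar(genome[[r$seq_name]])
  if (is.na(r$end)) r$end <- len
  if (r$start < 1L || r$end > len || r$start > r$end)
    stop("region error: ", r$seq_name, ":", r$start, "-", r$end,
         " outside 1-", len)
  r
}
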