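## formats_io: every external format the pipeline touches.
## Internal coordinate convention is 1-based inclusive on the forward strand
## (RepeatMasker-style); BED conversion happens only at the output boundary.

HIT_COLUMNS <- c("seq_id", "genome_start", "genome_end", "strand", "family",
                 "consensus_start", "consensus_end", "score", "divergence")

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased, U is mapped to T and IUPAC ambiguity codes are
#' collapsed to N, so downstream code only ever sees the A/C/G/T/N alphabet.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record ('>')",
                 nonempty[1]), call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    stop(sprintf("zero-length FASTA record '%s'", ids[empty[1]]),
         call. = FALSE)
  }
  setNames(normalize_seq(seqs, "FASTA record"), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (or XStringSet) of sequences
#' @param path output path
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_seq_vector(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct / validate a table of repeat hits
#'
#' A hit table is a data.frame with one row per annotated insertion:
#' `seq_id`, `genome_start`, `genome_end` (1-based inclusive), `strand`
#' (`+`/`-`), `family`, `consensus_start`, `consensus_end` (1-based inclusive
#' in consensus orientation, start <= end on both strands), `score` and
#' `divergence` (K2P distance to the consensus; may be NA before dating).
#' Rows are kept sorted by (`seq_id`, `genome_start`).
#'
#' @param df data.frame with the columns above
#' @return validated, sorted hit table
#' @export
hit_table <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(seq_id = character(), genome_start = integer(),
                     genome_end = integer(), strand = character(),
                     family = character(), consensus_start = integer(),
                     consensus_end = integer(), score = numeric(),
                     divergence = numeric())
  }
  missing <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("hit table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, HIT_COLUMNS]
  for (col in c("genome_start", "genome_end", "consensus_start", "consensus_end")) {
    df[[col]] <- as.integer(df[[col]])
  }
  bad <- which(df$genome_start > df$genome_end |
               df$consensus_start > df$consensus_end)
  if (length(bad) > 0) {
    stop("coordinate inversion (start > end) in hit table row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    stop("invalid strand in hit table row(s): ",
         paste(bad_strand, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$seq_id, df$genome_start, df$genome_end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a hit table
#'
#' Dialects: `tsv` (header + tab separation, lossless), `rm_out`
#' (whitespace table in RepeatMasker .out column order: score, divergence,
#' query, begin, end, strand, family, class, consensus begin/end; for
#' minus-strand hits the consensus coordinates are emitted in reading
#' order, i.e. swapped) and `bed` (BED6 with 0-based half-open
#' coordinates; write-only).
#'
#' @param hits hit table (see [hit_table()])
#' @param path output path
#' @param dialect one of `"tsv"`, `"rm_out"`, `"bed"`
#' @param taxonomy optional named character vector mapping family to class
#'   (used for the rm_out class column)
#' @return `path`, invisibly
#' @export
write_hit_table <- function(hits, path, dialect = "tsv", taxonomy = NULL) {
  hits <- hit_table(hits)
  if (!dialect %in% c("tsv", "rm_out", "bed")) {
    stop("unknown hit table dialect: ", dialect, call. = FALSE)
  }
  if (dialect == "tsv") {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (dialect == "bed") {
    bed <- data.frame(chrom = hits$seq_id,
                      start = hits$genome_start - 1L,
                      end = hits$genome_end,
                      name = hits$family,
                      score = hits$score,
                      strand = hits$strand)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(bed) > 0) {
      write.table(bed, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  } else {
    cls <- if (is.null(taxonomy)) rep("Unknown", nrow(hits)) else
      ifelse(is.na(taxonomy[hits$family]), "Unknown", taxonomy[hits$family])
    minus <- hits$strand == "-"
    cb <- ifelse(minus, hits$consensus_end, hits$consensus_start)
    ce <- ifelse(minus, hits$consensus_start, hits$consensus_end)
    out <- data.frame(score = hits$score,
                      div = format(hits$divergence, digits = 15, trim = TRUE),
                      query = hits$seq_id,
                      q_start = hits$genome_start,
                      q_end = hits$genome_end,
                      strand = hits$strand,
                      family = hits$family,
                      class = cls,
                      c_start = cb,
                      c_end = ce)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("score", "divergence", "query", "q_start", "q_end",
                     "strand", "family", "class", "c_start", "c_end"), con)
    if (nrow(out) > 0) {
      write.table(out, con, sep = " ", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a hit table
#'
#' Inverse of [write_hit_table()] for the `tsv` and `rm_out` dialects.
#'
#' @param path input path
#' @param dialect `"tsv"` or `"rm_out"`
#' @return hit table
#' @export
read_hit_table <- function(path, dialect = "tsv") {
  if (!dialect %in% c("tsv", "rm_out")) {
    stop("unknown hit table dialect: ", dialect, call. = FALSE)
  }
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c(seq_id = "character", strand = "character",
                                    family = "character"))
    return(hit_table(df))
  }
  cc <- rep(NA_character_, 10)
  cc[c(3, 6, 7, 8)] <- "character"
  df <- read.table(path, header = TRUE, sep = "", colClasses = cc)
  names(df) <- c("score", "divergence", "seq_id", "genome_start", "genome_end",
                 "strand", "family", "class", "c_start", "c_end")
  minus <- df$strand == "-"
  cs <- ifelse(minus, df$c_end, df$c_start)
  ce <- ifelse(minus, df$c_start, df$c_end)
  hit_table(data.frame(seq_id = df$seq_id, genome_start = df$genome_start,
                       genome_end = df$genome_end, strand = df$strand,
                       family = df$family, consensus_start = cs,
                       consensus_end = ce, score = df$score,
                       divergence = as.numeric(df$divergence)))
}

#' Load a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`, parsed by yaml, a JSON superset).
#'
#' @param path config file path
#' @return nested list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
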