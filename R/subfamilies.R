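## subfamilies: discovery of SINE subfamilies from co-segregating
## diagnostic sites. Intact insertions are aligned to the family consensus,
## and the set is split recursively wherever a pair (or triple) of columns
## shows significantly more members jointly carrying the minor alleles than
## independence predicts (one-sided binomial test, Bonferroni-corrected over
## the candidate combinations tested at that node).

#' Collect intact insertions of a family
#'
#' Keeps hits whose genomic length is within `tolerance` of the consensus
#' length (`[floor(L*(1-t)), ceiling(L*(1+t))]`, e.g. 240-294 for a 267-bp
#' consensus at 10%) and whose consensus span covers at least `1-tolerance`
#' of the consensus, then extracts their sequences in consensus
#' orientation.
#'
#' @param hits hit table (one family's hits, or a table that will be
#'   filtered with `family`)
#' @param genome named character vector of genome sequences
#' @param consensus family consensus sequence
#' @param tolerance length tolerance fraction (default 0.10)
#' @param family optional family name to filter `hits` by
#' @return named character vector of insertion sequences; the `hit_rows`
#'   attribute maps them back to rows of `hits`
#' @export
collect_intact_insertions <- function(hits, genome, consensus,
                                      tolerance = 0.10, family = NULL) {
  hits <- hit_table(hits)
  if (!is.null(family)) hits <- hits[hits$family == family, , drop = FALSE]
  genome <- as_seq_vector(genome, "genome")
  consensus <- normalize_seq(consensus, "consensus")
  L <- nchar(consensus)
  lo <- floor(L * (1 - tolerance))
  hi <- ceiling(L * (1 + tolerance))
  glen <- hits$genome_end - hits$genome_start + 1
  span <- hits$consensus_end - hits$consensus_start + 1
  keep <- which(glen >= lo & glen <= hi & span >= (1 - tolerance) * L)
  seqs <- character(length(keep))
  for (i in seq_along(keep)) {
    h <- hits[keep[i], ]
    s <- substr(genome[[h$seq_id]], h$genome_start, h$genome_end)
    if (h$strand == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  names(seqs) <- if (length(keep) == 0) character(0) else
    paste0("ins", keep)
  attr(seqs, "hit_rows") <- keep
  seqs
}

# n x L character matrix: each insertion globally aligned to the consensus,
# columns indexed by consensus position (insertions relative to the
# consensus are dropped, deletions appear as "-")
consensus_column_matrix <- function(insertions, consensus,
                                    scoring = scoring_scheme()) {
  L <- nchar(consensus)
  m <- matrix("-", nrow = length(insertions), ncol = L,
              dimnames = list(names(insertions), NULL))
  ba <- batch_align(insertions, consensus, scoring, type = "global")
  for (i in seq_along(insertions)) {
    ca <- seq_chars(ba$subject[i])   # consensus row
    cb <- seq_chars(ba$pattern[i])   # insertion row
    keep <- ca != "-"
    m[i, cumsum(ca != "-")[keep]] <- cb[keep]
  }
  m
}

# per-column major/minor allele among a subset of rows
column_alleles <- function(m, rows) {
  apply(m[rows, , drop = FALSE], 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) return(c(major = NA, minor = NA, minor_n = "0"))
    tab <- sort(table(col), decreasing = TRUE)
    c(major = names(tab)[1],
      minor = if (length(tab) > 1) names(tab)[2] else NA,
      minor_n = if (length(tab) > 1) as.character(tab[2]) else "0")
  })
}

#' Partition intact insertions into subfamilies by co-segregating sites
#'
#' Recursive splitting: at each node the candidate columns are those whose
#' minor allele is carried by at least `min_size` members; all candidate
#' pairs (and triples, when few candidates remain), in every viable allele
#' orientation (any allele carried by between `min_size` and
#' `n - min_size` members can mark the derived state), are scored by the
#' one-sided binomial probability of the observed number of members
#' jointly carrying the chosen alleles under independence, with Bonferroni
#' correction over all combination-orientation tests at the node. The
#' best significant combination splits the node into carriers vs rest;
#' recursion stops at `alpha`, `min_size` or `max_depth`.
#'
#' @param insertions named character vector of intact insertion sequences
#' @param consensus family consensus
#' @param min_size minimum subfamily size (default 50)
#' @param alpha significance threshold after Bonferroni (default 0.001)
#' @param max_depth maximum split depth
#' @param max_candidate_cols cap on candidate columns per node (kept by
#'   descending minor-allele count)
#' @param triple_max_cols enumerate triples as well when the number of
#'   candidate columns is at most this
#' @param scoring a [scoring_scheme()]
#' @return a `subfamily_assignment`: list with `labels` (per insertion),
#'   `subfamilies` (label, size), `splits` (per accepted split: sites,
#'   carriers, p), and the column `matrix` used
#' @export
find_cosegregating_subfamilies <- function(insertions, consensus,
                                           min_size = 50, alpha = 0.001,
                                           max_depth = 8,
                                           max_candidate_cols = 20,
                                           triple_max_cols = 12,
                                           scoring = scoring_scheme()) {
  consensus <- normalize_seq(consensus, "consensus")
  n <- length(insertions)
  labels <- rep(NA_character_, n)
  splits <- list()
  if (n < 2 * min_size) {
    labels[] <- "SF1"
    m <- NULL
  } else {
    m <- consensus_column_matrix(insertions, consensus, scoring)
    leaf_id <- 0L
    recurse <- function(rows, depth) {
      n_node <- length(rows)
      accept <- NULL
      if (n_node >= 2 * min_size && depth < max_depth) {
        al <- column_alleles(m, rows)
        minor_n <- as.integer(al["minor_n", ])
        cand <- which(minor_n >= min_size & !is.na(al["minor", ]))
        if (length(cand) >= 2) {
          cand <- cand[order(-minor_n[cand])]
          cand <- head(cand, max_candidate_cols)
          combos <- combn(cand, 2, simplify = FALSE)
          if (length(cand) <= triple_max_cols && length(cand) >= 3) {
            combos <- c(combos, combn(cand, 3, simplify = FALSE))
          }
          # per column, the alleles a subfamily could be defined by: any
          # allele carried by between min_size and n - min_size members
          # (near a 50/50 split either allele may mark the derived state)
          allele_opts <- lapply(seq_len(ncol(m)), function(col) NULL)
          for (col in cand) {
            x <- m[rows, col]
            tab <- sort(table(x[x %in% c("A", "C", "G", "T")]),
                        decreasing = TRUE)
            ok <- names(tab)[tab >= min_size & tab <= n_node - min_size]
            allele_opts[[col]] <- list(alleles = ok,
                                       counts = as.integer(tab[ok]))
          }
          tests <- list()
          for (cc in combos) {
            opts <- lapply(cc, function(col) allele_opts[[col]]$alleles)
            if (any(lengths(opts) == 0)) next
            grid <- expand.grid(opts, stringsAsFactors = FALSE)
            for (g in seq_len(nrow(grid))) {
              tests[[length(tests) + 1]] <-
                list(cols = cc, alleles = as.character(grid[g, ]))
            }
          }
          n_tests <- length(tests)
          best <- NULL
          for (tt in tests) {
            carrier <- rep(TRUE, n_node)
            p0 <- 1
            for (j in seq_along(tt$cols)) {
              col <- tt$cols[j]; a <- tt$alleles[j]
              carrier <- carrier & m[rows, col] == a
              cnt <- allele_opts[[col]]$counts[
                match(a, allele_opts[[col]]$alleles)]
              p0 <- p0 * cnt / n_node
            }
            k <- sum(carrier)
            if (k < min_size || n_node - k < min_size) next
            p <- pbinom(k - 1, n_node, p0, lower.tail = FALSE)
            p_adj <- min(1, p * n_tests)
            if (is.null(best) || p_adj < best$p_adj ||
                (p_adj == best$p_adj && length(tt$cols) < length(best$cols))) {
              best <- list(cols = tt$cols, alleles = tt$alleles,
                           carrier = carrier, k = k, p = p, p_adj = p_adj)
            }
          }
          if (!is.null(best) && best$p_adj < alpha) accept <- best
        }
      }
      if (is.null(accept)) {
        leaf_id <<- leaf_id + 1L
        labels[rows] <<- paste0("SF", leaf_id)
        return(invisible(NULL))
      }
      al <- column_alleles(m, rows)
      splits[[length(splits) + 1]] <<- list(
        n = n_node, depth = depth,
        sites = data.frame(column = accept$cols,
                           allele = accept$alleles,
                           major = al["major", accept$cols],
                           minor = al["minor", accept$cols]),
        carriers = accept$k, p_adjusted = accept$p_adj)
      recurse(rows[accept$carrier], depth + 1L)
      recurse(rows[!accept$carrier], depth + 1L)
    }
    recurse(seq_len(n), 0L)
  }
  sf <- table(labels)
  structure(list(labels = setNames(labels, names(insertions)),
                 subfamilies = data.frame(label = names(sf),
                                          size = as.integer(sf)),
                 splits = splits, matrix = m),
            class = "subfamily_assignment")
}

#' @export
print.subfamily_assignment <- function(x, ...) {
  cat(sprintf("subfamily assignment: %d insertions, %d subfamilies, %d splits\n",
              length(x$labels), nrow(x$subfamilies), length(x$splits)))
  invisible(x)
}

#' Refine per-subfamily consensi and re-assign members
#'
#' Each subfamily gets a majority-rule consensus from a center-star MSA of
#' its members; each insertion is then re-assigned to the nearest subfamily
#' consensus by K2P distance (ties to the first label in sort order) and
#' the consensi rebuilt, for up to `rounds` rounds or until stable.
#' Subfamilies falling below `min_size` are merged into the nearest sibling
#' (by consensus-to-consensus K2P distance) and the merge is logged.
#'
#' @param assignment a `subfamily_assignment`
#' @param insertions the insertion sequences the assignment refers to
#' @param min_size minimum surviving subfamily size
#' @param rounds maximum refinement rounds (default 2)
#' @param scoring a [scoring_scheme()]
#' @return list with updated `labels`, `consensi` (named character vector)
#'   and a character vector `log`
#' @export
refine_subfamily_consensus <- function(assignment, insertions, min_size = 50,
                                       rounds = 2,
                                       scoring = scoring_scheme()) {
  labels <- assignment$labels
  log <- character(0)
  build <- function(labels) {
    sapply(sort(unique(labels)), function(lb) {
      mem <- insertions[labels == lb]
      if (length(mem) == 1) return(unname(mem))
      majority_consensus(build_msa(mem, scoring))
    })
  }
  consensi <- build(labels)
  dist_to <- function(seqn, cons) {
    aln <- global_align(cons, seqn, scoring)
    tryCatch(as.numeric(k2p_distance(aln$aligned_a, aln$aligned_b,
                                     on_saturation = "nan")),
             error = function(e) Inf)
  }
  for (r in seq_len(rounds)) {
    lbs <- sort(names(consensi))
    d <- matrix(Inf, length(insertions), length(lbs),
                dimnames = list(names(insertions), lbs))
    for (lb in lbs) {
      ba <- batch_align(insertions, consensi[[lb]], scoring, "global")
      d[, lb] <- vapply(seq_along(insertions), function(i) {
        v <- tryCatch(as.numeric(k2p_distance(ba$pattern[i], ba$subject[i],
                                              on_saturation = "nan")),
                      error = function(e) Inf)
        if (is.nan(v)) Inf else v
      }, numeric(1))
    }
    new_labels <- lbs[apply(d, 1, which.min)]  # which.min: first label wins ties
    names(new_labels) <- names(insertions)
    # merge undersized subfamilies into the nearest sibling
    repeat {
      sizes <- table(factor(new_labels, levels = lbs))
      small <- names(sizes)[sizes > 0 & sizes < min_size]
      if (length(small) == 0 || length(lbs) < 2) break
      lb <- small[1]
      sib <- setdiff(lbs[table(factor(new_labels, levels = lbs)) > 0], lb)
      if (length(sib) == 0) break
      dd <- vapply(sib, function(s) dist_to(consensi[[lb]], consensi[[s]]),
                   numeric(1))
      tgt <- sib[which.min(dd)]
      log <- c(log, sprintf("round %d: merged %s (n=%d) into %s",
                            r, lb, sizes[lb], tgt))
      new_labels[new_labels == lb] <- tgt
      lbs <- setdiff(lbs, lb)
    }
    stable <- identical(unname(new_labels), unname(labels))
    labels <- new_labels
    consensi <- build(labels)
    if (stable) break
  }
  list(labels = labels, consensi = consensi, log = log)
}

#' Confirm subfamily presence in the genome
#'
#' Runs the masker with each subfamily consensus, keeps the top `top_n`
#' hits by score, and reports their count and mean identity to the
#' consensus. Subfamilies with duplicated consensus sequences are flagged
#' ambiguous.
#'
#' @param subfamily_consensi named character vector of subfamily consensi
#' @param genome named character vector of genome sequences
#' @param top_n number of top hits to examine per subfamily (default 150)
#' @param ... further arguments to [find_hits()]
#' @return data.frame: subfamily, n_hits, mean_identity, ambiguous
#' @export
confirm_subfamily_presence <- function(subfamily_consensi, genome,
                                       top_n = 150, ...) {
  genome <- as_seq_vector(genome, "genome")
  subfamily_consensi <- as_seq_vector(subfamily_consensi, "consensi")
  dup <- duplicated(subfamily_consensi) |
         duplicated(subfamily_consensi, fromLast = TRUE)
  rows <- lapply(seq_along(subfamily_consensi), function(i) {
    nm <- names(subfamily_consensi)[i]
    hits <- find_hits(genome, subfamily_consensi[i], ...)
    hits <- head(hits[order(-hits$score), , drop = FALSE], top_n)
    ident <- if (nrow(hits) == 0) NA_real_ else {
      mean(vapply(seq_len(nrow(hits)), function(r) {
        h <- hits[r, ]
        s <- substr(genome[[h$seq_id]], h$genome_start, h$genome_end)
        if (h$strand == "-") s <- revcomp(s)
        pairwise_identity_and_coverage(s, subfamily_consensi[[i]])$identity
      }, numeric(1)))
    }
    data.frame(subfamily = nm, n_hits = nrow(hits),
               mean_identity = ident, ambiguous = dup[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag composite subfamilies
#'
#' A subfamily whose members are embedded in another element (their flanks
#' are masked by a different family on both sides in more than
#' `threshold` of members) is flagged "composite"; such subfamilies were
#' spread by their host element, not by retrotransposition, and should be
#' excluded from dating.
#'
#' @param assignment refined labels (named character vector) for insertions
#' @param insertion_hit_rows rows of `hits` the insertions came from
#'   (the `hit_rows` attribute of [collect_intact_insertions()])
#' @param hits the full hit table (all families)
#' @param flank_window flank width examined on each side (bases)
#' @param min_cover fraction of flank bases that must be masked
#' @param threshold fraction of members embedded for the subfamily flag
#' @return named logical vector per subfamily label
#' @export
flag_composite_subfamilies <- function(assignment, insertion_hit_rows, hits,
                                       flank_window = 100, min_cover = 0.5,
                                       threshold = 0.8) {
  hits <- hit_table(hits)
  labels <- assignment
  member_embedded <- vapply(seq_along(labels), function(i) {
    h <- hits[insertion_hit_rows[i], ]
    other <- hits[hits$family != h$family & hits$seq_id == h$seq_id, ,
                  drop = FALSE]
    if (nrow(other) == 0) return(FALSE)
    covered <- function(s, e) {
      if (e < s) return(0)
      ir <- IRanges::IRanges(other$genome_start, other$genome_end)
      q <- IRanges::IRanges(s, e)
      ov <- IRanges::intersect(IRanges::reduce(ir), q)
      sum(IRanges::width(ov)) / (e - s + 1)
    }
    lc <- covered(max(1, h$genome_start - flank_window), h$genome_start - 1)
    rc <- covered(h$genome_end + 1, h$genome_end + flank_window)
    lc >= min_cover && rc >= min_cover
  }, logical(1))
  tapply(member_embedded, labels, function(x) mean(x) > threshold)
}
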