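## synthetic_data: genomes with planted TE copies and full ground truth.
## Copies descend from a family master (optionally via subfamily masters
## carrying diagnostic sites), are diverged by a seeded K2P substitution
## process, 5'-truncated and/or internally deleted, optionally nested into
## copies of an earlier family, and placed in i.i.d. background sequence.

# sample from a vector without the sample(5) == sample(1:5) surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Mutate a sequence under the Kimura 2-parameter model
#'
#' Per-site transition and transversion probabilities are the exact K2P
#' process probabilities at total divergence `d` with transition:
#' transversion rate ratio `kappa` (so the expected K2P estimate of the
#' mutated copy against the original is `d`). The realised distance is the
#' closed-form K2P distance of the realised substitution counts.
#'
#' @param seq sequence to mutate (single string)
#' @param d target divergence in substitutions/site (`0 <= d <= 3`)
#' @param kappa transition/transversion rate ratio (> 0)
#' @param seed optional integer seed; by default the current RNG state is
#'   used so the function composes inside larger simulations
#' @return list with `seq`, `realized_distance`, `transitions`,
#'   `transversions`
#' @export
mutate_k2p <- function(seq, d, kappa = 2, seed = NULL) {
  if (d < 0 || d > 3) stop("divergence d must be in [0, 3]", call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  seq <- normalize_seq(seq, "sequence")
  chars <- seq_chars(seq)
  acgt <- chars %in% c("A", "C", "G", "T")
  # alpha*t = kappa*d/(kappa+2), beta*t = d/(kappa+2)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  u <- runif(length(chars))
  pick <- runif(length(chars))
  ts_idx <- which(acgt & u < P)
  tv_idx <- which(acgt & u >= P & u < P + Q)
  out <- chars
  out[ts_idx] <- ts_map[chars[ts_idx]]
  out[tv_idx] <- vapply(seq_along(tv_idx), function(i) {
    alts <- tv_map[[chars[tv_idx[i]]]]
    alts[1 + (pick[tv_idx[i]] > 0.5)]
  }, character(1))
  n <- sum(acgt)
  Ph <- length(ts_idx) / n
  Qh <- length(tv_idx) / n
  w1 <- 1 - 2 * Ph - Qh; w2 <- 1 - 2 * Qh
  realized <- if (w1 > 0 && w2 > 0) -0.5 * log(w1 * sqrt(w2)) else NaN
  list(seq = paste(out, collapse = ""), realized_distance = realized,
       transitions = length(ts_idx), transversions = length(tv_idx))
}

#' Describe one simulated TE family
#'
#' @param name family name
#' @param n_copies number of copies to plant
#' @param master master (ancestral) sequence; drawn at random when NULL
#' @param length master length when drawn (bases)
#' @param divergence per-copy target K2P distance: a scalar, a vector of
#'   length `n_copies`, or `list(min=, max=)` for a uniform age mixture
#' @param kappa transition/transversion rate ratio of the mutation process
#' @param subfamilies optional list of subfamily specs, each
#'   `list(name=, sites=data.frame(pos, base), fraction=)`; fractions may
#'   sum to < 1, the remainder stays on the family master
#' @param truncation `list(fraction=, min_frac=, max_frac=)`: a fraction of
#'   copies lose a 5' prefix whose length is uniform between the two
#'   fractions of the master length (LINE-style incomplete reverse
#'   transcription)
#' @param deletion `list(fraction=, min_len=, max_len=, end3_bias=)`: a
#'   fraction of copies receive one post-insertion deletion; with
#'   probability `end3_bias` it removes the 3' terminus, otherwise an
#'   internal span (kept away from both ends)
#' @param orf_disruption optional `list(orf=c(start, end), n_nonsense=,
#'   n_frameshift=, n_truncated=)`: the stated copy counts receive a
#'   premature in-frame stop, a 1-bp frameshifting deletion, or a 5'
#'   truncation removing the ORF start; remaining copies are pristine
#' @param minus_prob probability a copy is planted on the minus strand
#' @param epoch activity epoch (smaller = earlier); used with nesting
#' @return a `sim_family` spec list
#' @export
sim_family <- function(name, n_copies, master = NULL, length = 300,
                       divergence = 0.1, kappa = 2, subfamilies = NULL,
                       truncation = list(fraction = 0, min_frac = 0.1,
                                         max_frac = 0.9),
                       deletion = list(fraction = 0, min_len = 40,
                                       max_len = 150, end3_bias = 0.5),
                       orf_disruption = NULL, minus_prob = 0.5, epoch = 1) {
  stopifnot(n_copies >= 0, is.character(name))
  structure(list(name = name, n_copies = n_copies, master = master,
                 length = length, divergence = divergence, kappa = kappa,
                 subfamilies = subfamilies, truncation = truncation,
                 deletion = deletion, orf_disruption = orf_disruption,
                 minus_prob = minus_prob, epoch = epoch),
            class = "sim_family")
}

# exact-count category assignment, shuffled
assign_counts <- function(n, counts, labels, default) {
  counts <- pmin(counts, n)
  lab <- rep(default, n)
  pool <- sample.int(n, min(n, sum(counts)))
  at <- 1
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    lab[pool[at:(at + counts[i] - 1)]] <- labels[i]
    at <- at + counts[i]
  }
  lab
}

copy_divergence <- function(spec, n) {
  d <- spec$divergence
  if (is.list(d)) return(runif(n, d$min, d$max))
  rep_len(d, n)
}

# generate all copies of one family; each copy carries `seq` (consensus
# orientation), `cpos` (consensus position of every base) and truth fields
generate_family_copies <- function(spec, masters) {
  master <- masters[[spec$name]]
  L <- nchar(master)
  n <- spec$n_copies
  if (n == 0) return(list())
  subfam_lab <- rep(spec$name, n)
  sf_master <- setNames(list(master), spec$name)
  if (!is.null(spec$subfamilies)) {
    counts <- vapply(spec$subfamilies, function(s) round(s$fraction * n),
                     numeric(1))
    labels <- vapply(spec$subfamilies, `[[`, character(1), "name")
    subfam_lab <- assign_counts(n, counts, labels, spec$name)
    for (s in spec$subfamilies) {
      ms <- master
      for (r in seq_len(nrow(s$sites))) {
        substr(ms, s$sites$pos[r], s$sites$pos[r]) <- s$sites$base[r]
      }
      sf_master[[s$name]] <- ms
    }
  }
  dvec <- copy_divergence(spec, n)
  orf_lab <- rep("none", n)
  if (!is.null(spec$orf_disruption)) {
    od <- spec$orf_disruption
    orf_lab <- assign_counts(
      n, c(od$n_nonsense %||% 0, od$n_frameshift %||% 0,
           od$n_truncated %||% 0),
      c("nonsense", "frameshift", "truncated"), "pristine")
  }
  copies <- vector("list", n)
  for (i in seq_len(n)) {
    seqn <- sf_master[[subfam_lab[i]]]
    mut <- mutate_k2p(seqn, dvec[i], spec$kappa)
    seqn <- mut$seq
    cpos <- seq_len(L)
    trunc_pt <- NA_integer_
    dels <- character(0)
    # LINE-style 5' truncation
    tr <- spec$truncation
    if ((tr$fraction %||% 0) > 0 && runif(1) < tr$fraction) {
      r <- round(L * runif(1, tr$min_frac, tr$max_frac))
      if (r >= 1 && L - r >= 30) {
        seqn <- substr(seqn, r + 1, L)
        cpos <- cpos[(r + 1):L]
        trunc_pt <- r + 1L
      }
    }
    # post-insertion deletion; the span shrinks on short copies so every
    # selected copy really receives one, leaving a detectable remnant
    dl <- spec$deletion
    if ((dl$fraction %||% 0) > 0 && runif(1) < dl$fraction) {
      min_remain <- dl$min_remain %||% 100
      span <- resample(dl$min_len:dl$max_len, 1)
      want_3prime <- runif(1) < (dl$end3_bias %||% 0.5)
      # short copies cannot host an internal deletion with two flanking
      # remnants; fall back to a 3'-terminal one
      if (!want_3prime && length(cpos) - 2 * min_remain < 10) {
        want_3prime <- TRUE
      }
      if (want_3prime) {
        # 3'-terminal deletion
        span <- min(span, length(cpos) - min_remain)
        if (span >= 10) {
          dels <- c(dels, sprintf("%d-%d", cpos[length(cpos) - span + 1],
                                  cpos[length(cpos)]))
          seqn <- substr(seqn, 1, nchar(seqn) - span)
          cpos <- cpos[seq_len(length(cpos) - span)]
        }
      } else {
        # internal deletion, kept away from both ends
        span <- min(span, length(cpos) - 2 * min_remain)
        lo <- min_remain + 1
        hi <- length(cpos) - min_remain - span + 1
        if (span >= 10 && hi >= lo) {
          at <- resample(lo:hi, 1)
          dels <- c(dels, sprintf("%d-%d", cpos[at], cpos[at + span - 1]))
          seqn <- paste0(substr(seqn, 1, at - 1),
                         substr(seqn, at + span, nchar(seqn)))
          cpos <- cpos[-(at:(at + span - 1))]
        }
      }
    }
    # ORF disruptions (applied on top; coordinates are consensus positions)
    if (orf_lab[i] %in% c("nonsense", "frameshift", "truncated")) {
      orf <- spec$orf_disruption$orf
      naa <- as.integer((orf[2] - orf[1] + 1) / 3) - 1L
      if (orf_lab[i] == "nonsense") {
        j <- resample(round(0.2 * naa):round(0.8 * naa), 1)
        p <- orf[1] + 3L * j          # start of codon j+1
        off <- match(p, cpos)
        if (!is.na(off)) substr(seqn, off, off + 2) <- "TAA"
      } else if (orf_lab[i] == "frameshift") {
        p <- orf[1] + 3L * resample(round(0.2 * naa):round(0.8 * naa), 1)
        off <- match(p, cpos)
        if (!is.na(off)) {
          dels <- c(dels, sprintf("%d-%d", p, p))
          seqn <- paste0(substr(seqn, 1, off - 1),
                         substr(seqn, off + 1, nchar(seqn)))
          cpos <- cpos[-off]
        }
      } else {
        cstart <- orf[1] + as.integer(ceiling(0.12 * (orf[2] - orf[1] + 1)))
        off <- match(cstart, cpos)
        if (!is.na(off) && off > 1) {
          seqn <- substr(seqn, off, nchar(seqn))
          cpos <- cpos[off:length(cpos)]
          trunc_pt <- cstart
        }
      }
    }
    copies[[i]] <- list(
      family = spec$name, subfamily = subfam_lab[i], seq = seqn,
      cpos = cpos, strand = if (runif(1) < spec$minus_prob) "-" else "+",
      realized_distance = mut$realized_distance,
      truncation_point = trunc_pt,
      deletions = paste(dels, collapse = ";"),
      orf_status = orf_lab[i], epoch = spec$epoch)
  }
  attr(copies, "subfamily_masters") <- sf_master
  copies
}

#' Simulate a genome with planted TE copies and ground truth
#'
#' Background sequence is i.i.d. at the requested GC content; copies are
#' placed at uniformly drawn, non-overlapping insertion points, except
#' where the nesting spec inserts a copy INTO an earlier family's copy,
#' splitting that copy's truth interval into two sub-records sharing a
#' parent id. The same seed reproduces the genome and truth byte for byte.
#'
#' @param families list of [sim_family()] specs
#' @param genome_length background length in bases
#' @param gc background GC content
#' @param seed integer seed (required: the simulation is defined by it)
#' @param nesting optional list of `list(inner=, outer=, count=,
#'   min_host_flank=)` directives; `count` copies of the inner family are
#'   inserted into distinct copies of the outer family, at least
#'   `min_host_flank` bases from either host end
#' @param min_spacing minimum spacing between background insertion points
#' @param seq_id name of the emitted sequence
#' @return list with `genome` (named character vector), `truth`
#'   (data.frame; one row per planted interval), `library` (family
#'   masters), `subfamily_masters`
#' @export
simulate_genome <- function(families, genome_length, gc = 0.35, seed,
                            nesting = NULL, min_spacing = 10,
                            seq_id = "chr1") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  background <- random_dna(genome_length, gc)
  families <- families[order(vapply(families, `[[`, numeric(1), "epoch"))]
  masters <- list()
  for (f in families) {
    masters[[f$name]] <- normalize_seq(f$master %||% random_dna(f$length, 0.5),
                                       "master")
  }
  copies <- list()
  sf_masters <- list()
  for (f in families) {
    fc <- generate_family_copies(f, masters)
    sf_masters <- c(sf_masters, attr(fc, "subfamily_masters"))
    copies <- c(copies, fc)
  }
  n_cp <- length(copies)
  for (i in seq_len(n_cp)) copies[[i]]$id <- sprintf("copy%04d", i)

  # nesting designation: inner copies go inside distinct outer hosts
  host_of <- setNames(rep(NA_integer_, n_cp), NULL)
  offset_in_host <- rep(NA_integer_, n_cp)
  if (!is.null(nesting)) {
    for (nst in nesting) {
      fams <- vapply(copies, `[[`, character(1), "family")
      inner_pool <- which(fams == nst$inner & is.na(host_of))
      host_pool <- which(fams == nst$outer & is.na(host_of))
      host_pool <- host_pool[!host_pool %in% which(!is.na(host_of))]
      if (length(inner_pool) < nst$count || length(host_pool) < nst$count) {
        stop(sprintf(
          "nesting %s-into-%s needs %d inner and %d host copies",
          nst$inner, nst$outer, nst$count, nst$count), call. = FALSE)
      }
      inner_sel <- resample(inner_pool, nst$count)
      host_sel <- resample(host_pool, nst$count)
      mh <- nst$min_host_flank %||% 50
      for (j in seq_len(nst$count)) {
        hl <- nchar(copies[[host_sel[j]]]$seq)
        if (hl < 2 * mh + 2) {
          stop("host copy too short for nesting with min_host_flank = ", mh,
               call. = FALSE)
        }
        host_of[inner_sel[j]] <- host_sel[j]
        offset_in_host[inner_sel[j]] <- resample(mh:(hl - mh), 1)
      }
    }
  }
  nested_in_host <- setNames(vector("list", n_cp), NULL)
  for (i in which(!is.na(host_of))) {
    nested_in_host[[host_of[i]]] <- c(nested_in_host[[host_of[i]]], i)
  }
  if (any(lengths(nested_in_host) > 1)) {
    stop("at most one nested insertion per host copy is supported",
         call. = FALSE)
  }
  bg_idx <- which(is.na(host_of))
  n_bg <- length(bg_idx)
  capacity <- floor(genome_length / min_spacing) - 1
  if (n_bg > capacity) {
    stop(sprintf(
      "genome too small for %d copies: need genome_length >= %d at min_spacing %d",
      n_bg, (n_bg + 1) * min_spacing, min_spacing), call. = FALSE)
  }
  slots <- sort(resample(seq_len(capacity), n_bg))
  points <- slots * min_spacing   # insertion after this background base
  bg_idx <- resample(bg_idx, n_bg)  # random copy order along the genome

  pieces <- character(0)
  truth <- list()
  cursor <- 0L   # background consumed so far
  glen <- 0L     # genome built so far
  add_piece <- function(s) {
    pieces[[length(pieces) + 1]] <<- s
    glen <<- glen + nchar(s)
  }
  part_span <- function(cpos_part) c(min(cpos_part), max(cpos_part))
  for (j in seq_len(n_bg)) {
    add_piece(substr(background, cursor + 1, points[j]))
    cursor <- points[j]
    i <- bg_idx[j]
    cp <- copies[[i]]
    planted <- if (cp$strand == "-") revcomp(cp$seq) else cp$seq
    inner_i <- nested_in_host[[i]]
    if (is.null(inner_i)) {
      gs <- glen + 1L
      add_piece(planted)
      sp <- part_span(cp$cpos)
      truth[[length(truth) + 1]] <- data.frame(
        id = cp$id, family = cp$family, subfamily = cp$subfamily,
        seq_id = seq_id, start = gs, end = glen, strand = cp$strand,
        realized_distance = cp$realized_distance,
        consensus_start = sp[1], consensus_end = sp[2],
        truncation_point = cp$truncation_point, deletions = cp$deletions,
        parent_id = NA_character_, orf_status = cp$orf_status)
    } else {
      icp <- copies[[inner_i]]
      off <- offset_in_host[inner_i]
      iplanted <- if (icp$strand == "-") revcomp(icp$seq) else icp$seq
      left <- substr(planted, 1, off)
      right <- substr(planted, off + 1, nchar(planted))
      hl <- nchar(planted)
      # consensus positions covered by each genomic part of the host
      if (cp$strand == "+") {
        cl <- cp$cpos[1:off]; cr <- cp$cpos[(off + 1):hl]
      } else {
        cl <- cp$cpos[(hl - off + 1):hl]; cr <- cp$cpos[1:(hl - off)]
      }
      gs <- glen + 1L; add_piece(left); le <- glen
      is_ <- glen + 1L; add_piece(iplanted); ie <- glen
      rs <- glen + 1L; add_piece(right); re <- glen
      spl <- part_span(cl); spr <- part_span(cr)
      truth[[length(truth) + 1]] <- data.frame(
        id = paste0(cp$id, ".1"), family = cp$family,
        subfamily = cp$subfamily, seq_id = seq_id, start = gs, end = le,
        strand = cp$strand, realized_distance = cp$realized_distance,
        consensus_start = spl[1], consensus_end = spl[2],
        truncation_point = cp$truncation_point, deletions = cp$deletions,
        parent_id = cp$id, orf_status = cp$orf_status)
      truth[[length(truth) + 1]] <- data.frame(
        id = paste0(cp$id, ".2"), family = cp$family,
        subfamily = cp$subfamily, seq_id = seq_id, start = rs, end = re,
        strand = cp$strand, realized_distance = cp$realized_distance,
        consensus_start = spr[1], consensus_end = spr[2],
        truncation_point = cp$truncation_point, deletions = cp$deletions,
        parent_id = cp$id, orf_status = cp$orf_status)
      spi <- part_span(icp$cpos)
      truth[[length(truth) + 1]] <- data.frame(
        id = icp$id, family = icp$family, subfamily = icp$subfamily,
        seq_id = seq_id, start = is_, end = ie, strand = icp$strand,
        realized_distance = icp$realized_distance,
        consensus_start = spi[1], consensus_end = spi[2],
        truncation_point = icp$truncation_point, deletions = icp$deletions,
        parent_id = cp$id, orf_status = icp$orf_status)
    }
  }
  add_piece(substr(background, cursor + 1, genome_length))
  genome <- setNames(paste(pieces, collapse = ""), seq_id)
  truth <- if (length(truth) == 0) {
    data.frame(id = character(), family = character(),
               subfamily = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               realized_distance = numeric(), consensus_start = integer(),
               consensus_end = integer(), truncation_point = integer(),
               deletions = character(), parent_id = character(),
               orf_status = character())
  } else {
    do.call(rbind, truth)
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome,
       truth = truth,
       library = setNames(unlist(masters), names(masters)),
       subfamily_masters = setNames(unlist(sf_masters), names(sf_masters)))
}
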