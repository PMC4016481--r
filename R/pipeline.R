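## pipeline: orchestration of mask -> subfamilies -> dating -> decay ->
## nesting -> orfs -> ht-screen with a single config and one seed.

default_config <- function() {
  list(
    seed = 1L,
    masker = list(k = 12, min_score = 150, min_len = 30, overlap_tol = 10,
                  split_gap = 40),
    dating = list(rate = 0.01909, mode = "consensus"),
    subfamilies = list(family = NULL, min_size = 50, alpha = 0.001,
                       tolerance = 0.10, top_n = 150),
    decay = list(epsilon_frac = 0.05, join_tol = 30),
    nesting = list(join_tol = 30, classes = NULL),
    orfs = list(min_len_nt = 1000, max_candidates = 50, buffer = 1000),
    ht = list(min_identity = 0.95, min_coverage = 0.80)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]] %||% NULL)) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full TE landscape analysis
#'
#' Stages run in dependency order (mask, then any of subfamilies, date,
#' decay, nesting, orfs, ht); each stage writes its table under `out_dir`
#' and a run log records parameters and the seed. A stage failure aborts
#' with the stage name; tables already written are retained.
#'
#' @param config nested list (or path to a YAML file): `input` must give
#'   `genome` and `library` (FASTA paths or in-memory named character
#'   vectors) and may give precomputed `hits` (tsv path); optional
#'   `taxonomy` named character vector (family -> class); per-stage
#'   parameter sections as in `default_config()`; `ht$subjects` gives
#'   foreign genome FASTA paths for the screen
#' @param out_dir output directory (created if needed)
#' @param stages character vector of stages to run (default: all
#'   applicable)
#' @return invisibly, a list with all in-memory stage results
#' @export
run_full_analysis <- function(config, out_dir,
                              stages = c("mask", "subfamilies", "date",
                                         "decay", "nesting", "orfs", "ht")) {
  if (is.character(config)) config <- load_config(config)
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$input$genome) || is.null(cfg$input$library)) {
    stop("config error: input$genome and input$library are required",
         call. = FALSE)
  }
  load_seqs <- function(x, what) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) read_fasta(x)
    else if (is.character(x) && length(x) == 1) {
      stop("config error: no such file: ", x, call. = FALSE)
    } else as_seq_vector(x, what)
  }
  genome <- load_seqs(cfg$input$genome, "genome")
  library <- load_seqs(cfg$input$library, "library")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  res <- list()
  logf <- file.path(out_dir, "run_log.txt")
  cat(sprintf("TElandscape %s\nseed: %s\nstages: %s\n",
              as.character(packageVersion("TElandscape")), cfg$seed,
              paste(stages, collapse = ",")),
      file = logf)
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    cat(sprintf("stage %s: started\n", name), file = logf, append = TRUE)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    cat(sprintf("stage %s: done\n", name), file = logf, append = TRUE)
  }

  run_stage("mask", function() {
    m <- cfg$masker
    res$hits <<- find_hits(genome, library, k = m$k,
                           min_score = m$min_score, min_len = m$min_len,
                           overlap_tol = m$overlap_tol,
                           split_gap = m$split_gap)
    write_hit_table(res$hits, file.path(out_dir, "hits.tsv"), "tsv")
    res$content <<- genome_fraction(res$hits, nchar(genome),
                                    unlist(cfg$taxonomy))
    write.table(res$content, file.path(out_dir, "content.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
  if (is.null(res$hits)) {
    if (!is.null(cfg$input$hits)) {
      res$hits <- read_hit_table(cfg$input$hits, "tsv")
    } else if (any(stages != "mask")) {
      stop("config error: later stages need 'mask' or input$hits",
           call. = FALSE)
    }
  }

  run_stage("subfamilies", function() {
    sf <- cfg$subfamilies
    fam <- sf$family
    if (is.null(fam)) return(invisible(NULL))
    ins <- collect_intact_insertions(res$hits, genome, library[[fam]],
                                     tolerance = sf$tolerance, family = fam)
    asn <- find_cosegregating_subfamilies(ins, library[[fam]],
                                          min_size = sf$min_size,
                                          alpha = sf$alpha)
    ref <- refine_subfamily_consensus(asn, ins, min_size = sf$min_size)
    comp <- flag_composite_subfamilies(ref$labels, attr(ins, "hit_rows"),
                                       res$hits)
    res$subfamilies <<- list(assignment = asn, refined = ref,
                             composite = comp)
    dir.create(file.path(out_dir, "subfamilies"), showWarnings = FALSE)
    write.table(data.frame(insertion = names(ref$labels),
                           subfamily = ref$labels),
                file.path(out_dir, "subfamilies", "assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(ref$consensi,
                file.path(out_dir, "subfamilies", "consensi.fa"))
  })

  run_stage("date", function() {
    d <- cfg$dating
    res$ages <<- family_divergence(res$hits, genome, library,
                                   mode = d$mode, rate = d$rate)
    write.table(res$ages, file.path(out_dir, "ages.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("decay", function() {
    dc <- cfg$decay
    res$decay <<- deletion_evidence_summary(res$hits, nchar(library),
                                            epsilon_frac = dc$epsilon_frac,
                                            join_tol = dc$join_tol)
    write.table(res$decay, file.path(out_dir, "decay_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    joined <- rejoin_split_fragments(res$hits, dc$join_tol)
    iv <- do.call(rbind, lapply(sort(unique(joined$family)), function(f) {
      pr <- decay_profile(joined[joined$family == f, ], nchar(library[[f]]),
                          dc$epsilon_frac)
      cbind(family = f, pr$intervals)
    }))
    write.table(iv, file.path(out_dir, "decay_intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("nesting", function() {
    nst <- cfg$nesting
    hits <- res$hits
    if (!is.null(nst$classes) && !is.null(cfg$taxonomy)) {
      tax <- unlist(cfg$taxonomy)
      hits <- hits[tax[hits$family] %in% nst$classes, , drop = FALSE]
    }
    ev <- detect_nested_insertions(hits, join_tol = nst$join_tol)
    res$nesting <<- list(events = ev,
                         matrix = nesting_matrix(ev, sort(unique(hits$family))))
    write.table(ev, file.path(out_dir, "nesting_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$nesting$matrix, file.path(out_dir, "nesting_matrix.tsv"),
                sep = "\t", quote = FALSE)
  })

  run_stage("orfs", function() {
    oc <- cfg$orfs
    rows <- list()
    for (fam in names(library)) {
      orfs <- find_orfs(library[[fam]], min_len_nt = oc$min_len_nt)
      if (nrow(orfs) == 0) next
      orf <- orfs[1, ]
      census <- count_intact_orfs(genome,
                                  res$hits[res$hits$family == fam, ],
                                  library[[fam]], orf,
                                  max_candidates = oc$max_candidates,
                                  buffer = oc$buffer)
      rows[[fam]] <- data.frame(element = fam, orf_start = orf$start,
                                orf_end = orf$end,
                                expected_aa = orf$expected_aa,
                                examined = census$examined,
                                intact = census$intact,
                                mean_identity = census$mean_identity_intact)
    }
    res$orfs <<- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(element = character(), orf_start = integer(),
                 orf_end = integer(), expected_aa = integer(),
                 examined = integer(), intact = integer(),
                 mean_identity = numeric())
    write.table(res$orfs, file.path(out_dir, "orf_census.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("ht", function() {
    h <- cfg$ht
    if (is.null(h$subjects)) return(invisible(NULL))
    subjects <- unlist(lapply(h$subjects, function(p) {
      if (is.character(p) && length(p) == 1 && file.exists(p)) read_fasta(p)
      else as_seq_vector(p, "subject")
    }))
    res$ht <<- screen_horizontal_transfer(library, subjects,
                                          min_identity = h$min_identity,
                                          min_coverage = h$min_coverage)
    write.table(res$ht, file.path(out_dir, "ht_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  invisible(res)
}
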