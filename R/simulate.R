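#' Enzyme-class proportions of the Archaea benchmark set
#'
#' The class composition emulated by the synthetic generator: about 45%
#' non-enzymes and a strongly skewed distribution over the seven enzyme
#' classes (class 2 most frequent, class 7 rare), as in the Swiss-Prot
#' Archaea benchmark the package's defaults mirror.
#'
#' @return Named numeric vector of 8 proportions
#'   (`non_enzyme`, `1`..`7`) summing to 1.
#' @export
archaea_class_proportions <- function() {
  counts <- c(
    non_enzyme = 8727, `1` = 1187, `2` = 3843, `3` = 2123,
    `4` = 1281, `5` = 603, `6` = 1715, `7` = 120
  )
  counts / sum(counts)
}

#' Default per-class motifs
#'
#' One fixed length-6 motif per enzyme class. Over a background of 20
#' residues a 6-mer collides with random sequence with probability well
#' below 1e-5 per position, so planted motifs identify their class almost
#' surely.
#'
#' @return Named character vector of 7 motifs (classes `"1"`..`"7"`).
#' @export
default_motifs <- function() {
  c(
    `1` = "CHWYEK", `2` = "DFKRYW", `3` = "EHMNPC", `4` = "FKQWCY",
    `5` = "GMYHDW", `6` = "HPWCKF", `7` = "KYEWMG"
  )
}

#' Configuration for the synthetic sequence generator
#'
#' @param n Number of sequences, default 1400.
#' @param length_min,length_max Residue length range, defaults 50-400
#'   (`length_max` must be <= 1000).
#' @param length_shape Optional positive shape for a symmetric Beta
#'   length distribution; `NULL` (default) draws lengths uniformly.
#' @param class_proportions 8 non-negative weights (non-enzyme then classes
#'   1-7) summing to 1; default [archaea_class_proportions()]. `"balanced"`
#'   gives equal weights.
#' @param motifs Named character vector of per-class motifs, default
#'   [default_motifs()].
#' @param motif_policy Where motifs are planted: `"n_term"` (default),
#'   `"middle"`, `"c_term"` or `"uniform"`.
#' @param multi_ec_rate Fraction of enzymes given a second, distinct class
#'   (default 0.01), yielding multi-EC records.
#' @param seed Integer seed making the generator fully reproducible.
#' @return A list of class `seqpad_sim_config`.
#' @export
sim_config <- function(n = 1400L, length_min = 50L, length_max = 400L,
                       length_shape = NULL,
                       class_proportions = archaea_class_proportions(),
                       motifs = default_motifs(),
                       motif_policy = c("n_term", "middle", "c_term", "uniform"),
                       multi_ec_rate = 0.01, seed = 1L) {
  motif_policy <- match.arg(motif_policy)
  if (identical(class_proportions, "balanced")) {
    class_proportions <- stats::setNames(rep(1 / 8, 8), c("non_enzyme", 1:7))
  }
  stopifnot(
    n >= 1, length_min >= 1, length_max <= 1000, length_min <= length_max,
    length(class_proportions) == 8, abs(sum(class_proportions) - 1) < 1e-8,
    length(motifs) == 7, all(nzchar(motifs)),
    multi_ec_rate >= 0, multi_ec_rate <= 1
  )
  if (max(nchar(motifs)) > length_min) {
    stop("longest motif (", max(nchar(motifs)),
      ") exceeds the minimum sequence length (", length_min, ")",
      call. = FALSE
    )
  }
  structure(
    list(
      n = as.integer(n), length_min = as.integer(length_min),
      length_max = as.integer(length_max), length_shape = length_shape,
      class_proportions = class_proportions, motifs = motifs,
      motif_policy = motif_policy, multi_ec_rate = multi_ec_rate,
      seed = as.integer(seed)
    ),
    class = "seqpad_sim_config"
  )
}

#' Substitute a motif into a background sequence
#'
#' The motif replaces (never inserts into) a window of the background, so
#' the sequence length is unchanged and independent of the class. Offsets
#' are 0-based in the formulas: `n_term` plants at offset 0, `c_term`
#' end-aligned, `middle` at `floor((L - m)/2)`, `uniform` at a random valid
#' offset drawn from the current RNG state.
#'
#' @param background Residue string of length L.
#' @param motif Motif string of length m <= L.
#' @param policy `"n_term"`, `"middle"`, `"c_term"` or `"uniform"`.
#' @return The background with the motif substituted.
#' @export
#' @examples
#' plant_motif("AAAAAA", "CDE", "n_term") # "CDEAAA"
#' plant_motif("AAAAAA", "CDE", "middle") # "ACDEAA"
plant_motif <- function(background, motif,
                        policy = c("n_term", "middle", "c_term", "uniform")) {
  policy <- match.arg(policy)
  L <- nchar(background)
  m <- nchar(motif)
  stopifnot(m <= L)
  offset <- switch(policy,
    n_term = 0L,
    c_term = L - m,
    middle = floor((L - m) / 2),
    uniform = sample.int(L - m + 1L, 1L) - 1L
  )
  paste0(
    substr(background, 1, offset),
    motif,
    substr(background, offset + m + 1, L)
  )
}

#' Generate a synthetic annotated sequence set
#'
#' Draws class labels from the configured proportions, i.i.d. background
#' residues over the 20 standard amino acids, and substitutes the class
#' motif at the policy position for every enzyme. A `multi_ec_rate`
#' fraction of enzymes receives a second distinct class whose motif is
#' planted at the opposite end (or a non-overlapping position), producing
#' multi-EC records. Labels are written as synthetic EC strings `d.0.0.0`.
#' Identical configurations (including seed) produce byte-identical output.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `sequences.fasta`
#'   and `annotations.tsv` there (TSV schema `id<TAB>ec1;ec2;...`).
#' @return A list with `sequences` (tibble `id`, `residues`),
#'   `annotations` (tibble `id`, `ec` semicolon-joined string) and, when
#'   written, `paths`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n = 20, seed = 7))
#' sim$sequences
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "seqpad_sim_config"))
  residues20 <- aa_residues()[1:20]
  withr::with_seed(config$seed, {
    n <- config$n
    classes <- sample(c(0L, 1:7), n, replace = TRUE, prob = config$class_proportions)
    lengths <- if (is.null(config$length_shape)) {
      sample(seq(config$length_min, config$length_max), n, replace = TRUE)
    } else {
      config$length_min + floor(
        stats::rbeta(n, config$length_shape, config$length_shape) *
          (config$length_max - config$length_min + 1)
      )
    }
    ids <- sprintf("SYN%05d", seq_len(n))
    second <- integer(n)
    is_enzyme <- classes > 0L
    pick_second <- is_enzyme & stats::runif(n) < config$multi_ec_rate
    second[pick_second] <- vapply(classes[pick_second], function(cl) {
      sample(setdiff(1:7, cl), 1L)
    }, integer(1))
    residues <- vapply(seq_len(n), function(i) {
      s <- paste(sample(residues20, lengths[i], replace = TRUE), collapse = "")
      if (classes[i] > 0L) {
        s <- plant_motif(s, config$motifs[[as.character(classes[i])]],
          policy = config$motif_policy
        )
        if (second[i] > 0L) {
          # secondary motif at the opposite end so both survive intact
          alt <- switch(config$motif_policy,
            c_term = "n_term", n_term = "c_term", "c_term"
          )
          s <- plant_motif(s, config$motifs[[as.character(second[i])]], policy = alt)
        }
      }
      s
    }, character(1))
    ec <- vapply(seq_len(n), function(i) {
      if (classes[i] == 0L) {
        ""
      } else if (second[i] > 0L) {
        paste(sprintf("%d.0.0.0", c(classes[i], second[i])), collapse = ";")
      } else {
        sprintf("%d.0.0.0", classes[i])
      }
    }, character(1))
  })
  sequences <- tibble::tibble(id = ids, residues = residues)
  annotations <- tibble::tibble(id = ids, ec = ec)
  out <- list(sequences = sequences, annotations = annotations)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fasta <- file.path(out_dir, "sequences.fasta")
    tsv <- file.path(out_dir, "annotations.tsv")
    write_fasta(sequences, fasta)
    readr::write_tsv(annotations, tsv, col_names = FALSE, progress = FALSE)
    out$paths <- c(fasta = fasta, tsv = tsv)
  }
  out
}

#' Recover class labels by motif scanning
#'
#' A label decoder used to check generator consistency: scans each sequence
#' for the class motifs and returns the matching class (0 when no motif is
#' found, the lowest class on the rare event of multiple matches beyond the
#' planted pair).
#'
#' @param residues Character vector of sequences.
#' @param motifs Named motif vector as in [default_motifs()].
#' @return Integer vector of predicted primary classes (0 = non-enzyme).
#' @export
scan_motifs <- function(residues, motifs = default_motifs()) {
  hit <- sapply(motifs, function(m) grepl(m, residues, fixed = TRUE))
  hit <- matrix(hit, nrow = length(residues))
  apply(hit, 1, function(h) if (any(h)) as.integer(names(motifs)[which(h)[1]]) else 0L)
}

#' Labelled samples straight from a generator run
#'
#' Convenience: round-trips the in-memory generator output through the
#' annotation schema, producing expanded labelled samples ready for
#' [make_splits()].
#'
#' @param sim A [simulate_dataset()] result.
#' @return A labelled sample tibble as from [expand_multi_ec()].
#' @export
simulated_samples <- function(sim) {
  records <- tibble::tibble(
    id = sim$sequences$id,
    residues = sim$sequences$residues,
    ec = lapply(sim$annotations$ec, function(x) {
      if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  )
  expand_multi_ec(records)
}
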